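#' Fit the weighted LASSO lifespan model
#'
#' Fits the model at the heart of the package: per-mutant percent lifespan
#' change regressed on genome-wide log2 expression fold-changes under an
#' L1 penalty, with per-strain reliability weights.  The objective is
#' \deqn{\mathrm{Cost}(\beta_0,\beta) = \sum_i w_i\bigl(y_i - \beta_0 -
#'   \textstyle\sum_j \beta_j x_{ij}\bigr)^2 + \alpha \sum_j |\beta_j|,}
#' with the intercept unpenalised, \eqn{w_i = n_i/(n_i + c)} the weight of a
#' strain assayed with \eqn{n_i} mother cells, and features on their native
#' log2-FC scale (no standardisation: the products \eqn{\beta_j x_{ij}} are
#' interpreted directly as per-gene lifespan contributions).  Before
#' fitting, the singular self-deletion entries are regularised by
#' [apply_self_handling()].  Genes with nonzero coefficients are the
#' model's master regulators, tagged positive or negative by coefficient
#' sign.
#'
#' The solver is cyclic coordinate descent with an active-set strategy,
#' iterated until the largest per-coordinate objective decrease in a sweep
#' falls below `tol` times the weighted null deviance (default 1e-9), or
#' `maxit` sweeps; non-convergence is recorded in the result and raised as
#' a warning.  The deviance-scaled criterion stays well behaved in the
#' overparameterised regime (more genes than mutants), where the minimiser
#' of the cost need not be unique although its value is.
#'
#' @param panel An `"mr_panel"` from [align_panel()].
#' @param alpha Penalty \eqn{\alpha \ge 0}.  A vector is allowed, in which
#'   case a decreasing path is fitted with warm starts and a list of fits is
#'   returned.
#' @param self_handling `"nonlinear"` (saturate every entry with
#'   \eqn{s\tanh(x/s)}), `"self0"` (zero each mutant's own deleted-gene
#'   entry), or `"none"`.
#' @param s Saturation scale for `"nonlinear"` (log2-FC units, default 2).
#' @param tol,maxit Convergence controls of the coordinate-descent solver.
#' @return An object of class `"mrlasso"` with components `beta0`, `beta`
#'   (named numeric over all genes), `alpha`, `selected_genes` (data frame:
#'   gene, coef, sign_class), `fitted`, `objective_value`, `converged`,
#'   `self_handling`, `s`, `weights`, and the training data needed by the
#'   methods.  Methods: [print()], [summary()], [coef()], [predict()],
#'   [fitted()], [residuals()], [plot()].
#' @examples
#' sim <- simulate_mutant_panel(sim_config(n_mutants = 60, n_genes = 120,
#'                                         n_mr = 5, seed = 3))
#' panel <- align_panel(sim)
#' fit <- mrlasso(panel, alpha = 50)
#' fit
#' head(coef(fit)[coef(fit) != 0])
#' @seealso [cv_mrlasso()] to choose `alpha`, [loo_validate()] for held-out
#'   validation, [assign_peripheral_genes()] for the downstream network.
#' @export
mrlasso <- function(panel, alpha, self_handling = c("nonlinear", "self0",
                                                    "none"),
                    s = 2, tol = 1e-9, maxit = 1e5) {
  self_handling <- match.arg(self_handling)
  stopifnot(inherits(panel, "mr_panel"))
  if (any(alpha < 0)) stop("'alpha' must be >= 0", call. = FALSE)
  Xt <- apply_self_handling(panel$X, self_handling, s = s,
                            deleted_gene_of = panel$deleted_gene_of)
  y <- panel$lifespan$pct_change
  w <- panel$weights

  zero_var <- apply(Xt, 2L, function(v) all(v == v[1L]))
  if (any(zero_var))
    warning(sum(zero_var), " zero-variance feature(s) dropped from the fit",
            call. = FALSE)
  keep <- which(!zero_var)

  path <- sort(as.numeric(alpha), decreasing = TRUE)
  res <- .cd_lasso_path(Xt[, keep, drop = FALSE], y, w, path,
                        tol, as.integer(maxit))

  make_fit <- function(k) {
    beta <- stats::setNames(numeric(ncol(Xt)), colnames(Xt))
    beta[keep] <- res$beta[, k]
    fitted <- drop(res$b0[k] + Xt %*% beta)
    names(fitted) <- rownames(Xt)
    sel <- which(beta != 0)
    if (!res$converged[k])
      warning("coordinate descent did not converge at alpha = ", path[k],
              " within ", maxit, " iterations", call. = FALSE)
    structure(list(
      beta0 = res$b0[k],
      beta = beta,
      alpha = path[k],
      selected_genes = data.frame(
        gene = names(beta)[sel],
        coef = unname(beta[sel]),
        sign_class = ifelse(beta[sel] > 0, "positive", "negative"),
        stringsAsFactors = FALSE, row.names = NULL),
      fitted = fitted,
      objective_value = sum(w * (y - fitted)^2) + path[k] * sum(abs(beta)),
      converged = res$converged[k],
      iterations = res$iter[k],
      self_handling = self_handling,
      s = s,
      weights = w,
      y = y,
      deleted_gene_of = panel$deleted_gene_of,
      call = match.call()), class = "mrlasso")
  }
  if (length(path) == 1L) make_fit(1L) else lapply(seq_along(path), make_fit)
}

#' Critical penalty above which the weighted LASSO support is empty
#'
#' Returns \eqn{\alpha_{\max} = 2\max_j |\sum_i w_i x_{ij} (y_i -
#' \bar y_w)|} with \eqn{\bar y_w} the weighted mean of the response; for
#' any \eqn{\alpha \ge \alpha_{\max}} the cost is minimised by the null
#' model (all coefficients zero, intercept at the weighted mean).
#'
#' @inheritParams mrlasso
#' @return A single number.
#' @export
alpha_max <- function(panel, self_handling = c("nonlinear", "self0", "none"),
                      s = 2) {
  self_handling <- match.arg(self_handling)
  stopifnot(inherits(panel, "mr_panel"))
  Xt <- apply_self_handling(panel$X, self_handling, s = s,
                            deleted_gene_of = panel$deleted_gene_of)
  y <- panel$lifespan$pct_change
  w <- panel$weights
  ybar <- sum(w * y) / sum(w)
  2 * max(abs(crossprod(Xt, w * (y - ybar))))
}

#' @export
print.mrlasso <- function(x, ...) {
  cat("Weighted LASSO lifespan model (self-handling:", x$self_handling,
      if (x$self_handling == "nonlinear") sprintf("s = %g", x$s) else "",
      ")\n")
  cat(sprintf("  alpha = %g; %d mutants; %d genes selected (%d positive, %d negative)\n",
              x$alpha, length(x$y), nrow(x$selected_genes),
              sum(x$selected_genes$sign_class == "positive"),
              sum(x$selected_genes$sign_class == "negative")))
  cat(sprintf("  intercept = %.4f; objective = %.4f%s\n", x$beta0,
              x$objective_value,
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' @export
summary.mrlasso <- function(object, ...) {
  w <- object$weights
  r <- object$y - object$fitted
  ybar <- sum(w * object$y) / sum(w)
  r2 <- 1 - sum(w * r^2) / sum(w * (object$y - ybar)^2)
  sel <- object$selected_genes[order(object$selected_genes$coef), ]
  structure(list(fit = object, weighted_r2 = r2,
                 selected = sel), class = "summary.mrlasso")
}

#' @export
print.summary.mrlasso <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  in-sample weighted R^2 = %.4f\n", x$weighted_r2))
  cat("  selected genes (most negative to most positive coefficient):\n")
  print(x$selected, row.names = FALSE)
  invisible(x)
}

#' @export
coef.mrlasso <- function(object, ...) {
  c("(Intercept)" = object$beta0, object$beta)
}

#' Predict lifespan change for new expression profiles
#'
#' Applies the fit's self-handling transform to `newdata` and returns
#' \eqn{\hat y = \beta_0 + \sum_j \beta_j \tilde x_{ij}}.
#'
#' @param object An `"mrlasso"` fit.
#' @param newdata Mutants x genes matrix, an `"mr_panel"`, or `NULL`
#'   (returns in-sample fitted values).  Must cover every gene in the fit's
#'   support.
#' @param deleted_gene_of Mutant-to-gene map for `"self0"` handling of a raw
#'   matrix (taken from the panel or matrix attribute when available).
#' @param ... Unused.
#' @return Named numeric vector of predicted percent lifespan changes.
#' @export
predict.mrlasso <- function(object, newdata = NULL, deleted_gene_of = NULL,
                            ...) {
  if (is.null(newdata)) return(object$fitted)
  if (inherits(newdata, "mr_panel")) {
    if (is.null(deleted_gene_of)) deleted_gene_of <- newdata$deleted_gene_of
    newdata <- newdata$X
  }
  stopifnot(is.matrix(newdata))
  if (is.null(deleted_gene_of))
    deleted_gene_of <- attr(newdata, "deleted_gene_of")
  support <- object$selected_genes$gene
  missing_genes <- setdiff(support, colnames(newdata))
  if (length(missing_genes))
    stop("newdata lacks gene(s) in the model support: ",
         paste(missing_genes, collapse = ", "), call. = FALSE)
  Xt <- apply_self_handling(newdata, object$self_handling, s = object$s,
                            deleted_gene_of = deleted_gene_of)
  beta <- stats::setNames(numeric(ncol(Xt)), colnames(Xt))
  beta[support] <- object$beta[support]
  out <- drop(object$beta0 + Xt %*% beta)
  names(out) <- rownames(Xt)
  out
}

#' @export
fitted.mrlasso <- function(object, ...) object$fitted

#' @export
residuals.mrlasso <- function(object, ...) object$y - object$fitted

#' Observed vs. predicted lifespan plot
#'
#' @param x An `"mrlasso"` fit.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.mrlasso <- function(x, ...) {
  graphics::plot(x$fitted, x$y, xlab = "predicted RLS change (%)",
                 ylab = "observed RLS change (%)",
                 cex = 0.4 + 0.8 * x$weights, ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
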