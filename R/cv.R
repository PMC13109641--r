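# Internal: fit the coordinate-descent path on pre-transformed features.
fit_path_raw <- function(Xt, y, w, path, tol = 1e-9, maxit = 1e5) {
  .cd_lasso_path(Xt, y, w, path, tol, as.integer(maxit))
}

#' Default penalty grid for cross-validation
#'
#' Log-spaced decreasing grid from the critical penalty [alpha_max()] (at
#' which the support is empty) down `decades` decades.
#'
#' @inheritParams mrlasso
#' @param n_alpha Number of grid points (default 50).
#' @param decades How far below the critical penalty to go (default 4).
#' @return Decreasing numeric vector.
#' @export
alpha_grid_default <- function(panel, self_handling = "nonlinear", s = 2,
                               n_alpha = 50, decades = 4) {
  amax <- alpha_max(panel, self_handling, s = s)
  exp(seq(log(amax), log(amax) - decades * log(10), length.out = n_alpha))
}

#' Choose the LASSO penalty by k-fold cross-validation
#'
#' Partitions the mutants into `k` seeded random folds, fits the penalty
#' path on each training set (warm-started from large to small alpha), and
#' scores each alpha by the weighted squared prediction error on the
#' held-out mutants, using the same reliability weights \eqn{w_i} as the
#' fitting cost.  The chosen alpha minimises the mean held-out error; ties
#' are broken toward the larger alpha (the sparser model).  The final model
#' is then refitted on the full panel at the chosen alpha.
#'
#' @inheritParams mrlasso
#' @param alpha_grid Penalty grid; defaults to [alpha_grid_default()].
#' @param k Number of folds (default 10).
#' @param seed Seed for the fold assignment.
#' @return An object of class `"cv_mrlasso"`: list with `alpha_grid`
#'   (decreasing), `cv_error` (mean held-out weighted squared error per
#'   grid point), `chosen_alpha`, `k`, `seed`, `fold_assignment` (named
#'   integer vector), and `fit`, the `"mrlasso"` refit at `chosen_alpha`.
#' @examples
#' sim <- simulate_mutant_panel(sim_config(n_mutants = 80, n_genes = 150,
#'                                         n_mr = 5, seed = 7))
#' cv <- cv_mrlasso(align_panel(sim), k = 5, seed = 7)
#' cv
#' @export
cv_mrlasso <- function(panel, alpha_grid = NULL, k = 10, seed = 1,
                       self_handling = c("nonlinear", "self0", "none"),
                       s = 2, tol = 1e-9, maxit = 1e5) {
  self_handling <- match.arg(self_handling)
  stopifnot(inherits(panel, "mr_panel"), k >= 2)
  if (is.null(alpha_grid))
    alpha_grid <- alpha_grid_default(panel, self_handling, s = s)
  path <- sort(as.numeric(alpha_grid), decreasing = TRUE)
  n <- nrow(panel$X)
  set.seed(seed)
  fold <- sample(rep_len(seq_len(k), n))
  names(fold) <- rownames(panel$X)
  if (min(table(fold)) < 2)
    stop("every fold needs at least 2 mutants; reduce k", call. = FALSE)

  Xt <- apply_self_handling(panel$X, self_handling, s = s,
                            deleted_gene_of = panel$deleted_gene_of)
  y <- panel$lifespan$pct_change
  w <- panel$weights

  err_w <- matrix(0, length(path), k)   # sum of w * (y - yhat)^2, held out
  sw <- numeric(k)
  for (f in seq_len(k)) {
    tr <- fold != f
    res <- fit_path_raw(Xt[tr, , drop = FALSE], y[tr], w[tr], path,
                        tol = tol, maxit = maxit)
    pred <- Xt[!tr, , drop = FALSE] %*% res$beta
    pred <- sweep(pred, 2L, res$b0, "+")
    err_w[, f] <- colSums(w[!tr] * (y[!tr] - pred)^2)
    sw[f] <- sum(w[!tr])
  }
  cv_error <- rowSums(err_w) / sum(sw)
  best <- which.min(cv_error)          # first index = largest alpha on ties
  structure(list(alpha_grid = path, cv_error = cv_error,
                 chosen_alpha = path[best], k = k, seed = seed,
                 fold_assignment = fold,
                 fit = mrlasso(panel, alpha = path[best],
                               self_handling = self_handling, s = s,
                               tol = tol, maxit = maxit)),
            class = "cv_mrlasso")
}

#' @export
print.cv_mrlasso <- function(x, ...) {
  cat(sprintf("%d-fold CV over %d penalties (seed %s)\n", x$k,
              length(x$alpha_grid), format(x$seed)))
  cat(sprintf("  chosen alpha = %g (held-out weighted MSE %.4f)\n",
              x$chosen_alpha, min(x$cv_error)))
  print(x$fit)
  invisible(x)
}

#' @export
plot.cv_mrlasso <- function(x, ...) {
  graphics::plot(log10(x$alpha_grid), x$cv_error, type = "b", pch = 16,
                 cex = 0.6, xlab = "log10(alpha)",
                 ylab = "held-out weighted MSE", ...)
  graphics::abline(v = log10(x$chosen_alpha), lty = 2)
  invisible(x)
}

#' Keep-one-out validation of the lifespan model
#'
#' For each mutant in turn, refits the model at a fixed penalty on all other
#' mutants and predicts the held-out one, yielding a per-mutant prediction
#' that never saw the mutant's own lifespan.
#'
#' @inheritParams mrlasso
#' @param alpha Fixed penalty (typically the CV choice).
#' @return Data frame with columns `strain`, `observed`, `predicted`.
#' @export
loo_validate <- function(panel, alpha,
                         self_handling = c("nonlinear", "self0", "none"),
                         s = 2, tol = 1e-9, maxit = 1e5) {
  self_handling <- match.arg(self_handling)
  stopifnot(inherits(panel, "mr_panel"), length(alpha) == 1L, alpha >= 0)
  n <- nrow(panel$X)
  if (n < 3) stop("keep-one-out validation needs at least 3 mutants",
                  call. = FALSE)
  Xt <- apply_self_handling(panel$X, self_handling, s = s,
                            deleted_gene_of = panel$deleted_gene_of)
  y <- panel$lifespan$pct_change
  w <- panel$weights
  pred <- numeric(n)
  for (i in seq_len(n)) {
    res <- fit_path_raw(Xt[-i, , drop = FALSE], y[-i], w[-i], alpha,
                        tol = tol, maxit = maxit)
    pred[i] <- res$b0[1L] + sum(Xt[i, ] * res$beta[, 1L])
  }
  data.frame(strain = rownames(panel$X), observed = y, predicted = pred,
             stringsAsFactors = FALSE)
}

#' Sensitivity of gene selection to the weighting constant
#'
#' Refits the model with reliability weights \eqn{w_i = n_i/(n_i + c)} for
#' each candidate constant `c` (penalty re-chosen by CV per constant) and
#' reports the pairwise Jaccard overlap of the selected gene sets.  A
#' mostly-overlapping family of sets indicates that the identified master
#' regulators are robust to the weighting choice.
#'
#' @inheritParams cv_mrlasso
#' @param c_values Candidate weighting constants (default 30, 50, 80).
#' @return An object of class `"mr_weight_sens"`: list with `c_values`,
#'   `sets` (selected gene sets per constant), `chosen_alpha` per constant,
#'   and `jaccard` (pairwise overlap matrix).
#' @export
weight_sensitivity <- function(panel, c_values = c(30, 50, 80),
                               alpha_grid = NULL, k = 10, seed = 1,
                               self_handling = c("nonlinear", "self0",
                                                 "none"), s = 2) {
  self_handling <- match.arg(self_handling)
  stopifnot(inherits(panel, "mr_panel"), length(c_values) >= 1)
  sets <- list(); alphas <- numeric(0)
  for (cc in c_values) {
    p2 <- panel
    p2$c <- cc
    p2$weights <- rls_weights(panel$lifespan$n_cells, c = cc)
    cv <- cv_mrlasso(p2, alpha_grid = alpha_grid, k = k, seed = seed,
                     self_handling = self_handling, s = s)
    sets[[as.character(cc)]] <- cv$fit$selected_genes$gene
    alphas[as.character(cc)] <- cv$chosen_alpha
  }
  m <- length(sets)
  jac <- matrix(1, m, m, dimnames = list(names(sets), names(sets)))
  if (m > 1) {
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      u <- length(union(sets[[i]], sets[[j]]))
      jac[i, j] <- jac[j, i] <-
        if (u == 0) 1 else length(intersect(sets[[i]], sets[[j]])) / u
    }
  }
  structure(list(c_values = c_values, sets = sets, chosen_alpha = alphas,
                 jaccard = jac), class = "mr_weight_sens")
}

#' @export
print.mr_weight_sens <- function(x, ...) {
  cat("Weighting-constant sensitivity (c =",
      paste(x$c_values, collapse = ", "), ")\n")
  cat("  selected-set sizes:", paste(lengths(x$sets), collapse = ", "), "\n")
  cat("  pairwise Jaccard overlap:\n")
  print(round(x$jaccard, 3))
  invisible(x)
}
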