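#' Select long-lived mutants
#'
#' Long-lived mutants are those with replicative lifespan extended by at
#' least `min_extension` percent (inclusive) at `p_value < max_p` (strict),
#' optionally restricted to strains with expression profiling data.
#'
#' @param lifespan Lifespan data frame (see [read_lifespan()]).
#' @param min_extension Minimum percent extension (default 15).
#' @param max_p P-value ceiling (default 0.05); rows with missing p-values
#'   are ineligible.
#' @param expression Optional mutants x genes matrix (or `"mr_panel"`);
#'   when supplied, only strains present in it qualify.
#' @return Character vector of strain identifiers; empty with a warning if
#'   nothing qualifies.
#' @export
select_long_lived <- function(lifespan, min_extension = 15, max_p = 0.05,
                              expression = NULL) {
  stopifnot(min_extension > 0, max_p > 0, max_p <= 1)
  ok <- lifespan$pct_change >= min_extension &
    !is.na(lifespan$p_value) & lifespan$p_value < max_p
  sel <- lifespan$strain[ok]
  if (!is.null(expression)) {
    if (inherits(expression, "mr_panel")) expression <- expression$X
    sel <- sel[sel %in% rownames(expression)]
  }
  if (!length(sel))
    warning("no mutants satisfy the long-lived criteria", call. = FALSE)
  sel
}

#' Per-gene responsiveness statistics across a set of mutants
#'
#' For each gene j over a chosen set of N mutants (typically the long-lived
#' ones), computes
#' \deqn{a_j = \frac{1}{N}\sum_i |x_{ij}|, \qquad
#'       b_j = \frac{1}{N}\bigl|\sum_i x_{ij}\bigr|, \qquad r_j = b_j/a_j.}
#' `a` measures the average magnitude of the expression response, `b` how
#' consistently the changes point in one direction (for random signs `b`
#' shrinks like a random walk, `b ~ a/sqrt(N)`), and the ratio `r` in
#' \[0, 1\] is a scale-free directional-consistency index (`r = 1` iff every
#' nonzero change shares one sign).  Missing entries are excluded from both
#' sums, with the per-gene effective N recorded; genes with `a = 0` get
#' `r = NA`.
#'
#' @param X Mutants x genes matrix of log2 fold-changes.
#' @param mutants Row identifiers of the mutants to use.
#' @return Data frame with columns `gene`, `a`, `b`, `r`, `n_used`.
#' @export
responsiveness <- function(X, mutants = rownames(X)) {
  if (inherits(X, "mr_panel")) X <- X$X
  missing_m <- setdiff(mutants, rownames(X))
  if (length(missing_m))
    stop("mutant(s) not in the expression matrix: ",
         paste(utils::head(missing_m, 5), collapse = ", "), call. = FALSE)
  if (!length(mutants)) stop("need at least one mutant", call. = FALSE)
  M <- X[mutants, , drop = FALSE]
  n_used <- colSums(!is.na(M))
  a <- colSums(abs(M), na.rm = TRUE) / n_used
  b <- abs(colSums(M, na.rm = TRUE)) / n_used
  r <- ifelse(a > 0, b / a, NA_real_)
  a[n_used == 0] <- NA_real_
  b[n_used == 0] <- NA_real_
  data.frame(gene = colnames(X), a = unname(a), b = unname(b),
             r = unname(r), n_used = unname(n_used),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Compare responsiveness of master regulators against background genes
#'
#' Two-sample Kolmogorov-Smirnov tests of the distributions of the
#' responsiveness statistics (`a`, `b`, and `r`) for the master-regulator
#' genes versus all other genes.  D is the supremum distance between the
#' empirical CDFs; the reported `direction` is `+1` when the MR median
#' exceeds the background median (the expected right shift), `-1` otherwise
#' -- it describes, and does not enforce, the direction.  P-values use the
#' asymptotic two-sided KS distribution, adequate for the group sizes
#' involved (hundreds of background genes).
#'
#' @param resp Result of [responsiveness()].
#' @param mr_genes Character vector of master-regulator gene identifiers
#'   (e.g. `fit$selected_genes$gene`).
#' @return Data frame with one row per statistic: `statistic`, `D`, `p`,
#'   `direction`, `n_mr`, `n_background`.
#' @export
compare_mr_background <- function(resp, mr_genes) {
  stopifnot(is.data.frame(resp), length(mr_genes) >= 1)
  is_mr <- resp$gene %in% mr_genes
  if (!any(is_mr)) stop("none of 'mr_genes' appear in 'resp'", call. = FALSE)
  if (all(is_mr)) stop("background gene set is empty", call. = FALSE)
  one <- function(stat) {
    v <- resp[[stat]]
    x <- v[is_mr & !is.na(v)]
    y <- v[!is_mr & !is.na(v)]
    if (length(x) < 2 || length(y) < 2)
      stop("fewer than 2 usable values for statistic '", stat, "'",
           call. = FALSE)
    ks <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
    data.frame(statistic = stat, D = unname(ks$statistic),
               p = ks$p.value,
               direction = if (stats::median(x) >= stats::median(y)) 1 else -1,
               n_mr = length(x), n_background = length(y),
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(c("a", "b", "r"), one))
  rownames(out) <- NULL
  out
}
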