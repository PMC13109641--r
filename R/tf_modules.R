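# Coerce a differential-expression profile to a named effect vector.
# Accepts a named numeric vector or a data frame with columns gene and
# effect (or log2fc).
as_effect_vector <- function(profile) {
  if (is.numeric(profile) && !is.null(names(profile))) return(profile)
  if (is.data.frame(profile)) {
    eff_col <- intersect(c("effect", "log2fc"), colnames(profile))[1L]
    if (!is.na(eff_col) && "gene" %in% colnames(profile))
      return(stats::setNames(profile[[eff_col]],
                             as.character(profile$gene)))
  }
  stop("a profile must be a named numeric vector or a data frame with ",
       "columns 'gene' and 'effect'/'log2fc'", call. = FALSE)
}

#' Rank-sum z-score of a TF target module on a DE profile
#'
#' Scores how strongly a transcription factor's target genes are
#' collectively shifted in a differential-expression ranking relative to
#' all other profiled genes.  All genes are ranked by effect (average ranks
#' on ties), the Mann-Whitney U statistic of targets versus background is
#' formed, and the score is the normal-approximation z
#' \deqn{z = (U - \mu_U)/\sigma_U, \quad \mu_U = n_1 n_2 / 2,}
#' with the standard tie-corrected \eqn{\sigma_U}.  Positive z means the
#' targets sit higher in the ranking than the background (collective
#' up-regulation); negating all effects negates z.  The score depends on
#' the effects only through their ranks, so it is invariant under any
#' strictly monotone transform.
#'
#' @param profile Named numeric vector of per-gene effects (log2
#'   fold-changes), or a data frame with columns `gene` and
#'   `effect`/`log2fc`.
#' @param targets Character vector of target-gene identifiers; only those
#'   present in the profile are used.
#' @return A one-row data frame: `z`, `p` (two-sided normal), `U`,
#'   `n_targets_used`, `n_background`, `direction` (`"up"`/`"down"`).
#' @examples
#' eff <- c(a = 3, b = 2.5, c = 2, d = 0, e = -1, f = 0.2, g = -0.4)
#' module_zscore(eff, c("a", "b", "c"))
#' @export
module_zscore <- function(profile, targets) {
  eff <- as_effect_vector(profile)
  in_mod <- names(eff) %in% targets
  n1 <- sum(in_mod); n2 <- sum(!in_mod)
  if (n1 < 1 || n2 < 1)
    stop("need at least one target and one background gene in the profile",
         call. = FALSE)
  rk <- rank(eff)
  U <- sum(rk[in_mod]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  N <- n1 + n2
  ties <- table(eff)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
  if (sigma2 <= 0) {
    warning("all effects identical; z set to 0", call. = FALSE)
    z <- 0
  } else {
    z <- (U - mu) / sqrt(sigma2)
  }
  data.frame(z = z, p = 2 * stats::pnorm(-abs(z)), U = U,
             n_targets_used = n1, n_background = n2,
             direction = if (z >= 0) "up" else "down",
             stringsAsFactors = FALSE)
}

#' Score every TF module on every DE profile
#'
#' @param profiles Named list of profiles (see [module_zscore()]), one per
#'   condition.
#' @param collection Named list of target-gene sets (e.g. from
#'   [read_gmt()]).
#' @return Numeric matrix of z-scores, modules x conditions; `NA` where a
#'   module has no gene in a profile.
#' @export
score_all <- function(profiles, collection) {
  stopifnot(length(profiles) >= 1, length(collection) >= 1)
  if (is.null(names(profiles)))
    names(profiles) <- paste0("condition", seq_along(profiles))
  out <- matrix(NA_real_, length(collection), length(profiles),
                dimnames = list(names(collection), names(profiles)))
  for (j in seq_along(profiles)) {
    eff <- as_effect_vector(profiles[[j]])
    for (i in seq_along(collection)) {
      n1 <- sum(names(eff) %in% collection[[i]])
      if (n1 >= 1 && n1 < length(eff))
        out[i, j] <- module_zscore(eff, collection[[i]])$z
    }
  }
  out
}

#' Modules significantly changed in each condition
#'
#' @param scores Module x condition z-score matrix from [score_all()].
#' @param threshold Absolute z cut-off; modules with `|z| > threshold`
#'   (strict) qualify.  Default 2.5.
#' @return Named list (per condition) of module names.
#' @export
significant_modules <- function(scores, threshold = 2.5) {
  stopifnot(is.matrix(scores))
  if (ncol(scores) == 0)
    return(stats::setNames(list(), character(0)))
  if (nrow(scores) == 0)
    return(stats::setNames(rep(list(character(0)), ncol(scores)),
                           colnames(scores)))
  apply(scores, 2L, function(z)
    rownames(scores)[!is.na(z) & abs(z) > threshold], simplify = FALSE)
}

#' Merge condition-specific variants of the same TF module
#'
#' ChIP-derived collections often carry several modules for one factor,
#' one per profiling condition, named like `"MSN2_cond1"`.  Rows whose
#' names share the base TF name (the part before the first `sep`) are
#' replaced by their per-condition mean z-score.
#'
#' @param scores Module x condition z-score matrix.
#' @param sep Separator between TF name and condition suffix (default
#'   `"_"`).
#' @return Merged matrix with base TF names as row names.
#' @export
merge_same_name <- function(scores, sep = "_") {
  base <- sub(paste0(sep, ".*$"), "", rownames(scores))
  groups <- split(seq_len(nrow(scores)), base)
  out <- t(vapply(groups, function(idx)
    colMeans(scores[idx, , drop = FALSE], na.rm = TRUE),
    numeric(ncol(scores))))
  out[is.nan(out)] <- NA_real_
  colnames(out) <- colnames(scores)
  out[unique(base), , drop = FALSE]
}

#' Average module scores over named timecourse conditions
#'
#' Collapses several timepoint columns (e.g. an over-expression timecourse)
#' into one per-module mean score; missing values are excluded with the
#' effective number of timepoints recorded.
#'
#' @param scores Module x condition z-score matrix.
#' @param conditions Column names to average.
#' @param name Name of the new column (default the conditions joined by
#'   `"+"`).
#' @return A one-column matrix of means with attribute `"n_used"`.
#' @export
timecourse_mean <- function(scores, conditions, name = NULL) {
  missing_cols <- setdiff(conditions, colnames(scores))
  if (length(missing_cols))
    stop("condition column(s) not found: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  sub <- scores[, conditions, drop = FALSE]
  m <- rowMeans(sub, na.rm = TRUE)
  m[is.nan(m)] <- NA_real_
  out <- matrix(m, ncol = 1,
                dimnames = list(rownames(scores),
                                name %||% paste(conditions,
                                                collapse = "+")))
  attr(out, "n_used") <- rowSums(!is.na(sub))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Filter differentially expressed genes
#'
#' Selects up-regulated genes with fold-change strictly above `fc_up` and
#' down-regulated genes with fold-change strictly below `fc_down`, both at
#' `p < max_p` (strict).  Thresholds are on the ratio scale (the defaults
#' 1.5 and 0.7 are deliberately asymmetric in log space); a profile stored
#' as log2 fold-changes is converted via `2^effect`.
#'
#' @param profile Data frame with columns `gene`, `effect` or `log2fc`,
#'   and `p_value` (or `fc` for ratio-scale fold changes).
#' @param fc_up,fc_down Ratio-scale thresholds (defaults 1.5 and 0.7).
#' @param max_p P-value ceiling (default 0.05).
#' @return List with character vectors `up` and `down` (always disjoint).
#' @export
deg_filter <- function(profile, fc_up = 1.5, fc_down = 0.7, max_p = 0.05) {
  stopifnot(is.data.frame(profile), fc_down < 1, fc_up > 1,
            max_p > 0, max_p <= 1)
  if (!"p_value" %in% colnames(profile))
    stop("deg_filter requires a 'p_value' column", call. = FALSE)
  fc <- if ("fc" %in% colnames(profile)) profile$fc
        else 2^as_effect_vector(profile)[as.character(profile$gene)]
  p <- profile$p_value
  ok <- !is.na(fc) & !is.na(p) & p < max_p
  list(up = as.character(profile$gene[ok & fc > fc_up]),
       down = as.character(profile$gene[ok & fc < fc_down]))
}

#' Rank test of ribosomal-gene expression in longevity mutants
#'
#' Tests whether ribosomal genes are collectively shifted relative to all
#' other genes across a set of long-lived mutants.  The overall test takes
#' each gene's mean effect across the mutant set and computes the rank-sum
#' z of ribosomal versus control genes on those means; the per-mutant tests
#' compute the same z within each mutant's own profile.
#'
#' @param X Mutants x genes matrix of log2 fold-changes (or `"mr_panel"`).
#' @param ribosome_genes Character vector of ribosomal-gene identifiers.
#' @param mutants Mutants to use (default all rows).
#' @return List with `overall` (one-row data frame from [module_zscore()])
#'   and `per_mutant` (data frame: `mutant`, `z`, `p`).
#' @export
ribosome_rank_test <- function(X, ribosome_genes, mutants = NULL) {
  if (inherits(X, "mr_panel")) X <- X$X
  if (is.null(mutants)) mutants <- rownames(X)
  M <- X[mutants, , drop = FALSE]
  if (!any(colnames(M) %in% ribosome_genes))
    stop("no ribosomal genes present in the expression matrix",
         call. = FALSE)
  mean_eff <- colMeans(M, na.rm = TRUE)
  overall <- module_zscore(mean_eff, ribosome_genes)
  per <- lapply(mutants, function(m) {
    sc <- module_zscore(M[m, ], ribosome_genes)
    data.frame(mutant = m, z = sc$z, p = sc$p, stringsAsFactors = FALSE)
  })
  list(overall = overall, per_mutant = do.call(rbind, per))
}

#' Differential-expression profile from FPKM replicate tables
#'
#' The effect is the log2 ratio of pseudo-counted mean FPKM,
#' \eqn{\log_2((\bar F_{case} + 1)/(\bar F_{ctrl} + 1))}; the p-value is a
#' two-sided Welch t-test on `log2(FPKM + 1)` across replicates (marked
#' missing when either group has a single replicate).  Genes with zero
#' FPKM in every sample are dropped.
#'
#' @param fpkm_case,fpkm_control Genes x replicates numeric matrices with
#'   shared row names.
#' @return Data frame with columns `gene`, `effect` (log2 ratio),
#'   `p_value`.
#' @export
compute_de_profile <- function(fpkm_case, fpkm_control) {
  stopifnot(is.matrix(fpkm_case), is.matrix(fpkm_control))
  genes <- intersect(rownames(fpkm_case), rownames(fpkm_control))
  if (!length(genes)) stop("no shared genes", call. = FALSE)
  A <- fpkm_case[genes, , drop = FALSE]
  B <- fpkm_control[genes, , drop = FALSE]
  keep <- rowSums(A) + rowSums(B) > 0
  A <- A[keep, , drop = FALSE]; B <- B[keep, , drop = FALSE]
  effect <- log2((rowMeans(A) + 1) / (rowMeans(B) + 1))
  na <- ncol(A); nb <- ncol(B)
  p <- rep(NA_real_, nrow(A))
  if (na >= 2 && nb >= 2) {
    la <- log2(A + 1); lb <- log2(B + 1)
    ma <- rowMeans(la); mb <- rowMeans(lb)
    va <- apply(la, 1L, stats::var); vb <- apply(lb, 1L, stats::var)
    se2 <- va / na + vb / nb
    tstat <- (ma - mb) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    p <- 2 * stats::pt(-abs(tstat), df)
    p[se2 == 0] <- ifelse(ma[se2 == 0] == mb[se2 == 0], 1, 0)
  }
  data.frame(gene = rownames(A), effect = unname(effect),
             p_value = unname(p), stringsAsFactors = FALSE, row.names = NULL)
}

#' Display ordering of a module score matrix by hierarchical clustering
#'
#' Agglomerative clustering (average linkage, correlation distance
#' `1 - cor`) of rows and, when possible, columns; purely cosmetic ordering
#' for heatmap display -- no downstream computation depends on it.
#' Correlations undefined because of constant rows are replaced by the
#' maximal distance 2.
#'
#' @param scores Module x condition numeric matrix with >= 2 rows.
#' @return List with integer vectors `row_order` and `col_order`.
#' @export
cluster_order <- function(scores) {
  stopifnot(is.matrix(scores), nrow(scores) >= 2)
  dist_cor <- function(M) {
    cc <- suppressWarnings(stats::cor(t(M), use = "pairwise.complete.obs"))
    cc[!is.finite(cc)] <- -1
    stats::as.dist(1 - cc)
  }
  ord <- function(M) {
    if (nrow(M) < 2) return(seq_len(nrow(M)))
    stats::hclust(dist_cor(M), method = "average")$order
  }
  M <- scores
  M[is.na(M)] <- 0
  list(row_order = ord(M),
       col_order = if (ncol(M) >= 2) ord(t(M)) else seq_len(ncol(M)))
}
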