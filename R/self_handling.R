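#' Regularise the self-deletion entry of a mutant expression panel
#'
#' In a deletion-mutant expression panel the log2 fold-change of the deleted
#' gene in its own mutant is singular: the transcript is essentially absent,
#' so even with pseudo-counts the entry is a large negative number (around -8
#' log2 units) that would dominate a linear lifespan model.  Two strategies
#' limit this self-contribution:
#'
#' * `"self0"` sets the entry at (mutant, its deleted gene) to exactly 0 and
#'   leaves everything else untouched.  This requires the mutant-to-gene
#'   mapping.
#' * `"nonlinear"` replaces every entry x by the saturating odd function
#'   \eqn{g(x) = s\,\tanh(x/s)}, which is the identity near 0 (g'(0) = 1) and
#'   bounded by \eqn{\pm s}, so moderate fold-changes are preserved while the
#'   self-entry is clipped to about \eqn{-s}.
#' * `"none"` returns the matrix unchanged (useful for diagnostics).
#'
#' @param X Numeric matrix, mutants in rows, genes in columns, log2
#'   fold-changes vs. wild type.
#' @param strategy One of `"self0"`, `"nonlinear"`, `"none"`.
#' @param s Saturation scale in log2-FC units for `"nonlinear"` (default 2).
#' @param deleted_gene_of Named character vector mapping mutant (row) names
#'   to the deleted gene (column) name; required for `"self0"`.  Mutants
#'   absent from the mapping (non-deletion perturbations) are left as-is.
#' @return The transformed matrix, same dimensions and dimnames.
#' @examples
#' X <- matrix(c(-8, 0.3, 0.1, -8), 2, 2,
#'             dimnames = list(c("g1-del", "g2-del"), c("g1", "g2")))
#' apply_self_handling(X, "self0",
#'                     deleted_gene_of = c("g1-del" = "g1", "g2-del" = "g2"))
#' apply_self_handling(X, "nonlinear", s = 2)
#' @export
apply_self_handling <- function(X, strategy = c("nonlinear", "self0", "none"),
                                s = 2, deleted_gene_of = NULL) {
  strategy <- match.arg(strategy)
  stopifnot(is.matrix(X), is.numeric(X))
  switch(strategy,
    none = X,
    nonlinear = {
      if (!is.numeric(s) || length(s) != 1L || !is.finite(s) || s <= 0)
        stop("'s' must be a single positive number", call. = FALSE)
      out <- s * tanh(X / s)
      dimnames(out) <- dimnames(X)
      out
    },
    self0 = {
      if (is.null(deleted_gene_of))
        stop("strategy 'self0' requires 'deleted_gene_of'", call. = FALSE)
      if (is.null(rownames(X)) || is.null(colnames(X)))
        stop("'X' must have row and column names for 'self0'", call. = FALSE)
      out <- X
      m <- intersect(names(deleted_gene_of), rownames(X))
      for (mut in m) {
        g <- deleted_gene_of[[mut]]
        if (!is.na(g) && g %in% colnames(X)) out[mut, g] <- 0
      }
      out
    })
}
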