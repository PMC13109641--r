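#' Reliability weights from mother-cell counts
#'
#' Replicative-lifespan estimates for different deletion strains rest on very
#' different numbers of microdissected mother cells (from 5 to well over a
#' thousand), so their reliabilities differ widely.  The weight
#' \deqn{w_i = n_i / (n_i + c)}
#' down-weights strains assayed with few cells (for the default \code{c = 50},
#' a 5-cell strain gets weight 1/11) and approaches 1 for strains with
#' hundreds of cells.
#'
#' @param n_cells Integer vector of mother-cell counts, all \eqn{\ge} 1.
#' @param c Positive stabilising constant, in cells.  Default 50; values 30
#'   and 80 are used for sensitivity analysis (see
#'   [weight_sensitivity()]).
#' @return Numeric vector of weights in (0, 1), one per strain.
#' @examples
#' rls_weights(c(5, 50, 1837))
#' @seealso [align_panel()], which attaches these weights to a panel.
#' @export
rls_weights <- function(n_cells, c = 50) {
  if (!is.numeric(c) || length(c) != 1L || !is.finite(c) || c <= 0)
    stop("'c' must be a single positive number", call. = FALSE)
  n_cells <- as.numeric(n_cells)
  if (any(!is.finite(n_cells)) || any(n_cells < 1))
    stop("all cell counts must be finite and >= 1", call. = FALSE)
  n_cells / (n_cells + c)
}
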