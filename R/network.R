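#' Relative discrepancy between observed and predicted lifespan
#'
#' \deqn{d = \frac{|L_1 - L_2|}{|L_1| + |L_2|}} with \eqn{L_1} the observed
#' and \eqn{L_2} the predicted percent lifespan change.  `d` lies in
#' \[0, 1\], is symmetric, scale-invariant, 0 for perfect agreement and 1
#' for predictions of opposite sign; the degenerate case
#' \eqn{L_1 = L_2 = 0} is defined as 0 (perfect agreement).
#'
#' @param L1,L2 Numeric vectors (recycled).
#' @return Numeric vector of discrepancies.
#' @examples
#' prediction_discrepancy(20, 10)   # 1/3
#' prediction_discrepancy(10, -10)  # 1
#' @export
prediction_discrepancy <- function(L1, L2) {
  den <- abs(L1) + abs(L2)
  ifelse(den > 0, abs(L1 - L2) / den, 0)
}

#' Assign peripheral genes
#'
#' A peripheral gene is the deleted gene of a long-lived mutant whose
#' lifespan change is well predicted by the master-regulator model and
#' which is not itself a selected master regulator.  Concretely, a mutant
#' qualifies when (i) it satisfies the long-lived criteria (extension >=
#' `min_extension`%, p < `max_p`, expression data present), (ii) its
#' prediction discrepancy [prediction_discrepancy()] is strictly below
#' `accuracy_threshold`, and (iii) its deleted gene is not in the fit's
#' selected set.
#'
#' @param panel The `"mr_panel"` the fit was trained on (or one covering
#'   the long-lived mutants).
#' @param fit An `"mrlasso"` fit.
#' @param min_extension,max_p Long-lived criteria (defaults 15, 0.05).
#' @param accuracy_threshold Strict upper bound on the discrepancy `d`
#'   (default 0.5; 0.3 is more stringent, 0.7 less).
#' @return Data frame with columns `mutant`, `gene` (the deleted gene),
#'   `observed`, `predicted`, `d`.  Possibly zero rows.
#' @export
assign_peripheral_genes <- function(panel, fit, min_extension = 15,
                                    max_p = 0.05,
                                    accuracy_threshold = 0.5) {
  stopifnot(inherits(panel, "mr_panel"), inherits(fit, "mrlasso"),
            accuracy_threshold > 0, accuracy_threshold < 1)
  ll <- suppressWarnings(
    select_long_lived(panel$lifespan, min_extension, max_p, panel$X))
  if (!length(ll))
    return(data.frame(mutant = character(0), gene = character(0),
                      observed = numeric(0), predicted = numeric(0),
                      d = numeric(0), stringsAsFactors = FALSE))
  obs <- panel$lifespan$pct_change[match(ll, panel$lifespan$strain)]
  pred <- predict(fit, panel)[ll]
  d <- prediction_discrepancy(obs, pred)
  gene <- rep(NA_character_, length(ll))
  hit <- ll %in% names(panel$deleted_gene_of)
  gene[hit] <- unname(panel$deleted_gene_of[ll[hit]])
  keep <- d < accuracy_threshold &
    !(gene %in% fit$selected_genes$gene) & !is.na(gene)
  out <- data.frame(mutant = ll, gene = gene, observed = obs,
                    predicted = unname(pred), d = d,
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the peripheral-gene to master-regulator contribution network
#'
#' For each peripheral-gene mutant i, the contribution of master regulator
#' j to its predicted lifespan change is \eqn{\tilde x_{ij} \beta_j}
#' (computed on the same self-handled features used in fitting).  The MRs
#' are ranked by contribution and the top `top_k` are linked to the
#' peripheral gene.  Ranking is by signed contribution descending by
#' default (largest positive contribution to lifespan extension first);
#' `rank_by = "abs"` ranks by absolute contribution instead.  Ties are
#' broken deterministically by gene name (ascending).
#'
#' @param panel The `"mr_panel"` providing expression profiles.
#' @param fit An `"mrlasso"` fit.
#' @param pg Data frame from [assign_peripheral_genes()].
#' @param top_k Number of MRs to link per peripheral gene (default 10);
#'   if fewer MRs are available, all are kept with a warning.
#' @param rank_by `"signed"` (default) or `"abs"`.
#' @return Data frame of edges: `pg_mutant`, `pg_gene`, `mr_gene`,
#'   `contribution` (percent-lifespan units), `rank`, `mr_sign`.
#' @export
build_pg_mr_network <- function(panel, fit, pg, top_k = 10,
                                rank_by = c("signed", "abs")) {
  rank_by <- match.arg(rank_by)
  stopifnot(inherits(panel, "mr_panel"), inherits(fit, "mrlasso"),
            top_k >= 1)
  mrs <- fit$selected_genes
  if (!nrow(mrs)) stop("the fit selected no genes", call. = FALSE)
  if (!nrow(pg))
    return(data.frame(pg_mutant = character(0), pg_gene = character(0),
                      mr_gene = character(0), contribution = numeric(0),
                      rank = integer(0), mr_sign = character(0),
                      stringsAsFactors = FALSE))
  if (nrow(mrs) < top_k)
    warning("only ", nrow(mrs), " master regulators available; top_k ",
            "reduced accordingly", call. = FALSE)
  Xt <- apply_self_handling(panel$X[pg$mutant, , drop = FALSE],
                            fit$self_handling, s = fit$s,
                            deleted_gene_of = panel$deleted_gene_of)
  contrib <- sweep(Xt[, mrs$gene, drop = FALSE], 2L, mrs$coef, "*")
  edges <- lapply(seq_len(nrow(pg)), function(i) {
    v <- contrib[i, ]
    key <- if (rank_by == "abs") abs(v) else v
    ord <- order(-key, names(v))
    keep <- ord[seq_len(min(top_k, length(ord)))]
    data.frame(pg_mutant = pg$mutant[i], pg_gene = pg$gene[i],
               mr_gene = names(v)[keep], contribution = unname(v[keep]),
               rank = seq_along(keep),
               mr_sign = mrs$sign_class[match(names(v)[keep], mrs$gene)],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, edges)
  rownames(out) <- NULL
  out
}

#' Summarise sign coherence of each peripheral gene's MR links
#'
#' Partitions each peripheral gene's edges by the sign class of the linked
#' master regulator and flags peripheral genes linked to both positive and
#' negative MRs.
#'
#' @param edges Edge data frame from [build_pg_mr_network()].
#' @return Data frame: `pg_mutant`, `n_positive`, `n_negative`,
#'   `mixed_signs`.
#' @export
coherence_summary <- function(edges) {
  if (!nrow(edges))
    return(data.frame(pg_mutant = character(0), n_positive = integer(0),
                      n_negative = integer(0), mixed_signs = logical(0),
                      stringsAsFactors = FALSE))
  sp <- split(edges$mr_sign, edges$pg_mutant)
  out <- data.frame(pg_mutant = names(sp),
                    n_positive = vapply(sp, function(s)
                      sum(s == "positive"), integer(1)),
                    n_negative = vapply(sp, function(s)
                      sum(s == "negative"), integer(1)),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$mixed_signs <- out$n_positive > 0 & out$n_negative > 0
  out
}

#' Stringency sensitivity of the peripheral-gene network
#'
#' Recomputes the peripheral-gene assignment and the PG-MR edge list over a
#' grid of accuracy thresholds and top-k values, so the stability of the
#' core network under parameter choices can be examined.  Peripheral-gene
#' sets are nested in the threshold (a stricter threshold selects a subset)
#' and edge lists are nested in k (top-5 is a prefix of top-10); the
#' returned object reports any violation (none are expected).
#'
#' @inheritParams build_pg_mr_network
#' @param thresholds Accuracy thresholds (default 0.3, 0.5, 0.7).
#' @param ks Top-k values (default 5, 10, 20).
#' @param min_extension,max_p Long-lived criteria.
#' @return An object of class `"mr_net_sens"`: list with `pg_sets` (per
#'   threshold), `edges` (per threshold x k, named `"<thr>/<k>"`),
#'   `core_pg` (intersection of PG sets over all thresholds), and
#'   `nesting_ok` (logical).
#' @export
threshold_sensitivity <- function(panel, fit, thresholds = c(0.3, 0.5, 0.7),
                                  ks = c(5, 10, 20), min_extension = 15,
                                  max_p = 0.05,
                                  rank_by = c("signed", "abs")) {
  rank_by <- match.arg(rank_by)
  stopifnot(length(thresholds) >= 1, length(ks) >= 1)
  thresholds <- sort(thresholds)
  ks <- sort(ks)
  pg_sets <- list(); edges <- list()
  for (th in thresholds) {
    pg <- assign_peripheral_genes(panel, fit, min_extension, max_p, th)
    pg_sets[[as.character(th)]] <- pg$mutant
    for (k in ks)
      edges[[paste0(th, "/", k)]] <-
        suppressWarnings(build_pg_mr_network(panel, fit, pg, top_k = k,
                                             rank_by = rank_by))
  }
  nest_pg <- all(vapply(seq_len(length(pg_sets) - 1L), function(i)
    all(pg_sets[[i]] %in% pg_sets[[i + 1L]]), logical(1)))
  edge_key <- function(e) paste(e$pg_mutant, e$mr_gene)
  nest_edges <- all(unlist(lapply(thresholds, function(th)
    vapply(seq_len(length(ks) - 1L), function(i)
      all(edge_key(edges[[paste0(th, "/", ks[i])]]) %in%
            edge_key(edges[[paste0(th, "/", ks[i + 1L])]])), logical(1)))))
  structure(list(thresholds = thresholds, ks = ks, pg_sets = pg_sets,
                 edges = edges,
                 core_pg = Reduce(intersect, pg_sets),
                 nesting_ok = nest_pg && nest_edges),
            class = "mr_net_sens")
}

#' @export
print.mr_net_sens <- function(x, ...) {
  cat("Peripheral-gene network sensitivity\n")
  cat("  PG counts by threshold:",
      paste(sprintf("%s: %d", names(x$pg_sets), lengths(x$pg_sets)),
            collapse = ", "), "\n")
  cat("  core PG set (all thresholds):", length(x$core_pg), "mutants\n")
  cat("  nesting (thresholds and top-k):",
      if (x$nesting_ok) "ok" else "VIOLATED", "\n")
  invisible(x)
}

#' Write a PG-MR edge list as TSV and SIF
#'
#' @param edges Edge data frame from [build_pg_mr_network()].
#' @param path Output TSV path; a `.sif` file with the same stem is written
#'   alongside for network viewers.
#' @return Invisibly, the TSV path.
#' @export
write_edges <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  sif <- paste(edges$pg_mutant, "contributes", edges$mr_gene)
  writeLines(sif, sub("\\.tsv$", ".sif", path))
  invisible(path)
}
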