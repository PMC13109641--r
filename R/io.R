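#' Read a mutant expression matrix from TSV
#'
#' Reads a tab-separated table of log2 fold-changes vs. wild type.  The
#' on-disk convention is genes in rows and mutants in columns (the usual
#' shape of published compendia); set `orientation = "mutants_by_genes"` for
#' the transposed layout.  The returned matrix is always mutants x genes.
#'
#' The deleted gene of each mutant is taken from `mapping` (a two-column
#' data frame or TSV path: mutant, gene) when supplied; otherwise it is
#' inferred from the `"<gene>-del"` naming convention for mutant identifiers.
#' Mutants where neither applies (non-deletion perturbations) simply get no
#' mapping entry.
#'
#' Missing values: cells equal to `na` are mean-imputed at 0 log2-FC
#' ("no change"), per gene, unless a gene exceeds `max_missing_frac`
#' missingness, in which case the gene is dropped (with a warning).
#'
#' @param path TSV file.
#' @param orientation `"genes_by_mutants"` (default) or `"mutants_by_genes"`.
#' @param mapping Optional mutant-to-deleted-gene map: a two-column data
#'   frame, a named character vector, or the path of a two-column TSV.
#' @param na Missing-value token (default `"NA"`).
#' @param max_missing_frac Per-gene missingness cap before the gene is
#'   dropped (default 0.2).
#' @return Numeric matrix (mutants x genes) with attribute
#'   `"deleted_gene_of"`, a named character vector.
#' @export
read_expression <- function(path, orientation = c("genes_by_mutants",
                                                  "mutants_by_genes"),
                            mapping = NULL, na = "NA",
                            max_missing_frac = 0.2) {
  orientation <- match.arg(orientation)
  df <- utils::read.delim(path, check.names = FALSE, na.strings = na,
                          stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate row identifier(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  if (anyDuplicated(colnames(df)[-1L]))
    stop("duplicate column header(s) in ", path, call. = FALSE)
  vals <- df[-1L]
  nonnum <- !vapply(vals, is.numeric, logical(1))
  if (any(nonnum)) {
    for (j in which(nonnum)) {
      v <- suppressWarnings(as.numeric(vals[[j]]))
      bad <- which(!is.na(vals[[j]]) & is.na(v))
      if (length(bad))
        stop("non-numeric cell in ", path, ", column '",
             colnames(vals)[j], "', line ", bad[1L] + 1L, call. = FALSE)
      vals[[j]] <- v
    }
  }
  M <- as.matrix(vals)
  rownames(M) <- ids
  if (orientation == "genes_by_mutants") M <- t(M)
  # mutants x genes from here on
  miss_frac <- colMeans(is.na(M))
  drop <- miss_frac > max_missing_frac
  if (any(drop)) {
    warning(sum(drop), " gene(s) exceeded the missingness cap and were ",
            "dropped: ", paste(utils::head(colnames(M)[drop], 5),
                               collapse = ", "),
            if (sum(drop) > 5) ", ..." else "", call. = FALSE)
    M <- M[, !drop, drop = FALSE]
  }
  M[is.na(M)] <- 0
  attr(M, "deleted_gene_of") <- resolve_deletion_map(rownames(M),
                                                     colnames(M), mapping)
  M
}

resolve_deletion_map <- function(mutants, genes, mapping = NULL) {
  if (!is.null(mapping)) {
    if (is.character(mapping) && length(mapping) == 1L && file.exists(mapping))
      mapping <- utils::read.delim(mapping, header = TRUE,
                                   stringsAsFactors = FALSE)
    if (is.data.frame(mapping)) {
      map <- stats::setNames(as.character(mapping[[2L]]),
                             as.character(mapping[[1L]]))
    } else if (!is.null(names(mapping))) {
      map <- mapping
    } else stop("'mapping' must be a two-column table or named vector",
                call. = FALSE)
  } else {
    # "<gene>-del" convention
    hit <- grepl("-del$", mutants)
    map <- stats::setNames(sub("-del$", "", mutants[hit]), mutants[hit])
  }
  map <- map[names(map) %in% mutants]
  map[map %in% genes]
}

#' Write an expression matrix to TSV (genes x mutants on disk)
#'
#' @param X Mutants x genes numeric matrix.
#' @param path Output TSV path.
#' @param deleted_gene_of Optional mutant-to-gene map written alongside as
#'   `<path>.mapping.tsv` (only for mutants whose mapping is not implied by
#'   the `"<gene>-del"` convention, i.e. always written when supplied).
#' @return Invisibly, `path`.
#' @export
write_expression <- function(X, path, deleted_gene_of = NULL) {
  out <- data.frame(gene = colnames(X), t(X), check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  if (!is.null(deleted_gene_of) && length(deleted_gene_of)) {
    mp <- data.frame(mutant = names(deleted_gene_of),
                     gene = unname(deleted_gene_of))
    utils::write.table(mp, paste0(path, ".mapping.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' Read a replicative-lifespan table
#'
#' Expects columns `strain`, `pct_change` (percent lifespan change vs. wild
#' type), `n_cells` (number of mother cells assayed) and optionally
#' `p_value`.
#'
#' @param path TSV file.
#' @return A validated data frame; `p_value` is `NA` when the column is
#'   absent.
#' @export
read_lifespan <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("strain", "pct_change", "n_cells")
  if (!all(need %in% colnames(df)))
    stop("lifespan table must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (!"p_value" %in% colnames(df)) df$p_value <- NA_real_
  df <- df[c("strain", "pct_change", "n_cells", "p_value")]
  df$strain <- as.character(df$strain)
  validate_lifespan(df)
}

validate_lifespan <- function(df) {
  if (anyDuplicated(df$strain))
    stop("duplicate strain(s): ",
         paste(unique(df$strain[duplicated(df$strain)]), collapse = ", "),
         call. = FALSE)
  if (any(is.na(df$n_cells)))
    stop("rows with missing n_cells are not allowed", call. = FALSE)
  if (any(df$n_cells < 1))
    stop("n_cells must be >= 1 for every strain", call. = FALSE)
  p <- df$p_value
  if (any(!is.na(p) & (p < 0 | p > 1)))
    stop("p_value must lie in [0, 1]", call. = FALSE)
  df
}

#' @rdname read_lifespan
#' @param df Lifespan data frame.
#' @export
write_lifespan <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated fields `name`,
#' `description`, then member genes.  Duplicated set names with identical
#' members are deduplicated with a warning; duplicated names with different
#' members are disambiguated by appending `"_2"`, `"_3"`, ... so that
#' condition-specific variants of the same factor survive until merging.
#'
#' @param path GMT file.
#' @return Named list of character vectors with attribute `"description"`
#'   (named character vector of per-set provenance notes).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- list(); descr <- character(0)
  for (f in fields) {
    if (length(f) < 3L || !any(nzchar(f[-(1:2)])))
      stop("gene set '", f[1L], "' has an empty member list", call. = FALSE)
    nm <- f[1L]; members <- unique(f[-(1:2)][nzchar(f[-(1:2)])])
    if (nm %in% names(sets)) {
      if (setequal(sets[[nm]], members)) {
        warning("duplicated gene set '", nm, "' with identical members; ",
                "deduplicated", call. = FALSE)
        next
      }
      k <- 2L
      while (paste0(nm, "_", k) %in% names(sets)) k <- k + 1L
      nm <- paste0(nm, "_", k)
    }
    sets[[nm]] <- members
    descr[nm] <- f[2L]
  }
  attr(sets, "description") <- descr
  sets
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @param description Per-set description field(s), recycled.
#' @export
write_gmt <- function(sets, path, description = "") {
  description <- rep_len(description, length(sets))
  lines <- mapply(function(nm, d, mem) paste(c(nm, d, mem), collapse = "\t"),
                  names(sets), description, sets)
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Align expression and lifespan data into a modelling panel
#'
#' Intersects the strain identifiers of an expression matrix and a lifespan
#' table, orders both identically, computes reliability weights
#' `w = n/(n + c)` from the cell counts, and reports what was dropped.
#' The result is the single input object of [mrlasso()] and friends.
#'
#' @param expression Mutants x genes matrix (e.g. from [read_expression()]
#'   or a simulated panel), optionally carrying a `"deleted_gene_of"`
#'   attribute.
#' @param lifespan Lifespan data frame (see [read_lifespan()]).
#' @param c Weighting constant passed to [rls_weights()] (default 50).
#' @param deleted_gene_of Optional explicit mutant-to-gene map overriding
#'   the matrix attribute.
#' @return An object of class `"mr_panel"`: list with `X` (aligned matrix),
#'   `lifespan` (aligned data frame), `weights`, `deleted_gene_of`, `c`, and
#'   `dropped` (list of strain identifiers present in only one input).
#' @export
align_panel <- function(expression, lifespan, c = 50,
                        deleted_gene_of = NULL) {
  if (inherits(expression, "mr_sim")) {
    if (is.null(deleted_gene_of)) deleted_gene_of <- expression$deleted_gene_of
    if (missing(lifespan)) lifespan <- expression$lifespan
    expression <- expression$expression
  }
  stopifnot(is.matrix(expression))
  lifespan <- validate_lifespan(lifespan)
  if (is.null(deleted_gene_of))
    deleted_gene_of <- attr(expression, "deleted_gene_of")
  if (is.null(deleted_gene_of))
    deleted_gene_of <- resolve_deletion_map(rownames(expression),
                                            colnames(expression))
  common <- intersect(rownames(expression), lifespan$strain)
  if (!length(common))
    stop("no strain identifiers shared between expression and lifespan data",
         call. = FALSE)
  ls <- lifespan[match(common, lifespan$strain), , drop = FALSE]
  rownames(ls) <- NULL
  X <- expression[common, , drop = FALSE]
  attr(X, "deleted_gene_of") <- NULL
  structure(list(
    X = X,
    lifespan = ls,
    weights = rls_weights(ls$n_cells, c = c),
    deleted_gene_of = deleted_gene_of[names(deleted_gene_of) %in% common],
    c = c,
    dropped = list(
      expression_only = setdiff(rownames(expression), common),
      lifespan_only = setdiff(lifespan$strain, common))),
    class = "mr_panel")
}

#' @export
print.mr_panel <- function(x, ...) {
  cat("Aligned mutant panel:", nrow(x$X), "strains x", ncol(x$X), "genes\n")
  cat("  weighting constant c =", x$c,
      sprintf("(weights %.3f-%.3f)\n", min(x$weights), max(x$weights)))
  nd <- lengths(x$dropped)
  cat("  dropped:", nd[["expression_only"]], "expression-only,",
      nd[["lifespan_only"]], "lifespan-only strains\n")
  invisible(x)
}
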