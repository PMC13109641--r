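#' Configuration for the synthetic mutant-panel generator
#'
#' Collects and validates all parameters of the generative model realised by
#' [simulate_mutant_panel()].  Defaults describe a panel with the statistical
#' structure the weighted lifespan regression assumes: a sparse signed
#' coefficient vector over genes, log2 fold-change expression with a large
#' negative self-deletion entry per mutant, lifespan equal to the linear
#' combination of expression changes plus heteroscedastic measurement noise
#' driven by the per-strain mother-cell count, and transcription-factor
#' modules with coordinated shifts in long-lived mutants.
#'
#' @param n_mutants Number of deletion mutants (one deleted gene each).
#' @param n_genes Number of genes in the expression panel.
#' @param n_mr Number of planted nonzero coefficients (master regulators).
#' @param beta_magnitude_range Length-2 positive range for |beta|, in percent
#'   lifespan per log2-FC.
#' @param frac_positive Fraction of planted coefficients that are positive.
#' @param noise_sd_base Lifespan measurement noise, in percent-lifespan
#'   units, for a strain of weight 1; strain i receives noise s.d.
#'   `noise_sd_base / sqrt(w_i)` with `w_i = n_i/(n_i + 50)`.
#' @param background_sd S.d. of unstructured background log2 fold-changes.
#' @param mr_response_sd S.d. of a master regulator's expression response in
#'   the mutants that perturb it.
#' @param mr_response_prob Probability that a given mutant perturbs a given
#'   master regulator (zero-inflation of the response: each MR responds, with
#'   a consistent magnitude scale, in only a subset of mutants).
#' @param self_effect Log2 fold-change planted at each mutant's own deleted
#'   gene; a large negative number emulating a near-absent transcript after
#'   pseudo-counts (default -8).
#' @param cellcount_law Distribution of mother-cell counts: either
#'   `list(type = "empirical", p_modal = 0.8, modal = 5, tail_range =
#'   c(10, 2000))` (default; 80% of strains at the modal count 5, the rest
#'   log-uniform up to ~2000) or `list(type = "constant", value = <n>)`.
#' @param n_tf_modules Number of planted TF target-gene modules.
#' @param module_size_range Length-2 integer range of module sizes.
#' @param module_shift Log2-FC offset added to a module's member genes in
#'   mutants whose true (noise-free) lifespan change exceeds +15%.
#' @param seed Integer seed; the whole dataset is a deterministic function
#'   of the configuration including this seed.
#' @return An object of class `"sim_config"` (a validated list).
#' @seealso [simulate_mutant_panel()]
#' @export
sim_config <- function(n_mutants = 200, n_genes = 500, n_mr = 10,
                       beta_magnitude_range = c(2, 10),
                       frac_positive = 0.65,
                       noise_sd_base = 5,
                       background_sd = 0.25,
                       mr_response_sd = 1,
                       mr_response_prob = 0.3,
                       self_effect = -8,
                       cellcount_law = list(type = "empirical", p_modal = 0.8,
                                            modal = 5,
                                            tail_range = c(10, 2000)),
                       n_tf_modules = 5,
                       module_size_range = c(20, 50),
                       module_shift = -1,
                       seed = 1L) {
  cfg <- list(n_mutants = as.integer(n_mutants), n_genes = as.integer(n_genes),
              n_mr = as.integer(n_mr),
              beta_magnitude_range = as.numeric(beta_magnitude_range),
              frac_positive = frac_positive, noise_sd_base = noise_sd_base,
              background_sd = background_sd, mr_response_sd = mr_response_sd,
              mr_response_prob = mr_response_prob, self_effect = self_effect,
              cellcount_law = cellcount_law,
              n_tf_modules = as.integer(n_tf_modules),
              module_size_range = as.integer(module_size_range),
              module_shift = module_shift, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  bad <- function(msg) stop("invalid simulation config: ", msg, call. = FALSE)
  if (cfg$n_mutants < 1) bad("n_mutants must be >= 1")
  if (cfg$n_mr < 0 || cfg$n_mr > cfg$n_genes)
    bad("n_mr must satisfy 0 <= n_mr <= n_genes")
  if (cfg$n_mutants > cfg$n_genes)
    bad("n_mutants must be <= n_genes (each mutant deletes a distinct gene)")
  if (length(cfg$beta_magnitude_range) != 2L ||
      any(cfg$beta_magnitude_range <= 0) ||
      diff(cfg$beta_magnitude_range) < 0)
    bad("beta_magnitude_range must be an increasing pair of positive values")
  if (cfg$frac_positive < 0 || cfg$frac_positive > 1)
    bad("frac_positive must be in [0, 1]")
  for (f in c("noise_sd_base", "background_sd", "mr_response_sd"))
    if (cfg[[f]] < 0) bad(paste(f, "must be >= 0"))
  if (cfg$mr_response_prob < 0 || cfg$mr_response_prob > 1)
    bad("mr_response_prob must be in [0, 1]")
  if (cfg$self_effect >= 0) bad("self_effect must be < 0")
  if (cfg$n_tf_modules > 0) {
    if (length(cfg$module_size_range) != 2L ||
        any(cfg$module_size_range < 1) || diff(cfg$module_size_range) < 0)
      bad("module_size_range must be an increasing pair of counts >= 1")
    if (max(cfg$module_size_range) > cfg$n_genes)
      bad("modules cannot be larger than the gene universe (n_genes)")
  }
  law <- cfg$cellcount_law
  if (!is.list(law) || is.null(law$type) ||
      !law$type %in% c("empirical", "constant"))
    bad("cellcount_law$type must be 'empirical' or 'constant'")
  if (law$type == "constant" && (is.null(law$value) || law$value < 1))
    bad("constant cellcount_law needs value >= 1")
  if (law$type == "empirical") {
    if (is.null(law$p_modal) || law$p_modal < 0 || law$p_modal > 1)
      bad("empirical cellcount_law needs p_modal in [0, 1]")
    if (is.null(law$modal) || law$modal < 1) bad("modal count must be >= 1")
    if (is.null(law$tail_range) || length(law$tail_range) != 2L ||
        any(law$tail_range < 1) || diff(law$tail_range) < 0)
      bad("tail_range must be an increasing pair of counts >= 1")
  }
  invisible(cfg)
}

#' Draw per-strain mother-cell counts
#'
#' Samples the number of mother cells assayed per strain from the
#' configured law.  The default empirical law places 80% of its mass at the
#' modal count 5 and spreads the remainder log-uniformly between 10 and
#' about 2000, mirroring the mix of a handful of deeply assayed strains among
#' many shallow ones seen in systematic lifespan screens.
#'
#' @param config A [sim_config()].
#' @param n Number of draws; defaults to `config$n_mutants`.
#' @return Integer vector of counts, all >= 1.
#' @export
generate_cell_counts <- function(config, n = config$n_mutants) {
  validate_sim_config(config)
  law <- config$cellcount_law
  if (law$type == "constant") return(rep(as.integer(law$value), n))
  modal <- runif(n) < law$p_modal
  lo <- log(law$tail_range[1]); hi <- log(law$tail_range[2])
  tail <- as.integer(round(exp(runif(n, lo, hi))))
  counts <- ifelse(modal, as.integer(law$modal), pmax(tail, 1L))
  as.integer(counts)
}

#' Simulate a mutant expression + lifespan panel with known ground truth
#'
#' Generates a deletion-mutant panel realising the additive expression model
#' of lifespan: a sparse signed coefficient vector `beta` over genes is
#' drawn, expression log2 fold-changes are background noise plus
#' zero-inflated master-regulator responses plus a large negative
#' self-deletion entry, the noise-free lifespan change of mutant i is
#' `y_i = sum_j beta_j x_ij`, and the observed lifespan adds Gaussian
#' measurement noise with s.d. `noise_sd_base / sqrt(w_i)` where
#' `w_i = n_i/(n_i + 50)` is the reliability weight of a strain assayed with
#' `n_i` mother cells.  Per-strain p-values are the two-sided normal tail
#' probability of the observed change against that measurement error.
#' Transcription-factor modules are planted with [plant_tf_modules()].
#'
#' @param config A [sim_config()].
#' @return An object of class `"mr_sim"`: a list with components
#'   `expression` (mutant x gene matrix), `lifespan` (data frame with
#'   `strain`, `pct_change`, `n_cells`, `p_value`), `deleted_gene_of`
#'   (named character), `true_beta` (named numeric over all genes),
#'   `y_true` (noise-free lifespan changes), `module_membership`
#'   (named list of gene sets), `config`, and `seed_used`.
#' @examples
#' sim <- simulate_mutant_panel(sim_config(n_mutants = 50, n_genes = 100,
#'                                         n_mr = 5, seed = 42))
#' sim
#' @export
simulate_mutant_panel <- function(config = sim_config()) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_mutants; p <- config$n_genes

  genes <- sprintf("G%04d", seq_len(p))
  deleted <- sample(genes, n)
  mutants <- paste0(deleted, "-del")
  deleted_gene_of <- stats::setNames(deleted, mutants)

  mr_genes <- if (config$n_mr > 0) sample(genes, config$n_mr) else character(0)
  n_pos <- round(config$frac_positive * config$n_mr)
  sgn <- sample(c(rep(1, n_pos), rep(-1, config$n_mr - n_pos)))
  mag <- runif(config$n_mr, config$beta_magnitude_range[1],
               config$beta_magnitude_range[2])
  true_beta <- stats::setNames(numeric(p), genes)
  true_beta[mr_genes] <- sgn * mag

  X <- matrix(rnorm(n * p, sd = config$background_sd), n, p,
              dimnames = list(mutants, genes))
  if (config$n_mr > 0) {
    resp <- matrix(rnorm(n * config$n_mr, sd = config$mr_response_sd) *
                     (runif(n * config$n_mr) < config$mr_response_prob),
                   n, config$n_mr)
    X[, mr_genes] <- X[, mr_genes] + resp
  }
  X[cbind(mutants, deleted)] <- config$self_effect

  y_true <- drop(X %*% true_beta)

  n_cells <- generate_cell_counts(config)
  w <- rls_weights(n_cells)
  noise_sd <- config$noise_sd_base / sqrt(w)
  y <- y_true + rnorm(n, sd = noise_sd)
  p_value <- if (config$noise_sd_base > 0) {
    2 * stats::pnorm(-abs(y) / noise_sd)
  } else {
    ifelse(y == 0, 1, 0)
  }

  sim <- structure(list(
    expression = X,
    lifespan = data.frame(strain = mutants, pct_change = y,
                          n_cells = n_cells, p_value = p_value,
                          stringsAsFactors = FALSE),
    deleted_gene_of = deleted_gene_of,
    true_beta = true_beta,
    y_true = y_true,
    module_membership = list(),
    config = config,
    seed_used = config$seed), class = "mr_sim")

  if (config$n_tf_modules > 0) sim <- plant_tf_modules(sim, config)
  sim
}

#' Plant transcription-factor modules into a simulated panel
#'
#' Samples `n_tf_modules` gene sets from the non-master-regulator genes
#' (sets may overlap, as real TF target sets do) and, in every mutant whose
#' true noise-free lifespan change exceeds +15%, adds `module_shift` log2-FC
#' units to the member genes.  Because members carry zero true coefficients,
#' the planted shift leaves the noise-free lifespan identity intact while
#' giving module-scoring methods a known coordinated signal to recover.
#'
#' @param sim An `"mr_sim"` object.
#' @param config A [sim_config()]; defaults to the one stored in `sim`.
#' @return `sim` with shifted expression and `module_membership` filled in.
#' @export
plant_tf_modules <- function(sim, config = sim$config) {
  stopifnot(inherits(sim, "mr_sim"))
  validate_sim_config(config)
  if (config$n_tf_modules == 0) return(sim)
  if (max(config$module_size_range) > ncol(sim$expression))
    stop("invalid simulation config: module larger than gene universe",
         call. = FALSE)
  set.seed(config$seed + 10007L)
  genes <- colnames(sim$expression)
  pool <- genes[sim$true_beta[genes] == 0]
  size_choices <- seq.int(config$module_size_range[1],
                          config$module_size_range[2])
  sizes <- size_choices[sample.int(length(size_choices),
                                   config$n_tf_modules, replace = TRUE)]
  membership <- lapply(sizes, function(k) sample(pool, k))
  names(membership) <- sprintf("TF%02d", seq_along(membership))
  long_lived <- sim$y_true > 15
  if (any(long_lived) && config$module_shift != 0) {
    for (mem in membership)
      sim$expression[long_lived, mem] <-
        sim$expression[long_lived, mem] + config$module_shift
  }
  sim$module_membership <- membership
  sim
}

#' @export
print.mr_sim <- function(x, ...) {
  cat("Synthetic mutant panel:", nrow(x$expression), "mutants x",
      ncol(x$expression), "genes\n")
  cat("  planted master regulators:", sum(x$true_beta != 0),
      sprintf("(%d positive, %d negative)\n",
              sum(x$true_beta > 0), sum(x$true_beta < 0)))
  cat("  planted TF modules:", length(x$module_membership), "\n")
  cat("  long-lived (true change > +15%):", sum(x$y_true > 15), "mutants\n")
  cat("  seed:", x$seed_used, "\n")
  invisible(x)
}

#' Write a simulated panel to disk in the package's exchange formats
#'
#' Emits the same TSV formats the readers accept (so synthetic and real data
#' are interchangeable at every pipeline stage), a GMT file with the planted
#' modules, and a JSON sidecar holding the ground truth for tests.
#'
#' @param sim An `"mr_sim"` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_mutant_panel <- function(sim, dir) {
  stopifnot(inherits(sim, "mr_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             lifespan = file.path(dir, "lifespan.tsv"),
             modules = file.path(dir, "modules.gmt"),
             truth = file.path(dir, "truth.json"))
  write_expression(sim$expression, paths["expression"],
                   deleted_gene_of = sim$deleted_gene_of)
  write_lifespan(sim$lifespan, paths["lifespan"])
  if (length(sim$module_membership))
    write_gmt(sim$module_membership, paths["modules"],
              description = "planted synthetic module")
  truth <- list(seed = sim$seed_used,
                true_beta = as.list(sim$true_beta[sim$true_beta != 0]),
                module_membership = sim$module_membership)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
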