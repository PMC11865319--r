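#' Configuration of the synthetic-data generator
#'
#' The generator plants a single-latent-factor co-expression module around a
#' seed gene in every condition: on the log2 scale, gene g in sample j is
#' `b_g + a_g * f_j + eps`, with `f_j ~ N(0,1)` a per-condition latent factor,
#' `eps ~ N(0, noise_sd^2)`, `a_g = loading_seed` for the seed,
#' `a_g ~ U(loading_module)` for module genes and 0 otherwise. Matrices are
#' returned on a linear TPM-like scale (`2^x - 1`, floored at 0) so the
#' pipeline's own log transform is exercised. Per-condition baselines `b_g`
#' are redrawn independently, so the cross-condition intersection is a real
#' filter rather than a repetition.
#'
#' Defaults mirror the scale of the motivating pan-cancer analysis — 36
#' conditions ("cancer types"), a 44-gene module (seed included), 7 human and
#' 4 mouse regulator databases — with the gene count scaled down to 2000 for
#' desk-size runs. All randomness derives from `seed`; each generator draws
#' from its own stream (`seed` + a fixed offset) so adding one generator never
#' perturbs another's output.
#'
#' @param seed master RNG seed (integer).
#' @param n_conditions number of bulk conditions (default 36).
#' @param n_samples_per_condition samples per condition (default 50).
#' @param n_genes total genes (default 2000).
#' @param module_size planted module size including the seed gene (default 44).
#' @param loading_seed latent-factor loading of the seed gene (default 0.9).
#' @param loading_module range of module-gene loadings (default c(0.5, 0.9)).
#' @param noise_sd residual sd on the log2 scale (default 1).
#' @param baseline_log2 range of per-gene baseline log2 expression (default
#'   c(3, 8), i.e. typical expressed-gene TPMs of ~8-250).
#' @param n_db_human,n_db_mouse number of human / mouse prediction databases
#'   (defaults 7 and 4).
#' @param n_regulators,n_true_regulators candidate regulators and how many are
#'   real (true regulators split evenly into activators and repressors;
#'   defaults 12 and 8).
#' @param p_detect_true,p_detect_false per-database detection probability for
#'   true and null regulators (defaults 0.8 and 0.1).
#' @param effect_size_perturbation signed log2 shift a true regulator's
#'   perturbation applies to seed + module (default 3).
#' @param n_datasets_per_regulator perturbation datasets per regulator
#'   (default 2).
#' @param n_per_group control / perturbed group size (default 4).
#' @param rho_target planted cross-species Spearman correlation (default 0.6).
#' @param n_profile_units organs / cell types in paired species profiles
#'   (default 40).
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_conditions = 36L,
                       n_samples_per_condition = 50L,
                       n_genes = 2000L,
                       module_size = 44L,
                       loading_seed = 0.9,
                       loading_module = c(0.5, 0.9),
                       noise_sd = 1,
                       baseline_log2 = c(3, 8),
                       n_db_human = 7L,
                       n_db_mouse = 4L,
                       n_regulators = 12L,
                       n_true_regulators = 8L,
                       p_detect_true = 0.8,
                       p_detect_false = 0.1,
                       effect_size_perturbation = 3,
                       n_datasets_per_regulator = 2L,
                       n_per_group = 4L,
                       rho_target = 0.6,
                       n_profile_units = 40L) {
  cfg <- list(seed = as.integer(seed), n_conditions = as.integer(n_conditions),
              n_samples_per_condition = as.integer(n_samples_per_condition),
              n_genes = as.integer(n_genes), module_size = as.integer(module_size),
              loading_seed = loading_seed, loading_module = loading_module,
              noise_sd = noise_sd, baseline_log2 = baseline_log2,
              n_db_human = as.integer(n_db_human), n_db_mouse = as.integer(n_db_mouse),
              n_regulators = as.integer(n_regulators),
              n_true_regulators = as.integer(n_true_regulators),
              p_detect_true = p_detect_true, p_detect_false = p_detect_false,
              effect_size_perturbation = effect_size_perturbation,
              n_datasets_per_regulator = as.integer(n_datasets_per_regulator),
              n_per_group = as.integer(n_per_group),
              rho_target = rho_target,
              n_profile_units = as.integer(n_profile_units))
  if (cfg$module_size >= cfg$n_genes) stop("module_size must be < n_genes")
  if (cfg$module_size < 2L) stop("module_size must be >= 2 (seed + partners)")
  if (cfg$n_conditions < 1L) stop("n_conditions must be >= 1")
  if (cfg$n_samples_per_condition < 4L)
    stop("need >= 4 samples per condition for stratification")
  for (f in c("p_detect_true", "p_detect_false"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must lie in [0, 1]")
  if (cfg$rho_target < -1 || cfg$rho_target > 1)
    stop("rho_target must lie in [-1, 1]")
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0")
  if (cfg$n_true_regulators > cfg$n_regulators)
    stop("n_true_regulators must be <= n_regulators")
  class(cfg) <- "sim_config"
  cfg
}

#' Named generator presets
#'
#' `default` is [sim_config()] as documented; `noiseless` sets `noise_sd = 0`
#' (exact recovery regime); `hard` doubles the noise and weakens database
#' detection (`noise_sd = 2`, `p_detect_true = 0.6`, `p_detect_false = 0.2`).
#'
#' @param preset `"default"`, `"noiseless"` or `"hard"`.
#' @param seed master seed.
#' @param ... overrides passed to [sim_config()].
#' @return a `sim_config`.
#' @export
sim_preset <- function(preset = c("default", "noiseless", "hard"), seed = 1L, ...) {
  preset <- match.arg(preset)
  switch(preset,
         default   = sim_config(seed = seed, ...),
         noiseless = sim_config(seed = seed, noise_sd = 0, ...),
         hard      = sim_config(seed = seed, noise_sd = 2, p_detect_true = 0.6,
                                p_detect_false = 0.2, ...))
}

# Fixed per-generator stream offsets off the master seed (kept within 32-bit).
.stream_seed <- function(cfg, offset) {
  as.integer((as.numeric(cfg$seed) + offset) %% (.Machine$integer.max - 7))
}

.sim_gene_ids <- function(cfg) sprintf("g%04d", seq_len(cfg$n_genes))

#' Simulate the multi-condition bulk expression panel
#'
#' Generates one linear-scale [expression_matrix()] per condition under the
#' planted latent-factor model described in [sim_config()], together with the
#' ground truth needed by recovery tests. The seed gene is the first gene
#' (`g0001`); the module comprises the first `module_size` genes. Module
#' loadings are drawn once and shared across conditions, so the module is the
#' same in every condition; baselines and factors are per-condition.
#'
#' @param config a [sim_config()].
#' @param truth optional `sim_truth` from an earlier call: reuse its module
#'   and loadings (e.g. to simulate an independent validation panel that
#'   shares the module).
#' @param n_conditions override the number of conditions (e.g. 1 validation
#'   dataset).
#' @param seed_offset offset added to the generator's stream seed; use a
#'   nonzero value to obtain an independent panel with the same truth.
#' @return list with `matrices` (list of [expression_matrix()]) and `truth`
#'   (class `sim_truth`: `seed_gene`, `module_gene_ids`, `loadings`,
#'   `regulator_signs`, `rho_target`, `factors`).
#' @export
simulate_panel <- function(config, truth = NULL, n_conditions = NULL,
                           seed_offset = 0L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.stream_seed(config, 0L + seed_offset))
  genes <- .sim_gene_ids(config)
  n_cond <- if (is.null(n_conditions)) config$n_conditions else as.integer(n_conditions)
  n <- config$n_samples_per_condition
  if (is.null(truth)) {
    loadings <- numeric(config$n_genes)
    loadings[1L] <- config$loading_seed
    loadings[2:config$module_size] <-
      stats::runif(config$module_size - 1L, config$loading_module[1L],
                   config$loading_module[2L])
    names(loadings) <- genes
    truth <- structure(list(seed_gene = genes[1L],
                            module_gene_ids = genes[seq_len(config$module_size)],
                            loadings = loadings,
                            regulator_signs = NULL,
                            rho_target = config$rho_target,
                            factors = NULL),
                       class = "sim_truth")
  } else {
    stopifnot(inherits(truth, "sim_truth"))
    loadings <- truth$loadings
  }
  factors <- vector("list", n_cond)
  mats <- vector("list", n_cond)
  for (ci in seq_len(n_cond)) {
    cond <- sprintf("condition_%02d", ci)
    f <- stats::rnorm(n)
    b <- stats::runif(config$n_genes, config$baseline_log2[1L],
                      config$baseline_log2[2L])
    eps <- matrix(stats::rnorm(config$n_genes * n, sd = config$noise_sd),
                  config$n_genes, n)
    log2x <- b + outer(loadings, f) + eps
    lin <- pmax(2^log2x - 1, 0)
    dimnames(lin) <- list(genes, sprintf("%s_s%03d", cond, seq_len(n)))
    mats[[ci]] <- expression_matrix(lin, unit = "TPM", species = "synthetic",
                                    condition = cond)
    factors[[ci]] <- f
  }
  names(mats) <- vapply(mats, attr, "", "condition")
  truth$factors <- factors
  list(matrices = mats, truth = truth)
}

#' Simulate regulator-prediction tables
#'
#' Builds a binary regulator x database prediction table over
#' `n_db_human + n_db_mouse` databases. True regulators (planted activators
#' and repressors, alternating) are detected by each database independently
#' with probability `p_detect_true`, null regulators with `p_detect_false`.
#'
#' @param config a [sim_config()].
#' @param truth optional `sim_truth` to extend with the planted regulator
#'   signs.
#' @return list with `table` (a [prediction_table()]) and `truth` (its
#'   `regulator_signs` is a named vector over regulators with values
#'   `activator`, `repressor` or `null`).
#' @export
simulate_prediction_tables <- function(config, truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.stream_seed(config, 1L))
  regs <- sprintf("TF%02d", seq_len(config$n_regulators))
  signs <- rep("null", config$n_regulators)
  if (config$n_true_regulators > 0L)
    signs[seq_len(config$n_true_regulators)] <-
      rep_len(c("activator", "repressor"), config$n_true_regulators)
  names(signs) <- regs
  dbs <- c(sprintf("db_h%d", seq_len(config$n_db_human)),
           sprintf("db_m%d", seq_len(config$n_db_mouse)))
  db_species <- rep(c("human", "mouse"), c(config$n_db_human, config$n_db_mouse))
  p_row <- ifelse(signs == "null", config$p_detect_false, config$p_detect_true)
  pred <- matrix(stats::rbinom(length(regs) * length(dbs), 1L,
                               rep(p_row, times = length(dbs))),
                 nrow = length(regs), ncol = length(dbs),
                 dimnames = list(regs, dbs))
  if (is.null(truth))
    truth <- structure(list(seed_gene = NA_character_, module_gene_ids = NULL,
                            loadings = NULL, regulator_signs = signs,
                            rho_target = config$rho_target, factors = NULL),
                       class = "sim_truth")
  else truth$regulator_signs <- signs
  list(table = prediction_table(pred, db_species), truth = truth)
}

#' Simulate regulator perturbation datasets
#'
#' For every regulator and dataset, draws a control and a perturbed group
#' (`n_per_group` each). Perturbing (inhibiting) a planted activator subtracts
#' `effect_size_perturbation` from the log2 means of seed + module genes; a
#' repressor adds it; null regulators and background genes are unshifted.
#' Matrices are linear-scale, like the panel.
#'
#' @param config a [sim_config()].
#' @param truth a `sim_truth` carrying `module_gene_ids` (from
#'   [simulate_panel()]) and `regulator_signs` (from
#'   [simulate_prediction_tables()]).
#' @return list of [perturbation_dataset()] objects (one per regulator x
#'   dataset).
#' @export
simulate_perturbations <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "sim_truth"))
  if (is.null(truth$module_gene_ids) || is.null(truth$regulator_signs))
    stop("truth must carry module_gene_ids and regulator_signs")
  set.seed(.stream_seed(config, 2L))
  genes <- .sim_gene_ids(config)
  module <- truth$module_gene_ids
  n <- config$n_per_group
  out <- list()
  for (reg in names(truth$regulator_signs)) {
    sign <- truth$regulator_signs[[reg]]
    shift <- switch(sign, activator = -config$effect_size_perturbation,
                    repressor = +config$effect_size_perturbation, null = 0)
    for (d in seq_len(config$n_datasets_per_regulator)) {
      b <- stats::runif(config$n_genes, config$baseline_log2[1L],
                        config$baseline_log2[2L])
      mu <- cbind(matrix(b, config$n_genes, n),
                  matrix(b + shift * (genes %in% module), config$n_genes, n))
      log2x <- mu + matrix(stats::rnorm(config$n_genes * 2 * n,
                                        sd = config$noise_sd),
                           config$n_genes, 2 * n)
      lin <- pmax(2^log2x - 1, 0)
      dimnames(lin) <- list(genes, c(sprintf("ctrl_%d", seq_len(n)),
                                     sprintf("pert_%d", seq_len(n))))
      em <- expression_matrix(lin, unit = "TPM", species = "synthetic",
                              condition = sprintf("%s_ds%d", reg, d))
      out[[length(out) + 1L]] <- perturbation_dataset(
        regulator = reg, dataset = sprintf("%s_ds%d", reg, d), matrix = em,
        group = rep(c("control", "perturbed"), each = n))
    }
  }
  out
}

#' Simulate paired cross-species expression profiles
#'
#' Draws paired per-organ (or per-cell-type) value vectors from a Gaussian
#' copula whose Pearson parameter is chosen so the population Spearman
#' correlation equals `rho_target` (`r = 2 sin(pi * rho / 6)`). Values are
#' mapped through `exp()` to a positive nTPM-like scale; the monotone map
#' leaves rank correlations untouched.
#'
#' @param config a [sim_config()].
#' @return list with `pair` (a [profile_pair()]) and `truth` (`sim_truth` with
#'   `rho_target`).
#' @export
simulate_species_profiles <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.stream_seed(config, 3L))
  n <- config$n_profile_units
  r <- 2 * sin(pi * config$rho_target / 6)
  z1 <- stats::rnorm(n)
  z2 <- r * z1 + sqrt(max(0, 1 - r^2)) * stats::rnorm(n)
  labels <- sprintf("organ_%02d", seq_len(n))
  pair <- profile_pair(labels = labels, x = exp(1.2 * z1 + 3),
                       y = exp(1.2 * z2 + 3),
                       modality_x = "mRNA nTPM (species A)",
                       modality_y = "mRNA nTPM (species B)")
  truth <- structure(list(seed_gene = NA_character_, module_gene_ids = NULL,
                          loadings = NULL, regulator_signs = NULL,
                          rho_target = config$rho_target, factors = NULL),
                     class = "sim_truth")
  list(pair = pair, truth = truth)
}

#' Simulate a gene annotation table consistent with the planted module
#'
#' Assigns compartment and functional-category labels so that the planted
#' module is enriched for mitochondrial, metabolism-tagged genes (half the
#' module mitochondrial, ~2/3 metabolic — mirroring the enrichment structure
#' the annotation stage is meant to detect) against a sparser background.
#'
#' @param config a [sim_config()].
#' @param truth `sim_truth` with `module_gene_ids`.
#' @param p_mito_module,p_mito_background probability of a mitochondrial label
#'   inside / outside the module (defaults 0.5 and 0.1).
#' @param p_metab_module,p_metab_background same for the metabolism category
#'   (defaults 0.66 and 0.2).
#' @return data.frame with columns `gene_id`, `compartment`
#'   (`mitochondrion`/`other`), `category` (`metabolism`/`other`).
#' @export
simulate_annotations <- function(config, truth, p_mito_module = 0.5,
                                 p_mito_background = 0.1,
                                 p_metab_module = 0.66,
                                 p_metab_background = 0.2) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "sim_truth"))
  set.seed(.stream_seed(config, 4L))
  genes <- .sim_gene_ids(config)
  in_mod <- genes %in% truth$module_gene_ids
  p_mito <- ifelse(in_mod, p_mito_module, p_mito_background)
  p_metab <- ifelse(in_mod, p_metab_module, p_metab_background)
  data.frame(gene_id = genes,
             compartment = ifelse(stats::runif(length(genes)) < p_mito,
                                  "mitochondrion", "other"),
             category = ifelse(stats::runif(length(genes)) < p_metab,
                               "metabolism", "other"),
             stringsAsFactors = FALSE)
}
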