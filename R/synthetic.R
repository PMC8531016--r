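#' Configuration for the synthetic drug/disease study generator
#'
#' Describes a drug-perturbation library (decoy compounds plus one planted
#' compound, each profiled under several cell-context x dose conditions
#' against vehicle controls) and a disease library in which one target
#' disease is an attenuated, noisy mirror image of the planted compound's
#' effect vector. Counts are negative-binomial around lognormal per-gene
#' baselines shared across the whole study.
#'
#' @param n_genes number of genes in the universe.
#' @param n_effect_genes number of planted effect genes per compound
#'   (and for the target disease); must not exceed `n_genes`.
#' @param effect_size log2 fold-change magnitude of planted genes at high
#'   dose; low-dose conditions use half this value.
#' @param reversal_strength attenuation in `[0, 1]` of the mirrored disease
#'   effect: target-disease effect genes shift by
#'   `-direction * reversal_strength * effect_size`.
#' @param n_compounds number of compounds (decoys plus one planted).
#' @param n_conditions number of experimental conditions per compound;
#'   conditions are laid out as cell contexts crossed with high/low dose
#'   (default 4 = 2 cells x 2 doses).
#' @param n_diseases number of diseases (decoys plus one target).
#' @param samples_per_arm samples in every treated/control arm. When `NULL`
#'   (the default) compound arms use 5 samples and disease cohorts use
#'   12 cases vs 5 controls.
#' @param dispersion negative-binomial overdispersion (NB `size = 1/dispersion`).
#' @param baseline_log_mean,baseline_log_sd natural-log mean and sd of the
#'   lognormal per-gene baseline abundances.
#' @param seed integer seed; every generator output is a pure function of
#'   the configuration including this seed.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 2000L, n_effect_genes = 150L,
                             effect_size = 2, reversal_strength = 0.5,
                             n_compounds = 51L, n_conditions = 4L,
                             n_diseases = 10L, samples_per_arm = NULL,
                             dispersion = 0.1, baseline_log_mean = 5,
                             baseline_log_sd = 1.5, seed) {
  if (missing(seed) || is.null(seed))
    stop_sigrev("synthetic_config() requires an explicit integer seed", "sigrev_config_error")
  cfg <- list(n_genes = as.integer(n_genes),
              n_effect_genes = as.integer(n_effect_genes),
              effect_size = effect_size,
              reversal_strength = reversal_strength,
              n_compounds = as.integer(n_compounds),
              n_conditions = as.integer(n_conditions),
              n_diseases = as.integer(n_diseases),
              samples_per_arm = if (is.null(samples_per_arm)) NULL else as.integer(samples_per_arm),
              dispersion = dispersion,
              baseline_log_mean = baseline_log_mean,
              baseline_log_sd = baseline_log_sd,
              seed = as.integer(seed))
  validate_config(cfg)
  class(cfg) <- "synthetic_config"
  cfg
}

validate_config <- function(cfg) {
  bad <- function(msg) stop_sigrev(msg, "sigrev_config_error")
  if (cfg$n_genes < 1L) bad("n_genes must be positive")
  if (cfg$n_effect_genes < 1L || cfg$n_effect_genes > cfg$n_genes)
    bad("n_effect_genes must be in [1, n_genes]")
  if (cfg$effect_size < 0) bad("effect_size must be non-negative")
  if (cfg$reversal_strength < 0 || cfg$reversal_strength > 1)
    bad("reversal_strength must be in [0, 1]")
  if (cfg$n_compounds < 1L) bad("n_compounds must be positive")
  if (cfg$n_conditions < 1L) bad("n_conditions must be positive")
  if (cfg$n_diseases < 1L) bad("n_diseases must be positive")
  if (!is.null(cfg$samples_per_arm) && cfg$samples_per_arm < 2L)
    bad("samples_per_arm must be >= 2")
  if (cfg$dispersion <= 0) bad("dispersion must be positive")
  invisible(cfg)
}

gene_universe <- function(cfg) sprintf("g%05d", seq_len(cfg$n_genes))
compound_ids <- function(cfg) sprintf("cpd%03d", seq_len(cfg$n_compounds))
disease_ids <- function(cfg) sprintf("dis%02d", seq_len(cfg$n_diseases))

#' Condition grid for a configuration
#'
#' Conditions are cell contexts crossed with high/low dose, taken in the
#' order cellA_high, cellA_low, cellB_high, cellB_low, ... All conditions of
#' a compound share its effect genes; cell contexts differ only in noise.
#'
#' @param cfg a `synthetic_config`.
#' @return data.frame with columns condition, cell, dose.
#' @export
condition_grid <- function(cfg) {
  n_cells <- ceiling(cfg$n_conditions / 2)
  cells <- paste0("cell", LETTERS[seq_len(n_cells)])
  grid <- expand.grid(dose = c("high", "low"), cell = cells,
                      stringsAsFactors = FALSE)[, c("cell", "dose")]
  grid <- grid[seq_len(cfg$n_conditions), , drop = FALSE]
  data.frame(condition = paste(grid$cell, grid$dose, sep = "_"),
             cell = grid$cell, dose = grid$dose,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Ground truth of the planted reversal structure
#'
#' A deterministic function of the configuration (draws only from the seed):
#' effect genes are sampled without replacement; directions are fair-coin
#' signs. The planted compound is always the first compound identifier and
#' the target disease the first disease identifier.
#'
#' @param cfg a `synthetic_config`.
#' @return an object of class `ground_truth`: list with
#'   `planted_compound_id`, `target_disease_id`, `effect_genes`,
#'   `effect_directions` (named +1/-1 vector over exactly the effect genes).
#' @export
ground_truth <- function(cfg) {
  validate_config(cfg)
  genes <- gene_universe(cfg)
  rng <- local({
    set.seed(entity_seed(cfg$seed, 1L))
    eg <- sort(sample.int(cfg$n_genes, cfg$n_effect_genes))
    dirs <- ifelse(stats::runif(cfg$n_effect_genes) < 0.5, -1L, 1L)
    list(eg = eg, dirs = dirs)
  })
  effect_genes <- genes[rng$eg]
  directions <- stats::setNames(rng$dirs, effect_genes)
  structure(list(planted_compound_id = compound_ids(cfg)[1L],
                 target_disease_id = disease_ids(cfg)[1L],
                 effect_genes = effect_genes,
                 effect_directions = directions),
            class = "ground_truth")
}

# Shared per-gene baseline means (lognormal), one draw per configuration.
baseline_means <- function(cfg) {
  set.seed(entity_seed(cfg$seed, 2L))
  exp(stats::rnorm(cfg$n_genes, cfg$baseline_log_mean, cfg$baseline_log_sd))
}

# Per-compound effect vectors: planted compound uses the ground truth,
# decoys draw independent effect genes and directions from their own stream.
compound_effects <- function(cfg, truth) {
  genes <- gene_universe(cfg)
  out <- vector("list", cfg$n_compounds)
  names(out) <- compound_ids(cfg)
  for (i in seq_len(cfg$n_compounds)) {
    if (i == 1L) {
      idx <- match(truth$effect_genes, genes)
      dirs <- unname(truth$effect_directions)
    } else {
      set.seed(entity_seed(cfg$seed, 100L + i))
      idx <- sort(sample.int(cfg$n_genes, cfg$n_effect_genes))
      dirs <- ifelse(stats::runif(cfg$n_effect_genes) < 0.5, -1L, 1L)
    }
    delta <- numeric(cfg$n_genes)
    delta[idx] <- dirs
    out[[i]] <- delta
  }
  out
}

nb_matrix <- function(mu_genes, n_samples, dispersion, sample_prefix) {
  m <- matrix(stats::rnbinom(length(mu_genes) * n_samples,
                             mu = rep(mu_genes, times = n_samples),
                             size = 1 / dispersion),
              nrow = length(mu_genes), ncol = n_samples)
  colnames(m) <- paste0(sample_prefix, seq_len(n_samples))
  m
}

#' Generate the drug-perturbation library
#'
#' One treated/control pair per compound-condition. Counts are drawn
#' negative-binomially around the shared per-gene baseline; for each
#' compound its effect genes shift the treated log2 mean by
#' `direction * effect_size` at high dose and half that at low dose.
#'
#' @param cfg a `synthetic_config`.
#' @param truth optional `ground_truth`; recomputed from `cfg` when omitted.
#' @return named list (key `"<compound>|<condition>"`) of lists with
#'   elements `compound`, `condition`, `cell`, `dose`, `treated`, `control`
#'   (both [expression_matrix()] objects).
#' @export
generate_compound_library <- function(cfg, truth = ground_truth(cfg)) {
  validate_config(cfg)
  check_truth(cfg, truth)
  genes <- gene_universe(cfg)
  mu <- baseline_means(cfg)
  effects <- compound_effects(cfg, truth)
  grid <- condition_grid(cfg)
  n_arm <- cfg$samples_per_arm %||% 5L
  out <- list()
  for (i in seq_along(effects)) {
    cpd <- names(effects)[i]
    for (k in seq_len(nrow(grid))) {
      scale <- if (grid$dose[k] == "high") cfg$effect_size else cfg$effect_size / 2
      mu_trt <- mu * 2 ^ (effects[[i]] * scale)
      set.seed(entity_seed(cfg$seed, 10000L + 64L * i + k))
      trt <- nb_matrix(mu_trt, n_arm, cfg$dispersion, "t")
      ctl <- nb_matrix(mu, n_arm, cfg$dispersion, "c")
      rownames(trt) <- rownames(ctl) <- genes
      key <- paste(cpd, grid$condition[k], sep = "|")
      out[[key]] <- list(
        compound = cpd, condition = grid$condition[k],
        cell = grid$cell[k], dose = grid$dose[k],
        treated = expression_matrix(trt, rep("treated", n_arm)),
        control = expression_matrix(ctl, rep("control", n_arm)))
    }
  }
  out
}

check_truth <- function(cfg, truth) {
  if (!inherits(truth, "ground_truth"))
    stop_sigrev("truth must be a ground_truth object", "sigrev_consistency_error")
  if (!all(truth$effect_genes %in% gene_universe(cfg)))
    stop_sigrev("ground truth refers to genes outside the configured universe",
                "sigrev_consistency_error")
  if (!setequal(names(truth$effect_directions), truth$effect_genes))
    stop_sigrev("effect directions must cover exactly the effect genes",
                "sigrev_consistency_error")
  invisible(truth)
}

#' Generate the disease expression library
#'
#' The target disease's effect genes are exactly the planted compound's,
#' with opposite directions and magnitude `reversal_strength * effect_size`;
#' decoy diseases draw independent effect genes and directions of the same
#' magnitude. Cohorts default to 12 cases vs 5 controls (emulating a small
#' NASH biopsy cohort) unless `samples_per_arm` is set in the configuration.
#'
#' @param cfg a `synthetic_config`.
#' @param truth the `ground_truth` produced from the same configuration.
#' @return named list (key = disease id) of lists with elements `disease`,
#'   `case`, `control` ([expression_matrix()] objects; cases carry group
#'   label "treated" so they slot directly into [differential_signature()]).
#' @export
generate_disease_library <- function(cfg, truth = ground_truth(cfg)) {
  validate_config(cfg)
  check_truth(cfg, truth)
  genes <- gene_universe(cfg)
  mu <- baseline_means(cfg)
  n_case <- cfg$samples_per_arm %||% 12L
  n_ctl <- cfg$samples_per_arm %||% 5L
  magnitude <- cfg$reversal_strength * cfg$effect_size
  out <- list()
  for (i in seq_len(cfg$n_diseases)) {
    dis <- disease_ids(cfg)[i]
    delta <- numeric(cfg$n_genes)
    if (i == 1L) {
      idx <- match(truth$effect_genes, genes)
      delta[idx] <- -unname(truth$effect_directions) * magnitude
    } else {
      set.seed(entity_seed(cfg$seed, 5000L + i))
      idx <- sort(sample.int(cfg$n_genes, cfg$n_effect_genes))
      delta[idx] <- ifelse(stats::runif(cfg$n_effect_genes) < 0.5, -1, 1) * magnitude
    }
    mu_case <- mu * 2 ^ delta
    set.seed(entity_seed(cfg$seed, 20000L + i))
    case <- nb_matrix(mu_case, n_case, cfg$dispersion, "case")
    ctl <- nb_matrix(mu, n_ctl, cfg$dispersion, "ctl")
    rownames(case) <- rownames(ctl) <- genes
    out[[dis]] <- list(disease = dis,
                       case = expression_matrix(case, rep("treated", n_case)),
                       control = expression_matrix(ctl, rep("control", n_ctl)))
  }
  out
}
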