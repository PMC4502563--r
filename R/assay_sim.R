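# log-normal draws parameterized by arithmetic mean and CV; cv = 0 is exact
rlnorm_cv <- function(n, mean, cv) {
  if (mean <= 0 || cv <= 0) return(rep(mean, n))
  sdl <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = log(mean) - sdl^2 / 2, sdlog = sdl)
}

#' ELISA simulation parameters
#'
#' Defaults are the pipeline's study conditions: moderate between-experiment
#' variation (CV 0.2) as seen across independent transfections, tight
#' duplicate noise (CV 0.05) typical of a commercial sandwich ELISA, and a
#' small additive matrix immunoreactive background (mean 5 ng/ml on a total
#' CLU of 200 ng/ml), genotype-independent, as observed in nontransfected
#' wells.
#'
#' @param total_clu_mean mean total CLU per experiment (ng/ml).
#' @param between_experiment_cv CV of the log-normal experiment totals.
#' @param replicate_cv CV of the multiplicative duplicate noise.
#' @param matrix_background_mean mean additive matrix background (ng/ml).
#' @param matrix_background_cv CV of the matrix-background draws.
#' @param normalizer_mean mean TGF-beta1 response (reference level).
#' @param normalizer_cv CV of the TGF-beta1 draws.
#' @return a named list.
#' @export
assay_params <- function(total_clu_mean = 200, between_experiment_cv = 0.2,
                         replicate_cv = 0.05, matrix_background_mean = 5,
                         matrix_background_cv = 0.1,
                         normalizer_mean = 100, normalizer_cv = 0.1) {
  p <- as.list(environment())
  if (any(unlist(p[c("between_experiment_cv", "replicate_cv",
                     "matrix_background_cv", "normalizer_cv")]) < 0)) {
    ct_abort("CVs must be >= 0", "parameter")
  }
  if (total_clu_mean <= 0 || normalizer_mean <= 0) {
    ct_abort("means must be > 0", "parameter")
  }
  p
}

#' Simulate a CM/CL ELISA assay table with known ground truth
#'
#' Per experiment a total CLU amount is drawn log-normally around
#' `total_clu_mean`; each genotype splits it into conditioned medium (CM) and
#' cell lysate (CL) according to its `true_secreted_fraction` `f`
#' (`CM = f * T`, `CL = (1 - f) * T`). Observed concentrations are the true
#' level scaled by the well's relative TGF-beta1 response, perturbed by
#' multiplicative duplicate noise, plus an additive matrix-background draw.
#' Nontransfected control wells carry matrix background only and are included
#' for every experiment and compartment.
#'
#' @param phenotypes list of [genotype_phenotype()] (or data frame rows).
#' @param n_experiments number of independent experiments (>= 1).
#' @param n_replicates wells per (experiment, genotype, compartment).
#' @param params see [assay_params()].
#' @param seed integer RNG seed.
#' @return a tibble with columns `experiment_id`, `genotype`, `compartment`
#'   (`"CM"`/`"CL"`), `replicate`, `concentration`, `normalizer`.
#' @export
simulate_assay <- function(phenotypes, n_experiments = 3L, n_replicates = 2L,
                           params = assay_params(), seed = 1L) {
  if (n_experiments < 1) ct_abort("n_experiments must be >= 1", "parameter")
  if (n_replicates < 1) ct_abort("n_replicates must be >= 1", "parameter")
  phenotypes <- as_phenotype_list(phenotypes)
  withr::with_seed(as.integer(seed), {
    totals <- rlnorm_cv(n_experiments, params$total_clu_mean,
                        params$between_experiment_cv)
    grid <- tidyr::expand_grid(
      experiment_id = seq_len(n_experiments),
      genotype = c(vapply(phenotypes, `[[`, "", "name"), "nontransfected"),
      compartment = c("CM", "CL"),
      replicate = seq_len(n_replicates))
    f_by_geno <- setNames(vapply(phenotypes, `[[`, 0, "true_secreted_fraction"),
                          vapply(phenotypes, `[[`, "", "name"))
    n <- nrow(grid)
    normalizer <- rlnorm_cv(n, params$normalizer_mean, params$normalizer_cv)
    rep_factor <- pmax(0, 1 + rnorm(n, 0, params$replicate_cv))
    background <- rlnorm_cv(n, params$matrix_background_mean,
                            params$matrix_background_cv)
    truth <- ifelse(
      grid$genotype == "nontransfected", 0,
      totals[grid$experiment_id] *
        ifelse(grid$compartment == "CM",
               f_by_geno[grid$genotype], 1 - f_by_geno[grid$genotype]))
    conc <- truth * (normalizer / params$normalizer_mean) * rep_factor + background
    tibble::tibble(
      experiment_id = grid$experiment_id, genotype = grid$genotype,
      compartment = grid$compartment, replicate = grid$replicate,
      concentration = conc, normalizer = normalizer)
  })
}

#' Western-blot simulation parameters
#'
#' @param total_intensity_mean mean total band intensity per experiment (AU).
#' @param between_experiment_cv CV of the log-normal experiment totals.
#' @param band_cv CV of the multiplicative band-intensity noise.
#' @param tubulin_mean mean alpha-tubulin loading-control intensity (AU).
#' @param tubulin_cv CV of the tubulin draws.
#' @return a named list.
#' @export
western_params <- function(total_intensity_mean = 1e5, between_experiment_cv = 0.2,
                           band_cv = 0.05, tubulin_mean = 5e4, tubulin_cv = 0.1) {
  p <- as.list(environment())
  if (any(unlist(p[c("between_experiment_cv", "band_cv", "tubulin_cv")]) < 0)) {
    ct_abort("CVs must be >= 0", "parameter")
  }
  if (total_intensity_mean <= 0 || tubulin_mean <= 0) {
    ct_abort("means must be > 0", "parameter")
  }
  p
}

#' Simulate western-blot band intensities in CM and CL
#'
#' One record per (experiment, genotype, compartment): the experiment total
#' splits into CM/CL by the genotype's true secreted fraction, with
#' multiplicative band noise; the alpha-tubulin loading control is drawn
#' around a common mean.
#'
#' @inheritParams simulate_assay
#' @param params see [western_params()].
#' @return a tibble with columns `experiment_id`, `genotype`, `compartment`,
#'   `band_intensity`, `tubulin_intensity`.
#' @export
simulate_western <- function(phenotypes, n_experiments = 3L,
                             params = western_params(), seed = 1L) {
  if (n_experiments < 1) ct_abort("n_experiments must be >= 1", "parameter")
  phenotypes <- as_phenotype_list(phenotypes)
  withr::with_seed(as.integer(seed), {
    totals <- rlnorm_cv(n_experiments, params$total_intensity_mean,
                        params$between_experiment_cv)
    grid <- tidyr::expand_grid(
      experiment_id = seq_len(n_experiments),
      genotype = vapply(phenotypes, `[[`, "", "name"),
      compartment = c("CM", "CL"))
    f_by_geno <- setNames(vapply(phenotypes, `[[`, 0, "true_secreted_fraction"),
                          vapply(phenotypes, `[[`, "", "name"))
    n <- nrow(grid)
    band <- totals[grid$experiment_id] *
      ifelse(grid$compartment == "CM",
             f_by_geno[grid$genotype], 1 - f_by_geno[grid$genotype]) *
      pmax(0, 1 + rnorm(n, 0, params$band_cv))
    tubulin <- rlnorm_cv(n, params$tubulin_mean, params$tubulin_cv)
    tibble::tibble(
      experiment_id = grid$experiment_id, genotype = grid$genotype,
      compartment = grid$compartment, band_intensity = band,
      tubulin_intensity = tubulin)
  })
}

#' Read or write assay tables as CSV
#'
#' Plain CSV with the canonical header
#' `experiment_id,genotype,compartment,replicate,concentration,normalizer`
#' (ELISA) or
#' `experiment_id,genotype,compartment,band_intensity,tubulin_intensity`
#' (western).
#'
#' @param table a tibble as returned by [simulate_assay()] /
#'   [simulate_western()].
#' @param path file path.
#' @return `write_assay_csv` returns `path` invisibly; `read_assay_csv`
#'   returns a tibble.
#' @export
write_assay_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_assay_csv
#' @export
read_assay_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
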