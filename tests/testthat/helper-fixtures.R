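# shared fixtures, built in code at test time

wt_like <- function() genotype_phenotype("wt", golgi_enrichment = 6,
                                         er_retention = 1, vesicle_density = 15,
                                         true_secreted_fraction = 0.91)
er_retained <- function() genotype_phenotype("mut", golgi_enrichment = 1,
                                             er_retention = 3, vesicle_density = 2,
                                             true_secreted_fraction = 0.15)

zero_noise <- function() scene_noise(background_level = 50, background_sd = 0,
                                     shot_scale = 0)

# one default-noise field reused across tests (built once per test run)
.fixture_env <- new.env(parent = emptyenv())
default_scene <- function() {
  if (is.null(.fixture_env$scene)) {
    .fixture_env$scene <- make_scene(
      6, list(wt_like(), er_retained()), image_shape = c(320L, 320L),
      seed = 101L)
  }
  .fixture_env$scene
}

# noiseless ELISA parameters
noiseless_params <- function(background = 0) {
  assay_params(between_experiment_cv = 0, replicate_cv = 0,
               matrix_background_mean = background, matrix_background_cv = 0,
               normalizer_cv = 0)
}
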