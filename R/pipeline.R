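#' Default pipeline configuration
#'
#' A nested list describing one end-to-end run: which genotypes are imaged
#' (HeLa fields) and assayed (HEK Flp-In ELISA), the field geometry and noise,
#' the assay design (3 experiments, duplicates), and the analysis parameters
#' (Golgi size filter, exclusion-cutoff rule, outlier multiplier, alpha,
#' number of constructs for Bonferroni, pseudo-count total for the CMH
#' strata). Amend fields before passing to [run_pipeline()], or load
#' overrides from YAML with [read_config()].
#'
#' @param seed master seed; per-stage streams are derived from it so that
#'   disabling one stage does not shift another stage's draws.
#' @return a config list.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    images = list(
      genotypes = c("wt", "p.R338W", "p.I360N"),
      cell_line = "HeLa",
      n_fields = 3L, cells_per_field = 8L, image_shape = c(400L, 400L),
      noise = scene_noise(), geometry = scene_geometry(cell_radius = 24)),
    assay = list(
      genotypes = c("wt", "p.R338W", "p.I360N"),
      cell_line = "HEK Flp-In",
      n_experiments = 3L, n_replicates = 2L, params = assay_params()),
    analysis = list(
      reference = "wt", min_object_px = 20L, cutoff_k = 2,
      outlier_k = 3, alpha = 0.05, m_constructs = 11L, pseudo_n = 1000L)
  )
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file and merges it over [default_config()]; nested keys
#' override individually.
#'
#' @param path YAML file path.
#' @return a config list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_lists(default_config(), user)
}

merge_lists <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(base[[nm]]) && is.list(over[[nm]])) {
      base[[nm]] <- merge_lists(base[[nm]], over[[nm]])
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  base
}

write_stamped_csv <- function(df, path, stamp) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# clutraffic seed=%d config_hash=%s", stamp$seed,
                     stamp$hash), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full simulate-quantify-compare pipeline
#'
#' Simulates imaging fields and an ELISA assay for the configured genotypes,
#' quantifies every cell (Golgi enrichment ratio, ER Pearson, exclusion),
#' applies the secretion corrections (matrix-background subtraction,
#' TGF-beta1 normalization, compartment fractions), and runs the statistical
#' layer (pooled outlier removal, Tukey HSD vs wild type, CMH odds ratios per
#' mutant, Bonferroni thresholding). Deterministic given (config, seed):
#' each stage draws from its own seed stream derived from the master seed.
#'
#' @param config a config list (see [default_config()]).
#' @param out_dir output directory; if non-NULL, `cells.csv`,
#'   `secretion_estimates.csv`, `comparisons.csv` and `summary.json` are
#'   written there, each stamped with the seed and a config hash. On any
#'   stage error, partial outputs are removed.
#' @param verbose log stage boundaries and record counts.
#' @return a list with `cells`, `fractions`, `comparisons`, `summary`,
#'   `seed`, `config_hash`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL,
                         verbose = FALSE) {
  stamp <- list(seed = config$seed, hash = rlang::hash(config))
  say <- function(...) if (verbose) message(sprintf(...))
  written <- character()
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fail <- function(stage, e) {
    unlink(written)
    ct_abort(sprintf("pipeline stage '%s' failed: %s", stage,
                     conditionMessage(e)), "pipeline")
  }

  cells <- tryCatch({
    img <- config$images
    phen <- get_phenotypes(img$genotypes, img$cell_line)
    seeds <- stage_seed(config$seed, "images") + seq_len(img$n_fields) - 1L
    rows <- lapply(seq_len(img$n_fields), function(fi) {
      sc <- make_scene(img$cells_per_field, phen,
                       image_shape = img$image_shape, noise = img$noise,
                       geometry = img$geometry, seed = seeds[fi])
      quantify_scene(sc, min_object_px = config$analysis$min_object_px,
                     cutoff_k = config$analysis$cutoff_k,
                     image_id = sprintf("field%02d", fi))
    })
    dplyr::bind_rows(rows)
  }, error = function(e) fail("images", e))
  say("images: %d cells measured, %d excluded", nrow(cells), sum(cells$excluded))

  fractions <- tryCatch({
    asy <- config$assay
    phen <- get_phenotypes(asy$genotypes, asy$cell_line)
    tab <- simulate_assay(phen, asy$n_experiments, asy$n_replicates,
                          asy$params, seed = stage_seed(config$seed, "elisa"))
    tab |> subtract_matrix_background() |> normalize_by_tgfb() |>
      compartment_fractions()
  }, error = function(e) fail("elisa", e))
  say("elisa: %d estimate rows", nrow(fractions))

  comparisons <- tryCatch({
    compare_genotypes(cells, fractions,
                      reference = config$analysis$reference,
                      alpha = config$analysis$alpha,
                      m = config$analysis$m_constructs,
                      k = config$analysis$outlier_k,
                      pseudo_n = config$analysis$pseudo_n)
  }, error = function(e) fail("compare", e))
  say("compare: %d comparison rows", nrow(comparisons))

  summary_list <- list(
    seed = stamp$seed, config_hash = stamp$hash,
    n_cells = nrow(cells), n_excluded = sum(cells$excluded),
    per_genotype = cells |>
      dplyr::filter(!.data$excluded) |>
      dplyr::group_by(.data$genotype) |>
      dplyr::summarise(
        n = dplyr::n(),
        golgi_ratio_median = median(.data$golgi_ratio, na.rm = TRUE),
        golgi_ratio_q1 = quantile(.data$golgi_ratio, 0.25, na.rm = TRUE,
                                  names = FALSE),
        golgi_ratio_q3 = quantile(.data$golgi_ratio, 0.75, na.rm = TRUE,
                                  names = FALSE),
        pearson_er_median = median(.data$pearson_er, na.rm = TRUE),
        .groups = "drop"),
    cm_cl_proportions = fractions |>
      dplyr::filter(.data$level == "pooled") |>
      dplyr::transmute(.data$genotype, cm_pct = 100 * .data$cm_fraction,
                       cl_pct = 100 * (1 - .data$cm_fraction)),
    significance = comparisons |>
      dplyr::select("genotype", "metric", "p_raw", "significant"))

  if (!is.null(out_dir)) {
    tryCatch({
      written <<- c(
        write_stamped_csv(cells, file.path(out_dir, "cells.csv"), stamp),
        write_stamped_csv(fractions,
                          file.path(out_dir, "secretion_estimates.csv"), stamp),
        write_stamped_csv(comparisons,
                          file.path(out_dir, "comparisons.csv"), stamp))
      jsonlite::write_json(summary_list,
                           file.path(out_dir, "summary.json"),
                           auto_unbox = TRUE, digits = NA, dataframe = "rows")
      written <<- c(written, file.path(out_dir, "summary.json"))
    }, error = function(e) fail("write", e))
  }

  list(cells = cells, fractions = fractions, comparisons = comparisons,
       summary = summary_list, seed = stamp$seed, config_hash = stamp$hash)
}
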