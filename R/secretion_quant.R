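#' Subtract the matrix immunoreactive background
#'
#' The background is the mean concentration of all nontransfected control
#' wells, pooled across experiments; it is subtracted from every non-control
#' concentration. Corrected values below zero are clamped to zero with a
#' warning (negative concentrations are physically meaningless). Control
#' records are removed from the output.
#'
#' @param table an assay tibble as from [simulate_assay()] /
#'   [read_assay_csv()].
#' @param control_label genotype label of the control wells.
#' @return the corrected tibble without control rows.
#' @export
subtract_matrix_background <- function(table, control_label = "nontransfected") {
  is_ctrl <- table$genotype == control_label
  if (!any(is_ctrl)) {
    ct_abort(sprintf("no '%s' control records present", control_label),
             "missing_control")
  }
  background <- mean(table$concentration[is_ctrl])
  out <- table[!is_ctrl, , drop = FALSE]
  corrected <- out$concentration - background
  n_neg <- sum(corrected < 0)
  if (n_neg > 0) {
    rlang::warn(sprintf(
      "%d corrected concentration(s) below zero clamped to 0", n_neg))
  }
  out$concentration <- pmax(corrected, 0)
  out
}

#' Normalize concentrations by the TGF-beta1 response
#'
#' Each concentration is divided by the well's relative normalizer,
#' `normalizer / grand-mean normalizer`, so units are preserved and a well
#' whose TGF-beta1 response ran high is scaled down proportionally. Applied
#' to all records (both compartments).
#'
#' @param table an assay tibble with a strictly positive `normalizer` column.
#' @return the normalized tibble.
#' @export
normalize_by_tgfb <- function(table) {
  bad <- which(!is.finite(table$normalizer) | table$normalizer <= 0)
  if (length(bad) > 0) {
    ct_abort(sprintf("non-positive normalizer in record(s) %s",
                     paste(utils::head(bad, 5), collapse = ", ")), "data")
  }
  ref <- mean(table$normalizer)
  table$concentration <- table$concentration / (table$normalizer / ref)
  table
}

#' Per-genotype secreted fractions from a corrected assay table
#'
#' Replicates are averaged within (genotype, experiment, compartment); the
#' per-experiment CM fraction is `CM / (CM + CL)`, and the pooled fraction is
#' the ratio of summed amounts across experiments (a single stacked bar per
#' genotype).
#'
#' @param table a corrected, normalized assay tibble.
#' @return a tibble with one row per (genotype, experiment) plus one pooled
#'   row per genotype: columns `genotype`, `level` (`"experiment"` /
#'   `"pooled"`), `experiment_id` (`NA` for pooled), `cm_amount`,
#'   `cl_amount`, `cm_fraction`, `n_experiments`.
#' @export
compartment_fractions <- function(table) {
  wide <- table |>
    dplyr::group_by(.data$genotype, .data$experiment_id, .data$compartment) |>
    dplyr::summarise(amount = mean(.data$concentration), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "compartment", values_from = "amount")
  if (!all(c("CM", "CL") %in% names(wide)) || anyNA(wide$CM) || anyNA(wide$CL)) {
    ct_abort("both CM and CL must be present for every (genotype, experiment)",
             "incomplete_pair")
  }
  per_exp <- wide |>
    dplyr::transmute(
      genotype = .data$genotype, level = "experiment",
      experiment_id = .data$experiment_id,
      cm_amount = .data$CM, cl_amount = .data$CL,
      cm_fraction = .data$CM / (.data$CM + .data$CL))
  pooled <- per_exp |>
    dplyr::group_by(.data$genotype) |>
    dplyr::summarise(level = "pooled", experiment_id = NA_integer_,
                     cm_amount = sum(.data$cm_amount),
                     cl_amount = sum(.data$cl_amount),
                     n_experiments = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(cm_fraction = .data$cm_amount /
                    (.data$cm_amount + .data$cl_amount))
  per_exp |>
    dplyr::left_join(
      dplyr::distinct(pooled, .data$genotype, .data$n_experiments),
      by = "genotype") |>
    dplyr::bind_rows(pooled) |>
    dplyr::arrange(.data$genotype, .data$level, .data$experiment_id)
}

#' Pooled CM fraction of one genotype
#'
#' Convenience accessor on the output of [compartment_fractions()].
#'
#' @param fractions tibble from [compartment_fractions()].
#' @param genotype genotype label.
#' @return the pooled CM fraction (scalar in `[0, 1]`).
#' @export
pooled_cm_fraction <- function(fractions, genotype) {
  row <- fractions[fractions$genotype == genotype & fractions$level == "pooled", ]
  if (nrow(row) != 1L) ct_abort(sprintf("no pooled row for '%s'", genotype),
                                "parameter")
  row$cm_fraction
}

#' Western-blot CM/CL fractions and log-rescaled intensities
#'
#' Band intensities are first normalized by the alpha-tubulin loading
#' control (`intensity = band / tubulin`); CM/CL fractions then follow
#' [compartment_fractions()], and each normalized intensity is additionally
#' log2-rescaled against the wild-type intensity of the same experiment and
#' compartment (wild type maps to 0).
#'
#' @param table a western tibble as from [simulate_western()].
#' @param wt_label wild-type genotype label.
#' @return a list with `fractions` (as in [compartment_fractions()]) and
#'   `log_rescaled` (tibble with `experiment_id`, `genotype`, `compartment`,
#'   `norm_intensity`, `log2_vs_wt`).
#' @export
western_fractions <- function(table, wt_label = "wt") {
  if (!wt_label %in% table$genotype) {
    ct_abort(sprintf("reference genotype '%s' absent", wt_label), "reference")
  }
  if (any(table$tubulin_intensity <= 0)) {
    ct_abort("tubulin intensities must be strictly positive", "data")
  }
  norm <- table |>
    dplyr::mutate(norm_intensity = .data$band_intensity / .data$tubulin_intensity)
  wt <- norm |>
    dplyr::filter(.data$genotype == wt_label) |>
    dplyr::select("experiment_id", "compartment",
                  wt_intensity = "norm_intensity")
  log_rescaled <- norm |>
    dplyr::left_join(wt, by = c("experiment_id", "compartment")) |>
    dplyr::mutate(log2_vs_wt = log2(.data$norm_intensity / .data$wt_intensity)) |>
    dplyr::select("experiment_id", "genotype", "compartment",
                  "norm_intensity", "log2_vs_wt")
  fractions <- norm |>
    dplyr::transmute(.data$experiment_id, .data$genotype, .data$compartment,
                     replicate = 1L, concentration = .data$norm_intensity) |>
    compartment_fractions()
  list(fractions = fractions, log_rescaled = log_rescaled)
}
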