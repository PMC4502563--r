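toy_table <- function(conc, genotype = "wt", experiment = 1L, compartment = "CM",
                      normalizer = 100) {
  n <- length(conc)
  tibble::tibble(experiment_id = rep_len(experiment, n),
                 genotype = rep_len(genotype, n),
                 compartment = rep_len(compartment, n),
                 replicate = seq_len(n),
                 concentration = conc,
                 normalizer = rep_len(normalizer, n))
}

test_that("matrix background subtraction follows the pooled control mean", {
  tab <- dplyr::bind_rows(
    toy_table(c(2, 4, 6), genotype = "nontransfected", experiment = 1:3),
    toy_table(10, genotype = "wt"))
  out <- subtract_matrix_background(tab)
  expect_identical(out$genotype, "wt")
  expect_equal(out$concentration, 10 - 4)

  # all samples at the control mean correct to zero
  tab2 <- dplyr::bind_rows(
    toy_table(c(4, 4), genotype = "nontransfected"),
    toy_table(c(4, 4), genotype = "wt"))
  expect_equal(subtract_matrix_background(tab2)$concentration, c(0, 0))

  # zero controls leave samples untouched
  tab3 <- dplyr::bind_rows(
    toy_table(c(0, 0), genotype = "nontransfected"),
    toy_table(c(7, 9), genotype = "wt"))
  expect_equal(subtract_matrix_background(tab3)$concentration, c(7, 9))

  expect_error(subtract_matrix_background(toy_table(1)),
               class = "clutraffic_error_missing_control")
  expect_warning(subtract_matrix_background(dplyr::bind_rows(
    toy_table(10, genotype = "nontransfected"), toy_table(2, "wt"))),
    "clamped")
})

test_that("TGF-beta1 normalization divides by the relative normalizer", {
  tab <- toy_table(c(10, 10, 10), normalizer = 100)
  expect_equal(normalize_by_tgfb(tab)$concentration, c(10, 10, 10))

  # a record whose normalizer is twice the grand mean is halved
  tab2 <- toy_table(rep(10, 4))
  tab2$normalizer <- c(300, 100, 100, 100) # grand mean 150
  out <- normalize_by_tgfb(tab2)
  expect_equal(out$concentration[1], 5)
  expect_equal(out$concentration, 10 / (tab2$normalizer / 150))

  set.seed(8)
  tab3 <- toy_table(runif(20, 1, 50), normalizer = 1)
  tab3$normalizer <- runif(20, 50, 150)
  out3 <- normalize_by_tgfb(tab3)
  expect_lt(max(abs(out3$concentration -
                      tab3$concentration / (tab3$normalizer / mean(tab3$normalizer)))),
            1e-12)

  bad <- toy_table(1, normalizer = -1)
  expect_error(normalize_by_tgfb(bad), class = "clutraffic_error_data")
})

test_that("compartment fractions average replicates and pool by summed amounts", {
  tab <- dplyr::bind_rows(
    toy_table(c(10, 12), "wt", 1L, "CM"), toy_table(c(10, 12), "wt", 1L, "CL"),
    toy_table(c(4, 6), "wt", 2L, "CM"), toy_table(c(4, 6), "wt", 2L, "CL"))
  fr <- compartment_fractions(tab)
  expect_true(all(fr$cm_fraction == 0.5))

  tab_cl0 <- dplyr::bind_rows(
    toy_table(c(8, 8), "wt", 1L, "CM"), toy_table(c(0, 0), "wt", 1L, "CL"))
  expect_true(all(compartment_fractions(tab_cl0)$cm_fraction == 1))

  # pooled fraction is the ratio of totals, not the mean of ratios
  tab_mix <- dplyr::bind_rows(
    toy_table(90, "wt", 1L, "CM"), toy_table(10, "wt", 1L, "CL"),
    toy_table(10, "wt", 2L, "CM"), toy_table(90, "wt", 2L, "CL"))
  fr_mix <- compartment_fractions(tab_mix)
  expect_equal(pooled_cm_fraction(fr_mix, "wt"), (90 + 10) / 200)

  expect_error(compartment_fractions(toy_table(5, "wt", 1L, "CM")),
               class = "clutraffic_error_incomplete_pair")
})

test_that("CM and CL fractions sum to one for every estimate", {
  tab <- simulate_assay(list(wt_like(), er_retained()), seed = 12) |>
    subtract_matrix_background() |> normalize_by_tgfb()
  fr <- compartment_fractions(tab)
  cl_fraction <- fr$cl_amount / (fr$cm_amount + fr$cl_amount)
  expect_equal(fr$cm_fraction + cl_fraction, rep(1, nrow(fr)))
})

test_that("noise-free corrections preserve genotype ranking by CM fraction", {
  ph <- list(genotype_phenotype("a", true_secreted_fraction = 0.2),
             genotype_phenotype("b", true_secreted_fraction = 0.5),
             genotype_phenotype("c", true_secreted_fraction = 0.8))
  tab <- simulate_assay(ph, params = noiseless_params(background = 5), seed = 1)
  fr <- tab |> subtract_matrix_background() |> normalize_by_tgfb() |>
    compartment_fractions()
  pooled <- fr[fr$level == "pooled", ]
  expect_identical(pooled$genotype[order(pooled$cm_fraction)], c("a", "b", "c"))
})

test_that("western quantification log2-rescales against wild type", {
  tab <- tibble::tibble(
    experiment_id = rep(1L, 4),
    genotype = rep(c("wt", "mut"), each = 2),
    compartment = rep(c("CM", "CL"), 2),
    band_intensity = c(80, 20, 20, 20),
    tubulin_intensity = rep(10, 4))
  wf <- western_fractions(tab, "wt")
  wt_rows <- wf$log_rescaled[wf$log_rescaled$genotype == "wt", ]
  expect_true(all(wt_rows$log2_vs_wt == 0))
  mut_cm <- wf$log_rescaled[wf$log_rescaled$genotype == "mut" &
                              wf$log_rescaled$compartment == "CM", ]
  expect_equal(mut_cm$log2_vs_wt, log2(20 / 80)) # quarter of wt -> -2
  expect_equal(mut_cm$log2_vs_wt, -2)

  ident <- tab; ident$band_intensity <- rep(c(80, 20), 2)
  wf2 <- western_fractions(ident, "wt")
  expect_true(all(wf2$log_rescaled$log2_vs_wt == 0))

  expect_error(western_fractions(tab[tab$genotype == "mut", ], "wt"),
               class = "clutraffic_error_reference")
})
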