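#' Construct a genotype phenotype
#'
#' A `genotype_phenotype` bundles the axes along which CLU trafficking
#' genotypes differ in this pipeline: how strongly the reporter is enriched
#' in the Golgi relative to the ER, how strongly it is retained in the ER
#' relative to the general cytoplasm, the expected number of cytoplasmic
#' vesicle puncta per cell, and the true fraction of total CLU exported to
#' the conditioned medium.
#'
#' @param name genotype label, e.g. `"wt"` or `"p.R338W"`.
#' @param golgi_enrichment reporter intensity multiplier in the Golgi
#'   relative to the ER (dimensionless, >= 0).
#' @param er_retention reporter intensity multiplier in the ER relative to
#'   the general cytoplasm (dimensionless, >= 0).
#' @param vesicle_density expected vesicle puncta per cell (>= 0).
#' @param true_secreted_fraction fraction of total CLU in conditioned medium,
#'   in `[0, 1]`.
#' @return an object of class `genotype_phenotype` (a named list).
#' @export
genotype_phenotype <- function(name, golgi_enrichment = 1, er_retention = 1,
                               vesicle_density = 0, true_secreted_fraction = 0.5) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  num_ok <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0
  if (!num_ok(golgi_enrichment) || !num_ok(er_retention) || !num_ok(vesicle_density)) {
    ct_abort("phenotype multipliers must be finite and non-negative", "parameter")
  }
  if (!num_ok(true_secreted_fraction) || true_secreted_fraction > 1) {
    ct_abort("true_secreted_fraction must lie in [0, 1]", "parameter")
  }
  structure(
    list(name = name, golgi_enrichment = golgi_enrichment,
         er_retention = er_retention, vesicle_density = vesicle_density,
         true_secreted_fraction = true_secreted_fraction),
    class = "genotype_phenotype"
  )
}

#' @export
print.genotype_phenotype <- function(x, ...) {
  cat(sprintf(
    "<genotype_phenotype> %s: golgi_enrichment=%g, er_retention=%g, vesicles=%g, secreted=%g\n",
    x$name, x$golgi_enrichment, x$er_retention, x$vesicle_density,
    x$true_secreted_fraction))
  invisible(x)
}

#' Packaged CLU genotype-phenotype table
#'
#' The study conditions the pipeline ships with. Imaging rows (HeLa) encode
#' the qualitative trafficking phenotypes: wild type accumulates the reporter
#' in a perinuclear Golgi zone with weak ER signal and cytoplasmic vesicles;
#' the ER-retained beta-chain mutants (p.I303NfsX13, p.R338W, p.I360N) lose
#' Golgi enrichment and show near-exclusive ER signal. Secretion rows (HEK
#' Flp-In and HEK293T) carry the true secreted fractions used as generator
#' ground truth: 0.91 / 0.68 / 0.15 for wt / p.R338W / p.I360N in Flp-In
#' cells, and 0.766 / 0.528 / 0.123 in HEK293T cells.
#'
#' @return a tibble with columns `name`, `cell_line`, `golgi_enrichment`,
#'   `er_retention`, `vesicle_density`, `true_secreted_fraction`.
#' @export
clu_phenotypes <- function() {
  tibble::tribble(
    ~name,           ~cell_line,   ~golgi_enrichment, ~er_retention, ~vesicle_density, ~true_secreted_fraction,
    "wt",            "HeLa",       6,                 1,             15,               0.91,
    "p.I303NfsX13",  "HeLa",       1,                 3,             2,                0.15,
    "p.R338W",       "HeLa",       1,                 3,             2,                0.68,
    "p.I360N",       "HeLa",       1,                 3,             2,                0.15,
    "wt",            "HEK Flp-In", 6,                 1,             15,               0.91,
    "p.R338W",       "HEK Flp-In", 1,                 3,             2,                0.68,
    "p.I360N",       "HEK Flp-In", 1,                 3,             2,                0.15,
    "wt",            "HEK293T",    6,                 1,             15,               0.766,
    "p.R338W",       "HEK293T",    1,                 3,             2,                0.528,
    "p.I360N",       "HEK293T",    1,                 3,             2,                0.123
  )
}

#' Look up packaged phenotypes for one cell line
#'
#' @param genotypes character vector of genotype names.
#' @param cell_line one of `"HeLa"`, `"HEK Flp-In"`, `"HEK293T"`.
#' @return a list of [genotype_phenotype()] objects.
#' @export
get_phenotypes <- function(genotypes, cell_line = "HEK Flp-In") {
  tab <- clu_phenotypes()
  lapply(genotypes, function(g) {
    row <- tab[tab$name == g & tab$cell_line == cell_line, ]
    if (nrow(row) != 1L) {
      ct_abort(sprintf("no packaged phenotype for genotype '%s' in cell line '%s'",
                       g, cell_line), "parameter")
    }
    genotype_phenotype(row$name, row$golgi_enrichment, row$er_retention,
                       row$vesicle_density, row$true_secreted_fraction)
  })
}

as_phenotype_list <- function(phenotypes) {
  if (inherits(phenotypes, "genotype_phenotype")) phenotypes <- list(phenotypes)
  if (is.data.frame(phenotypes)) {
    phenotypes <- lapply(seq_len(nrow(phenotypes)), function(i) {
      genotype_phenotype(phenotypes$name[i], phenotypes$golgi_enrichment[i],
                         phenotypes$er_retention[i], phenotypes$vesicle_density[i],
                         phenotypes$true_secreted_fraction[i])
    })
  }
  stopifnot(length(phenotypes) >= 1L,
            all(vapply(phenotypes, inherits, TRUE, "genotype_phenotype")))
  phenotypes
}
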