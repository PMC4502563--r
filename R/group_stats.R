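#' Single-pass 3-SD outlier removal
#'
#' Mean and standard deviation are computed once on the full list; values
#' farther than `k` standard deviations from that mean are removed. A second
#' pass with the original mean/sd would remove nothing (single-pass
#' contract). With zero spread nothing is removed.
#'
#' @param values numeric vector (length >= 3).
#' @param k multiplier on the standard deviation (default 3).
#' @return a list with `kept` (values retained, order preserved) and
#'   `removed` (integer indices of removed values).
#' @export
remove_outliers <- function(values, k = 3) {
  stopifnot(length(values) >= 3L, k > 0)
  m <- mean(values); s <- stats::sd(values)
  if (!is.finite(s) || s == 0) {
    return(list(kept = values, removed = integer()))
  }
  removed <- which(abs(values - m) > k * s)
  list(kept = if (length(removed)) values[-removed] else values,
       removed = removed)
}

#' One-way ANOVA with Tukey HSD contrasts against a reference group
#'
#' Fits a one-way ANOVA across all groups and computes Tukey HSD adjusted
#' p-values from the studentized-range distribution (Tukey-Kramer for
#' unbalanced groups, as implemented by [stats::TukeyHSD()]). By default only
#' the contrasts against `reference` are returned; `contrasts = "all"`
#' returns the full all-pairs family. When the between-group variance is
#' degenerate (all values identical) the F statistic is undefined and all
#' contrasts are reported non-significant with `NA` p-values.
#'
#' @param groups named list mapping group label to a numeric vector
#'   (each length >= 2).
#' @param reference reference group label (e.g. `"wt"`).
#' @param contrasts `"reference"` (default) or `"all"`.
#' @return a tibble with columns `contrast`, `genotype`, `diff`, `p_tukey`,
#'   `significant_05`; attributes `f_statistic` and `f_p` carry the omnibus
#'   test.
#' @export
anova_tukey <- function(groups, reference = "wt", contrasts = c("reference", "all")) {
  contrasts <- match.arg(contrasts)
  stopifnot(is.list(groups), !is.null(names(groups)))
  if (!reference %in% names(groups)) {
    ct_abort(sprintf("reference group '%s' absent", reference), "reference")
  }
  if (any(vapply(groups, length, 0L) < 2L)) {
    ct_abort("every group needs >= 2 values", "degrees_of_freedom")
  }
  df <- data.frame(
    y = unlist(groups, use.names = FALSE),
    g = factor(rep(names(groups), vapply(groups, length, 0L)),
               levels = names(groups)))
  if (stats::sd(df$y) == 0) {
    pairs <- make_pairs(names(groups), reference, contrasts)
    return(structure(
      tibble::tibble(contrast = pairs$contrast, genotype = pairs$genotype,
                     diff = 0, p_tukey = NA_real_, significant_05 = FALSE),
      f_statistic = NA_real_, f_p = NA_real_))
  }
  fit <- stats::aov(y ~ g, data = df)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$g
  pairs <- make_pairs(names(groups), reference, contrasts)
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    key1 <- paste0(pairs$b[i], "-", pairs$a[i])
    key2 <- paste0(pairs$a[i], "-", pairs$b[i])
    if (key1 %in% rownames(tk)) {
      r <- tk[key1, ]
    } else {
      r <- tk[key2, ]; r["diff"] <- -r["diff"]
    }
    tibble::tibble(contrast = pairs$contrast[i], genotype = pairs$genotype[i],
                   diff = unname(r["diff"]), p_tukey = unname(r["p adj"]),
                   significant_05 = unname(r["p adj"]) < 0.05)
  })
  structure(dplyr::bind_rows(rows),
            f_statistic = an[["F value"]][1], f_p = an[["Pr(>F)"]][1])
}

make_pairs <- function(labels, reference, contrasts) {
  if (contrasts == "reference") {
    others <- setdiff(labels, reference)
    data.frame(a = rep(reference, length(others)), b = others,
               contrast = paste0(others, " vs ", reference),
               genotype = others, stringsAsFactors = FALSE)
  } else {
    cmb <- utils::combn(labels, 2)
    data.frame(a = cmb[1, ], b = cmb[2, ],
               contrast = paste0(cmb[2, ], " vs ", cmb[1, ]),
               genotype = cmb[2, ], stringsAsFactors = FALSE)
  }
}

#' Bonferroni significance threshold
#'
#' @param alpha family-wise error rate, in (0, 1).
#' @param m number of tests (constructs), >= 1.
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m = 11L) {
  stopifnot(alpha > 0, alpha < 1, m >= 1)
  alpha / m
}

#' Build stratified 2x2 pseudo-count tables from secretion estimates
#'
#' For each experiment stratum the wild-type and mutant CM/CL amounts are
#' rescaled so each genotype row sums to `pseudo_n`, with largest-remainder
#' rounding so row sums are exact. Rows are (reference, mutant), columns
#' (CM, CL).
#'
#' @param est_ref,est_mut [compartment_fractions()] outputs (or subsets) for
#'   the reference and mutant genotype; per-experiment rows are used.
#' @param pseudo_n integer row total per genotype per stratum.
#' @return a `2 x 2 x K` integer array with dimnames (genotype, compartment,
#'   experiment), suitable for [cmh_test()].
#' @export
build_strata <- function(est_ref, est_mut, pseudo_n = 1000L) {
  ref <- est_ref[est_ref$level == "experiment", ]
  mut <- est_mut[est_mut$level == "experiment", ]
  if (!setequal(ref$experiment_id, mut$experiment_id) || nrow(ref) == 0) {
    ct_abort("experiment ids differ between the two genotypes", "stratification")
  }
  ids <- sort(unique(ref$experiment_id))
  arr <- array(0L, dim = c(2, 2, length(ids)),
               dimnames = list(genotype = c(ref$genotype[1], mut$genotype[1]),
                               compartment = c("CM", "CL"),
                               experiment = as.character(ids)))
  for (k in seq_along(ids)) {
    r <- ref[ref$experiment_id == ids[k], ]
    m <- mut[mut$experiment_id == ids[k], ]
    arr[1, , k] <- largest_remainder(c(r$cm_amount, r$cl_amount), pseudo_n)
    arr[2, , k] <- largest_remainder(c(m$cm_amount, m$cl_amount), pseudo_n)
  }
  arr
}

#' Cochran-Mantel-Haenszel test with Mantel-Haenszel odds ratio
#'
#' The CMH chi-square statistic (1 df; continuity correction off by default),
#' the Mantel-Haenszel common odds ratio
#' `OR = sum(a_i d_i / n_i) / sum(b_i c_i / n_i)`, and its 95% confidence
#' interval from the Robins-Breslow-Greenland variance of `log(OR)`.
#'
#' @param strata a `2 x 2 x K` array of non-negative counts (as from
#'   [build_strata()]) or a single 2x2 matrix.
#' @param correct logical; apply the 0.5 continuity correction to the
#'   chi-square statistic.
#' @param conf_level confidence level for the odds-ratio interval.
#' @return a list with `statistic`, `p_value`, `or_mh`, `ci_lower`,
#'   `ci_upper`, `n_strata`.
#' @export
cmh_test <- function(strata, correct = FALSE, conf_level = 0.95) {
  if (is.matrix(strata)) strata <- array(strata, c(2, 2, 1))
  stopifnot(length(dim(strata)) == 3L, all(dim(strata)[1:2] == 2L),
            all(strata >= 0))
  strata <- array(as.numeric(strata), dim(strata), dimnames(strata))
  a <- strata[1, 1, ]; b <- strata[1, 2, ]
  c_ <- strata[2, 1, ]; d <- strata[2, 2, ]
  n <- a + b + c_ + d
  if (any(n <= 0)) ct_abort("stratum with zero total", "parameter")
  r <- sum(a * d / n); s <- sum(b * c_ / n)
  if (r == 0 && s == 0) {
    ct_abort("all strata degenerate (zero cross-products); OR undefined",
             "undefined_or")
  }
  or_mh <- r / s
  # RBG variance of log(OR_MH)
  p <- (a + d) / n; q <- (b + c_) / n
  var_log <- sum(p * a * d / n) / (2 * r^2) +
    sum(p * b * c_ / n + q * a * d / n) / (2 * r * s) +
    sum(q * b * c_ / n) / (2 * s^2)
  z <- qnorm(1 - (1 - conf_level) / 2)
  ci <- exp(log(or_mh) + c(-1, 1) * z * sqrt(var_log))
  # CMH statistic
  e <- (a + b) * (a + c_) / n
  v <- (a + b) * (c_ + d) * (a + c_) * (b + d) / (n^2 * (n - 1))
  num <- abs(sum(a) - sum(e))
  if (correct) num <- max(0, num - 0.5)
  stat <- num^2 / sum(v)
  list(statistic = stat, p_value = pchisq(stat, 1, lower.tail = FALSE),
       or_mh = or_mh, ci_lower = ci[1], ci_upper = ci[2],
       n_strata = dim(strata)[3])
}

#' Compare genotypes on imaging and secretion metrics
#'
#' The grouping layer used by the pipeline: pooled single-pass outlier
#' removal per metric, Tukey HSD contrasts against wild type for the per-cell
#' metrics, and a CMH test per mutant for the secretion strata. Every p-value
#' is compared with the Bonferroni threshold over `m` constructs.
#'
#' @param cells per-cell measurements ([quantify_cells()] output, possibly
#'   several fields bound together).
#' @param fractions [compartment_fractions()] output.
#' @param reference wild-type label.
#' @param alpha family-wise alpha.
#' @param m number of constructs for the Bonferroni correction.
#' @param k outlier multiplier.
#' @param pseudo_n pseudo-count row total for [build_strata()].
#' @return a tibble of comparison rows: `genotype`, `metric`, `statistic`,
#'   `p_raw`, `p_adjusted`, `or_mh`, `ci_lower`, `ci_upper`, `significant`.
#' @export
compare_genotypes <- function(cells = NULL, fractions = NULL, reference = "wt",
                              alpha = 0.05, m = 11L, k = 3, pseudo_n = 1000L) {
  thr <- bonferroni_threshold(alpha, m)
  out <- list()
  if (!is.null(cells)) {
    for (metric in c("golgi_ratio", "pearson_er")) {
      keep <- !cells$excluded & !is.na(cells[[metric]])
      vals <- cells[[metric]][keep]
      genos <- cells$genotype[keep]
      if (length(vals) >= 3) {
        kept <- remove_outliers(vals, k)
        vals <- kept$kept
        genos <- if (length(kept$removed)) genos[-kept$removed] else genos
      }
      groups <- split(vals, genos)
      groups <- groups[vapply(groups, length, 0L) >= 2L]
      if (length(groups) < 2L || !reference %in% names(groups)) next
      tk <- anova_tukey(groups, reference)
      out[[length(out) + 1L]] <- tibble::tibble(
        genotype = tk$genotype, metric = metric, statistic = tk$diff,
        p_raw = tk$p_tukey, p_adjusted = pmin(1, tk$p_tukey * m),
        or_mh = NA_real_, ci_lower = NA_real_, ci_upper = NA_real_,
        significant = !is.na(tk$p_tukey) & tk$p_tukey < thr)
    }
  }
  if (!is.null(fractions)) {
    genos <- setdiff(unique(fractions$genotype), reference)
    ref_est <- fractions[fractions$genotype == reference, ]
    for (g in genos) {
      strata <- build_strata(ref_est, fractions[fractions$genotype == g, ],
                             pseudo_n)
      res <- cmh_test(strata)
      # report the mutant-vs-reference odds of being secreted (CM), the
      # orientation in which the ratios and CIs are conventionally printed
      out[[length(out) + 1L]] <- tibble::tibble(
        genotype = g, metric = "cm_fraction", statistic = res$statistic,
        p_raw = res$p_value, p_adjusted = pmin(1, res$p_value * m),
        or_mh = 1 / res$or_mh, ci_lower = 1 / res$ci_upper,
        ci_upper = 1 / res$ci_lower, significant = res$p_value < thr)
    }
  }
  if (length(out) == 0L) {
    return(tibble::tibble(genotype = character(), metric = character(),
                          statistic = double(), p_raw = double(),
                          p_adjusted = double(), or_mh = double(),
                          ci_lower = double(), ci_upper = double(),
                          significant = logical()))
  }
  dplyr::bind_rows(out)
}
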