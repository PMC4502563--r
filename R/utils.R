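#' @importFrom rlang abort warn .data
#' @importFrom stats rnorm rpois runif rlnorm sd quantile median var cor
#'   pchisq qnorm aov TukeyHSD complete.cases setNames
NULL

# classed abort so callers (and the batch quantifier) can catch precisely
ct_abort <- function(message, class) {
  rlang::abort(message, class = c(paste0("clutraffic_error_", class), "clutraffic_error"))
}

#' Otsu threshold of a pixel-intensity sample
#'
#' Classic histogram-based Otsu threshold computed on an arbitrary vector of
#' intensities (typically the pixels of one channel restricted to a cell ROI),
#' maximizing between-class variance over `levels` equal-width bins.
#'
#' @param x numeric vector of intensities.
#' @param levels number of histogram bins (default 256).
#' @return the threshold value; pixels strictly above it belong to the
#'   foreground class.
#' @export
otsu_threshold <- function(x, levels = 256L) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) ct_abort("need at least 2 finite intensities", "degenerate_threshold")
  rng <- range(x)
  if (diff(rng) == 0) {
    ct_abort("intensities are constant; automatic threshold undefined", "degenerate_threshold")
  }
  breaks <- seq(rng[1], rng[2], length.out = levels + 1L)
  h <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE), nbins = levels)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-(levels + 1L)]) / 2
  omega <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[levels]
  denom <- omega * (1 - omega)
  bcv <- (mu_t * omega - mu)^2 / ifelse(denom > 0, denom, NA_real_)
  k <- which.max(bcv)
  breaks[k + 1L]
}

# largest-remainder rounding of non-negative weights to integers summing to n
largest_remainder <- function(w, n) {
  stopifnot(all(w >= 0), n >= 0)
  if (sum(w) == 0) w <- rep(1, length(w))
  x <- w / sum(w) * n
  fl <- floor(x)
  left <- n - sum(fl)
  if (left > 0) {
    ord <- order(x - fl, decreasing = TRUE)
    fl[ord[seq_len(left)]] <- fl[ord[seq_len(left)]] + 1
  }
  as.integer(fl)
}

# per-stage RNG seed derived from a master seed; keeps values in 32-bit range
stage_seed <- function(seed, stage) {
  offsets <- c(images = 11L, elisa = 23L, western = 37L, analysis = 53L)
  off <- offsets[[stage]]
  as.integer((as.numeric(seed) * 1009 + off * 7919) %% 2147483647)
}
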