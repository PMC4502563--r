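#' Estimate the field background from pixels outside all cell ROIs
#'
#' @param channel numeric matrix.
#' @param cell_labels integer label matrix (0 = background, positive = cell
#'   ids) or a list of logical ROI masks.
#' @return named numeric vector `c(mean, sd)` over the non-cell pixels.
#' @export
estimate_background <- function(channel, cell_labels) {
  outside <- !roi_union(cell_labels, dim(channel))
  n <- sum(outside)
  if (n < 100L) {
    ct_abort(sprintf("only %d pixels outside cell ROIs; need >= 100", n),
             "coverage")
  }
  v <- channel[outside]
  c(mean = mean(v), sd = stats::sd(v))
}

roi_union <- function(cell_labels, dims) {
  if (is.list(cell_labels)) {
    out <- matrix(FALSE, dims[1], dims[2])
    for (m in cell_labels) out <- out | m
    out
  } else {
    cell_labels > 0
  }
}

#' Segment the Golgi within one cell by automatic thresholding
#'
#' An Otsu threshold is computed on the Golgi-marker intensities restricted
#' to the cell ROI; pixels above it form the candidate mask, and connected
#' components (8-connectivity) smaller than `min_object_px` are removed. The
#' result may be empty.
#'
#' @param golgi_channel numeric matrix (Golgi-marker channel).
#' @param cell_roi logical matrix, the cell region.
#' @param min_object_px minimum connected-component size kept (pixels).
#' @return a list of class `golgi_segmentation` with `mask` (logical matrix),
#'   `threshold_value` and `min_object_px`.
#' @export
segment_golgi <- function(golgi_channel, cell_roi, min_object_px = 20L) {
  if (!any(cell_roi)) ct_abort("empty cell ROI", "parameter")
  thr <- otsu_threshold(golgi_channel[cell_roi])
  mask <- cell_roi & golgi_channel > thr
  if (any(mask)) {
    lab <- EBImage::bwlabel(mask * 1)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= min_object_px)
    mask <- matrix(lab %in% keep, nrow(mask), ncol(mask))
  }
  structure(list(mask = mask, threshold_value = thr,
                 min_object_px = as.integer(min_object_px)),
            class = "golgi_segmentation")
}

#' Background-corrected Golgi enrichment ratio for one cell
#'
#' `ratio = (mean_in - background) / (mean_out - background)`, where
#' `mean_in` is the mean reporter intensity over the Golgi mask and
#' `mean_out` the mean over the remaining cell region. `mean_outside`
#' (`mean_out - background`) is returned for the low-signal exclusion rule.
#'
#' @param reporter_channel numeric matrix.
#' @param cell_roi logical matrix.
#' @param golgi_mask logical matrix, subset of `cell_roi`.
#' @param background_mean scalar background level to subtract.
#' @return a list with `golgi_ratio`, `mean_outside`, and `flag`
#'   (`"ok"`, `"empty_golgi"`, or `"degenerate_denominator"`); the ratio is
#'   `NA` when flagged.
#' @export
golgi_enrichment_ratio <- function(reporter_channel, cell_roi, golgi_mask,
                                   background_mean) {
  stopifnot(!any(golgi_mask & !cell_roi))
  outside <- cell_roi & !golgi_mask
  if (!any(outside)) ct_abort("cell ROI minus Golgi mask is empty", "parameter")
  mean_out <- mean(reporter_channel[outside]) - background_mean
  if (!any(golgi_mask)) {
    return(list(golgi_ratio = NA_real_, mean_outside = mean_out,
                flag = "empty_golgi"))
  }
  mean_in <- mean(reporter_channel[golgi_mask]) - background_mean
  if (mean_out <= 0) {
    return(list(golgi_ratio = NA_real_, mean_outside = mean_out,
                flag = "degenerate_denominator"))
  }
  list(golgi_ratio = mean_in / mean_out, mean_outside = mean_out, flag = "ok")
}

#' Flag cells with low reporter signal outside the Golgi
#'
#' A fixed cutoff on the background-corrected mean reporter intensity outside
#' the Golgi region: `excluded` is set to `mean_outside < cutoff`. No records
#' are dropped and the order is preserved.
#'
#' @param measurements a data frame with a `mean_outside` column (e.g. from
#'   [quantify_cells()]).
#' @param cutoff intensity cutoff (>= 0).
#' @return `measurements` with its `excluded` column set.
#' @export
exclude_low_signal <- function(measurements, cutoff) {
  stopifnot(cutoff >= 0)
  measurements$excluded <- !is.na(measurements$mean_outside) &
    measurements$mean_outside < cutoff
  measurements
}

#' Pearson colocalization between two channels within one cell
#'
#' Plain sample Pearson correlation over all ROI pixels (no Costes
#' thresholding), as in a default Coloc2 Pearson measurement.
#'
#' @param channel_a,channel_b numeric matrices of identical shape.
#' @param cell_roi logical matrix.
#' @return correlation in `[-1, 1]`.
#' @export
pearson_colocalization <- function(channel_a, channel_b, cell_roi) {
  a <- channel_a[cell_roi]; b <- channel_b[cell_roi]
  if (length(a) < 2L) ct_abort("need >= 2 ROI pixels", "parameter")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    ct_abort("constant channel over ROI; correlation undefined",
             "constant_channel")
  }
  stats::cor(a, b)
}

#' Quantify every cell of a field
#'
#' Batch per-cell measurement: field background estimation, Golgi
#' segmentation on the Golgi-marker channel, background-corrected Golgi
#' enrichment ratio of the reporter, low-signal exclusion, and Pearson
#' colocalization of reporter with the ER marker. Per-cell failures
#' (degenerate threshold, constant channel, empty Golgi) are recorded as
#' flagged rows; the batch never aborts. Deterministic given inputs and
#' configuration.
#'
#' @param channels named list of numeric matrices including `reporter`,
#'   `golgi`, `er`.
#' @param cell_labels integer label matrix of cell ROIs.
#' @param genotype_by_cell optional character vector mapping cell id to
#'   genotype (names are cell ids).
#' @param min_object_px Golgi size filter, pixels.
#' @param cutoff exclusion cutoff on `mean_outside`; `NULL` (default) uses
#'   `background mean + cutoff_k * background sd` estimated from the
#'   reporter channel.
#' @param cutoff_k multiplier for the automatic cutoff rule.
#' @param image_id identifier copied into the output.
#' @return a tibble with one row per cell: `image_id`, `cell_id`, `genotype`,
#'   `golgi_ratio`, `mean_outside`, `pearson_er`, `excluded`, `flag`.
#' @export
quantify_cells <- function(channels, cell_labels, genotype_by_cell = NULL,
                           min_object_px = 20L, cutoff = NULL, cutoff_k = 2,
                           image_id = "field1") {
  stopifnot(all(c("reporter", "golgi", "er") %in% names(channels)))
  dims <- dim(channels$reporter)
  stopifnot(all(vapply(channels, function(m) identical(dim(m), dims), TRUE)))
  ids <- sort(setdiff(unique(as.vector(cell_labels)), 0L))
  if (length(ids) == 0L) {
    return(tibble::tibble(image_id = character(), cell_id = integer(),
                          genotype = character(), golgi_ratio = double(),
                          mean_outside = double(), pearson_er = double(),
                          excluded = logical(), flag = character()))
  }
  bg <- estimate_background(channels$reporter, cell_labels)
  if (is.null(cutoff)) cutoff <- bg[["mean"]] + cutoff_k * bg[["sd"]]

  rows <- lapply(ids, function(id) {
    roi <- cell_labels == id
    geno <- if (!is.null(genotype_by_cell)) {
      unname(genotype_by_cell[as.character(id)])
    } else NA_character_
    gr <- NA_real_; mo <- NA_real_; flag <- "ok"
    seg <- tryCatch(segment_golgi(channels$golgi, roi, min_object_px),
                    clutraffic_error_degenerate_threshold = function(e) NULL)
    if (is.null(seg)) {
      flag <- "degenerate_threshold"
    } else {
      res <- golgi_enrichment_ratio(channels$reporter, roi, seg$mask,
                                    bg[["mean"]])
      gr <- res$golgi_ratio; mo <- res$mean_outside
      if (res$flag != "ok") flag <- res$flag
    }
    pe <- tryCatch(pearson_colocalization(channels$reporter, channels$er, roi),
                   clutraffic_error_constant_channel = function(e) NA_real_)
    if (is.na(pe) && flag == "ok") flag <- "constant_channel"
    tibble::tibble(image_id = image_id, cell_id = as.integer(id),
                   genotype = geno, golgi_ratio = gr, mean_outside = mo,
                   pearson_er = pe, excluded = FALSE, flag = flag)
  })
  out <- dplyr::bind_rows(rows)
  exclude_low_signal(out, max(cutoff, 0))
}

#' @rdname quantify_cells
#' @param scene a `clu_scene` from [make_scene()]; its truth cell mask serves
#'   as the ROI set (standing in for manual F-actin delineation).
#' @param ... passed on to [quantify_cells()].
#' @export
quantify_scene <- function(scene, ..., image_id = paste0("seed", scene$seed)) {
  quantify_cells(scene$channels, scene$truth$cell,
                 genotype_by_cell = scene$phenotype_by_cell,
                 image_id = image_id, ...)
}
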