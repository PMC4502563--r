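#' Noise model parameters for synthetic fields
#'
#' Signal-dependent (scaled-Poisson) shot noise plus additive Gaussian read
#' noise, both applied to every channel and clipped at zero. Setting
#' `shot_scale = 0` and `background_sd = 0` renders noise-free expectations.
#'
#' @param background_level additive offset present in every channel (counts).
#' @param background_sd standard deviation of the additive Gaussian noise.
#' @param shot_scale scale of the Poisson shot noise: a pixel with expectation
#'   `E` is drawn as `shot_scale * Poisson(E / shot_scale)`; 0 disables it.
#' @return a named list.
#' @export
scene_noise <- function(background_level = 100, background_sd = 10, shot_scale = 1) {
  stopifnot(background_level >= 0, background_sd >= 0, shot_scale >= 0)
  list(background_level = background_level, background_sd = background_sd,
       shot_scale = shot_scale)
}

#' Geometry and amplitude parameters for synthetic cells
#'
#' Cells are Fourier-perturbed ellipses; the nucleus is a contained ellipse;
#' the Golgi is a perinuclear crescent broken into 2-4 cisterna ribbons; the
#' ER is a reticular web obtained by thresholding band-pass-filtered noise
#' inside the cytoplasm; vesicles are Poisson-placed puncta.
#'
#' @param cell_radius mean cell radius in pixels.
#' @param nucleus_frac nucleus radius as a fraction of the cell radius.
#' @param golgi_inner,golgi_outer radial extent of the Golgi band beyond the
#'   nucleus boundary, in pixels.
#' @param er_coverage fraction of the cytoplasm covered by the ER web.
#' @param vesicle_radius vesicle punctum radius in pixels.
#' @param reporter_amp base reporter amplitude (counts); phenotype multipliers
#'   scale it (ER pixels get `er_retention * reporter_amp`, Golgi pixels
#'   `golgi_enrichment * er_retention * reporter_amp`).
#' @param marker_amp amplitude of the organelle marker channels (counts).
#' @param vesicle_amp vesicle amplitude relative to `reporter_amp`.
#' @param psf_blur logical; blur expectations with a Gaussian (sd 1 px) before
#'   adding noise, mimicking a point-spread function.
#' @return a named list.
#' @export
scene_geometry <- function(cell_radius = 30, nucleus_frac = 0.38,
                           golgi_inner = 2, golgi_outer = 7,
                           er_coverage = 0.30, vesicle_radius = 1.5,
                           reporter_amp = 2000, marker_amp = 2000,
                           vesicle_amp = 0.5, psf_blur = FALSE) {
  list(cell_radius = cell_radius, nucleus_frac = nucleus_frac,
       golgi_inner = golgi_inner, golgi_outer = golgi_outer,
       er_coverage = er_coverage, vesicle_radius = vesicle_radius,
       reporter_amp = reporter_amp, marker_amp = marker_amp,
       vesicle_amp = vesicle_amp, psf_blur = psf_blur)
}

apply_noise <- function(expectation, noise) {
  x <- expectation
  if (noise$shot_scale > 0) {
    x[] <- noise$shot_scale * rpois(length(x), pmax(x, 0) / noise$shot_scale)
  }
  if (noise$background_sd > 0) {
    x[] <- x + rnorm(length(x), 0, noise$background_sd)
  }
  pmax(x, 0)
}

# rasterize one cell at (cy, cx); returns integer index vector of pixels and
# the per-cell organelle masks (as index vectors into the full image)
rasterize_cell <- function(cy, cx, dims, geom, vesicle_density, bandpass) {
  r0 <- geom$cell_radius * runif(1, 0.85, 1.15)
  a <- c(runif(1, 0, 0.12), runif(1, 0, 0.08), runif(1, 0, 0.05))
  ph <- runif(3, 0, 2 * pi)
  rmax <- r0 * (1 + sum(a))
  rows <- max(1L, floor(cy - rmax)):min(dims[1], ceiling(cy + rmax))
  cols <- max(1L, floor(cx - rmax)):min(dims[2], ceiling(cx + rmax))
  DY <- outer(rows - cy, rep(1, length(cols)))
  DX <- outer(rep(1, length(rows)), cols - cx)
  TH <- atan2(DY, DX)
  RAD <- sqrt(DY^2 + DX^2)
  rb <- r0 * (1 + a[1] * cos(2 * TH - ph[1]) + a[2] * cos(3 * TH - ph[2]) +
                a[3] * cos(5 * TH - ph[3]))
  inside <- RAD <= rb

  # nucleus: ellipse near the cell center
  off_a <- runif(1, 0, 2 * pi); off_r <- runif(1, 0, 0.12 * r0)
  ny <- cy + off_r * sin(off_a); nx <- cx + off_r * cos(off_a)
  rn <- geom$nucleus_frac * r0 * runif(2, 0.9, 1.1)
  rot <- runif(1, 0, pi)
  NDY <- outer(rows - ny, rep(1, length(cols)))
  NDX <- outer(rep(1, length(rows)), cols - nx)
  U <- NDX * cos(rot) + NDY * sin(rot)
  V <- -NDX * sin(rot) + NDY * cos(rot)
  nucleus <- inside & ((U / rn[1])^2 + (V / rn[2])^2 <= 1)

  # Golgi: perinuclear crescent of 2-4 ribbons in an annular band
  rn_eff <- max(rn)
  NRAD <- sqrt(NDY^2 + NDX^2)
  NTH <- atan2(NDY, NDX)
  band <- NRAD >= rn_eff + geom$golgi_inner & NRAD <= rn_eff + geom$golgi_outer
  dir0 <- runif(1, 0, 2 * pi)
  span <- runif(1, 2.2, 3.2)
  n_rib <- sample(2:4, 1)
  delta <- (NTH - dir0) %% (2 * pi)
  seg <- span / n_rib
  gap <- min(0.15, seg / 4)
  in_arc <- delta <= span &
    ((delta %% seg) >= gap / 2) & ((delta %% seg) <= seg - gap / 2)
  golgi <- inside & !nucleus & band & in_arc

  cyto <- inside & !nucleus & !golgi

  # ER web: upper quantile of the band-pass field within the cytoplasm
  er <- matrix(FALSE, length(rows), length(cols))
  bp <- bandpass[rows, cols, drop = FALSE]
  if (any(cyto)) {
    thr <- quantile(bp[cyto], 1 - geom$er_coverage, names = FALSE)
    er <- cyto & bp > thr
  }

  # vesicles: Poisson-placed puncta in the cytoplasm
  ves <- matrix(FALSE, length(rows), length(cols))
  n_ves <- rpois(1, vesicle_density)
  cand <- which(cyto)
  if (n_ves > 0 && length(cand) > 0) {
    centers <- cand[sample.int(length(cand), min(n_ves, length(cand)))]
    vr <- ceiling(geom$vesicle_radius)
    nr <- length(rows)
    for (cc in centers) {
      ci <- ((cc - 1) %% nr) + 1; cj <- ((cc - 1) %/% nr) + 1
      ii <- max(1, ci - vr):min(nr, ci + vr)
      jj <- max(1, cj - vr):min(length(cols), cj + vr)
      d2 <- outer((ii - ci)^2, rep(1, length(jj))) +
        outer(rep(1, length(ii)), (jj - cj)^2)
      ves[ii, jj] <- ves[ii, jj] | (d2 <= geom$vesicle_radius^2)
    }
    ves <- ves & inside & !nucleus & !golgi
  }

  to_idx <- function(m) {
    w <- which(m, arr.ind = TRUE)
    (rows[w[, 1]]) + (cols[w[, 2]] - 1L) * dims[1]
  }
  list(cell = to_idx(inside), nucleus = to_idx(nucleus), golgi = to_idx(golgi),
       er = to_idx(er), vesicles = to_idx(ves))
}

#' Simulate one multi-channel fluorescence field with ground truth
#'
#' Places `n_cells` non-overlapping cells (phenotypes assigned by cycling
#' through `phenotypes`), builds ground-truth label masks for cell, nucleus,
#' ER, Golgi and vesicles, and renders five channels (reporter, golgi, er,
#' nucleus, actin). The reporter expectation per pixel is
#' `background_level + A * er_retention * [ER] +
#'  A * golgi_enrichment * er_retention * [Golgi] + A * vesicle_amp * [vesicles]`
#' with `A = reporter_amp`; marker channels trace their truth masks. Shot and
#' read noise follow [scene_noise()]. Identical inputs and seed reproduce the
#' arrays bit for bit.
#'
#' @param n_cells number of cells to place (>= 1).
#' @param phenotypes a list of [genotype_phenotype()] objects (or a data frame
#'   with the same columns, e.g. rows of [clu_phenotypes()]).
#' @param image_shape image dimensions `c(rows, cols)` in pixels.
#' @param noise see [scene_noise()].
#' @param seed integer RNG seed.
#' @param geometry see [scene_geometry()].
#' @param pixel_size physical pixel edge length in micrometres.
#' @return an object of class `clu_scene`: a list with `channels` (named list
#'   of numeric matrices), `truth` (named list of integer label matrices with
#'   0 background and cell ids), `pixel_size`, `seed`, `phenotype_by_cell`,
#'   and `phenotypes`.
#' @export
make_scene <- function(n_cells, phenotypes, image_shape = c(512L, 512L),
                       noise = scene_noise(), seed = 1L,
                       geometry = scene_geometry(), pixel_size = 0.106) {
  stopifnot(n_cells >= 1, length(image_shape) == 2L)
  phenotypes <- as_phenotype_list(phenotypes)
  dims <- as.integer(image_shape)
  geom <- geometry
  withr::with_seed(as.integer(seed), {
    rmax <- geom$cell_radius * 1.15 * 1.25
    margin <- rmax + 2
    mind <- 2 * rmax + 2
    if (2 * margin >= min(dims)) {
      ct_abort("image too small for even one cell at this geometry (cell index 1)",
               "placement")
    }
    centers <- matrix(NA_real_, n_cells, 2)
    for (i in seq_len(n_cells)) {
      placed <- FALSE
      for (try in seq_len(500L)) {
        cy <- runif(1, margin, dims[1] - margin)
        cx <- runif(1, margin, dims[2] - margin)
        if (i == 1L ||
            all(sqrt((centers[seq_len(i - 1), 1] - cy)^2 +
                       (centers[seq_len(i - 1), 2] - cx)^2) >= mind)) {
          centers[i, ] <- c(cy, cx); placed <- TRUE; break
        }
      }
      if (!placed) {
        ct_abort(sprintf("cannot place cell %d without overlap in a %dx%d image",
                         i, dims[1], dims[2]), "placement")
      }
    }

    w <- matrix(rnorm(prod(dims)), dims[1], dims[2])
    bandpass <- EBImage::gblur(w, sigma = 1) - EBImage::gblur(w, sigma = 2.5)

    truth <- lapply(setNames(nm = c("cell", "nucleus", "er", "golgi", "vesicles")),
                    function(nm) matrix(0L, dims[1], dims[2]))
    pheno_idx <- ((seq_len(n_cells) - 1L) %% length(phenotypes)) + 1L
    rep_e <- matrix(noise$background_level, dims[1], dims[2])
    amp_on <- function(base, idx, amount) { base[idx] <- base[idx] + amount; base }
    masks_by_cell <- vector("list", n_cells)
    for (i in seq_len(n_cells)) {
      ph <- phenotypes[[pheno_idx[i]]]
      m <- rasterize_cell(centers[i, 1], centers[i, 2], dims, geom,
                          ph$vesicle_density, bandpass)
      masks_by_cell[[i]] <- m
      for (nm in names(truth)) truth[[nm]][m[[nm]]] <- i
      A <- geom$reporter_amp
      rep_e <- amp_on(rep_e, m$er, A * ph$er_retention)
      rep_e <- amp_on(rep_e, m$golgi, A * ph$golgi_enrichment * ph$er_retention)
      rep_e <- amp_on(rep_e, m$vesicles, A * geom$vesicle_amp)
    }
    channel_e <- list(
      reporter = rep_e,
      golgi = matrix(noise$background_level, dims[1], dims[2]),
      er = matrix(noise$background_level, dims[1], dims[2]),
      nucleus = matrix(noise$background_level, dims[1], dims[2]),
      actin = matrix(noise$background_level, dims[1], dims[2])
    )
    channel_e$golgi[truth$golgi > 0] <- channel_e$golgi[truth$golgi > 0] + geom$marker_amp
    channel_e$er[truth$er > 0] <- channel_e$er[truth$er > 0] + geom$marker_amp
    channel_e$nucleus[truth$nucleus > 0] <- channel_e$nucleus[truth$nucleus > 0] + geom$marker_amp
    channel_e$actin[truth$cell > 0] <- channel_e$actin[truth$cell > 0] + 0.6 * geom$marker_amp
    if (isTRUE(geom$psf_blur)) {
      channel_e <- lapply(channel_e, EBImage::gblur, sigma = 1)
    }
    channels <- lapply(channel_e, apply_noise, noise = noise)

    structure(
      list(channels = channels, truth = truth, pixel_size = pixel_size,
           seed = as.integer(seed),
           phenotype_by_cell = setNames(
             vapply(phenotypes[pheno_idx], `[[`, "", "name"),
             as.character(seq_len(n_cells))),
           phenotypes = phenotypes),
      class = "clu_scene")
  })
}

#' @export
print.clu_scene <- function(x, ...) {
  cat(sprintf("<clu_scene> %d x %d px, %d cells, seed %d\n",
              nrow(x$channels$reporter), ncol(x$channels$reporter),
              max(x$truth$cell), x$seed))
  invisible(x)
}

#' Write a scene to disk as multi-channel TIFF plus sidecar JSON
#'
#' Channels go to `<prefix>_channels.tif` (one 16-bit page per channel, fixed
#' order reporter, golgi, er, nucleus, actin, clipped to the 16-bit range),
#' truth masks to `<prefix>_truth.tif` (16-bit labels, order cell, nucleus,
#' er, golgi, vesicles), and seed / pixel size / phenotype assignment to
#' `<prefix>_meta.json`.
#'
#' @param scene a `clu_scene`.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @return the three file paths, invisibly.
#' @export
write_scene <- function(scene, dir, prefix = "scene") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  chan_path <- file.path(dir, paste0(prefix, "_channels.tif"))
  truth_path <- file.path(dir, paste0(prefix, "_truth.tif"))
  meta_path <- file.path(dir, paste0(prefix, "_meta.json"))
  tiff::writeTIFF(lapply(scene$channels, function(m) pmin(m, 65535) / 65535),
                  chan_path, bits.per.sample = 16L)
  tiff::writeTIFF(lapply(scene$truth, function(m) m / 65535),
                  truth_path, bits.per.sample = 16L)
  jsonlite::write_json(
    list(seed = scene$seed, pixel_size = scene$pixel_size,
         channel_order = names(scene$channels),
         truth_order = names(scene$truth),
         phenotype_by_cell = as.list(scene$phenotype_by_cell)),
    meta_path, auto_unbox = TRUE, digits = NA)
  invisible(c(channels = chan_path, truth = truth_path, meta = meta_path))
}

#' Read a scene written by [write_scene()]
#'
#' @param dir directory holding the files.
#' @param prefix file-name prefix used when writing.
#' @return a `clu_scene` (channel intensities restored to counts; truth masks
#'   restored to integer labels).
#' @export
read_scene <- function(dir, prefix = "scene") {
  meta <- jsonlite::read_json(file.path(dir, paste0(prefix, "_meta.json")),
                              simplifyVector = TRUE)
  chans <- tiff::readTIFF(file.path(dir, paste0(prefix, "_channels.tif")),
                          all = TRUE)
  truths <- tiff::readTIFF(file.path(dir, paste0(prefix, "_truth.tif")),
                           all = TRUE)
  channels <- setNames(lapply(chans, function(m) round(m * 65535)),
                       meta$channel_order)
  truth <- lapply(truths, function(m) {
    mm <- round(m * 65535); storage.mode(mm) <- "integer"; mm
  })
  names(truth) <- meta$truth_order
  structure(
    list(channels = channels, truth = truth, pixel_size = meta$pixel_size,
         seed = meta$seed,
         phenotype_by_cell = unlist(meta$phenotype_by_cell),
         phenotypes = NULL),
    class = "clu_scene")
}
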