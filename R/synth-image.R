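#' Configuration for the synthetic microscopy image generator
#'
#' Describes noiseless multi-channel (nuclei / reporter / stain) images with
#' planted cells and aggregates of known pixel-exact areas, plus ground-truth
#' masks, for benchmarking the deterministic quantification pipeline. Cells
#' are laid out on a non-overlapping grid (ground-truth masks are disjoint by
#' construction); each aggregate-positive cell receives one planted
#' aggregate per entry of `agg_area_um2`, rendered as a disc of exactly
#' `round(area / pixel_size_um^2)` pixels. In `neuron_mode` the generator
#' emulates the neuronal mutant-FUS phenotype: several large cytoplasmic
#' aggregates plus many small foci per positive cell, with the nuclear region
#' devoid of reporter signal.
#'
#' @param height_px,width_px image size in pixels.
#' @param n_z number of z slices (1 for 2-D). Aggregates are planted in a
#'   single slice (the central one); diffuse signal spans all slices.
#' @param pixel_size_um microns per pixel.
#' @param n_cells number of cells.
#' @param nucleus_radius_um,cell_radius_um object radii (um).
#' @param p_agg fraction of aggregate-positive cells; the positive count is
#'   `round(p_agg * n_cells)`.
#' @param agg_area_um2 planted aggregate areas (um^2), one aggregate per
#'   entry per positive cell.
#' @param agg_intensity,cell_intensity,background 8-bit levels of aggregate,
#'   diffuse-cell and background pixels in the reporter channel.
#' @param nucleus_intensity,stain_intensity 8-bit levels of the nuclei and
#'   stain channels.
#' @param neuron_mode logical; plant `n_large_agg` large aggregates (areas
#'   recycled from `agg_area_um2`) plus `n_small_foci` small foci per
#'   positive cell and empty the nuclear region of reporter signal.
#' @param n_large_agg,n_small_foci,small_focus_area_um2 neuron-mode layout
#'   (defaults: 3 large aggregates and 10 small foci of 0.5 um^2).
#' @param n_nuclei_only number of additional nucleus-only objects (no stain,
#'   no reporter), used to exercise dual-channel cell counting.
#' @param seed integer seed (controls which cells are aggregate-positive).
#' @return an object of class `sim_image_config`.
#' @export
sim_image_config <- function(height_px = 256, width_px = 256, n_z = 1,
                             pixel_size_um = 0.5, n_cells = 20,
                             nucleus_radius_um = 3, cell_radius_um = 8,
                             p_agg = 0.3, agg_area_um2 = 6,
                             agg_intensity = 255, cell_intensity = 250,
                             background = 10,
                             nucleus_intensity = 200, stain_intensity = 200,
                             neuron_mode = FALSE, n_large_agg = 3,
                             n_small_foci = 10, small_focus_area_um2 = 0.5,
                             n_nuclei_only = 0, seed = 1L) {
  cfg <- list(
    height_px = .chk_count(height_px, "height_px", 8L),
    width_px = .chk_count(width_px, "width_px", 8L),
    n_z = .chk_count(n_z, "n_z"),
    pixel_size_um = .chk_pos(pixel_size_um, "pixel_size_um"),
    n_cells = .chk_count(n_cells, "n_cells", 0L),
    nucleus_radius_um = .chk_pos(nucleus_radius_um, "nucleus_radius_um"),
    cell_radius_um = .chk_pos(cell_radius_um, "cell_radius_um"),
    p_agg = .chk_fraction(p_agg, "p_agg"),
    agg_area_um2 = as.numeric(agg_area_um2),
    agg_intensity = .chk_pos(agg_intensity, "agg_intensity"),
    cell_intensity = .chk_pos(cell_intensity, "cell_intensity"),
    background = .chk_pos(background, "background", strict = FALSE),
    nucleus_intensity = .chk_pos(nucleus_intensity, "nucleus_intensity"),
    stain_intensity = .chk_pos(stain_intensity, "stain_intensity"),
    neuron_mode = isTRUE(neuron_mode),
    n_large_agg = .chk_count(n_large_agg, "n_large_agg"),
    n_small_foci = .chk_count(n_small_foci, "n_small_foci", 0L),
    small_focus_area_um2 = .chk_pos(small_focus_area_um2, "small_focus_area_um2"),
    n_nuclei_only = .chk_count(n_nuclei_only, "n_nuclei_only", 0L),
    seed = .chk_seed(seed)
  )
  if (any(cfg$agg_area_um2 <= 0)) stop("'agg_area_um2' entries must be positive", call. = FALSE)
  if (cfg$nucleus_radius_um >= cfg$cell_radius_um) {
    stop("'nucleus_radius_um' must be smaller than 'cell_radius_um'", call. = FALSE)
  }
  class(cfg) <- "sim_image_config"
  cfg
}

# Pixels of a disc of exactly n_px pixels centred at (r, c): the n_px pixels
# nearest the centre, with a deterministic tie-break.
.disc_pixels <- function(r, c, n_px, height, width) {
  rad <- ceiling(sqrt(n_px / pi)) + 2
  rr <- max(1, r - rad):min(height, r + rad)
  cc <- max(1, c - rad):min(width, c + rad)
  grid <- expand.grid(row = rr, col = cc)
  d2 <- (grid$row - r)^2 + (grid$col - c)^2
  ord <- order(d2, grid$row, grid$col)
  if (n_px > nrow(grid)) stop("object does not fit in the image", call. = FALSE)
  grid[ord[seq_len(n_px)], , drop = FALSE]
}

.paint <- function(mat, px, value) {
  mat[cbind(px$row, px$col)] <- value
  mat
}

#' Simulate a multi-channel microscopy image with ground truth
#'
#' Renders the image described by a [sim_image_config()] and returns both the
#' image and the planted ground truth. Ground-truth areas equal the
#' requested areas up to one pixel-area of quantization; downstream analyses
#' never see the truth masks.
#'
#' @param config a [sim_image_config()] object.
#' @return a list with elements
#'   * `image`: an `mc_image` (list of channel arrays `nuclei`, `reporter`,
#'     `stain`, each `height x width` or `height x width x n_z`, plus
#'     `pixel_size_um` and `bit_depth = 8`),
#'   * `truth`: list with `cell_labels` (label mask), `nucleus_mask`
#'     (binary), `agg_labels` (label mask, aggregates planted in slice
#'     `agg_z`), `aggregates` (data frame `label`, `cell`, `area_um2`, `z`),
#'     `per_cell` (data frame `cell`, `truth_agg`, `agg_area_um2`) and
#'     `agg_z`.
#' @export
simulate_image <- function(config) {
  if (!inherits(config, "sim_image_config")) {
    stop("'config' must be created with sim_image_config()", call. = FALSE)
  }
  px <- config$pixel_size_um
  H <- config$height_px; W <- config$width_px
  cell_r_px <- config$cell_radius_um / px
  spacing <- 2 * ceiling(cell_r_px) + 4
  n_rows <- floor((H - 2) / spacing)
  n_cols <- floor((W - 2) / spacing)
  n_objects <- config$n_cells + config$n_nuclei_only
  if (n_objects > n_rows * n_cols) {
    stop(sprintf("objects exceed image bounds: %d objects requested, grid fits %d",
                 n_objects, n_rows * n_cols), call. = FALSE)
  }
  centers <- expand.grid(gr = seq_len(n_rows), gc = seq_len(n_cols))
  centers <- centers[seq_len(max(n_objects, 0)), , drop = FALSE]
  centers$row <- round((centers$gr - 0.5) * spacing) + 1
  centers$col <- round((centers$gc - 0.5) * spacing) + 1

  blank <- matrix(config$background, H, W)
  nuclei <- matrix(0, H, W)
  reporter <- blank
  stain <- matrix(0, H, W)
  cell_labels <- matrix(0L, H, W)
  nucleus_mask <- matrix(FALSE, H, W)
  agg_labels <- matrix(0L, H, W)

  cell_px_n <- max(1L, round(pi * cell_r_px^2))
  nuc_px_n <- max(1L, round(pi * (config$nucleus_radius_um / px)^2))

  n_agg_cells <- round(config$p_agg * config$n_cells)
  agg_cells <- integer(0)
  if (config$n_cells > 0 && n_agg_cells > 0) {
    agg_cells <- withr::with_seed(config$seed,
                                  sort(sample(seq_len(config$n_cells), n_agg_cells)))
  }

  # per-cell aggregate plan: areas planted in each positive cell
  if (config$neuron_mode) {
    large <- rep_len(config$agg_area_um2, config$n_large_agg)
    plan <- c(large, rep(config$small_focus_area_um2, config$n_small_foci))
  } else {
    plan <- config$agg_area_um2
  }

  aggregates <- list()
  per_cell <- data.frame(cell = seq_len(config$n_cells),
                         truth_agg = seq_len(config$n_cells) %in% agg_cells,
                         agg_area_um2 = rep(0, config$n_cells))
  label_next <- 1L

  for (i in seq_len(config$n_cells)) {
    ctr <- centers[i, ]
    cpx <- .disc_pixels(ctr$row, ctr$col, cell_px_n, H, W)
    npx <- .disc_pixels(ctr$row, ctr$col, nuc_px_n, H, W)
    cell_labels <- .paint(cell_labels, cpx, i)
    nucleus_mask <- .paint(nucleus_mask, npx, TRUE)
    nuclei <- .paint(nuclei, npx, config$nucleus_intensity)
    stain <- .paint(stain, cpx, config$stain_intensity)
    reporter <- .paint(reporter, cpx, config$cell_intensity)
    if (config$neuron_mode) {
      reporter <- .paint(reporter, npx, config$background)
    }
    if (i %in% agg_cells && length(plan) > 0) {
      nuc_r_px <- sqrt(nuc_px_n / pi)
      for (k in seq_along(plan)) {
        a_px_n <- max(1L, round(plan[k] / px^2))
        a_r_px <- sqrt(a_px_n / pi)
        dist <- nuc_r_px + a_r_px + 2
        if (dist + a_r_px > cell_r_px) {
          stop(sprintf("aggregate of %.1f um^2 does not fit in the cytoplasm of cell %d",
                       plan[k], i), call. = FALSE)
        }
        ang <- 2 * pi * (k - 1) / length(plan) + 0.4
        ar <- round(ctr$row + dist * sin(ang))
        ac <- round(ctr$col + dist * cos(ang))
        apx <- .disc_pixels(ar, ac, a_px_n, H, W)
        reporter <- .paint(reporter, apx, config$agg_intensity)
        agg_labels <- .paint(agg_labels, apx, label_next)
        aggregates[[label_next]] <- data.frame(
          label = label_next, cell = i, area_um2 = nrow(apx) * px^2,
          z = ceiling(config$n_z / 2))
        per_cell$agg_area_um2[i] <- per_cell$agg_area_um2[i] + nrow(apx) * px^2
        label_next <- label_next + 1L
      }
    }
  }
  # nucleus-only objects (no stain, no reporter)
  if (config$n_nuclei_only > 0) {
    for (j in seq_len(config$n_nuclei_only)) {
      ctr <- centers[config$n_cells + j, ]
      npx <- .disc_pixels(ctr$row, ctr$col, nuc_px_n, H, W)
      nuclei <- .paint(nuclei, npx, config$nucleus_intensity)
    }
  }

  agg_z <- ceiling(config$n_z / 2)
  to_stack <- function(diffuse, agg_slice = NULL) {
    if (config$n_z == 1) {
      if (is.null(agg_slice)) diffuse else agg_slice
    } else {
      arr <- array(rep(diffuse, config$n_z), dim = c(H, W, config$n_z))
      if (!is.null(agg_slice)) arr[, , agg_z] <- agg_slice
      arr
    }
  }
  # reporter: diffuse signal in every slice, aggregates only in slice agg_z
  reporter_diffuse <- reporter
  reporter_diffuse[agg_labels > 0] <-
    ifelse(cell_labels[agg_labels > 0] > 0, config$cell_intensity, config$background)
  if (config$neuron_mode) {
    reporter_diffuse[agg_labels > 0 & nucleus_mask] <- config$background
  }
  image <- list(
    channels = list(
      nuclei = to_stack(nuclei),
      reporter = to_stack(reporter_diffuse, reporter),
      stain = to_stack(stain)
    ),
    pixel_size_um = px,
    bit_depth = 8L
  )
  class(image) <- "mc_image"

  agg_labels_stack <- if (config$n_z == 1) agg_labels else {
    arr <- array(0L, dim = c(H, W, config$n_z))
    arr[, , agg_z] <- agg_labels
    arr
  }
  truth <- list(
    cell_labels = cell_labels,
    nucleus_mask = nucleus_mask,
    agg_labels = agg_labels_stack,
    aggregates = if (length(aggregates)) do.call(rbind, aggregates) else
      data.frame(label = integer(0), cell = integer(0),
                 area_um2 = numeric(0), z = integer(0)),
    per_cell = per_cell,
    agg_z = agg_z
  )
  list(image = image, truth = truth)
}

#' Write / read a multi-channel image as TIFF
#'
#' Channels (and z slices) are stored as successive TIFF directories in
#' channel-major order; the pixel size, channel names, z count and bit depth
#' are recorded as JSON in a metadata sidecar (`<path>.json`) written next to
#' the TIFF, so the pair round-trips through [read_mc_tiff()].
#'
#' @param image an `mc_image`.
#' @param path file path.
#' @return `path` invisibly (writer); an `mc_image` (reader).
#' @export
write_mc_tiff <- function(image, path) {
  if (!inherits(image, "mc_image")) stop("'image' must be an mc_image", call. = FALSE)
  slices <- list()
  n_z_of <- function(ch) if (length(dim(ch)) == 3) dim(ch)[3] else 1L
  n_z <- n_z_of(image$channels[[1]])
  for (ch in names(image$channels)) {
    arr <- image$channels[[ch]]
    for (z in seq_len(n_z)) {
      sl <- if (n_z == 1) arr else arr[, , z]
      slices[[length(slices) + 1]] <- sl / 255
    }
  }
  tiff::writeTIFF(slices, path, bits.per.sample = 8L)
  jsonlite::write_json(list(channels = names(image$channels),
                            n_z = n_z,
                            pixel_size_um = image$pixel_size_um,
                            bit_depth = image$bit_depth),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_mc_tiff
#' @export
read_mc_tiff <- function(path) {
  if (!file.exists(path)) stop(sprintf("file '%s' does not exist", path), call. = FALSE)
  slices <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) {
    stop(sprintf("image '%s' lacks its metadata sidecar '%s'", path, sidecar),
         call. = FALSE)
  }
  meta <- jsonlite::fromJSON(sidecar)
  n_z <- meta$n_z
  channels <- list()
  idx <- 1L
  for (ch in meta$channels) {
    if (n_z == 1) {
      channels[[ch]] <- slices[[idx]] * 1.0
      idx <- idx + 1L
    } else {
      H <- nrow(slices[[idx]]); W <- ncol(slices[[idx]])
      arr <- array(0, dim = c(H, W, n_z))
      for (z in seq_len(n_z)) {
        arr[, , z] <- slices[[idx]]
        idx <- idx + 1L
      }
      channels[[ch]] <- arr
    }
  }
  image <- list(channels = channels,
                pixel_size_um = meta$pixel_size_um,
                bit_depth = meta$bit_depth)
  class(image) <- "mc_image"
  image
}
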