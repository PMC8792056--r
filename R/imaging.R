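# Deterministic image quantification: thresholds, connected components,
# distance-transform watershed. EBImage supplies the morphological operators.

.as_2d <- function(ch) {
  if (length(dim(ch)) == 3) apply(ch, c(1, 2), max) else ch
}

.label_areas <- function(labels) {
  tab <- table(labels[labels > 0])
  data.frame(label = as.integer(names(tab)), n_px = as.integer(tab))
}

#' Count cells positive in both the nuclear and the stain channel
#'
#' Reproduces dual-channel cell counting: the stain channel (e.g. a
#' FLAG-tagged chaperone) is thresholded and labelled into connected
#' components, and a component is counted as a cell only if it also contains
#' nuclear-marker signal above its threshold and its area reaches
#' `min_cell_area_um2` (non-strict). Thresholds are strict (`value >
#' threshold`).
#'
#' @param image an `mc_image` with `nuclei` and `stain` channels (z-stacks
#'   are maximum-projected first).
#' @param nuc_threshold,stain_threshold 8-bit intensity thresholds.
#' @param min_cell_area_um2 minimum cell area (um^2), inclusive.
#' @return list with `mask` (label matrix, labels `1..n_cells`) and
#'   `n_cells`.
#' @export
detect_cells <- function(image, nuc_threshold = 50, stain_threshold = 50,
                         min_cell_area_um2 = 50) {
  if (!inherits(image, "mc_image")) stop("'image' must be an mc_image", call. = FALSE)
  for (ch in c("nuclei", "stain")) {
    if (is.null(image$channels[[ch]])) {
      stop(sprintf("image lacks the '%s' channel", ch), call. = FALSE)
    }
  }
  px2 <- image$pixel_size_um^2
  nuc <- .as_2d(image$channels$nuclei) > nuc_threshold
  stn <- .as_2d(image$channels$stain) > stain_threshold
  labels <- EBImage::bwlabel(stn)
  labels <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  keep <- integer(0)
  if (any(labels > 0)) {
    areas <- .label_areas(labels)
    has_nucleus <- vapply(areas$label, function(l) any(nuc[labels == l]), logical(1))
    big_enough <- areas$n_px * px2 >= min_cell_area_um2
    keep <- areas$label[has_nucleus & big_enough]
  }
  out <- matrix(0L, nrow(labels), ncol(labels))
  for (i in seq_along(keep)) out[labels == keep[i]] <- i
  list(mask = out, n_cells = length(keep))
}

#' Segment aggregates by threshold and distance-transform watershed
#'
#' The reporter channel is thresholded (strict `>`), touching blobs are
#' split by a watershed on the distance transform (seeded at its maxima),
#' and objects whose area reaches `min_agg_area_um2` (non-strict) are
#' retained with areas in um^2. This is a deterministic operator chain:
#' identical input yields identical tables.
#'
#' @param image an `mc_image` (its `reporter` channel is used; z-stacks are
#'   maximum-projected) or a plain numeric matrix, in which case
#'   `pixel_size_um` must be given.
#' @param intensity_threshold 8-bit intensity threshold (strict).
#' @param min_agg_area_um2 minimum object area (um^2), inclusive.
#' @param pixel_size_um microns per pixel (only for matrix input).
#' @return list with `labels` (label matrix) and `table` (data frame
#'   `label`, `area_um2`, `centroid_row`, `centroid_col`).
#' @export
segment_aggregates <- function(image, intensity_threshold = 252,
                               min_agg_area_um2 = 0.25, pixel_size_um = NULL) {
  if (inherits(image, "mc_image")) {
    if (is.null(image$channels$reporter)) {
      stop("image lacks the 'reporter' channel", call. = FALSE)
    }
    mat <- .as_2d(image$channels$reporter)
    pixel_size_um <- image$pixel_size_um
  } else {
    mat <- image
    if (is.null(pixel_size_um)) stop("'pixel_size_um' required for matrix input", call. = FALSE)
  }
  px2 <- pixel_size_um^2
  bin <- mat > intensity_threshold
  empty <- list(labels = matrix(0L, nrow(mat), ncol(mat)),
                table = data.frame(label = integer(0), area_um2 = numeric(0),
                                   centroid_row = numeric(0), centroid_col = numeric(0)))
  if (!any(bin)) return(empty)
  dm <- EBImage::distmap(bin)
  ws <- EBImage::watershed(dm, tolerance = 1)
  labels <- matrix(as.integer(ws), nrow(mat), ncol(mat))
  areas <- .label_areas(labels)
  keep <- areas$label[areas$n_px * px2 >= min_agg_area_um2]
  if (length(keep) == 0) return(empty)
  out <- matrix(0L, nrow(mat), ncol(mat))
  rows <- data.frame(label = seq_along(keep), area_um2 = NA_real_,
                     centroid_row = NA_real_, centroid_col = NA_real_)
  for (i in seq_along(keep)) {
    sel <- labels == keep[i]
    out[sel] <- i
    idx <- which(sel, arr.ind = TRUE)
    rows$area_um2[i] <- nrow(idx) * px2
    rows$centroid_row[i] <- mean(idx[, 1])
    rows$centroid_col[i] <- mean(idx[, 2])
  }
  list(labels = out, table = rows)
}

#' Partition aggregate areas into nuclear and extranuclear components
#'
#' The nuclear mask is dilated by `perinuclear_radius_um` to form the
#' nuclear-plus-perinuclear region; for each aggregate, the signal falling
#' inside that region is counted as its nuclear share and subtracted from
#' the total to give the extranuclear share, so the two components always
#' sum to the object's area. Each aggregate is assigned to the cell whose
#' label it overlaps most; an aggregate overlapping no cell is assigned to
#' the nearest cell within `orphan_cap_um`, else flagged as an orphan.
#'
#' @param agg result of [segment_aggregates()] (list with `labels`, `table`).
#' @param nucleus_mask logical/binary matrix of nuclear-marker signal.
#' @param pixel_size_um microns per pixel.
#' @param perinuclear_radius_um dilation radius (um) defining the fixed area
#'   around the nucleus (default 2 um).
#' @param cell_labels optional cell label matrix for parent assignment.
#' @param orphan_cap_um maximum centroid distance for rescuing an orphan
#'   aggregate (um).
#' @return the aggregate table with added columns `nuclear_area_um2`,
#'   `extranuclear_area_um2`, `parent_cell` (NA for orphans) and `orphan`.
#' @export
localize_aggregates <- function(agg, nucleus_mask, pixel_size_um,
                                perinuclear_radius_um = 2,
                                cell_labels = NULL, orphan_cap_um = 20) {
  px2 <- pixel_size_um^2
  tab <- agg$table
  labels <- agg$labels
  r_px <- max(0L, round(perinuclear_radius_um / pixel_size_um))
  region <- nucleus_mask > 0
  if (r_px > 0) {
    brush <- EBImage::makeBrush(2L * r_px + 1L, shape = "disc")
    region <- EBImage::dilate(region, brush) > 0
  }
  tab$nuclear_area_um2 <- NA_real_
  tab$extranuclear_area_um2 <- NA_real_
  tab$parent_cell <- NA_integer_
  tab$orphan <- FALSE
  if (nrow(tab) == 0) return(tab)
  cell_centroids <- NULL
  if (!is.null(cell_labels) && any(cell_labels > 0)) {
    cl <- .label_areas(cell_labels)
    cell_centroids <- t(vapply(cl$label, function(l) {
      idx <- which(cell_labels == l, arr.ind = TRUE)
      c(mean(idx[, 1]), mean(idx[, 2]))
    }, numeric(2)))
    rownames(cell_centroids) <- cl$label
  }
  for (i in seq_len(nrow(tab))) {
    sel <- labels == tab$label[i]
    n_px <- sum(sel)
    n_nuc <- sum(sel & region)
    tab$nuclear_area_um2[i] <- n_nuc * px2
    tab$extranuclear_area_um2[i] <- (n_px - n_nuc) * px2
    if (!is.null(cell_labels)) {
      over <- cell_labels[sel]
      over <- over[over > 0]
      if (length(over)) {
        tab$parent_cell[i] <- as.integer(names(which.max(table(over))))
      } else if (!is.null(cell_centroids)) {
        d <- sqrt((cell_centroids[, 1] - tab$centroid_row[i])^2 +
                  (cell_centroids[, 2] - tab$centroid_col[i])^2) * pixel_size_um
        if (min(d) <= orphan_cap_um) {
          tab$parent_cell[i] <- as.integer(rownames(cell_centroids)[which.min(d)])
        } else {
          tab$orphan[i] <- TRUE
        }
      } else {
        tab$orphan[i] <- TRUE
      }
    }
  }
  tab
}

#' Neuron z-stack aggregation-fraction pipeline
#'
#' For each confocal z-stack: `n_slices` successive central slices are
#' maximum-intensity projected; fluorescent cells are found by intensity
#' threshold (strict `> intensity_threshold`), separated by watershed on the
#' distance transform, and filtered by size (strict `> min_cell_area_um2`);
#' aggregate pixels (strict `> agg_intensity_threshold`) are summed per
#' cell, and a cell is aggregate-containing iff its summed aggregate area
#' strictly exceeds `agg_area_rule_um2`. The per-image readout is the
#' fraction of aggregate-containing cells among all detected cells.
#'
#' @param zstacks list of `mc_image` z-stacks (reporter channel used).
#' @param n_slices number of successive slices to project (default 15).
#' @param intensity_threshold cell detection threshold on 8-bit data
#'   (default 240, strict).
#' @param min_cell_area_um2 cell size filter (default 50 um^2, strict).
#' @param agg_area_rule_um2 per-cell summed aggregate area above which a
#'   cell is aggregate-containing (default 5 um^2, strict).
#' @param agg_intensity_threshold aggregate detection threshold (strict).
#' @param image_ids optional character vector of image ids.
#' @return data frame with one row per stack: `image_id`, `n_cells`,
#'   `n_agg_cells`, `f_agg` (NA with `valid = FALSE` when no cell is
#'   detected).
#' @export
neuron_batch <- function(zstacks, n_slices = 15, intensity_threshold = 240,
                         min_cell_area_um2 = 50, agg_area_rule_um2 = 5,
                         agg_intensity_threshold = 252, image_ids = NULL) {
  if (inherits(zstacks, "mc_image")) zstacks <- list(zstacks)
  if (is.null(image_ids)) image_ids <- sprintf("image_%02d", seq_along(zstacks))
  rows <- vector("list", length(zstacks))
  for (j in seq_along(zstacks)) {
    img <- zstacks[[j]]
    rep_ch <- img$channels$reporter
    nz <- if (length(dim(rep_ch)) == 3) dim(rep_ch)[3] else 1L
    if (nz < n_slices) {
      stop(sprintf("stack '%s' has %d slices (need >= %d)", image_ids[j], nz, n_slices),
           call. = FALSE)
    }
    start <- floor((nz - n_slices) / 2) + 1
    mip <- if (nz == 1) rep_ch else
      apply(rep_ch[, , start:(start + n_slices - 1), drop = FALSE], c(1, 2), max)
    px2 <- img$pixel_size_um^2
    bin <- mip > intensity_threshold
    n_cells <- 0L; n_agg_cells <- 0L
    if (any(bin)) {
      ws <- EBImage::watershed(EBImage::distmap(bin), tolerance = 1)
      cl <- matrix(as.integer(ws), nrow(mip), ncol(mip))
      areas <- .label_areas(cl)
      keep <- areas$label[areas$n_px * px2 > min_cell_area_um2]
      n_cells <- length(keep)
      if (n_cells > 0) {
        abin <- mip > agg_intensity_threshold
        agg_area <- vapply(keep, function(l) sum(abin[cl == l]) * px2, numeric(1))
        n_agg_cells <- sum(agg_area > agg_area_rule_um2)
      }
    }
    rows[[j]] <- data.frame(image_id = image_ids[j],
                            n_cells = n_cells,
                            n_agg_cells = n_agg_cells,
                            f_agg = if (n_cells > 0) n_agg_cells / n_cells else NA_real_,
                            valid = n_cells > 0)
  }
  do.call(rbind, rows)
}

#' Compare aggregation fractions between two conditions across experiments
#'
#' Within each experiment, every image's aggregate-containing-cell fraction
#' is normalized to the mean fraction over all images of both conditions
#' (so the normalized fractions of an experiment average to 1), and the two
#' conditions are compared with a two-sided two-sample Student t-test on
#' the normalized fractions.
#'
#' @param results_a,results_b data frames with columns `image_id`,
#'   `experiment`, `f_agg` for the two conditions.
#' @return list with `per_image` (both conditions, with `norm_f_agg`) and
#'   `per_experiment` (means +/- SEM per condition, `t`, `p`).
#' @export
batch_compare <- function(results_a, results_b) {
  .chk_cols(results_a, c("image_id", "experiment", "f_agg"), "results_a")
  .chk_cols(results_b, c("image_id", "experiment", "f_agg"), "results_b")
  results_a$condition <- "A"; results_b$condition <- "B"
  all_res <- rbind(results_a[, c("image_id", "experiment", "f_agg", "condition")],
                   results_b[, c("image_id", "experiment", "f_agg", "condition")])
  sem <- function(v) sd(v) / sqrt(length(v))
  per_image <- list(); per_exp <- list()
  for (e in unique(all_res$experiment)) {
    sub <- all_res[all_res$experiment == e, , drop = FALSE]
    if (any(table(sub$condition) < 2) || length(unique(sub$condition)) < 2) {
      stop(sprintf("experiment '%s' needs >= 2 images per condition", e), call. = FALSE)
    }
    m <- mean(sub$f_agg)
    if (m == 0) {
      stop(sprintf("experiment '%s' has mean f_agg = 0; normalization refused", e),
           call. = FALSE)
    }
    sub$norm_f_agg <- sub$f_agg / m
    a <- sub$norm_f_agg[sub$condition == "A"]
    b <- sub$norm_f_agg[sub$condition == "B"]
    if (identical(a, b)) {
      tstat <- 0; pval <- 1
    } else {
      tt <- t.test(a, b, var.equal = TRUE, alternative = "two.sided")
      tstat <- unname(tt$statistic); pval <- tt$p.value
    }
    per_image[[e]] <- sub
    per_exp[[e]] <- data.frame(experiment = e,
                               mean_a = mean(a), sem_a = sem(a),
                               mean_b = mean(b), sem_b = sem(b),
                               t = tstat, p = pval)
  }
  list(per_image = do.call(rbind, per_image),
       per_experiment = do.call(rbind, per_exp))
}
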