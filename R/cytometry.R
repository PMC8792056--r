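#' Read cytometry events from CSV or FCS into an event table
#'
#' Builds the canonical `event_table` used by the gating functions: one row
#' per event with reporter pulse height `reporter_H`, width `reporter_W`,
#' area `reporter_A`, a viability channel `dapi` and a size (scatter) channel
#' `fsc`. CSV files written by [write_events_csv()] round-trip without a
#' channel map; other sources supply `channel_map`, a named list/vector with
#' entries `height`, `width`, `area`, `viability`, `scatter` giving the
#' source column (CSV) or `$PnN` parameter name (FCS) for each canonical
#' channel.
#'
#' @param path input file.
#' @param format `"csv"` or `"fcs"`.
#' @param channel_map named list mapping
#'   `height`/`width`/`area`/`viability`/`scatter` to source channel names;
#'   may be `NULL` for canonical CSV files.
#' @return an `event_table` data frame. Truth columns (`truth_agg`,
#'   `truth_dead`), when present in a CSV, are carried through.
#' @export
read_events <- function(path, format = c("csv", "fcs"), channel_map = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file '%s' does not exist", path), call. = FALSE)
  canonical <- c(height = "reporter_H", width = "reporter_W",
                 area = "reporter_A", viability = "dapi", scatter = "fsc")
  if (format == "csv") {
    if (file.size(path) == 0) stop(sprintf("file '%s' is empty", path), call. = FALSE)
    raw <- read.csv(path, check.names = FALSE)
    if (nrow(raw) == 0) stop(sprintf("file '%s' contains no events", path), call. = FALSE)
    if (is.null(channel_map)) {
      channel_map <- as.list(canonical)
    }
    src <- raw
  } else {
    fcs <- read_fcs(path)
    if (is.null(channel_map)) {
      stop("reading FCS requires a 'channel_map' naming the $PnN channels",
           call. = FALSE)
    }
    src <- as.data.frame(fcs$data, check.names = FALSE)
    if (nrow(src) == 0) stop(sprintf("file '%s' contains no events", path), call. = FALSE)
  }
  channel_map <- as.list(channel_map)
  missing_keys <- setdiff(names(canonical), names(channel_map))
  if (length(missing_keys)) {
    stop(sprintf("channel_map lacks entries for: %s",
                 paste(missing_keys, collapse = ", ")), call. = FALSE)
  }
  ev <- data.frame(event_id = seq_len(nrow(src)))
  for (key in names(canonical)) {
    col <- channel_map[[key]]
    if (!col %in% names(src)) {
      stop(sprintf("mapped channel '%s' (%s) not found in %s", col, key, path),
           call. = FALSE)
    }
    ev[[canonical[[key]]]] <- as.numeric(src[[col]])
  }
  for (extra in intersect(c("truth_agg", "truth_dead"), names(src))) {
    ev[[extra]] <- as.logical(src[[extra]])
  }
  bad <- which(!(ev$reporter_W > 0))
  if (length(bad)) {
    stop(sprintf("non-positive pulse width in %d event(s): %s", length(bad),
                 paste(head(bad, 10), collapse = ", ")), call. = FALSE)
  }
  class(ev) <- c("event_table", "data.frame")
  ev
}

#' Pulse-shape gating statistic
#'
#' The scalar statistic used for the aggregate gate: `R = H / W`, the ratio
#' of reporter pulse height to pulse width. Cells whose reporter is
#' concentrated in an aggregate produce taller, narrower pulses at matched
#' total fluorescence, so `R` rises in aggregate-bearing cells; the gate is a
#' one-sided upper threshold on `R`.
#'
#' @param events an `event_table`.
#' @return numeric vector of `R` values, one per event.
#' @export
pulse_ratio <- function(events) {
  .chk_cols(events, c("reporter_H", "reporter_W"), "event table")
  events$reporter_H / events$reporter_W
}

.pregate <- function(events, viability_threshold, scatter_bounds) {
  viable <- events[events$dapi < viability_threshold, , drop = FALSE]
  sized <- viable[viable$fsc >= scatter_bounds[1] & viable$fsc <= scatter_bounds[2],
                  , drop = FALSE]
  list(viable = viable, sized = sized)
}

#' Calibrate the aggregate (AGG+) gate on a wild-type sample
#'
#' The gate threshold is set so that an AGG+ population is, by construction,
#' (almost) absent from cells expressing the non-aggregating wild-type
#' protein: after viability and size gating of the wild-type events, the
#' threshold is the empirical `(1 - alpha)` quantile (the
#' `ceiling((1-alpha) * n)`-th order statistic) of the pulse statistic
#' `R = H/W`. Events are later called AGG+ iff `R` exceeds the threshold
#' strictly, so re-applying the gate to its own calibration sample yields an
#' AGG+ fraction of at most `alpha`.
#'
#' @param wt_events `event_table` of the wild-type (non-aggregating) sample.
#' @param alpha calibration false-positive rate on the wild-type sample, in
#'   (0, 0.05]. The default 0.001 makes the wild-type read back an effective
#'   AGG+ fraction of zero.
#' @param viability_threshold events with viability channel value at or above
#'   this are excluded as dead.
#' @param scatter_bounds length-2 numeric `[low, high]`; events with scatter
#'   outside this window are excluded as inappropriately sized.
#' @return a `pulsa_gate` object (threshold plus the pre-gate parameters).
#' @export
calibrate_pulsa_gate <- function(wt_events, alpha = 0.001,
                                 viability_threshold = 1000,
                                 scatter_bounds = c(60, 140)) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 0.05) {
    stop("'alpha' must be in (0, 0.05]", call. = FALSE)
  }
  if (length(scatter_bounds) != 2L || scatter_bounds[1] >= scatter_bounds[2]) {
    stop("'scatter_bounds' must be an increasing [low, high] pair", call. = FALSE)
  }
  g <- .pregate(wt_events, viability_threshold, scatter_bounds)
  n <- nrow(g$sized)
  if (n < 100) {
    stop(sprintf("calibration refused: only %d wild-type events survive viability+size gating (need >= 100)", n),
         call. = FALSE)
  }
  r <- sort(pulse_ratio(g$sized))
  threshold <- r[ceiling((1 - alpha) * n)]
  gate <- list(statistic = "H/W",
               threshold = threshold,
               alpha = alpha,
               viability_threshold = viability_threshold,
               scatter_bounds = as.numeric(scatter_bounds),
               n_calibration = n)
  class(gate) <- "pulsa_gate"
  gate
}

#' Apply viability, size and pulse-shape gates to an event table
#'
#' Sequential gating, mirroring the order of operations on the cytometer:
#' cells of appropriate size are kept (scatter within bounds), non-viable
#' cells (viability-dye positive) are excluded, then an event is AGG+ iff its
#' pulse statistic `R = H/W` strictly exceeds the calibrated threshold. The
#' AGG+ fraction is reported out of the events surviving the viability and
#' size gates.
#'
#' @param events an `event_table`.
#' @param gate a `pulsa_gate` from [calibrate_pulsa_gate()].
#' @return a `gating_result` list: counts `n_total`, `n_viable`, `n_sized`,
#'   `n_aggpos`, the fraction `f_AGG = n_aggpos / n_sized`, and `valid`
#'   (`FALSE`, with `f_AGG = NA`, when no event survives the pre-gates).
#' @export
apply_gates <- function(events, gate) {
  if (!inherits(gate, "pulsa_gate")) {
    stop("'gate' must be a calibrated pulsa_gate", call. = FALSE)
  }
  .chk_cols(events, c("reporter_H", "reporter_W", "dapi", "fsc"), "event table")
  g <- .pregate(events, gate$viability_threshold, gate$scatter_bounds)
  n_sized <- nrow(g$sized)
  if (n_sized == 0) {
    res <- list(n_total = nrow(events), n_viable = nrow(g$viable),
                n_sized = 0L, n_aggpos = 0L, f_AGG = NA_real_, valid = FALSE)
  } else {
    n_aggpos <- sum(pulse_ratio(g$sized) > gate$threshold)
    res <- list(n_total = nrow(events), n_viable = nrow(g$viable),
                n_sized = n_sized, n_aggpos = n_aggpos,
                f_AGG = n_aggpos / n_sized, valid = TRUE)
  }
  class(res) <- "gating_result"
  res
}

#' @export
print.gating_result <- function(x, ...) {
  cat(sprintf("PulSA gating: %d events -> %d viable -> %d sized -> %d AGG+ (f_AGG = %s)\n",
              x$n_total, x$n_viable, x$n_sized, x$n_aggpos,
              if (x$valid) sprintf("%.4f", x$f_AGG) else "undefined"))
  invisible(x)
}

#' Gate a set of samples and tabulate AGG+ fractions
#'
#' Convenience wrapper applying one calibrated gate to several samples and
#' returning the one-row-per-sample summary consumed by
#' [modulation_scores()].
#'
#' @param samples named list of `event_table`s.
#' @param gate a `pulsa_gate`.
#' @return data frame with columns `sample_id`, `n_total`, `n_viable`,
#'   `n_sized`, `n_aggpos`, `f_AGG`.
#' @export
gate_samples <- function(samples, gate) {
  stopifnot(is.list(samples), length(names(samples)) == length(samples))
  rows <- lapply(names(samples), function(id) {
    r <- apply_gates(samples[[id]], gate)
    data.frame(sample_id = id, n_total = r$n_total, n_viable = r$n_viable,
               n_sized = r$n_sized, n_aggpos = r$n_aggpos, f_AGG = r$f_AGG)
  })
  do.call(rbind, rows)
}
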