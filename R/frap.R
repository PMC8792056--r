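#' Normalize FRAP traces to pre-bleach baseline and align to the bleach
#'
#' Every intensity of a trace is divided by the median of the 27 frames
#' immediately preceding the bleach, so the pre-bleach plateau reads 1
#' regardless of expression level or laser settings, and timestamps are
#' shifted so the first post-bleach frame is t = 0. Traces with fewer than 27
#' pre-bleach frames are rejected by name.
#'
#' @param traces a `frap_traces` data frame (long form: `trace_id`, `t_s`,
#'   `intensity`, `is_prebleach`).
#' @return a `frap_traces_norm` data frame: `trace_id`, `t_s` (aligned, t = 0
#'   at the first post-bleach frame), `norm_intensity`, `is_prebleach`.
#' @export
normalize_and_align <- function(traces) {
  .chk_cols(traces, c("trace_id", "t_s", "intensity", "is_prebleach"), "trace table")
  out <- lapply(split(traces, traces$trace_id), function(tr) {
    tr <- tr[order(tr$t_s), , drop = FALSE]
    pre <- which(tr$is_prebleach)
    post <- which(!tr$is_prebleach)
    if (length(pre) < 27) {
      stop(sprintf("trace '%s' has %d pre-bleach frames (need >= 27)",
                   tr$trace_id[1], length(pre)), call. = FALSE)
    }
    if (length(post) == 0) {
      stop(sprintf("trace '%s' has no post-bleach frames", tr$trace_id[1]),
           call. = FALSE)
    }
    baseline <- median(tr$intensity[tail(pre, 27)])
    data.frame(trace_id = tr$trace_id,
               t_s = tr$t_s - tr$t_s[post[1]],
               norm_intensity = tr$intensity / baseline,
               is_prebleach = tr$is_prebleach)
  })
  nt <- do.call(rbind, out)
  rownames(nt) <- NULL
  class(nt) <- c("frap_traces_norm", "data.frame")
  nt
}

#' Bin post-bleach recovery curves into fixed-size time bins
#'
#' For each aggregate (trace), the post-bleach samples from t = 0 onwards are
#' split into consecutive windows of `samples_per_bin` timepoints and the
#' median of each window is taken, giving a per-aggregate binned curve that
#' is robust to single-frame outliers. A trailing partial window is kept only
#' when it contains at least half a bin of samples. All traces of a
#' condition must yield the same number of bins; when acquisition lengths
#' differ the curves are truncated to the shortest with a warning.
#'
#' @param norm a `frap_traces_norm` data frame from [normalize_and_align()].
#' @param samples_per_bin samples per bin (default 20 timepoints).
#' @param condition optional condition label carried into comparisons.
#' @return a `binned_curve` list: `mat` (aggregates x bins matrix of bin
#'   medians), `bin_center_s` (median sample time per bin, seconds),
#'   `samples_per_bin`, `condition`.
#' @export
bin_curve <- function(norm, samples_per_bin = 20, condition = NA_character_) {
  .chk_cols(norm, c("trace_id", "t_s", "norm_intensity"), "normalized traces")
  samples_per_bin <- .chk_count(samples_per_bin, "samples_per_bin")
  per_trace <- split(norm[norm$t_s >= 0, , drop = FALSE],
                     norm$trace_id[norm$t_s >= 0])
  per_trace <- Filter(function(x) nrow(x) > 0, per_trace)
  if (length(per_trace) == 0) stop("no post-bleach samples to bin", call. = FALSE)
  n_bins_of <- function(n) {
    full <- n %/% samples_per_bin
    tailn <- n - full * samples_per_bin
    full + as.integer(tailn >= ceiling(samples_per_bin / 2))
  }
  nb <- vapply(per_trace, function(x) n_bins_of(nrow(x)), integer(1))
  if (any(nb == 0)) stop("a trace has too few post-bleach samples to form a bin", call. = FALSE)
  use_bins <- min(nb)
  if (length(unique(nb)) > 1) {
    warning(sprintf("traces yield different bin counts; truncating to %d bins", use_bins),
            call. = FALSE)
  }
  mat <- matrix(NA_real_, nrow = length(per_trace), ncol = use_bins,
                dimnames = list(names(per_trace), NULL))
  times <- vector("list", use_bins)
  for (i in seq_along(per_trace)) {
    x <- per_trace[[i]][order(per_trace[[i]]$t_s), , drop = FALSE]
    for (b in seq_len(use_bins)) {
      lo <- (b - 1) * samples_per_bin + 1
      hi <- min(b * samples_per_bin, nrow(x))
      mat[i, b] <- median(x$norm_intensity[lo:hi])
      times[[b]] <- c(times[[b]], x$t_s[lo:hi])
    }
  }
  out <- list(mat = mat,
              bin_center_s = vapply(times, median, numeric(1)),
              samples_per_bin = samples_per_bin,
              condition = condition)
  class(out) <- "binned_curve"
  out
}

#' Recovery percentage of a binned FRAP curve
#'
#' Summary mobility readout: 100 times the median over aggregates of the
#' final-bin median normalized intensity. With intensities normalized to a
#' pre-bleach plateau of 1, this is the percent of the original signal
#' recovered at the end of the acquisition, set by the mobile fraction and
#' the bleach depth.
#'
#' @param binned a `binned_curve`.
#' @return recovery percent (scalar).
#' @export
recovery_percent <- function(binned) {
  if (!inherits(binned, "binned_curve")) stop("'binned' must be a binned_curve", call. = FALSE)
  100 * median(binned$mat[, ncol(binned$mat)])
}

#' Compare two FRAP conditions bin by bin
#'
#' For each time bin, a two-sided two-sample t-test across aggregates of the
#' per-aggregate bin medians, with Benjamini-Hochberg adjustment across bins;
#' per condition the bin median and SEM are reported. Conditions must share
#' bin edges; bins with fewer than two aggregates on either side are skipped
#' with a warning.
#'
#' @param binned_a,binned_b `binned_curve` objects for the two conditions.
#' @return a data frame with one row per bin: `bin_center_s`, `median_a`,
#'   `sem_a`, `median_b`, `sem_b`, `t`, `p`, `q` (BH-adjusted).
#' @export
compare_conditions <- function(binned_a, binned_b) {
  if (!inherits(binned_a, "binned_curve") || !inherits(binned_b, "binned_curve")) {
    stop("both conditions must be binned_curve objects", call. = FALSE)
  }
  if (ncol(binned_a$mat) != ncol(binned_b$mat) ||
      any(abs(binned_a$bin_center_s - binned_b$bin_center_s) >
          binned_a$samples_per_bin)) {
    stop("conditions do not share bin edges", call. = FALSE)
  }
  nb <- ncol(binned_a$mat)
  res <- data.frame(bin_center_s = binned_a$bin_center_s,
                    median_a = NA_real_, sem_a = NA_real_,
                    median_b = NA_real_, sem_b = NA_real_,
                    t = NA_real_, p = NA_real_, q = NA_real_)
  sem <- function(v) sd(v) / sqrt(length(v))
  for (b in seq_len(nb)) {
    va <- binned_a$mat[, b]
    vb <- binned_b$mat[, b]
    res$median_a[b] <- median(va); res$sem_a[b] <- sem(va)
    res$median_b[b] <- median(vb); res$sem_b[b] <- sem(vb)
    if (length(va) < 2 || length(vb) < 2) {
      warning(sprintf("bin %d skipped: fewer than 2 aggregates in a condition", b),
              call. = FALSE)
      next
    }
    if (sd(va) == 0 && sd(vb) == 0 && median(va) == median(vb)) {
      res$t[b] <- 0; res$p[b] <- 1
    } else {
      tt <- t.test(va, vb, alternative = "two.sided")
      res$t[b] <- unname(tt$statistic)
      res$p[b] <- tt$p.value
    }
  }
  done <- !is.na(res$p)
  res$q[done] <- p.adjust(res$p[done], method = "BH")
  res
}
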