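#' Aggregation Modulation Scores from gated AGG+ fractions
#'
#' The score of a chaperone replicate is
#' `S = log2(f_AGG(chaperone) / f_AGG(control))`, where the control fraction
#' is the mean AGG+ fraction of the neutral-protein (e.g. DsRed) control
#' samples run in the same batch (day). Negative scores mean aggregation
#' alleviation (a score of -1 corresponds to a 50% reduction in
#' aggregate-containing cells), positive scores aggravation. Replicates are
#' aggregated per chaperone across batches as mean +/- SEM.
#'
#' A chaperone replicate with `f_AGG = 0` cannot be log-transformed; it is
#' scored with the continuity substitution `0.5 / n_sized` (half an event out
#' of the gated denominator) and flagged, which requires the `n_sized` column.
#'
#' @param fractions data frame with columns `sample_id`, `chaperone_id`,
#'   `batch`, `f_AGG`, and optionally `n_sized`. Control samples carry
#'   `control_id` in `chaperone_id`.
#' @param control_id value of `chaperone_id` identifying control samples
#'   (default `"DsRed"`).
#' @return a `screen_scores` list: `$replicates` (per-replicate scores with a
#'   `flagged` column) and `$summary` (per chaperone: `n`, `mean_score`,
#'   `sem`; `sem` is `sd/sqrt(n)` and `NA` when `n = 1`).
#' @export
modulation_scores <- function(fractions, control_id = "DsRed") {
  .chk_cols(fractions, c("sample_id", "chaperone_id", "batch", "f_AGG"),
            "fractions table")
  is_ctrl <- fractions$chaperone_id == control_id
  if (!any(is_ctrl)) {
    stop(sprintf("no control samples (chaperone_id == '%s') found", control_id),
         call. = FALSE)
  }
  ctrl_mean <- tapply(fractions$f_AGG[is_ctrl], fractions$batch[is_ctrl], mean)
  chap <- fractions[!is_ctrl, , drop = FALSE]
  missing_ctrl <- setdiff(unique(chap$batch), names(ctrl_mean))
  if (length(missing_ctrl)) {
    stop(sprintf("batch(es) without control samples: %s",
                 paste(missing_ctrl, collapse = ", ")), call. = FALSE)
  }
  if (any(ctrl_mean[unique(chap$batch)] <= 0)) {
    stop("every batch must have a positive mean control AGG+ fraction", call. = FALSE)
  }
  f <- chap$f_AGG
  flagged <- f == 0
  if (any(flagged)) {
    if (!"n_sized" %in% names(chap)) {
      stop("replicates with f_AGG = 0 require an 'n_sized' column for the continuity substitution",
           call. = FALSE)
    }
    f[flagged] <- 0.5 / chap$n_sized[flagged]
  }
  score <- log2(f / as.numeric(ctrl_mean[as.character(chap$batch)]))
  replicates <- data.frame(chaperone_id = chap$chaperone_id,
                           sample_id = chap$sample_id,
                           batch = chap$batch,
                           score = score,
                           flagged = flagged)
  agg <- split(replicates$score, replicates$chaperone_id)
  summary <- data.frame(
    chaperone_id = names(agg),
    n = vapply(agg, length, integer(1)),
    mean_score = vapply(agg, mean, numeric(1)),
    sem = vapply(agg, function(s) if (length(s) >= 2) sd(s) / sqrt(length(s)) else NA_real_,
                 numeric(1)),
    row.names = NULL
  )
  out <- list(replicates = replicates, summary = summary, control_id = control_id)
  class(out) <- "screen_scores"
  out
}

#' Empirical confidence bands from control replicates
#'
#' The screen's null distribution is built from the control (e.g. DsRed)
#' replicates themselves: each control replicate is scored leave-one-out
#' against the mean of the other controls of the same batch, and the sample
#' standard deviation (n-1 denominator) of those scores sets the bands. The
#' 95% band half-width is exactly `2 * STD` and the 99.7% half-width exactly
#' `3 * STD` -- the two-sided Gaussian tail beyond them being ~4.6% and
#' ~0.27%, hence the empirical significance labels p < 0.05 and p < 0.003.
#' Batches with a single control cannot be scored leave-one-out and are
#' excluded with a warning.
#'
#' @param control_fractions data frame with columns `batch` and `f_AGG`, one
#'   row per control replicate.
#' @return a `control_interval` list: `std`, `ci95_halfwidth` (= 2 * std),
#'   `ci997_halfwidth` (= 3 * std), `n_controls`, and the leave-one-out
#'   `scores`.
#' @export
control_interval <- function(control_fractions) {
  .chk_cols(control_fractions, c("batch", "f_AGG"), "control fractions table")
  scores <- numeric(0)
  for (b in unique(control_fractions$batch)) {
    f <- control_fractions$f_AGG[control_fractions$batch == b]
    if (length(f) < 2) {
      warning(sprintf("batch '%s' has a single control replicate; excluded from the null", b),
              call. = FALSE)
      next
    }
    loo_mean <- (sum(f) - f) / (length(f) - 1)
    scores <- c(scores, log2(f / loo_mean))
  }
  if (length(scores) < 3) {
    stop("need >= 3 usable control replicates to build the empirical interval",
         call. = FALSE)
  }
  std <- sd(scores)
  out <- list(std = std,
              ci95_halfwidth = 2 * std,
              ci997_halfwidth = 3 * std,
              n_controls = length(scores),
              scores = scores)
  class(out) <- "control_interval"
  out
}

#' Two-sided Gaussian tail mass beyond k standard deviations
#'
#' Consistency helper for the empirical significance labels: the mass beyond
#' the 95% band (k = 2) is ~0.0455 and beyond the 99.7% band (k = 3) is
#' ~0.0027, below the printed bounds of 0.05 and 0.003.
#'
#' @param k number of standard deviations.
#' @return `2 * pnorm(-k)`.
#' @export
band_tail_prob <- function(k) {
  2 * pnorm(-abs(k))
}

#' Call a chaperone as alleviator, aggravator or not significant
#'
#' A chaperone is a significant alleviator when even the conservative edge of
#' its score, mean + SEM, lies below the negative 95% band
#' (`mean + sem < -ci95_halfwidth`), at the stronger p < 0.003 level when it
#' lies below the 99.7% band. Aggravators are symmetric with
#' `mean - sem > +halfwidth`. A record with a single replicate has no SEM and
#' the call is refused.
#'
#' @param summary either a `screen_scores` object or its `$summary` data
#'   frame (columns `chaperone_id`, `n`, `mean_score`, `sem`).
#' @param ci a `control_interval`.
#' @return data frame `summary` with added columns `call` (one of
#'   `"alleviator"`, `"aggravator"`, `"not-significant"`, `"refused"`) and
#'   `p_level` (`"p<0.003"`, `"p<0.05"` or `"none"`).
#' @export
call_significance <- function(summary, ci) {
  if (inherits(summary, "screen_scores")) summary <- summary$summary
  .chk_cols(summary, c("chaperone_id", "mean_score", "sem"), "score summary")
  if (!inherits(ci, "control_interval")) {
    stop("'ci' must be a control_interval", call. = FALSE)
  }
  call <- character(nrow(summary))
  p_level <- character(nrow(summary))
  for (i in seq_len(nrow(summary))) {
    m <- summary$mean_score[i]
    s <- summary$sem[i]
    if (is.na(s)) {
      call[i] <- "refused"; p_level[i] <- "none"; next
    }
    if (m + s < -ci$ci95_halfwidth) {
      call[i] <- "alleviator"
      p_level[i] <- if (m + s < -ci$ci997_halfwidth) "p<0.003" else "p<0.05"
    } else if (m - s > ci$ci95_halfwidth) {
      call[i] <- "aggravator"
      p_level[i] <- if (m - s > ci$ci997_halfwidth) "p<0.003" else "p<0.05"
    } else {
      call[i] <- "not-significant"; p_level[i] <- "none"
    }
  }
  summary$call <- call
  summary$p_level <- p_level
  summary
}

#' Dose-response trend over increasing chaperone doses
#'
#' Applies [call_significance()] per dose and flags a monotone dose-response
#' when the mean scores are strictly ordered (all decreasing, deepening
#' alleviation with dose, or all increasing).
#'
#' @param series data frame with columns `dose`, `mean_score`, `sem`
#'   (strictly increasing `dose`; at least two doses).
#' @param ci a `control_interval`.
#' @return list with `per_dose` (the series with `call`/`p_level` columns),
#'   `monotone` (logical) and `direction` (`"alleviation"`, `"aggravation"`
#'   or `NA`).
#' @export
dose_response <- function(series, ci) {
  .chk_cols(series, c("dose", "mean_score", "sem"), "dose series")
  if (nrow(series) < 2) stop("need >= 2 doses", call. = FALSE)
  if (any(diff(series$dose) <= 0)) {
    stop("doses must be strictly increasing", call. = FALSE)
  }
  per_dose <- series
  per_dose$chaperone_id <- sprintf("dose_%g", series$dose)
  per_dose <- call_significance(
    data.frame(chaperone_id = per_dose$chaperone_id, n = NA_integer_,
               mean_score = series$mean_score, sem = series$sem), ci)
  per_dose <- cbind(dose = series$dose, per_dose[, c("mean_score", "sem", "call", "p_level")])
  d <- diff(series$mean_score)
  monotone <- all(d < 0) || all(d > 0)
  direction <- if (!monotone) NA_character_ else if (all(d < 0)) "alleviation" else "aggravation"
  list(per_dose = per_dose, monotone = monotone, direction = direction)
}

#' Heat-shock-reporter induction score
#'
#' Plate-reader fluorescence of a stress-inducible promoter reporter,
#' normalized per timepoint: the mean of the empty-vector baseline wells is
#' subtracted, and values are expressed as a percentage of the
#' proteasome-inhibitor (MG132) positive-control wells. Each well's score is
#' the mean of its per-timepoint percentages over the analysis window
#' (default 12-24 h). Timepoints where the positive control does not rise
#' above baseline are dropped with a warning.
#'
#' @param fluor data frame with columns `well`, `timepoint_h`, `value`.
#' @param baseline_wells,mg132_wells character vectors of well ids.
#' @param window numeric length-2, hours (inclusive).
#' @return data frame `well`, `score` (percent of the MG132 response) for
#'   wells that are neither baseline nor positive control.
#' @export
hsr_reporter_score <- function(fluor, baseline_wells, mg132_wells,
                               window = c(12, 24)) {
  .chk_cols(fluor, c("well", "timepoint_h", "value"), "fluorescence table")
  fl <- fluor[fluor$timepoint_h >= window[1] & fluor$timepoint_h <= window[2], ,
              drop = FALSE]
  if (nrow(fl) == 0) stop("no timepoints inside the analysis window", call. = FALSE)
  tps <- sort(unique(fl$timepoint_h))
  keep_tp <- numeric(0)
  base_mean <- mg_mean <- numeric(0)
  for (tp in tps) {
    at <- fl[fl$timepoint_h == tp, , drop = FALSE]
    b <- at$value[at$well %in% baseline_wells]
    m <- at$value[at$well %in% mg132_wells]
    if (length(b) == 0 || length(m) == 0) {
      stop(sprintf("timepoint %g h lacks baseline or MG132 wells", tp), call. = FALSE)
    }
    if (mean(m) == mean(b)) {
      warning(sprintf("timepoint %g h dropped: MG132 mean equals baseline mean", tp),
              call. = FALSE)
      next
    }
    keep_tp <- c(keep_tp, tp)
    base_mean <- c(base_mean, mean(b))
    mg_mean <- c(mg_mean, mean(m))
  }
  if (length(keep_tp) == 0) stop("no usable timepoints in window", call. = FALSE)
  test_wells <- setdiff(unique(fl$well), c(baseline_wells, mg132_wells))
  score <- vapply(test_wells, function(w) {
    s <- vapply(seq_along(keep_tp), function(i) {
      at <- fl[fl$timepoint_h == keep_tp[i] & fl$well == w, "value"]
      100 * (mean(at) - base_mean[i]) / (mg_mean[i] - base_mean[i])
    }, numeric(1))
    mean(s)
  }, numeric(1))
  data.frame(well = test_wells, score = score, row.names = NULL)
}
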