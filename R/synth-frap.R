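#' Configuration for the synthetic FRAP trace generator
#'
#' Each trace is an intensity time course of one bleached aggregate: a
#' pre-bleach plateau at a per-trace baseline `B` (drawn log-normally to
#' emulate expression-level differences between cells), then an exponential
#' recovery. With `t` measured from the first post-bleach frame, the
#' noiseless post-bleach mean is
#' `I(t) = B * ((1 - bleach_depth) + mobile_fraction * bleach_depth * (1 - exp(-t / tau)))`,
#' i.e. the bleach removes a fraction `bleach_depth` of the signal and only
#' the mobile fraction of molecules exchanges back, with time constant `tau`.
#' Additive Gaussian noise is applied as a fraction of the baseline.
#'
#' @param n_traces number of traces (bleached aggregates).
#' @param mobile_fraction fraction of exchanging molecules in `[0,1]`; sets
#'   the recovery plateau.
#' @param tau recovery time constant (s).
#' @param frame_interval frame spacing (s); default 0.93 s.
#' @param n_prebleach number of pre-bleach frames, at least 27 (the
#'   normalization window downstream).
#' @param bleach_depth fraction of signal removed by the bleach, in (0,1].
#' @param post_frames number of post-bleach frames.
#' @param baseline_logsd log-sd of the per-trace baseline.
#' @param noise_sd additive noise, as a fraction of the baseline.
#' @param seed integer seed.
#' @return an object of class `sim_frap_config`.
#' @export
sim_frap_config <- function(n_traces = 150,
                            mobile_fraction = 0.42,
                            tau = 60,
                            frame_interval = 0.93,
                            n_prebleach = 27,
                            bleach_depth = 0.95,
                            post_frames = 302,
                            baseline_logsd = 0.3,
                            noise_sd = 0.05,
                            seed = 1L) {
  cfg <- list(
    n_traces = .chk_count(n_traces, "n_traces"),
    mobile_fraction = .chk_fraction(mobile_fraction, "mobile_fraction"),
    tau = .chk_pos(tau, "tau"),
    frame_interval = .chk_pos(frame_interval, "frame_interval"),
    n_prebleach = .chk_count(n_prebleach, "n_prebleach", min = 27L),
    bleach_depth = .chk_fraction(bleach_depth, "bleach_depth", lower_open = TRUE),
    post_frames = .chk_count(post_frames, "post_frames"),
    baseline_logsd = .chk_pos(baseline_logsd, "baseline_logsd", strict = FALSE),
    noise_sd = .chk_pos(noise_sd, "noise_sd", strict = FALSE),
    seed = .chk_seed(seed)
  )
  class(cfg) <- "sim_frap_config"
  cfg
}

#' Simulate bleach-recovery traces with known truth parameters
#'
#' Draws `n_traces` FRAP traces under [sim_frap_config()]. Frames are sampled
#' at `frame_interval`; the first `n_prebleach` frames sit at the per-trace
#' baseline and the bleach happens between frame `n_prebleach` and frame
#' `n_prebleach + 1` (the first post-bleach frame, which downstream alignment
#' places at t = 0).
#'
#' @param config a [sim_frap_config()] object.
#' @return a `frap_traces` data frame in long form: `trace_id`, `t_s`
#'   (acquisition time), `intensity`, `is_prebleach`. The truth parameters
#'   are attached as `attr(x, "truth")` and are never consulted by the
#'   analysis functions.
#' @export
simulate_frap <- function(config) {
  if (!inherits(config, "sim_frap_config")) {
    stop("'config' must be created with sim_frap_config()", call. = FALSE)
  }
  npre <- config$n_prebleach
  npost <- config$post_frames
  dt <- config$frame_interval
  t_all <- (seq_len(npre + npost) - 1) * dt
  t_post <- (seq_len(npost) - 1) * dt
  mean_post <- (1 - config$bleach_depth) +
    config$mobile_fraction * config$bleach_depth * (1 - exp(-t_post / config$tau))
  withr::with_seed(config$seed, {
    out <- vector("list", config$n_traces)
    for (i in seq_len(config$n_traces)) {
      B <- exp(rnorm(1, 0, config$baseline_logsd)) * 1000
      shape <- c(rep(1, npre), mean_post)
      intensity <- B * shape + rnorm(npre + npost, 0, config$noise_sd * B)
      out[[i]] <- data.frame(
        trace_id = sprintf("trace_%03d", i),
        t_s = t_all,
        intensity = intensity,
        is_prebleach = c(rep(TRUE, npre), rep(FALSE, npost))
      )
    }
  })
  tr <- do.call(rbind, out)
  class(tr) <- c("frap_traces", "data.frame")
  attr(tr, "truth") <- list(mobile_fraction = config$mobile_fraction,
                            tau = config$tau,
                            bleach_depth = config$bleach_depth,
                            frame_interval = dt)
  tr
}

#' Write / read FRAP traces as CSV
#'
#' Long-form CSV with columns `trace_id`, `t_s`, `intensity`,
#' `is_prebleach`.
#'
#' @param traces a `frap_traces` data frame.
#' @param path file path.
#' @return `path` invisibly (writer); a `frap_traces` data frame (reader).
#' @export
write_frap_csv <- function(traces, path) {
  .chk_cols(traces, c("trace_id", "t_s", "intensity", "is_prebleach"), "trace table")
  write.csv(traces, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_frap_csv
#' @export
read_frap_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file '%s' does not exist", path), call. = FALSE)
  tr <- read.csv(path)
  .chk_cols(tr, c("trace_id", "t_s", "intensity", "is_prebleach"), "trace table")
  tr$is_prebleach <- as.logical(tr$is_prebleach)
  class(tr) <- c("frap_traces", "data.frame")
  tr
}
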