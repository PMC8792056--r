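# Shared fixtures, built in code at test time.

# Byte-level FCS 3.0 writer used as an independent fixture generator for the
# reader tests. Follows the FCS 3.0 layout directly: 58-byte header (version,
# then right-justified 8-char ASCII offsets of the TEXT and DATA segments),
# delimiter-framed TEXT keywords, float32 list-mode DATA.
write_fcs_fixture <- function(path, mat, pnn, endian = "little") {
  stopifnot(ncol(mat) == length(pnn))
  n_par <- ncol(mat)
  n_tot <- nrow(mat)
  kv <- c("$DATATYPE", "F", "$MODE", "L",
          "$BYTEORD", if (endian == "little") "1,2,3,4" else "4,3,2,1",
          "$PAR", n_par, "$TOT", n_tot, "$NEXTDATA", "0")
  for (i in seq_len(n_par)) {
    kv <- c(kv, sprintf("$P%dB", i), "32", sprintf("$P%dN", i), pnn[i],
            sprintf("$P%dR", i), "262144", sprintf("$P%dE", i), "0,0")
  }
  delim <- "/"
  text <- paste0(delim, paste(kv, collapse = delim), delim)
  text_start <- 58L
  text_end <- text_start + nchar(text) - 1L
  data_start <- text_end + 1L
  data_end <- data_start + 4L * n_par * n_tot - 1L
  header <- sprintf("FCS3.0    %8d%8d%8d%8d%8d%8d",
                    text_start, text_end, data_start, data_end, 0L, 0L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(text, con, eos = NULL)
  writeBin(as.vector(t(mat)), con, size = 4, endian = endian)
  invisible(path)
}

# Control fractions whose leave-one-out scores have the sample SD of a target
# score vector. Power iteration on f_i <- mean_{-i}(f) * 2^s_i (renormalized
# each step); at the fixed point the leave-one-out scores equal the target up
# to a common additive offset, which leaves their SD untouched.
fractions_from_loo_scores <- function(scores, base = 0.3) {
  n <- length(scores)
  f <- rep(base, n)
  for (it in 1:500) {
    loo <- (sum(f) - f) / (n - 1)
    f_new <- loo * 2^scores
    f_new <- f_new * base / mean(f_new)
    if (max(abs(f_new - f)) < 1e-14) break
    f <- f_new
  }
  f
}

# Fraction-level screen simulator: control and chaperone AGG+ fractions with
# log-normal replicate noise around a base rate, organized in batches. Returns
# the tables consumed by modulation_scores() / control_interval().
sim_screen_fractions <- function(n_batches, n_ctrl_per_batch, chaperone_m,
                                 n_rep_per_chap, p0 = 0.3, sigma_log2 = 0.08,
                                 seed = 1) {
  withr::with_seed(seed, {
    rows <- list()
    for (b in seq_len(n_batches)) {
      for (j in seq_len(n_ctrl_per_batch)) {
        rows[[length(rows) + 1]] <- data.frame(
          sample_id = sprintf("ctrl_b%d_%d", b, j), chaperone_id = "DsRed",
          batch = sprintf("b%d", b),
          f_AGG = p0 * 2^rnorm(1, 0, sigma_log2))
      }
    }
    for (ch in names(chaperone_m)) {
      batches <- rep_len(seq_len(n_batches), n_rep_per_chap)
      for (r in seq_len(n_rep_per_chap)) {
        rows[[length(rows) + 1]] <- data.frame(
          sample_id = sprintf("%s_r%d", ch, r), chaperone_id = ch,
          batch = sprintf("b%d", batches[r]),
          f_AGG = chaperone_m[[ch]] * p0 * 2^rnorm(1, 0, sigma_log2))
      }
    }
    do.call(rbind, rows)
  })
}

# A control_interval with a prescribed STD (for direct rule-application tests).
ci_with_std <- function(std) {
  structure(list(std = std, ci95_halfwidth = 2 * std,
                 ci997_halfwidth = 3 * std, n_controls = NA_integer_,
                 scores = NULL),
            class = "control_interval")
}

# Minimal mc_image built from explicit channel matrices.
mc_image_from <- function(nuclei, reporter, stain = NULL, pixel_size_um = 1) {
  structure(list(channels = Filter(Negate(is.null),
                                   list(nuclei = nuclei, reporter = reporter,
                                        stain = stain)),
                 pixel_size_um = pixel_size_um, bit_depth = 8L),
            class = "mc_image")
}

# Normalized FRAP trace table built from explicit post-bleach values.
norm_traces_from <- function(values_by_trace, dt = 1) {
  rows <- lapply(names(values_by_trace), function(id) {
    v <- values_by_trace[[id]]
    data.frame(trace_id = id, t_s = (seq_along(v) - 1) * dt,
               norm_intensity = v, is_prebleach = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("frap_traces_norm", "data.frame")
  out
}

# Independent Benjamini-Hochberg step-up oracle.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  pmin(1, adj)[order(o)]
}

# Closed-form noiseless FRAP recovery curve.
frap_closed_form <- function(t, mobile_fraction, depth, tau) {
  (1 - depth) + mobile_fraction * depth * (1 - exp(-t / tau))
}
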