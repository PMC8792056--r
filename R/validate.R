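# Shared argument validation. All errors are named after the offending field
# so config problems surface as single-line causes.

.chk_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != trunc(x)) {
    stop(sprintf("'%s' must be a single integer >= %d", name, min), call. = FALSE)
  }
  as.integer(x)
}

.chk_fraction <- function(x, name, lower_open = FALSE, upper_open = FALSE) {
  lo_ok <- if (lower_open) x > 0 else x >= 0
  hi_ok <- if (upper_open) x < 1 else x <= 1
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || !lo_ok || !hi_ok) {
    stop(sprintf("'%s' must be a fraction in %s0,1%s", name,
                 if (lower_open) "(" else "[", if (upper_open) ")" else "]"),
         call. = FALSE)
  }
  as.numeric(x)
}

.chk_pos <- function(x, name, strict = TRUE) {
  ok <- if (strict) x > 0 else x >= 0
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || !ok) {
    stop(sprintf("'%s' must be a single %s number", name,
                 if (strict) "positive" else "non-negative"), call. = FALSE)
  }
  as.numeric(x)
}

.chk_seed <- function(x, name = "seed") {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != trunc(x)) {
    stop(sprintf("'%s' must be a single integer", name), call. = FALSE)
  }
  as.integer(x)
}

.chk_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}
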