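# Minimal FCS 3.0/3.1 list-mode reader.
#
# Supports the subset of the standard that cytometer exports of pulse
# parameters actually use: $MODE L, $DATATYPE F/D/I with a uniform bit width
# per parameter, and little- or big-endian $BYTEORD. Spillover, gating-ML and
# analysis segments are ignored.

.fcs_read_header_offsets <- function(con) {
  hdr <- readBin(con, "raw", n = 58)
  if (length(hdr) < 58) stop("file too short to be an FCS file", call. = FALSE)
  version <- rawToChar(hdr[1:6])
  if (!version %in% c("FCS3.0", "FCS3.1")) {
    stop(sprintf("unsupported FCS version '%s' (need FCS3.0 or FCS3.1)", version),
         call. = FALSE)
  }
  off <- function(i, j) as.numeric(trimws(rawToChar(hdr[i:j])))
  list(version = version,
       text_start = off(11, 18), text_end = off(19, 26),
       data_start = off(27, 34), data_end = off(35, 42))
}

.fcs_parse_text <- function(raw_text) {
  delim <- rawToChar(raw_text[1])
  body <- rawToChar(raw_text[-1])
  parts <- strsplit(body, delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2 == 1) parts <- parts[-length(parts)]
  keys <- toupper(trimws(parts[seq(1, length(parts), 2)]))
  vals <- trimws(parts[seq(2, length(parts), 2)])
  setNames(as.list(vals), keys)
}

#' Read an FCS 3.0 / 3.1 file into an event matrix
#'
#' A compact list-mode reader for the common case of floating-point or
#' uniform-width integer data. Returns the raw event matrix with one column
#' per parameter, named after the `$PnN` keywords, plus the parsed TEXT
#' keywords. [read_events()] maps these columns onto the canonical pulse
#' channels via a `channel_map`.
#'
#' @param path path to an FCS 3.0 or 3.1 file.
#' @return a list with elements `data` (numeric matrix, events x parameters,
#'   columns named by `$PnN`), `keywords` (named list of TEXT keywords) and
#'   `version`.
#' @export
read_fcs <- function(path) {
  if (!file.exists(path)) stop(sprintf("file '%s' does not exist", path), call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- .fcs_read_header_offsets(con)
  seek(con, hdr$text_start)
  txt <- readBin(con, "raw", n = hdr$text_end - hdr$text_start + 1)
  kw <- .fcs_parse_text(txt)

  need <- c("$PAR", "$TOT", "$DATATYPE", "$BYTEORD")
  missing <- setdiff(need, names(kw))
  if (length(missing)) {
    stop(sprintf("FCS TEXT segment lacks required keyword(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (!is.null(kw[["$MODE"]]) && toupper(kw[["$MODE"]]) != "L") {
    stop("only list-mode ($MODE L) FCS data are supported", call. = FALSE)
  }
  n_par <- as.integer(kw[["$PAR"]])
  n_tot <- as.integer(kw[["$TOT"]])
  dtype <- toupper(kw[["$DATATYPE"]])
  endian <- switch(kw[["$BYTEORD"]],
                   "1,2,3,4" = "little", "4,3,2,1" = "big",
                   stop(sprintf("unsupported $BYTEORD '%s'", kw[["$BYTEORD"]]),
                        call. = FALSE))

  data_start <- hdr$data_start
  data_end <- hdr$data_end
  if (data_start == 0 && !is.null(kw[["$BEGINDATA"]])) {
    data_start <- as.numeric(kw[["$BEGINDATA"]])
    data_end <- as.numeric(kw[["$ENDDATA"]])
  }
  seek(con, data_start)

  bits <- vapply(seq_len(n_par), function(i) {
    b <- kw[[sprintf("$P%dB", i)]]
    if (is.null(b)) NA_integer_ else as.integer(b)
  }, integer(1))
  n_values <- n_par * n_tot
  if (dtype %in% c("F", "D")) {
    size <- if (dtype == "F") 4L else 8L
    vals <- readBin(con, "numeric", n = n_values, size = size, endian = endian)
  } else if (dtype == "I") {
    if (any(is.na(bits)) || length(unique(bits)) != 1L || !unique(bits) %in% c(16L, 32L)) {
      stop("integer FCS data require a uniform $PnB of 16 or 32 bits", call. = FALSE)
    }
    size <- unique(bits) / 8L
    vals <- readBin(con, "integer", n = n_values, size = size,
                    endian = endian, signed = size == 4L)
    if (size == 2L) vals[vals < 0] <- vals[vals < 0] + 65536
  } else {
    stop(sprintf("unsupported $DATATYPE '%s'", dtype), call. = FALSE)
  }
  if (length(vals) < n_values) {
    stop("FCS DATA segment shorter than $PAR * $TOT values", call. = FALSE)
  }
  mat <- matrix(vals[seq_len(n_values)], nrow = n_tot, ncol = n_par, byrow = TRUE)
  pn <- vapply(seq_len(n_par), function(i) {
    nm <- kw[[sprintf("$P%dN", i)]]
    if (is.null(nm)) sprintf("P%d", i) else nm
  }, character(1))
  colnames(mat) <- pn
  list(data = mat, keywords = kw, version = hdr$version)
}
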