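#' Filter expressed genes by TPM cutoff
#'
#' A gene is expressed when its TPM (transcripts per million) reaches the
#' cutoff in at least one sample; the comparison is non-strict
#' (`TPM >= cutoff`). Typical cutoffs used with this rule are 6 or 10 for
#' whole-transcriptome experiments and 2 for smaller libraries.
#'
#' @param tpm numeric gene x sample matrix (or data frame) with gene ids as
#'   row names; values must be non-negative.
#' @param cutoff positive TPM cutoff.
#' @return character vector of expressed gene ids (empty for an empty
#'   table).
#' @export
filter_expressed <- function(tpm, cutoff) {
  cutoff <- .chk_pos(cutoff, "cutoff")
  tpm <- as.matrix(tpm)
  if (length(tpm) == 0 || nrow(tpm) == 0) return(character(0))
  if (any(tpm < 0, na.rm = TRUE)) stop("TPM values must be non-negative", call. = FALSE)
  if (is.null(rownames(tpm))) stop("TPM table must have gene ids as row names", call. = FALSE)
  rownames(tpm)[apply(tpm, 1, max, na.rm = TRUE) >= cutoff]
}

#' Define a differential gene set from per-comparison LFC tables
#'
#' A gene is differential when it is significantly changed in at least one
#' comparison: FDR-adjusted p strictly below `fdr_cutoff`, and, when
#' `abs_lfc_cutoff` is set (as for FUS experiments, cutoff 1), absolute LFC
#' at or above that cutoff (non-strict).
#'
#' @param lfc data frame with columns `gene`, `lfc`, `padj` and optionally
#'   `comparison`; rows from multiple comparisons are unioned.
#' @param fdr_cutoff FDR threshold (default 0.05, strict).
#' @param abs_lfc_cutoff optional absolute-LFC threshold (non-strict); `NULL`
#'   disables it.
#' @return character vector of differential gene ids.
#' @export
define_degs <- function(lfc, fdr_cutoff = 0.05, abs_lfc_cutoff = NULL) {
  if (is.null(lfc) || nrow(lfc) == 0) return(character(0))
  .chk_cols(lfc, c("gene", "lfc"), "LFC table")
  if (!"padj" %in% names(lfc)) {
    stop("LFC table is missing the adjusted-p column 'padj'", call. = FALSE)
  }
  if (any(!is.na(lfc$padj) & (lfc$padj < 0 | lfc$padj > 1))) {
    stop("'padj' values must lie in [0, 1]", call. = FALSE)
  }
  hit <- !is.na(lfc$padj) & lfc$padj < fdr_cutoff
  if (!is.null(abs_lfc_cutoff)) {
    hit <- hit & abs(lfc$lfc) >= abs_lfc_cutoff
  }
  sort(unique(lfc$gene[hit]))
}

#' Test whether a gene set's LFC distribution is shifted from the background
#'
#' Two-sided two-sample Student t-test (pooled variance by default) of the
#' set genes' LFC values against the remaining background genes, with
#' empirical CDF coordinates for both groups for the standard CDF-shift
#' presentation.
#'
#' @param lfc named numeric vector of per-gene LFC values (names = gene
#'   ids), covering all expressed genes (the background).
#' @param gene_set character vector of set gene ids; must be contained in
#'   `names(lfc)` and have at least 3 members.
#' @param pooled logical; `TRUE` (default) uses the pooled-variance Student
#'   test, `FALSE` the Welch test.
#' @return a `shift_test` list: `n_set`, `n_background`, `mean_shift` (set
#'   mean minus non-set background mean), `t`, `p`, and `cdf_set` /
#'   `cdf_background` data frames of (x, F(x)) coordinates.
#' @export
geneset_shift <- function(lfc, gene_set, pooled = TRUE) {
  if (is.null(names(lfc))) stop("'lfc' must be a named vector", call. = FALSE)
  missing <- setdiff(gene_set, names(lfc))
  if (length(missing)) {
    stop(sprintf("%d set gene(s) absent from the background index", length(missing)),
         call. = FALSE)
  }
  if (length(gene_set) < 3) stop("shift test refused: need >= 3 set genes", call. = FALSE)
  set_vals <- lfc[gene_set]
  bg_vals <- lfc[setdiff(names(lfc), gene_set)]
  tt <- t.test(set_vals, bg_vals, var.equal = pooled, alternative = "two.sided")
  cdf_coords <- function(v) {
    x <- sort(v)
    data.frame(x = x, F = seq_along(x) / length(x))
  }
  out <- list(n_set = length(set_vals),
              n_background = length(lfc),
              mean_shift = mean(set_vals) - mean(bg_vals),
              t = unname(tt$statistic),
              p = tt$p.value,
              cdf_set = cdf_coords(set_vals),
              cdf_background = cdf_coords(lfc))
  class(out) <- "shift_test"
  out
}

#' Summarize restoration of a differential gene set across conditions
#'
#' Given a differential gene set defined in a reference condition, each
#' condition's LFC distribution over that set is summarized (median, IQR,
#' mean absolute LFC) together with a one-sample t-test against zero, and
#' conditions are ranked by mean |LFC|: the condition whose set
#' distribution sits closest to zero is the most restored (closest to the
#' unperturbed state).
#'
#' @param deg_set character vector of gene ids (nonempty).
#' @param lfc_by_condition named list of per-condition LFC tables (data
#'   frames `gene`, `lfc`) or named numeric vectors.
#' @return data frame, one row per condition, ordered most-restored first:
#'   `condition`, `n_genes`, `median_lfc`, `iqr_lfc`, `mean_abs_lfc`,
#'   `t_vs_zero`, `p_vs_zero`, `rank_restored`.
#' @export
restoration_summary <- function(deg_set, lfc_by_condition) {
  if (length(deg_set) == 0) stop("'deg_set' must be nonempty", call. = FALSE)
  if (is.null(names(lfc_by_condition))) {
    stop("'lfc_by_condition' must be a named list", call. = FALSE)
  }
  rows <- lapply(names(lfc_by_condition), function(cond) {
    x <- lfc_by_condition[[cond]]
    v <- if (is.data.frame(x)) setNames(x$lfc, x$gene) else x
    present <- intersect(deg_set, names(v))
    if (length(present) < length(deg_set) * 0.9) {
      warning(sprintf("condition '%s' is missing %d%% of the set; computed on the intersection",
                      cond, round(100 * (1 - length(present) / length(deg_set)))),
              call. = FALSE)
    }
    vals <- v[present]
    tt <- if (sd(vals) > 0) t.test(vals, mu = 0) else
      list(statistic = c(t = if (all(vals == 0)) 0 else Inf), p.value = NA_real_)
    data.frame(condition = cond,
               n_genes = length(vals),
               median_lfc = median(vals),
               iqr_lfc = IQR(vals),
               mean_abs_lfc = mean(abs(vals)),
               t_vs_zero = unname(tt$statistic),
               p_vs_zero = tt$p.value)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$mean_abs_lfc), , drop = FALSE]
  out$rank_restored <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Read / write gene-level tables as TSV
#'
#' Plain TSV serialization for TPM matrices (gene ids in the first column),
#' LFC tables and gene-set files (one gene id per line).
#'
#' @param path file path.
#' @param tpm,lfc,genes object to write.
#' @return read functions return the parsed object; write functions return
#'   `path` invisibly.
#' @name expression_io
NULL

#' @rdname expression_io
#' @export
read_tpm_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' @rdname expression_io
#' @export
write_tpm_tsv <- function(tpm, path) {
  df <- data.frame(gene = rownames(tpm), as.data.frame(tpm), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname expression_io
#' @export
read_lfc_tsv <- function(path) {
  df <- read.delim(path)
  .chk_cols(df, c("gene", "lfc"), "LFC table")
  df
}

#' @rdname expression_io
#' @export
write_lfc_tsv <- function(lfc, path) {
  write.table(lfc, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname expression_io
#' @export
read_geneset <- function(path) {
  readLines(path, warn = FALSE)
}

#' @rdname expression_io
#' @export
write_geneset <- function(genes, path) {
  writeLines(genes, path)
  invisible(path)
}
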