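# Pipeline orchestration: one structured config drives the simulate / gate /
# score / frap / image-quant / expr-shift stages; a thin Rscript wrapper
# (inst/cli/aggscreen.R) exposes the same stages as shell subcommands.

.known_keys <- list(
  top = c("seed", "out_dir", "simulate", "gate", "score", "frap",
          "image_quant", "expr_shift", "channel_map"),
  simulate = c("cytometry", "frap", "lfc", "image"),
  gate = c("alpha", "viability_threshold", "scatter_bounds", "events_dir",
           "sample_sheet"),
  score = c("control_id", "gating"),
  frap = c("samples_per_bin", "traces"),
  image_quant = c("paths", "n_slices", "intensity_threshold",
                  "min_cell_area_um2", "agg_area_rule_um2",
                  "agg_intensity_threshold"),
  expr_shift = c("lfc", "geneset")
)

#' Validate a pipeline configuration
#'
#' Checks the per-stage blocks of a pipeline config against the known keys;
#' unknown keys are rejected by name so typos fail loudly rather than being
#' silently ignored.
#'
#' @param config a named list (typically from [yaml::read_yaml()]).
#' @return the config, invisibly, on success.
#' @export
validate_config <- function(config) {
  if (!is.list(config)) stop("config must be a named list", call. = FALSE)
  chk <- function(block, allowed, where) {
    unknown <- setdiff(names(block), allowed)
    if (length(unknown)) {
      stop(sprintf("unknown config key '%s' in %s", unknown[1], where), call. = FALSE)
    }
  }
  chk(config, .known_keys$top, "top level")
  for (stage in c("simulate", "gate", "score", "frap", "image_quant", "expr_shift")) {
    if (!is.null(config[[stage]])) chk(config[[stage]], .known_keys[[stage]], stage)
  }
  if (is.null(config$seed)) stop("config must set 'seed'", call. = FALSE)
  .chk_seed(config$seed, "seed")
  invisible(config)
}

.cfg_apply <- function(constructor, overrides, fixed = list()) {
  args <- utils::modifyList(as.list(overrides), fixed)
  do.call(constructor, args)
}

.stage_simulate <- function(config, out_dir) {
  sim <- config$simulate
  if (is.null(sim)) stop("config has no 'simulate' block", call. = FALSE)
  seed <- config$seed
  written <- character(0)
  if (!is.null(sim$cytometry)) {
    wt_over <- sim$cytometry$wt %||% list()
    wt_over$p_agg <- wt_over$p_agg %||% 0
    wt_cfg <- .cfg_apply(sim_cytometry_config, wt_over, list(seed = seed))
    p <- file.path(out_dir, "events_wt.csv")
    write_events_csv(simulate_cytometry(wt_cfg), p)
    written <- c(written, p)
    sheet <- list()
    samples <- sim$cytometry$samples %||% list()
    for (i in seq_along(samples)) {
      id <- names(samples)[i]
      over <- samples[[i]]
      meta <- list(chaperone_id = over$chaperone_id %||% id,
                   batch = over$batch %||% "batch1")
      over$chaperone_id <- NULL; over$batch <- NULL
      cfg <- .cfg_apply(sim_cytometry_config, over, list(seed = seed + i))
      p <- file.path(out_dir, sprintf("events_%s.csv", id))
      write_events_csv(simulate_cytometry(cfg), p)
      written <- c(written, p)
      sheet[[i]] <- data.frame(sample_id = id, chaperone_id = meta$chaperone_id,
                               batch = meta$batch)
    }
    if (length(sheet)) {
      p <- file.path(out_dir, "sample_sheet.tsv")
      write.table(do.call(rbind, sheet), p, sep = "\t", quote = FALSE, row.names = FALSE)
      written <- c(written, p)
    }
  }
  if (!is.null(sim$frap)) {
    conds <- sim$frap$conditions %||% sim$frap
    for (i in seq_along(conds)) {
      cfg <- .cfg_apply(sim_frap_config, conds[[i]], list(seed = seed + 100 + i))
      p <- file.path(out_dir, sprintf("frap_%s.csv", names(conds)[i]))
      write_frap_csv(simulate_frap(cfg), p)
      written <- c(written, p)
    }
  }
  if (!is.null(sim$lfc)) {
    cfg <- .cfg_apply(sim_lfc_config, sim$lfc, list(seed = seed + 200))
    out <- simulate_lfc(cfg)
    p1 <- file.path(out_dir, "lfc.tsv"); write_lfc_tsv(out$lfc, p1)
    p2 <- file.path(out_dir, "lfc_restored.tsv"); write_lfc_tsv(out$restored, p2)
    p3 <- file.path(out_dir, "geneset.txt"); write_geneset(out$set, p3)
    written <- c(written, p1, p2, p3)
  }
  if (!is.null(sim$image)) {
    cfg <- .cfg_apply(sim_image_config, sim$image, list(seed = seed + 300))
    out <- simulate_image(cfg)
    p <- file.path(out_dir, "image_01.tiff")
    write_mc_tiff(out$image, p)
    written <- c(written, p)
  }
  written
}

.stage_gate <- function(config, out_dir) {
  gcfg <- config$gate %||% list()
  events_dir <- gcfg$events_dir %||% out_dir
  sheet_path <- gcfg$sample_sheet %||% file.path(events_dir, "sample_sheet.tsv")
  wt <- read_events(file.path(events_dir, "events_wt.csv"))
  gate <- calibrate_pulsa_gate(
    wt,
    alpha = gcfg$alpha %||% 0.001,
    viability_threshold = gcfg$viability_threshold %||% 1000,
    scatter_bounds = unlist(gcfg$scatter_bounds %||% c(60, 140))
  )
  sheet <- read.delim(sheet_path)
  rows <- lapply(seq_len(nrow(sheet)), function(i) {
    ev <- read_events(file.path(events_dir, sprintf("events_%s.csv", sheet$sample_id[i])))
    r <- apply_gates(ev, gate)
    data.frame(sample_id = sheet$sample_id[i],
               chaperone_id = sheet$chaperone_id[i],
               batch = sheet$batch[i],
               n_total = r$n_total, n_viable = r$n_viable,
               n_sized = r$n_sized, n_aggpos = r$n_aggpos, f_AGG = r$f_AGG)
  })
  p <- file.path(out_dir, "gating.tsv")
  write.table(do.call(rbind, rows), p, sep = "\t", quote = FALSE, row.names = FALSE)
  p
}

.stage_score <- function(config, out_dir) {
  scfg <- config$score %||% list()
  gating_path <- scfg$gating %||% file.path(out_dir, "gating.tsv")
  gating <- read.delim(gating_path)
  control_id <- scfg$control_id %||% "DsRed"
  scores <- modulation_scores(gating, control_id = control_id)
  ctrl <- gating[gating$chaperone_id == control_id, c("batch", "f_AGG")]
  ci <- control_interval(ctrl)
  called <- call_significance(scores, ci)
  p1 <- file.path(out_dir, "scores.tsv")
  write.table(called, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  p2 <- file.path(out_dir, "control_interval.tsv")
  write.table(data.frame(std = ci$std, ci95_halfwidth = ci$ci95_halfwidth,
                         ci997_halfwidth = ci$ci997_halfwidth,
                         n_controls = ci$n_controls),
              p2, sep = "\t", quote = FALSE, row.names = FALSE)
  c(p1, p2)
}

.stage_frap <- function(config, out_dir) {
  fcfg <- config$frap %||% list()
  traces <- fcfg$traces
  if (is.null(traces)) {
    files <- list.files(out_dir, pattern = "^frap_.*\\.csv$", full.names = TRUE)
    traces <- setNames(as.list(files), sub("^frap_(.*)\\.csv$", "\\1", basename(files)))
  }
  if (length(traces) != 2) stop("frap stage needs exactly two condition trace files", call. = FALSE)
  spb <- fcfg$samples_per_bin %||% 20
  binned <- lapply(names(traces), function(cond) {
    bin_curve(normalize_and_align(read_frap_csv(traces[[cond]])),
              samples_per_bin = spb, condition = cond)
  })
  comp <- compare_conditions(binned[[1]], binned[[2]])
  p1 <- file.path(out_dir, "frap_bins.tsv")
  write.table(comp, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  p2 <- file.path(out_dir, "frap_recovery.tsv")
  write.table(data.frame(condition = names(traces),
                         recovery_percent = vapply(binned, recovery_percent, numeric(1))),
              p2, sep = "\t", quote = FALSE, row.names = FALSE)
  c(p1, p2)
}

.stage_image_quant <- function(config, out_dir) {
  icfg <- config$image_quant %||% list()
  paths <- icfg$paths %||% list.files(out_dir, pattern = "\\.tiff?$", full.names = TRUE)
  if (length(paths) == 0) stop("image-quant stage found no TIFF inputs", call. = FALSE)
  imgs <- lapply(paths, read_mc_tiff)
  res <- neuron_batch(imgs,
                      n_slices = icfg$n_slices %||% 1,
                      intensity_threshold = icfg$intensity_threshold %||% 240,
                      min_cell_area_um2 = icfg$min_cell_area_um2 %||% 50,
                      agg_area_rule_um2 = icfg$agg_area_rule_um2 %||% 5,
                      agg_intensity_threshold = icfg$agg_intensity_threshold %||% 252,
                      image_ids = basename(unlist(paths)))
  p <- file.path(out_dir, "image_quant.tsv")
  write.table(res, p, sep = "\t", quote = FALSE, row.names = FALSE)
  p
}

.stage_expr_shift <- function(config, out_dir) {
  ecfg <- config$expr_shift %||% list()
  lfc <- read_lfc_tsv(ecfg$lfc %||% file.path(out_dir, "lfc.tsv"))
  set <- read_geneset(ecfg$geneset %||% file.path(out_dir, "geneset.txt"))
  v <- setNames(lfc$lfc, lfc$gene)
  res <- geneset_shift(v, set)
  p1 <- file.path(out_dir, "shift_test.tsv")
  write.table(data.frame(n_set = res$n_set, n_background = res$n_background,
                         mean_shift = res$mean_shift, t = res$t, p = res$p),
              p1, sep = "\t", quote = FALSE, row.names = FALSE)
  p2 <- file.path(out_dir, "cdf_coords.tsv")
  cdf <- rbind(cbind(group = "set", res$cdf_set),
               cbind(group = "background", res$cdf_background))
  write.table(cdf, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  c(p1, p2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a pipeline stage from a structured config
#'
#' Single entry point behind the command-line wrapper. The config (a named
#' list, usually parsed from YAML) carries a global `seed` and one block per
#' stage; unknown keys are rejected. Every run writes a `manifest.json`
#' recording the resolved config, the seed and the package version, so any
#' run can be reproduced from its manifest. Outputs are TSV/CSV/TIFF files
#' under `out_dir`; identical config and seed give byte-identical tables.
#'
#' @param subcommand one of `"simulate"`, `"gate"`, `"score"`, `"frap"`,
#'   `"image-quant"`, `"expr-shift"`.
#' @param config named list or path to a YAML config file.
#' @param out_dir output directory (created if missing); defaults to
#'   `config$out_dir`.
#' @return character vector of files written, invisibly.
#' @export
run_pipeline <- function(subcommand, config, out_dir = NULL) {
  subcommand <- match.arg(subcommand,
                          c("simulate", "gate", "score", "frap",
                            "image-quant", "expr-shift"))
  if (is.character(config)) config <- yaml::read_yaml(config)
  validate_config(config)
  out_dir <- out_dir %||% config$out_dir %||% stop("no 'out_dir' given", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- switch(subcommand,
                    "simulate" = .stage_simulate(config, out_dir),
                    "gate" = .stage_gate(config, out_dir),
                    "score" = .stage_score(config, out_dir),
                    "frap" = .stage_frap(config, out_dir),
                    "image-quant" = .stage_image_quant(config, out_dir),
                    "expr-shift" = .stage_expr_shift(config, out_dir))
  manifest <- list(subcommand = subcommand,
                   seed = config$seed,
                   config = config,
                   package_version = as.character(utils::packageVersion("aggscreen")),
                   outputs = basename(written))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(written)
}
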