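#' Configuration for the synthetic gene-level log-fold-change generator
#'
#' Emulates a per-gene LFC vector in which one gene set is shifted: set
#' genes have true shift `delta`, background genes 0, and every observed
#' LFC adds Gaussian noise `sigma`. A "restored" condition multiplies each
#' gene's true shift by `restore_factor` (1 = no restoration, 0 = complete
#' restoration to the unperturbed state) before adding fresh noise,
#' emulating a rescue condition whose expression distribution moves back
#' toward wild type.
#'
#' @param n_genes number of genes.
#' @param set_size size of the shifted gene set (`<= n_genes`).
#' @param delta mean LFC shift of the set (log2 units).
#' @param sigma per-gene noise sd (log2 units).
#' @param restore_factor multiplier in `[0,1]` applied to true shifts in the
#'   restored condition.
#' @param seed integer seed.
#' @return an object of class `sim_lfc_config`.
#' @export
sim_lfc_config <- function(n_genes = 5000, set_size = 200, delta = 0.5,
                           sigma = 0.3, restore_factor = 0.5, seed = 1L) {
  cfg <- list(
    n_genes = .chk_count(n_genes, "n_genes"),
    set_size = .chk_count(set_size, "set_size"),
    delta = as.numeric(delta),
    sigma = .chk_pos(sigma, "sigma"),
    restore_factor = .chk_fraction(restore_factor, "restore_factor"),
    seed = .chk_seed(seed)
  )
  if (cfg$set_size > cfg$n_genes) stop("'set_size' must be <= 'n_genes'", call. = FALSE)
  class(cfg) <- "sim_lfc_config"
  cfg
}

#' Simulate gene-level LFC tables with a shifted set and a restored condition
#'
#' @param config a [sim_lfc_config()] object.
#' @return list with `lfc` (data frame `gene`, `lfc` for the perturbed
#'   condition), `restored` (same genes, shifts multiplied by
#'   `restore_factor`), `set` (character vector of set gene ids) and
#'   `truth` (per-gene true shifts).
#' @export
simulate_lfc <- function(config) {
  if (!inherits(config, "sim_lfc_config")) {
    stop("'config' must be created with sim_lfc_config()", call. = FALSE)
  }
  genes <- sprintf("gene_%05d", seq_len(config$n_genes))
  withr::with_seed(config$seed, {
    set_idx <- sort(sample(config$n_genes, config$set_size))
    true_shift <- numeric(config$n_genes)
    true_shift[set_idx] <- config$delta
    lfc <- true_shift + rnorm(config$n_genes, 0, config$sigma)
    restored <- true_shift * config$restore_factor +
      rnorm(config$n_genes, 0, config$sigma)
  })
  list(lfc = data.frame(gene = genes, lfc = lfc),
       restored = data.frame(gene = genes, lfc = restored),
       set = genes[set_idx],
       truth = data.frame(gene = genes, true_shift = true_shift))
}
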