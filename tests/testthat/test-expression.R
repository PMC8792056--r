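# Expression-layer statistics.

test_that("expressed-gene filtering uses a non-strict max-over-samples rule", {
  tpm <- matrix(c(6, 0, 0, 0,
                  5.9, 5.9, 5.9, 5.9,
                  0, 0, 0, 0,
                  12, 1, 1, 1,
                  2, 3, 7, 1), nrow = 5, byrow = TRUE,
                dimnames = list(sprintf("g%d", 1:5), sprintf("s%d", 1:4)))
  got <- filter_expressed(tpm, cutoff = 6)
  # brute-force oracle: max per row compared to the cutoff
  oracle <- rownames(tpm)[apply(tpm, 1, max) >= 6]
  expect_identical(got, oracle)
  expect_true("g1" %in% got)      # TPM exactly 6 is retained
  expect_false("g3" %in% got)     # all-zero gene is excluded
  expect_identical(filter_expressed(tpm[0, , drop = FALSE], 6), character(0))
  # order invariance / idempotence
  perm <- tpm[c(3, 5, 1, 2, 4), ]
  expect_identical(sort(filter_expressed(perm, 6)), sort(got))
})

test_that("differential gene sets follow the FDR and LFC cutoffs", {
  lfc <- data.frame(gene = c("a", "b", "c", "d"),
                    comparison = "mut_vs_wt",
                    lfc = c(1.2, 0.5, -1.5, 2.0),
                    padj = c(0.04, 0.04, 0.01, 0.05))
  # FUS mode: FDR < 0.05 strict, |LFC| >= 1 non-strict
  expect_identical(define_degs(lfc, abs_lfc_cutoff = 1), c("a", "c"))
  # without the LFC cutoff, b joins; d stays out (padj not < 0.05)
  expect_identical(define_degs(lfc), c("a", "b", "c"))
  expect_identical(define_degs(lfc[0, ]), character(0))
  expect_error(define_degs(data.frame(gene = "a", lfc = 1)), "padj")
  # boundary: |LFC| exactly 1 is kept in FUS mode
  lfc1 <- data.frame(gene = "e", lfc = 1.0, padj = 0.01)
  expect_identical(define_degs(lfc1, abs_lfc_cutoff = 1), "e")
})

test_that("gene-set shift test matches the pooled-variance formula on toy data", {
  set_vals <- c(0.9, 1.1, 1.0, 1.3, 0.7)
  bg_vals <- c(0.1, -0.2, 0.3, 0.0, 0.15, -0.1, 0.2, -0.3, 0.05, 0.1)
  lfc <- setNames(c(set_vals, bg_vals), sprintf("g%d", 1:15))
  res <- geneset_shift(lfc, sprintf("g%d", 1:5))
  # hand-computed pooled-variance t statistic
  n1 <- 5; n2 <- 10
  sp2 <- ((n1 - 1) * var(set_vals) + (n2 - 1) * var(bg_vals)) / (n1 + n2 - 2)
  t_hand <- (mean(set_vals) - mean(bg_vals)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  expect_equal(res$t, t_hand)
  expect_equal(res$mean_shift, mean(set_vals) - mean(bg_vals))
  # CDFs are nondecreasing from ~0 to 1
  expect_true(all(diff(res$cdf_set$F) >= 0))
  expect_equal(max(res$cdf_background$F), 1)
  expect_error(geneset_shift(lfc, c("g1", "g2")), ">= 3")
  expect_error(geneset_shift(lfc, c("g1", "g2", "nope")), "absent")
})

test_that("shift test detects a simulated delta and is quiet under the null", {
  hits <- 0L
  for (s in 1:25) {
    out <- simulate_lfc(sim_lfc_config(n_genes = 2000, set_size = 50,
                                       delta = 0.5, sigma = 0.3, seed = 100 + s))
    v <- setNames(out$lfc$lfc, out$lfc$gene)
    if (geneset_shift(v, out$set)$p < 0.01) hits <- hits + 1L
  }
  expect_gte(hits, 24L)

  null_p <- vapply(1:50, function(s) {
    out <- simulate_lfc(sim_lfc_config(n_genes = 1000, set_size = 50,
                                       delta = 0, sigma = 0.3, seed = 500 + s))
    geneset_shift(setNames(out$lfc$lfc, out$lfc$gene), out$set)$p
  }, numeric(1))
  expect_lt(mean(null_p < 0.05), 0.2) # not systematically small under the null
  expect_gt(min(null_p), 0)
  expect_gt(diff(range(null_p)), 0.3) # p-values spread over the unit interval
})

test_that("restoration summary ranks conditions by closeness to wild type", {
  base <- sim_lfc_config(n_genes = 3000, set_size = 150, delta = 0.8,
                         sigma = 0.3, restore_factor = 0.5, seed = 11)
  full <- simulate_lfc(base)
  none <- simulate_lfc(sim_lfc_config(n_genes = 3000, set_size = 150, delta = 0.8,
                                      sigma = 0.3, restore_factor = 0, seed = 11))
  conds <- list(perturbed = full$lfc,
                half_restored = full$restored,
                fully_restored = none$restored)
  rs <- restoration_summary(full$set, conds)
  expect_identical(rs$condition,
                   c("fully_restored", "half_restored", "perturbed"))
  expect_true(all(diff(rs$mean_abs_lfc) > 0))
  # summary statistics match brute-force quantile computation
  vals <- setNames(full$lfc$lfc, full$lfc$gene)[full$set]
  expect_equal(rs$median_lfc[rs$condition == "perturbed"], median(vals))
  expect_equal(rs$iqr_lfc[rs$condition == "perturbed"],
               unname(diff(quantile(vals, c(0.25, 0.75)))))
})

test_that("restoration ranking recovers the simulated restore factors across seeds", {
  ok <- 0L
  for (s in 1:20) {
    full <- simulate_lfc(sim_lfc_config(n_genes = 2000, set_size = 100, delta = 0.8,
                                        sigma = 0.3, restore_factor = 0.5, seed = s))
    none <- simulate_lfc(sim_lfc_config(n_genes = 2000, set_size = 100, delta = 0.8,
                                        sigma = 0.3, restore_factor = 0, seed = s))
    rs <- restoration_summary(full$set,
                              list(m0 = none$restored, m05 = full$restored,
                                   m1 = full$lfc))
    if (identical(rs$condition, c("m0", "m05", "m1"))) ok <- ok + 1L
  }
  expect_gte(ok, 19L)
})

test_that("expression tables round-trip through TSV", {
  dir <- withr::local_tempdir()
  tpm <- matrix(runif(12, 0, 20), 3, 4,
                dimnames = list(c("g1", "g2", "g3"), sprintf("s%d", 1:4)))
  write_tpm_tsv(tpm, file.path(dir, "tpm.tsv"))
  expect_equal(read_tpm_tsv(file.path(dir, "tpm.tsv")), tpm)
  lfc <- data.frame(gene = c("g1", "g2"), lfc = c(0.5, -1), padj = c(0.01, 0.2))
  write_lfc_tsv(lfc, file.path(dir, "lfc.tsv"))
  expect_equal(read_lfc_tsv(file.path(dir, "lfc.tsv")), lfc)
  write_geneset(c("g1", "g2"), file.path(dir, "set.txt"))
  expect_identical(read_geneset(file.path(dir, "set.txt")), c("g1", "g2"))
})
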