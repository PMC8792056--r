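# Aggregation Modulation Scores, empirical confidence bands, calls.

test_that("modulation scores follow the log2 ratio to same-batch controls", {
  fr <- data.frame(
    sample_id = c("c1", "c2", "a1", "b1", "d1"),
    chaperone_id = c("DsRed", "DsRed", "half", "equal", "double"),
    batch = "day1",
    f_AGG = c(0.30, 0.30, 0.15, 0.30, 0.60))
  sc <- modulation_scores(fr)
  s <- setNames(sc$summary$mean_score, sc$summary$chaperone_id)
  expect_equal(unname(s["half"]), -1)     # 50% reduction <-> score of -1
  expect_equal(unname(s["equal"]), 0)
  expect_equal(unname(s["double"]), +1)

  # scores are invariant to a global rescaling of all fractions
  fr2 <- fr; fr2$f_AGG <- fr2$f_AGG * 0.37
  sc2 <- modulation_scores(fr2)
  expect_equal(sc2$summary$mean_score, sc$summary$mean_score)
})

test_that("log2 arithmetic example: 0.40 over control 0.20 scores +1", {
  fr <- data.frame(sample_id = c("c", "x"), chaperone_id = c("DsRed", "chap"),
                   batch = "b", f_AGG = c(0.20, 0.40))
  expect_equal(modulation_scores(fr)$summary$mean_score, 1)
})

test_that("zero fractions get the continuity substitution and batches need controls", {
  fr <- data.frame(sample_id = c("c1", "x1"), chaperone_id = c("DsRed", "chap"),
                   batch = "b1", f_AGG = c(0.3, 0), n_sized = c(9000, 9000))
  sc <- modulation_scores(fr)
  expect_true(sc$replicates$flagged[sc$replicates$chaperone_id == "chap"])
  expect_equal(sc$replicates$score[sc$replicates$chaperone_id == "chap"],
               log2((0.5 / 9000) / 0.3))

  fr_bad <- data.frame(sample_id = c("c1", "x1"), chaperone_id = c("DsRed", "chap"),
                       batch = c("b1", "b2"), f_AGG = c(0.3, 0.2))
  expect_error(modulation_scores(fr_bad), "b2")
})

test_that("control interval is exactly twice and three times the null STD", {
  # leave-one-out scores engineered to have sample SD 0.0584 reproduce the
  # printed 95% half-width of 0.1168
  f <- fractions_from_loo_scores(c(-1, 0, 1) * 0.0584)
  ci <- control_interval(data.frame(batch = "d1", f_AGG = f))
  expect_equal(ci$std, 0.0584, tolerance = 1e-8)
  expect_identical(ci$ci95_halfwidth, 2 * ci$std)
  expect_identical(ci$ci997_halfwidth, 3 * ci$std)
  expect_equal(ci$ci95_halfwidth, 0.1168, tolerance = 1e-7)

  # a target vector with SD 0.1 gives half-width 0.2
  f2 <- fractions_from_loo_scores(c(-0.1, 0, 0.1))
  ci2 <- control_interval(data.frame(batch = "d1", f_AGG = f2))
  expect_equal(ci2$ci95_halfwidth, 0.2, tolerance = 1e-7)

  # identical fractions give a null of zero width
  ci0 <- control_interval(data.frame(batch = "d1", f_AGG = rep(0.3, 4)))
  expect_identical(ci0$std, 0)
  expect_identical(ci0$ci95_halfwidth, 0)
})

test_that("single-control batches are excluded from the null with a warning", {
  fr <- data.frame(batch = c("d1", "d1", "d1", "d2"), f_AGG = c(0.3, 0.32, 0.29, 0.4))
  expect_warning(ci <- control_interval(fr), "d2")
  expect_identical(ci$n_controls, 3L)
})

test_that("the 3*STD band tail is below the printed 0.003 bound", {
  expect_lt(band_tail_prob(3), 0.003)
  expect_equal(band_tail_prob(3), 0.0027, tolerance = 1e-3)
  expect_lt(band_tail_prob(2), 0.05)
})

test_that("significance calls apply the mean +/- SEM band rule", {
  # printed FUS-screen interval: ci95 = 0.1577 (STD = 0.07885)
  ci <- ci_with_std(0.1577 / 2)
  # mean + SEM lands between the 2*STD and 3*STD bands: alleviator at p<0.05
  rec <- data.frame(chaperone_id = "x", n = 4, mean_score = -0.25, sem = 0.05)
  out <- call_significance(rec, ci)
  expect_identical(out$call, "alleviator")
  expect_identical(out$p_level, "p<0.05")

  ci2 <- ci_with_std(0.0789)
  out2 <- call_significance(data.frame(chaperone_id = "y", n = 4,
                                       mean_score = -0.60, sem = 0.05), ci2)
  expect_identical(out2$call, "alleviator")
  expect_identical(out2$p_level, "p<0.003")

  out3 <- call_significance(data.frame(chaperone_id = "z", n = 4,
                                       mean_score = 0, sem = 0.2), ci)
  expect_identical(out3$call, "not-significant")

  out4 <- call_significance(data.frame(chaperone_id = "w", n = 1,
                                       mean_score = -2, sem = NA_real_), ci)
  expect_identical(out4$call, "refused")

  out5 <- call_significance(data.frame(chaperone_id = "v", n = 4,
                                       mean_score = 0.5, sem = 0.05), ci)
  expect_identical(out5$call, "aggravator")
})

test_that("dose-response reports per-dose calls and strict monotonicity", {
  ci <- ci_with_std(0.1577 / 2)
  # deepening alleviation: -2.18 = log2(0.22), the 78%-reduction regime
  series <- data.frame(dose = c(500, 1250, 1800),
                       mean_score = c(-0.3, -1.0, log2(0.22)),
                       sem = c(0.05, 0.05, 0.05))
  dr <- dose_response(series, ci)
  expect_true(dr$monotone)
  expect_identical(dr$direction, "alleviation")
  expect_identical(dr$per_dose$call, rep("alleviator", 3))

  flat <- data.frame(dose = 1:3, mean_score = c(-0.3, -0.3, -0.3), sem = 0.05)
  expect_false(dose_response(flat, ci)$monotone)
  two <- data.frame(dose = 1:2, mean_score = c(-0.3, -0.5), sem = 0.05)
  expect_true(dose_response(two, ci)$monotone)
  bad <- data.frame(dose = c(2, 1), mean_score = c(-0.3, -0.5), sem = 0.05)
  expect_error(dose_response(bad, ci), "increasing")
})

test_that("heat-shock reporter scores are percent of the MG132 span", {
  tp <- seq(12, 24, by = 2)
  fl <- do.call(rbind, lapply(tp, function(t) {
    data.frame(well = c("base1", "base2", "mg1", "mg2", "w_zero", "w_full", "w_half"),
               timepoint_h = t,
               value = c(100, 100, 500, 500, 100, 500, 300))
  }))
  sc <- hsr_reporter_score(fl, baseline_wells = c("base1", "base2"),
                           mg132_wells = c("mg1", "mg2"))
  s <- setNames(sc$score, sc$well)
  expect_equal(unname(s["w_zero"]), 0)
  expect_equal(unname(s["w_full"]), 100)
  expect_equal(unname(s["w_half"]), 50)
})

test_that("simulated chaperone effects are recovered within the SEM envelope", {
  hits <- 0L; total <- 0L
  for (s in 1:20) {
    for (m in c(0.25, 0.5, 1, 2)) {
      fr <- sim_screen_fractions(n_batches = 8, n_ctrl_per_batch = 6,
                                 chaperone_m = list(chap = m),
                                 n_rep_per_chap = 8, seed = 7000 + 17 * s + round(100 * m))
      rec <- modulation_scores(fr)$summary
      total <- total + 1L
      if (abs(rec$mean_score - log2(m)) <= 3 * rec$sem) hits <- hits + 1L
    }
  }
  expect_gte(hits / total, 0.9)
})
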