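test_that("ev_params validates and prints its settings", {
  p <- ev_params()
  expect_equal(p$d_r, 1.0)
  expect_equal(p$n, 1)
  expect_equal(p$band_width, 0.3)
  expect_equal(p$mode, "banded")
  expect_error(ev_params(d_r = 0), "d_r")
  expect_error(ev_params(n = -1), "`n`")
  expect_error(ev_params(band_width = 0.25), "multiple")
  expect_error(ev_params(mode = "fuzzy"))
})

test_that("equivalent_volume weights bands by (d/d_r)^n", {
  one_band <- function(d, v) {
    structure(list(bands = data.frame(band = 1L, distance_cm = d,
                                      volume_cc = v),
                   band_width = 0.3, mode = "banded", total_volume_cc = v),
              class = "banded_decomposition")
  }
  # at d_r = 1, n = 1 a volume at 0.2..1.0 cm counts 2/10..10/10 of itself
  p <- ev_params()
  for (d in seq(0.2, 1.0, 0.2))
    expect_equal(equivalent_volume(one_band(d, 10), p), 10 * d)
  # n = 0 disables the weighting entirely
  expect_equal(equivalent_volume(one_band(0.2, 10), ev_params(n = 0)), 10)
  # weights above 1 beyond d_r are applied literally, unless capped
  expect_equal(equivalent_volume(one_band(1.5, 10), p), 15)
  expect_equal(equivalent_volume(one_band(1.5, 10),
                                 ev_params(cap_weights = TRUE)), 10)
  # quadratic penalty
  expect_equal(equivalent_volume(one_band(0.5, 8), ev_params(n = 2)), 2)
})

test_that("continuous-mode equivalent volume approaches the shell integral", {
  ph <- make_sphere_pair_uniform(r0 = 2.0, margin = 0.6, spacing = 0.1)
  shell <- mask_volume(ph$ref$grid & !ph$std$grid, ph$ref$spacing)
  dec <- band_nonoverlap(shell, ph$std, w = 0.3, mode = "continuous")
  ev <- equivalent_volume(dec, ev_params(mode = "continuous"))
  oracle <- shell_ev_oracle(2.0, 2.6, d_r = 1, n = 1)
  # center-to-center distances overestimate the analytic distance by a
  # fraction of a voxel, so the discrete EV sits a little above the integral
  expect_gt(ev, oracle)
  expect_rel_equal(ev, oracle, 0.12)
})

test_that("cc_ev_from_components reproduces the published worked example", {
  # uniform-expansion group: V_I 19.4, EV_Ref 28.25 (incl. intersection)
  r <- cc_ev_from_components(19.4, 0, 28.25 - 19.4)
  expect_equal(round(r$JC_EV, 3), 0.687)
  expect_equal(round(r$DSC_EV, 3), 0.814)
  # displaced-reference group at equal reference volume: EV_Ref 31.19
  r2 <- cc_ev_from_components(19.4, 0, 31.19 - 19.4)
  expect_equal(round(r2$JC_EV, 3), 0.622)
  expect_equal(round(r2$DSC_EV, 3), 0.767)
  # perfect concordance and degenerate zero
  r3 <- cc_ev_from_components(5, 0, 0)
  expect_equal(r3$JC_EV, 1)
  expect_equal(r3$DSC_EV, 1)
  expect_warning(r0 <- cc_ev_from_components(0, 0, 0), "zero")
  expect_equal(r0$JC_EV, 0)
  expect_error(cc_ev_from_components(-1, 0, 0), "non-negative")
})

test_that("JC_EV equals the diagnostic-test agreement rate with zero TN", {
  # 2x2 table: TP = V_I, FP = EV_Ref-I, FN = EV_Std-I, TN = 0;
  # agreement rate (TP + TN) / total
  set.seed(7)
  for (i in 1:20) {
    vi <- runif(1, 0, 50); evs <- runif(1, 0, 20); evr <- runif(1, 0, 20)
    r <- cc_ev_from_components(vi, evs, evr)
    expect_equal(r$JC_EV, (vi + 0) / (vi + evs + evr))
  }
})

test_that("classic_coefficients match the published volumes", {
  r <- classic_coefficients(19.4, 43.7, 19.4)
  expect_equal(round(r$JC, 3), 0.444)
  expect_equal(round(r$DSC, 3), 0.615)
  r2 <- classic_coefficients(38.5, 42.1, 35.5)
  expect_equal(round(r2$JC, 3), 0.787)
  expect_equal(round(r2$DSC, 3), 0.881)
  expect_equal(classic_coefficients(5, 5, 5), list(JC = 1, DSC = 1))
  expect_equal(classic_coefficients(0, 0, 0), list(JC = 0, DSC = 0))
  expect_error(classic_coefficients(5, 5, 6), "exceeds")
})

test_that("agreement thresholds follow the equal-volume construction", {
  thr <- agreement_thresholds(0.95, 2)
  expect_equal(thr$JC_EV_threshold, 0.90)
  expect_equal(thr$DSC_EV_threshold, 0.95)
  expect_equal(agreement_thresholds(1, 2),
               list(JC_EV_threshold = 1, DSC_EV_threshold = 1))
  exact <- agreement_thresholds(0.90, Inf)
  expect_equal(exact$JC_EV_threshold, 0.9 / 1.1)
  expect_equal(exact$DSC_EV_threshold, 0.90)
  expect_error(agreement_thresholds(0), "0, 1")
  expect_error(agreement_thresholds(1.2), "0, 1")
})

test_that("concordance of a mask with itself is perfect", {
  m <- cuboid_mask(c(14, 14, 14), c(3, 3, 3), c(10, 10, 10))
  r <- concordance(m, m)
  expect_equal(r$JC, 1)
  expect_equal(r$DSC, 1)
  expect_equal(r$JC_EV, 1)
  expect_equal(r$DSC_EV, 1)
  expect_true(r$concordant_JC_EV && r$concordant_DSC_EV)
  expect_false(r$size_mismatch_caveat)
})

test_that("concordance result satisfies the algebraic identities", {
  for (ph in list(make_sphere_pair_uniform(2.0, 0.6, spacing = 0.1),
                  make_sphere_pair_displaced(2.0, 2.6, 0.5, spacing = 0.1),
                  lobe_pair(3))) {
    for (mode in c("banded", "continuous")) {
      r <- concordance(ph$std, ph$ref, ev_params(mode = mode))
      expect_true(r$JC_EV >= 0 && r$JC_EV <= 1)
      expect_true(r$JC <= r$DSC && r$JC_EV <= r$DSC_EV)
      expect_equal(r$DSC_EV, 2 * r$JC_EV / (1 + r$JC_EV))
      expect_equal(r$DSC, 2 * r$JC / (1 + r$JC))
      expect_equal(r$EV_Std, r$V_I + r$EV_Std_minus_I)
      expect_equal(r$EV_Ref, r$V_I + r$EV_Ref_minus_I)
      # n = 0 reduces to the classic coefficients exactly
      r0 <- concordance(ph$std, ph$ref, ev_params(n = 0, mode = mode))
      expect_equal(r0$JC_EV, r0$JC)
      expect_equal(r0$DSC_EV, r0$DSC)
    }
  }
})

test_that("coefficients are symmetric under swapping standard and reference", {
  ph <- make_sphere_pair_displaced(1.8, 2.2, offset = 0.7, spacing = 0.1)
  a <- concordance(ph$std, ph$ref, ev_params())
  b <- concordance(ph$ref, ph$std, ev_params())
  expect_equal(a$JC_EV, b$JC_EV)
  expect_equal(a$DSC_EV, b$DSC_EV)
  expect_equal(a$EV_Std_minus_I, b$EV_Ref_minus_I)
})

test_that("moving a discrepant lobe farther away lowers JC_EV but not JC", {
  near <- lobe_pair(2)
  far <- lobe_pair(8)
  rn <- concordance(near$std, near$ref, ev_params())
  rf <- concordance(far$std, far$ref, ev_params())
  expect_equal(rn$JC, rf$JC)    # same volumes, classic coefficient blind
  expect_lt(rf$JC_EV, rn$JC_EV) # EV penalty grows with distance
  # with no penalty the distinction disappears
  rn0 <- concordance(near$std, near$ref, ev_params(n = 0))
  rf0 <- concordance(far$std, far$ref, ev_params(n = 0))
  expect_equal(rn0$JC_EV, rf0$JC_EV)
})

test_that("coarser banding lowers JC_EV when most discrepancy is proximal", {
  # most of the non-overlap within the first 0.3 cm, as in clinical pairs:
  # widening the band raises the representative distance of that volume
  ph <- make_sphere_pair_uniform(2.0, 0.4, spacing = 0.1)
  r3 <- concordance(ph$std, ph$ref, ev_params(band_width = 0.3))
  r6 <- concordance(ph$std, ph$ref, ev_params(band_width = 0.6))
  expect_lt(r6$JC_EV, r3$JC_EV)
})

test_that("size-mismatch caveat flags unequal structures", {
  ph <- make_sphere_pair_uniform(2.0, 0.6, spacing = 0.1)
  expect_true(concordance(ph$std, ph$ref)$size_mismatch_caveat)
  m <- cuboid_mask(c(14, 14, 14), c(3, 3, 3), c(10, 10, 10))
  expect_false(concordance(m, m)$size_mismatch_caveat)
})
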