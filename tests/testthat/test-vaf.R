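test_that("detection filter is inclusive at the limit", {
  spec <- make_spectrum(c(0.009, 0.01, 0.011, 0.5), universe_size = 1000)
  kept <- detection_filter(spec, 0.01)
  expect_equal(kept$cell_fraction, c(0.01, 0.011, 0.5))
  expect_equal(nrow(detection_filter(spec, 0)), 4)   # identity
  expect_equal(attr(kept, "universe_size"), 1000)
})

test_that("cumulative curves match the hand-enumerated binary tree", {
  # G = 3 generations, k = 10 mutations per daughter: cell fractions
  # 2^-g carried by k * 2^g mutations, so M(v) = k (1/v - 2) in the
  # diploid convention (v = f/2, v_max = 1/2)
  tree <- build_tree_tumour(3, 10)
  curve <- cumulative_vaf(mutation_frequencies(tree), "diploid_vaf")
  expect_equal(curve$freq, c(0.25, 0.125, 0.0625))
  expect_equal(curve$cumulative_count, c(20, 60, 140))
  expect_equal(curve$cumulative_count, 10 * (curve$inv_freq - 2))
  expect_equal(attr(curve, "f_max"), 0.5)

  # cell-fraction convention: same counts at doubled frequencies
  cf <- cumulative_vaf(mutation_frequencies(tree), "cell_fraction")
  expect_equal(cf$freq, c(0.5, 0.25, 0.125))
  expect_equal(cf$cumulative_count, c(20, 60, 140))

  # single mutation at v = 0.5 gives the single point (2, 1)
  one <- cumulative_vaf(make_spectrum(1), "diploid_vaf")
  expect_equal(one$inv_freq, 2)
  expect_equal(one$cumulative_count, 1)

  expect_error(cumulative_vaf(make_spectrum(numeric(0))), "empty")
})

test_that("M is non-decreasing in 1/v for arbitrary spectra", {
  set.seed(41)
  for (i in 1:20) {
    f <- round(runif(50, 1, 100)) / 100
    curve <- cumulative_vaf(make_spectrum(f))
    expect_true(all(diff(curve$cumulative_count[
      order(curve$inv_freq)]) >= 0))
  }
})

test_that("truncation removes exactly the lowest-frequency points", {
  curve <- cumulative_vaf(make_spectrum(seq(0.1, 1, by = 0.1)))
  expect_equal(nrow(curve), 10)
  tr <- truncate_low_frequency(curve, 3)
  expect_equal(nrow(tr), 7)
  expect_equal(max(tr$inv_freq), sort(curve$inv_freq)[7])
  expect_true(attr(tr, "truncated"))
  expect_identical(truncate_low_frequency(curve, 0), curve)
  expect_error(truncate_low_frequency(curve, 10), "too few")
})

test_that("OLS recovers exact lines and the binary-tree slope equals lambda", {
  # collinear points M = 10 / v - 20
  spec <- make_spectrum(2 * 1 / c(4, 8, 16, 32), universe_size = 64)
  curve <- cumulative_vaf(spec)
  curve$cumulative_count <- 10 * curve$inv_freq - 20
  fit <- fit_effective_mutation_rate(curve)
  expect_equal(fit$slope, 10, tolerance = 1e-10)
  expect_equal(fit$intercept, -20, tolerance = 1e-10)
  expect_equal(fit$ks_distance, 0, tolerance = 1e-10)

  # closed-form oracle: deterministic k per daughter makes the diploid
  # curve exactly linear with slope k and intercept -2k
  for (k in c(1, 10)) {
    tree <- build_tree_tumour(4, k)
    fitk <- fit_effective_mutation_rate(
      cumulative_vaf(mutation_frequencies(tree), "diploid_vaf"))
    expect_equal(fitk$slope, k, tolerance = 1e-9)
    expect_equal(fitk$intercept, -2 * k, tolerance = 1e-9)
    expect_equal(fitk$ks_distance, 0, tolerance = 1e-9)
  }

  expect_error(fit_effective_mutation_rate(
    cumulative_vaf(make_spectrum(0.5))), "at least 2")
})

test_that("ks_distance is zero on the fit line and scales into [0, 1]", {
  curve <- cumulative_vaf(make_spectrum(c(0.5, 0.25, 0.25, 0.125)))
  fit <- fit_effective_mutation_rate(curve)
  expect_gte(fit$ks_distance, 0)
  expect_lte(fit$ks_distance, 1)
  expect_equal(ks_distance(curve, 0, max(curve$cumulative_count) + 100), 1)
})

test_that("whole-population inference recovers the mutation rate at p = 1", {
  tum <- grown_fixture("p1_4k10", push_rate = 1, mutation_rate = 10,
                       target_size = 2^12, seed = 17)
  fit <- infer_mutation_rate(tum)
  expect_gt(fit$slope, 7)
  expect_lt(fit$slope, 13)
  expect_lt(fit$ks_distance, 0.1)
  # frequencies are the exact dyadic ladder
  spec <- mutation_frequencies(tum)
  expect_true(all(spec$cell_fraction %in% 2^-(1:12)))
})
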