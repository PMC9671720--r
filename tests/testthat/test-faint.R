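test_that("weight to concentration reproduces the gravimetric table", {
  expect_equal(weight_to_concentration(1.03, 324.42, 0.6), 5.29,
               tolerance = 0.005 / 5.29)
  expect_equal(weight_to_concentration(21.09, 324.42, 0.6), 108.35,
               tolerance = 0.005 / 108.35)
  expect_equal(weight_to_concentration(324.42, 324.42, 1000), 1.0)
  expect_error(weight_to_concentration(-1, 324.42, 0.6), "weight_mg")
  expect_error(weight_to_concentration(1, 0, 0.6), "molecular_weight")
})

test_that("normalized increment is the direct product formula", {
  expect_equal(normalized_increment(1650, 1, 1, 1, 1), 1650)
  expect_equal(normalized_increment(1650 * 64 * 161 * 5 * 3, 64, 161, 5, 3),
               1650)
  set.seed(5)
  for (i in 1:25) {
    v <- exp(rnorm(5))
    expect_equal(normalized_increment(v[1], v[2], v[3], v[4], v[5]),
                 v[1] / (v[2] * v[3] * v[4] * v[5]), tolerance = 1e-12)
  }
  expect_error(normalized_increment(0, 1, 1, 1, 1), "intensity")
  expect_error(normalized_increment(1, 1, -2, 1, 1), "rg")
})

fake_integrals <- function(ig, samples, regions, dev = function(rg) 1) {
  # algebraically exact integrals I = ig * ns * g(rg) * nH * c
  do.call(rbind, lapply(seq_len(nrow(samples)), function(i) {
    data.frame(sample_id = samples$sample_id[i], label = regions$label,
               intensity = ig * samples$ns[i] * samples$rg[i] *
                 dev(samples$rg[i]) * regions$n_protons *
                 samples$known_concentration_mM[i],
               snr = Inf, ns = samples$ns[i], rg = samples$rg[i],
               stringsAsFactors = FALSE)
  }))
}

test_that("IG calibration is the mean of normalized increments", {
  reg <- three_regions()
  samples <- data.frame(sample_id = c("x", "y"), ns = c(2L, 8L),
                        rg = c(25.4, 90.5),
                        known_concentration_mM = c(5, 50))
  ints <- fake_integrals(1650, samples, reg)
  cal <- calibrate_ig(ints, samples, reg)
  expect_equal(cal$ig, 1650, tolerance = 1e-12)
  expect_equal(cal$dispersion, 0, tolerance = 1e-9)

  one <- calibrate_ig(ints[1, ], samples, reg)
  expect_equal(one$ig, ints$intensity[1] / (2 * 25.4 * 5 * 1))

  # two hand-made observations: mean 1650, rms deviation 50
  two <- data.frame(sample_id = "x", label = c("a", "a"),
                    intensity = c(1600, 1700) * 2 * 25.4 * 5,
                    snr = Inf, ns = 2L, rg = 25.4)
  cal2 <- calibrate_ig(two, samples, reg)
  expect_equal(cal2$ig, 1650)
  expect_equal(cal2$dispersion, 50)

  expect_error(calibrate_ig(transform(ints, sample_id = "zz"), samples, reg),
               "zz")
  expect_equal(calibrate_ig(two, samples, reg, center = "median")$ig, 1650)
})

test_that("IG is scale-equivariant and back-calculation scale-invariant", {
  reg <- three_regions()
  samples <- data.frame(sample_id = c("x", "y"), ns = c(2L, 8L),
                        rg = c(25.4, 90.5),
                        known_concentration_mM = c(5, 50))
  ints <- fake_integrals(1650, samples, reg)
  ints_k <- transform(ints, intensity = intensity * 3.7)
  cal <- calibrate_ig(ints, samples, reg)
  cal_k <- calibrate_ig(ints_k, samples, reg)
  expect_equal(cal_k$ig, 3.7 * cal$ig)
  bc <- back_calculate(ints, cal, reg)
  bc_k <- back_calculate(ints_k, cal_k, reg)
  expect_equal(bc_k$bc_mM, bc$bc_mM)
})

test_that("back-calculation inverts the intensity model exactly", {
  reg <- three_regions()
  samples <- data.frame(sample_id = "s", ns = 16L, rg = 64,
                        known_concentration_mM = 5)
  cal <- structure(list(ig = 1650, center = "mean",
                        observations = data.frame(), dispersion = 0),
                   class = "ig_calibration")
  ints <- fake_integrals(1650, samples, reg)
  res <- back_calculate(ints, cal, reg)
  expect_equal(res$bc_mM, 5, tolerance = 1e-14)
  expect_equal(res$sigma_mM, 0)
  expect_equal(res$n_estimates, 3L)
  expect_false(res$linearized)
  expect_error(back_calculate(transform(ints, label = "nope"), cal, reg),
               "nope")
})

test_that("linearization estimates gain deviations up to a common scale", {
  reg <- three_regions()
  dev <- function(rg) c(`25.4` = 0.93, `57` = 0.96, `90.5` = 0.95)[
    as.character(rg)]
  samples <- data.frame(sample_id = c("a", "b", "c"), ns = 4L,
                        rg = c(25.4, 57, 90.5),
                        known_concentration_mM = c(5, 30, 80))
  ints <- fake_integrals(1650, samples, reg, dev = dev)
  cal <- calibrate_ig(ints, samples, reg)
  lin <- estimate_linearization(cal)
  ratio <- lin$table$rg_linearized / lin$table$rg_original
  expect_equal(ratio / mean(ratio),
               unname(dev(lin$table$rg_original) / mean(dev(lin$table$rg_original))),
               tolerance = 1e-9)

  ident <- calibrate_ig(fake_integrals(1650, samples, reg), samples, reg)
  lin_id <- estimate_linearization(ident)
  expect_equal(lin_id$table$rg_linearized / lin_id$table$rg_original,
               rep(1, 3), tolerance = 1e-6)

  single <- calibrate_ig(ints[ints$rg == 57, ], samples, reg)
  expect_error(estimate_linearization(single), "single RG step")
})

test_that("the published linearization table is looked up and interpolated", {
  lin <- published_linearization()
  expect_equal(apply_linearization(lin, 25.4), 23.58)
  expect_equal(apply_linearization(lin, 161), 153.00)
  expect_equal(apply_linearization(lin, 90.5), 85.10)
  # hand-computed midpoint between the first two rows
  expect_equal(apply_linearization(lin, 26.95),
               23.58 + (26.95 - 25.4) / (28.5 - 25.4) * (26.35 - 23.58))
  expect_error(apply_linearization(lin, 200), "outside")
  expect_equal(apply_linearization(lin, 200, allow_extrapolate = TRUE),
               200 * 153 / 161)
  # serialization round-trip
  p <- withr::local_tempfile(fileext = ".csv")
  write_linearization(lin, p)
  expect_equal(read_linearization(p)$table, lin$table)
})

test_that("simulated calibration recovers concentrations and gain benefit", {
  reg <- three_regions()
  cond <- table2_conditions()
  set <- simulate_calibration_set(cond, three_signals(),
                                  gain = default_gain_model(),
                                  ig_true = 1650, noise_sigma = 0, seed = 2L,
                                  replicates = 1L)
  ints <- integrate_set(set$spectra, reg, set$manifest)
  cal <- calibrate_ig(ints, known_samples(cond), reg)
  lin <- estimate_linearization(cal)
  bc  <- back_calculate(ints, cal, reg)
  bcl <- back_calculate(ints, cal, reg, lin)
  truth <- cond$concentration_mM[match(bc$sample_id, cond$sample_id)]
  # per-condition recovery: linearized strictly better in the mean
  expect_lt(mean(abs(bcl$bc_mM - truth)), mean(abs(bc$bc_mM - truth)))
  expect_lt(max(abs(bcl$bc_mM / truth - 1)), 0.005)
  expect_true(all(bcl$linearized) && !any(bc$linearized))
})

test_that("aggregate standard error shrinks with the root of the pool size", {
  reg <- three_regions()
  gain <- gain_model(25.4)
  one_sem <- function(n_rep, seed) {
    cond <- data.frame(sample_id = "s", concentration_mM = 48.19,
                       ns = 4L, rg = 25.4)
    noise <- noise_sigma_for_snr(three_signals(), cond, gain,
                                 min_snr = 100)
    set <- simulate_calibration_set(cond, three_signals(), gain,
                                    ig_true = 1650, noise_sigma = noise,
                                    seed = seed, replicates = n_rep,
                                    n_points = 8192L)
    ints <- integrate_set(set$spectra, reg, set$manifest)
    cal <- structure(list(ig = 1650, center = "mean",
                          observations = data.frame(), dispersion = 0),
                     class = "ig_calibration")
    back_calculate(ints, cal, reg)$sem_mM
  }
  s2 <- sapply(1:8, function(k) one_sem(2L, 100 + k))
  s8 <- sapply(1:8, function(k) one_sem(8L, 200 + k))
  # pools of 6 vs 24 estimates: the standard error should drop ~ 2-fold
  expect_lt(abs(mean(s8) / mean(s2) - 0.5), 0.25 * 0.5)
})

test_that("noisy round trip stays within three sigma of the truth", {
  reg <- three_regions()
  cond <- calibration_conditions()
  noise <- noise_sigma_for_snr(three_signals(), cond, NULL, min_snr = 200)
  set <- simulate_calibration_set(cond, three_signals(), gain = NULL,
                                  ig_true = 1650, noise_sigma = noise,
                                  seed = 31L, replicates = 1L)
  ints <- integrate_set(set$spectra, reg, set$manifest)
  cal <- calibrate_ig(ints, known_samples(cond), reg)
  expect_lt(abs(cal$ig / 1650 - 1), 0.01)
  bc <- back_calculate(ints, cal, reg)
  truth <- cond$concentration_mM[match(bc$sample_id, cond$sample_id)]
  ok <- abs(bc$bc_mM - truth) <= 3 * pmax(bc$sigma_mM, 1e-6) |
    abs(bc$bc_mM / truth - 1) < 0.01
  expect_true(all(ok))
})
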