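test_that("FT of a decaying complex exponential peaks at its frequency", {
  # analytic oracle: fid(t) = exp(i*2*pi*f0*t - t/T2) transforms to a
  # Lorentzian centered at f0; the discrete peak must land within one
  # digital resolution step (sweep/n) of the true position
  meta <- acq_meta(ns = 1, rg = 1, sweep_ppm = 12, n_points = 4096L,
                   spectrometer_freq_MHz = 400, center_ppm = 5)
  sw_hz <- 12 * 400
  dt <- 1 / sw_hz
  f0_ppm <- 7.37
  f0_hz <- (f0_ppm - 5) * 400
  t <- (0:4095) * dt
  fid <- new_fid(meta, exp(complex(imaginary = 2 * pi * f0_hz * t) - t / 0.5))
  sp <- fourier_transform(fid)
  expect_lt(abs(sp$ppm[which.max(sp$real)] - f0_ppm), 12 / 4096)
})

test_that("zero FID transforms to a zero spectrum", {
  meta <- acq_meta(ns = 1, rg = 1, n_points = 512L)
  sp <- fourier_transform(new_fid(meta, complex(length.out = 512L)))
  expect_true(all(sp$real == 0) && all(sp$imag == 0))
})

test_that("the transform satisfies Parseval's identity", {
  set.seed(3)
  n <- 2048L
  meta <- acq_meta(ns = 1, rg = 1, n_points = n)
  x <- complex(real = rnorm(n), imaginary = rnorm(n))
  sp <- fourier_transform(new_fid(meta, x))
  e_time <- sum(Mod(x)^2)
  e_freq <- sum(sp$real^2 + sp$imag^2) / n   # unnormalized DFT convention
  expect_equal(e_freq, e_time, tolerance = 1e-9)
})

test_that("zero-filling interpolates without changing region integrals", {
  # a causal, fully decayed exponential FID: zero-filling then only refines
  # the sampling of the same underlying lineshape
  meta <- acq_meta(ns = 1, rg = 1, sweep_ppm = 14, n_points = 4096L,
                   spectrometer_freq_MHz = 400, center_ppm = 5)
  sw_hz <- 14 * 400
  t <- (0:4095) / sw_hz
  fid <- new_fid(meta, 50 * exp(complex(imaginary = 2 * pi * (4 - 5) * 400 * t)
                                - t / 0.05))
  reg <- integration_regions("A", 5, 3, 1)
  I1 <- integrate_regions(fourier_transform(fid, 1), reg)$intensity
  I2 <- integrate_regions(fourier_transform(fid, 2), reg)$intensity
  I4 <- integrate_regions(fourier_transform(fid, 4), reg)$intensity
  expect_length(fourier_transform(fid, 4)$ppm, 16384L)
  expect_equal(I2 / I1, 1, tolerance = 1e-3)
  expect_equal(I4 / I1, 1, tolerance = 1e-3)
  expect_error(fourier_transform(fid, 3), "zero_fill_factor")
})

test_that("auto-phase recovers applied dephasing and preserves integrals", {
  sp <- simulate_spectrum(three_signals(),
                          sim_config(ig_true = 1650, ns = 4, rg = 25.4,
                                     concentration_mM = 10, n_points = 8192L))
  reg <- three_regions()
  I0 <- integrate_regions(sp, reg)$intensity
  for (ph in list(c(30, 0), c(45, 20))) {
    rec <- attr(auto_phase(apply_phase(sp, ph[1], ph[2])), "phases")
    expect_lt(abs(rec[["ph0"]] + ph[1]), 1)
    expect_lt(abs(rec[["ph1"]] + ph[2]), 1)
    I <- integrate_regions(auto_phase(apply_phase(sp, ph[1], ph[2])),
                           reg)$intensity
    expect_lt(max(abs(I / I0 - 1)), if (ph[1] == 30) 0.005 else 0.01)
  }
  # fixed point: an already-phased spectrum moves by < 0.5 degrees
  rec0 <- attr(auto_phase(sp), "phases")
  expect_lt(max(abs(rec0)), 0.5)
  # the phased real part is essentially all-positive area
  ph <- auto_phase(apply_phase(sp, 45, 20))
  expect_gt(sum(pmax(ph$real, 0)) / sum(abs(ph$real)), 0.99)
})

test_that("baseline correction removes offsets and ramps", {
  # amplitudes chosen so the baseline features are a realistic fraction of
  # the peaks (an offset drowned 1e7-fold under the peaks is not resolvable
  # by any baseline model)
  sp <- simulate_spectrum(three_signals(),
                          sim_config(ig_true = 1650, ns = 1, rg = 1,
                                     concentration_mM = 1, n_points = 8192L))
  reg <- three_regions()
  I0 <- integrate_regions(sp, reg)$intensity

  off <- sp; off$real <- off$real + 100
  corr <- baseline_correct(off)
  expect_lt(abs(median(corr$real[sp$ppm < 0])), 1)   # offset gone to < 1%
  expect_lt(max(abs(integrate_regions(corr, reg)$intensity / I0 - 1)), 0.005)

  ramp <- sp; ramp$real <- ramp$real + seq(200, -50, length.out = 8192)
  corr2 <- baseline_correct(ramp)
  expect_lt(max(abs(integrate_regions(corr2, reg)$intensity / I0 - 1)), 0.005)

  flat <- new_spectrum(sp$meta, sp$ppm, rep(0, 8192))
  expect_equal(baseline_correct(flat)$real, rep(0, 8192))
  expect_error(baseline_correct(sp, method = "spline"), "poly")
})

test_that("processing is deterministic", {
  sp <- simulate_spectrum(three_signals(),
                          sim_config(ig_true = 1650, ns = 2, rg = 25.4,
                                     concentration_mM = 20, n_points = 4096L))
  fid <- fid_from_spectrum(apply_phase(sp, 20, 5))
  a <- process_fid(fid)
  b <- process_fid(fid)
  expect_identical(a, b)
})

test_that("full pipeline reproduces model integrals within 1%", {
  lw <- c(1.2, 1.0, 1.5)
  conc <- 15
  sp <- simulate_spectrum(three_signals(),
                          sim_config(ig_true = 1650, ns = 8, rg = 25.4,
                                     concentration_mM = conc,
                                     n_points = 16384L))
  truth <- model_integral(1650, 8, 25.4, c(1, 3, 2), conc,
                          half_width_ppm = 0.5, linewidth_hz = lw)
  fid <- fid_from_spectrum(apply_phase(sp, 35, 15))
  out <- process_fid(fid)
  got <- integrate_regions(out, three_regions())$intensity
  expect_lt(max(abs(got / truth - 1)), 0.01)
})
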