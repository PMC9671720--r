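#' Signal specification for the spectrum simulator
#'
#' Describes one resonance as a Lorentzian multiplet: a chemical-shift
#' center, a full width at half maximum, the number of protons contributing,
#' and optional multiplet components given as (offset in Hz, relative weight)
#' pairs whose weights sum to one.
#'
#' @param center_ppm Chemical shift of the multiplet center (ppm).
#' @param linewidth_hz Full width at half maximum, Hz (> 0).
#' @param n_protons Integer proton count contributing to the signal (>= 1).
#' @param multiplet Two-column matrix or list of `c(offset_hz, weight)` pairs;
#'   default a singlet. Weights must sum to 1 within 1e-9.
#' @param label Signal name (used for integration-region bookkeeping).
#' @return An object of class `signal_spec`.
#' @export
signal_spec <- function(center_ppm, linewidth_hz, n_protons,
                        multiplet = NULL, label = NULL) {
  stopifnot("linewidth_hz must be > 0" = is.finite(linewidth_hz) && linewidth_hz > 0,
            "n_protons must be >= 1" = n_protons >= 1)
  if (is.null(multiplet)) multiplet <- matrix(c(0, 1), ncol = 2)
  if (is.list(multiplet)) multiplet <- do.call(rbind, multiplet)
  multiplet <- matrix(as.numeric(multiplet), ncol = 2)
  if (abs(sum(multiplet[, 2]) - 1) > 1e-9)
    stop("multiplet relative weights must sum to 1 (got ",
         num_str(sum(multiplet[, 2])), ")")
  if (is.null(label)) label <- sprintf("s%.3fppm", center_ppm)
  structure(list(center_ppm = as.numeric(center_ppm),
                 linewidth_hz = as.numeric(linewidth_hz),
                 n_protons = as.integer(n_protons),
                 multiplet = multiplet, label = as.character(label)),
            class = "signal_spec")
}

#' Receiver-gain response model
#'
#' The amplifier response at nominal gain RG is `g(RG) = RG * deviation(RG)`.
#' An ideal (perfectly linear) amplifier has deviation 1 at every step; real
#' amplifiers deviate by a few percent, which is what the receiver-gain
#' linearization estimates from calibration data.
#'
#' @param rg Ordered vector of nominal instrument RG steps (> 0).
#' @param deviation Per-step multiplicative deviation `g(RG)/RG`, each within
#'   `[0.85, 1.15]`. Default 1 (ideal amplifier).
#' @return An object of class `gain_model`.
#' @export
gain_model <- function(rg, deviation = rep(1, length(rg))) {
  stopifnot("rg steps must be > 0" = all(is.finite(rg) & rg > 0),
            "rg steps must be strictly increasing" = all(diff(rg) > 0),
            "deviation length mismatch" = length(deviation) == length(rg),
            "deviation factors must lie in [0.85, 1.15]" =
              all(deviation >= 0.85 & deviation <= 1.15))
  structure(list(rg = as.numeric(rg), deviation = as.numeric(deviation)),
            class = "gain_model")
}

#' Default gain model with realistic nonlinearity
#'
#' The instrument RG ladder with per-step deviations of realistic magnitude
#' (a few percent, non-monotone across steps), the regime the linearization
#' stage is designed to correct.
#'
#' @return A `gain_model` over the 17 RG steps from 25.4 to 161.
#' @export
default_gain_model <- function() {
  tab <- rg_table_printed()
  gain_model(tab$rg_original, tab$rg_linearized / tab$rg_original)
}

g_of_rg <- function(gain, rg) {
  if (is.null(gain)) return(rg)
  i <- match(rg, gain$rg)
  if (is.na(i))
    stop("unknown RG step ", num_str(rg), "; known steps: ",
         paste(num_str(gain$rg), collapse = ", "))
  gain$rg[i] * gain$deviation[i]
}

#' Simulation configuration
#'
#' Fixes the intensity model of one simulated experiment. The absolute
#' integral of each signal is
#' `ig_true * ns * g(rg) * n_protons * concentration_mM`
#' (intensity-ppm units), i.e. intensity per scan, per effective receiver-gain
#' unit, per proton and per mM — the quantity the IG calibration estimates.
#'
#' @param ig_true True intensity-gain factor (> 0).
#' @param ns Number of scans (>= 1).
#' @param rg Nominal receiver gain; must be a step of the gain model in use.
#' @param concentration_mM Analyte concentration in mM.
#' @param noise_sigma Additive white Gaussian noise, std per spectral point in
#'   receiver units; the realized std is `noise_sigma * g(rg) * sqrt(ns)`,
#'   matching per-scan co-addition through the amplifier. Default 0.
#' @param sweep_ppm,n_points,center_ppm,spectrometer_freq_MHz Spectral window
#'   and grid; `n_points` must be a power of two.
#' @param seed RNG seed recorded in the spectrum provenance; `NULL` leaves the
#'   RNG state untouched.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(ig_true = 1650, ns = 1L, rg = 1, concentration_mM = 1,
                       noise_sigma = 0, sweep_ppm = 14, n_points = 16384L,
                       center_ppm = 5, spectrometer_freq_MHz = 400.13,
                       seed = NULL) {
  stopifnot("ig_true must be > 0" = is.finite(ig_true) && ig_true > 0,
            "ns must be >= 1" = ns >= 1,
            "noise_sigma must be >= 0" = noise_sigma >= 0,
            "n_points must be a power of two" = is_power_of_two(n_points))
  structure(list(ig_true = as.numeric(ig_true), ns = as.integer(ns),
                 rg = as.numeric(rg),
                 concentration_mM = as.numeric(concentration_mM),
                 noise_sigma = as.numeric(noise_sigma),
                 sweep_ppm = as.numeric(sweep_ppm),
                 n_points = as.integer(n_points),
                 center_ppm = as.numeric(center_ppm),
                 spectrometer_freq_MHz = as.numeric(spectrometer_freq_MHz),
                 seed = seed),
            class = "sim_config")
}

# Complex Lorentzian with unit area in ppm units: absorption + i * dispersion.
lorentzian_complex <- function(ppm, center, hw_ppm) {
  d <- ppm - center
  den <- d * d + hw_ppm * hw_ppm
  complex(real = (hw_ppm / pi) / den, imaginary = (-d / pi) / den)
}

#' Simulate an absorption-mode spectrum
#'
#' Builds the spectrum directly in the frequency domain as a sum of complex
#' Lorentzians on the same grid the Fourier-transform stage produces, so the
#' simulator is independent of the processing code under test. The noiseless
#' analytic integral of each signal equals
#' `ig_true * ns * g(rg) * n_protons * concentration_mM`; what a finite
#' integration region recovers is that value times the truncated-Lorentzian
#' mass fraction `(2/pi) * atan(half_width / hwhm)`, see
#' [lorentzian_region_fraction()]. Optional noise is additive white Gaussian
#' on both quadratures.
#'
#' @param signals List of [signal_spec()] objects (or a single one).
#' @param cfg A [sim_config()].
#' @param gain A [gain_model()] containing `cfg$rg`, or `NULL` for an ideal
#'   amplifier (`g(rg) = rg`).
#' @return An `nmr_spectrum` with absorption in `real`, dispersion in `imag`.
#' @export
simulate_spectrum <- function(signals, cfg, gain = NULL) {
  if (inherits(signals, "signal_spec")) signals <- list(signals)
  if (!length(signals)) stop("signal list is empty")
  stopifnot(all(vapply(signals, inherits, TRUE, "signal_spec")))
  if (!is.null(gain)) stopifnot(inherits(gain, "gain_model"))

  lo <- cfg$center_ppm - cfg$sweep_ppm / 2
  hi <- cfg$center_ppm + cfg$sweep_ppm / 2
  g <- g_of_rg(gain, cfg$rg)
  ppm <- ppm_axis(cfg$center_ppm, cfg$sweep_ppm, cfg$n_points)
  y <- complex(length.out = cfg$n_points)
  for (s in signals) {
    for (k in seq_len(nrow(s$multiplet))) {
      center <- s$center_ppm + s$multiplet[k, 1] / cfg$spectrometer_freq_MHz
      if (center < lo || center > hi)
        stop(sprintf("signal '%s' component at %.4f ppm lies outside the sweep window [%.3f, %.3f] ppm",
                     s$label, center, lo, hi))
      area <- cfg$ig_true * cfg$ns * g * s$n_protons * cfg$concentration_mM *
        s$multiplet[k, 2]
      hw <- (s$linewidth_hz / 2) / cfg$spectrometer_freq_MHz
      y <- y + area * lorentzian_complex(ppm, center, hw)
    }
  }
  prov <- sprintf("simulate(ig=%g, ns=%d, rg=%g, g=%g, c=%g mM, noise=%g%s)",
                  cfg$ig_true, cfg$ns, cfg$rg, g, cfg$concentration_mM,
                  cfg$noise_sigma,
                  if (is.null(cfg$seed)) "" else paste0(", seed=", cfg$seed))
  if (cfg$noise_sigma > 0) {
    if (!is.null(cfg$seed)) {
      old <- get_rng_state()
      on.exit(restore_rng_state(old), add = TRUE)
      set.seed(cfg$seed)
    }
    sd_pt <- cfg$noise_sigma * g * sqrt(cfg$ns)
    y <- y + complex(real = stats::rnorm(cfg$n_points, sd = sd_pt),
                     imaginary = stats::rnorm(cfg$n_points, sd = sd_pt))
  }
  meta <- acq_meta(ns = cfg$ns, rg = cfg$rg, d1_s = 16,
                   sweep_ppm = cfg$sweep_ppm, n_points = cfg$n_points,
                   spectrometer_freq_MHz = cfg$spectrometer_freq_MHz,
                   center_ppm = cfg$center_ppm)
  new_spectrum(meta, ppm, Re(y), Im(y), provenance = prov)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' Fraction of a Lorentzian's mass inside a symmetric region
#'
#' For a Lorentzian of half width at half maximum `hwhm` centered in a region
#' of half-width `w`, the captured mass fraction is `(2/pi) * atan(w / hwhm)`.
#' Used to make integral expectations truncation-aware.
#'
#' @param half_width_ppm Region half-width (ppm).
#' @param linewidth_hz Full width at half maximum (Hz).
#' @param spectrometer_freq_MHz Proton frequency, to convert Hz to ppm.
#' @return Mass fraction in (0, 1).
#' @export
lorentzian_region_fraction <- function(half_width_ppm, linewidth_hz,
                                       spectrometer_freq_MHz = 400.13) {
  hw <- (linewidth_hz / 2) / spectrometer_freq_MHz
  (2 / pi) * atan(half_width_ppm / hw)
}

#' Convert a frequency-domain spectrum to its matching FID
#'
#' Inverse discrete Fourier transform of the complex spectrum, the exact
#' inverse of [fourier_transform()] at zero-fill factor 1. Used by the
#' simulator's FID path so that processing a simulated FID reproduces the
#' directly simulated spectrum bit-for-bit.
#'
#' @param spec A complex `nmr_spectrum` (dispersion part present).
#' @return An `nmr_fid`.
#' @export
fid_from_spectrum <- function(spec) {
  if (is.null(spec$imag))
    stop("fid_from_spectrum() needs a complex spectrum (imag part present)")
  n <- length(spec$ppm)
  if (!is_power_of_two(n)) stop("spectrum length must be a power of two")
  s_desc <- complex(real = spec$real, imaginary = spec$imag)
  s_asc <- rev(s_desc)                       # ascending frequency
  s_std <- c(s_asc[(n / 2 + 1):n], s_asc[1:(n / 2)])   # undo fftshift
  x <- stats::fft(s_std, inverse = TRUE) / n
  meta <- spec$meta
  meta$n_points <- n
  new_fid(meta, x, source = "fid_from_spectrum")
}

#' Simulate a calibration measurement set
#'
#' One spectrum per (sample, replicate), each sample a (concentration, NS, RG)
#' condition, plus a ground-truth manifest. Reproducible: per-spectrum seeds
#' are derived from `seed` so a fixed seed yields bitwise-identical output.
#'
#' @param samples `data.frame` with columns `sample_id`, `concentration_mM`,
#'   `ns`, `rg` (one row per measurement condition).
#' @param signals List of [signal_spec()] objects (nonempty).
#' @param gain A [gain_model()] or `NULL` for an ideal amplifier.
#' @param ig_true True intensity-gain factor.
#' @param noise_sigma Per-point noise std (receiver units); see [sim_config()].
#' @param seed Integer master seed.
#' @param replicates Replicate spectra per condition (the reference study used
#'   duplicates).
#' @param sweep_ppm,n_points,center_ppm,spectrometer_freq_MHz Spectral grid.
#' @return `list(spectra = named list of nmr_spectrum, manifest = data.frame)`
#'   with manifest columns `sample_id`, `replicate`, `concentration_mM`, `ns`,
#'   `rg`, `g_of_rg`, `seed`.
#' @export
simulate_calibration_set <- function(samples, signals, gain = NULL,
                                     ig_true = 1650, noise_sigma = 0,
                                     seed = 1L, replicates = 2L,
                                     sweep_ppm = 14, n_points = 16384L,
                                     center_ppm = 5,
                                     spectrometer_freq_MHz = 400.13) {
  stopifnot(is.data.frame(samples),
            all(c("sample_id", "concentration_mM", "ns", "rg") %in% names(samples)))
  if (!nrow(samples)) stop("sample list is empty")
  if (inherits(signals, "signal_spec")) signals <- list(signals)
  if (!length(signals)) stop("signal list is empty")
  spectra <- list()
  rows <- list()
  idx <- 0L
  for (i in seq_len(nrow(samples))) {
    for (rep_k in seq_len(replicates)) {
      idx <- idx + 1L
      sp_seed <- (as.integer(seed) + 7919L * idx) %% .Machine$integer.max
      cfg <- sim_config(ig_true = ig_true, ns = samples$ns[i],
                        rg = samples$rg[i],
                        concentration_mM = samples$concentration_mM[i],
                        noise_sigma = noise_sigma, sweep_ppm = sweep_ppm,
                        n_points = n_points, center_ppm = center_ppm,
                        spectrometer_freq_MHz = spectrometer_freq_MHz,
                        seed = sp_seed)
      key <- sprintf("%s_r%d", samples$sample_id[i], rep_k)
      spectra[[key]] <- simulate_spectrum(signals, cfg, gain)
      rows[[idx]] <- data.frame(
        sample_id = as.character(samples$sample_id[i]), replicate = rep_k,
        concentration_mM = samples$concentration_mM[i],
        ns = as.integer(samples$ns[i]), rg = samples$rg[i],
        g_of_rg = g_of_rg(gain, samples$rg[i]), seed = sp_seed,
        stringsAsFactors = FALSE)
    }
  }
  list(spectra = spectra, manifest = do.call(rbind, rows))
}

#' Noise level giving a target minimum signal-to-noise ratio
#'
#' Chooses the per-point noise std so that the weakest peak in a simulated
#' condition set reaches `min_snr` (peak height over twice the noise std),
#' the regime reported for well-designed quantitative acquisitions
#' (all signals above 200:1).
#'
#' @param signals List of [signal_spec()] objects.
#' @param samples Condition `data.frame` as in [simulate_calibration_set()].
#' @param gain A [gain_model()] or `NULL`.
#' @param ig_true Intensity-gain factor.
#' @param min_snr Target SNR for the weakest signal (default 200).
#' @param spectrometer_freq_MHz Proton frequency.
#' @return Noise std per point, in receiver units.
#' @export
noise_sigma_for_snr <- function(signals, samples, gain = NULL, ig_true = 1650,
                                min_snr = 200, spectrometer_freq_MHz = 400.13) {
  if (inherits(signals, "signal_spec")) signals <- list(signals)
  worst <- Inf
  for (i in seq_len(nrow(samples))) {
    g <- g_of_rg(gain, samples$rg[i])
    for (s in signals) {
      hw <- (s$linewidth_hz / 2) / spectrometer_freq_MHz
      peak <- ig_true * samples$ns[i] * g * s$n_protons *
        samples$concentration_mM[i] * min(s$multiplet[, 2]) / (pi * hw)
      # realized noise std is noise_sigma * g * sqrt(ns); SNR = peak/(2 sd)
      worst <- min(worst, peak / (g * sqrt(samples$ns[i])))
    }
  }
  worst / (2 * min_snr)
}
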