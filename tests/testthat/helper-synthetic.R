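# Shared builders for synthetic test inputs. Regions are wide relative to the
# linewidth (half-width 0.5 ppm vs ~1 Hz FWHM) so Lorentzian tail truncation
# stays below 0.2% of the analytic mass.

three_signals <- function() {
  list(signal_spec(7.5, linewidth_hz = 1.2, n_protons = 1, label = "a"),
       signal_spec(4.0, linewidth_hz = 1.0, n_protons = 3, label = "b"),
       signal_spec(1.8, linewidth_hz = 1.5, n_protons = 2, label = "c"))
}

three_regions <- function(half_width = 0.5) {
  integration_regions(c("a", "b", "c"),
                      ppm_high = c(7.5, 4.0, 1.8) + half_width,
                      ppm_low = c(7.5, 4.0, 1.8) - half_width,
                      n_protons = c(1, 3, 2))
}

# expected region integral for a centered singlet, truncation-aware
model_integral <- function(ig, ns, g, n_h, conc, half_width_ppm, linewidth_hz,
                           sfo1 = 400.13) {
  ig * ns * g * n_h * conc *
    lorentzian_region_fraction(half_width_ppm, linewidth_hz, sfo1)
}

# the study condition grids are package API (calibration_conditions(),
# gravimetric_conditions()); tests use them directly

# samples table (sample_id -> known concentration) for calibrate_ig()
known_samples <- function(conditions) {
  unique(data.frame(sample_id = conditions$sample_id,
                    known_concentration_mM = conditions$concentration_mM,
                    stringsAsFactors = FALSE))
}

table2_conditions <- function(max_settings = 4L) {
  gravimetric_conditions(max_settings)
}
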