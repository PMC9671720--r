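#' Acquisition metadata for a 1D NMR experiment
#'
#' Bundles the acquisition parameters that matter for absolute-intensity
#' quantification: the number of co-added scans (NS), the receiver gain (RG),
#' the inter-scan delay (D1), temperature, spectral width, number of complex
#' observe points and the spectrometer proton frequency.
#'
#' @param ns Number of scans (integer, >= 1). Signal adds linearly in NS.
#' @param rg Receiver gain in instrument units (> 0).
#' @param d1_s Inter-scan delay in seconds (>= 0). For quantitative work it
#'   must be several times the longest longitudinal relaxation time T1.
#' @param temperature_K Sample temperature in kelvin.
#' @param sweep_ppm Spectral width in ppm.
#' @param n_points Number of complex observe points (>= 2).
#' @param spectrometer_freq_MHz Proton carrier frequency in MHz.
#' @param center_ppm Chemical shift at the center of the spectral window.
#' @return An object of class `acq_meta`.
#' @export
acq_meta <- function(ns, rg, d1_s = 0, temperature_K = 298.15,
                     sweep_ppm = 14, n_points = 16384L,
                     spectrometer_freq_MHz = 400.13, center_ppm = 5) {
  ns <- as.integer(ns)
  n_points <- as.integer(n_points)
  stopifnot(
    "ns must be >= 1" = length(ns) == 1 && !is.na(ns) && ns >= 1L,
    "rg must be > 0" = length(rg) == 1 && is.finite(rg) && rg > 0,
    "d1_s must be >= 0" = length(d1_s) == 1 && is.finite(d1_s) && d1_s >= 0,
    "n_points must be >= 2" = n_points >= 2L,
    "sweep_ppm must be > 0" = sweep_ppm > 0,
    "spectrometer_freq_MHz must be > 0" = spectrometer_freq_MHz > 0
  )
  structure(
    list(ns = ns, rg = as.numeric(rg), d1_s = as.numeric(d1_s),
         temperature_K = as.numeric(temperature_K),
         sweep_ppm = as.numeric(sweep_ppm), n_points = n_points,
         spectrometer_freq_MHz = as.numeric(spectrometer_freq_MHz),
         center_ppm = as.numeric(center_ppm)),
    class = "acq_meta"
  )
}

#' @export
print.acq_meta <- function(x, ...) {
  cat(sprintf(
    "<acq_meta> NS=%d RG=%g D1=%gs T=%gK SW=%g ppm TD=%d SFO1=%g MHz O1P=%g\n",
    x$ns, x$rg, x$d1_s, x$temperature_K, x$sweep_ppm, x$n_points,
    x$spectrometer_freq_MHz, x$center_ppm))
  invisible(x)
}

#' Free induction decay (time-domain signal)
#'
#' @param meta An [acq_meta()] object.
#' @param data Complex vector of length `meta$n_points`.
#' @param source Provenance string (file path or simulator tag).
#' @return An object of class `nmr_fid`.
#' @export
new_fid <- function(meta, data, source = "in-memory") {
  stopifnot(inherits(meta, "acq_meta"),
            "fid length must equal n_points" = length(data) == meta$n_points)
  structure(list(meta = meta, data = as.complex(data), source = source),
            class = "nmr_fid")
}

#' @export
print.nmr_fid <- function(x, ...) {
  cat(sprintf("<nmr_fid> %d complex points, source: %s\n",
              length(x$data), x$source))
  print(x$meta)
  invisible(x)
}

#' Frequency-domain NMR spectrum
#'
#' The ppm axis is stored high-to-low (left to right), the NMR display
#' convention. `real` holds the absorption-mode intensities; `imag` (the
#' dispersion part) is kept while the spectrum is still complex, i.e. before
#' or during phase correction, and may be `NULL` afterwards.
#'
#' @param meta An [acq_meta()] object describing the acquisition.
#' @param ppm Strictly decreasing chemical-shift axis.
#' @param real Real (absorption) intensities, same length as `ppm`.
#' @param imag Optional imaginary (dispersion) intensities.
#' @param provenance Character vector of processing steps applied, in order.
#' @return An object of class `nmr_spectrum`.
#' @export
new_spectrum <- function(meta, ppm, real, imag = NULL,
                         provenance = character()) {
  stopifnot(inherits(meta, "acq_meta"),
            "ppm and real must have equal length" = length(ppm) == length(real),
            "ppm must be strictly decreasing" = all(diff(ppm) < 0))
  if (!is.null(imag))
    stopifnot("imag length mismatch" = length(imag) == length(real))
  structure(list(meta = meta, ppm = as.numeric(ppm), real = as.numeric(real),
                 imag = if (is.null(imag)) NULL else as.numeric(imag),
                 provenance = as.character(provenance)),
            class = "nmr_spectrum")
}

#' @export
print.nmr_spectrum <- function(x, ...) {
  cat(sprintf("<nmr_spectrum> %d points, %.3f .. %.3f ppm%s\n",
              length(x$ppm), x$ppm[1], x$ppm[length(x$ppm)],
              if (is.null(x$imag)) " (real)" else " (complex)"))
  if (length(x$provenance))
    cat("  provenance:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

# Shared frequency grid: bin k of the shifted DFT maps to
# center + (n/2 - k) * sweep / n for k = 1..n, giving a strictly
# decreasing axis spanning (center + sw/2 - sw/n) .. (center - sw/2).
ppm_axis <- function(center_ppm, sweep_ppm, n) {
  center_ppm + (n / 2 - seq_len(n)) * sweep_ppm / n
}

is_power_of_two <- function(n) {
  n >= 1 && bitwAnd(as.integer(n), as.integer(n) - 1L) == 0L
}

append_provenance <- function(spec, step) {
  spec$provenance <- c(spec$provenance, step)
  spec
}
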