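#' Integration regions
#'
#' A region set names each signal, bounds it by a ppm interval and records the
#' proton count contributing to it. Regions are defined once, on a reference
#' experiment, and applied unchanged to every spectrum of a quantification
#' set.
#'
#' @param label Unique signal names.
#' @param ppm_high,ppm_low Region bounds, `ppm_high > ppm_low`.
#' @param n_protons Proton counts (>= 1).
#' @return A `data.frame` of class `integration_regions`.
#' @export
integration_regions <- function(label, ppm_high, ppm_low, n_protons) {
  stopifnot("ppm_high must exceed ppm_low" = all(ppm_high > ppm_low),
            "n_protons must be >= 1" = all(n_protons >= 1),
            "labels must be unique" = !anyDuplicated(label))
  structure(data.frame(label = as.character(label),
                       ppm_high = as.numeric(ppm_high),
                       ppm_low = as.numeric(ppm_low),
                       n_protons = as.integer(n_protons),
                       stringsAsFactors = FALSE),
            class = c("integration_regions", "data.frame"))
}

#' Read / write an integration-region CSV
#'
#' Plain CSV with columns `label`, `ppm_high`, `ppm_low`, `n_protons`;
#' round-trips losslessly.
#'
#' @param path CSV file path.
#' @param regions An [integration_regions()] set.
#' @return `read_regions()` returns the region set; `write_regions()` returns
#'   `path` invisibly.
#' @export
read_regions <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "ppm_high", "ppm_low", "n_protons")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("region file is missing column(s): ", paste(missing_cols, collapse = ", "))
  integration_regions(df$label, df$ppm_high, df$ppm_low, df$n_protons)
}

#' @rdname read_regions
#' @export
write_regions <- function(regions, path) {
  write_csv_full(as.data.frame(regions)[, c("label", "ppm_high", "ppm_low",
                                            "n_protons")], path)
  invisible(path)
}

default_noise_region <- function(spec) {
  # rightmost 5% of the axis, keeping 1% clear of the window edge
  lo <- min(spec$ppm)
  sw <- spec$meta$sweep_ppm
  c(lo + 0.06 * sw, lo + 0.01 * sw)
}

#' Integrate named ppm regions of a spectrum
#'
#' Absolute trapezoidal integrals in intensity-ppm units over each region.
#' Grid points are assigned with a half-open rule: a point exactly on
#' `ppm_low` belongs to the region, one exactly on `ppm_high` does not, so
#' adjacent regions never double-count a point. The signal-to-noise ratio is
#' the maximum intensity in the region divided by twice the standard deviation
#' of a signal-free noise region. Overlapping regions are allowed but warned
#' about.
#'
#' @param spec A real (phased, baseline-corrected) `nmr_spectrum`.
#' @param regions An [integration_regions()] set, all within the ppm axis.
#' @param noise_region `c(ppm_high, ppm_low)` of a signal-free stretch used
#'   for the noise estimate; default the rightmost few percent of the axis.
#' @param sample_id Optional sample identifier copied into the result.
#' @return `data.frame` with columns `sample_id`, `label`, `intensity`, `snr`,
#'   `ns`, `rg` (one row per region).
#' @export
integrate_regions <- function(spec, regions, noise_region = NULL,
                              sample_id = NA_character_) {
  stopifnot(inherits(spec, "nmr_spectrum"),
            inherits(regions, "integration_regions"))
  ppm <- spec$ppm
  hi_ax <- max(ppm); lo_ax <- min(ppm)
  bad <- regions$ppm_high > hi_ax | regions$ppm_low < lo_ax
  if (any(bad))
    stop("region(s) outside the spectrum axis [", sprintf("%.4f, %.4f", lo_ax, hi_ax),
         "] ppm: ", paste(regions$label[bad], collapse = ", "))
  # overlap warning (regions may legitimately touch at a shared bound)
  o <- order(regions$ppm_low)
  rl <- regions[o, ]
  if (nrow(rl) > 1) {
    ov <- rl$ppm_high[-nrow(rl)] > rl$ppm_low[-1]
    if (any(ov))
      warning("overlapping integration regions: ",
              paste(sprintf("%s/%s", rl$label[-nrow(rl)][ov], rl$label[-1][ov]),
                    collapse = ", "), call. = FALSE)
  }
  if (is.null(noise_region)) noise_region <- default_noise_region(spec)
  noise_idx <- ppm >= min(noise_region) & ppm < max(noise_region)
  noise_sd <- if (sum(noise_idx) > 1) stats::sd(spec$real[noise_idx]) else 0

  out <- lapply(seq_len(nrow(regions)), function(i) {
    idx <- ppm >= regions$ppm_low[i] & ppm < regions$ppm_high[i]
    xi <- rev(ppm[idx]); yi <- rev(spec$real[idx])   # ascending for quadrature
    intensity <- if (length(xi) > 1) pracma::trapz(xi, yi) else 0
    peak <- if (any(idx)) max(spec$real[idx]) else 0
    snr <- if (peak <= 0) 0 else if (noise_sd == 0) Inf else peak / (2 * noise_sd)
    data.frame(sample_id = sample_id, label = regions$label[i],
               intensity = intensity, snr = snr,
               ns = spec$meta$ns, rg = spec$meta$rg, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Integrate a set of spectra against one region set
#'
#' Applies [integrate_regions()] to each spectrum of a measurement set (for
#' example [simulate_calibration_set()] output), tagging rows with the
#' manifest's sample identifiers.
#'
#' @param spectra Named list of `nmr_spectrum` objects.
#' @param regions An [integration_regions()] set.
#' @param manifest Optional manifest `data.frame` whose rows parallel
#'   `spectra`; its `sample_id` is used for tagging. Defaults to the list
#'   names.
#' @param noise_region See [integrate_regions()].
#' @return Row-bound integral `data.frame`.
#' @export
integrate_set <- function(spectra, regions, manifest = NULL,
                          noise_region = NULL) {
  ids <- if (!is.null(manifest)) manifest$sample_id else names(spectra)
  do.call(rbind, lapply(seq_along(spectra), function(i) {
    integrate_regions(spectra[[i]], regions, noise_region = noise_region,
                      sample_id = ids[[i]])
  }))
}

#' Warn about signals below a signal-to-noise threshold
#'
#' Quantified signals should stay above roughly 200:1; weaker signals carry
#' integration noise straight into the concentration estimate.
#'
#' @param integrals Output of [integrate_regions()].
#' @param threshold Minimum acceptable SNR (> 0), default 200.
#' @return Character vector of warning messages (also signalled), invisibly.
#' @export
check_snr <- function(integrals, threshold = 200) {
  if (!is.finite(threshold) || threshold <= 0)
    stop("threshold must be > 0, got ", threshold)
  low <- integrals$snr < threshold
  msgs <- sprintf("signal '%s' has SNR %.1f, below the %g threshold",
                  integrals$label[low], integrals$snr[low], threshold)
  for (msg in msgs) warning(msg, call. = FALSE)
  invisible(msgs)
}
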