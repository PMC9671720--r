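#' Measurement conditions of the reference calibration study
#'
#' Two condition grids over the five gravimetric quinine concentrations
#' (5.29, 29.44, 48.19, 77.78 and 108.35 mM):
#'
#' * `calibration_conditions()` — every concentration measured under the same
#'   four (NS, RG) settings spanning 2–64 scans and receiver gains 25.4–90.5,
#'   the balanced grid used for intensity-gain calibration checks.
#' * `gravimetric_conditions()` — per-sample RG availability as on the
#'   instrument: concentrated samples saturate the receiver earlier, so each
#'   sample only reaches the highest non-clipping RG recorded for it (161,
#'   90.5, 90.5, 40.3 and 36 respectively), sliced evenly from the instrument
#'   RG ladder. This asymmetry is what turns an uncorrected gain nonlinearity
#'   into a concentration-dependent bias (a regression slope away from 1).
#'
#' @param max_settings Maximum number of (NS, RG) settings per sample in
#'   `gravimetric_conditions()`.
#' @return `data.frame` with columns `sample_id` (one per condition),
#'   `sample`, `concentration_mM`, `ns`, `rg`.
#' @export
calibration_conditions <- function() {
  tab <- quinine_samples()
  settings <- data.frame(ns = c(2L, 8L, 32L, 64L),
                         rg = c(25.4, 36, 57, 90.5))
  do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
    data.frame(sample_id = sprintf("s%d_ns%d_rg%g", i, settings$ns,
                                   settings$rg),
               sample = sprintf("s%d", i),
               concentration_mM = tab$rc_mM[i],
               ns = settings$ns, rg = settings$rg,
               stringsAsFactors = FALSE)
  }))
}

#' @rdname calibration_conditions
#' @export
gravimetric_conditions <- function(max_settings = 4L) {
  tab <- quinine_samples()
  ladder <- rg_table_printed()$rg_original
  ns_cycle <- c(2L, 8L, 32L, 64L)
  do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
    avail <- ladder[ladder <= tab$highest_rg[i]]
    idx <- unique(round(seq(1, length(avail),
                            length.out = min(max_settings, length(avail)))))
    data.frame(sample_id = sprintf("s%d_c%d", i, seq_along(idx)),
               sample = sprintf("s%d", i),
               concentration_mM = tab$rc_mM[i],
               ns = ns_cycle[seq_along(idx)],
               rg = avail[idx], stringsAsFactors = FALSE)
  }))
}
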