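#' Read a Bruker-style 1D dataset directory
#'
#' Reads the subset of the Bruker directory dialect needed for
#' absolute-intensity quantification: a plain-text acquisition-parameter file
#' `acqus` with JCAMP-style `##$KEY= value` lines, and a binary `fid` with
#' interleaved real/imaginary samples. Required parameter keys are `NS`, `RG`,
#' `D1`, `TE` (temperature, K), `SW` (ppm), `TD` (total real+imaginary
#' points), `SFO1` (MHz); `O1P` (carrier, ppm), `BYTORDA` (0 little-endian,
#' 1 big-endian) and `DTYPA` (0 int32, 2 float64) are honored when present
#' and default to 5 ppm, little-endian int32 otherwise. `TD` counts real and
#' imaginary values, so the FID holds `TD/2` complex points.
#'
#' A missing required key is an error listing every absent key; a truncated
#' binary is an error reporting expected versus found lengths. `NS` and `RG`
#' are never silently defaulted.
#'
#' @param path Directory containing `acqus` and `fid`.
#' @return An `nmr_fid`.
#' @seealso [write_bruker_dir()] to generate fixture directories.
#' @export
read_bruker_dir <- function(path) {
  if (!dir.exists(path)) stop("Bruker dataset directory not found: ", path)
  acqus <- file.path(path, "acqus")
  fid_file <- file.path(path, "fid")
  if (!file.exists(acqus)) stop("missing acquisition-parameter file: ", acqus)
  if (!file.exists(fid_file)) stop("missing binary fid: ", fid_file)

  lines <- readLines(acqus, warn = FALSE)
  m <- regmatches(lines, regexec("^##\\$([A-Za-z0-9]+)=\\s*(.*)$", lines))
  keys <- vapply(m, function(x) if (length(x) == 3) x[2] else NA_character_, "")
  values <- vapply(m, function(x) if (length(x) == 3) x[3] else NA_character_, "")
  params <- stats::setNames(values[!is.na(keys)], keys[!is.na(keys)])

  required <- c("NS", "RG", "D1", "TE", "SW", "TD", "SFO1")
  missing_keys <- setdiff(required, names(params))
  if (length(missing_keys))
    stop("acqus is missing required parameter key(s): ",
         paste(missing_keys, collapse = ", "))

  p <- function(key, default = NULL) {
    if (key %in% names(params)) as.numeric(params[[key]]) else default
  }
  td <- as.integer(p("TD"))
  if (td %% 2L != 0L) stop("TD must be even (interleaved real/imaginary): ", td)
  meta <- acq_meta(
    ns = as.integer(p("NS")), rg = p("RG"), d1_s = p("D1"),
    temperature_K = p("TE"), sweep_ppm = p("SW"), n_points = td %/% 2L,
    spectrometer_freq_MHz = p("SFO1"), center_ppm = p("O1P", default = 5))

  endian <- if (isTRUE(p("BYTORDA", 0) == 1)) "big" else "little"
  dtypa <- p("DTYPA", 0)
  if (!dtypa %in% c(0, 2))
    stop("unsupported DTYPA (expected 0 = int32 or 2 = float64): ", dtypa)
  size <- if (dtypa == 2) 8L else 4L
  what <- if (dtypa == 2) "numeric" else "integer"

  con <- file(fid_file, "rb")
  on.exit(close(con))
  raw_vals <- readBin(con, what = what, n = td + 1L, size = size,
                      endian = endian)
  if (length(raw_vals) != td)
    stop(sprintf("truncated fid binary: expected %d values, found %d",
                 td, length(raw_vals)))
  re <- raw_vals[seq(1L, td, by = 2L)]
  im <- raw_vals[seq(2L, td, by = 2L)]
  new_fid(meta, complex(real = re, imaginary = im),
          source = normalizePath(path))
}

#' Write a Bruker-style 1D dataset directory
#'
#' Emits the same dialect [read_bruker_dir()] consumes. Mainly used to build
#' test fixtures and to export simulated FIDs. With `dtypa = 0` (the classic
#' int32 encoding) data are rounded to integers, so round-trips are only exact
#' for integer-valued FIDs; `dtypa = 2` stores float64 losslessly.
#'
#' @param fid An `nmr_fid`.
#' @param path Output directory (created if needed).
#' @param bytorda 0 for little-endian, 1 for big-endian.
#' @param dtypa 0 for int32, 2 for float64.
#' @return `path`, invisibly.
#' @export
write_bruker_dir <- function(fid, path, bytorda = 0, dtypa = 2) {
  stopifnot(inherits(fid, "nmr_fid"), bytorda %in% c(0, 1), dtypa %in% c(0, 2))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- fid$meta
  writeLines(c(
    "##TITLE= acquisition parameters",
    "##JCAMPDX= 5.0",
    paste0("##$NS= ", meta$ns),
    paste0("##$RG= ", num_str(meta$rg)),
    paste0("##$D1= ", num_str(meta$d1_s)),
    paste0("##$TE= ", num_str(meta$temperature_K)),
    paste0("##$SW= ", num_str(meta$sweep_ppm)),
    paste0("##$TD= ", 2L * meta$n_points),
    paste0("##$SFO1= ", num_str(meta$spectrometer_freq_MHz)),
    paste0("##$O1P= ", num_str(meta$center_ppm)),
    paste0("##$BYTORDA= ", bytorda),
    paste0("##$DTYPA= ", dtypa),
    "##END="
  ), file.path(path, "acqus"))
  interleaved <- as.numeric(rbind(Re(fid$data), Im(fid$data)))
  con <- file(file.path(path, "fid"), "wb")
  on.exit(close(con))
  endian <- if (bytorda == 1) "big" else "little"
  if (dtypa == 2) {
    writeBin(interleaved, con, size = 8L, endian = endian)
  } else {
    writeBin(as.integer(round(interleaved)), con, size = 4L, endian = endian)
  }
  invisible(path)
}

#' Check acquisition metadata for quantitative suitability
#'
#' Returns (and signals) warnings for conditions that bias absolute-intensity
#' quantification: an inter-scan delay shorter than five times the longest T1
#' (incomplete longitudinal relaxation attenuates integrals), and temperature
#' differing across a set of experiments (it shifts signal positions and
#' intensities, so varying it within one quantification set is not
#' recommended). NS and RG may vary freely: the intensity model normalizes
#' them out.
#'
#' @param meta An `acq_meta` or a list of them (a measurement set).
#' @param t1_max_s Longest longitudinal relaxation time T1 of the analyte, in
#'   seconds (> 0).
#' @param temperature_tol_K Tolerance for temperature agreement across a set.
#' @return Character vector of warning messages (empty when all checks pass),
#'   invisibly. Each message is also signalled via [warning()].
#' @export
validate_for_quantification <- function(meta, t1_max_s,
                                        temperature_tol_K = 0.5) {
  stopifnot("t1_max_s must be > 0" = is.finite(t1_max_s) && t1_max_s > 0)
  metas <- if (inherits(meta, "acq_meta")) list(meta) else meta
  stopifnot(all(vapply(metas, inherits, TRUE, "acq_meta")))
  msgs <- character()
  for (m in metas) {
    if (m$d1_s < 5 * t1_max_s)
      msgs <- c(msgs, sprintf(
        "inter-scan delay D1 = %g s is below 5 x T1max = %g s: incomplete relaxation will bias integrals",
        m$d1_s, 5 * t1_max_s))
  }
  temps <- vapply(metas, `[[`, 0, "temperature_K")
  if (length(temps) > 1 && diff(range(temps)) > temperature_tol_K)
    msgs <- c(msgs, sprintf(
      "temperature varies across the set (%g .. %g K): not recommended for one quantification set",
      min(temps), max(temps)))
  for (msg in msgs) warning(msg, call. = FALSE)
  invisible(msgs)
}
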