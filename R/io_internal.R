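#' Internal spectrum/FID file format
#'
#' A lossless two-file pair: `<path>` is a plain-text header (key: value
#' lines, `provenance:` entries repeated) and `<path>.bin` holds the numeric
#' arrays as little-endian float64. FIDs store the interleaved real/imaginary
#' time-domain samples; spectra store the ppm axis, the real part and (if
#' present) the imaginary part. The header carries an explicit format version;
#' reading a file with a different version is an error.
#'
#' @param obj An `nmr_fid` or `nmr_spectrum`.
#' @param path Header file path (the binary companion gets `.bin` appended).
#' @return `write_internal()` returns `path` invisibly; `read_internal()`
#'   returns the stored `nmr_fid` or `nmr_spectrum`.
#' @export
write_internal <- function(obj, path) {
  meta <- obj$meta
  hdr <- c(
    paste0("format: ", .fnmr_version),
    paste0("kind: ", if (inherits(obj, "nmr_fid")) "fid" else "spectrum"),
    paste0("ns: ", meta$ns),
    paste0("rg: ", num_str(meta$rg)),
    paste0("d1_s: ", num_str(meta$d1_s)),
    paste0("temperature_K: ", num_str(meta$temperature_K)),
    paste0("sweep_ppm: ", num_str(meta$sweep_ppm)),
    paste0("n_points: ", meta$n_points),
    paste0("spectrometer_freq_MHz: ", num_str(meta$spectrometer_freq_MHz)),
    paste0("center_ppm: ", num_str(meta$center_ppm))
  )
  if (inherits(obj, "nmr_fid")) {
    hdr <- c(hdr, paste0("source: ", obj$source),
             paste0("n_values: ", 2L * length(obj$data)))
    values <- as.numeric(rbind(Re(obj$data), Im(obj$data)))
  } else if (inherits(obj, "nmr_spectrum")) {
    n <- length(obj$ppm)
    hdr <- c(hdr,
             paste0("n_spectrum: ", n),
             paste0("has_imag: ", as.integer(!is.null(obj$imag))),
             paste0("n_values: ", n * (2L + !is.null(obj$imag))))
    if (length(obj$provenance))   # paste0 maps character(0) to "", keep it out
      hdr <- c(hdr, paste0("provenance: ", obj$provenance))
    values <- c(obj$ppm, obj$real, obj$imag)
  } else {
    stop("write_internal() handles nmr_fid and nmr_spectrum objects only")
  }
  writeLines(hdr, path)
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con))
  writeBin(values, con, size = 8L, endian = "little")
  invisible(path)
}

.fnmr_version <- "fnmr-1"

# shortest decimal string that parses back to the identical double
num_str <- function(x) {
  vapply(x, function(v) {
    if (!is.finite(v)) return(as.character(v))
    for (d in c(15L, 16L, 17L)) {
      s <- trimws(formatC(v, digits = d, format = "g"))
      if (as.numeric(s) == v) return(s)
    }
    s
  }, character(1))
}

#' @rdname write_internal
#' @export
read_internal <- function(path) {
  if (!file.exists(path)) stop("internal-format header not found: ", path)
  lines <- readLines(path)
  kv <- regmatches(lines, regexpr("^[^:]+", lines))
  vals <- sub("^[^:]+:\\s?", "", lines)
  get1 <- function(key) {
    i <- which(kv == key)
    if (!length(i)) stop("internal-format header missing key: ", key)
    vals[i[1]]
  }
  ver <- get1("format")
  if (!identical(ver, .fnmr_version))
    stop(sprintf("internal-format version mismatch: file has '%s', reader supports '%s'",
                 ver, .fnmr_version))
  meta <- acq_meta(
    ns = as.integer(get1("ns")), rg = as.numeric(get1("rg")),
    d1_s = as.numeric(get1("d1_s")),
    temperature_K = as.numeric(get1("temperature_K")),
    sweep_ppm = as.numeric(get1("sweep_ppm")),
    n_points = as.integer(get1("n_points")),
    spectrometer_freq_MHz = as.numeric(get1("spectrometer_freq_MHz")),
    center_ppm = as.numeric(get1("center_ppm")))
  n_values <- as.integer(get1("n_values"))
  bin <- paste0(path, ".bin")
  if (!file.exists(bin)) stop("internal-format binary not found: ", bin)
  con <- file(bin, "rb")
  on.exit(close(con))
  values <- readBin(con, what = "numeric", n = n_values + 1L, size = 8L,
                    endian = "little")
  if (length(values) != n_values)
    stop(sprintf("internal-format binary length mismatch: expected %d values, found %d",
                 n_values, length(values)))
  kind <- get1("kind")
  if (kind == "fid") {
    re <- values[seq(1L, n_values, by = 2L)]
    im <- values[seq(2L, n_values, by = 2L)]
    new_fid(meta, complex(real = re, imaginary = im), source = get1("source"))
  } else if (kind == "spectrum") {
    n <- as.integer(get1("n_spectrum"))
    has_imag <- as.integer(get1("has_imag")) == 1L
    prov <- vals[kv == "provenance"]
    new_spectrum(meta,
                 ppm = values[seq_len(n)],
                 real = values[n + seq_len(n)],
                 imag = if (has_imag) values[2L * n + seq_len(n)],
                 provenance = prov)
  } else {
    stop("unknown internal-format kind: ", kind)
  }
}
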