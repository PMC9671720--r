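#' Sample description for quantification
#'
#' A calibration or analysis sample is described either by a known
#' concentration or by the gravimetric route: analyte weight, molecular
#' weight and solvent volume, from which [weight_to_concentration()] derives
#' the concentration.
#'
#' @param sample_id Identifier.
#' @param weight_mg Analyte weight (mg), gravimetric route.
#' @param molecular_weight Molecular weight (g/mol).
#' @param volume_ml Solvent volume (ml).
#' @param known_concentration_mM Concentration (mM) if known directly.
#' @return A one-row `data.frame` with columns `sample_id`, `weight_mg`,
#'   `molecular_weight`, `volume_ml`, `known_concentration_mM`.
#' @export
sample_info <- function(sample_id, weight_mg = NA, molecular_weight = NA,
                        volume_ml = NA, known_concentration_mM = NA) {
  if (is.na(known_concentration_mM)) {
    known_concentration_mM <-
      weight_to_concentration(weight_mg, molecular_weight, volume_ml)
  }
  data.frame(sample_id = as.character(sample_id),
             weight_mg = as.numeric(weight_mg),
             molecular_weight = as.numeric(molecular_weight),
             volume_ml = as.numeric(volume_ml),
             known_concentration_mM = as.numeric(known_concentration_mM),
             stringsAsFactors = FALSE)
}

#' Concentration from weight, molecular weight and volume
#'
#' `c [mM] = (weight_mg / molecular_weight) / volume_ml * 1000`:
#' milligrams over g/mol gives millimoles; dividing by the volume in ml and
#' scaling by 1000 gives millimoles per litre.
#'
#' @param weight_mg Analyte weight (mg, > 0). Vectorized.
#' @param molecular_weight Molecular weight (g/mol, > 0).
#' @param volume_ml Solvent volume (ml, > 0).
#' @return Concentration in mM.
#' @examples
#' weight_to_concentration(1.03, 324.42, 0.6)   # 5.29 mM of quinine
#' @export
weight_to_concentration <- function(weight_mg, molecular_weight, volume_ml) {
  for (nm in c("weight_mg", "molecular_weight", "volume_ml")) {
    v <- get(nm)
    if (any(!is.finite(v) | v <= 0))
      stop(nm, " must be > 0")
  }
  (weight_mg / molecular_weight) / volume_ml * 1000
}

#' Normalized intensity increment
#'
#' The absolute signal intensity divided by the number of scans, the receiver
#' gain, the concentration and the proton count:
#' `I / (ns * rg * concentration_mM * n_protons)`. For an ideal instrument
#' this is a constant — the intensity-gain (IG) factor — independent of the
#' acquisition settings, which is what makes reference-free quantification
#' possible.
#'
#' @param intensity Absolute signal integral `I` (instrument units, > 0).
#' @param ns Number of scans (> 0).
#' @param rg Receiver gain (> 0).
#' @param concentration_mM Concentration (mM, > 0).
#' @param n_protons Proton count (> 0).
#' @return The normalized increment. Vectorized.
#' @export
normalized_increment <- function(intensity, ns, rg, concentration_mM,
                                 n_protons) {
  for (nm in c("intensity", "ns", "rg", "concentration_mM", "n_protons")) {
    v <- get(nm)
    if (any(!is.finite(v) | v <= 0))
      stop("normalized_increment(): ", nm, " must be > 0")
  }
  intensity / (ns * rg * concentration_mM * n_protons)
}

#' Calibrate the intensity-gain (IG) factor
#'
#' Normalizes every observed integral of the calibration samples by scans,
#' receiver gain, concentration and proton count, and takes the central value
#' of the pooled increments as the IG factor. The per-observation increments
#' and their dispersion are retained: the receiver-gain linearization is
#' estimated from their structure across RG steps, and the scatter is the
#' first diagnostic of calibration quality.
#'
#' @param integrals Integral `data.frame` ([integrate_regions()] /
#'   [integrate_set()] output) with columns `sample_id`, `label`, `intensity`,
#'   `ns`, `rg`.
#' @param samples `data.frame` with `sample_id` and `known_concentration_mM`
#'   (e.g. built from [sample_info()] rows).
#' @param regions [integration_regions()] supplying proton counts per label.
#' @param center `"mean"` (default; the increments scatter around an average)
#'   or `"median"` for a robust variant.
#' @return An object of class `ig_calibration`: list with `ig`, `center`,
#'   `observations` (label, sample_id, ns, rg, concentration_mM, n_protons,
#'   increment) and `dispersion`, the root-mean-square deviation of the
#'   increments about the IG factor.
#' @export
calibrate_ig <- function(integrals, samples, regions,
                         center = c("mean", "median")) {
  center <- match.arg(center)
  stopifnot(inherits(regions, "integration_regions"))
  conc <- samples$known_concentration_mM[match(integrals$sample_id,
                                               samples$sample_id)]
  if (any(is.na(conc)))
    stop("integrals without a known-concentration sample: ",
         paste(unique(integrals$sample_id[is.na(conc)]), collapse = ", "))
  n_h <- regions$n_protons[match(integrals$label, regions$label)]
  if (any(is.na(n_h)))
    stop("integral label(s) missing from the region set: ",
         paste(unique(integrals$label[is.na(n_h)]), collapse = ", "))
  inc <- normalized_increment(integrals$intensity, integrals$ns,
                              integrals$rg, conc, n_h)
  obs <- data.frame(label = integrals$label, sample_id = integrals$sample_id,
                    ns = integrals$ns, rg = integrals$rg,
                    concentration_mM = conc, n_protons = n_h,
                    increment = inc, stringsAsFactors = FALSE)
  ig <- if (center == "mean") mean(inc) else stats::median(inc)
  structure(list(ig = ig, center = center, observations = obs,
                 dispersion = sqrt(mean((inc - ig)^2))),
            class = "ig_calibration")
}

#' @export
print.ig_calibration <- function(x, ...) {
  cat(sprintf("<ig_calibration> IG = %.4f (%s of %d observations, sd %.4f)\n",
              x$ig, x$center, nrow(x$observations), x$dispersion))
  invisible(x)
}

#' Estimate a receiver-gain linearization from calibration scatter
#'
#' For each distinct nominal RG step in the calibration observations, the
#' multiplicative correction `f(rg)` is the mean normalized increment at that
#' step divided by the global IG factor; the linearized value is
#' `rg * f(rg)`. No smoothing is applied across steps (real amplifier
#' corrections are not monotone). Requires at least two distinct RG steps.
#'
#' @param cal An `ig_calibration`.
#' @return An object of class `rg_linearization`: `table` (`data.frame` of
#'   `rg_original`, `rg_linearized`, ordered by `rg_original`) and
#'   `interpolation = "linear"`.
#' @export
estimate_linearization <- function(cal) {
  stopifnot(inherits(cal, "ig_calibration"))
  obs <- cal$observations
  steps <- sort(unique(obs$rg))
  if (length(steps) < 2)
    stop("cannot linearize: calibration observations cover a single RG step (",
         num_str(steps), ")")
  f <- vapply(steps, function(r) mean(obs$increment[obs$rg == r]) / cal$ig, 0)
  rg_linearization(steps, steps * f)
}

#' Receiver-gain linearization table
#'
#' @param rg_original Strictly increasing nominal RG values.
#' @param rg_linearized Effective (linearized) RG values (> 0).
#' @param interpolation Interpolation rule between tabulated steps; only
#'   `"linear"` is implemented.
#' @return An object of class `rg_linearization`.
#' @export
rg_linearization <- function(rg_original, rg_linearized,
                             interpolation = "linear") {
  stopifnot("rg_original must be strictly increasing" = all(diff(rg_original) > 0),
            "rg_linearized must be > 0" = all(rg_linearized > 0),
            "lengths differ" = length(rg_original) == length(rg_linearized),
            "only linear interpolation is implemented" =
              identical(interpolation, "linear"))
  structure(list(table = data.frame(rg_original = as.numeric(rg_original),
                                    rg_linearized = as.numeric(rg_linearized)),
                 interpolation = interpolation),
            class = "rg_linearization")
}

#' @export
print.rg_linearization <- function(x, ...) {
  cat(sprintf("<rg_linearization> %d steps, %g .. %g (%s interpolation)\n",
              nrow(x$table), min(x$table$rg_original), max(x$table$rg_original),
              x$interpolation))
  invisible(x)
}

#' Read / write a linearization table CSV
#'
#' Two-column CSV `rg_original`, `rg_linearized`.
#'
#' @param path CSV path.
#' @param lin An `rg_linearization`.
#' @return `read_linearization()` returns the `rg_linearization`;
#'   `write_linearization()` returns `path` invisibly.
#' @export
read_linearization <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("rg_original", "rg_linearized") %in% names(df)))
    stop("linearization file needs columns rg_original, rg_linearized")
  rg_linearization(df$rg_original, df$rg_linearized)
}

#' @rdname read_linearization
#' @export
write_linearization <- function(lin, path) {
  write_csv_full(lin$table, path)
  invisible(path)
}

#' Map a nominal RG to its linearized value
#'
#' Exact table rows are returned as tabulated; values between rows are
#' linearly interpolated. Values outside the tabulated range are an error
#' unless `allow_extrapolate = TRUE`, in which case the nearest edge's
#' correction factor is applied.
#'
#' @param lin An `rg_linearization`.
#' @param rg Nominal receiver-gain value(s).
#' @param allow_extrapolate Permit out-of-range values (edge-factor rule).
#' @return Linearized RG value(s).
#' @export
apply_linearization <- function(lin, rg, allow_extrapolate = FALSE) {
  stopifnot(inherits(lin, "rg_linearization"))
  tab <- lin$table
  out <- numeric(length(rg))
  for (i in seq_along(rg)) {
    r <- rg[i]
    j <- which(abs(tab$rg_original - r) <= 1e-9 * max(r, 1))
    if (length(j)) {
      out[i] <- tab$rg_linearized[j[1]]
    } else if (r >= min(tab$rg_original) && r <= max(tab$rg_original)) {
      out[i] <- stats::approx(tab$rg_original, tab$rg_linearized, xout = r)$y
    } else if (allow_extrapolate) {
      k <- if (r < min(tab$rg_original)) 1L else nrow(tab)
      out[i] <- r * tab$rg_linearized[k] / tab$rg_original[k]
    } else {
      stop(sprintf("RG %g outside the linearization range [%g, %g]; set allow_extrapolate = TRUE for the nearest-edge correction",
                   r, min(tab$rg_original), max(tab$rg_original)))
    }
  }
  out
}

#' Back-calculate concentrations from absolute intensities
#'
#' The reference-free estimate for each (signal, experiment) observation is
#' `c = I / (IG * ns * rg_eff * n_protons)` with `rg_eff` the nominal RG or,
#' when a linearization is supplied, the linearized RG. Per sample, the pooled
#' estimates are aggregated to a mean concentration and its standard
#' deviation.
#'
#' @param integrals Integral `data.frame` with `sample_id`, `label`,
#'   `intensity`, `ns`, `rg`.
#' @param cal An `ig_calibration` (only its `ig` is used).
#' @param regions [integration_regions()] supplying proton counts.
#' @param lin Optional `rg_linearization`; `NULL` uses nominal RG values.
#' @param pooling `"flat"` (default): every signal x replicate estimate enters
#'   the pool equally; `"per_signal"`: estimates are first averaged per signal
#'   label, then aggregated across labels.
#' @param allow_extrapolate Passed to [apply_linearization()].
#' @return A `data.frame` of class `quant_result` with columns `sample_id`,
#'   `bc_mM`, `sigma_mM` (sample standard deviation of the estimate pool,
#'   the scatter of individual back-calculations), `sem_mM` (standard error
#'   of `bc_mM`, i.e. `sigma_mM / sqrt(n_estimates)`), `n_estimates`,
#'   `linearized`; the per-estimate pool is kept in attribute `"estimates"`.
#' @export
back_calculate <- function(integrals, cal, regions, lin = NULL,
                           pooling = c("flat", "per_signal"),
                           allow_extrapolate = FALSE) {
  pooling <- match.arg(pooling)
  stopifnot(inherits(cal, "ig_calibration"),
            inherits(regions, "integration_regions"),
            "ig must be > 0" = cal$ig > 0)
  n_h <- regions$n_protons[match(integrals$label, regions$label)]
  if (any(is.na(n_h)))
    stop("missing proton count for label(s): ",
         paste(unique(integrals$label[is.na(n_h)]), collapse = ", "))
  rg_eff <- if (is.null(lin)) integrals$rg else
    apply_linearization(lin, integrals$rg, allow_extrapolate)
  est <- data.frame(sample_id = integrals$sample_id, label = integrals$label,
                    concentration_mM = integrals$intensity /
                      (cal$ig * integrals$ns * rg_eff * n_h),
                    stringsAsFactors = FALSE)
  agg_pool <- function(v) c(bc = mean(v),
                            sigma = if (length(v) > 1) stats::sd(v) else 0,
                            n = length(v))
  ids <- unique(est$sample_id)
  rows <- lapply(ids, function(id) {
    v <- est$concentration_mM[est$sample_id == id]
    if (pooling == "per_signal") {
      labs <- est$label[est$sample_id == id]
      v <- tapply(v, labs, mean)
    }
    a <- agg_pool(as.numeric(v))
    data.frame(sample_id = id, bc_mM = a[["bc"]], sigma_mM = a[["sigma"]],
               sem_mM = a[["sigma"]] / sqrt(a[["n"]]),
               n_estimates = as.integer(a[["n"]]),
               linearized = !is.null(lin), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("quant_result", "data.frame")
  attr(out, "estimates") <- est
  out
}
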