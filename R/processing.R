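#' Fourier transform an FID into a complex spectrum
#'
#' Discrete Fourier transform with optional zero-filling, mapped onto a
#' descending ppm axis via the spectrometer frequency and sweep width. The
#' transform is unnormalized (`sum |S|^2 = m * sum |fid|^2` for output length
#' `m`), the exact inverse of [fid_from_spectrum()] at zero-fill factor 1.
#' Zero-filling interpolates the spectrum and conserves region integrals.
#'
#' @param fid An `nmr_fid`.
#' @param zero_fill_factor 1, 2 or 4: output length is
#'   `n_points * zero_fill_factor`.
#' @return A complex `nmr_spectrum` (absorption candidate in `real`,
#'   dispersion in `imag`), provenance appended.
#' @export
fourier_transform <- function(fid, zero_fill_factor = 1) {
  stopifnot(inherits(fid, "nmr_fid"),
            "zero_fill_factor must be 1, 2 or 4" = zero_fill_factor %in% c(1, 2, 4))
  n <- length(fid$data)
  m <- n * as.integer(zero_fill_factor)
  x <- c(fid$data, complex(length.out = m - n))
  s_std <- stats::fft(x)
  s_asc <- c(s_std[(m / 2 + 1):m], s_std[1:(m / 2)])  # fftshift
  s_desc <- rev(s_asc)
  meta <- fid$meta
  ppm <- ppm_axis(meta$center_ppm, meta$sweep_ppm, m)
  new_spectrum(meta, ppm, Re(s_desc), Im(s_desc),
               provenance = c(paste0("source:", fid$source),
                              sprintf("fourier_transform(zero_fill=%d)",
                                      as.integer(zero_fill_factor))))
}

#' Apply zeroth- and first-order phase correction
#'
#' Rotates the complex spectrum by `ph0 + ph1 * f`, where `f` runs linearly
#' from 0 at the left (high-ppm) edge to 1 at the right edge. Requires the
#' dispersion part.
#'
#' @param spec A complex `nmr_spectrum`.
#' @param ph0_deg Zeroth-order (frequency-independent) phase, degrees.
#' @param ph1_deg First-order phase, degrees across the full window.
#' @return The rotated complex `nmr_spectrum`.
#' @export
apply_phase <- function(spec, ph0_deg, ph1_deg = 0) {
  if (is.null(spec$imag)) stop("apply_phase() needs a complex spectrum")
  n <- length(spec$ppm)
  frac <- (seq_len(n) - 1) / (n - 1)
  phi <- (ph0_deg + ph1_deg * frac) * pi / 180
  s <- complex(real = spec$real, imaginary = spec$imag) *
    complex(argument = phi)
  spec$real <- Re(s)
  spec$imag <- Im(s)
  append_provenance(spec, sprintf("phase(ph0=%.4f, ph1=%.4f)",
                                  ph0_deg, ph1_deg))
}

# Phase-quality objective: a penalty on negative intensity (dominant term;
# any dispersion admixture creates negative lobes, so its minimum is the pure
# absorption spectrum) plus the entropy of the absolute first derivative,
# which breaks the 180-degree sign ambiguity and regularizes noisy input.
# Both terms are scale-invariant.
phase_objective <- function(re, scale) {
  r <- re / scale
  tot2 <- sum(r * r)
  negpen <- if (tot2 > 0) sum(pmin(r, 0)^2) / tot2 else 0
  dr <- abs(diff(r))
  tot <- sum(dr)
  ent <- if (tot > 0) {
    h <- dr / tot
    h <- h[h > 0]
    -sum(h * log(h))
  } else 0
  ent + 1e6 * negpen
}

#' Automated phase correction
#'
#' Chooses zeroth- and first-order phase by minimizing a hybrid objective:
#' the entropy of the absolute first derivative of the real part plus a
#' penalty on negative intensity. A coarse grid over (ph0, ph1) is refined by
#' Nelder-Mead. On clean absorption-mode input the minimum is the identity,
#' so the optimizer is a fixed point there; on dephased input it recovers the
#' applied phases.
#'
#' @param spec A complex `nmr_spectrum`.
#' @param ph0_grid_deg,ph1_grid_deg Coarse-search grids (degrees).
#' @param reltol Convergence tolerance handed to [stats::optim()].
#' @return The phased `nmr_spectrum`, with the applied corrections retrievable
#'   from attribute `"phases"` (`c(ph0, ph1)` in degrees) and recorded in the
#'   provenance.
#' @export
auto_phase <- function(spec,
                       ph0_grid_deg = seq(-180, 175, by = 5),
                       ph1_grid_deg = seq(-40, 40, by = 10),
                       reltol = 1e-10) {
  if (is.null(spec$imag)) stop("auto_phase() needs a complex spectrum")
  s <- complex(real = spec$real, imaginary = spec$imag)
  n <- length(s)
  frac <- (seq_len(n) - 1) / (n - 1)
  scale <- max(Mod(s))
  if (scale == 0) {              # zero spectrum: nothing to phase
    out <- append_provenance(spec, "phase(ph0=0, ph1=0, auto)")
    attr(out, "phases") <- c(ph0 = 0, ph1 = 0)
    return(out)
  }
  rot_re <- function(p) {
    phi <- (p[1] + p[2] * frac) * pi / 180
    Re(s * complex(argument = phi))
  }
  obj_coarse <- function(p) phase_objective(rot_re(p), scale)
  # refinement objective: negative-intensity penalty only — it is exactly
  # zero at the true phase of a clean absorption spectrum, so its minimum is
  # unbiased, while the entropy term (used in the coarse stage to reject the
  # 180-degree flip) would drag the optimum a few degrees off
  obj_neg <- function(p) {
    r <- rot_re(p) / scale
    sum(pmin(r, 0)^2) / sum(r * r)
  }
  best <- NULL
  best_val <- Inf
  for (p0 in ph0_grid_deg) for (p1 in ph1_grid_deg) {
    v <- obj_coarse(c(p0, p1))
    if (v < best_val) { best_val <- v; best <- c(p0, p1) }
  }
  fit <- stats::optim(best, obj_neg, method = "Nelder-Mead",
                      control = list(reltol = reltol, maxit = 2000))
  if (fit$convergence != 0)
    stop(sprintf("auto_phase() did not converge (code %d); best-found phases ph0=%.4f, ph1=%.4f deg",
                 fit$convergence, fit$par[1], fit$par[2]))
  # polish with a second restart to escape a flat simplex
  fit2 <- stats::optim(fit$par, obj_neg, method = "Nelder-Mead",
                       control = list(reltol = reltol, maxit = 2000))
  if (fit2$value < fit$value) fit <- fit2
  ph <- fit$par
  # normalize ph0 to (-180, 180]
  ph[1] <- ((ph[1] + 180) %% 360) - 180
  out <- apply_phase(spec, ph[1], ph[2])
  out$provenance[length(out$provenance)] <-
    sprintf("phase(ph0=%.4f, ph1=%.4f, auto)", ph[1], ph[2])
  attr(out, "phases") <- c(ph0 = ph[1], ph1 = ph[2])
  out
}

#' Baseline correction
#'
#' Fits a low-order polynomial to automatically detected signal-free points
#' and subtracts it. Detection is iterative asymmetric clipping: fit to all
#' points, drop points more than `clip` residual standard deviations above
#' the fit (signals are positive in absorption mode), refit until stable.
#' Handles constant offsets and slow ramps; it is not a peak-fitting step.
#'
#' @param spec A real or complex `nmr_spectrum` (the correction is applied to
#'   the real part; any dispersion part is left untouched).
#' @param method Baseline model; only `"poly"` is implemented.
#' @param degree Polynomial degree, 0 to 2.
#' @param clip Clipping threshold in residual standard deviations.
#' @param max_iter Maximum clipping iterations.
#' @return The corrected `nmr_spectrum`, provenance appended.
#' @export
baseline_correct <- function(spec, method = "poly", degree = 2, clip = 2.5,
                             max_iter = 20) {
  stopifnot(inherits(spec, "nmr_spectrum"))
  supported <- c("poly")
  if (!method %in% supported)
    stop("unknown baseline method '", method, "'; supported: ",
         paste(supported, collapse = ", "))
  stopifnot("degree must be 0, 1 or 2" = degree %in% 0:2)
  y <- spec$real
  n <- length(y)
  x <- seq(-1, 1, length.out = n)      # scaled abscissa for conditioning
  X <- stats::poly(x, degree = max(degree, 1), raw = TRUE)
  if (degree == 0) X <- X[, 0, drop = FALSE]
  keep <- rep(TRUE, n)
  base <- rep(0, n)
  eps <- 1e-12 * max(abs(y), 1)
  for (it in seq_len(max_iter)) {
    fit <- stats::lm.fit(cbind(1, X[keep, , drop = FALSE]), y[keep])
    base <- drop(cbind(1, X) %*% fit$coefficients)
    res <- y - base
    s <- stats::sd(res[keep])
    if (!is.finite(s)) s <- 0
    new_keep <- res <= clip * max(s, eps)
    if (identical(new_keep, keep)) break
    keep <- new_keep
    if (sum(keep) < degree + 2) break    # degenerate: almost all points clipped
  }
  spec$real <- y - base
  append_provenance(spec, sprintf("baseline(method=%s, degree=%d)",
                                  method, degree))
}

#' Full processing pipeline: FT, phase, baseline
#'
#' Convenience wrapper applying [fourier_transform()], then automatic or
#' manual phase correction, then [baseline_correct()].
#'
#' @param fid An `nmr_fid`.
#' @param zero_fill_factor See [fourier_transform()].
#' @param phase `"auto"` or `"manual"`.
#' @param ph0,ph1 Manual phases (degrees), used when `phase = "manual"`.
#' @param baseline_method,baseline_degree See [baseline_correct()].
#' @return A baseline-corrected absorption-mode `nmr_spectrum`.
#' @export
process_fid <- function(fid, zero_fill_factor = 1, phase = c("auto", "manual"),
                        ph0 = 0, ph1 = 0, baseline_method = "poly",
                        baseline_degree = 2) {
  phase <- match.arg(phase)
  spec <- fourier_transform(fid, zero_fill_factor)
  spec <- if (phase == "auto") auto_phase(spec) else apply_phase(spec, ph0, ph1)
  baseline_correct(spec, method = baseline_method, degree = baseline_degree)
}
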