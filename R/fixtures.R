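#' Bundled reference tables
#'
#' Small plain-text tables shipped with the package, as printed in the
#' reference quinine study:
#' * `quinine_samples()` — the five gravimetrically prepared quinine samples
#'   (target and real concentrations, weights, available RG range) for
#'   MW 324.42 g/mol in 0.6 ml DMSO-d6.
#' * `rg_table_printed()` — the published receiver-gain linearization table
#'   (original vs linearized RG over the 17 steps from 25.4 to 161).
#' * `quinine_backcalc()` — the published per-sample back-calculated
#'   concentrations, native (`bc_mM`) and with linearized RG (`bcl_mM`), each
#'   with its standard deviation.
#' * `example_regions()` — an illustrative 13-signal integration-region set
#'   for quinine in DMSO-d6 (synthetic bounds, for demonstrations and the
#'   simulator; the study's exact limits were defined graphically on a
#'   reference experiment and are not reproduced here).
#'
#' @return A `data.frame` (an [integration_regions()] set for
#'   `example_regions()`).
#' @name bundled_tables
NULL

extdata <- function(name) {
  path <- system.file("extdata", name, package = "faintnmr", mustWork = FALSE)
  if (!nzchar(path)) {
    # during in-source development (pkgload) fall back to inst/
    path <- file.path("inst", "extdata", name)
  }
  if (!file.exists(path)) stop("bundled table not found: ", name)
  path
}

#' @rdname bundled_tables
#' @export
quinine_samples <- function() {
  utils::read.csv(extdata("quinine_samples.csv"), stringsAsFactors = FALSE)
}

#' @rdname bundled_tables
#' @export
rg_table_printed <- function() {
  utils::read.csv(extdata("rg_linearization_printed.csv"),
                  stringsAsFactors = FALSE)
}

#' @rdname bundled_tables
#' @export
quinine_backcalc <- function() {
  utils::read.csv(extdata("quinine_backcalc.csv"), stringsAsFactors = FALSE)
}

#' @rdname bundled_tables
#' @export
example_regions <- function() {
  read_regions(extdata("example_regions_synthetic.csv"))
}

#' The published receiver-gain linearization as a lookup object
#'
#' Convenience wrapper turning [rg_table_printed()] into an
#' [rg_linearization()] usable with [apply_linearization()] and
#' [back_calculate()].
#'
#' @return An `rg_linearization`.
#' @export
published_linearization <- function() {
  tab <- rg_table_printed()
  rg_linearization(tab$rg_original, tab$rg_linearized)
}
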