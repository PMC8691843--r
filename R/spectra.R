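#' Construct a transmittance spectrum
#'
#' A transmittance spectrum holds the specular transmittance `T(lambda)` of
#' one measured wing spot of one species, as a dimensionless fraction.
#' Wavelengths must be strictly increasing and cover the full 300-700 nm
#' measurement band. Values slightly below zero (instrument noise) are
#' tolerated at ingestion and clamped during smoothing; values above 1.5
#' are rejected as sensor artefacts.
#'
#' @param species_id Character scalar.
#' @param spot_id Integer spot index (1-5 in the study design).
#' @param wavelength Numeric vector of wavelengths in nm, strictly
#'   increasing, spanning at least `[300, 700]`.
#' @param transmittance Numeric vector of the same length, fractional
#'   transmittance (divide percent data by 100 first).
#' @return An object of class `"txspec"`.
#' @export
transmittance_spectrum <- function(species_id, spot_id, wavelength, transmittance) {
  stopifnot(length(species_id) == 1L, length(spot_id) == 1L)
  wavelength <- as.numeric(wavelength)
  transmittance <- as.numeric(transmittance)
  if (length(wavelength) != length(transmittance))
    stop("wavelength and transmittance must have the same length")
  if (anyNA(wavelength) || anyNA(transmittance))
    stop("missing values in spectrum for ", species_id, " spot ", spot_id)
  if (any(diff(wavelength) <= 0))
    stop("wavelengths must be strictly increasing (", species_id,
         " spot ", spot_id, ")")
  if (min(wavelength) > 300 || max(wavelength) < 700)
    stop("spectrum must cover [300, 700] nm; got [",
         min(wavelength), ", ", max(wavelength), "]")
  if (any(transmittance > 1.5))
    stop("transmittance above the 1.5 artefact ceiling for ", species_id,
         " spot ", spot_id, "; forgot percent = TRUE?")
  if (any(transmittance < -0.5))
    stop("grossly negative transmittance for ", species_id, " spot ", spot_id)
  structure(
    list(species_id = as.character(species_id), spot_id = as.integer(spot_id),
         wavelength = wavelength, transmittance = transmittance),
    class = "txspec")
}

#' @export
print.txspec <- function(x, ...) {
  cat("Transmittance spectrum:", x$species_id, "spot", x$spot_id, "\n")
  cat("  ", length(x$wavelength), "points over [", min(x$wavelength), ",",
      max(x$wavelength), "] nm; mean T =",
      round(mean_transmittance(x), 4), "\n")
  invisible(x)
}

#' Read transmittance spectra from a long-format CSV
#'
#' Expects columns `species_id`, `spot_id`, `wavelength` (or
#' `wavelength_nm`) and `transmittance`. One spectrum is built per
#' (species, spot). Rows outside the 300-700 nm band are retained and the
#' spectrum is flagged via the `"out_of_band"` attribute.
#'
#' @param path CSV file path.
#' @param percent If `TRUE`, transmittance values are percentages and are
#'   divided by 100.
#' @return A named list of [transmittance_spectrum()] objects, keyed
#'   `"<species_id>.<spot_id>"`.
#' @export
read_spectra <- function(path, percent = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("wavelength_nm" %in% names(df) && !"wavelength" %in% names(df))
    names(df)[names(df) == "wavelength_nm"] <- "wavelength"
  for (col in c("species_id", "spot_id", "wavelength", "transmittance"))
    if (!col %in% names(df))
      stop("spectra file is missing required column '", col, "'")
  if (!is.numeric(df$wavelength))
    stop("column 'wavelength' must be numeric")
  key <- paste(df$species_id, df$spot_id, df$wavelength, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), , drop = FALSE][1L, ]
    stop("duplicate measurement for species ", d$species_id, " spot ",
         d$spot_id, " at ", d$wavelength, " nm")
  }
  if (percent) df$transmittance <- df$transmittance / 100
  groups <- split(df, list(df$species_id, df$spot_id), drop = TRUE)
  out <- lapply(groups, function(g) {
    s <- transmittance_spectrum(g$species_id[1L], g$spot_id[1L],
                                g$wavelength, g$transmittance)
    oob <- g$wavelength < 300 | g$wavelength > 700
    if (any(oob)) attr(s, "out_of_band") <- sum(oob)
    s
  })
  out[order(names(out))]
}

#' Write spectra to a long-format CSV
#'
#' @param spectra List of `"txspec"` objects.
#' @param path Output CSV path.
#' @export
write_spectra <- function(spectra, path) {
  rows <- lapply(spectra, function(s)
    data.frame(species_id = s$species_id, spot_id = s$spot_id,
               wavelength = s$wavelength, transmittance = s$transmittance))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Smooth a spectrum onto the canonical grid
#'
#' Local quadratic regression with tricube weights (loess, degree 2) over a
#' sliding window holding a `span` fraction of the points, then linear
#' resampling onto the canonical 1-nm grid and clamping below
#' `clamp_floor`. Negative instrument noise is clamped only here, after
#' smoothing, so the smoother sees the unaltered noise structure.
#'
#' @param s A `"txspec"` object.
#' @param span Smoothing span, fraction of points in the local window.
#' @param clamp_floor Values below this are set to it (default 0).
#' @return A smoothed `"txspec"` on the 401-point canonical grid.
#' @export
smooth_spectrum <- function(s, span = 0.25, clamp_floor = 0) {
  stopifnot(inherits(s, "txspec"), span > 0, span <= 1, clamp_floor >= 0)
  n <- length(s$wavelength)
  if (n < 5L) stop("cannot smooth a spectrum with fewer than 5 points")
  fit <- stats::loess(transmittance ~ wavelength,
                      data = data.frame(wavelength = s$wavelength,
                                        transmittance = s$transmittance),
                      span = span, degree = 2, family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  sm <- stats::predict(fit, newdata = data.frame(wavelength = s$wavelength))
  grid <- canonical_grid()
  y <- stats::approx(s$wavelength, sm, xout = grid, rule = 2)$y
  y <- pmax(y, clamp_floor)
  out <- transmittance_spectrum(s$species_id, s$spot_id, grid, y)
  attr(out, "span") <- span
  out
}

#' Mean transmittance over a wavelength band
#'
#' Trapezoid-rule integral of `T(lambda)` over `[lo, hi]` divided by the
#' band width. Returned as a fraction; multiply by 100 for percent.
#'
#' @param s A `"txspec"` object.
#' @param lo,hi Band limits in nm, within the spectrum's support.
#' @return Band-averaged transmittance (scalar fraction).
#' @export
mean_transmittance <- function(s, lo = 300, hi = 700) {
  stopifnot(inherits(s, "txspec"))
  if (lo >= hi) stop("lo must be smaller than hi")
  if (lo < min(s$wavelength) || hi > max(s$wavelength))
    stop("[lo, hi] outside the spectrum's support")
  inner <- s$wavelength > lo & s$wavelength < hi
  x <- c(lo, s$wavelength[inner], hi)
  y <- stats::approx(s$wavelength, s$transmittance, xout = x)$y
  trapz(x, y) / (hi - lo)
}
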