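#' Receptor sensitivity curve
#'
#' Holds one cone class's spectral sensitivity on the canonical grid,
#' peak-normalised to 1.
#'
#' @param label Receptor label (e.g. `"UVS"`, `"S"`, `"M"`, `"L"`, `"DBL"`).
#' @param lambda_max Wavelength of peak sensitivity, nm.
#' @param sensitivity Numeric vector on the canonical grid, values in
#'   `[0, 1]` with a single global maximum of 1.
#' @return An object of class `"receptor_sensitivity"`.
#' @export
receptor_sensitivity <- function(label, lambda_max, sensitivity) {
  grid <- canonical_grid()
  stopifnot(length(sensitivity) == length(grid))
  if (any(sensitivity < 0) || any(sensitivity > 1 + 1e-9))
    stop("sensitivity values must lie in [0, 1]")
  if (abs(max(sensitivity) - 1) > 1e-9)
    stop("sensitivity must be peak-normalised to 1")
  structure(list(label = as.character(label), lambda_max = lambda_max,
                 wavelength = grid, sensitivity = as.numeric(sensitivity)),
            class = "receptor_sensitivity")
}

#' A1 visual-pigment absorbance template
#'
#' Govardovskii-type alpha-band nomogram for an A1 pigment with the given
#' peak wavelength, evaluated on the canonical grid and peak-normalised.
#' Used as a parametric stand-in for published bird cone sensitivities,
#' keeping the package self-contained; measured curves can be supplied via
#' [receptor_sensitivity()] instead.
#'
#' @param lambda_max Peak wavelength in nm, within `[300, 700]`.
#' @param label Optional receptor label (default `"pigment<lambda_max>"`).
#' @return A `"receptor_sensitivity"` object.
#' @export
pigment_template <- function(lambda_max, label = NULL) {
  if (lambda_max < 300 || lambda_max > 700)
    stop("lambda_max must lie within [300, 700] nm")
  grid <- canonical_grid()
  x <- lambda_max / grid
  a <- 0.8795 + 0.0459 * exp(-(lambda_max - 300)^2 / 11940)
  s <- 1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
              exp(-14.9 * (1.104 - x)) + 0.674)
  s <- s / max(s)
  receptor_sensitivity(label %||% paste0("pigment", lambda_max),
                       lambda_max, s)
}

#' Illuminant spectrum
#'
#' Relative irradiance on the canonical grid. Only the spectral shape
#' matters for the contrasts computed downstream; the overall scale cancels
#' in log-ratios.
#'
#' @param name Illuminant name.
#' @param irradiance Non-negative values on the canonical grid, not all
#'   zero.
#' @return An object of class `"illuminant"`.
#' @export
illuminant_spectrum <- function(name, irradiance) {
  grid <- canonical_grid()
  stopifnot(length(irradiance) == length(grid))
  if (any(irradiance < 0)) stop("irradiance must be non-negative")
  if (all(irradiance == 0)) stop("irradiance must not be identically zero")
  structure(list(name = as.character(name), wavelength = grid,
                 irradiance = as.numeric(irradiance)),
            class = "illuminant")
}

#' Visual system: receptor set with noise parameters
#'
#' Bundles ordered cone sensitivities (shortest to longest peak), their
#' relative densities, the chromatic and achromatic Weber fractions, and
#' the label of the receptor used for the achromatic (luminance) channel.
#'
#' @param receptors List of `"receptor_sensitivity"` objects ordered by
#'   increasing `lambda_max`.
#' @param densities Relative cone densities, same order, all positive.
#' @param weber_chromatic Weber fraction of the chromatic channel (0.1 in
#'   the study's models).
#' @param weber_achromatic Weber fraction of the achromatic channel (0.2).
#' @param achromatic_channel Label of the receptor used for luminance;
#'   defaults to the longest-wavelength receptor.
#' @param name Optional visual-system name (e.g. `"UVS"`, `"VS"`).
#' @return An object of class `"receptor_set"`.
#' @export
receptor_set <- function(receptors, densities, weber_chromatic = 0.1,
                         weber_achromatic = 0.2, achromatic_channel = NULL,
                         name = "custom") {
  stopifnot(length(receptors) >= 2L,
            length(densities) == length(receptors),
            all(densities > 0),
            weber_chromatic > 0, weber_chromatic < 1,
            weber_achromatic > 0, weber_achromatic < 1)
  if (!all(vapply(receptors, inherits, logical(1), "receptor_sensitivity")))
    stop("receptors must be receptor_sensitivity objects")
  lm <- vapply(receptors, `[[`, numeric(1), "lambda_max")
  if (is.unsorted(lm)) stop("receptors must be ordered by increasing lambda_max")
  labels <- vapply(receptors, `[[`, character(1), "label")
  achromatic_channel <- achromatic_channel %||% labels[length(labels)]
  if (!achromatic_channel %in% labels)
    stop("achromatic_channel '", achromatic_channel, "' not among receptors")
  structure(list(receptors = receptors, densities = as.numeric(densities),
                 weber_chromatic = weber_chromatic,
                 weber_achromatic = weber_achromatic,
                 achromatic_channel = achromatic_channel,
                 labels = labels, name = name),
            class = "receptor_set")
}

#' @export
print.receptor_set <- function(x, ...) {
  cat("Visual system '", x$name, "': ", length(x$receptors),
      " receptors (", paste(x$labels, collapse = ", "), ")\n", sep = "")
  cat("  densities", paste(x$densities, collapse = ":"),
      " | Weber chromatic", x$weber_chromatic,
      " achromatic", x$weber_achromatic,
      " | luminance channel", x$achromatic_channel, "\n")
  invisible(x)
}

#' Quantum catch of one receptor for transmitted light
#'
#' The stimulus is the wing seen against the sky, so the receptor
#' integrates transmitted light directly:
#' `Q = integral of T(lambda) I(lambda) S(lambda) dlambda` (trapezoid rule
#' on the canonical grid). No von Kries normalisation is applied; it
#' cancels in the log-ratio contrasts.
#'
#' @param t A smoothed `"txspec"` on the canonical grid.
#' @param i An `"illuminant"`.
#' @param r A `"receptor_sensitivity"`.
#' @return Positive scalar catch in arbitrary linear units. A zero catch is
#'   returned with a warning; contrasts on zero catches error downstream.
#' @export
quantum_catch <- function(t, i, r) {
  stopifnot(inherits(t, "txspec"), inherits(i, "illuminant"),
            inherits(r, "receptor_sensitivity"))
  grid <- canonical_grid()
  if (!identical(as.numeric(t$wavelength), as.numeric(grid)))
    stop("spectrum is not on the canonical grid; smooth_spectrum() it first")
  q <- trapz(grid, t$transmittance * i$irradiance * r$sensitivity)
  if (q <= 0) warning("zero quantum catch for ", t$species_id,
                      " spot ", t$spot_id, " receptor ", r$label)
  q
}

#' Quantum catches of a full receptor set
#'
#' @param t A smoothed `"txspec"` on the canonical grid.
#' @param i An `"illuminant"`.
#' @param r A `"receptor_set"`.
#' @return An object of class `"receptor_catch"` with catches `q` and log
#'   catches `f = log(q)` per receptor.
#' @export
receptor_catch <- function(t, i, r) {
  stopifnot(inherits(r, "receptor_set"))
  q <- vapply(r$receptors, function(rc) quantum_catch(t, i, rc), numeric(1))
  names(q) <- r$labels
  structure(list(species_id = t$species_id, spot_id = t$spot_id,
                 q = q, f = suppressWarnings(log(q))),
            class = "receptor_catch")
}

#' Receptor noise values
#'
#' Neural-noise scaling: the reference receptor is the most abundant cone
#' class (ties broken towards the longest peak wavelength); its noise is
#' the chromatic Weber fraction, and sparser classes are noisier by the
#' square root of the density ratio:
#' `e_i = omega * sqrt(eta_ref / eta_i)`.
#'
#' @param r A `"receptor_set"`.
#' @return Named numeric vector of noise values, one per receptor.
#' @export
receptor_noise <- function(r) {
  stopifnot(inherits(r, "receptor_set"))
  ref <- max(which(r$densities == max(r$densities)))
  e <- r$weber_chromatic * sqrt(r$densities[ref] / r$densities)
  names(e) <- r$labels
  e
}

#' Chromatic contrast (dS) in just-noticeable differences
#'
#' Receptor-noise-limited chromatic distance between two stimuli viewed
#' under the same illuminant. For receptor signals
#' `df_i = f_i(a) - f_i(b)` and noises `e_i`,
#' `dS^2 = sum over pairs i<j of (prod of e_k, k not in {i,j})^2 (df_j - df_i)^2`
#' divided by `sum over i of (prod of e_k, k != i)^2`, which reduces to the
#' familiar closed forms for di-, tri- and tetrachromats.
#'
#' @param a,b `"receptor_catch"` objects under the same illuminant and
#'   receptor set.
#' @param r The `"receptor_set"` both catches were computed with.
#' @return Non-negative scalar contrast in JND.
#' @export
chromatic_contrast <- function(a, b, r) {
  stopifnot(inherits(a, "receptor_catch"), inherits(b, "receptor_catch"),
            inherits(r, "receptor_set"))
  n <- length(r$receptors)
  if (length(a$q) != n || length(b$q) != n)
    stop("receptor count mismatch between catches and receptor set")
  if (any(a$q <= 0) || any(b$q <= 0))
    stop("chromatic contrast undefined for non-positive quantum catches")
  e <- receptor_noise(r)
  df <- a$f - b$f
  num <- 0
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    num <- num + prod(e[-c(i, j)])^2 * (df[j] - df[i])^2
  }
  den <- sum(vapply(seq_len(n), function(i) prod(e[-i])^2, numeric(1)))
  sqrt(num / den)
}

#' Achromatic contrast (dL) in just-noticeable differences
#'
#' `dL = |log(Q_ach(a) / Q_ach(b))| / omega_ach` using the designated
#' luminance receptor.
#'
#' @inheritParams chromatic_contrast
#' @return Non-negative scalar contrast in JND.
#' @export
achromatic_contrast <- function(a, b, r) {
  stopifnot(inherits(a, "receptor_catch"), inherits(b, "receptor_catch"),
            inherits(r, "receptor_set"))
  i <- match(r$achromatic_channel, r$labels)
  qa <- a$q[i]; qb <- b$q[i]
  if (qa <= 0 || qb <= 0)
    stop("achromatic contrast undefined for non-positive quantum catches")
  abs(log(qa / qb)) / r$weber_achromatic
}

#' Pairwise contrast tables for one wing spot
#'
#' Computes chromatic (dS) and achromatic (dL) contrasts between every
#' unordered pair of species for one analogous spot, under one visual
#' system and one illuminant. Species missing the spot are dropped with a
#' message, not an error.
#'
#' @param spectra List of smoothed `"txspec"` objects for one spot, at
#'   most one per species.
#' @param illum An `"illuminant"`.
#' @param vis A `"receptor_set"`.
#' @return An object of class `"contrast_tables"`: symmetric `dS` and `dL`
#'   matrices with zero diagonals, plus spot / visual system / illuminant
#'   metadata.
#' @export
contrast_matrix <- function(spectra, illum, vis) {
  spectra <- Filter(Negate(is.null), spectra)
  spp <- vapply(spectra, `[[`, character(1), "species_id")
  if (anyDuplicated(spp)) stop("more than one spectrum per species for this spot")
  if (length(spp) < 2L) stop("need at least 2 species")
  spots <- unique(vapply(spectra, `[[`, integer(1), "spot_id"))
  if (length(spots) > 1L) stop("spectra must all be for the same spot")
  catches <- lapply(spectra, receptor_catch, i = illum, r = vis)
  n <- length(spp)
  dS <- dL <- matrix(0, n, n, dimnames = list(spp, spp))
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    dS[i, j] <- dS[j, i] <- chromatic_contrast(catches[[i]], catches[[j]], vis)
    dL[i, j] <- dL[j, i] <- achromatic_contrast(catches[[i]], catches[[j]], vis)
  }
  structure(list(species = spp, dS = dS, dL = dL, spot = spots,
                 visual_system = vis$name, illuminant = illum$name),
            class = "contrast_tables")
}

#' Long-format view of a symmetric pairwise table
#'
#' @param m Symmetric matrix with species dimnames.
#' @return Data frame with columns `species_a`, `species_b`, `value`, one
#'   row per unordered pair (`a` before `b` in the matrix ordering).
#' @export
pair_table <- function(m) {
  stopifnot(is.matrix(m), !is.null(rownames(m)))
  idx <- which(upper.tri(m), arr.ind = TRUE)
  data.frame(species_a = rownames(m)[idx[, 1L]],
             species_b = colnames(m)[idx[, 2L]],
             value = m[idx], stringsAsFactors = FALSE)
}
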