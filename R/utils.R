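#' Canonical wavelength grid
#'
#' All integration and vision modelling in the package happens on a fixed
#' 1-nm grid from 300 to 700 nm (401 points), the band over which specular
#' transmittance is measured and to which both birds and butterflies are
#' sensitive. A fixed grid makes every integral reproducible.
#'
#' @return Integer vector of wavelengths in nm, `300:700`.
#' @export
canonical_grid <- function() 300:700

# trapezoid integral of y over x (x strictly increasing)
trapz <- function(x, y) {
  sum(diff(x) * (y[-length(y)] + y[-1]) / 2)
}

# set.seed only when a seed is supplied; all stochastic entry points funnel
# through here so results are reproducible from (inputs, seed)
seed_if <- function(seed) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}

# permutation p-values: raw proportion (as the original procedure reports)
# and the (count + 1)/(n + 1) version used for decisions. Ties count as
# "as extreme" in both.
perm_pvalues <- function(null, observed, direction = c("le", "ge")) {
  direction <- match.arg(direction)
  hits <- if (direction == "le") sum(null <= observed) else sum(null >= observed)
  n <- length(null)
  list(p_raw = hits / n, p_plus_one = (hits + 1) / (n + 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
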