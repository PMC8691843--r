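#' Ring-size census of the study community
#'
#' The mimicry-ring sizes used by the default study configuration:
#' 62 species across the 10 rings, reproducing every published count of
#' the community design (2-species 'blue' ring, 3-species 'hewitsoni'
#' ring, and 213 co-mimetic pairs in total). Species identities in
#' generated bundles are synthetic; only the census is anchored.
#'
#' @return Named integer vector of ring sizes.
#' @export
ring_census <- function() {
  c(eurimedia = 13L, lerida = 10L, panthyale = 8L, agnosia = 7L,
    confusa = 6L, theudelinda = 5L, aureliana = 4L, `banjana-m` = 4L,
    hewitsoni = 3L, blue = 2L)
}

#' Study configuration for the synthetic generator
#'
#' Defines the conditions a generated study bundle emulates: community
#' size and ring structure, number of analogous wing spots, the
#' evolutionary model of species-level mean transmittance (Ornstein-
#' Uhlenbeck with ring-specific optima for convergence, Brownian motion
#' when `alpha = 0`), the spectral observation model, and the structural
#' trait models (equal-rates Mk with optional ring-convergent overrides;
#' Brownian/OU continuous traits).
#'
#' @param n_species Number of species (62, the study community size).
#' @param ring_sizes Named integer vector of ring sizes summing to
#'   `n_species`; defaults to [ring_census()].
#' @param ring_assignment_mode `"random"` (rings independent of the tree)
#'   or `"clade"` (rings painted on the largest monophyletic groups,
#'   creating the shared-ancestry confound).
#' @param spots_per_species Number of analogous wing spots (5).
#' @param birth_rate Yule speciation rate for the simulated tree.
#' @param alpha OU selection strength towards ring optima, per unit tree
#'   depth; `0` gives the Brownian null with no convergence. When `NULL`
#'   (default) it is set so that adjacent ring optima sit two stationary
#'   standard deviations apart — the weakest separation under which
#'   convergence is reliably detectable.
#' @param sigma2 Diffusion rate of mean transmittance.
#' @param theta Per-ring transmittance optima in (0, 1); defaults spread
#'   the rings evenly so adjacent optima sit 2 stationary standard
#'   deviations apart under the default `alpha` and `sigma2`.
#' @param spot_offsets Additive spot effects on transmittance.
#' @param tilt_range Range of the linear spectral tilt drawn per spectrum.
#' @param noise_sd Per-wavelength measurement noise standard deviation.
#' @param mk_rate Per-pair Mk rate of the discrete structural traits.
#' @param convergence_override Probability `q` that a species is switched
#'   to its ring's typical state for each discrete trait (0 under the
#'   null).
#' @param density_theta Per-ring optima of nanostructure density (per
#'   square micrometre) when convergence is on.
#' @param density_alpha,density_sigma2 OU parameters of nanostructure
#'   density.
#' @param seed Master seed of the bundle.
#' @return A list of class `"study_config"`.
#' @export
study_config <- function(n_species = 62, ring_sizes = NULL,
                         ring_assignment_mode = c("random", "clade"),
                         spots_per_species = 5, birth_rate = 1,
                         alpha = NULL, sigma2 = 0.06, theta = NULL,
                         spot_offsets = NULL, tilt_range = c(-0.1, 0.1),
                         noise_sd = 0.01, mk_rate = 0.5,
                         convergence_override = 0.7,
                         density_theta = NULL, density_alpha = 3,
                         density_sigma2 = 3, seed = 1) {
  ring_assignment_mode <- match.arg(ring_assignment_mode)
  if (is.null(ring_sizes)) {
    ring_sizes <- ring_census()
    if (n_species != 62) {
      # scale the census shape to the requested community size
      base <- ring_sizes / sum(ring_sizes) * n_species
      ring_sizes <- pmax(round(base), 2)
      while (sum(ring_sizes) != n_species) {
        i <- if (sum(ring_sizes) > n_species)
          which.max(ring_sizes) else which.min(ring_sizes)
        ring_sizes[i] <- ring_sizes[i] + sign(n_species - sum(ring_sizes))
      }
    }
  }
  n_rings <- length(ring_sizes)
  if (sum(ring_sizes) != n_species)
    stop("ring sizes must sum to n_species")
  if (n_rings > n_species / 2)
    stop("need n_rings <= n_species / 2")
  step_max <- if (n_rings > 1) 0.84 / (n_rings - 1) else 0.2
  if (is.null(alpha)) {
    # default selection strength: strong enough that the stationary SD is
    # half the optimum spacing (adjacent optima 2 SDs apart), capped so
    # the SD never exceeds 0.1 on the transmittance scale
    sd_target <- min(step_max / 2, 0.1)
    alpha <- sigma2 / (2 * sd_target^2)
  }
  if (is.null(theta)) {
    sd_st <- if (alpha > 0) sqrt(sigma2 / (2 * alpha)) else sqrt(sigma2)
    step <- min(2 * sd_st, step_max)
    theta <- 0.5 + step * (seq_len(n_rings) - (n_rings + 1) / 2)
  }
  if (any(theta <= 0 | theta >= 1)) stop("theta must lie in (0, 1)")
  names(theta) <- names(ring_sizes)
  if (is.null(spot_offsets))
    spot_offsets <- if (spots_per_species == 1L) 0 else
      seq(-0.06, 0.06, length.out = spots_per_species)
  if (convergence_override < 0 || convergence_override > 1)
    stop("convergence_override must lie in [0, 1]")
  if (is.null(density_theta)) {
    sd_d <- sqrt(density_sigma2 / (2 * max(density_alpha, 1e-8)))
    density_theta <- seq(8, 8 + 2 * sd_d * (n_rings - 1),
                         length.out = n_rings)
  }
  names(density_theta) <- names(ring_sizes)
  structure(list(n_species = n_species, ring_sizes = ring_sizes,
                 ring_assignment_mode = ring_assignment_mode,
                 spots_per_species = spots_per_species,
                 birth_rate = birth_rate, alpha = alpha, sigma2 = sigma2,
                 theta = theta, spot_offsets = spot_offsets,
                 tilt_range = tilt_range, noise_sd = noise_sd,
                 mk_rate = mk_rate,
                 convergence_override = convergence_override,
                 density_theta = density_theta,
                 density_alpha = density_alpha,
                 density_sigma2 = density_sigma2, seed = seed),
            class = "study_config")
}

# partition the tips into n_groups monophyletic groups by repeatedly
# splitting the largest current clade at its root; returns a list of tip
# index vectors sorted by decreasing size
clade_partition <- function(tree, n_groups) {
  ntip <- length(tree$tip.label)
  children <- tree_children(tree)
  tips_under <- function(node) {
    if (node <= ntip) return(node)
    unlist(lapply(children[[as.character(node)]]$node, tips_under))
  }
  groups <- list(list(node = ntip + 1L, tips = seq_len(ntip)))
  repeat {
    if (length(groups) >= n_groups) break
    sizes <- vapply(groups, function(g) length(g$tips), integer(1))
    splittable <- which(sizes >= 2L)
    if (!length(splittable)) break
    big <- splittable[which.max(sizes[splittable])]
    v <- groups[[big]]$node
    kids <- children[[as.character(v)]]$node
    new <- lapply(kids, function(k) list(node = k, tips = tips_under(k)))
    groups <- c(groups[-big], new)
  }
  groups <- lapply(groups, `[[`, "tips")
  groups[order(-lengths(groups))]
}

#' Generate a complete synthetic study bundle
#'
#' Produces a tree, a ring assignment, per-spot transmittance spectra and
#' a structural trait table under the configured evolutionary models,
#' along with the latent ground truth for recovery tests. Species-level
#' mean transmittance evolves by OU towards ring optima (convergence) or
#' by Brownian motion (`alpha = 0`); each spectrum is the species mean
#' plus a spot offset, a linear spectral tilt and Gaussian measurement
#' noise, clipped to `[0, 1]`. Discrete structural traits follow an
#' equal-rates Mk process with ring-typical overrides applied with
#' probability `convergence_override`; nanostructure density follows OU
#' with ring optima when convergence is on.
#'
#' @param cfg A [study_config()].
#' @return A list of class `"study_bundle"` with elements `tree`, `rings`
#'   (named character), `spectra` (list of `"txspec"`), `traits` (data
#'   frame), `truth` (latent parameters) and `config`.
#' @export
generate_study <- function(cfg = study_config()) {
  stopifnot(inherits(cfg, "study_config"))
  seed_if(cfg$seed)
  tree <- simulate_tree(cfg$n_species, cfg$birth_rate)
  spp <- tree$tip.label
  ring_names <- names(cfg$ring_sizes)

  if (cfg$ring_assignment_mode == "random") {
    rings <- stats::setNames(
      sample(rep(ring_names, times = cfg$ring_sizes)), spp)
  } else {
    # clade mode ignores the ring-size census: rings are painted on the
    # n_rings largest monophyletic groups (largest ring name -> largest
    # clade), creating the shared-ancestry confound
    groups <- clade_partition(tree, length(ring_names))
    ord <- order(-cfg$ring_sizes)
    rings <- character(cfg$n_species)
    for (i in seq_along(groups)) {
      lab <- ring_names[ord[((i - 1L) %% length(ring_names)) + 1L]]
      rings[groups[[i]]] <- lab
    }
    names(rings) <- spp
  }

  # regime of every branch = ring of the tipward species for terminal
  # branches; internal branches evolve towards the community mean optimum
  mid_regime <- "ancestral"
  optima <- c(cfg$theta, stats::setNames(mean(cfg$theta), mid_regime))
  regime_map <- rep(mid_regime, nrow(tree$edge))
  term <- tree$edge[, 2L] <= cfg$n_species
  regime_map[term] <- rings[tree$edge[term, 2L]]
  mu <- if (cfg$alpha > 0)
    simulate_ou_regimes(tree, cfg$alpha, cfg$sigma2, optima, regime_map,
                        root_value = mean(cfg$theta))
  else simulate_bm(tree, cfg$sigma2, root = mean(cfg$theta))
  mu <- pmin(pmax(mu, 0.02), 0.98)

  grid <- canonical_grid()
  spectra <- list()
  tilt <- matrix(stats::runif(cfg$n_species * cfg$spots_per_species,
                              cfg$tilt_range[1L], cfg$tilt_range[2L]),
                 cfg$n_species)
  for (i in seq_len(cfg$n_species)) {
    for (j in seq_len(cfg$spots_per_species)) {
      tt <- mu[i] + cfg$spot_offsets[j] + tilt[i, j] * (grid - 500) / 400 +
        stats::rnorm(length(grid), 0, cfg$noise_sd)
      # clip to [0.001, 1]: real spectrophotometry never reads exactly zero,
      # and a strictly positive floor keeps quantum catches defined
      spectra[[paste0(spp[i], ".", j)]] <-
        transmittance_spectrum(spp[i], j, grid, pmin(pmax(tt, 0.001), 1))
    }
  }

  trait_levels <- list(
    scale_type = c("LE", "LF", "P"),
    scale_colour = c("coloured", "transparent"),
    nanostructure_type = c("absent", "maze", "nipple", "pillar", "sponge"))
  ring_typical <- lapply(trait_levels, function(lv)
    stats::setNames(sample(lv, length(ring_names), replace = TRUE),
                    ring_names))
  traits <- data.frame(species_id = spp, stringsAsFactors = FALSE)
  for (nm in names(trait_levels)) {
    lv <- trait_levels[[nm]]
    st <- simulate_mk(tree, n_states = length(lv), rate = cfg$mk_rate)
    val <- lv[st]
    override <- stats::runif(cfg$n_species) < cfg$convergence_override
    val[override] <- ring_typical[[nm]][rings[override]]
    traits[[nm]] <- unname(val)
  }
  dens_optima <- c(cfg$density_theta,
                   stats::setNames(mean(cfg$density_theta), mid_regime))
  dens <- if (cfg$alpha > 0)
    simulate_ou_regimes(tree, cfg$density_alpha, cfg$density_sigma2,
                        dens_optima, regime_map,
                        root_value = mean(cfg$density_theta))
  else simulate_bm(tree, cfg$density_sigma2,
                   root = mean(cfg$density_theta))
  traits$nanostructure_density <- pmax(unname(dens[spp]), 0.1)
  traits$scale_density <- pmax(
    unname(simulate_bm(tree, 40000, root = 400)[spp]), 20)
  traits$scale_length <- pmax(
    unname(simulate_bm(tree, 10000, root = 150)[spp]), 20)
  traits$scale_width <- pmax(
    unname(simulate_bm(tree, 400, root = 40)[spp]), 5)
  traits$membrane_thickness <- pmax(
    unname(simulate_bm(tree, 0.15, root = 1.2)[spp]), 0.2)
  traits$structural_syndrome <- paste(traits$scale_type,
                                      traits$nanostructure_type, sep = "/")

  structure(list(tree = tree, rings = rings, spectra = spectra,
                 traits = traits,
                 truth = list(mu = mu, theta = cfg$theta,
                              ring_typical = ring_typical,
                              density_theta = cfg$density_theta,
                              tilt = tilt),
                 config = cfg),
            class = "study_bundle")
}

#' @export
print.study_bundle <- function(x, ...) {
  cat("Synthetic study bundle:", x$config$n_species, "species,",
      length(unique(x$rings)), "mimicry rings,",
      x$config$spots_per_species, "spots/species\n")
  cat("  convergence:",
      if (x$config$alpha > 0) sprintf("OU (alpha = %g)", x$config$alpha)
      else "off (Brownian null)",
      "| discrete override q =", x$config$convergence_override, "\n")
  invisible(x)
}

#' Write a study bundle to plain-text files
#'
#' Emits `spectra.csv`, `tree.nwk`, `rings.csv` and `traits.csv` in the
#' same dialects the package readers consume, plus `truth.json` when
#' jsonlite is available.
#'
#' @param bundle A `"study_bundle"`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_study_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_spectra(bundle$spectra, file.path(dir, "spectra.csv"))
  ape::write.tree(bundle$tree, file.path(dir, "tree.nwk"))
  utils::write.csv(data.frame(species_id = names(bundle$rings),
                              ring = unname(bundle$rings)),
                   file.path(dir, "rings.csv"), row.names = FALSE)
  utils::write.csv(bundle$traits, file.path(dir, "traits.csv"),
                   row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE))
    jsonlite::write_json(bundle$truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Built-in avian visual systems
#'
#' Parametric UVS (blue-tit-like) and VS (shearwater-like) tetrachromatic
#' receptor sets built from A1 pigment templates, with the study's
#' relative cone densities (1:1.9:2.7:2.7 for UVS, 1:0.7:1:1.4 for VS)
#' and Weber fractions (0.1 chromatic, 0.2 achromatic).
#'
#' @param model `"UVS"` or `"VS"`.
#' @param lambda_max Optional length-4 override of the peak wavelengths.
#' @return A `"receptor_set"`.
#' @export
generate_sensitivity_set <- function(model = c("UVS", "VS"),
                                     lambda_max = NULL) {
  model <- match.arg(model)
  defaults <- list(UVS = list(lm = c(371, 448, 503, 563),
                              dens = c(1, 1.9, 2.7, 2.7),
                              labs = c("UVS", "S", "M", "L")),
                   VS = list(lm = c(406, 450, 503, 566),
                             dens = c(1, 0.7, 1, 1.4),
                             labs = c("VS", "S", "M", "L")))
  d <- defaults[[model]]
  lambda_max <- lambda_max %||% d$lm
  if (length(lambda_max) != 4L)
    stop("lambda_max override must have length 4")
  receptors <- Map(pigment_template, lambda_max, d$labs)
  receptor_set(receptors, d$dens, weber_chromatic = 0.1,
               weber_achromatic = 0.2, achromatic_channel = "L",
               name = model)
}

#' Parametric illuminants
#'
#' Stand-ins for the two forest light environments: `"large_gap"` is a
#' broad daylight-like curve; `"forest_shade"` is the large-gap curve
#' filtered through a green canopy window (Gaussian bump centred at
#' 550 nm) and scaled to a quarter of the irradiance; `"flat"` is
#' constant.
#'
#' @param kind `"large_gap"`, `"forest_shade"` or `"flat"`.
#' @return An `"illuminant"`.
#' @export
generate_illuminant <- function(kind = c("large_gap", "forest_shade",
                                         "flat")) {
  kind <- match.arg(kind)
  grid <- canonical_grid()
  u <- (grid - 300) / 400
  large_gap <- 0.55 + 0.65 * stats::plogis((grid - 420) / 45) - 0.15 * u^2
  curve <- switch(kind,
    flat = rep(1, length(grid)),
    large_gap = large_gap,
    forest_shade = 0.25 * large_gap *
      (0.35 + 0.65 * exp(-(grid - 550)^2 / (2 * 60^2))))
  illuminant_spectrum(kind, curve)
}
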