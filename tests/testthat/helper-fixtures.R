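# shared fixtures and independent oracles, all built in code

tri_tree <- function() read_newick(text = "((A:1,B:1):1,C:2);")

star_tree <- function(n, depth = 1) {
  tr <- ape::stree(n, "star")
  tr$edge.length <- rep(depth, nrow(tr$edge))
  tr$tip.label <- sprintf("t%02d", seq_len(n))
  tr
}

const_spec <- function(value, species = "a", spot = 1L) {
  transmittance_spectrum(species, spot, canonical_grid(),
                         rep(value, length(canonical_grid())))
}

# a receptor_catch built directly from catch values
make_catch <- function(q, species = "x", spot = 1L) {
  structure(list(species_id = species, spot_id = spot, q = q, f = log(q)),
            class = "receptor_catch")
}

# independent receptor-noise oracle: noise-weighted distance in
# receptor-contrast space after projecting out the achromatic direction
rnl_quadform_oracle <- function(df, e) {
  iE <- diag(1 / e^2)
  one <- rep(1, length(e))
  Q <- iE - (iE %*% one %*% t(one) %*% iE) / drop(t(one) %*% iE %*% one)
  sqrt(drop(t(df) %*% Q %*% df))
}

# brute-force step-down Holm, straight from the definition
brute_holm <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    val <- min(1, (m - i + 1) * p[ord[i]])
    running <- max(running, val)
    adj[ord[i]] <- running
  }
  adj
}

# symmetric distance matrix from pair values in utils::combn(species, 2)
# order (the order pair_frame() enumerates)
dist_from_pairs <- function(species, values) {
  n <- length(species)
  m <- matrix(0, n, n, dimnames = list(species, species))
  cmb <- utils::combn(species, 2L)
  m[cbind(cmb[1L, ], cmb[2L, ])] <- values
  m[cbind(cmb[2L, ], cmb[1L, ])] <- values
  m
}

# dL distance matrix of a one-spot bundle under one vision model
bundle_dl <- function(bundle, model = "UVS", illum = "large_gap") {
  contrast_matrix(bundle$spectra, generate_illuminant(illum),
                  generate_sensitivity_set(model))$dL
}

five_ring_config <- function(seed, alpha = 0, mode = "random",
                             n_species = 40, q = 0) {
  study_config(n_species = n_species,
               ring_sizes = stats::setNames(rep(n_species / 5, 5),
                                            paste0("ring", 1:5)),
               spots_per_species = 1, alpha = alpha,
               convergence_override = q, ring_assignment_mode = mode,
               seed = seed)
}
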