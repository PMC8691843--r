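#' @title Convergence permutation tests
#' @description Tests of whether co-mimetic species are more similar than
#'   expected at random and than expected given the phylogeny, for
#'   continuous pairwise contrasts (dS, dL), shared discrete structural
#'   traits, and nanostructure-density differences; global and per-ring
#'   variants with Holm correction within test series.
#' @name convergence
NULL

# normalise a ring assignment to a named character vector species -> ring
as_ring_assignment <- function(rings) {
  if (is.data.frame(rings)) {
    if (!all(c("species_id", "ring") %in% names(rings)))
      stop("ring table needs columns species_id and ring")
    out <- stats::setNames(as.character(rings$ring),
                           as.character(rings$species_id))
  } else {
    out <- stats::setNames(as.character(rings), names(rings))
  }
  if (is.null(names(out)) || any(names(out) == ""))
    stop("every species must be named in the ring assignment")
  if (anyDuplicated(names(out)))
    stop("species assigned more than once: ",
         paste(unique(names(out)[duplicated(names(out))]), collapse = ", "))
  sizes <- table(out)
  if (any(sizes == 1L))
    warning("singleton ring(s) cannot be tested: ",
            paste(names(sizes)[sizes == 1L], collapse = ", "))
  out
}

#' Read a species-to-ring assignment from CSV
#'
#' @param path CSV with columns `species_id` and `ring`.
#' @return Named character vector, species to ring label.
#' @export
read_rings <- function(path) {
  as_ring_assignment(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Co-mimetic species pairs
#'
#' All unordered pairs of species assigned to the same mimicry ring; the
#' set over which observed similarity statistics are averaged.
#'
#' @param rings Named character vector (species to ring) or a data frame
#'   with columns `species_id`, `ring`.
#' @return Data frame with columns `species_a`, `species_b`, `ring`.
#' @export
comimic_pairs <- function(rings) {
  r <- as_ring_assignment(rings)
  out <- lapply(sort(unique(r)), function(lab) {
    sp <- sort(names(r)[r == lab])
    if (length(sp) < 2L) return(NULL)
    cmb <- utils::combn(sp, 2L)
    data.frame(species_a = cmb[1L, ], species_b = cmb[2L, ], ring = lab,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE))) %||%
    data.frame(species_a = character(), species_b = character(),
               ring = character())
}

# all unordered pairs among the assigned species, with a comimic indicator
# (optionally restricted to one focal ring)
pair_frame <- function(species, rings, ring = NULL) {
  r <- as_ring_assignment(rings)
  missing <- setdiff(names(r), species)
  if (length(missing))
    stop("distance table does not cover: ", paste(missing, collapse = ", "))
  sp <- sort(names(r))
  cmb <- utils::combn(sp, 2L)
  same <- r[cmb[1L, ]] == r[cmb[2L, ]]
  focal <- if (is.null(ring)) same else same & r[cmb[1L, ]] == ring
  if (!is.null(ring) && sum(r == ring) < 2L)
    stop("ring '", ring, "' has fewer than 2 species")
  data.frame(species_a = cmb[1L, ], species_b = cmb[2L, ],
             comimic = unname(focal), stringsAsFactors = FALSE)
}

perm_test_result <- function(scope, layer, correction, observed, null,
                             pv, n_rand, seed, k, flag = NULL) {
  structure(list(scope = scope, layer = layer, correction = correction,
                 observed = observed,
                 null_mean = mean(null), null_sd = stats::sd(null),
                 p_raw = pv$p_raw, p_plus_one = pv$p_plus_one,
                 p_holm = NA_real_, n_randomisations = n_rand,
                 n_pairs = k, seed = seed, flag = flag),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat("Permutation test [", x$layer, ", ", x$correction, " correction, ",
      x$scope, "]\n", sep = "")
  cat("  observed =", format(x$observed, digits = 4),
      " null =", format(x$null_mean, digits = 4),
      "+/-", format(x$null_sd, digits = 3), "\n")
  cat("  p =", format(x$p_plus_one, digits = 3),
      " (raw ", format(x$p_raw, digits = 3), ", ",
      x$n_randomisations, " randomisations, ", x$n_pairs, " pairs)\n",
      sep = "")
  if (!is.null(x$flag)) cat("  [", x$flag, "]\n")
  invisible(x)
}

# shared engine: mean of `vals` over comimic pairs vs means of k random
# pairs; direction "le" = smaller is extreme, "ge" = larger is extreme
pairwise_perm_test <- function(vals, pf, n_rand, seed, direction,
                               scope, layer, correction,
                               statistic = mean) {
  k <- sum(pf$comimic)
  if (k < 1L) stop("no co-mimetic pairs to test")
  observed <- statistic(vals[pf$comimic])
  seed_if(seed)
  null <- vapply(seq_len(n_rand),
                 function(i) statistic(vals[sample.int(length(vals), k)]),
                 numeric(1))
  pv <- perm_pvalues(null, observed, direction)
  perm_test_result(scope, layer, correction, observed, null, pv,
                   n_rand, seed, k)
}

#' Similarity test: are co-mimics more alike than random pairs?
#'
#' The observed mean pairwise distance (chromatic or achromatic contrast,
#' or any non-negative dissimilarity) over co-mimetic pairs is compared
#' with the distribution of the mean of equally many pairs drawn at random
#' from all unordered pairs (equivalently, of the distance values permuted
#' over pairs). Small p means co-mimics are more similar than expected at
#' random, irrespective of the evolutionary mechanism.
#'
#' @param d Symmetric distance matrix with species dimnames.
#' @param rings Ring assignment (named vector or data frame).
#' @param n_rand Number of randomisations (10,000 by default, matching the
#'   published procedure).
#' @param seed Optional integer seed.
#' @param ring Optional focal ring label for the per-ring variant: the
#'   observed mean is over that ring's pairs and the null draws the same
#'   number of pairs.
#' @param layer Label stored in the result (e.g. `"dS"`, `"dL"`).
#' @return A `"perm_test"` object.
#' @export
similarity_test <- function(d, rings, n_rand = 10000, seed = NULL,
                            ring = NULL, layer = "distance") {
  pf <- pair_frame(rownames(d), rings, ring)
  vals <- d[cbind(pf$species_a, pf$species_b)]
  pairwise_perm_test(vals, pf, n_rand, seed, "le",
                     scope = ring %||% "global", layer = layer,
                     correction = "none")
}

#' Phylogeny-corrected convergence test
#'
#' Phenotypic distance is regressed (ordinary least squares) on patristic
#' distance over all unordered pairs; pairs below the regression line are
#' more similar than their phylogenetic distance predicts. The observed
#' mean residual over co-mimetic pairs is compared with means of equally
#' many residuals drawn at random. Small p indicates convergence beyond
#' shared ancestry.
#'
#' @inheritParams similarity_test
#' @param phylo_d Patristic distance matrix covering the same species.
#' @return A `"perm_test"` object; also carries the regression slope and
#'   intercept as attributes.
#' @export
phylo_corrected_test <- function(d, phylo_d, rings, n_rand = 10000,
                                 seed = NULL, ring = NULL,
                                 layer = "distance") {
  pf <- pair_frame(rownames(d), rings, ring)
  if (nrow(pf) < 3L) stop("need at least 3 species pairs")
  y <- d[cbind(pf$species_a, pf$species_b)]
  x <- phylo_d[cbind(pf$species_a, pf$species_b)]
  fit <- stats::lm.fit(cbind(1, x), y)
  res <- fit$residuals
  out <- pairwise_perm_test(res, pf, n_rand, seed, "le",
                            scope = ring %||% "global", layer = layer,
                            correction = "phylogenetic")
  attr(out, "intercept") <- unname(fit$coefficients[1L])
  attr(out, "slope") <- unname(fit$coefficients[2L])
  out
}

#' Structure-sharing similarity test
#'
#' Counts co-mimetic pairs sharing the same level of a categorical
#' structural trait and compares the count with that of equally many
#' random pairs. Large counts (small p) mean co-mimics share structures
#' more than expected at random.
#'
#' @param trait Named categorical vector (species to level).
#' @inheritParams similarity_test
#' @return A `"perm_test"` object (observed value is a count).
#' @export
sharing_similarity_test <- function(trait, rings, n_rand = 10000,
                                    seed = NULL, ring = NULL,
                                    layer = "sharing") {
  r <- as_ring_assignment(rings)
  trait <- trait[names(r)]
  if (anyNA(trait)) stop("trait must be defined for every assigned species")
  pf <- pair_frame(names(r), rings, ring)
  ind <- as.numeric(trait[pf$species_a] == trait[pf$species_b])
  if (all(ind == 1)) {
    k <- sum(pf$comimic)
    res <- perm_test_result(ring %||% "global", layer, "none",
                            observed = k, null = rep(k, 2L),
                            pv = list(p_raw = 1, p_plus_one = 1),
                            n_rand, seed, k, flag = "constant trait")
    warning("trait is constant; sharing test is degenerate (p = 1)")
    return(res)
  }
  pairwise_perm_test(ind, pf, n_rand, seed, "ge",
                     scope = ring %||% "global", layer = layer,
                     correction = "none", statistic = sum)
}

#' Structure-sharing convergence test
#'
#' A binomial GLM links the pairwise sharing indicator to patristic
#' distance; the observed mean model residual over co-mimetic pairs is
#' compared with means of randomly drawn residuals. Positive residuals
#' mean more sharing than the phylogenetic distance predicts, so large
#' observed means (small p) indicate convergence.
#'
#' @inheritParams sharing_similarity_test
#' @param phylo_d Patristic distance matrix.
#' @param residual_type `"response"` (default) or `"deviance"`.
#' @return A `"perm_test"` object. Complete separation is flagged and
#'   reported observed-only (p = NA).
#' @export
sharing_convergence_test <- function(trait, phylo_d, rings, n_rand = 10000,
                                     seed = NULL, ring = NULL,
                                     layer = "sharing",
                                     residual_type = c("response", "deviance")) {
  residual_type <- match.arg(residual_type)
  r <- as_ring_assignment(rings)
  trait <- trait[names(r)]
  if (anyNA(trait)) stop("trait must be defined for every assigned species")
  pf <- pair_frame(names(r), rings, ring)
  ind <- as.numeric(trait[pf$species_a] == trait[pf$species_b])
  x <- phylo_d[cbind(pf$species_a, pf$species_b)]
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(ind ~ x, family = stats::binomial(),
               control = stats::glm.control(maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (length(unique(ind)) == 1L) separated <- TRUE
  if (!fit$converged && !separated)
    stop("binomial GLM did not converge within 100 iterations")
  res <- stats::residuals(fit, type = residual_type)
  if (separated) {
    k <- sum(pf$comimic)
    obs <- mean(res[pf$comimic])
    out <- perm_test_result(ring %||% "global", layer, "phylogenetic",
                            observed = obs, null = rep(obs, 2L),
                            pv = list(p_raw = NA_real_,
                                      p_plus_one = NA_real_),
                            n_rand, seed, k, flag = "complete separation")
    return(out)
  }
  pairwise_perm_test(res, pf, n_rand, seed, "ge",
                     scope = ring %||% "global", layer = layer,
                     correction = "phylogenetic")
}

#' Nanostructure-density convergence tests
#'
#' Builds the pairwise absolute density-difference table and applies both
#' the uncorrected similarity test (smaller mean difference among
#' co-mimics) and the phylogeny-corrected residual test (linear model of
#' density difference on patristic distance; smaller mean residual among
#' co-mimics).
#'
#' @param x Named numeric vector of nanostructure densities per species.
#' @inheritParams phylo_corrected_test
#' @return List with elements `similarity` and `convergence`, both
#'   `"perm_test"` objects.
#' @export
density_convergence_test <- function(x, phylo_d, rings, n_rand = 10000,
                                     seed = NULL, ring = NULL,
                                     layer = "nanostructure_density") {
  r <- as_ring_assignment(rings)
  x <- x[names(r)]
  if (anyNA(x)) stop("density must be defined for every assigned species")
  d <- abs(outer(x, x, "-"))
  dimnames(d) <- list(names(r), names(r))
  list(similarity = similarity_test(d, rings, n_rand, seed, ring, layer),
       convergence = phylo_corrected_test(d, phylo_d, rings, n_rand,
                                          seed, ring, layer))
}

#' Holm multiple-testing correction
#'
#' Step-down Holm adjustment (sort ascending, multiply the i-th smallest
#' by m - i + 1, enforce a running maximum, cap at 1).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
holm_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "holm")
}

# one result row for the suite table
as_suite_row <- function(t, spot = NA, visual_system = NA, illuminant = NA,
                         family = NA) {
  data.frame(scope = t$scope, layer = t$layer, spot = spot,
             visual_system = visual_system, illuminant = illuminant,
             correction = t$correction, observed = t$observed,
             null_mean = t$null_mean, null_sd = t$null_sd,
             p_raw = t$p_raw, p_plus_one = t$p_plus_one,
             n_randomisations = t$n_randomisations, n_pairs = t$n_pairs,
             family = family, stringsAsFactors = FALSE)
}

#' Run the full convergence test battery
#'
#' Executes the global and per-ring similarity and phylogeny-corrected
#' tests for every contrast table (layer dS and dL, per spot, visual
#' system and illuminant), every categorical structural trait, and
#' nanostructure density. Holm families follow the published grouping:
#' one series is fixed (correction, layer, spot, visual system,
#' illuminant) and is adjusted across the rings within it; global tests
#' are adjusted across spots within (correction, layer, visual system,
#' illuminant). Family membership is recorded per row so users can
#' re-group.
#'
#' @param contrasts List of `"contrast_tables"` objects (one per spot x
#'   visual system x illuminant combination).
#' @param traits Optional named list of categorical trait vectors.
#' @param density Optional named numeric vector of nanostructure density.
#' @param phylo_d Patristic distance matrix.
#' @param rings Ring assignment.
#' @param n_rand Randomisations per test.
#' @param seed Master seed; per-test seeds are derived deterministically.
#' @param per_ring If `TRUE` (default) also run every testable ring.
#' @return Data frame of class `"convergence_suite"`, one row per test,
#'   with `p_holm` filled within families.
#' @export
run_convergence_suite <- function(contrasts, traits = NULL, density = NULL,
                                  phylo_d, rings, n_rand = 1000,
                                  seed = 1, per_ring = TRUE) {
  r <- as_ring_assignment(rings)
  sizes <- table(r)
  testable <- if (per_ring) names(sizes)[sizes >= 2L] else character(0)
  rows <- list()
  counter <- 0L
  next_seed <- function() {
    counter <<- counter + 1L
    (seed + counter * 10007L) %% .Machine$integer.max
  }
  add <- function(t, ...) rows[[length(rows) + 1L]] <<- as_suite_row(t, ...)

  for (ct in contrasts) {
    for (layer in c("dS", "dL")) {
      d <- ct[[layer]]
      fam_global <- paste("global", "none", layer, ct$visual_system,
                          ct$illuminant, sep = "|")
      add(similarity_test(d, r, n_rand, next_seed(), layer = layer),
          spot = ct$spot, visual_system = ct$visual_system,
          illuminant = ct$illuminant, family = fam_global)
      fam_globalc <- paste("global", "phylo", layer, ct$visual_system,
                           ct$illuminant, sep = "|")
      add(phylo_corrected_test(d, phylo_d, r, n_rand, next_seed(),
                               layer = layer),
          spot = ct$spot, visual_system = ct$visual_system,
          illuminant = ct$illuminant, family = fam_globalc)
      fam_ring <- paste("rings", "none", layer, ct$spot, ct$visual_system,
                        ct$illuminant, sep = "|")
      fam_ringc <- paste("rings", "phylo", layer, ct$spot,
                         ct$visual_system, ct$illuminant, sep = "|")
      for (rg in testable) {
        add(similarity_test(d, r, n_rand, next_seed(), ring = rg,
                            layer = layer),
            spot = ct$spot, visual_system = ct$visual_system,
            illuminant = ct$illuminant, family = fam_ring)
        add(phylo_corrected_test(d, phylo_d, r, n_rand, next_seed(),
                                 ring = rg, layer = layer),
            spot = ct$spot, visual_system = ct$visual_system,
            illuminant = ct$illuminant, family = fam_ringc)
      }
    }
  }

  for (nm in names(traits)) {
    tr <- traits[[nm]]
    add(sharing_similarity_test(tr, r, n_rand, next_seed(), layer = nm),
        family = paste("global", "none", "traits", sep = "|"))
    add(sharing_convergence_test(tr, phylo_d, r, n_rand, next_seed(),
                                 layer = nm),
        family = paste("global", "phylo", "traits", sep = "|"))
    for (rg in testable) {
      add(sharing_similarity_test(tr, r, n_rand, next_seed(), ring = rg,
                                  layer = nm),
          family = paste("rings", "none", nm, sep = "|"))
      add(sharing_convergence_test(tr, phylo_d, r, n_rand, next_seed(),
                                   ring = rg, layer = nm),
          family = paste("rings", "phylo", nm, sep = "|"))
    }
  }

  if (!is.null(density)) {
    dt <- density_convergence_test(density, phylo_d, r, n_rand, next_seed())
    add(dt$similarity, family = "global|none|traits")
    add(dt$convergence, family = "global|phylo|traits")
    for (rg in testable) {
      dtr <- density_convergence_test(density, phylo_d, r, n_rand,
                                      next_seed(), ring = rg)
      add(dtr$similarity,
          family = paste("rings", "none", "nanostructure_density", sep = "|"))
      add(dtr$convergence,
          family = paste("rings", "phylo", "nanostructure_density", sep = "|"))
    }
  }

  out <- do.call(rbind, rows)
  out$p_holm <- NA_real_
  for (f in unique(out$family)) {
    i <- which(out$family == f & !is.na(out$p_plus_one))
    out$p_holm[i] <- holm_adjust(out$p_plus_one[i])
  }
  out$master_seed <- seed
  class(out) <- c("convergence_suite", class(out))
  out
}
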