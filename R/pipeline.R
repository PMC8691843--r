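#' Run the full analysis pipeline on a study bundle
#'
#' Orchestrates the end-to-end analysis: spectrum smoothing, mean
#' transmittance, the four vision models (UVS/VS crossed with forest
#' shade and large gap) per analogous spot, the convergence test battery
#' (contrasts, structural traits, nanostructure density), phylogenetic
#' signal for every trait, the phylogenetic ANOVA of nanostructure
#' density on nanostructure type, and PGLS all-subsets selection of the
#' structure-transmittance link. Deterministic given the seed. Partial
#' failures leave completed stages in place with a failure marker in the
#' manifest.
#'
#' @param bundle A `"study_bundle"` (from [generate_study()]) or a list
#'   with elements `tree`, `rings`, `spectra`, `traits` read from files.
#' @param n_rand Randomisations per permutation test (10,000 matches the
#'   published procedure; reduce for quick runs).
#' @param n_rand_delta Tip randomisations for the delta statistic null.
#' @param seed Master seed; all stage seeds derive from it.
#' @param smooth_span Smoothing span for the spectra.
#' @param per_ring Run the per-ring convergence variants as well.
#' @param out_dir Optional directory; when given, result tables are
#'   written there as CSV along with a JSON manifest.
#' @return A list of class `"pipeline_run"` with `mean_transmittance`,
#'   `contrasts`, `convergence`, `signal`, `anova`, `pgls` and
#'   `manifest`.
#' @export
run_all <- function(bundle, n_rand = 10000, n_rand_delta = 99, seed = 1,
                    smooth_span = 0.25, per_ring = TRUE, out_dir = NULL) {
  tree <- bundle$tree
  rings <- as_ring_assignment(bundle$rings)
  traits <- bundle$traits
  spectra <- bundle$spectra
  spp_tree <- tree$tip.label
  spp_spec <- unique(vapply(spectra, `[[`, character(1), "species_id"))
  spp_traits <- traits$species_id
  mism <- c(setdiff(spp_spec, spp_tree), setdiff(spp_tree, spp_spec),
            setdiff(names(rings), spp_tree), setdiff(spp_tree, names(rings)),
            setdiff(spp_traits, spp_tree), setdiff(spp_tree, spp_traits))
  if (length(mism))
    stop("species sets differ across inputs: ",
         paste(unique(mism), collapse = ", "))

  manifest <- list(seed = seed, n_rand = n_rand, stages = list(),
                   warnings = character(0))
  stamp <- function(name, nrows) {
    manifest$stages[[name]] <<- list(status = "complete", rows = nrows)
  }

  # 1. smoothing -----------------------------------------------------
  smoothed <- lapply(spectra, smooth_spectrum, span = smooth_span)
  stamp("smooth", length(smoothed))

  # 2. mean transmittance --------------------------------------------
  mt_rows <- do.call(rbind, lapply(smoothed, function(s)
    data.frame(species_id = s$species_id, spot_id = s$spot_id,
               mean_transmittance = mean_transmittance(s))))
  mt_species <- tapply(mt_rows$mean_transmittance, mt_rows$species_id, mean)
  mt_species <- stats::setNames(as.numeric(mt_species), names(mt_species))
  stamp("mean_transmittance", nrow(mt_rows))

  # 3. vision models ---------------------------------------------------
  systems <- list(UVS = generate_sensitivity_set("UVS"),
                  VS = generate_sensitivity_set("VS"))
  illums <- list(forest_shade = generate_illuminant("forest_shade"),
                 large_gap = generate_illuminant("large_gap"))
  spots <- sort(unique(vapply(smoothed, `[[`, integer(1), "spot_id")))
  contrasts <- list()
  for (vs in names(systems)) for (il in names(illums)) for (sp in spots) {
    sel <- Filter(function(s) s$spot_id == sp, smoothed)
    contrasts[[length(contrasts) + 1L]] <-
      contrast_matrix(sel, illums[[il]], systems[[vs]])
  }
  stamp("contrasts", length(contrasts))

  # 4. convergence battery ---------------------------------------------
  phylo_d <- patristic_distances(tree)
  cat_traits <- list(scale_type = stats::setNames(traits$scale_type,
                                                  traits$species_id),
                     nanostructure_type = stats::setNames(
                       traits$nanostructure_type, traits$species_id),
                     structural_syndrome = stats::setNames(
                       traits$structural_syndrome, traits$species_id))
  density <- stats::setNames(traits$nanostructure_density,
                             traits$species_id)
  suite <- run_convergence_suite(contrasts, cat_traits, density, phylo_d,
                                 rings, n_rand = n_rand, seed = seed,
                                 per_ring = per_ring)
  stamp("convergence", nrow(suite))

  # 5. phylogenetic signal ----------------------------------------------
  cont <- list(mean_transmittance = mt_species)
  for (nm in c("scale_density", "scale_length", "scale_width",
               "nanostructure_density", "membrane_thickness"))
    cont[[nm]] <- stats::setNames(traits[[nm]], traits$species_id)
  signal <- list()
  sseed <- seed + 101L
  for (nm in names(cont)) {
    signal[[paste0("lambda.", nm)]] <- pagel_lambda(tree, cont[[nm]])
    signal[[paste0("K.", nm)]] <- blomberg_k(tree, cont[[nm]],
                                             n_perm = 999, seed = sseed)
    sseed <- sseed + 1L
  }
  for (nm in c("scale_type", "nanostructure_type")) {
    signal[[paste0("delta.", nm)]] <-
      delta_categorical(tree, cat_traits[[nm]],
                        mcmc = list(iterations = 4000, burn_in = 0.1,
                                    thinning = 5),
                        n_rand = n_rand_delta, seed = sseed)
    sseed <- sseed + 1L
  }
  sc <- stats::setNames(as.integer(traits$scale_colour == "transparent"),
                        traits$species_id)
  signal$D.scale_colour <- if (length(unique(sc)) == 2L)
    fritz_purvis_d(tree, sc, n_sim = 500, seed = sseed) else NULL
  stamp("signal", length(Filter(Negate(is.null), signal)))

  # 6. phylogenetic ANOVA of nanostructure density on type --------------
  # levels represented by a single species carry no within-group variance
  # and are dropped (with a note) before testing
  nt <- stats::setNames(traits$nanostructure_type, traits$species_id)
  keep_lv <- names(which(table(nt) >= 2L))
  if (length(keep_lv) < length(unique(nt)))
    manifest$warnings <- c(manifest$warnings,
                           paste("phylo_anova: dropped singleton type(s):",
                                 paste(setdiff(unique(nt), keep_lv),
                                       collapse = ", ")))
  keep_sp <- names(nt)[nt %in% keep_lv]
  anova_res <- tryCatch(
    phylo_anova(ape::keep.tip(tree, keep_sp), density[keep_sp],
                nt[keep_sp], n_sim = 999, seed = seed + 997L),
    error = function(e) {
      manifest$warnings <<- c(manifest$warnings, conditionMessage(e))
      NULL
    })
  stamp("phylo_anova", if (is.null(anova_res)) 0L else 1L)

  # 7. PGLS model selection ---------------------------------------------
  mains <- c("scale_type", "scale_colour", "scale_density", "scale_length",
             "scale_width", "nanostructure_type", "nanostructure_density",
             "membrane_thickness")
  inter <- c("scale_type:scale_density",
             "scale_density:nanostructure_density",
             "scale_density:scale_length:scale_width")
  models <- enumerate_models(mains, inter,
                             exclusions = list(c("nanostructure_type",
                                                 "nanostructure_density")))
  fits <- fit_model_set(tree, mt_species, traits, models, lambda = "ML")
  selection <- select_models(fits, delta = 2)
  stamp("pgls", length(models))

  run <- structure(list(mean_transmittance = mt_rows,
                        mean_transmittance_species = mt_species,
                        contrasts = contrasts, convergence = suite,
                        signal = signal, anova = anova_res,
                        pgls = selection, manifest = manifest),
                   class = "pipeline_run")
  if (!is.null(out_dir)) write_pipeline_run(run, out_dir)
  run
}

write_pipeline_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(run$mean_transmittance,
                   file.path(out_dir, "mean_transmittance.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(run$convergence),
                   file.path(out_dir, "convergence_tests.csv"),
                   row.names = FALSE)
  utils::write.csv(run$pgls$aicc_table,
                   file.path(out_dir, "pgls_models.csv"), row.names = FALSE)
  sig <- do.call(rbind, lapply(names(run$signal), function(nm) {
    s <- run$signal[[nm]]
    if (is.null(s)) return(NULL)
    data.frame(test = nm, statistic = s$statistic, estimate = s$estimate,
               p_value = s$p_value %||% NA_real_)
  }))
  utils::write.csv(sig, file.path(out_dir, "signal.csv"), row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE))
    jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("Pipeline run:", length(x$manifest$stages), "stages complete\n")
  cat("  mean transmittance:",
      format(100 * mean(x$mean_transmittance_species), digits = 3),
      "% (community mean)\n")
  cat("  convergence tests:", nrow(x$convergence), "rows |",
      "PGLS models:", nrow(x$pgls$aicc_table),
      "| retained:", length(x$pgls$retained), "\n")
  invisible(x)
}

#' Per-ring verdict table
#'
#' Classifies every (ring, layer) cell of a convergence-suite table using
#' Holm-adjusted p-values, mirroring the four-way categorisation of
#' similarity (uncorrected test) crossed with convergence
#' (phylogeny-corrected test): `"neither"`, `"similar"` (similar at
#' random only), `"convergent"` (corrected only) or
#' `"similar+convergent"`.
#'
#' @param suite A `"convergence_suite"` data frame.
#' @param alpha Significance level (default 0.05).
#' @return Data frame with one row per ring x layer (x spot, visual
#'   system, illuminant where applicable) and a `verdict` column.
#' @export
report <- function(suite, alpha = 0.05) {
  stopifnot(inherits(suite, "convergence_suite") || is.data.frame(suite))
  if (nrow(suite) == 0L) stop("empty results: nothing to report")
  rings <- suite[suite$scope != "global", , drop = FALSE]
  if (nrow(rings) == 0L) stop("no per-ring results to report")
  key <- c("scope", "layer", "spot", "visual_system", "illuminant")
  id <- do.call(paste, c(rings[key], sep = "|"))
  out <- do.call(rbind, lapply(split(rings, id), function(g) {
    sim <- g$p_holm[g$correction == "none"]
    con <- g$p_holm[g$correction == "phylogenetic"]
    sim_sig <- length(sim) > 0 && !is.na(sim[1L]) && sim[1L] <= alpha
    con_sig <- length(con) > 0 && !is.na(con[1L]) && con[1L] <= alpha
    verdict <- if (sim_sig && con_sig) "similar+convergent"
    else if (con_sig) "convergent"
    else if (sim_sig) "similar"
    else "neither"
    data.frame(g[1L, key, drop = FALSE], verdict = verdict,
               p_similarity = if (length(sim)) sim[1L] else NA_real_,
               p_convergence = if (length(con)) con[1L] else NA_real_,
               row.names = NULL)
  }))
  rownames(out) <- NULL
  out
}
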