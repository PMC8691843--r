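#' @title Phylogenetic generalised least squares and model selection
#' @description Links mean transmittance (or any continuous species trait)
#'   to structural predictors while accounting for phylogeny: GLS with a
#'   Pagel's-lambda residual covariance, AICc, all-subsets model
#'   enumeration under exclusion and marginality constraints, and
#'   retention of models within a delta-AICc window.
#' @name pgls
NULL

# variables entering a term ("a:b" -> c("a", "b"))
term_vars <- function(term) strsplit(term, ":", fixed = TRUE)[[1L]]

# every lower-order term implied by an interaction under marginality;
# a triple interaction implies all mains and all pairwise products
implied_terms <- function(term) {
  v <- term_vars(term)
  if (length(v) == 1L) return(character(0))
  out <- v
  if (length(v) >= 3L) {
    cmb <- utils::combn(v, 2L)
    out <- c(out, apply(cmb, 2L, paste, collapse = ":"))
  }
  out
}

# canonical form so "b:a" matches "a:b"
canon_term <- function(term) {
  vapply(term, function(t) paste(sort(term_vars(t)), collapse = ":"),
         character(1), USE.NAMES = FALSE)
}

#' Design matrix for a structural term set
#'
#' Treatment (dummy) coding with the alphabetically first level of each
#' categorical variable as reference; continuous variables enter unscaled
#' and uncentred; interaction columns are elementwise products. Enforces
#' marginality: an interaction may only appear with all the terms it
#' implies.
#'
#' @param traits Data frame of structural measurements, one row per
#'   species, with a `species_id` column or species row names.
#' @param terms Character vector of term labels, e.g.
#'   `c("scale_type", "scale_density", "scale_density:nanostructure_density")`.
#'   Empty for an intercept-only design.
#' @return List with the model matrix `X` (rows named by species), the
#'   term vector, and the `assign` map of columns to terms.
#' @export
design_matrix <- function(traits, terms = character(0)) {
  traits <- as.data.frame(traits)
  if ("species_id" %in% names(traits)) {
    rownames(traits) <- traits$species_id
    traits$species_id <- NULL
  }
  terms <- canon_term(terms)
  vars <- unique(unlist(lapply(terms, term_vars)))
  unknown <- setdiff(vars, names(traits))
  if (length(unknown))
    stop("unknown term variable(s): ", paste(unknown, collapse = ", "))
  for (term in terms) {
    need <- setdiff(canon_term(implied_terms(term)), terms)
    if (length(need))
      stop("marginality violation: '", term, "' requires ",
           paste(need, collapse = ", "))
  }
  if (length(vars)) {
    bad <- rownames(traits)[!stats::complete.cases(traits[, vars, drop = FALSE])]
    if (length(bad))
      stop("missing structural values for: ", paste(bad, collapse = ", "))
  }
  for (v in vars) if (!is.numeric(traits[[v]]))
    traits[[v]] <- factor(traits[[v]], levels = sort(unique(as.character(traits[[v]]))))
  f <- if (length(terms)) stats::reformulate(terms) else ~ 1
  X <- stats::model.matrix(f, data = traits)
  rownames(X) <- rownames(traits)
  list(X = X, terms = terms, assign = attr(X, "assign"))
}

# log-likelihood and GLS fit pieces for a fixed covariance V
gls_fit_V <- function(y, X, V) {
  n <- length(y)
  U <- chol(V)
  wy <- backsolve(U, y, transpose = TRUE)
  wX <- backsolve(U, X, transpose = TRUE)
  qr_ <- qr(wX)
  if (qr_$rank < ncol(wX)) {
    keep <- qr_$pivot[seq_len(qr_$rank)]
    stop("singular design: collinear column(s) ",
         paste(colnames(X)[-keep], collapse = ", "))
  }
  beta <- qr.coef(qr_, wy)
  res_w <- wy - wX %*% beta
  rss <- sum(res_w^2)
  s2_ml <- rss / n
  ll <- -n / 2 * log(2 * pi * s2_ml) - sum(log(diag(U))) - n / 2
  list(beta = beta, rss = rss, loglik = ll, U = U, wX = wX, wy = wy,
       qr = qr_)
}

#' Fit a phylogenetic generalised least squares model
#'
#' GLS regression with residual covariance `sigma2 * C(lambda)`, where
#' `C(lambda)` is the phylogenetic covariance with off-diagonals scaled by
#' Pagel's lambda. Lambda is either profiled by maximum likelihood over
#' `[0, 1]` or fixed. R-squared is computed from whitened residual and
#' total sums of squares against the intercept-only GLS null under the
#' same covariance.
#'
#' @param tree An [ape::phylo] tree.
#' @param y Named response vector (e.g. mean transmittance per species).
#' @param X Design matrix from [design_matrix()] (rows named by species,
#'   including an intercept column), or a `design_matrix()` result list.
#' @param lambda `"ML"` (default) or a fixed value in `[0, 1]`.
#' @return An object of class `"pgls_fit"`.
#' @export
pgls_fit <- function(tree, y, X, lambda = "ML") {
  if (is.list(X) && !is.null(X$X)) { terms <- X$terms; X <- X$X }
  else terms <- colnames(X)
  spp <- tree$tip.label
  if (!setequal(names(y), spp) || !setequal(rownames(X), spp))
    stop("species mismatch between tree, response and design: ",
         paste(union(setdiff(names(y), spp), setdiff(spp, names(y))),
               collapse = ", "))
  y <- y[spp]; X <- X[spp, , drop = FALSE]
  n <- length(y)
  C <- phylo_vcv(tree)
  star <- max(abs(C[upper.tri(C)])) < 1e-12 * max(diag(C))
  estimated <- identical(lambda, "ML")
  if (estimated) {
    if (star) {
      lam <- 0
      flag <- "lambda unidentifiable on a star tree; reported as 0"
    } else {
      llf <- function(l) gls_fit_V(y, X, lambda_transform(C, l))$loglik
      opt <- stats::optimize(llf, c(0, 1), maximum = TRUE, tol = 1e-8)
      cand <- c(opt$maximum, 0, 1)
      lls <- c(opt$objective, llf(0), llf(1))
      lam <- cand[which.max(lls)]
      flag <- NULL
    }
  } else {
    stopifnot(is.numeric(lambda), lambda >= 0, lambda <= 1)
    lam <- lambda
    flag <- if (star) "star tree" else NULL
  }
  V <- lambda_transform(C, lam)
  fit <- gls_fit_V(y, X, V)
  p_coef <- ncol(X)
  k <- p_coef + 1L + as.integer(estimated)  # + sigma2 (+ lambda if ML)
  # intercept-only GLS null under the same covariance
  null <- gls_fit_V(y, matrix(1, n, 1, dimnames = list(spp, "(Intercept)")), V)
  r2 <- 1 - fit$rss / null$rss
  p_pred <- p_coef - 1L
  r2_adj <- 1 - (1 - r2) * (n - 1) / (n - p_pred - 1)
  s2_u <- fit$rss / (n - p_coef)
  XtViX_inv <- chol2inv(qr.R(fit$qr))
  se <- sqrt(pmax(diag(XtViX_inv), 0) * s2_u)
  tval <- drop(fit$beta) / se
  pval <- 2 * stats::pt(abs(tval), df = n - p_coef, lower.tail = FALSE)
  fstat <- if (p_pred > 0)
    ((null$rss - fit$rss) / p_pred) / (fit$rss / (n - p_coef)) else NA_real_
  fitted <- drop(X %*% fit$beta)
  structure(list(coefficients = stats::setNames(drop(fit$beta), colnames(X)),
                 se = stats::setNames(se, colnames(X)),
                 t_value = tval, p_coef_value = pval,
                 lambda = lam, lambda_mode = if (estimated) "ML" else "fixed",
                 sigma2 = fit$rss / n, log_likelihood = fit$loglik,
                 aicc = if (n - k - 1 > 0) aicc_value(fit$loglik, k, n)
                        else NA_real_,  # finite only when n - k - 1 > 0
                 r2 = r2, r2_adjusted = r2_adj,
                 fstat = fstat, df1 = p_pred, df2 = n - p_coef,
                 n = n, k = k, terms = terms,
                 residuals = stats::setNames(y - fitted, spp),
                 fitted = stats::setNames(fitted, spp),
                 flag = flag),
            class = "pgls_fit")
}

aicc_value <- function(loglik, k, n) {
  if (n - k - 1 <= 0) stop("AICc undefined: n - k - 1 <= 0")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Small-sample corrected AIC
#'
#' `AICc = -2 logLik + 2k + 2k(k + 1)/(n - k - 1)` with `k` the parameter
#' count (coefficients + sigma2, + lambda when estimated).
#'
#' @param fit A `"pgls_fit"` object, or any list with elements
#'   `log_likelihood`, `k`, `n`.
#' @return AICc value.
#' @export
aicc <- function(fit) {
  stopifnot(!is.null(fit$log_likelihood), !is.null(fit$k), !is.null(fit$n))
  if (fit$k < 2) stop("k must count at least the intercept and sigma2")
  aicc_value(fit$log_likelihood, fit$k, fit$n)
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat("PGLS fit (lambda =", format(x$lambda, digits = 3),
      paste0("[", x$lambda_mode, "]"),
      ") n =", x$n, " k =", x$k, "\n")
  tab <- cbind(Estimate = x$coefficients, `Std.Error` = x$se,
               t = x$t_value, p = x$p_coef_value)
  print(round(tab, 4))
  cat("logLik =", format(x$log_likelihood, digits = 6),
      " AICc =", format(x$aicc, digits = 6),
      " R2adj =", format(x$r2_adjusted, digits = 3), "\n")
  if (!is.null(x$fstat) && !is.na(x$fstat))
    cat("F(", x$df1, ",", x$df2, ") =", format(x$fstat, digits = 4), "\n")
  if (!is.null(x$flag)) cat("[", x$flag, "]\n")
  invisible(x)
}

#' @export
summary.pgls_fit <- function(object, ...) object

#' @export
coef.pgls_fit <- function(object, ...) object$coefficients

#' @export
residuals.pgls_fit <- function(object, ...) object$residuals

#' @export
fitted.pgls_fit <- function(object, ...) object$fitted

#' @export
logLik.pgls_fit <- function(object, ...) {
  structure(object$log_likelihood, df = object$k, class = "logLik")
}

#' Enumerate candidate model term sets
#'
#' All subsets of the declared main effects and interactions that satisfy
#' the exclusion constraints (pairs of variables too correlated to enter
#' one model together) and marginality (an interaction brings every term
#' it implies). Deterministic ordering: by model size, then
#' lexicographically.
#'
#' @param mains Character vector of main-effect variables.
#' @param interactions Character vector of interaction terms (`"a:b"`,
#'   `"a:b:c"`).
#' @param exclusions List of length-2 character vectors of variables
#'   forbidden to co-occur.
#' @param marginality Enforce marginality (default `TRUE`).
#' @return List of character term vectors, the first being `character(0)`
#'   (the intercept-only model).
#' @export
enumerate_models <- function(mains, interactions = character(0),
                             exclusions = list(), marginality = TRUE) {
  terms <- c(mains, canon_term(interactions))
  known_vars <- unique(unlist(lapply(terms, term_vars)))
  for (ex in exclusions) {
    if (length(ex) != 2L) stop("each exclusion must name exactly 2 variables")
    if (!all(ex %in% known_vars))
      stop("exclusion references unknown variable(s): ",
           paste(setdiff(ex, known_vars), collapse = ", "))
  }
  m <- length(terms)
  keep <- list()
  for (code in seq_len(2^m) - 1L) {
    sel <- terms[bitwAnd(bitwShiftR(code, seq_len(m) - 1L), 1L) == 1L]
    if (marginality) {
      ok <- all(vapply(sel, function(t)
        all(canon_term(implied_terms(t)) %in% sel), logical(1)))
      if (!ok) next
    }
    vars <- unique(unlist(lapply(sel, term_vars)))
    bad <- any(vapply(exclusions, function(ex) all(ex %in% vars), logical(1)))
    if (bad) next
    keep[[length(keep) + 1L]] <- sel
  }
  ord <- order(lengths(keep),
               vapply(keep, function(s) paste(sort(s), collapse = "+"),
                      character(1)))
  keep[ord]
}

#' Fit every candidate model
#'
#' @param tree An [ape::phylo] tree.
#' @param y Named response vector.
#' @param traits Structural trait data frame.
#' @param models List of term sets from [enumerate_models()].
#' @param lambda `"ML"` or fixed value, passed to [pgls_fit()].
#' @return List of `"pgls_fit"` objects, named by their formulas.
#'   Candidate models that cannot be fitted (rank-deficient designs on
#'   small communities) are dropped with a message.
#' @export
fit_model_set <- function(tree, y, traits, models, lambda = "ML") {
  fits <- lapply(models, function(terms)
    tryCatch(pgls_fit(tree, y, design_matrix(traits, terms),
                      lambda = lambda),
             error = function(e) e))
  names(fits) <- vapply(models, function(s)
    if (length(s)) paste(s, collapse = " + ") else "1", character(1))
  bad <- vapply(fits, inherits, logical(1), "error")
  if (any(bad))
    message(sum(bad), " candidate model(s) could not be fitted and were ",
            "dropped: ", paste(utils::head(names(fits)[bad], 3),
                               collapse = "; "),
            if (sum(bad) > 3) " ..." else "")
  fits[!bad]
}

#' Retain models within a delta-AICc window
#'
#' Keeps every fit whose AICc is within `delta` of the minimum, sorted
#' ascending, and summarises how often each term is retained, the sign of
#' its (first) coefficient and whether it is significant at 0.05 in each
#' retained model.
#'
#' @param fits List of `"pgls_fit"` objects (e.g. from [fit_model_set()]).
#' @param delta AICc window (default 2).
#' @return List of class `"pgls_selection"` with `retained` (named fit
#'   list), `aicc_table` (all models) and `term_summary`.
#' @export
select_models <- function(fits, delta = 2) {
  stopifnot(length(fits) >= 1L)
  a <- vapply(fits, `[[`, numeric(1), "aicc")
  if (all(is.na(a))) stop("no model has a defined AICc (n too small)")
  tab <- data.frame(model = names(fits), aicc = a,
                    delta_aicc = a - min(a, na.rm = TRUE),
                    lambda = vapply(fits, `[[`, numeric(1), "lambda"),
                    loglik = vapply(fits, `[[`, numeric(1), "log_likelihood"),
                    r2_adjusted = vapply(fits, `[[`, numeric(1), "r2_adjusted"),
                    row.names = NULL, stringsAsFactors = FALSE)
  tab <- tab[order(tab$aicc), ]
  keep <- which(!is.na(a) & a - min(a, na.rm = TRUE) < delta)
  keep <- keep[order(a[keep])]
  retained <- fits[keep]
  all_terms <- unique(unlist(lapply(retained, `[[`, "terms")))
  coef_of_term <- function(f, tm) {
    tparts <- term_vars(tm)
    hit <- vapply(names(f$coefficients), function(cn) {
      cparts <- strsplit(cn, ":", fixed = TRUE)[[1L]]
      length(cparts) == length(tparts) &&
        all(mapply(startsWith, cparts, tparts))
    }, logical(1))
    which(hit)[1L]
  }
  term_summary <- do.call(rbind, lapply(all_terms, function(tm) {
    inmods <- vapply(retained, function(f) tm %in% f$terms, logical(1))
    signs <- vapply(retained[inmods], function(f) {
      i <- coef_of_term(f, tm)
      if (is.na(i)) NA_real_ else sign(f$coefficients[i])
    }, numeric(1))
    sig <- vapply(retained[inmods], function(f) {
      i <- coef_of_term(f, tm)
      if (is.na(i)) NA else f$p_coef_value[i] < 0.05
    }, logical(1))
    sgn <- unique(signs[!is.na(signs)])
    data.frame(term = tm, n_retained = sum(inmods),
               n_models = length(retained),
               sign = if (length(sgn) == 1L) sgn else NA_real_,
               n_significant = sum(sig, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  structure(list(retained = retained, aicc_table = tab,
                 term_summary = term_summary, delta = delta),
            class = "pgls_selection")
}

#' @export
print.pgls_selection <- function(x, ...) {
  cat(length(x$retained), "model(s) retained within", x$delta,
      "AICc units of the best (of", nrow(x$aicc_table), "candidates)\n")
  print(utils::head(x$aicc_table, 10), row.names = FALSE)
  if (!is.null(x$term_summary)) {
    cat("\nTerm retention across retained models:\n")
    print(x$term_summary, row.names = FALSE)
  }
  invisible(x)
}
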