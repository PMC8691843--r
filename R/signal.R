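#' @title Phylogenetic-signal statistics
#' @description Signal statistics for continuous (Pagel's lambda,
#'   Blomberg's K), multistate (delta) and binary (Fritz & Purvis' D)
#'   traits, plus a simulation-based phylogenetic ANOVA. All permutation
#'   p-values are reported both as raw proportions and with the
#'   `(count + 1) / (n + 1)` convention; the latter drives decisions.
#' @name signal
NULL

signal_result <- function(statistic, estimate, p_value, n_randomisations = NA,
                          seed = NULL, ...) {
  structure(c(list(statistic = statistic, estimate = estimate,
                   p_value = p_value,
                   n_randomisations = n_randomisations,
                   seed = seed), list(...)),
            class = "signal_result")
}

#' @export
print.signal_result <- function(x, ...) {
  cat("Phylogenetic signal:", x$statistic, "=",
      format(x$estimate, digits = 4), "\n")
  if (!is.null(x$p_value) && !is.na(x$p_value))
    cat("  p =", format(x$p_value, digits = 3),
        if (!is.na(x$n_randomisations)) paste0("(", x$n_randomisations,
                                               " randomisations)") else "", "\n")
  if (!is.null(x$p_random))
    cat("  p (vs random) =", format(x$p_random, digits = 3),
        " p (vs Brownian) =", format(x$p_bm, digits = 3), "\n")
  if (isTRUE(x$degenerate)) cat("  [degenerate geometry flagged]\n")
  invisible(x)
}

# ---- Gaussian phylogenetic likelihood machinery ------------------------

# GLS phylogenetic mean, residual quadratic form and profile log-likelihood
# of x ~ N(a 1, s2 V), with s2 profiled out.
gls_profile <- function(x, V) {
  n <- length(x)
  U <- chol(V)
  iV1 <- backsolve(U, backsolve(U, rep(1, n), transpose = TRUE))
  a <- sum(iV1 * x) / sum(iV1)
  r <- x - a
  iVr <- backsolve(U, backsolve(U, r, transpose = TRUE))
  rss <- sum(r * iVr)
  s2 <- rss / n
  ll <- -n / 2 * log(2 * pi * s2) - sum(log(diag(U))) - n / 2
  list(a = a, rss = rss, sigma2 = s2, loglik = ll, logdet = 2 * sum(log(diag(U))))
}

#' Pagel's lambda for a continuous trait
#'
#' Maximum-likelihood estimate of the off-diagonal scaling of the
#' phylogenetic covariance, bounded to `[0, 1]`, with a likelihood-ratio
#' test against `lambda = 0` (chi-squared, 1 df).
#'
#' @param tree An [ape::phylo] tree.
#' @param x Named numeric vector of tip values.
#' @return A `"signal_result"` with fields `estimate` (lambda-hat),
#'   `p_value`, `loglik`, `loglik0` and a `degenerate` flag for star-like
#'   trees.
#' @export
pagel_lambda <- function(tree, x) {
  x <- x[tree$tip.label]
  if (anyNA(x)) stop("tip values must be named and cover all tips")
  if (length(x) < 4L) stop("need at least 4 tips")
  if (stats::var(x) == 0) stop("trait has zero variance")
  C <- phylo_vcv(tree)
  if (max(abs(C[upper.tri(C)])) < 1e-12 * max(diag(C)))
    return(signal_result("lambda", 0, 1, degenerate = TRUE,
                         loglik = gls_profile(x, C)$loglik,
                         loglik0 = gls_profile(x, C)$loglik))
  ll_fun <- function(lam) gls_profile(x, lambda_transform(C, lam))$loglik
  opt <- stats::optimize(ll_fun, interval = c(0, 1), maximum = TRUE,
                         tol = 1e-8)
  cand <- c(opt$maximum, 0, 1)
  lls <- c(opt$objective, ll_fun(0), ll_fun(1))
  best <- which.max(lls)
  lam <- cand[best]; ll <- lls[best]; ll0 <- lls[2L]
  p <- stats::pchisq(2 * (ll - ll0), df = 1, lower.tail = FALSE)
  signal_result("lambda", lam, p, loglik = ll, loglik0 = ll0,
                degenerate = FALSE)
}

#' Blomberg's K for a continuous trait
#'
#' `K` compares the observed ratio of tip variance to
#' phylogenetically-corrected variance against its Brownian expectation;
#' `K` is near 1 under Brownian evolution and near 0 for phylogenetically
#' random data. Significance comes from tip permutations: the observed
#' phylogenetic mean squared error is compared with the permuted ones.
#'
#' @param tree An [ape::phylo] tree.
#' @param x Named numeric vector of tip values.
#' @param n_perm Number of tip permutations.
#' @param seed Optional integer seed.
#' @return A `"signal_result"` with `estimate` (K), `p_value`
#'   (`(count + 1)/(n + 1)` convention), `p_raw`, and a `degenerate`
#'   flag on star-like trees (where K is identically 1).
#' @export
blomberg_k <- function(tree, x, n_perm = 999, seed = NULL) {
  x <- x[tree$tip.label]
  if (anyNA(x)) stop("tip values must be named and cover all tips")
  n <- length(x)
  if (n < 4L) stop("need at least 4 tips")
  C <- phylo_vcv(tree)
  U <- chol(C)
  iC1 <- backsolve(U, backsolve(U, rep(1, n), transpose = TRUE))
  denom_expect <- (sum(diag(C)) - n / sum(iC1)) / (n - 1)

  k_parts <- function(x) {
    a <- sum(iC1 * x) / sum(iC1)
    r <- x - a
    mse0 <- sum(r^2) / (n - 1)
    iCr <- backsolve(U, backsolve(U, r, transpose = TRUE))
    mse <- sum(r * iCr) / (n - 1)
    c(k = (mse0 / mse) / denom_expect, mse = mse)
  }
  obs <- k_parts(x)
  seed_if(seed)
  mse_perm <- vapply(seq_len(n_perm),
                     function(i) k_parts(sample(x))[["mse"]], numeric(1))
  pv <- perm_pvalues(mse_perm, obs[["mse"]], "le")
  degenerate <- max(abs(C[upper.tri(C)])) < 1e-12 * max(diag(C))
  signal_result("K", unname(obs[["k"]]), pv$p_plus_one, n_perm, seed,
                p_raw = pv$p_raw, mse = unname(obs[["mse"]]),
                degenerate = degenerate)
}

# ---- Equal-rates Mk machinery (likelihood, ancestral states) -----------

# children and branch lengths indexed by node
tree_children <- function(tree) {
  split(data.frame(node = tree$edge[, 2L], len = tree$edge.length),
        tree$edge[, 1L])
}

# ER transition probability matrix for k states, per-pair rate q, time t
mk_pmat <- function(k, q, t) {
  w <- exp(-k * q * t)
  matrix((1 - w) / k, k, k) + diag(w, k)
}

# postorder conditional likelihoods; returns per-node scaled likelihood
# matrix and the total log-likelihood under a uniform root
mk_pruning <- function(tree, states_int, k, q) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  D <- matrix(0, nn, k)
  D[cbind(seq_len(ntip), states_int)] <- 1
  logscale <- 0
  po <- ape::postorder(tree)
  parents <- unique(tree$edge[po, 1L])
  ch <- tree_children(tree)
  for (v in parents) {
    kids <- ch[[as.character(v)]]
    prod_v <- rep(1, k)
    for (i in seq_len(nrow(kids))) {
      P <- mk_pmat(k, q, kids$len[i])
      prod_v <- prod_v * drop(P %*% D[kids$node[i], ])
    }
    sc <- max(prod_v)
    if (sc <= 0) return(list(D = D, loglik = -Inf, parents = parents, ch = ch))
    D[v, ] <- prod_v / sc
    logscale <- logscale + log(sc)
  }
  root <- ntip + 1L
  list(D = D, loglik = log(mean(D[root, ])) + logscale,
       parents = parents, ch = ch)
}

# ML per-pair rate of the equal-rates Mk model
mk_fit_rate <- function(tree, states_int, k) {
  f <- function(logq) mk_pruning(tree, states_int, k, exp(logq))$loglik
  opt <- stats::optimize(f, interval = c(log(1e-6), log(1e3)), maximum = TRUE)
  list(rate = exp(opt$maximum), loglik = opt$objective)
}

# marginal ancestral state probabilities at internal nodes via the
# standard two-pass (down/up, equivalent to rerooting) algorithm
mk_asr_marginal <- function(tree, states_int, k, q) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  pr <- mk_pruning(tree, states_int, k, q)
  D <- pr$D; ch <- pr$ch
  nn <- ntip + tree$Nnode
  A <- matrix(0, nn, k)
  A[root, ] <- 1 / k
  # preorder over internal nodes: reverse of the postorder parent sequence
  pre_nodes <- rev(pr$parents)
  for (v in pre_nodes) {
    kids <- ch[[as.character(v)]]
    down <- vector("list", nrow(kids))
    for (i in seq_len(nrow(kids))) {
      P <- mk_pmat(k, q, kids$len[i])
      down[[i]] <- drop(P %*% D[kids$node[i], ])
    }
    for (i in seq_len(nrow(kids))) {
      partial <- A[v, ]
      for (j in seq_len(nrow(kids))) if (j != i) partial <- partial * down[[j]]
      P <- mk_pmat(k, q, kids$len[i])
      a <- drop(partial %*% P)  # P symmetric under ER
      s <- sum(a)
      A[kids$node[i], ] <- if (s > 0) a / s else 1 / k
    }
  }
  marg <- D * A
  marg <- marg / pmax(rowSums(marg), .Machine$double.xmin)
  internal <- seq.int(root, nn)
  marg[internal, , drop = FALSE]
}

# normalised Shannon entropy (base k) of each row of a probability matrix
node_entropies <- function(p) {
  k <- ncol(p)
  p <- pmin(pmax(p, 1e-12), 1)
  h <- -rowSums(p * log(p)) / log(k)
  pmin(pmax(h, 1e-8), 1 - 1e-8)
}

# Metropolis-Hastings over the (alpha, beta) parameters of a Beta model
# for the node entropies; exponential priors, lognormal proposals.
# Returns the posterior-mean ratio beta/alpha (high = low entropies =
# strong signal).
entropy_delta_sampler <- function(h, iterations = 10000, burn_in = 0.1,
                                  thinning = 10, prior_rate = 0.1,
                                  proposal_sd = 0.5) {
  lp <- function(a, b) sum(stats::dbeta(h, a, b, log = TRUE)) +
    stats::dexp(a, prior_rate, log = TRUE) +
    stats::dexp(b, prior_rate, log = TRUE)
  a <- 1; b <- 1
  cur <- lp(a, b)
  keep_from <- ceiling(burn_in * iterations)
  asum <- bsum <- 0; nkeep <- 0L
  for (it in seq_len(iterations)) {
    ap <- a * exp(proposal_sd * stats::rnorm(1L))
    new <- lp(ap, b)
    if (log(stats::runif(1L)) < new - cur + log(ap) - log(a)) { a <- ap; cur <- new }
    bp <- b * exp(proposal_sd * stats::rnorm(1L))
    new <- lp(a, bp)
    if (log(stats::runif(1L)) < new - cur + log(bp) - log(b)) { b <- bp; cur <- new }
    if (it > keep_from && it %% thinning == 0L) {
      asum <- asum + a; bsum <- bsum + b; nkeep <- nkeep + 1L
    }
  }
  (bsum / nkeep) / (asum / nkeep)
}

#' Entropy-based delta statistic for a multistate trait
#'
#' Fits an equal-rates Mk model by maximum likelihood, reconstructs
#' marginal ancestral state probabilities at every internal node
#' (two-pass algorithm), summarises each node by its normalised Shannon
#' entropy, and measures signal as the posterior-mean ratio of the two
#' parameters of a Beta model for those entropies (low entropies, i.e.
#' confident reconstructions, give large delta). Significance comes from
#' tip-label randomisations: p is the proportion of shuffles whose delta
#' reaches the observed one.
#'
#' @param tree An [ape::phylo] tree (at least 8 tips).
#' @param states Named character/factor vector of tip states (at least 2
#'   observed states).
#' @param mcmc List with `iterations`, `burn_in` (fraction) and
#'   `thinning` for the entropy sampler.
#' @param n_rand Number of tip randomisations for the null.
#' @param seed Optional integer seed.
#' @return A `"signal_result"` with `estimate` (delta), `p_value`,
#'   `p_raw`, the fitted Mk `rate`, and the null delta summary.
#' @export
delta_categorical <- function(tree, states,
                              mcmc = list(iterations = 10000,
                                          burn_in = 0.1, thinning = 10),
                              n_rand = 99, seed = NULL) {
  states <- states[tree$tip.label]
  if (anyNA(states)) stop("tip states must be named and cover all tips")
  if (length(states) < 8L) stop("need at least 8 tips")
  lev <- sort(unique(as.character(states)))
  if (length(lev) < 2L) stop("signal undefined for a single-state trait")
  k <- length(lev)
  si <- match(as.character(states), lev)
  seed_if(seed)
  one_delta <- function(si) {
    fit <- mk_fit_rate(tree, si, k)
    marg <- mk_asr_marginal(tree, si, k, fit$rate)
    entropy_delta_sampler(node_entropies(marg),
                          iterations = mcmc$iterations,
                          burn_in = mcmc$burn_in, thinning = mcmc$thinning)
  }
  obs_fit <- mk_fit_rate(tree, si, k)
  delta_obs <- one_delta(si)
  null <- vapply(seq_len(n_rand), function(i) one_delta(sample(si)),
                 numeric(1))
  pv <- perm_pvalues(null, delta_obs, "ge")
  signal_result("delta", delta_obs, pv$p_plus_one, n_rand, seed,
                p_raw = pv$p_raw, rate = obs_fit$rate,
                null_mean = mean(null), null_sd = stats::sd(null))
}

#' Fritz and Purvis' D for a binary trait
#'
#' Nodal values are estimated post-order as unweighted means of daughter
#' values; the raw dispersion `d` sums the absolute daughter-value
#' contrasts over all internal nodes. `D` rescales `d` between its
#' expectations under tip permutation (D = 1) and under threshold-Brownian
#' evolution at the observed prevalence (D = 0); clumped traits give
#' D < 0.
#'
#' @param tree An [ape::phylo] tree (at least 8 tips).
#' @param x Named 0/1 vector with both states present.
#' @param n_sim Number of permutations and Brownian simulations.
#' @param seed Optional integer seed.
#' @return A `"signal_result"` with `estimate` (D), `p_random`
#'   (`Pr(d_rand <= d_obs)`), `p_bm` (`Pr(d_BM >= d_obs)`), both with the
#'   `+1` convention, and the null summaries.
#' @export
fritz_purvis_d <- function(tree, x, n_sim = 500, seed = NULL) {
  x <- x[tree$tip.label]
  if (anyNA(x)) stop("tip values must be named and cover all tips")
  if (length(x) < 8L) stop("need at least 8 tips")
  x <- as.numeric(x)
  if (all(x == 0) || all(x == 1)) stop("both states must be present")
  ntip <- length(tree$tip.label)
  po <- ape::postorder(tree)
  parents <- unique(tree$edge[po, 1L])
  ch <- tree_children(tree)
  d_sum <- function(x) {
    vals <- numeric(ntip + tree$Nnode)
    vals[seq_len(ntip)] <- x
    d <- 0
    for (v in parents) {
      kids <- ch[[as.character(v)]]$node
      m <- mean(vals[kids])
      vals[v] <- m
      d <- d + sum(abs(vals[kids] - m))
    }
    d
  }
  d_obs <- d_sum(x)
  seed_if(seed)
  d_rand <- vapply(seq_len(n_sim), function(i) d_sum(sample(x)), numeric(1))
  prev <- mean(x)
  d_bm <- vapply(seq_len(n_sim), function(i)
    d_sum(as.numeric(simulate_threshold_binary(tree, prev)[tree$tip.label])),
    numeric(1))
  D <- (d_obs - mean(d_bm)) / (mean(d_rand) - mean(d_bm))
  pr <- perm_pvalues(d_rand, d_obs, "le")
  pb <- perm_pvalues(d_bm, d_obs, "ge")
  signal_result("D", D, NA_real_, n_sim, seed,
                p_random = pr$p_plus_one, p_random_raw = pr$p_raw,
                p_bm = pb$p_plus_one, p_bm_raw = pb$p_raw,
                d_obs = d_obs, d_rand_mean = mean(d_rand),
                d_bm_mean = mean(d_bm))
}

#' Phylogenetic ANOVA
#'
#' Ordinary one-way ANOVA F of a continuous trait on a grouping factor,
#' with significance judged against F values recomputed on Brownian
#' simulations along the tree (rate estimated from the observed trait by
#' the phylogenetic mean square), groups held fixed.
#'
#' @param tree An [ape::phylo] tree.
#' @param y Named numeric tip values.
#' @param groups Named factor/character of group memberships; every group
#'   needs at least 2 members.
#' @param n_sim Number of Brownian simulations.
#' @param seed Optional integer seed.
#' @return A `"signal_result"` with `estimate` (F), `p_value`
#'   (`(count + 1)/(n + 1)`), `p_raw` and the estimated Brownian rate.
#' @export
phylo_anova <- function(tree, y, groups, n_sim = 999, seed = NULL) {
  y <- y[tree$tip.label]
  groups <- factor(groups[tree$tip.label])
  if (anyNA(y) || anyNA(groups)) stop("y and groups must cover all tips")
  tab <- table(groups)
  if (length(tab) < 2L) stop("need at least 2 groups")
  if (any(tab < 2L))
    stop("group(s) with fewer than 2 members: ",
         paste(names(tab)[tab < 2L], collapse = ", "))
  n <- length(y); g <- length(tab)
  idx <- split(seq_len(n), groups)
  f_stat <- function(y) {
    gm <- mean(y)
    ssb <- sum(vapply(idx, function(i) length(i) * (mean(y[i]) - gm)^2,
                      numeric(1)))
    ssw <- sum(vapply(idx, function(i) sum((y[i] - mean(y[i]))^2), numeric(1)))
    (ssb / (g - 1)) / (ssw / (n - g))
  }
  f_obs <- f_stat(y)
  C <- phylo_vcv(tree)
  prof <- gls_profile(y, C)
  sigma2 <- prof$rss / (n - 1)  # phylogenetic mean square
  seed_if(seed)
  L <- chol(C + diag(1e-12, n))
  f_sim <- vapply(seq_len(n_sim), function(i) {
    ysim <- drop(crossprod(L, stats::rnorm(n))) * sqrt(sigma2)
    f_stat(ysim)
  }, numeric(1))
  pv <- perm_pvalues(f_sim, f_obs, "ge")
  signal_result("F", f_obs, pv$p_plus_one, n_sim, seed, p_raw = pv$p_raw,
                sigma2 = sigma2, df1 = g - 1, df2 = n - g)
}
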