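#' Read and validate a Newick tree
#'
#' Thin validating wrapper around [ape::read.tree()]: requires branch
#' lengths, uniquely labelled tips and non-negative edge lengths.
#' Polytomies are permitted. Zero-length branches are allowed but flagged
#' with a warning (sampled ancestors).
#'
#' @param path Newick file path (or a Newick string via `text`).
#' @param text Optional Newick text, used instead of `path`.
#' @return An [ape::phylo] tree.
#' @export
read_newick <- function(path = NULL, text = NULL) {
  tree <- if (!is.null(text)) ape::read.tree(text = text) else ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick input")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(is.na(tree$tip.label)) || any(tree$tip.label == ""))
    stop("tree has unlabelled tips")
  dup <- tree$tip.label[duplicated(tree$tip.label)]
  if (length(dup))
    stop("duplicate tip label(s): ", paste(unique(dup), collapse = ", "))
  if (any(tree$edge.length < 0)) stop("tree has negative branch lengths")
  if (any(tree$edge.length == 0))
    warning("tree contains zero-length branches")
  tree
}

#' Check ultrametricity
#'
#' @param tree An [ape::phylo] tree.
#' @param tol Absolute tolerance on root-to-tip depth differences.
#' @return Logical scalar.
#' @export
is_time_calibrated <- function(tree, tol = 1e-6) {
  depths <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  diff(range(depths)) <= tol
}

#' Patristic distance matrix
#'
#' Sum of branch lengths along the tree path between each pair of tips;
#' the "phylogenetic distance" regressed against phenotypic distance in
#' the convergence tests.
#'
#' @param tree An [ape::phylo] tree.
#' @return Symmetric matrix with tip labels as dimnames, tips in
#'   `tree$tip.label` order.
#' @export
patristic_distances <- function(tree) {
  d <- stats::cophenetic(tree)
  d[tree$tip.label, tree$tip.label]
}

#' Phylogenetic variance-covariance matrix
#'
#' `C[i, j]` is the shared root-to-MRCA path length of tips i and j;
#' `C[i, i]` the root-to-tip depth.
#'
#' @param tree An [ape::phylo] tree.
#' @return Symmetric matrix in `tree$tip.label` order.
#' @export
phylo_vcv <- function(tree) {
  C <- ape::vcv(tree)
  C[tree$tip.label, tree$tip.label]
}

#' Pagel's lambda transform of a covariance matrix
#'
#' Multiplies all off-diagonal entries by `lam`, leaving the diagonal
#' unchanged. `lam = 1` returns the Brownian covariance, `lam = 0` a
#' star-like diagonal matrix.
#'
#' @param C Phylogenetic covariance matrix.
#' @param lam Scalar in `[0, 1]`.
#' @return Transformed matrix.
#' @export
lambda_transform <- function(C, lam) {
  if (!is.numeric(lam) || length(lam) != 1L || lam < 0 || lam > 1)
    stop("lam must be a scalar in [0, 1]")
  Cl <- C * lam
  diag(Cl) <- diag(C)
  Cl
}

#' Simulate Brownian motion on a tree
#'
#' One multivariate-normal draw with mean `root` and covariance
#' `sigma2 * C`.
#'
#' @param tree An [ape::phylo] tree.
#' @param sigma2 Brownian rate (variance per unit branch length).
#' @param root Root value.
#' @param seed Optional integer seed.
#' @return Named numeric vector of tip values.
#' @export
simulate_bm <- function(tree, sigma2 = 1, root = 0, seed = NULL) {
  stopifnot(sigma2 > 0)
  seed_if(seed)
  C <- phylo_vcv(tree)
  L <- chol(C + diag(1e-12, nrow(C)))
  x <- root + sqrt(sigma2) * drop(crossprod(L, stats::rnorm(nrow(C))))
  names(x) <- tree$tip.label
  x
}

#' Simulate an Ornstein-Uhlenbeck process with branch regimes
#'
#' Exact branch-wise OU transitions: along a branch of length `t` in
#' regime `r`, the value decays towards the regime optimum with rate
#' `alpha` and picks up variance `sigma2 (1 - exp(-2 alpha t)) / (2 alpha)`.
#' With `alpha = 0` this is exactly Brownian motion.
#'
#' @param tree An [ape::phylo] tree.
#' @param alpha Selection strength (per unit branch length), `>= 0`.
#' @param sigma2 Diffusion rate.
#' @param optima Named vector of regime optima.
#' @param regime_map Character vector of regime labels, one per edge (in
#'   `tree$edge` row order).
#' @param root_value Starting value at the root; defaults to the optimum
#'   of the regime of the root's first descending edge.
#' @param seed Optional integer seed.
#' @return Named numeric vector of tip values.
#' @export
simulate_ou_regimes <- function(tree, alpha, sigma2, optima, regime_map,
                                root_value = NULL, seed = NULL) {
  stopifnot(alpha >= 0, sigma2 > 0)
  ne <- nrow(tree$edge)
  if (length(regime_map) != ne)
    stop("regime_map must label every branch (", ne, " edges)")
  if (!all(regime_map %in% names(optima)))
    stop("unmapped regime(s): ",
         paste(setdiff(regime_map, names(optima)), collapse = ", "))
  seed_if(seed)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  root_edge <- which(tree$edge[, 1L] == root)[1L]
  x0 <- root_value %||% unname(optima[regime_map[root_edge]])
  vals <- numeric(ntip + tree$Nnode)
  vals[root] <- x0
  ord <- rev(ape::postorder(tree))  # preorder over edges
  for (e in ord) {
    par <- tree$edge[e, 1L]; child <- tree$edge[e, 2L]
    t <- tree$edge.length[e]
    th <- optima[regime_map[e]]
    if (alpha == 0) {
      m <- vals[par]
      v <- sigma2 * t
    } else {
      w <- exp(-alpha * t)
      m <- th + (vals[par] - th) * w
      v <- sigma2 * (1 - w^2) / (2 * alpha)
    }
    vals[child] <- stats::rnorm(1L, m, sqrt(v))
  }
  out <- vals[seq_len(ntip)]
  names(out) <- tree$tip.label
  out
}

#' Simulate an equal-rates Mk discrete trait
#'
#' Root state uniform over states; state changes along branches follow
#' exponential waiting times with per-pair rate `rate` (so the total rate
#' of leaving a state is `rate * (n_states - 1)`) and uniform jumps among
#' the other states.
#'
#' @param tree An [ape::phylo] tree.
#' @param n_states Number of states, `>= 2`.
#' @param rate Per-pair transition rate, `> 0`.
#' @param seed Optional integer seed.
#' @return Named integer vector of tip states in `1:n_states`.
#' @export
simulate_mk <- function(tree, n_states = 2, rate = 1, seed = NULL) {
  stopifnot(n_states >= 2, rate > 0)
  seed_if(seed)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  states <- integer(ntip + tree$Nnode)
  states[root] <- sample.int(n_states, 1L)
  leave_rate <- rate * (n_states - 1)
  ord <- rev(ape::postorder(tree))
  for (e in ord) {
    par <- tree$edge[e, 1L]; child <- tree$edge[e, 2L]
    t <- tree$edge.length[e]
    s <- states[par]
    repeat {
      w <- stats::rexp(1L, leave_rate)
      if (w >= t) break
      t <- t - w
      others <- seq_len(n_states)[-s]
      s <- others[sample.int(length(others), 1L)]
    }
    states[child] <- s
  }
  out <- states[seq_len(ntip)]
  names(out) <- tree$tip.label
  out
}

#' Simulate a binary trait under the threshold-Brownian model
#'
#' A Brownian liability is simulated and thresholded at its empirical
#' quantile so that exactly `round(prevalence * n)` tips carry state 1.
#' This is the Brownian reference used to scale Fritz and Purvis' D.
#'
#' @param tree An [ape::phylo] tree.
#' @param prevalence Target fraction of tips in state 1, in `(0, 1)`.
#' @param seed Optional integer seed.
#' @return Named integer vector of 0/1 tip states.
#' @export
simulate_threshold_binary <- function(tree, prevalence, seed = NULL) {
  stopifnot(prevalence > 0, prevalence < 1)
  n <- length(tree$tip.label)
  m <- round(prevalence * n)
  if (m == 0L || m == n)
    stop("prevalence rounds to an all-0 or all-1 trait on ", n, " tips")
  liab <- simulate_bm(tree, sigma2 = 1, root = 0, seed = seed)
  out <- as.integer(rank(liab, ties.method = "first") > n - m)
  names(out) <- names(liab)
  out
}

#' Simulate an ultrametric pure-birth tree
#'
#' A Yule tree with the requested number of tips, rescaled to unit root
#' depth so that rates and selection strengths are expressed per tree
#' depth.
#'
#' @param n_tips Number of tips, `>= 3`.
#' @param birth_rate Speciation rate (shape parameter of the Yule draw).
#' @param seed Optional integer seed.
#' @return An ultrametric [ape::phylo] tree with tips `sp01, sp02, ...`.
#' @export
simulate_tree <- function(n_tips, birth_rate = 1, seed = NULL) {
  stopifnot(n_tips >= 3)
  seed_if(seed)
  tree <- ape::rphylo(n_tips, birth = birth_rate, death = 0)
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  tree$tip.label <- sprintf("sp%02d", seq_len(n_tips))
  tree
}
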