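#' Build an Mk instantaneous rate matrix
#'
#' ER ("Mk1": one shared rate, gains and losses equally likely) or ARD
#' ("Mk2": one free rate per ordered state pair). Rows sum to zero; rates
#' are per million years when branch lengths are in My.
#'
#' @param rates Numeric: length 1 for ER, length k*(k-1) for ARD (filled
#'   row-wise over off-diagonal entries).
#' @param states Character vector of state labels (k >= 2), order fixed.
#' @param model "ER" or "ARD".
#' @return k x k rate matrix with dimnames = states.
#' @export
build_q <- function(rates, states, model = c("ER", "ARD")) {
  model <- match.arg(model)
  k <- length(states)
  if (k < 2) stop("need at least 2 states")
  if (anyDuplicated(states)) stop("state labels must be unique")
  if (any(rates < 0)) stop("rates must be non-negative")
  Q <- matrix(0, k, k, dimnames = list(states, states))
  off <- which(row(Q) != col(Q))
  off <- off[order(row(Q)[off], col(Q)[off])]  # row-wise fill order
  if (model == "ER") {
    if (length(rates) != 1) stop("ER takes a single rate")
    Q[off] <- rates
  } else {
    if (length(rates) != k * (k - 1)) {
      stop("ARD takes ", k * (k - 1), " rates for k = ", k)
    }
    Q[off] <- rates
  }
  diag(Q) <- -rowSums(Q)
  Q
}

#' Number of free rate parameters of an Mk parameterization
#' @param k Number of states.
#' @param model "ER" or "ARD".
#' @return Integer parameter count (1 for ER, k(k-1) for ARD).
#' @export
mk_n_params <- function(k, model = c("ER", "ARD")) {
  model <- match.arg(model)
  if (model == "ER") 1L else as.integer(k * (k - 1))
}

#' CTMC transition probability matrix exp(Q t)
#'
#' Spectral route (eigendecomposition of Q) when the eigenvector basis is
#' well conditioned, otherwise scaling-and-squaring on a truncated Taylor
#' series. Both agree to machine precision on the small (k <= 6) matrices
#' used here; the spectral route is exact for symmetric ER generators.
#'
#' @param Q Rate matrix (rows sum to 0).
#' @param t Elapsed time, same units as 1/rates; must be >= 0.
#' @return Stochastic matrix P(t); rows sum to 1.
#' @export
transition_probs <- function(Q, t) {
  if (t < 0) stop("t must be >= 0")
  k <- nrow(Q)
  if (t == 0) return(diag(k))
  sp <- q_spectral(Q)
  P <- if (!is.null(sp)) spectral_expm(sp, t) else expm_ss(Q * t)
  P[P < 0] <- 0
  P / rowSums(P)
}

# one-time spectral factorization of Q; NULL if the eigenvector basis is
# ill-conditioned (caller falls back to scaling-and-squaring)
#' @keywords internal
q_spectral <- function(Q) {
  eg <- tryCatch(eigen(Q), error = function(e) NULL)
  if (is.null(eg)) return(NULL)
  V <- eg$vectors
  rc <- tryCatch(rcond(V), error = function(e) 0)
  if (!is.finite(rc) || rc <= 1e-10) return(NULL)
  list(V = V, Vinv = solve(V), lambda = eg$values, k = nrow(Q))
}

#' @keywords internal
spectral_expm <- function(sp, t) {
  Re(sp$V %*% (exp(sp$lambda * t) * sp$Vinv))
}

# scaling-and-squaring matrix exponential (Taylor core); small dense inputs
#' @keywords internal
expm_ss <- function(A) {
  k <- nrow(A)
  nrm <- max(abs(A))
  s <- max(0L, ceiling(log2(max(nrm, 1e-300))) + 1L)
  B <- A / 2^s
  P <- diag(k); term <- diag(k)
  for (i in 1:30) {
    term <- term %*% B / i
    P <- P + term
    if (max(abs(term)) < 1e-18) break
  }
  for (i in seq_len(s)) P <- P %*% P
  P
}

# Internal pruning engine: per-node conditional (downward) likelihoods with
# per-node log scalers, postorder. `tipliks` is an n_tip x k matrix of tip
# partial likelihoods (degenerate rows for observed states, ones for
# missing). Returns list(L = node x k matrix of scaled conditionals,
# logscale = per-node accumulated log scale, Pmats = per-edge P matrices).
#' @keywords internal
prune_conditionals <- function(tree, tipliks, Q) {
  n_tip <- nrow(tipliks)
  k <- ncol(tipliks)
  n_node <- n_tip + tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  L <- matrix(1, n_node, k)
  L[seq_len(n_tip), ] <- tipliks
  logscale <- numeric(n_node)
  sp <- q_spectral(Q)
  pmat <- function(t) {
    if (t == 0) return(diag(k))
    P <- if (!is.null(sp)) spectral_expm(sp, t) else expm_ss(Q * t)
    P[P < 0] <- 0
    P / rowSums(P)
  }
  Pmats <- vector("list", nrow(po$edge))
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]
    P <- pmat(po$edge.length[e])
    Pmats[[e]] <- P
    msg <- as.vector(P %*% L[ch, ])
    L[p, ] <- L[p, ] * msg
    logscale[p] <- logscale[p] + logscale[ch]
    m <- max(L[p, ])
    if (m > 0 && (m < 1e-100 || m > 1e100)) {
      L[p, ] <- L[p, ] / m
      logscale[p] <- logscale[p] + log(m)
    }
  }
  list(L = L, logscale = logscale, edge = po$edge,
       edge.length = po$edge.length, Pmats = Pmats)
}

# build tip partial-likelihood matrix from a state vector (NA = missing)
#' @keywords internal
tip_likelihoods <- function(tree, states, state_space) {
  x <- states[tree$tip.label]
  if (length(states) != length(tree$tip.label) || anyNA(names(states)) ||
      any(!tree$tip.label %in% names(states))) {
    stop("`states` must be a named vector covering every tip label")
  }
  k <- length(state_space)
  bad <- setdiff(unique(x[!is.na(x)]), state_space)
  if (length(bad)) stop("state label(s) outside state space: ",
                        paste(bad, collapse = ", "))
  tl <- matrix(0, length(x), k)
  for (j in seq_len(k)) tl[, j] <- ifelse(is.na(x), 1, as.numeric(x == state_space[j]))
  tl
}

#' Mk log-likelihood by Felsenstein pruning
#'
#' @param tree Rooted binary `phylo` with branch lengths.
#' @param states Named character vector (names = tip labels); `NA` marks a
#'   missing observation, contributing a vector of ones (full ambiguity).
#' @param Q Rate matrix over `state_space`.
#' @param root_prior Probability vector over states (default flat).
#' @param state_space Character vector of state labels; defaults to
#'   `colnames(Q)`.
#' @return Natural-log likelihood; `-Inf` if the data have probability zero.
#' @export
mk_loglik <- function(tree, states, Q, root_prior = NULL, state_space = colnames(Q)) {
  if (is.null(state_space)) stop("state space required (name Q's columns)")
  k <- length(state_space)
  if (is.null(root_prior)) root_prior <- rep(1 / k, k)
  stopifnot(abs(sum(root_prior) - 1) < 1e-8)
  tl <- tip_likelihoods(tree, states, state_space)
  pr <- prune_conditionals(tree, tl, Q)
  root <- length(tree$tip.label) + 1L
  lik <- sum(root_prior * pr$L[root, ])
  if (lik <= 0) return(-Inf)
  log(lik) + pr$logscale[root]
}

#' Sample-size-corrected AIC
#' @param loglik Log-likelihood at the optimum.
#' @param n_params Number of free parameters.
#' @param n Sample size (number of tips, the conventional unit for
#'   comparative data).
#' @return AICc value.
#' @export
aicc <- function(loglik, n_params, n) {
  -2 * loglik + 2 * n_params + 2 * n_params * (n_params + 1) / (n - n_params - 1)
}

#' Maximum-likelihood fit of an Mk model
#'
#' Bounded quasi-Newton (L-BFGS-B) on log rates with five dispersed
#' deterministic starts; bounds 1e-8 to 1e3 per My. AICc uses n = number of
#' tips.
#'
#' @inheritParams mk_loglik
#' @param model "ER" (equal rates) or "ARD" (all rates different).
#' @param root_prior_mode "flat", "stationary", or a numeric vector.
#' @param state_space State labels; default = sorted observed states.
#' @return Object of class `mk_fit`: list with `model`, `state_space`,
#'   `rates`, `Q`, `loglik`, `n_params`, `aicc`, `root_prior`, `n_tips`,
#'   `convergence`.
#' @export
fit_mk <- function(tree, states, model = c("ER", "ARD"),
                   root_prior_mode = "flat", state_space = NULL) {
  model <- match.arg(model)
  states <- states[!is.na(names(states))]
  if (is.null(state_space)) state_space <- sort(unique(states[!is.na(states)]))
  k <- length(state_space)
  if (k < 2) {
    stop("fewer than 2 states observed; an Mk fit is not identifiable")
  }
  obs <- table(factor(states, levels = state_space))
  monomorphic <- sum(obs > 0) < 2
  if (monomorphic) {
    warning("all tips share one state; rate estimate will sit at the lower bound")
  }
  np <- mk_n_params(k, model)
  root_prior <- resolve_root_prior(root_prior_mode, k)
  nll <- function(logr) {
    Q <- build_q(exp(logr), state_space, model)
    rp <- if (identical(root_prior_mode, "stationary")) stationary_dist(Q) else root_prior
    -mk_loglik(tree, states, Q, rp, state_space)
  }
  depth <- max(ape::node.depth.edgelength(tree))
  starts <- log(c(0.1, 1, 0.01, 10, 0.5) / max(depth, 1e-8))
  lb <- log(1e-8); ub <- log(1e3)
  best <- NULL
  for (s0 in starts) {
    o <- tryCatch(
      stats::optim(rep(min(max(s0, lb), ub), np), nll, method = "L-BFGS-B",
                   lower = lb, upper = ub,
                   control = list(factr = 1e7, maxit = 500)),
      error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) stop("optimizer failed to converge from all starts")
  rates <- exp(best$par)
  Q <- build_q(rates, state_space, model)
  rp <- if (identical(root_prior_mode, "stationary")) stationary_dist(Q) else root_prior
  ll <- -best$value
  structure(list(model = model, state_space = state_space, rates = rates,
                 Q = Q, loglik = ll, n_params = np,
                 aicc = aicc(ll, np, length(tree$tip.label)),
                 root_prior = rp, n_tips = length(tree$tip.label),
                 convergence = best$convergence),
            class = "mk_fit")
}

#' @export
print.mk_fit <- function(x, ...) {
  cat("Mk model fit (", x$model, ", k = ", length(x$state_space), " states)\n",
      sep = "")
  cat("  states:", paste(x$state_space, collapse = ", "), "\n")
  cat("  rates: ", paste(signif(x$rates, 5), collapse = ", "), " per My\n", sep = "")
  cat("  log-likelihood:", format(x$loglik, digits = 8),
      "  AICc:", format(x$aicc, digits = 8), "\n")
  invisible(x)
}

#' @keywords internal
resolve_root_prior <- function(mode, k) {
  if (is.numeric(mode)) {
    stopifnot(length(mode) == k, abs(sum(mode) - 1) < 1e-8)
    return(mode)
  }
  rep(1 / k, k)  # flat; "stationary" resolved against the fitted Q
}

#' @keywords internal
stationary_dist <- function(Q) {
  k <- nrow(Q)
  A <- rbind(t(Q), rep(1, k))
  pi <- stats::lsfit(A, c(rep(0, k), 1), intercept = FALSE)$coefficients
  pi <- pmax(pi, 0); pi / sum(pi)
}

#' Marginal ancestral state probabilities
#'
#' Combines downward conditional likelihoods (pruning) with upward partial
#' likelihoods so each internal node's vector is proportional to the
#' probability of the full data given the node's state — the standard
#' marginal (empirical Bayes) reconstruction.
#'
#' @inheritParams mk_loglik
#' @return Matrix (rows = nodes, tips first then internals, in the tree's
#'   node numbering) of state probabilities; rows sum to 1. Tip rows with
#'   observed states are degenerate.
#' @export
marginal_ancestral <- function(tree, states, Q, root_prior = NULL,
                               state_space = colnames(Q)) {
  if (is.null(state_space)) stop("state space required (name Q's columns)")
  k <- length(state_space)
  if (is.null(root_prior)) root_prior <- rep(1 / k, k)
  tl <- tip_likelihoods(tree, states, state_space)
  pr <- prune_conditionals(tree, tl, Q)
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  root <- n_tip + 1L
  # upward pass, preorder (reverse postorder): U[v, s] = partial likelihood
  # of everything outside v's subtree, given state s at v (unnormalized;
  # scalers cancel in the per-node normalization)
  U <- matrix(0, n_node, k)
  U[root, ] <- root_prior
  edges <- pr$edge
  for (e in rev(seq_len(nrow(edges)))) {
    p <- edges[e, 1]; ch <- edges[e, 2]
    P <- pr$Pmats[[e]]
    # message from parent to child: exclude child's own contribution
    msg <- as.vector(P %*% pr$L[ch, ])
    msg[msg <= 0] <- .Machine$double.xmin
    sib_part <- pr$L[p, ] / msg
    up <- as.vector(t(P) %*% (U[p, ] * sib_part))
    m <- max(up)
    U[ch, ] <- if (m > 0) up / m else up
  }
  M <- U * pr$L
  M <- M / rowSums(M)
  dimnames(M) <- list(NULL, state_space)
  M
}
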