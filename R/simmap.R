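#' Joint sample of ancestral node states
#'
#' Draws one assignment of states to all nodes from the joint posterior
#' given tip data and a rate matrix: the root is drawn from its marginal,
#' then each child is drawn conditional on its parent and the data below it
#' (standard forward-filter backward-sample on the tree).
#'
#' @inheritParams mk_loglik
#' @return Integer vector of state indices (1-based into `state_space`) for
#'   every node, tips included.
#' @export
sample_node_states <- function(tree, states, Q, root_prior = NULL,
                               state_space = colnames(Q)) {
  k <- length(state_space)
  if (is.null(root_prior)) root_prior <- rep(1 / k, k)
  tl <- tip_likelihoods(tree, states, state_space)
  pr <- prune_conditionals(tree, tl, Q)
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  root <- n_tip + 1L
  draw_node_states(pr, root_prior, root, k)
}

# backward-sampling pass over a precomputed pruning result
#' @keywords internal
draw_node_states <- function(pr, root_prior, root, k) {
  n_node <- nrow(pr$L)
  z <- integer(n_node)
  w <- root_prior * pr$L[root, ]
  if (sum(w) <= 0) stop("data have probability zero under this model")
  z[root] <- sample.int(k, 1, prob = w)
  edges <- pr$edge
  for (e in rev(seq_len(nrow(edges)))) {
    p <- edges[e, 1]; ch <- edges[e, 2]
    w <- pr$Pmats[[e]][z[p], ] * pr$L[ch, ]
    if (sum(w) <= 0) stop("zero-probability branch endpoint combination")
    z[ch] <- sample.int(k, 1, prob = w)
  }
  z
}

#' Precompute the uniformization cache for one (Q, t) bridge family
#'
#' Endpoint-conditioned CTMC paths are sampled by uniformization: a
#' dominating rate mu >= max(-diag(Q)) turns the chain into a Poisson(mu t)
#' number of candidate jumps of the discrete kernel R = I + Q/mu; the jump
#' count is drawn from its endpoint-conditioned distribution and the state
#' sequence from the discrete bridge. Rejection sampling, the naive
#' alternative, is kept as a test oracle only — it is exponentially slow for
#' unlikely endpoint pairs.
#'
#' @param Q Rate matrix.
#' @param t Branch duration (> 0).
#' @param nmax Truncation for the jump-count distribution (auto-extended to
#'   cover 1 - 1e-12 of the Poisson mass).
#' @return List with `R`, `Rpow` (list of matrix powers), `pois` (Poisson
#'   weights), `mu`, `t`, `P` (the transition matrix).
#' @keywords internal
bridge_cache <- function(Q, t, nmax = NULL) {
  k <- nrow(Q)
  mu <- max(-diag(Q))
  if (mu <= 0) mu <- 1e-12
  R <- diag(k) + Q / mu
  lam <- mu * t
  if (is.null(nmax)) nmax <- max(10, ceiling(lam + 10 * sqrt(lam) + 10))
  pois <- stats::dpois(0:nmax, lam)
  Rpow <- vector("list", nmax + 1)
  Rpow[[1]] <- diag(k)
  for (n in seq_len(nmax)) Rpow[[n + 1]] <- Rpow[[n]] %*% R
  P <- matrix(0, k, k)
  for (n in 0:nmax) P <- P + pois[n + 1] * Rpow[[n + 1]]
  # per-endpoint-pair vectors of (R^n)[a, b] over n, for fast bridge draws
  Rab <- vector("list", k * k)
  for (a in seq_len(k)) for (b in seq_len(k)) {
    Rab[[(a - 1L) * k + b]] <- vapply(Rpow, function(M) M[a, b], numeric(1))
  }
  list(R = R, Rpow = Rpow, Rab = Rab, pois = pois, mu = mu, t = t, P = P,
       nmax = nmax)
}

#' Sample one endpoint-conditioned CTMC path
#'
#' @param Q Rate matrix (or a cache from [bridge_cache()] via `cache`).
#' @param t Duration.
#' @param a,b Start and end state indices (1-based).
#' @param cache Optional precomputed [bridge_cache()] for repeated draws.
#' @return data.frame with `state` (index) and `duration` columns; durations
#'   sum to `t`, first state `a`, last state `b`, adjacent states differ.
#' @export
endpoint_conditioned_path <- function(Q, t, a, b, cache = NULL) {
  if (is.null(cache)) cache <- bridge_cache(Q, t)
  h <- bridge_draw(cache, a, b)
  data.frame(state = h$state, duration = h$duration)
}

# core bridge sampler; returns bare list(state, duration) for speed
#' @keywords internal
bridge_draw <- function(cache, a, b) {
  k <- nrow(cache$R)
  if (cache$P[a, b] <= 0) stop("cannot bridge: P[a,b](t) = 0")
  t <- cache$t
  # jump-count posterior: P(N = n | a, b) proportional to pois[n] * (R^n)[a, b]
  wn <- cache$pois * cache$Rab[[(a - 1L) * k + b]]
  n_jump <- sample.int(length(wn), 1, prob = wn) - 1L
  if (n_jump == 0L) return(list(state = a, duration = t))
  if (n_jump == 1L && a != b) {
    # single real jump at a uniform time
    u <- stats::runif(1, 0, t)
    return(list(state = c(a, b), duration = c(u, t - u)))
  }
  seqs <- integer(n_jump + 2)
  seqs[1] <- a; seqs[n_jump + 2] <- b
  for (i in seq_len(n_jump)) {
    # state after i-th candidate jump, conditioned on reaching b
    w <- cache$R[seqs[i], ] * cache$Rpow[[n_jump - i + 1]][, b]
    seqs[i + 1] <- sample.int(k, 1, prob = w)
  }
  times <- c(0, sort(stats::runif(n_jump, 0, t)))
  keep <- c(TRUE, diff(seqs[seq_len(n_jump + 1)]) != 0)
  st <- seqs[seq_len(n_jump + 1)][keep]
  t0 <- times[keep]
  dur <- diff(c(t0, t))
  pos <- dur > 0 | seq_along(dur) == 1
  list(state = st[pos], duration = dur[pos])
}

#' Sample stochastic character maps
#'
#' Full character histories conditional on tip data and a rate matrix: node
#' states are drawn jointly, then every branch is filled with an
#' endpoint-conditioned path. Rates are held at the supplied (typically ML)
#' estimate — the empirical-Bayes convention.
#'
#' @inheritParams mk_loglik
#' @param n_maps Number of maps (>= 1).
#' @param seed Integer seed; map i uses substream `seed + i` so the set is
#'   reproducible and order-independent.
#' @return Object of class `simmap_set`: list with `maps` (each a list with
#'   `node_states` and `histories`, a per-edge list of `state`/`duration`
#'   segment vectors ordered from the parent end), `tree` (postorder),
#'   `state_space`, `seed`, `Q`.
#' @export
sample_maps <- function(tree, states, Q, n_maps, seed = 1L,
                        root_prior = NULL, state_space = colnames(Q)) {
  stopifnot(n_maps >= 1)
  k <- length(state_space)
  if (is.null(root_prior)) root_prior <- rep(1 / k, k)
  po <- ape::reorder.phylo(tree, "postorder")
  # prune once: tip data and Q are fixed across maps
  tl <- tip_likelihoods(po, states, state_space)
  pr <- prune_conditionals(po, tl, Q)
  root <- length(po$tip.label) + 1L
  # one bridge cache per distinct branch length
  lens <- po$edge.length
  ulen <- unique(lens[lens > 0])
  caches <- lapply(ulen, function(t) bridge_cache(Q, t))
  cache_idx <- match(lens, ulen)
  maps <- vector("list", n_maps)
  for (i in seq_len(n_maps)) {
    set.seed((seed + i) %% .Machine$integer.max)
    z <- draw_node_states(pr, root_prior, root, k)
    hist <- vector("list", nrow(po$edge))
    for (e in seq_len(nrow(po$edge))) {
      p <- po$edge[e, 1]; ch <- po$edge[e, 2]
      if (lens[e] == 0) {
        if (z[p] != z[ch]) stop("state change across zero-length branch")
        hist[[e]] <- list(state = z[p], duration = 0)
      } else {
        hist[[e]] <- bridge_draw(caches[[cache_idx[e]]], z[p], z[ch])
      }
    }
    maps[[i]] <- list(node_states = z, histories = hist)
  }
  structure(list(maps = maps, tree = po, state_space = state_space,
                 seed = seed, Q = Q), class = "simmap_set")
}

#' @export
print.simmap_set <- function(x, ...) {
  cat("Stochastic character map set:", length(x$maps), "maps,",
      length(x$tree$tip.label), "tips, states:",
      paste(x$state_space, collapse = ", "), "\n")
  invisible(x)
}

#' Count transitions per map
#'
#' @param ms A `simmap_set`.
#' @return List of k x k transition-count matrices, one per map (rows =
#'   from-state, cols = to-state).
#' @export
transition_counts <- function(ms) {
  k <- length(ms$state_space)
  lapply(ms$maps, function(m) {
    cnt <- matrix(0L, k, k, dimnames = list(ms$state_space, ms$state_space))
    for (h in m$histories) {
      s <- h$state
      if (length(s) > 1) {
        for (j in seq_len(length(s) - 1)) {
          cnt[s[j], s[j + 1]] <- cnt[s[j], s[j + 1]] + 1L
        }
      }
    }
    cnt
  })
}

#' Distribution of independent origins of a focal state
#'
#' Per map, counts transitions *into* `to_state` anywhere on the tree (each
#' such transition is one independent origin on that history); summarizes
#' the distribution across maps.
#'
#' @param ms A `simmap_set`.
#' @param to_state Focal (derived) state label.
#' @return List: `counts` (per-map origin counts), `histogram` (table),
#'   `mode`, `range` (min-max), `q95` (central 95% interval).
#' @export
origin_count_distribution <- function(ms, to_state) {
  if (!length(ms$maps)) stop("empty map list")
  j <- match(to_state, ms$state_space)
  if (is.na(j)) stop("to_state not in state space")
  tc <- transition_counts(ms)
  counts <- vapply(tc, function(m) sum(m[-j, j]), numeric(1))
  tab <- table(counts)
  md <- as.integer(names(tab)[which.max(tab)])
  list(counts = counts, histogram = tab, mode = md,
       range = range(counts),
       q95 = unname(stats::quantile(counts, c(0.025, 0.975))))
}

#' Summarize a map set
#'
#' @param ms A `simmap_set`.
#' @return List: `node_state_freqs` (nodes x k matrix of empirical state
#'   frequencies across maps), `mean_transitions` (k x k mean count matrix),
#'   `time_in_state` (edges x k matrix of mean fraction of branch time).
#' @export
summarize_maps <- function(ms) {
  k <- length(ms$state_space)
  n_tip <- length(ms$tree$tip.label)
  n_node <- n_tip + ms$tree$Nnode
  freq <- matrix(0, n_node, k)
  for (m in ms$maps) {
    freq[cbind(seq_len(n_node), m$node_states)] <-
      freq[cbind(seq_len(n_node), m$node_states)] + 1
  }
  freq <- freq / length(ms$maps)
  colnames(freq) <- ms$state_space
  tc <- transition_counts(ms)
  mt <- Reduce(`+`, tc) / length(tc)
  n_edge <- nrow(ms$tree$edge)
  tis <- matrix(0, n_edge, k)
  for (m in ms$maps) {
    for (e in seq_len(n_edge)) {
      h <- m$histories[[e]]
      tot <- sum(h$duration)
      if (tot > 0) {
        for (r in seq_along(h$state)) {
          tis[e, h$state[r]] <- tis[e, h$state[r]] + h$duration[r] / tot
        }
      } else {
        tis[e, h$state[1]] <- tis[e, h$state[1]] + 1
      }
    }
  }
  tis <- tis / length(ms$maps)
  colnames(tis) <- ms$state_space
  list(node_state_freqs = freq, mean_transitions = mt, time_in_state = tis)
}

#' Stochastic mapping of single-area biogeographic states
#'
#' The paper-scale convention: each species occupies exactly one of six
#' regions, and ancestral ranges are sampled under an equal-rates Mk model
#' (no explicit range-expansion modeling). The ER rate is fit by ML first,
#' then maps are drawn at that estimate.
#'
#' @param tree Rooted binary `phylo`.
#' @param regions Named character vector, one region per tip.
#' @param n_maps Number of maps.
#' @param seed Integer seed.
#' @param regions_space Optional fixed region label order.
#' @return List with the `simmap_set` (`maps`), the ER `fit`, and the
#'   node-region frequency summary (`summary`).
#' @export
biogeo_map <- function(tree, regions, n_maps = 500, seed = 1L,
                       regions_space = NULL) {
  if (anyNA(regions)) stop("every tip needs exactly one region")
  miss <- setdiff(tree$tip.label, names(regions))
  if (length(miss)) stop("tips without a region: ", paste(miss, collapse = ", "))
  if (is.null(regions_space)) regions_space <- sort(unique(regions))
  fit <- fit_mk(tree, regions, model = "ER", state_space = regions_space)
  ms <- sample_maps(tree, regions, fit$Q, n_maps, seed = seed,
                    root_prior = fit$root_prior, state_space = regions_space)
  list(maps = ms, fit = fit, summary = summarize_maps(ms))
}

#' Serialize a map set to a segment table
#'
#' @param ms A `simmap_set`.
#' @param file Optional TSV path.
#' @return data.frame: map_id, branch_id, segment_start, segment_end, state
#'   (times measured from the branch's parent end).
#' @export
maps_to_table <- function(ms, file = NULL) {
  ids <- branch_ids(ms$tree)
  rows <- list()
  for (i in seq_along(ms$maps)) {
    m <- ms$maps[[i]]
    for (e in seq_along(m$histories)) {
      h <- m$histories[[e]]
      ends <- cumsum(h$duration)
      rows[[length(rows) + 1]] <- data.frame(
        map_id = i, branch_id = ids[e],
        segment_start = c(0, ends[-length(ends)]), segment_end = ends,
        state = ms$state_space[h$state], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(file)) {
    utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
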