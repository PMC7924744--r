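#' Simulate a Yule (pure-birth) tree
#'
#' Straightforward exponential-splitting construction: starting from two
#' lineages, waiting times between successive splits are Exp(m * lambda)
#' with m the current lineage count, the splitting lineage chosen uniformly;
#' after the (n-1)-th split the final inter-event time extends all tips to
#' the present, giving an ultrametric dated tree.
#'
#' @param n_tips Number of tips (>= 2).
#' @param birth_rate Speciation rate per lineage per My (> 0).
#' @param seed Integer seed (byte-reproducible output).
#' @return Rooted binary ultrametric `phylo` with tips `t1..tn`.
#' @export
simulate_yule_tree <- function(n_tips, birth_rate, seed = 1L) {
  stopifnot(n_tips >= 2, birth_rate > 0)
  set.seed(seed)
  # active lineages tracked by their pendant-edge start times
  max_nodes <- 2L * n_tips - 1L
  edge <- matrix(0L, max_nodes - 1L, 2)
  edge_len <- numeric(max_nodes - 1L)
  # grow as a list of active lineage records: (parent node id, birth time)
  next_node <- 1L
  new_node <- function() { v <- next_node; next_node <<- next_node + 1L; v }
  root <- new_node()
  active_parent <- c(root, root)
  active_birth <- c(0, 0)
  t_now <- 0
  e <- 0L
  while (length(active_parent) < n_tips) {
    m <- length(active_parent)
    t_now <- t_now + stats::rexp(1, m * birth_rate)
    i <- sample.int(m, 1)
    v <- new_node()
    e <- e + 1L
    edge[e, ] <- c(active_parent[i], v)
    edge_len[e] <- t_now - active_birth[i]
    active_parent[i] <- v; active_birth[i] <- t_now
    active_parent <- c(active_parent, v)
    active_birth <- c(active_birth, t_now)
  }
  t_now <- t_now + stats::rexp(1, n_tips * birth_rate)
  # close pendant edges; internal ids first assigned 1..(n-1), remap to
  # ape convention: tips 1..n, root n+1, internals n+1..2n-1
  tip_edges <- cbind(active_parent, seq_len(n_tips))
  n_int <- n_tips - 1L
  remap_int <- function(x) x + n_tips  # internal i -> n_tips + i
  edges_all <- rbind(cbind(remap_int(edge[seq_len(e), 1]),
                           remap_int(edge[seq_len(e), 2])),
                     cbind(remap_int(tip_edges[, 1]), tip_edges[, 2]))
  lens_all <- c(edge_len[seq_len(e)], t_now - active_birth)
  tr <- list(edge = edges_all, edge.length = lens_all,
             tip.label = paste0("t", seq_len(n_tips)), Nnode = n_int)
  class(tr) <- "phylo"
  tr <- ape::reorder.phylo(tr, "cladewise")
  validate_tree(tr)
}

#' Simulate discrete-character evolution along a tree
#'
#' Exact CTMC simulation branch by branch (exponential waiting times,
#' embedded-chain jumps), recording the full history of every transition.
#'
#' @param tree Rooted binary `phylo`.
#' @param Q Rate matrix with state-labelled dimnames.
#' @param root_state Label of the state at the root.
#' @param seed Integer seed.
#' @return List: `states` (named vector of tip states), `history` (list per
#'   edge, in `tree$edge` row order, of state/duration data.frames),
#'   `node_states` (true state index at every node), `n_transitions` (k x k
#'   true transition-count matrix), `state_space`.
#' @export
simulate_mk <- function(tree, Q, root_state, seed = 1L) {
  set.seed(seed)
  state_space <- colnames(Q)
  k <- length(state_space)
  r0 <- match(root_state, state_space)
  if (is.na(r0)) stop("root_state not in state space")
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  node_states <- integer(n_node)
  node_states[n_tip + 1L] <- r0
  cw <- ape::reorder.phylo(tree, "cladewise")  # parents before children
  histories <- vector("list", nrow(cw$edge))
  cnt <- matrix(0L, k, k, dimnames = list(state_space, state_space))
  for (e in seq_len(nrow(cw$edge))) {
    p <- cw$edge[e, 1]; ch <- cw$edge[e, 2]
    s <- node_states[p]
    t_left <- cw$edge.length[e]
    st <- integer(0); du <- numeric(0)
    repeat {
      rate <- -Q[s, s]
      w <- if (rate > 0) stats::rexp(1, rate) else Inf
      if (w >= t_left) {
        st <- c(st, s); du <- c(du, t_left)
        break
      }
      st <- c(st, s); du <- c(du, w)
      t_left <- t_left - w
      s_new <- sample.int(k, 1, prob = pmax(Q[s, ], 0) * (seq_len(k) != s))
      cnt[s, s_new] <- cnt[s, s_new] + 1L
      s <- s_new
    }
    histories[[e]] <- data.frame(state = st, duration = du)
    node_states[ch] <- s
  }
  # map histories back to tree$edge row order
  ord <- match(paste(tree$edge[, 1], tree$edge[, 2]),
               paste(cw$edge[, 1], cw$edge[, 2]))
  states <- stats::setNames(state_space[node_states[seq_len(n_tip)]],
                            tree$tip.label)
  list(states = states, history = histories[ord],
       node_states = node_states, n_transitions = cnt,
       state_space = state_space)
}

#' Engineer a radiation with an exact number of convergent origins
#'
#' Rather than tuning rates and hoping, the history is painted explicitly:
#' `n_origins` disjoint clades (tip counts within `clade_size`) are chosen
#' on a simulated Yule tree, a single 0 -> 1 transition is placed at the
#' midpoint of each clade's stem branch, and no losses occur. The emitted
#' truth is therefore exact by construction.
#'
#' @param n_tips Tree size.
#' @param n_origins Exact number of independent origins of the derived
#'   state (>= 1).
#' @param birth_rate Yule speciation rate (per My).
#' @param seed Integer seed.
#' @param clade_size Allowed tip-count range for each derived clade.
#' @param states Labels for (ancestral, derived), default GRP/TRAP.
#' @param max_attempts Trees tried before giving up (infeasible request).
#' @return List: `tree`, `states` (named tip vector), `truth` (list with
#'   `origin_edges` — child-node ids of stem branches, `n_origins`,
#'   `n_losses`, `node_states`).
#' @export
simulate_radiation_with_convergence <- function(n_tips, n_origins,
                                                birth_rate = 0.1, seed = 1L,
                                                clade_size = c(5, 40),
                                                states = c("GRP", "TRAP"),
                                                max_attempts = 50) {
  stopifnot(n_origins >= 1)
  for (att in seq_len(max_attempts)) {
    tree <- simulate_yule_tree(n_tips, birth_rate,
                               seed = (seed * 131L + att) %% 2147483647L)
    sets <- clade_tip_sets(tree)
    n_tip <- length(tree$tip.label)
    sizes <- lengths(sets)
    cand <- which(sizes >= clade_size[1] & sizes <= clade_size[2] &
                    seq_along(sets) > n_tip)
    # greedily pick disjoint clades, randomized
    set.seed((seed * 977L + att) %% 2147483647L)
    cand <- sample(cand)
    chosen <- integer(0)
    used <- logical(n_tip)
    for (v in cand) {
      tips_v <- sets[[v]]
      if (!any(used[tips_v])) {
        chosen <- c(chosen, v)
        used[tips_v] <- TRUE
        if (length(chosen) == n_origins) break
      }
    }
    if (length(chosen) < n_origins) next
    derived_tips <- sort(unlist(sets[chosen]))
    if (length(derived_tips) == n_tip) next  # need at least one ancestral tip
    tipstates <- rep(states[1], n_tip)
    tipstates[derived_tips] <- states[2]
    node_states <- rep(1L, n_tip + tree$Nnode)
    for (v in chosen) {
      below <- c(v, which(vapply(seq_along(sets), function(u)
        u > n_tip && all(sets[[u]] %in% sets[[v]]), logical(1))))
      node_states[unique(c(below, sets[[v]]))] <- 2L
    }
    return(list(tree = tree,
                states = stats::setNames(tipstates, tree$tip.label),
                truth = list(origin_edges = chosen, n_origins = n_origins,
                             n_losses = 0L, node_states = node_states,
                             state_space = states)))
  }
  stop("could not place ", n_origins, " disjoint clades of size ",
       clade_size[1], "-", clade_size[2], " in ", max_attempts, " attempts")
}

#' Simulate a digitized strike trace with analytic truth
#'
#' Profiles: `linear` theta = A t / T; `quadratic` theta = A (t/T)^2
#' (constant angular acceleration 2A/T^2); `logistic`
#' theta = A / (1 + exp(-(t - t0)/tau)) with t0 = T/2, tau = T/20
#' (peak angular velocity A/(4 tau) at t0). Gaussian angle noise is added
#' after sampling.
#'
#' @param profile "linear", "quadratic", or "logistic".
#' @param amplitude Total excursion A (rad).
#' @param timescale Event duration T (s).
#' @param fps Frame rate; `fps * timescale` must give >= 8 samples.
#' @param noise_sd Angle noise SD (rad).
#' @param seed Integer seed.
#' @return List: `trace` (a [strike_trace()]), `truth` (list with
#'   `omega_max`, `alpha_max`, `t_omega_max`, and the profile function
#'   `theta`).
#' @export
simulate_strike <- function(profile = c("linear", "quadratic", "logistic"),
                            amplitude = 1, timescale = 1e-3, fps = 1e5,
                            noise_sd = 0, seed = 1L) {
  profile <- match.arg(profile)
  n <- floor(fps * timescale) + 1
  if (n < 8) stop("under-sampled: fps * timescale gives fewer than 8 samples")
  t <- seq(0, by = 1 / fps, length.out = n)
  TT <- timescale; A <- amplitude
  if (profile == "linear") {
    theta <- function(x) A * x / TT
    truth <- list(omega_max = A / TT, alpha_max = 0, t_omega_max = TT)
  } else if (profile == "quadratic") {
    theta <- function(x) A * (x / TT)^2
    truth <- list(omega_max = 2 * A / TT, alpha_max = 2 * A / TT^2,
                  t_omega_max = TT)
  } else {
    t0 <- TT / 2; tau <- TT / 20
    theta <- function(x) A / (1 + exp(-(x - t0) / tau))
    # peak |theta''| of the logistic: A/tau^2 * 1/(6*sqrt(3))
    truth <- list(omega_max = A / (4 * tau),
                  alpha_max = A / (tau^2 * 6 * sqrt(3)),
                  t_omega_max = t0)
  }
  set.seed(seed)
  y <- theta(t) + if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else 0
  truth$theta <- theta
  list(trace = strike_trace(t, y, specimen = paste0(profile, "_s", seed)),
       truth = truth)
}

#' Simulate landmark configurations for ecomorph groups
#'
#' Per specimen: group mean shape + isotropic Gaussian landmark noise, then
#' a random rigid motion and positive scaling (the nuisance transforms GPA
#' must remove).
#'
#' @param group_means List of landmarks x 3 mean shapes (one per group,
#'   named).
#' @param within_sd Landmark noise SD (same units as the means).
#' @param n_per_group Specimens per group.
#' @param scale_range Range of random positive scales.
#' @param translate_range Max |translation| per axis.
#' @param seed Integer seed.
#' @return List: `configs` (named list of matrices), `groups` (factor).
#' @export
simulate_landmarks <- function(group_means, within_sd = 0, n_per_group = 5,
                               scale_range = c(0.5, 2),
                               translate_range = 5, seed = 1L) {
  set.seed(seed)
  if (is.null(names(group_means))) {
    names(group_means) <- paste0("g", seq_along(group_means))
  }
  configs <- list(); groups <- character(0)
  for (g in names(group_means)) {
    mu <- as.matrix(group_means[[g]])
    for (i in seq_len(n_per_group)) {
      x <- mu + matrix(stats::rnorm(length(mu), 0, within_sd), nrow(mu), 3)
      R <- random_rotation()
      s <- stats::runif(1, scale_range[1], scale_range[2])
      tr <- stats::runif(3, -translate_range, translate_range)
      y <- sweep(s * x %*% t(R), 2, tr, `+`)
      nm <- paste0(g, "_", i)
      configs[[nm]] <- y
      groups <- c(groups, g)
    }
  }
  list(configs = configs, groups = factor(groups, levels = names(group_means)))
}

# uniform random proper rotation via QR of a Gaussian matrix
#' @keywords internal
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  d <- diag(sign(diag(qr.R(qr_))))
  R <- R %*% d
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

#' Simulate a locus presence/absence matrix
#'
#' `random` model: each cell present independently with probability
#' `1 - dropout`. `clade` model: each locus is born on a random branch
#' (so only that clade can carry it) and then lost along descendant
#' branches at `disruption_rate` per My; once lost in a lineage it stays
#' lost — absence is blocked by clade, the mutation-disruption signature.
#'
#' @param tree Rooted binary `phylo`.
#' @param n_loci Number of loci (columns).
#' @param model "random" or "clade".
#' @param dropout Per-cell absence probability (random model).
#' @param disruption_rate Loss rate per My along branches (clade model).
#' @param seed Integer seed.
#' @return Binary matrix, rows = tip labels, columns = loci.
#' @export
simulate_locus_presence <- function(tree, n_loci, model = c("random", "clade"),
                                    dropout = 0.5, disruption_rate = 0.05,
                                    seed = 1L) {
  model <- match.arg(model)
  set.seed(seed)
  n_tip <- length(tree$tip.label)
  if (model == "random") {
    m <- matrix(stats::rbinom(n_tip * n_loci, 1, 1 - dropout), n_tip, n_loci)
  } else {
    sets <- clade_tip_sets(tree)
    cw <- ape::reorder.phylo(tree, "cladewise")
    n_node <- n_tip + tree$Nnode
    parent_edge <- match(seq_len(n_node), cw$edge[, 2])
    m <- matrix(0L, n_tip, n_loci)
    # birth branch chosen length-weighted; root allowed (whole tree)
    birth_nodes <- c(n_tip + 1L, cw$edge[, 2])
    birth_w <- c(mean(cw$edge.length), cw$edge.length)
    for (l in seq_len(n_loci)) {
      b <- birth_nodes[sample.int(length(birth_nodes), 1, prob = birth_w)]
      alive <- rep(FALSE, n_node); alive[b] <- TRUE
      for (e in seq_len(nrow(cw$edge))) {
        p <- cw$edge[e, 1]; ch <- cw$edge[e, 2]
        if (alive[p]) {
          alive[ch] <- stats::runif(1) <
            exp(-disruption_rate * cw$edge.length[e])
        }
      }
      m[, l] <- as.integer(alive[seq_len(n_tip)])
    }
  }
  rownames(m) <- tree$tip.label
  colnames(m) <- paste0("locus", seq_len(n_loci))
  m
}
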