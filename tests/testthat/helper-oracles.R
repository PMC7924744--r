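# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: transition probabilities come from closed forms,
# likelihoods from exhaustive enumeration, quartet counts from per-locus
# set logic, and bridge distributions from parity/rejection arguments.

# closed-form 2-state transition matrix, general rates a (1->2) and b (2->1)
p2_closed <- function(a, b, t) {
  s <- a + b
  if (s == 0) return(diag(2))
  e <- exp(-s * t)
  rbind(c(b / s + a / s * e, a / s - a / s * e),
        c(b / s - b / s * e, a / s + b / s * e))
}

# closed-form k-state equal-rates transition matrix (off-diagonal rate q)
pk_er_closed <- function(k, q, t) {
  e <- exp(-k * q * t)
  matrix((1 - e) / k, k, k) + diag(rep(e, k))
}

# exhaustive-enumeration Mk likelihood: sums over every assignment of
# states to interior nodes, multiplying closed-form edge probabilities
enum_loglik <- function(tree, states, pfun, k, root_prior = rep(1 / k, k)) {
  n_tip <- length(tree$tip.label)
  n_int <- tree$Nnode
  tipidx <- match(states[tree$tip.label], seq_len(k))
  total <- 0
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), n_int)))
  for (g in seq_len(nrow(grid))) {
    assign_state <- function(v) {
      if (v <= n_tip) tipidx[v] else grid[g, v - n_tip]
    }
    p <- root_prior[assign_state(n_tip + 1L)]
    for (e in seq_len(nrow(tree$edge))) {
      sp <- assign_state(tree$edge[e, 1])
      sc <- assign_state(tree$edge[e, 2])
      p <- p * pfun(tree$edge.length[e])[sp, sc]
    }
    total <- total + p
  }
  log(total)
}

# brute-force quartet-informative counts: per internal branch, build the
# four tip sets directly from clade membership and loop over loci
quartet_oracle <- function(tree, mat) {
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  desc <- function(v) {
    if (v <= n_tip) return(tree$tip.label[v])
    ape::extract.clade(tree, v)$tip.label
  }
  kids_of <- function(v) tree$edge[tree$edge[, 1] == v, 2]
  internal <- tree$edge[, 2][tree$edge[, 2] > n_tip]
  out <- sapply(internal, function(v) {
    ch <- kids_of(v)
    p <- tree$edge[tree$edge[, 2] == v, 1]
    sib <- setdiff(kids_of(p), v)
    if (p == root) {
      if (sib <= n_tip) return(NA_integer_)
      gk <- kids_of(sib)
      sets <- list(desc(ch[1]), desc(ch[2]), desc(gk[1]), desc(gk[2]))
    } else {
      rest <- setdiff(tree$tip.label, c(desc(p)))
      sets <- list(desc(ch[1]), desc(ch[2]), desc(sib), rest)
    }
    sum(apply(mat, 2, function(col) {
      all(vapply(sets, function(s) any(col[s] > 0), logical(1)))
    }))
  })
  data.frame(child_node = internal, n_informative = out)
}

# random small ultrametric-ish tree via ape (independent of the package's
# Yule generator)
random_small_tree <- function(n) {
  tr <- ape::rtree(n)
  tr$edge.length <- tr$edge.length + 0.1
  tr
}

# dense-grid numerical derivative check utility
num_deriv_max <- function(f, lo, hi, order = 1, n = 20001) {
  x <- seq(lo, hi, length.out = n)
  y <- f(x)
  d <- y
  for (i in seq_len(order)) d <- diff(d) / diff(x)[1]
  max(abs(d))
}
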