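test_that("transition probabilities obey CTMC basics and the 2-state closed form", {
  Q <- build_q(0.5, c("0", "1"), "ER")
  expect_equal(transition_probs(Q, 0), diag(2))
  # stay probability (1 + exp(-2qt))/2 at q = 0.5, t = 1
  P <- transition_probs(Q, 1)
  expect_equal(P[1, 1], 0.5 * (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(rowSums(P), c(1, 1), tolerance = 1e-12)
  # stationary limit
  Pinf <- transition_probs(Q, 1e6 / 0.5)
  expect_equal(as.vector(Pinf), rep(0.5, 4), tolerance = 1e-6)
  expect_error(transition_probs(Q, -1), ">= 0")

  # spectral route agrees with scaling-and-squaring and Matrix::expm on an
  # asymmetric generator
  Qa <- build_q(c(0.3, 1.2), c("0", "1"), "ARD")
  P1 <- transition_probs(Qa, 0.7)
  P2 <- trapjawkit:::expm_ss(Qa * 0.7)
  expect_equal(P1, P2, tolerance = 1e-10, ignore_attr = TRUE)
  skip_if_not_installed("Matrix")
  P3 <- as.matrix(Matrix::expm(Qa * 0.7))
  expect_equal(P1, P3, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("pruning log-likelihood matches exhaustive enumeration", {
  # binary ER and ARD, and 3-state ER, random small trees
  for (sd in 1:20) {
    set.seed(sd)
    tr <- random_small_tree(sample(3:6, 1))
    k <- sample(2:3, 1)
    labs <- as.character(seq_len(k))
    states <- setNames(labs[sample.int(k, length(tr$tip.label), replace = TRUE)],
                       tr$tip.label)
    if (k == 2 && sd %% 2 == 0) {
      a <- runif(1, 0.05, 1); b <- runif(1, 0.05, 1)
      Q <- build_q(c(a, b), labs, "ARD")
      pfun <- function(t) p2_closed(a, b, t)
    } else {
      q <- runif(1, 0.05, 1)
      Q <- build_q(q, labs, "ER")
      pfun <- function(t) pk_er_closed(k, q, t)
    }
    want <- enum_loglik(tr, states, pfun, k)
    got <- mk_loglik(tr, states, Q)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("likelihood limits behave: concordant cherry, impossible data, missing tips", {
  tr <- parse_newick("(A:1,B:1):0;")
  labs <- c("0", "1")
  same <- setNames(c("0", "0"), c("A", "B"))
  diff <- setNames(c("0", "1"), c("A", "B"))
  # q -> 0 with equal tip states: loglik -> log(0.5) under a flat prior
  expect_equal(mk_loglik(tr, same, build_q(1e-9, labs, "ER")),
               log(0.5), tolerance = 1e-6)
  # q = 0 with differing states: impossible
  expect_equal(mk_loglik(tr, diff, build_q(0, labs, "ER")), -Inf)
  # missing tip = full ambiguity: cherry with one NA reduces to one tip
  miss <- setNames(c("0", NA), c("A", "B"))
  expect_equal(mk_loglik(tr, miss, build_q(0.3, labs, "ER")),
               log(0.5), tolerance = 1e-9)
  # unknown state label errors
  expect_error(mk_loglik(tr, setNames(c("0", "2"), c("A", "B")),
                         build_q(0.3, labs, "ER")), "outside state space")
})

test_that("likelihood is invariant to branch/rate rescaling", {
  tr <- simulate_yule_tree(40, 0.2, seed = 9)
  Q <- build_q(0.07, c("GRP", "TRAP"), "ER")
  sim <- simulate_mk(tr, Q, "GRP", seed = 2)
  l1 <- mk_loglik(tr, sim$states, Q)
  tr2 <- tr; tr2$edge.length <- tr$edge.length * 3.7
  l2 <- mk_loglik(tr2, sim$states, build_q(0.07 / 3.7, c("GRP", "TRAP"), "ER"))
  expect_equal(l1, l2, tolerance = 1e-9)
})

test_that("AICc formula and large-n limit", {
  expect_equal(aicc(-10, 1, 20), 22 + 2 / 9)
  # AICc - AIC -> 0 as n grows
  expect_lt(abs(aicc(-10, 2, 1e4) - (-2 * -10 + 4)), 0.01)
})

test_that("fit_mk recovers rates and matches an independent ML fitter", {
  tr <- simulate_yule_tree(150, 0.2, seed = 21)
  Q <- build_q(0.05, c("GRP", "TRAP"), "ER")
  sim <- simulate_mk(tr, Q, "GRP", seed = 22)
  fit <- fit_mk(tr, sim$states, "ER")
  expect_lt(abs(fit$rates - 0.05) / 0.05, 1)  # same order of magnitude
  # loglik at the optimum beats the truth's loglik or matches it
  expect_gte(fit$loglik + 1e-6, mk_loglik(tr, sim$states, Q))
  skip_if_not_installed("phytools")
  x <- factor(sim$states)
  pf <- phytools::fitMk(tr, setNames(x, names(sim$states)), model = "ER",
                        pi = "equal")
  expect_equal(fit$loglik, pf$logLik, tolerance = 1e-4, ignore_attr = TRUE)
  expect_equal(unname(fit$rates), pf$rates, tolerance = 0.02)
})

test_that("monomorphic tip data warn and pin the rate at the lower bound", {
  tr <- simulate_yule_tree(20, 0.2, seed = 3)
  states <- setNames(rep("GRP", 20), tr$tip.label)
  expect_warning(
    fit <- fit_mk(tr, states, "ER", state_space = c("GRP", "TRAP")),
    "lower bound")
  expect_lt(fit$rates, 1e-7)
})

test_that("marginal ancestral states match brute-force marginalization", {
  # 3-tip tree: marginalize the non-focal interior node by enumeration
  tr <- parse_newick("((A:0.6,B:0.9):0.5,C:1.2);")
  labs <- c("0", "1")
  states <- setNames(c("0", "1", "1"), c("A", "B", "C"))
  q <- 0.4
  Q <- build_q(q, labs, "ER")
  M <- marginal_ancestral(tr, states, Q)
  pfun <- function(t) pk_er_closed(2, q, t)
  # enumerate over both interior nodes, fixing the focal one
  tipidx <- match(states[tr$tip.label], labs)
  joint <- matrix(0, 2, 2)  # joint[root_state, inner_state]
  for (r in 1:2) for (i in 1:2) {
    st <- c(tipidx, r, i)   # nodes 4 (root), 5 (inner)
    p <- 0.5
    for (e in seq_len(nrow(tr$edge))) {
      p <- p * pfun(tr$edge.length[e])[st[tr$edge[e, 1]], st[tr$edge[e, 2]]]
    }
    joint[r, i] <- p
  }
  expect_equal(M[4, ], rowSums(joint) / sum(joint), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(M[5, ], colSums(joint) / sum(joint), tolerance = 1e-10,
               ignore_attr = TRUE)
  # root marginal weighted by the prior reproduces the pruning likelihood
  expect_equal(sum(joint), exp(mk_loglik(tr, states, Q)), tolerance = 1e-12)
})

test_that("marginal reconstructions honor symmetry and concordant limits", {
  tr <- parse_newick("(A:1,B:1):0;")
  labs <- c("0", "1")
  M <- marginal_ancestral(tr, setNames(c("0", "1"), c("A", "B")),
                         build_q(0.3, labs, "ER"))
  expect_equal(M[3, ], c(0.5, 0.5), tolerance = 1e-12, ignore_attr = TRUE)

  tr2 <- simulate_yule_tree(10, 0.3, seed = 4)
  M2 <- marginal_ancestral(tr2, setNames(rep("1", 10), tr2$tip.label),
                           build_q(1e-6, c("0", "1"), "ER"))
  expect_true(all(M2[11:19, 2] > 0.999))
})
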