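ref_tetra <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))

test_that("centering and scaling remove location and size", {
  shifted <- sweep(ref_tetra, 2, c(5, 5, 5), `+`)
  cs <- center_and_scale(shifted)
  expect_equal(colMeans(cs$coords), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(sqrt(sum(cs$coords^2)), 1, tolerance = 1e-12)
  cs3 <- center_and_scale(ref_tetra * 3)
  expect_equal(cs3$coords, cs$coords, tolerance = 1e-12)
  expect_equal(cs3$centroid_size / center_and_scale(ref_tetra)$centroid_size, 3)
  expect_error(center_and_scale(matrix(1, 4, 3)), "degenerate")
})

test_that("pairwise superimposition recovers rotations and rejects reflections", {
  a <- center_and_scale(ref_tetra)$coords
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  b <- a %*% t(R)
  fit <- procrustes_superimpose(a, b)
  expect_lt(fit$distance, 1e-10)
  expect_equal(fit$rotation %*% R, diag(3), tolerance = 1e-10)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-12)
  # mirrored copy cannot be aligned exactly (chirality preserved)
  m <- a %*% diag(c(-1, 1, 1))
  fitm <- procrustes_superimpose(a, m)
  expect_gt(fitm$distance, 0.1)
  expect_equal(det(fitm$rotation), 1, tolerance = 1e-12)
})

test_that("superimposition matches a rotation-grid brute force", {
  set.seed(8)
  a <- center_and_scale(matrix(rnorm(12 * 3), 12, 3))$coords
  b <- center_and_scale(matrix(rnorm(12 * 3), 12, 3))$coords
  fit <- procrustes_superimpose(a, b)
  # coarse search over rotations (axis-angle grid), then refine nothing:
  # the SVD optimum must beat or match every grid rotation
  gr <- seq(0, 2 * pi, length.out = 25)[-25]
  best <- Inf
  for (ax in list(c(1,0,0), c(0,1,0), c(0,0,1), c(1,1,1)/sqrt(3))) {
    for (th in gr) {
      K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3,
                  byrow = TRUE)
      R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
      best <- min(best, sqrt(sum((b %*% t(R) - a)^2)))
    }
  }
  expect_lte(fit$distance, best + 1e-9)
})

test_that("GPA collapses nuisance-only variation and ignores input order", {
  sim <- simulate_landmarks(list(g = ref_tetra), within_sd = 0,
                            n_per_group = 10, seed = 3)
  g <- gpa(sim$configs)
  d <- vapply(g$aligned, function(x) sqrt(sum((x - g$aligned[[1]])^2)),
              numeric(1))
  expect_lt(max(d), 1e-8)
  expect_equal(g$mean_shape, g$aligned[[1]], tolerance = 1e-7)
  # permutation invariance of the consensus
  g2 <- gpa(rev(sim$configs))
  expect_equal(procrustes_superimpose(g$mean_shape, g2$mean_shape)$distance, 0,
               tolerance = 1e-7)
  expect_error(gpa(sim$configs[1]), "at least 2")
})

test_that("GPA is invariant to fresh nuisance transforms of the same shapes", {
  base <- list(A = ref_tetra, B = ref_tetra + 0.2 * diag(4)[, 1:3] %*% diag(3))
  shapes <- rep(base, 3)
  names(shapes) <- paste0(names(shapes), 1:6)
  for (sd in c(4, 5)) {
    set.seed(sd)
    pert <- lapply(shapes, function(x) {
      R <- trapjawkit:::random_rotation()
      runif(1, 0.5, 2) * x %*% t(R) + matrix(runif(3, -5, 5), 4, 3,
                                             byrow = TRUE)
    })
    g <- gpa(pert)
    if (sd == 4) mean4 <- g$mean_shape
    else expect_equal(procrustes_superimpose(mean4, g$mean_shape)$distance, 0,
                      tolerance = 1e-6)
  }
})

test_that("tangent PCA decomposes variance exactly", {
  set.seed(10)
  shapes <- lapply(1:8, function(i) ref_tetra + matrix(rnorm(12, 0, 0.05), 4, 3))
  g <- gpa(shapes)
  p <- tangent_pca(g)
  V <- t(vapply(g$aligned, as.vector, numeric(12)))
  total_var <- sum(apply(V, 2, var))
  expect_equal(sum(p$eigenvalues), total_var, tolerance = 1e-9)
  expect_true(all(diff(p$eigenvalues) <= 1e-12))
  expect_equal(sum(p$proportion_variance), 1, tolerance = 1e-9)
  expect_equal(colMeans(p$scores), rep(0, ncol(p$scores)), tolerance = 1e-10,
               ignore_attr = TRUE)
  # full reconstruction from all components
  rec <- p$scores %*% p$loadings + matrix(p$center, 8, 12, byrow = TRUE)
  expect_equal(rec, V, tolerance = 1e-9, ignore_attr = TRUE)
  # identical specimens: zero variance
  g0 <- gpa(rep(list(ref_tetra), 4))
  expect_lt(sum(tangent_pca(g0)$eigenvalues), 1e-15)
  expect_error(tangent_pca(g0$aligned[1:2]), "at least 3")
})

test_that("ecomorph groups separate in tangent space when shifts dominate noise", {
  means <- list(GRP = ref_tetra,
                STRAP = ref_tetra + 0.3 * outer(c(1, 0, 1, 0), c(1, 0, 0)),
                LTRAP = ref_tetra + 0.3 * outer(c(0, 1, 0, 1), c(0, 0, 1)))
  sim <- simulate_landmarks(means, within_sd = 0.01, n_per_group = 9, seed = 12)
  p <- tangent_pca(gpa(sim$configs))
  skip_if_not_installed("cluster")
  sil <- cluster::silhouette(as.integer(sim$groups),
                             dist(p$scores[, 1:2]))
  expect_gt(mean(sil[, 3]), 0.5)
})

test_that("mandible index is a plain scale-free ratio", {
  expect_equal(mandible_index(1, 1), 1)
  expect_equal(mandible_index(0.5, 1), 0.5)
  expect_equal(mandible_index(0.5 * 1000, 1 * 1000), 0.5)
  expect_equal(mandible_index(median_of_range(0.4, 0.6), 1), 0.5)
  expect_error(mandible_index(0, 1), "positive")
})

test_that("latch angle handles planar, subparallel, and reflex geometries", {
  fwd <- c(1, 0, 0)
  expect_equal(latch_angle(c(1, 1, 0), c(0, 0, 0), c(1, -1, 0), c(0, 0, 0),
                           anterior = fwd), 90, tolerance = 1e-9)
  expect_equal(latch_angle(c(2, 0.001, 0), c(0, 0.001, 0), c(2, -0.001, 0),
                           c(0, -0.001, 0), anterior = fwd), 0,
               tolerance = 1e-2)
  expect_equal(latch_angle(c(-1, 1, 0), c(0, 0, 0), c(-1, -1, 0), c(0, 0, 0),
                           anterior = fwd), 270, tolerance = 1e-9)
  expect_error(latch_angle(c(0, 0, 0), c(0, 0, 0), c(1, 1, 0), c(0, 0, 0)),
               "coincident")
  # rigid-motion invariance
  set.seed(2)
  R <- trapjawkit:::random_rotation(); shift <- c(3, -2, 5)
  mv <- function(x) as.vector(R %*% x + shift)
  expect_equal(
    latch_angle(mv(c(1, 1, 0)), mv(c(0, 0, 0)), mv(c(1, -1, 0)), mv(c(0, 0, 0)),
                anterior = as.vector(R %*% fwd)),
    90, tolerance = 1e-6)
  # reflecting through the plane perpendicular to the anterior axis
  # complements the angle to 360
  expect_equal(
    latch_angle(c(-1, 1, 0), c(0, 0, 0), c(-1, -1, 0), c(0, 0, 0),
                anterior = fwd) +
      latch_angle(c(1, 1, 0), c(0, 0, 0), c(1, -1, 0), c(0, 0, 0),
                  anterior = fwd),
    360, tolerance = 1e-9)
})
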