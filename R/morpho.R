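#' Center a landmark configuration and scale to unit centroid size
#'
#' @param config Numeric matrix, landmarks x 3.
#' @return List: `coords` (centered, unit centroid size), `centroid_size`
#'   (original, root-sum-of-squares of distances to the centroid).
#' @export
center_and_scale <- function(config) {
  config <- as.matrix(config)
  if (any(!is.finite(config))) stop("non-finite landmark coordinates")
  ctr <- colMeans(config)
  x <- sweep(config, 2, ctr)
  cs <- sqrt(sum(x^2))
  if (cs < 1e-12) stop("degenerate configuration: all landmarks coincide")
  list(coords = x / cs, centroid_size = cs)
}

#' Optimal rotation of one configuration onto another
#'
#' Ordinary Procrustes superimposition of two centered, unit-size
#' configurations: the rotation (proper, det +1; reflections excluded
#' because left/right anatomy is chiral) minimizing the sum of squared
#' landmark differences, by SVD of the cross-covariance. Degenerate
#' cross-covariance is tie-broken deterministically by flipping the sign of
#' the smallest singular vector.
#'
#' @param a,b Landmarks x 3 matrices, centered and unit centroid size
#'   (`b` is rotated onto `a`).
#' @return List: `rotation` (3x3, det +1), `aligned` (b rotated),
#'   `distance` (root-sum-of-squares Procrustes distance).
#' @export
procrustes_superimpose <- function(a, b) {
  H <- crossprod(b, a)   # 3x3 cross-covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1  # rank-deficient tie: keep orientation
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  aligned <- b %*% t(R)
  list(rotation = R, aligned = aligned,
       distance = sqrt(sum((aligned - a)^2)))
}

#' Generalized Procrustes analysis
#'
#' Removes translation, scale, and rotation from a set of landmark
#' configurations by iterating align-to-mean / update-mean until the mean
#' shape stabilizes. All configurations end centered with unit centroid
#' size; the consensus is their coordinate-wise mean at convergence.
#'
#' @param configs List of landmarks x 3 matrices (same landmark count and
#'   order), optionally named.
#' @param tol Convergence tolerance on the root-sum-of-squares change of the
#'   mean shape (default 1e-10).
#' @param max_iter Iteration cap.
#' @return Object of class `gpa_fit`: `aligned` (list of matrices),
#'   `mean_shape`, `centroid_sizes`, `iterations`.
#' @export
gpa <- function(configs, tol = 1e-10, max_iter = 100) {
  if (length(configs) < 2) stop("GPA needs at least 2 configurations")
  dims <- vapply(configs, dim, integer(2))
  if (length(unique(dims[1, ])) != 1 || any(dims[2, ] != 3)) {
    stop("all configurations must share the same landmarks x 3 dimensions")
  }
  cs <- lapply(configs, center_and_scale)
  X <- lapply(cs, `[[`, "coords")
  sizes <- vapply(cs, `[[`, numeric(1), "centroid_size")
  mean_shape <- X[[1]]
  for (it in seq_len(max_iter)) {
    X <- lapply(X, function(x) procrustes_superimpose(mean_shape, x)$aligned)
    new_mean <- Reduce(`+`, X) / length(X)
    new_mean <- center_and_scale(new_mean)$coords  # keep consensus unit-size
    delta <- sqrt(sum((new_mean - mean_shape)^2))
    mean_shape <- new_mean
    if (delta < tol) {
      return(structure(list(aligned = X, mean_shape = mean_shape,
                            centroid_sizes = sizes, iterations = it),
                       class = "gpa_fit"))
    }
  }
  stop("GPA failed to converge in ", max_iter,
       " iterations (last change ", format(delta), ")")
}

#' @export
print.gpa_fit <- function(x, ...) {
  cat("GPA: ", length(x$aligned), " configurations, ",
      nrow(x$mean_shape), " landmarks, converged in ", x$iterations,
      " iteration(s)\n", sep = "")
  invisible(x)
}

#' Tangent-space principal component analysis of aligned shapes
#'
#' PCA of the vectorized Procrustes-aligned coordinates (the standard
#' tangent-space approximation; shape variation is assumed small). Each
#' loading vector's largest-magnitude element is made positive so scores
#' are reproducible across platforms.
#'
#' @param aligned A `gpa_fit` (or list of aligned landmarks x 3 matrices).
#' @return Object of class `shape_pca`: `scores` (specimens x components),
#'   `eigenvalues` (descending), `proportion_variance`, `loadings`
#'   (components x 3p), `center` (mean vector).
#' @export
tangent_pca <- function(aligned) {
  X <- if (inherits(aligned, "gpa_fit")) aligned$aligned else aligned
  n <- length(X)
  if (n < 3) stop("tangent PCA needs at least 3 specimens")
  V <- t(vapply(X, as.vector, numeric(length(X[[1]]))))
  ctr <- colMeans(V)
  Vc <- sweep(V, 2, ctr)
  pc <- stats::prcomp(Vc, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2
  # deterministic sign convention
  load <- t(pc$rotation)
  for (i in seq_len(nrow(load))) {
    j <- which.max(abs(load[i, ]))
    if (load[i, j] < 0) {
      load[i, ] <- -load[i, ]
      pc$x[, i] <- -pc$x[, i]
    }
  }
  structure(list(scores = pc$x, eigenvalues = ev,
                 proportion_variance = ev / sum(ev),
                 loadings = load, center = ctr,
                 names = names(X)),
            class = "shape_pca")
}

#' @export
print.shape_pca <- function(x, ...) {
  cat("Tangent-space PCA: ", nrow(x$scores), " specimens\n", sep = "")
  pv <- round(100 * x$proportion_variance[1:min(4, length(x$eigenvalues))], 1)
  cat("  variance explained (PC1..):", paste0(pv, "%", collapse = ", "), "\n")
  invisible(x)
}

#' Mandible index
#'
#' Mandible length relative to head length, the primary linear descriptor
#' of mandible elongation. When a description gives a measurement range not
#' tied to individual specimens, pass the median of the range.
#'
#' @param mandible_length,head_length Lengths in the same unit (> 0).
#' @return Dimensionless ratio (vectorized).
#' @export
mandible_index <- function(mandible_length, head_length) {
  if (any(mandible_length <= 0) || any(head_length <= 0)) {
    stop("lengths must be positive")
  }
  mandible_length / head_length
}

#' Median-of-range helper for literature measurements
#' @param lo,hi Range endpoints.
#' @return Midpoint of the range.
#' @export
median_of_range <- function(lo, hi) (lo + hi) / 2

#' Latch (mandible opening) angle
#'
#' Angle between the two mandible lines, each directed from the base of the
#' basal mandibular process through the base of the apical tooth, measured
#' in the best-fit plane of the four points. The angle is reflex-capable:
#' it opens on the anterior side (defined by `anterior`, default +y), so
#' mandibles latched past straight read as > 180 deg, up to the observed
#' extreme near 270 deg; parallel forward-pointing mandibles read 0
#' ("subparallel").
#'
#' @param apical_L,bmp_L,apical_R,bmp_R 3D points (length-3 numerics): base
#'   of the apical tooth and base of the basal mandibular process, left and
#'   right mandibles.
#' @param anterior Direction of the head's anterior axis used to orient the
#'   angle (default `c(0, 1, 0)`).
#' @return Angle in degrees, in [0, 360).
#' @export
latch_angle <- function(apical_L, bmp_L, apical_R, bmp_R,
                        anterior = c(0, 1, 0)) {
  vL <- apical_L - bmp_L
  vR <- apical_R - bmp_R
  if (sqrt(sum(vL^2)) < 1e-12 || sqrt(sum(vR^2)) < 1e-12) {
    stop("coincident apical/bmp points")
  }
  pts <- rbind(apical_L, bmp_L, apical_R, bmp_R)
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2, ctr))
  nrm <- sv$v[, 3]                   # best-fit plane normal
  cond <- sv$d[2] / max(sv$d[1], 1e-300)
  if (cond < 1e-6) {
    warning("near-degenerate landmark plane (condition ", format(cond), ")")
  }
  proj <- function(v) v - nrm * sum(nrm * v)
  uL <- proj(vL); uR <- proj(vR)
  uL <- uL / sqrt(sum(uL^2)); uR <- uR / sqrt(sum(uR^2))
  ant <- proj(anterior)
  if (sqrt(sum(ant^2)) < 1e-12) ant <- sv$v[, 1] else ant <- ant / sqrt(sum(ant^2))
  # opening angle = sum of each ray's (unsigned) angle from the anterior
  # axis, so mandibles latched past straight read as reflex (> 180 deg)
  half <- function(u) acos(max(-1, min(1, sum(ant * u))))
  ((half(uL) + half(uR)) * 180 / pi) %% 360
}
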