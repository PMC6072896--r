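# Shared fixtures and independent oracles, built in code at test time.

# Uniform random rotation matrix (QR of a Gaussian matrix, det +1).
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Random symmetric PSD tensor with eigenvalues in [lo, hi] (mm^2/s scale).
random_psd_tensor <- function(lo = 0, hi = 3e-3) {
  r <- random_rotation()
  ev <- sort(runif(3, lo, hi), decreasing = TRUE)
  list(m = r %*% diag(ev) %*% t(r), eigenvalues = ev)
}

# Brute-force eigenvalues of a symmetric 3x3 matrix via the roots of the
# characteristic polynomial (independent of LAPACK's route).
charpoly_eigenvalues <- function(m) {
  tr <- sum(diag(m))
  c2 <- (m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1]) +
        (m[1, 1] * m[3, 3] - m[1, 3] * m[3, 1]) +
        (m[2, 2] * m[3, 3] - m[2, 3] * m[3, 2])
  roots <- polyroot(c(-det(m), c2, -tr, 1))
  sort(Re(roots), decreasing = TRUE)
}

# Analytic mean of the Rice distribution via Laguerre L_{1/2}:
# E = sigma * sqrt(pi/2) * L_{1/2}(-nu^2 / (2 sigma^2)).
rice_mean <- function(nu, sigma) {
  x <- -nu^2 / (2 * sigma^2)
  l_half <- exp(x / 2) * ((1 - x) * besselI(-x / 2, 0) - x * besselI(-x / 2, 1))
  sigma * sqrt(pi / 2) * l_half
}

# Small fast phantom used across tests (one z-slab per material).
small_phantom_spec <- function(...) {
  phantom_spec(grid_shape = c(10, 10, 15), ...)
}

# Third eigenvalue of each row of a V x 6 tensor map.
tensor_map_lambda3 <- function(tensor_map) {
  apply(tensor_map, 1, function(d)
    min(eigen(tensor_matrix(d), symmetric = TRUE, only.values = TRUE)$values))
}
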