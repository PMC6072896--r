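#' Fit the single-compartment diffusion tensor for one voxel
#'
#' Log-linear least-squares fit of the Stejskal-Tanner attenuation:
#' `log(S_i/S0) = -b_i g_i' D g_i` over all diffusion-weighted volumes,
#' with `S0` the mean of the b0 volumes. Ordinary least squares is the
#' default; weighted least squares (weights `S_i^2`, the standard
#' first-order variance correction for log-transformed signals) is
#' available via `method = "wls"`.
#'
#' Non-positive diffusion-weighted signals cannot be log-transformed; they
#' are floored to `floor_frac * S0` and the voxel is flagged.
#'
#' @param signals numeric vector of per-volume signal values for one voxel.
#' @param scheme a [gradient_scheme()].
#' @param method `"ols"` (default) or `"wls"`.
#' @param floor_frac non-positive signals are floored to this fraction of
#'   S0 (default 1e-6).
#' @return Object of class `diffusion_tensor`: list with `d` (named
#'   6-vector `Dxx, Dyy, Dzz, Dxy, Dxz, Dyz`, mm^2/s when b is in s/mm^2),
#'   `s0`, and `flagged` (TRUE if any signal was floored).
#' @examples
#' sch <- gradient_scheme(c(0, rep(1000, 15)), rbind(0, fibonacci_directions(15)))
#' s <- simulate_signals(diag(3) * 0.7e-3, f = 0, d_water = 3.04e-3, scheme = sch)
#' fit_tensor(s, sch)$d
#' @export
fit_tensor <- function(signals, scheme, method = c("ols", "wls"),
                       floor_frac = 1e-6) {
  method <- match.arg(method)
  signals <- as.numeric(signals)
  if (length(signals) != length(scheme$bvals))
    stop("signal vector length ", length(signals),
         " does not match scheme (", length(scheme$bvals), " volumes)")
  b0 <- is_b0(scheme)
  s0 <- mean(signals[b0])
  if (!is.finite(s0) || s0 <= 0)
    stop("mean b0 signal is not positive; cannot fit tensor")

  s <- signals[!b0]
  flagged <- any(s <= 0)
  s <- pmax(s, floor_frac * s0)
  y <- -log(s / s0)
  B <- design_matrix(scheme)
  if (method == "wls") {
    w <- s^2
    fit <- lm.wfit(B, y, w)
  } else {
    fit <- lm.fit(B, y)
  }
  if (fit$rank < 6L)
    stop("tensor fit is underdetermined (design rank ", fit$rank, " < 6)")
  d <- fit$coefficients
  names(d) <- colnames(B)
  structure(list(d = d, s0 = s0, flagged = flagged),
            class = "diffusion_tensor")
}

#' Convert between the 6-component tensor vector and the symmetric matrix
#'
#' The 6 unique components are stored in the order
#' `Dxx, Dyy, Dzz, Dxy, Dxz, Dyz`; the matrix form is symmetric by
#' construction.
#'
#' @param d numeric 6-vector, or a `diffusion_tensor`.
#' @return `tensor_matrix()`: symmetric 3x3 matrix. `tensor_vector()`: the
#'   named 6-vector of a symmetric 3x3 matrix.
#' @export
tensor_matrix <- function(d) {
  if (inherits(d, "diffusion_tensor")) d <- d$d
  stopifnot(length(d) == 6L)
  matrix(c(d[1], d[4], d[5],
           d[4], d[2], d[6],
           d[5], d[6], d[3]), 3, 3)
}

#' @param m symmetric 3x3 matrix.
#' @rdname tensor_matrix
#' @export
tensor_vector <- function(m) {
  stopifnot(is.matrix(m), all(dim(m) == 3L))
  if (max(abs(m - t(m))) > 1e-8 * max(1, max(abs(m))))
    stop("matrix is not symmetric")
  setNames(c(m[1, 1], m[2, 2], m[3, 3], m[1, 2], m[1, 3], m[2, 3]),
           c("Dxx", "Dyy", "Dzz", "Dxy", "Dxz", "Dyz"))
}

#' Eigendecomposition of a diffusion tensor
#'
#' Eigenvalues are returned sorted in descending order (lambda1 >= lambda2
#' >= lambda3) with orthonormal eigenvectors as matrix columns; the third
#' eigenvalue is the diffusivity along the direction of least diffusion,
#' the quantity the free-water bound is built from.
#'
#' @param tensor a `diffusion_tensor`, a 6-vector, or a symmetric 3x3
#'   matrix.
#' @param voxel optional voxel identifier used in error messages.
#' @return Object of class `dti_eigensystem`: list with `values`
#'   (descending 3-vector) and `vectors` (3x3, columns v1, v2, v3).
#' @examples
#' eigendecompose(diag(c(3, 2, 1)))$values
#' @export
eigendecompose <- function(tensor, voxel = NULL) {
  m <- if (is.matrix(tensor)) tensor else tensor_matrix(tensor)
  if (!all(is.finite(m)))
    stop("non-finite tensor components",
         if (!is.null(voxel)) paste0(" at voxel ", voxel) else "")
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  structure(list(values = e$values, vectors = e$vectors),
            class = "dti_eigensystem")
}

#' Standard DTI indices from an eigensystem
#'
#' Mean diffusivity is the eigenvalue mean; axial diffusivity is lambda1;
#' radial diffusivity is the mean of lambda2 and lambda3. Fractional
#' anisotropy is the normalized eigenvalue dispersion
#' `sqrt(3/2) * ||lambda - MD|| / ||lambda||`, defined as 0 for an all-zero
#' tensor.
#'
#' @param eig a `dti_eigensystem`, or a numeric 3-vector of eigenvalues
#'   sorted in descending order.
#' @return Named list: `fa` (dimensionless), `md`, `axial`, `radial`
#'   (units of the eigenvalues, mm^2/s in this package).
#' @examples
#' compute_indices(c(1.7e-3, 0.4e-3, 0.2e-3))
#' @export
compute_indices <- function(eig) {
  l <- if (inherits(eig, "dti_eigensystem")) eig$values else as.numeric(eig)
  stopifnot(length(l) == 3L, all(is.finite(l)))
  if (is.unsorted(rev(l))) stop("eigenvalues must be sorted descending")
  md <- mean(l)
  nrm <- sqrt(sum(l^2))
  fa <- if (nrm == 0) 0 else sqrt(1.5) * sqrt(sum((l - md)^2)) / nrm
  list(fa = fa, md = md, axial = l[1], radial = (l[2] + l[3]) / 2)
}

#' @export
print.diffusion_tensor <- function(x, ...) {
  cat("diffusion_tensor (mm^2/s), s0 =", format(x$s0), "\n")
  print(tensor_matrix(x))
  invisible(x)
}
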