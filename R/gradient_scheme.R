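#' Construct a diffusion gradient scheme
#'
#' Bundles b-values and unit gradient directions for a DWI acquisition.
#' Directions are normalized on load; volumes with `bval <= b0_threshold`
#' count as non-diffusion-weighted (b0).
#'
#' `bvecs` may be given in either FSL dialect: 3 rows x N columns (one row
#' per spatial axis) or N rows x 3 columns. The orientation is auto-detected
#' from the shape; a 3x3 table is read as the FSL row-per-axis convention.
#'
#' @param bvals numeric vector of b-values (s/mm^2), one per volume.
#' @param bvecs numeric matrix of gradient directions, `3 x N` or `N x 3`.
#' @param b0_threshold b-value at or below which a volume is treated as b0
#'   (s/mm^2). Default 50.
#' @return An object of class `gradient_scheme`: list with `bvals` (length
#'   N), `bvecs` (N x 3, unit rows for diffusion-weighted volumes) and
#'   `b0_threshold`.
#' @examples
#' sch <- gradient_scheme(c(0, rep(1000, 15)), rbind(0, fibonacci_directions(15)))
#' sum(is_b0(sch))
#' @export
gradient_scheme <- function(bvals, bvecs, b0_threshold = 50) {
  bvals <- as.numeric(bvals)
  n <- length(bvals)
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) == 3L && ncol(bvecs) == n) {
    bvecs <- t(bvecs)                       # FSL 3 x N dialect
  } else if (!(ncol(bvecs) == 3L && nrow(bvecs) == n)) {
    stop("bvecs must be 3 x ", n, " or ", n, " x 3 to match ", n, " b-values")
  }
  storage.mode(bvecs) <- "double"
  dimnames(bvecs) <- NULL
  if (!all(is.finite(bvals)) || !all(is.finite(bvecs)))
    stop("non-finite values in gradient table")
  if (any(bvals < 0)) stop("negative b-values")

  nrm <- sqrt(rowSums(bvecs^2))
  dw <- bvals > b0_threshold
  if (any(dw & nrm == 0))
    stop("zero gradient direction for diffusion-weighted volume(s) ",
         paste(which(dw & nrm == 0), collapse = ", "))
  bvecs[nrm > 0, ] <- bvecs[nrm > 0, , drop = FALSE] / nrm[nrm > 0]

  scheme <- structure(
    list(bvals = bvals, bvecs = bvecs, b0_threshold = b0_threshold),
    class = "gradient_scheme")
  validate_scheme(scheme)
  scheme
}

validate_scheme <- function(scheme) {
  if (!any(is_b0(scheme)))
    stop("gradient scheme has no b0 volume (bval <= ", scheme$b0_threshold, ")")
  dw <- !is_b0(scheme)
  if (sum(dw) < 6L)
    stop("tensor fit is underdetermined: only ", sum(dw),
         " diffusion-weighted volumes (need >= 6)")
  if (qr(design_matrix(scheme))$rank < 6L)
    stop("tensor fit is underdetermined: gradient directions span < 6 ",
         "independent tensor components")
  invisible(scheme)
}

#' Which volumes are non-diffusion-weighted?
#'
#' @param scheme a [gradient_scheme()].
#' @return logical vector, `TRUE` for volumes with `bval <= b0_threshold`.
#' @export
is_b0 <- function(scheme) scheme$bvals <= scheme$b0_threshold

#' Diffusion design matrix for the log-linear tensor fit
#'
#' One row per diffusion-weighted volume:
#' `b * (gx^2, gy^2, gz^2, 2 gx gy, 2 gx gz, 2 gy gz)`, so that
#' `-log(S/S0) = B d` for the 6 unique tensor components
#' `d = (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz)`.
#'
#' @param scheme a [gradient_scheme()].
#' @return numeric matrix, `n_dw x 6`.
#' @export
design_matrix <- function(scheme) {
  dw <- !is_b0(scheme)
  g <- scheme$bvecs[dw, , drop = FALSE]
  b <- scheme$bvals[dw]
  B <- cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
             2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3], 2 * g[, 2] * g[, 3])
  colnames(B) <- c("Dxx", "Dyy", "Dzz", "Dxy", "Dxz", "Dyz")
  B * b
}

#' Evenly spread unit directions on the sphere
#'
#' Deterministic spherical Fibonacci lattice; a standard way to lay out a
#' well-conditioned single-shell direction set of any size.
#'
#' @param n number of directions.
#' @return `n x 3` matrix of unit vectors.
#' @export
fibonacci_directions <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' @export
print.gradient_scheme <- function(x, ...) {
  cat("gradient_scheme:", length(x$bvals), "volumes (",
      sum(is_b0(x)), "b0,", sum(!is_b0(x)), "diffusion-weighted ), b =",
      paste(unique(round(x$bvals[!is_b0(x)])), collapse = "/"), "s/mm^2\n")
  invisible(x)
}
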