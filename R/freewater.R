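#' Diffusivity of water at a given temperature
#'
#' Self-diffusion of bulk water, linearly interpolated between tabulated
#' reference values 2.30e-9 m^2/s at 298.15 K and 3.55e-9 m^2/s at
#' 318.15 K. At the default brain temperature of 310 K this gives
#' 3.04e-9 m^2/s (to 3 significant figures), the constant used to convert
#' the third tensor eigenvalue into an upper bound on the free-water
#' fraction. Intracranial pressure variation has negligible effect at
#' physiological levels and is not modelled.
#'
#' @param temperature temperature in kelvin; must lie in [273, 330]. A
#'   warning is issued outside the physiologically plausible band
#'   [306, 314].
#' @return Diffusivity in m^2/s (multiply by 1e6 for mm^2/s).
#' @examples
#' water_diffusivity(310)            # ~3.04e-9 m^2/s
#' water_diffusivity(298.15)         # lower reference point, 2.30e-9
#' @seealso [default_water_diffusivity()] for the mm^2/s mapping constant.
#' @export
water_diffusivity <- function(temperature = 310) {
  stopifnot(is.numeric(temperature), length(temperature) == 1L,
            is.finite(temperature))
  if (temperature < 273 || temperature > 330)
    stop("temperature ", temperature, " K outside supported range [273, 330]")
  if (temperature < 306 || temperature > 314)
    warning("temperature ", temperature,
            " K is outside the physiological band [306, 314] K")
  t_lo <- 298.15; d_lo <- 2.30e-9
  t_hi <- 318.15; d_hi <- 3.55e-9
  d_lo + (temperature - t_lo) / (t_hi - t_lo) * (d_hi - d_lo)
}

#' Default water diffusivity for map production, in mm^2/s
#'
#' The 310 K interpolated water diffusivity rounded to 3 significant
#' figures and expressed in the native DTI unit: 3.04e-3 mm^2/s. This is
#' the denominator of the free-water upper limit unless the caller
#' supplies an explicit value or temperature.
#'
#' @param temperature temperature in kelvin (default 310).
#' @return Diffusivity in mm^2/s, rounded to 3 significant figures.
#' @export
default_water_diffusivity <- function(temperature = 310) {
  signif(water_diffusivity(temperature) * 1e6, 3)
}

#' Upper limit on the free-water fraction from the third eigenvalue
#'
#' The free-water compartment diffuses isotropically, so its contribution
#' to every eigenvalue of the voxel tensor is `f * D_W`; each eigenvalue
#' divided by `D_W` therefore bounds `f` from above, and the smallest
#' eigenvalue gives the tightest bound: `f_UL = lambda3 / D_W`. Because
#' noisy fits can push the ratio outside [0, 1], the returned fraction is
#' clamped: above at 1 always, below at 0 when `clamp_low = TRUE` (the
#' default; a volume fraction cannot be negative).
#'
#' Both arguments must be in the same units (mm^2/s and m^2/s both work;
#' mixing them is a silent 1e6 error, so the mapping code keeps everything
#' in mm^2/s).
#'
#' @param lambda3 third (smallest) eigenvalue(s) of the diffusion tensor;
#'   any numeric array, may be negative in noisy data.
#' @param d_water diffusivity of water in the same units as `lambda3`;
#'   must be a positive scalar.
#' @param clamp_low clamp negative ratios to 0 (default TRUE).
#' @return List of arrays shaped like `lambda3`: `f_ul` (clamped
#'   fraction), `raw_ratio` (lambda3 / d_water before clamping),
#'   `clamped_high`, `clamped_low` (logical).
#' @examples
#' compute_ful(1.52e-3, 3.04e-3)$f_ul    # 0.5
#' compute_ful(4.0e-3, 3.04e-3)          # clamped to 1
#' @export
compute_ful <- function(lambda3, d_water = default_water_diffusivity(),
                        clamp_low = TRUE) {
  stopifnot(is.numeric(d_water), length(d_water) == 1L, is.finite(d_water))
  if (d_water <= 0) stop("d_water must be positive")
  if (!all(is.finite(lambda3))) stop("non-finite lambda3 values")
  raw <- lambda3 / d_water
  high <- raw > 1
  low <- raw < 0
  f_ul <- pmin(raw, 1)
  if (clamp_low) f_ul <- pmax(f_ul, 0)
  dim(f_ul) <- dim(high) <- dim(low) <- dim(lambda3)
  list(f_ul = f_ul, raw_ratio = raw, clamped_high = high, clamped_low = low)
}

#' Two-compartment voxel tensor
#'
#' Mixes a tissue tensor with an isotropic free-water tensor under the
#' linear (fraction-weighted) two-compartment model:
#' `D_vox = (1 - f) D_t + f * D_W * I`.
#'
#' @param f free-water volume fraction in [0, 1].
#' @param tissue_tensor symmetric 3x3 tissue tensor (mm^2/s), or a
#'   6-vector as in [tensor_vector()].
#' @param d_water water diffusivity (mm^2/s).
#' @return Symmetric 3x3 voxel tensor.
#' @examples
#' mix_tensors(0.3, diag(c(1.7, 0.4, 0.2)) * 1e-3, 3.04e-3)
#' @export
mix_tensors <- function(f, tissue_tensor, d_water = default_water_diffusivity()) {
  stopifnot(length(f) == 1L, is.finite(f), f >= 0, f <= 1, d_water > 0)
  m <- if (is.matrix(tissue_tensor)) tissue_tensor else tensor_matrix(tissue_tensor)
  tensor_vector(m)  # symmetry check
  (1 - f) * m + f * d_water * diag(3)
}

#' Per-axis solutions of the two-compartment model
#'
#' In the eigenframe of the voxel tensor the two-compartment model gives
#' three scalar equations, each solvable for the fraction:
#' `f_i = (lambda_i - L_ii) / (D_W - L_ii)` where `L_ii` is the diagonal
#' of the rotated tissue tensor. With the true tissue diagonal all three
#' recover the same `f` exactly; with the tissue term unknown, setting
#' `L_ii = 0` yields the upper bounds of [bound_chain()]. This function is
#' for verification and teaching, not for map production.
#'
#' @param eig a `dti_eigensystem` or descending 3-vector of voxel-tensor
#'   eigenvalues.
#' @param tissue_diag diagonal of the tissue tensor in the voxel
#'   eigenframe (3-vector, mm^2/s).
#' @param d_water water diffusivity (mm^2/s).
#' @return 3-vector of per-axis fractions; entries where
#'   `|d_water - L_ii| < 1e-12` are undefined and returned as `NA`.
#' @export
per_axis_solutions <- function(eig, tissue_diag,
                               d_water = default_water_diffusivity()) {
  l <- if (inherits(eig, "dti_eigensystem")) eig$values else as.numeric(eig)
  stopifnot(length(l) == 3L, length(tissue_diag) == 3L, d_water > 0)
  den <- d_water - tissue_diag
  f <- (l - tissue_diag) / den
  f[abs(den) < 1e-12] <- NA_real_
  f
}

#' The chain of upper bounds on the free-water fraction
#'
#' Each eigenvalue divided by the water diffusivity bounds the fraction
#' from above; with eigenvalues sorted descending the third ratio is the
#' minimum, and is the reported upper limit `f_UL`.
#'
#' @inheritParams per_axis_solutions
#' @return List: `bounds` (3-vector `lambda_i / d_water`) and `f_ul` (the
#'   third, smallest, bound — unclamped; see [compute_ful()] for the
#'   clamped map value).
#' @examples
#' bound_chain(c(3e-3, 2e-3, 1e-3), 3.04e-3)
#' @export
bound_chain <- function(eig, d_water = default_water_diffusivity()) {
  l <- if (inherits(eig, "dti_eigensystem")) eig$values else as.numeric(eig)
  stopifnot(length(l) == 3L, d_water > 0)
  if (is.unsorted(rev(l))) stop("eigenvalues must be sorted descending")
  bounds <- l / d_water
  stopifnot(which.min(bounds) == 3L || bounds[3] == min(bounds))
  list(bounds = bounds, f_ul = bounds[3])
}
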