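#' Default single-shell acquisition scheme for phantoms
#'
#' One b0 volume followed by 15 diffusion-weighted volumes at
#' b = 1000 s/mm^2, the protocol of typical clinical single-shell DTI.
#' Directions come from a deterministic spherical Fibonacci lattice.
#'
#' @param n_directions number of diffusion-weighted directions (default 15).
#' @param bvalue shell b-value in s/mm^2 (default 1000).
#' @return A [gradient_scheme()].
#' @export
default_scheme <- function(n_directions = 15, bvalue = 1000) {
  gradient_scheme(c(0, rep(bvalue, n_directions)),
                  rbind(0, fibonacci_directions(n_directions)))
}

#' Default phantom materials
#'
#' Five materials spanning the tensor shape classes seen in brain: pure
#' CSF (f = 1), isotropic gray-like tissue, a prolate white-matter-like
#' tensor, a planar (oblate) tensor, and a slab over which f sweeps 0 to 1
#' on a fixed prolate tensor. Tissue diffusivities follow the magnitudes
#' observed in brain DTI: gray-like MD ~0.9e-3 mm^2/s, white-like radial
#' ~0.5e-3 mm^2/s.
#'
#' @return Named list of materials; each has `label`, `f` (NA for the
#'   gradient slab, where f varies by voxel), and `tensor` (3x3, mm^2/s).
#' @export
default_materials <- function() {
  list(
    csf      = list(label = 1L, f = 1,    tensor = diag(3) * 0.9e-3),
    gray     = list(label = 2L, f = 0.10, tensor = diag(3) * 0.9e-3),
    white    = list(label = 3L, f = 0.02, tensor = diag(c(1.7, 0.5, 0.5)) * 1e-3),
    planar   = list(label = 4L, f = 0.05, tensor = diag(c(1.2, 1.2, 0.3)) * 1e-3),
    gradient = list(label = 5L, f = NA_real_, tensor = diag(c(1.7, 0.5, 0.5)) * 1e-3)
  )
}

#' Specification of a synthetic two-compartment DWI phantom
#'
#' Collects everything needed to generate a reproducible synthetic
#' dataset: grid, materials, acquisition scheme, water diffusivity,
#' baseline signal, noise level and seed. The grid is divided into equal
#' z-slabs, one per material, with the gradient slab sweeping f from 0 to
#' 1 along x.
#'
#' @param grid_shape integer 3-vector of voxel dimensions (default
#'   `c(32, 32, 32)`).
#' @param voxel_size physical voxel size in mm per axis (default
#'   `c(2, 2, 2)`).
#' @param materials material list as from [default_materials()].
#' @param scheme a [gradient_scheme()] (default [default_scheme()]).
#' @param d_water water diffusivity in mm^2/s (default
#'   [default_water_diffusivity()]).
#' @param s0 baseline (b0) signal (default 1000).
#' @param noise_sigma Rician noise level in signal units; 0 (default) is
#'   noiseless.
#' @param seed integer RNG seed; fully determines the noisy output.
#' @param mixing_mode `"tensor"` (single mixed tensor, the model the upper
#'   bound is derived under) or `"signal"` (bi-exponential compartment
#'   signals, the physically realistic alternative).
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(32, 32, 32),
                         voxel_size = c(2, 2, 2),
                         materials = default_materials(),
                         scheme = default_scheme(),
                         d_water = default_water_diffusivity(),
                         s0 = 1000,
                         noise_sigma = 0,
                         seed = 42L,
                         mixing_mode = c("tensor", "signal")) {
  mixing_mode <- match.arg(mixing_mode)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1),
            length(voxel_size) == 3L, all(voxel_size > 0),
            s0 > 0, noise_sigma >= 0, d_water > 0)
  for (m in materials) {
    stopifnot(is.na(m$f) || (m$f >= 0 && m$f <= 1))
    ev <- eigen(m$tensor, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 0) stop("material tissue tensor is not positive semidefinite")
  }
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_size = voxel_size, materials = materials,
                 scheme = scheme, d_water = d_water, s0 = s0,
                 noise_sigma = noise_sigma, seed = as.integer(seed),
                 mixing_mode = mixing_mode),
            class = "phantom_spec")
}

#' Simulate the DWI signal of one two-compartment voxel
#'
#' In `"tensor"` mode the compartments are mixed at the tensor level,
#' `D_vox = (1 - f) D_t + f D_W I`, and the signal is the monoexponential
#' `s0 * exp(-b g' D_vox g)` — the linearity assumption the upper bound is
#' derived under. In `"signal"` mode each compartment contributes its own
#' exponential, `s0 * ((1 - f) exp(-b g' D_t g) + f exp(-b D_W))` — the
#' physically realistic bi-exponential that the tensor-mixing model
#' approximates. The two coincide at f = 0 and f = 1.
#'
#' @param tissue_tensor symmetric 3x3 tissue tensor (mm^2/s).
#' @param f free-water fraction in [0, 1].
#' @param d_water water diffusivity (mm^2/s).
#' @param scheme a [gradient_scheme()].
#' @param s0 baseline signal.
#' @param mode `"tensor"` or `"signal"`.
#' @return Strictly positive signal vector, one value per volume
#'   (b0 volumes give exactly `s0`).
#' @export
simulate_signals <- function(tissue_tensor, f, d_water, scheme, s0 = 1000,
                             mode = c("tensor", "signal")) {
  mode <- match.arg(mode)
  stopifnot(f >= 0, f <= 1, s0 > 0, d_water > 0)
  m <- if (is.matrix(tissue_tensor)) tissue_tensor else tensor_matrix(tissue_tensor)
  b <- scheme$bvals
  g <- scheme$bvecs
  quad <- function(mm) rowSums((g %*% mm) * g)   # g_i' M g_i per volume
  if (mode == "tensor") {
    s <- s0 * exp(-b * quad(mix_tensors(f, m, d_water)))
  } else {
    s <- s0 * ((1 - f) * exp(-b * quad(m)) + f * exp(-b * d_water))
  }
  s
}

#' Add Rician noise to magnitude MRI signals
#'
#' Magnitude MRI noise: each value is replaced by
#' `sqrt((S + n1)^2 + n2^2)` with `n1, n2 ~ Normal(0, sigma^2)`,
#' the magnitude of a complex Gaussian perturbation. `sigma = 0` returns
#' the input unchanged. The caller controls reproducibility via the R RNG
#' state (`set.seed`).
#'
#' @param signals numeric vector or array of noiseless signals.
#' @param sigma noise standard deviation, in signal units (>= 0).
#' @return Noisy signals, same shape as the input.
#' @export
add_rician_noise <- function(signals, sigma) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(signals)
  n <- length(signals)
  noisy <- sqrt((signals + rnorm(n, 0, sigma))^2 + rnorm(n, 0, sigma)^2)
  dim(noisy) <- dim(signals)
  noisy
}

#' Build a synthetic DWI phantom with known ground truth
#'
#' Generates the 4D signal volume for a [phantom_spec()], plus the ground
#' truth needed to validate every downstream stage: the true free-water
#' fraction map, the per-voxel tissue tensor, and integer material labels.
#' Output is bit-reproducible for a fixed spec (the seed drives all
#' stochastic draws; the RNG state of the session is left untouched).
#'
#' @param spec a [phantom_spec()].
#' @return List of class `dwi_phantom`: `dwi` (4D array, x-y-z-volume),
#'   `truth` (list: `f_map` 3D array, `tensor_map` V x 6 matrix in
#'   [tensor_vector()] order, `labels` 3D integer array), `scheme`, and
#'   `spec`.
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dims <- spec$grid_shape
  nvol <- length(spec$scheme$bvals)
  nvox <- prod(dims)

  # material slabs along z; gradient slab sweeps f along x
  zs <- slab_assignment(dims[3], length(spec$materials))
  labels <- array(0L, dims)
  f_map <- array(0, dims)
  tensor_map <- matrix(0, nvox, 6,
                       dimnames = list(NULL, c("Dxx","Dyy","Dzz","Dxy","Dxz","Dyz")))
  dwi <- array(0, c(dims, nvol))

  xfrac <- if (dims[1] > 1) (seq_len(dims[1]) - 1) / (dims[1] - 1) else 0.5
  mats <- spec$materials
  for (k in seq_along(mats)) {
    m <- mats[[k]]
    z_idx <- which(zs == k)
    if (!length(z_idx)) next
    labels[, , z_idx] <- m$label
    d6 <- tensor_vector(m$tensor)
    vox_idx <- which(array(rep(zs == k, each = dims[1] * dims[2]), dims))
    tensor_map[vox_idx, ] <- matrix(d6, length(vox_idx), 6, byrow = TRUE)
    if (is.na(m$f)) {
      # f varies along x: simulate one column of signals per x index
      for (i in seq_len(dims[1])) {
        f_map[i, , z_idx] <- xfrac[i]
        sig <- simulate_signals(m$tensor, xfrac[i], spec$d_water, spec$scheme,
                                spec$s0, spec$mixing_mode)
        dwi[i, , z_idx, ] <- rep(sig, each = dims[2] * length(z_idx))
      }
    } else {
      f_map[, , z_idx] <- m$f
      sig <- simulate_signals(m$tensor, m$f, spec$d_water, spec$scheme,
                              spec$s0, spec$mixing_mode)
      dwi[, , z_idx, ] <- rep(sig, each = dims[1] * dims[2] * length(z_idx))
    }
  }

  if (spec$noise_sigma > 0) {
    old_seed <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                           envir = globalenv()))
    set.seed(spec$seed)
    dwi <- add_rician_noise(dwi, spec$noise_sigma)
  }

  structure(list(dwi = dwi,
                 truth = list(f_map = f_map, tensor_map = tensor_map,
                              labels = labels),
                 scheme = spec$scheme, spec = spec),
            class = "dwi_phantom")
}

slab_assignment <- function(nz, n_materials) {
  as.integer(cut(seq_len(nz), breaks = n_materials, labels = FALSE))
}

#' Closed-form f_UL of a noiseless tensor-mixing phantom
#'
#' Adding an isotropic tensor preserves eigenvectors, so the third
#' eigenvalue of the mixed tensor is
#' `(1 - f) lambda3(D_t) + f D_W`, giving
#' `f_UL = f + (1 - f) lambda3(D_t) / D_W`. This is the analytic value
#' every noiseless tensor-mixing voxel must reproduce, and shows
#' `f_UL >= f` with equality iff `lambda3(D_t) = 0` or `f = 1`.
#'
#' @param f true free-water fraction (any numeric array).
#' @param lambda3_tissue third eigenvalue of the tissue tensor, same shape
#'   or scalar (mm^2/s).
#' @param d_water water diffusivity (mm^2/s).
#' @return Array of f_UL values, shaped like `f`.
#' @export
ful_closed_form <- function(f, lambda3_tissue,
                            d_water = default_water_diffusivity()) {
  f + (1 - f) * lambda3_tissue / d_water
}

#' Write a phantom to disk in standard formats
#'
#' Writes the 4D DWI as NIfTI-1, the gradient table in FSL `.bval`/`.bvec`
#' convention (b-values on one row; directions as 3 rows x N columns), the
#' ground-truth fraction and label maps as NIfTI-1, and a JSON sidecar
#' recording the spec.
#'
#' @param phantom a `dwi_phantom` from [build_phantom()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix (default `"phantom"`).
#' @return Invisibly, the named character vector of paths written.
#' @export
write_phantom <- function(phantom, dir, prefix = "phantom") {
  stopifnot(inherits(phantom, "dwi_phantom"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  spec <- phantom$spec
  pix <- spec$voxel_size
  paths <- c(
    dwi = file.path(dir, paste0(prefix, "_dwi.nii.gz")),
    bval = file.path(dir, paste0(prefix, ".bval")),
    bvec = file.path(dir, paste0(prefix, ".bvec")),
    truth_f = file.path(dir, paste0(prefix, "_truth_f.nii.gz")),
    labels = file.path(dir, paste0(prefix, "_truth_labels.nii.gz")),
    spec = file.path(dir, paste0(prefix, "_spec.json"))
  )
  RNifti::writeNifti(as_nifti_grid(phantom$dwi, pix), paths["dwi"],
                     datatype = "double")
  writeLines(paste(format(phantom$scheme$bvals, trim = TRUE), collapse = " "),
             paths["bval"])
  bv <- t(phantom$scheme$bvecs)       # FSL: 3 rows, one per axis
  writeLines(apply(bv, 1, function(r)
    paste(format(r, trim = TRUE, digits = 15), collapse = " ")), paths["bvec"])
  RNifti::writeNifti(as_nifti_grid(phantom$truth$f_map, pix),
                     paths["truth_f"], datatype = "float")
  RNifti::writeNifti(as_nifti_grid(phantom$truth$labels, pix),
                     paths["labels"], datatype = "uint8")
  jsonlite::write_json(spec_as_json(spec), paths["spec"],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}

as_nifti_grid <- function(arr, voxel_size) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- voxel_size
  img
}

spec_as_json <- function(spec) {
  list(grid_shape = spec$grid_shape, voxel_size = spec$voxel_size,
       materials = lapply(spec$materials, function(m)
         list(label = m$label, f = m$f, tensor = tensor_vector(m$tensor))),
       bvals = spec$scheme$bvals, bvecs = spec$scheme$bvecs,
       b0_threshold = spec$scheme$b0_threshold,
       d_water_mm2s = spec$d_water, s0 = spec$s0,
       noise_sigma = spec$noise_sigma, seed = spec$seed,
       mixing_mode = spec$mixing_mode)
}
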