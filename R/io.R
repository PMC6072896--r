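#' Read a 4D DWI volume with its FSL-style gradient table
#'
#' Loads a NIfTI-1 image together with `.bval`/`.bvec` text tables,
#' checks that the volume count matches the table length, and normalizes
#' the gradient directions. Both bvec dialects (3 rows x N columns, or N
#' rows x 3 columns) are accepted. Orientation metadata (affine, pixdim)
#' is preserved on the returned image.
#'
#' @param nifti_path path to a `.nii` or `.nii.gz` 4D image.
#' @param bval_path path to the whitespace-separated b-value table.
#' @param bvec_path path to the gradient-direction table.
#' @param b0_threshold b-value at or below which a volume counts as b0.
#' @return List: `image` (an `RNifti` image, 4D array with header
#'   attributes) and `scheme` (a [gradient_scheme()]).
#' @export
read_dwi <- function(nifti_path, bval_path, bvec_path, b0_threshold = 50) {
  for (p in c(nifti_path, bval_path, bvec_path))
    if (!file.exists(p)) stop("file not found: ", p)
  img <- RNifti::readNifti(nifti_path)
  if (length(dim(img)) != 4L)
    stop("expected a 4D DWI volume, got ", length(dim(img)), "D: ", nifti_path)
  bvals <- scan(bval_path, quiet = TRUE)
  bvec_rows <- lapply(readLines(bvec_path), function(l) scan(text = l, quiet = TRUE))
  bvec_rows <- bvec_rows[vapply(bvec_rows, length, 1L) > 0]
  lens <- unique(vapply(bvec_rows, length, 1L))
  if (length(lens) != 1L) stop("ragged bvec table: ", bvec_path)
  bvecs <- do.call(rbind, bvec_rows)
  if (dim(img)[4] != length(bvals))
    stop("DWI has ", dim(img)[4], " volumes but bval table has ",
         length(bvals), " entries")
  scheme <- gradient_scheme(bvals, bvecs, b0_threshold)
  list(image = img, scheme = scheme)
}

# QC flag bits used in the qc mask
QC_FLOORED_SIGNAL <- 1L   # non-positive DW signal floored before log
QC_NEGATIVE_L3 <- 2L      # lambda3 < 0 (f_UL clamped at 0)
QC_CLAMPED_HIGH <- 4L     # lambda3 > D_W (f_UL clamped at 1)
QC_FIT_FAILURE <- 8L      # voxel not fitted (bad b0 / non-finite / masked out)

#' Voxelwise f_UL and DTI index maps from a DWI volume
#'
#' Runs the full per-voxel pipeline — log-linear tensor fit,
#' eigendecomposition, DTI indices, free-water upper limit — over a 4D
#' DWI array. Voxels outside the mask, or whose fit fails (non-positive
#' mean b0, non-finite signals), are zero-filled and flagged in the QC
#' mask rather than aborting the volume.
#'
#' QC mask bits: 1 = a non-positive diffusion-weighted signal was floored;
#' 2 = negative third eigenvalue (f_UL clamped to 0); 4 = ratio above 1
#' (f_UL clamped to 1); 8 = voxel not fitted.
#'
#' @param dwi 4D numeric array (x-y-z-volume), e.g. the `image` of
#'   [read_dwi()] or the `dwi` of [build_phantom()].
#' @param scheme a [gradient_scheme()] matching the 4th dimension.
#' @param d_water water diffusivity in mm^2/s (default
#'   [default_water_diffusivity()]).
#' @param mask optional 3D logical/numeric array; voxels where it is 0 are
#'   skipped.
#' @param method tensor estimator, `"ols"` or `"wls"`.
#' @param floor_frac flooring fraction for non-positive signals.
#' @return Object of class `index_maps`: list of 3D arrays `f_ul`, `fa`,
#'   `md`, `axial`, `radial`, `lambda3`, `qc` (integer bit flags), plus
#'   `d_water` and the input `scheme`. The affine/pixdim of `dwi` (if an
#'   RNifti image) is kept in attribute `reference`.
#' @export
compute_maps <- function(dwi, scheme, d_water = default_water_diffusivity(),
                         mask = NULL, method = c("ols", "wls"),
                         floor_frac = 1e-6) {
  method <- match.arg(method)
  dims <- dim(dwi)
  if (length(dims) != 4L) stop("dwi must be a 4D array")
  if (dims[4] != length(scheme$bvals))
    stop("DWI has ", dims[4], " volumes but scheme has ",
         length(scheme$bvals))
  if (d_water <= 0) stop("d_water must be positive")
  nvox <- prod(dims[1:3])
  sig <- matrix(as.numeric(dwi), nvox, dims[4])

  in_mask <- if (is.null(mask)) rep(TRUE, nvox) else {
    if (!all(dim(mask) == dims[1:3])) stop("mask grid does not match DWI grid")
    as.vector(mask) != 0
  }

  b0 <- is_b0(scheme)
  s0 <- rowMeans(sig[, b0, drop = FALSE])
  fitted <- in_mask & is.finite(s0) & s0 > 0 &
    apply(is.finite(sig), 1, all)

  qc <- integer(nvox)
  qc[!fitted] <- QC_FIT_FAILURE

  f_ul <- fa <- md <- ax <- rad <- l3 <- numeric(nvox)
  if (any(fitted)) {
    s <- sig[fitted, !b0, drop = FALSE]
    floored <- rowSums(s <= 0) > 0
    qc[fitted][floored] <- bitwOr(qc[fitted][floored], QC_FLOORED_SIGNAL)
    s <- pmax(s, floor_frac * s0[fitted])
    y <- -log(s / s0[fitted])
    B <- design_matrix(scheme)
    if (qr(B)$rank < 6L) stop("tensor fit is underdetermined")
    if (method == "ols") {
      # D6' = (B'B)^-1 B' y' for all voxels at once
      d6 <- y %*% B %*% solve(crossprod(B))
    } else {
      d6 <- t(vapply(seq_len(nrow(y)), function(i)
        lm.wfit(B, y[i, ], s[i, ]^2)$coefficients, numeric(6)))
    }
    ev <- eigenvalues_sym3(d6)
    idx <- compute_indices_vec(ev)
    fw <- compute_ful(ev[, 3], d_water)

    f_ul[fitted] <- fw$f_ul
    fa[fitted] <- idx$fa
    md[fitted] <- idx$md
    ax[fitted] <- idx$axial
    rad[fitted] <- idx$radial
    l3[fitted] <- ev[, 3]
    qc[fitted][fw$clamped_low] <- bitwOr(qc[fitted][fw$clamped_low],
                                         QC_NEGATIVE_L3)
    qc[fitted][fw$clamped_high] <- bitwOr(qc[fitted][fw$clamped_high],
                                          QC_CLAMPED_HIGH)
  }

  shape3 <- function(x) array(x, dims[1:3])
  maps <- structure(
    list(f_ul = shape3(f_ul), fa = shape3(fa), md = shape3(md),
         axial = shape3(ax), radial = shape3(rad), lambda3 = shape3(l3),
         qc = shape3(qc), d_water = d_water, scheme = scheme),
    class = "index_maps")
  if (inherits(dwi, "niftiImage"))
    attr(maps, "reference") <- RNifti::asNifti(array(0, dims[1:3]),
                                               reference = dwi)
  maps
}

# Eigenvalues of many symmetric 3x3 tensors, rows of a V x 6 matrix in
# (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz) order; returns V x 3, sorted descending.
eigenvalues_sym3 <- function(d6) {
  t(apply(d6, 1, function(d)
    eigen(tensor_matrix(d), symmetric = TRUE, only.values = TRUE)$values))
}

# Vectorized DTI indices from a V x 3 matrix of descending eigenvalues.
compute_indices_vec <- function(ev) {
  md <- rowMeans(ev)
  nrm <- sqrt(rowSums(ev^2))
  fa <- ifelse(nrm == 0, 0, sqrt(1.5) * sqrt(rowSums((ev - md)^2)) / nrm)
  list(fa = fa, md = md, axial = ev[, 1], radial = (ev[, 2] + ev[, 3]) / 2)
}

#' Write index maps as float32 NIfTI volumes with a provenance sidecar
#'
#' Each map is written as `<prefix>_<name>.nii.gz` in float32 (the QC mask
#' as uint8), carrying the affine and pixdim of the reference image; a
#' JSON sidecar records the water diffusivity, gradient scheme and
#' package version so the run can be reproduced.
#'
#' @param maps an `index_maps` object from [compute_maps()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix (default `"dti"`).
#' @param reference optional NIfTI image supplying header/affine; defaults
#'   to the reference captured by [compute_maps()], if any.
#' @param extra_provenance named list merged into the JSON sidecar.
#' @return Invisibly, named character vector of the paths written.
#' @export
write_maps <- function(maps, dir, prefix = "dti", reference = NULL,
                       extra_provenance = list()) {
  stopifnot(inherits(maps, "index_maps"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(reference)) reference <- attr(maps, "reference")
  to_img <- function(arr) {
    if (is.null(reference)) RNifti::asNifti(arr)
    else RNifti::asNifti(arr, reference = reference)
  }
  names <- c("f_ul", "fa", "md", "axial", "radial", "lambda3")
  paths <- setNames(file.path(dir, paste0(prefix, "_", names, ".nii.gz")), names)
  for (nm in names)
    RNifti::writeNifti(to_img(maps[[nm]]), paths[nm], datatype = "float")
  qc_path <- file.path(dir, paste0(prefix, "_qc.nii.gz"))
  RNifti::writeNifti(to_img(maps$qc), qc_path, datatype = "uint8")
  paths <- c(paths, qc = qc_path)

  prov <- modifyList(list(
    tool = "freewater", version = as.character(packageVersion("freewater")),
    d_water_mm2s = maps$d_water,
    bvals = maps$scheme$bvals, bvecs = maps$scheme$bvecs,
    b0_threshold = maps$scheme$b0_threshold,
    n_voxels = length(maps$f_ul),
    pct_clamped_high = 100 * mean(bitwAnd(maps$qc, QC_CLAMPED_HIGH) > 0),
    pct_clamped_low = 100 * mean(bitwAnd(maps$qc, QC_NEGATIVE_L3) > 0)),
    extra_provenance)
  prov_path <- file.path(dir, paste0(prefix, "_provenance.json"))
  jsonlite::write_json(prov, prov_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, provenance = prov_path))
}
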