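#' Per-voxel index values for one labelled region
#'
#' Extracts one row per in-region voxel with the f_UL and DTI index
#' values, optionally joined with extra co-registered maps (e.g. tissue
#' probabilities). The label volume must already be on the same grid as
#' the maps; resampling across spaces is the caller's job
#' (nearest-neighbour for labels).
#'
#' @param maps an `index_maps` object from [compute_maps()].
#' @param labels 3D integer array (or NIfTI image) of region labels on
#'   the same grid.
#' @param label region label id to extract.
#' @param extra optional named list of additional 3D arrays on the same
#'   grid, added as columns.
#' @param exclude_flagged drop voxels whose QC mask has the fit-failure
#'   or floored-signal bits set (default TRUE). Clamp flags do not
#'   exclude: clamping is part of the measure.
#' @return `data.frame` with columns `f_ul`, `fa`, `md`, `axial`,
#'   `radial`, any extras, and `qc`; zero rows (with a warning) if the
#'   label is absent.
#' @export
extract_region_values <- function(maps, labels, label, extra = NULL,
                                  exclude_flagged = TRUE) {
  stopifnot(inherits(maps, "index_maps"))
  if (!all(dim(labels)[1:3] == dim(maps$f_ul)))
    stop("label grid does not match map grid; resample the labels first")
  sel <- as.vector(labels) == label
  if (exclude_flagged)
    sel <- sel & bitwAnd(as.vector(maps$qc),
                         QC_FIT_FAILURE + QC_FLOORED_SIGNAL) == 0L
  if (!any(sel)) warning("region label ", label, " selects no voxels")
  df <- data.frame(f_ul = as.vector(maps$f_ul)[sel],
                   fa = as.vector(maps$fa)[sel],
                   md = as.vector(maps$md)[sel],
                   axial = as.vector(maps$axial)[sel],
                   radial = as.vector(maps$radial)[sel])
  for (nm in names(extra)) {
    if (!all(dim(extra[[nm]])[1:3] == dim(maps$f_ul)))
      stop("extra map '", nm, "' grid does not match")
    df[[nm]] <- as.vector(extra[[nm]])[sel]
  }
  df$qc <- as.vector(maps$qc)[sel]
  df
}

#' Pearson correlation of each index against f_UL for one region table
#'
#' Computes, for every non-reference column, the Pearson correlation with
#' the reference column and its two-sided p-value from the exact
#' t-transform, flagging significance at P < 0.05 (uncorrected). A
#' zero-variance column has no defined correlation and is reported as
#' `NA`, not 0.
#'
#' @param table data.frame as from [extract_region_values()].
#' @param reference name of the reference column (default `"f_ul"`).
#' @return `data.frame`, one row per compared column: `index`, `r`,
#'   `p_value`, `significant`.
#' @export
correlate_with_ful <- function(table, reference = "f_ul") {
  stopifnot(reference %in% names(table))
  if (nrow(table) < 2L) stop("need at least 2 voxels to correlate")
  ref <- table[[reference]]
  cols <- setdiff(names(table), c(reference, "qc"))
  rows <- lapply(cols, function(nm) {
    x <- table[[nm]]
    if (!all(is.finite(x)) || !all(is.finite(ref)))
      stop("non-finite values in column ", nm)
    if (sd(x) == 0 || sd(ref) == 0)
      return(data.frame(index = nm, r = NA_real_, p_value = NA_real_,
                        significant = NA))
    ct <- cor.test(ref, x, method = "pearson", alternative = "two.sided")
    data.frame(index = nm, r = unname(ct$estimate),
               p_value = ct$p.value, significant = ct$p.value < 0.05)
  })
  do.call(rbind, rows)
}

#' Region-by-region descriptive statistics and correlations with f_UL
#'
#' Mirrors the shape of an atlas-based analysis: one row per region with
#' voxel count, percent included, mean +/- sd of each index, and the
#' Pearson r (with p-value) of each index against f_UL in that region.
#'
#' @inheritParams extract_region_values
#' @param region_ids label ids to report; default: every nonzero label
#'   present in `labels`.
#' @return `data.frame`, one row per region. Columns: `label`,
#'   `n_voxels` (in-region voxels), `n_included`, `pct_included`, then
#'   `<index>_mean` / `<index>_sd` / `<index>_r` / `<index>_p` for each
#'   index.
#' @export
region_report <- function(maps, labels, region_ids = NULL, extra = NULL,
                          exclude_flagged = TRUE) {
  if (is.null(region_ids)) {
    region_ids <- sort(unique(as.vector(labels)))
    region_ids <- region_ids[region_ids != 0]
  }
  rows <- lapply(region_ids, function(lab) {
    n_total <- sum(as.vector(labels) == lab)
    tab <- suppressWarnings(
      extract_region_values(maps, labels, lab, extra, exclude_flagged))
    row <- data.frame(label = lab, n_voxels = n_total, n_included = nrow(tab),
                      pct_included = if (n_total > 0)
                        100 * nrow(tab) / n_total else NA_real_)
    idx_cols <- setdiff(names(tab), "qc")
    for (nm in idx_cols) {
      row[[paste0(nm, "_mean")]] <- if (nrow(tab)) mean(tab[[nm]]) else NA_real_
      row[[paste0(nm, "_sd")]] <- if (nrow(tab) > 1) sd(tab[[nm]]) else NA_real_
    }
    if (nrow(tab) >= 2L) {
      cr <- correlate_with_ful(tab)
      for (i in seq_len(nrow(cr))) {
        row[[paste0(cr$index[i], "_r")]] <- cr$r[i]
        row[[paste0(cr$index[i], "_p")]] <- cr$p_value[i]
      }
    }
    row
  })
  out <- do.call(rbind, lapply(rows, function(r) {
    # pad missing columns so rbind aligns across regions
    all_cols <- unique(unlist(lapply(rows, names)))
    for (nm in setdiff(all_cols, names(r))) r[[nm]] <- NA
    r[all_cols]
  }))
  rownames(out) <- NULL
  out
}

#' Write a region report as CSV and JSON
#'
#' @param report data.frame from [region_report()].
#' @param csv_path output CSV path.
#' @param json_path optional output JSON path (default: CSV path with
#'   `.json` extension).
#' @return Invisibly, the paths written.
#' @export
write_region_report <- function(report, csv_path,
                                json_path = sub("\\.csv$", ".json", csv_path)) {
  write.csv(report, csv_path, row.names = FALSE)
  jsonlite::write_json(report, json_path, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(csv = csv_path, json = json_path))
}

#' Deterministic strided subsample for scatterplots
#'
#' Keeps every `stride`-th value starting at the first, the standard way
#' to thin millions of voxel values to a plottable subset without
#' changing the distribution shape.
#'
#' @param x numeric vector.
#' @param stride keep every `stride`-th element (>= 1).
#' @return The subsampled vector; `stride = 1` is the identity.
#' @export
subsample_stride <- function(x, stride = 200L) {
  stopifnot(stride >= 1)
  x[seq(1L, length(x), by = as.integer(stride))]
}

#' Histogram counts for fraction-valued maps
#'
#' Fixed bin edges on [0, 1] (50 bins by default) so histograms of f_UL
#' from different runs or regions are directly comparable.
#'
#' @param x numeric vector of values in [0, 1].
#' @param n_bins number of equal-width bins (default 50).
#' @return List: `breaks` (length `n_bins + 1`), `mids`, `counts`.
#' @export
fraction_histogram <- function(x, n_bins = 50L) {
  stopifnot(n_bins >= 1, all(x >= 0 & x <= 1))
  breaks <- seq(0, 1, length.out = n_bins + 1L)
  counts <- tabulate(pmin(findInterval(x, breaks, rightmost.closed = TRUE),
                          n_bins), nbins = n_bins)
  list(breaks = breaks, mids = (breaks[-1] + breaks[-(n_bins + 1L)]) / 2,
       counts = counts)
}

#' Plot-ready subsampled scatter data
#'
#' Pairs two co-registered maps, applies the same strided subsample to
#' both, and attaches the marker transparency to use (heavily transparent
#' markers are the convention for million-point voxel scatterplots).
#'
#' @param x,y numeric vectors of equal length.
#' @param stride subsampling stride (default 200).
#' @param alpha marker opacity in (0, 1]; default 0.05 (95% transparent).
#' @return List: `x`, `y` (subsampled), `alpha`.
#' @export
scatter_data <- function(x, y, stride = 200L, alpha = 0.05) {
  stopifnot(length(x) == length(y), alpha > 0, alpha <= 1)
  list(x = subsample_stride(x, stride), y = subsample_stride(y, stride),
       alpha = alpha)
}
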