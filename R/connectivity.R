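#' A 3D per-voxel statistic map
#'
#' @param data 3D numeric array (0 outside the mask).
#' @param mask 3D logical array of defined voxels.
#' @param kind one of `"dc"`, `"fc_z"`, `"t"`, `"F"`, `"p"`.
#' @param voxel_mm voxel size.
#' @param flags optional 3D logical array of flagged voxels (zero variance,
#'   capped correlations, ...).
#' @return Object of class `scalar_map`.
#' @export
scalar_map <- function(data, mask, kind = c("dc", "fc_z", "t", "F", "p"),
                       voxel_mm = c(3, 3, 3), flags = NULL) {
  kind <- match.arg(kind)
  stopifnot(identical(dim(data), dim(mask) + 0L) || identical(dim(data), dim(mask)))
  structure(list(data = data, mask = array(as.logical(mask), dim(mask)),
                 kind = kind, voxel_mm = voxel_mm, flags = flags),
            class = "scalar_map")
}

#' @export
print.scalar_map <- function(x, ...) {
  v <- x$data[x$mask]
  cat(sprintf("<scalar_map %s> %s, %d in-mask voxels, range [%.4g, %.4g]\n",
              x$kind, paste(dim(x$data), collapse = "x"), sum(x$mask),
              min(v), max(v)))
  invisible(x)
}

map_values <- function(map) {
  if (inherits(map, "scalar_map")) map$data[map$mask] else stop_psd("not a scalar_map")
}

#' Voxel-wise degree centrality
#'
#' Treats every in-mask voxel as a node of the whole-brain correlation
#' graph: for voxel i the raw degree is the number (or, with
#' `binary = FALSE`, the sum) of Pearson correlations with all other in-mask
#' voxels strictly above `r_threshold` (one-sided on signed r; negative
#' correlations never contribute; the self-correlation is excluded). The map
#' is then normalized by its mean degree so the in-graph mean is exactly 1.
#'
#' Correlations are streamed in voxel blocks: the full V x V matrix is never
#' materialized. Zero-variance voxels are dropped from the graph, assigned
#' degree 0, and flagged.
#'
#' @param bold a [bold_series()] or 4D array.
#' @param mask 3D logical analysis mask (>= 2 voxels).
#' @param r_threshold correlation threshold (default 0.32, the conventional
#'   whole-brain Bonferroni point); edges require the correlation to exceed
#'   it strictly.
#' @param binary count edges (`TRUE`, default) or sum supra-threshold r.
#' @param normalize divide by the mean in-graph degree (default).
#' @param block_size number of voxel columns per streamed block.
#' @return A [scalar_map()] of kind `"dc"`.
#' @seealso [bonferroni_r_threshold()]
#' @export
compute_dc <- function(bold, mask, r_threshold = 0.32, binary = TRUE,
                       normalize = TRUE, block_size = 512L) {
  if (abs(r_threshold) >= 1) stop_psd("r_threshold must lie in (-1, 1)")
  arr <- if (inherits(bold, "bold_series")) bold$data else bold
  vm <- if (inherits(bold, "bold_series")) bold$voxel_mm else c(3, 3, 3)
  mask <- array(as.logical(mask), dim(arr)[1:3])
  v <- sum(mask)
  if (v < 2L) stop_psd("need at least 2 in-mask voxels")
  Y <- bold_matrix(arr, mask)
  Xs <- unit_cols(Y)
  zv <- attr(Xs, "zero_var")
  deg <- numeric(v)
  live <- which(!zv)
  if (length(live) >= 2L) {
    Xl <- Xs[, live, drop = FALSE]
    for (start in seq(1L, length(live), by = block_size)) {
      cols <- start:min(start + block_size - 1L, length(live))
      cc <- crossprod(Xl, Xl[, cols, drop = FALSE])   # live-V x block
      over <- cc > r_threshold
      if (binary) {
        deg[live[cols]] <- colSums(over) - 1           # self r = 1 excluded
      } else {
        deg[live[cols]] <- colSums(cc * over) - 1
      }
    }
  }
  if (normalize) {
    md <- mean(deg[live])
    if (!is.finite(md) || md == 0)
      stop_psd("all degrees are zero at r_threshold = %g; lower the threshold",
               r_threshold)
    deg <- deg / md
  }
  data <- array(0, dim(mask))
  data[mask] <- deg
  flags <- array(FALSE, dim(mask))
  flags[mask] <- zv
  scalar_map(data, mask, kind = "dc", voxel_mm = vm, flags = flags)
}

#' Bonferroni-corrected correlation threshold
#'
#' Returns the two-sided Pearson-r threshold at which the per-edge p-value
#' equals `alpha / n_voxels`, for a series of length `n_timepoints`
#' (`df = n_timepoints - 2`). Provided as a helper; the conventional 0.32
#' default of [compute_dc()] is unchanged by it.
#'
#' @param n_timepoints series length.
#' @param n_voxels number of in-mask voxels in the correction family.
#' @param alpha family-wise level.
#' @return Correlation threshold in (0, 1).
#' @export
bonferroni_r_threshold <- function(n_timepoints, n_voxels, alpha = 0.05) {
  df <- n_timepoints - 2
  if (df < 1) stop_psd("need n_timepoints >= 3")
  tcrit <- stats::qt(1 - (alpha / n_voxels) / 2, df)
  tcrit / sqrt(tcrit^2 + df)
}

#' Seed-based functional connectivity (Fisher z)
#'
#' Correlates the mean time course over the seed voxels with every in-mask
#' voxel and applies the Fisher r-to-z transform `z = atanh(r)`.
#' Correlations with `|r| >= 1 - 1e-7` (e.g. voxels inside the seed equal to
#' its mean) are capped at `1 - 1e-7` in magnitude and flagged, keeping the
#' map finite.
#'
#' @param bold a [bold_series()] or 4D array.
#' @param seed integer voxel indices, or a 3D logical array.
#' @param mask 3D logical analysis mask.
#' @return A [scalar_map()] of kind `"fc_z"`; capped voxels are flagged.
#' @export
compute_seed_fc <- function(bold, seed, mask) {
  arr <- if (inherits(bold, "bold_series")) bold$data else bold
  vm <- if (inherits(bold, "bold_series")) bold$voxel_mm else c(3, 3, 3)
  d3 <- dim(arr)[1:3]
  mask <- array(as.logical(mask), d3)
  seed_idx <- if (is.array(seed)) mask_indices(seed) else as.integer(seed)
  if (length(seed_idx) == 0L) stop_psd("seed is empty")
  flat <- matrix(arr, prod(d3), dim(arr)[4])
  seed_mean <- colMeans(flat[seed_idx, , drop = FALSE])
  if (stats::sd(seed_mean) == 0) stop_psd("seed mean series has zero variance")
  Y <- bold_matrix(arr, mask)
  r <- cor_with_reference(Y, seed_mean)
  r[is.na(r)] <- 0
  cap <- 1 - 1e-7
  capped <- abs(r) >= cap
  r <- clamp(r, -cap, cap)
  z <- atanh(r)
  data <- array(0, d3); data[mask] <- z
  flags <- array(FALSE, d3); flags[mask] <- capped
  scalar_map(data, mask, kind = "fc_z", voxel_mm = vm, flags = flags)
}

#' Mean of a map over an ROI
#'
#' @param map a [scalar_map()].
#' @param roi integer voxel indices or a 3D logical array.
#' @return Arithmetic mean of the map over the ROI voxels inside the map's
#'   mask; errors if the intersection is empty.
#' @export
extract_roi_mean <- function(map, roi) {
  stopifnot(inherits(map, "scalar_map"))
  idx <- if (is.array(roi)) mask_indices(roi) else as.integer(roi)
  idx <- idx[map$mask[idx]]
  if (length(idx) == 0L) stop_psd("ROI does not intersect the map mask")
  mean(map$data[idx])
}

#' Write a scalar map as NIfTI-1
#'
#' The map kind is recorded in the header description field; the mask is
#' written alongside when `write_mask = TRUE`.
#'
#' @param map a [scalar_map()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @param write_mask also write `<path>_mask`.
#' @return `path`, invisibly.
#' @export
write_scalar_map <- function(map, path, write_mask = FALSE) {
  img <- RNifti::asNifti(map$data, pixdim = map$voxel_mm,
                         descrip = paste0("psdconn:", map$kind))
  RNifti::writeNifti(img, path)
  if (write_mask) {
    mpath <- sub("(\\.nii(\\.gz)?)$", "_mask\\1", path)
    write_nifti_vol(map$mask * 1L, mpath, map$voxel_mm)
  }
  invisible(path)
}
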