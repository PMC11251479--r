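#' Specification of a synthetic three-group resting-state cohort
#'
#' Defines the data-generating conditions for a synthetic BOLD cohort with
#' three groups (healthy controls `HC`, nondepressed stroke `Stroke`, and
#' post-stroke depression `PSD`), block-structured voxel covariance
#' ("networks"), elevated coupling of designated hub blocks in the PSD group,
#' unilateral lesions, per-voxel hemodynamic lags in the stroke groups,
#' motion traces, and depression scores coupled to each subject's realized
#' hub connectivity.
#'
#' Every voxel time series follows the common-factor model
#' \deqn{v(t) = \sqrt{\rho}\, f_b(t - \ell_v) + \sqrt{1-\rho}\, \epsilon_v(t)}
#' where \eqn{f_b} is the unit-variance factor of the voxel's network block
#' (a stationary AR(1) process, giving the factor the temporal smoothness of
#' low-frequency BOLD fluctuations without changing the equal-time
#' correlation target),
#' \eqn{\rho} the group- and block-specific target correlation, \eqn{\ell_v}
#' the subject's voxel lag (circular shift of the factor), and
#' \eqn{\epsilon_v} i.i.d. unit Gaussian noise, so that two lag-aligned
#' voxels of one block have population correlation exactly \eqn{\rho}.
#' For PSD subjects, hub blocks use \eqn{\rho + \Delta} (`effect_delta_r`).
#'
#' All structure is defined in the canonical analysis space in which the
#' ipsilesional hemisphere is the left one (axis 1 is left-right); subjects
#' assigned a right-sided lesion have their volumes mirrored to native
#' orientation on output, which [flip_to_ipsilesional()] undoes.
#'
#' @param n_per_group named integer vector of group sizes; names must be
#'   `HC`, `Stroke`, `PSD`.
#' @param grid_shape three positive integers, voxels per axis
#'   (axis 1 = left-right).
#' @param n_timepoints number of volumes per subject.
#' @param tr_seconds repetition time in seconds.
#' @param network_blocks named list of integer voxel-index vectors (linear
#'   indices into the grid), one per network block; `NULL` uses
#'   [default_network_blocks()].
#' @param within_block_r either a single number in `[0, 1]` applied to every
#'   group and block, or a groups-by-blocks matrix of factor-model target
#'   correlations. The value 1 is the documented noiseless edge case.
#' @param hub_blocks character vector of block names whose PSD-group coupling
#'   is elevated by `effect_delta_r`; default picks the two right-hemisphere
#'   (contralesional) blocks.
#' @param effect_delta_r added correlation for PSD hub blocks
#'   (`within_block_r + effect_delta_r` must not exceed 1).
#' @param lesion_size_range integer range (min, max) of lesion extent in
#'   voxels.
#' @param lesion_right_prob probability that a patient's lesion is
#'   right-sided (volumes are then mirrored to native orientation).
#' @param lag_range_tr maximum absolute hemodynamic lag, in TR units,
#'   injected in the stroke groups (0 disables lags).
#' @param lag_mode `"block"` (default) draws one lag per subject per block,
#'   giving spatially coherent lag territories; `"voxel"` draws i.i.d.
#'   per-voxel lags.
#' @param motion_sd_mm innovation scale of the AR(1) motion traces (mm).
#' @param behavior_coupling named list with entries `PHQ9`, `HAMD`, `CESD`,
#'   each `list(slope, noise_sd)`, linking a PSD subject's realized mean
#'   within-hub-block Fisher z to the score.
#' @param rng_seed integer seed; identical spec + seed reproduce identical
#'   cohorts bit for bit.
#'
#' @return An object of class `cohort_spec`.
#' @seealso [generate_cohort()], [cohort_masks()]
#' @export
cohort_spec <- function(n_per_group = c(HC = 15L, Stroke = 15L, PSD = 15L),
                        grid_shape = c(16L, 16L, 12L),
                        n_timepoints = 150L,
                        tr_seconds = 2,
                        network_blocks = NULL,
                        within_block_r = 0.30,
                        hub_blocks = NULL,
                        effect_delta_r = 0.25,
                        lesion_size_range = c(4L, 20L),
                        lesion_right_prob = 0.5,
                        lag_range_tr = 2L,
                        lag_mode = c("block", "voxel"),
                        motion_sd_mm = 0.05,
                        behavior_coupling = NULL,
                        rng_seed = 1L) {
  lag_mode <- match.arg(lag_mode)
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 4L))
    stop_psd("grid_shape must be 3 integers >= 4")
  groups <- c("HC", "Stroke", "PSD")
  if (is.null(names(n_per_group)) || !setequal(names(n_per_group), groups))
    stop_psd("n_per_group must be named HC, Stroke, PSD")
  n_per_group <- as.integer(n_per_group[groups])
  names(n_per_group) <- groups
  if (any(n_per_group < 2L)) stop_psd("need at least 2 subjects per group")

  if (is.null(network_blocks)) network_blocks <- default_network_blocks(grid_shape)
  if (is.null(names(network_blocks)) || anyDuplicated(names(network_blocks)))
    stop_psd("network_blocks must be a uniquely named list")
  nb <- length(network_blocks)
  all_idx <- unlist(network_blocks, use.names = FALSE)
  if (anyDuplicated(all_idx)) stop_psd("network blocks must be disjoint")
  if (any(all_idx < 1L | all_idx > prod(grid_shape)))
    stop_psd("network block indices outside grid")

  if (is.null(hub_blocks)) {
    hub_blocks <- grep("^R", names(network_blocks), value = TRUE)[1:2]
    hub_blocks <- hub_blocks[!is.na(hub_blocks)]
    if (length(hub_blocks) == 0L) hub_blocks <- names(network_blocks)[1]
  }
  if (!all(hub_blocks %in% names(network_blocks)))
    stop_psd("hub_blocks must name network blocks")

  if (is.matrix(within_block_r)) {
    r_mat <- within_block_r
    if (!identical(dim(r_mat), c(3L, nb)))
      stop_psd("within_block_r matrix must be 3 groups x %d blocks", nb)
    rownames(r_mat) <- groups
  } else {
    r_mat <- matrix(within_block_r, nrow = 3L, ncol = nb,
                    dimnames = list(groups, names(network_blocks)))
  }
  colnames(r_mat) <- names(network_blocks)
  if (any(r_mat < 0 | r_mat > 1)) stop_psd("within_block_r must lie in [0, 1]")
  if (effect_delta_r < 0) stop_psd("effect_delta_r must be >= 0")
  if (any(r_mat["PSD", hub_blocks] + effect_delta_r > 1 + 1e-12))
    stop_psd("infeasible coupling: within_block_r + effect_delta_r exceeds 1")

  lag_range_tr <- as.integer(lag_range_tr)
  if (lag_range_tr < 0L) stop_psd("lag_range_tr must be >= 0")
  if (n_timepoints <= 2L * max(1L, lag_range_tr))
    stop_psd("n_timepoints must exceed 2 * lag_range_tr")

  if (is.null(behavior_coupling)) {
    behavior_coupling <- list(
      PHQ9 = list(slope = 80, noise_sd = 1.5),
      HAMD = list(slope = 50, noise_sd = 1.2),
      CESD = list(slope = 110, noise_sd = 2.5))
  }
  stopifnot(all(c("PHQ9", "HAMD", "CESD") %in% names(behavior_coupling)))

  spec <- list(
    n_per_group = n_per_group,
    grid_shape = grid_shape,
    n_timepoints = as.integer(n_timepoints),
    tr_seconds = tr_seconds,
    network_blocks = network_blocks,
    within_block_r = r_mat,
    hub_blocks = hub_blocks,
    effect_delta_r = effect_delta_r,
    lesion_size_range = as.integer(lesion_size_range),
    lesion_right_prob = lesion_right_prob,
    lag_range_tr = lag_range_tr,
    lag_mode = lag_mode,
    motion_sd_mm = motion_sd_mm,
    behavior_coupling = behavior_coupling,
    rng_seed = as.integer(rng_seed))
  class(spec) <- "cohort_spec"
  spec
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic cohort spec\n")
  cat("  groups      :", paste(sprintf("%s=%d", names(x$n_per_group), x$n_per_group),
                               collapse = ", "), "\n")
  cat("  grid        :", paste(x$grid_shape, collapse = " x "),
      sprintf(" T=%d TR=%gs", x$n_timepoints, x$tr_seconds), "\n")
  cat("  blocks      :", length(x$network_blocks),
      sprintf("(hubs: %s, delta r = %g)", paste(x$hub_blocks, collapse = ","),
              x$effect_delta_r), "\n")
  cat("  lags        :", sprintf("+/-%d TR (%s)", x$lag_range_tr, x$lag_mode), "\n")
  cat("  seed        :", x$rng_seed, "\n")
  invisible(x)
}

#' Default network blocks for a synthetic grid
#'
#' Places six disjoint voxel cubes inside the ellipsoidal gray-matter mask,
#' in mirror-symmetric pairs (`L1`/`R1`, `L2`/`R2`, `L3`/`R3`) so that a
#' left-right flip maps the block set onto itself; the `R*` blocks sit in
#' the right (contralesional, in canonical space) hemisphere. Placement is a
#' deterministic search over left-hemisphere positions that keeps a margin
#' to the midline and at least one voxel between blocks.
#'
#' @param grid_shape three positive integers.
#' @param side integer cube side length; default 3 (27 voxels, clearing the
#'   conventional cluster-extent criterion of more than 20 contiguous
#'   voxels) on grids of at least 12 voxels per axis, else 2.
#' @return Named list of linear voxel-index vectors.
#' @export
default_network_blocks <- function(grid_shape, side = NULL) {
  grid_shape <- as.integer(grid_shape)
  if (is.null(side)) side <- if (min(grid_shape) >= 12L) 3L else 2L
  gm <- ellipsoid_mask(grid_shape)
  nx <- grid_shape[1]
  x_hi <- max(side, nx %/% 2L - 1L)      # one-voxel margin to the midline
  x_lo <- x_hi - side + 1L
  found <- list()
  # three passes: spread with a gap, dense with a gap, dense allowing
  # touching (still disjoint) cubes
  for (pass in list(c(side + 1L, 1L), c(1L, 1L), c(1L, 0L))) {
    found <- list()
    taken <- array(FALSE, grid_shape)
    step <- pass[1]; margin <- pass[2]
    for (z0 in seq(2L, max(2L, grid_shape[3] - side), by = step)) {
      for (y0 in seq(2L, max(2L, grid_shape[2] - side), by = step)) {
        if (length(found) >= 3L) break
        idx <- box_indices(c(x_lo, y0, z0), c(x_hi, y0 + side - 1L,
                                              z0 + side - 1L), grid_shape)
        if (is.null(idx) || !all(gm[idx]) || any(taken[idx])) next
        found[[length(found) + 1L]] <- idx
        dil <- box_indices(pmax(1L, c(x_lo, y0, z0) - margin),
                           pmin(grid_shape, c(x_hi, y0 + side - 1L,
                                              z0 + side - 1L) + margin),
                           grid_shape)
        taken[dil] <- TRUE
      }
    }
    if (length(found) >= 3L) break
  }
  if (length(found) < 3L)
    stop_psd("grid %s too small to place 3 mirror block pairs (side %d)",
             paste(grid_shape, collapse = "x"), side)
  blocks <- list()
  for (i in 1:3) {
    idx <- found[[i]]
    xyz <- arrayInd(idx, grid_shape)
    mirror <- as.integer((nx + 1L - xyz[, 1]) + (xyz[, 2] - 1L) * nx +
                         (xyz[, 3] - 1L) * nx * grid_shape[2])
    blocks[[paste0("L", i)]] <- sort(idx)
    blocks[[paste0("R", i)]] <- sort(mirror)
  }
  if (anyDuplicated(unlist(blocks))) stop_psd("default blocks overlap; grid too small")
  blocks
}

box_indices <- function(lo, hi, grid_shape) {
  if (any(lo < 1L) || any(hi > grid_shape) || any(lo > hi)) return(NULL)
  g <- as.matrix(expand.grid(x = lo[1]:hi[1], y = lo[2]:hi[2], z = lo[3]:hi[3]))
  as.integer(g[, 1] + (g[, 2] - 1L) * grid_shape[1] +
             (g[, 3] - 1L) * grid_shape[1] * grid_shape[2])
}

# Inscribed ellipsoid; stands in for a brain / gray-matter mask on the
# synthetic grid (a brain mask is never the full bounding box).
ellipsoid_mask <- function(grid_shape, shrink = 0.6) {
  ctr <- (grid_shape + 1) / 2
  semi <- grid_shape / 2 - shrink
  g <- expand.grid(x = seq_len(grid_shape[1]), y = seq_len(grid_shape[2]),
                   z = seq_len(grid_shape[3]))
  d <- ((g$x - ctr[1]) / semi[1])^2 + ((g$y - ctr[2]) / semi[2])^2 +
       ((g$z - ctr[3]) / semi[3])^2
  array(d <= 1, dim = grid_shape)
}

#' Tissue and atlas masks implied by a cohort spec
#'
#' The gray-matter/atlas mask is an ellipsoid inscribed in the grid; the WM
#' and CSF label regions are small corner boxes outside it (their mean
#' series serve as nuisance signals).
#'
#' @param spec a [cohort_spec()], or a length-3 grid-shape vector.
#' @return List with logical 3D arrays `gray_matter`, `atlas`, `wm`, `csf`.
#' @export
cohort_masks <- function(spec) {
  gs <- if (inherits(spec, "cohort_spec")) spec$grid_shape else as.integer(spec)
  stopifnot(length(gs) == 3L)
  gm <- ellipsoid_mask(gs)
  corner_box <- function(lo_frac, hi_frac) {
    lo <- pmax(1L, as.integer(ceiling(lo_frac * gs)))
    hi <- pmin(gs, as.integer(floor(hi_frac * gs)))
    m <- array(FALSE, gs)
    m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
    m & !gm
  }
  wm <- corner_box(c(0.01, 0.01, 0.01), c(0.2, 0.2, 0.2))
  csf <- corner_box(c(0.81, 0.81, 0.81), c(1, 1, 1))
  if (!any(wm) || !any(csf)) stop_psd("grid too small to place WM/CSF regions")
  list(gray_matter = gm, atlas = gm, wm = wm, csf = csf)
}
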