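# Shared fixture builders; everything is generated in code at test time.

# Reduced-size cohort spec for fast end-to-end tests.
tiny_spec <- function(..., grid_shape = c(10, 10, 8), n_timepoints = 100L,
                      n_per_group = c(HC = 10L, Stroke = 10L, PSD = 10L),
                      rng_seed = 1L) {
  cohort_spec(n_per_group = n_per_group, grid_shape = grid_shape,
              n_timepoints = n_timepoints, rng_seed = rng_seed, ...)
}

# A 4D array with given dims filled from a seeded normal draw.
rand_bold_array <- function(dims, seed = 1) {
  set.seed(seed)
  array(rnorm(prod(dims)), dim = dims)
}

# Per-subject ROI-mean DC over ground-truth blocks for a generated cohort,
# computed on raw (flip-corrected) series; used by specificity simulations.
cohort_block_dc_means <- function(spec, cohort) {
  masks <- cohort_masks(spec)
  lesions <- Filter(Negate(is.null),
                    lapply(names(cohort$bold), function(s) cohort$truth$lesions[[s]]))
  gmask <- build_group_mask(list(), masks$atlas, lesions)
  dcm <- lapply(cohort$bold, function(b) {
    arr <- if (identical(b$lesion_side, "right"))
      flip_to_ipsilesional(b$data, "right") else b$data
    compute_dc(arr, gmask)
  })
  # blocks restricted to the group mask; blocks fully swallowed by the
  # lesion union (possible on tiny left-hemisphere grids) are dropped
  rois <- lapply(spec$network_blocks, function(b) intersect(b, which(gmask)))
  rois <- rois[lengths(rois) >= 2L]
  sapply(names(rois), function(bn)
    vapply(dcm, extract_roi_mean, numeric(1), roi = rois[[bn]]))
}

# Records table reconstructed from printed three-group contingency counts.
records_from_counts <- function(male, female, groups = c("Stroke", "PSD", "HC")) {
  data.frame(
    group = rep(rep(groups, times = 2), c(male, female)),
    gender = rep(c("M", "F"), c(sum(male), sum(female))),
    stringsAsFactors = FALSE)
}
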