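#' One subject's 4D BOLD series
#'
#' Lightweight container for a subject's 4D BOLD array on a common voxel
#' grid, with TR, voxel size, and a flag recording whether the volume has
#' been flipped so the ipsilesional hemisphere is on the conventional (left)
#' side of axis 1.
#'
#' @param data 4D numeric array (x, y, z, t); axis 1 is left-right.
#' @param tr_seconds repetition time in seconds.
#' @param subject_id,group,lesion_side subject metadata.
#' @param voxel_mm voxel edge lengths in mm.
#' @param flipped logical; `TRUE` once the volume is in canonical
#'   ipsilesional-left orientation.
#' @return An object of class `bold_series`.
#' @export
bold_series <- function(data, tr_seconds, subject_id = NA_character_,
                        group = NA_character_, lesion_side = NA_character_,
                        voxel_mm = c(3, 3, 3), flipped = FALSE) {
  d <- dim(data)
  if (length(d) != 4L || d[4] < 2L)
    stop_psd("bold_series needs a 4D array with at least 2 timepoints")
  structure(list(data = data, tr_seconds = tr_seconds, subject_id = subject_id,
                 group = group, lesion_side = lesion_side, voxel_mm = voxel_mm,
                 flipped = flipped),
            class = "bold_series")
}

#' @export
print.bold_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_series %s> %dx%dx%d, T=%d, TR=%gs, group=%s, side=%s%s\n",
              x$subject_id, d[1], d[2], d[3], d[4], x$tr_seconds, x$group,
              x$lesion_side, if (isTRUE(x$flipped)) ", flipped" else ""))
  invisible(x)
}

# Circular shift: out[t] = x[t - lag], indices wrapped.
circshift <- function(x, lag) {
  n <- length(x)
  if (lag %% n == 0) return(x)
  x[((seq_len(n) - 1L - lag) %% n) + 1L]
}

#' Generate a synthetic three-group BOLD cohort
#'
#' Draws a full cohort under the factor model of [cohort_spec()]: per-block
#' standard-normal factors, group-specific within-block coupling with the
#' PSD hub elevation, blockwise or voxelwise circularly-shifted hemodynamic
#' lags for the stroke groups, unilateral lesions that zero the BOLD signal,
#' AR(1) motion traces, group-typical demographics and clinical scores, and
#' depression scores linearly coupled (plus noise) to each PSD subject's
#' realized hub connectivity.
#'
#' Identical `spec` (including `rng_seed`) yields identical output.
#'
#' @param spec a [cohort_spec()].
#' @return A list with elements
#'   \describe{
#'     \item{bold}{list of [bold_series()] in native orientation (right-sided
#'       lesions mirrored),}
#'     \item{records}{data.frame of subject metadata (one row per subject),}
#'     \item{motion}{named list of T x 6 motion-parameter matrices,}
#'     \item{truth}{ground truth: hub block names, block index sets, per-subject
#'       canonical lag maps, lesion masks, sides, block factors, realized hub
#'       coupling, and the behavior slopes used.}
#'   }
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$rng_seed)
  gs <- spec$grid_shape
  Tn <- spec$n_timepoints
  nvox <- prod(gs)
  masks <- cohort_masks(spec)
  gm_idx <- mask_indices(masks$gray_matter)
  wm_idx <- mask_indices(masks$wm)
  csf_idx <- mask_indices(masks$csf)
  blocks <- spec$network_blocks
  nb <- length(blocks)
  groups <- rep(names(spec$n_per_group), spec$n_per_group)
  nsub <- length(groups)
  ids <- sprintf("sub-%03d", seq_len(nsub))

  left_half <- floor(gs[1] / 2)
  block_vox <- unlist(blocks, use.names = FALSE)
  left_gray <- gm_idx[((gm_idx - 1L) %% gs[1]) + 1L <= left_half]

  demo <- list(
    HC = list(age = c(57.43, 6.83), male_p = 43 / 74, phq = c(0.69, 1.18),
              hamd = c(0.3, 0.8), cesd = c(11.5, 2.0), adl = c(100, 0)),
    Stroke = list(age = c(59.41, 6.45), male_p = 50 / 82, phq = c(0.23, 0.69),
                  hamd = c(0.23, 0.79), cesd = c(12.12, 0.57), adl = c(82.8, 16.76),
                  onset = c(4.85, 3.26), nihss = c(2.54, 2.18)),
    PSD = list(age = c(60.00, 9.41), male_p = 21 / 39,
               hamd_base = 19.23, cesd_base = 24.44, phq_base = 8.23,
               adl = c(67.05, 18.05), onset = c(9.92, 4.92), nihss = c(5.18, 3.49)))

  # Expected realized hub coupling (Fisher z) for a PSD subject; the
  # behavior slopes act on deviations from this reference.
  rho_hub <- clamp(spec$within_block_r["PSD", spec$hub_blocks] +
                   spec$effect_delta_r, 0, 1 - 1e-7)
  z_ref <- mean(atanh(rho_hub))

  bold <- vector("list", nsub)
  motion <- vector("list", nsub)
  lag_maps <- vector("list", nsub)
  lesions <- vector("list", nsub)
  factors <- vector("list", nsub)
  coupling <- rep(NA_real_, nsub)
  rec <- vector("list", nsub)

  for (i in seq_len(nsub)) {
    g <- groups[i]
    is_patient <- g %in% c("Stroke", "PSD")

    # Block factors are stationary AR(1) with unit marginal variance: BOLD
    # fluctuations are temporally smooth, and the equal-time within-block
    # correlation target is unchanged by the autocorrelation.
    fac <- vapply(seq_len(nb), function(b) ar1_series(Tn, 0.5), numeric(Tn))
    colnames(fac) <- names(blocks)
    wm_f <- stats::rnorm(Tn)
    csf_f <- stats::rnorm(Tn)

    dat <- matrix(0, nvox, Tn)
    dat[gm_idx, ] <- stats::rnorm(length(gm_idx) * Tn)
    dat[wm_idx, ] <- 0.8 * matrix(wm_f, length(wm_idx), Tn, byrow = TRUE) +
      0.6 * stats::rnorm(length(wm_idx) * Tn)
    dat[csf_idx, ] <- 0.8 * matrix(csf_f, length(csf_idx), Tn, byrow = TRUE) +
      0.6 * stats::rnorm(length(csf_idx) * Tn)

    lag_map <- array(0L, gs)
    L <- if (is_patient) spec$lag_range_tr else 0L
    for (b in seq_len(nb)) {
      idx <- blocks[[b]]
      rho <- spec$within_block_r[g, b]
      if (g == "PSD" && names(blocks)[b] %in% spec$hub_blocks)
        rho <- min(rho + spec$effect_delta_r, 1)
      lags <- if (L > 0L) {
        if (spec$lag_mode == "block")
          rep(sample(seq(-L, L), 1L), length(idx))
        else sample(seq(-L, L), length(idx), replace = TRUE)
      } else rep(0L, length(idx))
      lag_map[idx] <- lags
      for (lv in unique(lags)) {
        sel <- idx[lags == lv]
        fs <- circshift(fac[, b], lv)
        dat[sel, ] <- sqrt(rho) * matrix(fs, length(sel), Tn, byrow = TRUE) +
          sqrt(1 - rho) * dat[sel, , drop = FALSE]
      }
    }

    lesion <- array(FALSE, gs)
    side <- NA_character_
    if (is_patient) {
      side <- if (stats::runif(1) < spec$lesion_right_prob) "right" else "left"
      lesion <- draw_lesion(spec, left_gray, block_vox)
      dat[mask_indices(lesion), ] <- 0
    }

    if (g == "PSD") coupling[i] <- realized_hub_coupling(dat, spec, lesion)

    mot <- ar1_motion(Tn, spec$motion_sd_mm)

    age <- round(stats::rnorm(1, demo[[g]]$age[1], demo[[g]]$age[2]), 1)
    gender <- if (stats::runif(1) < demo[[g]]$male_p) "M" else "F"
    adl <- round(clamp(stats::rnorm(1, demo[[g]]$adl[1], demo[[g]]$adl[2]), 0, 100))
    if (is_patient) {
      onset <- round(clamp(stats::rnorm(1, demo[[g]]$onset[1], demo[[g]]$onset[2]), 1, Inf))
      nihss <- round(clamp(stats::rnorm(1, demo[[g]]$nihss[1], demo[[g]]$nihss[2]), 0, 42))
    } else onset <- nihss <- NA_real_

    bc <- spec$behavior_coupling
    if (g == "PSD") {
      dz <- coupling[i] - z_ref
      phq <- demo$PSD$phq_base + bc$PHQ9$slope * dz + stats::rnorm(1, 0, bc$PHQ9$noise_sd)
      hamd <- demo$PSD$hamd_base + bc$HAMD$slope * dz + stats::rnorm(1, 0, bc$HAMD$noise_sd)
      cesd <- demo$PSD$cesd_base + bc$CESD$slope * dz + stats::rnorm(1, 0, bc$CESD$noise_sd)
    } else {
      phq <- stats::rnorm(1, demo[[g]]$phq[1], demo[[g]]$phq[2])
      hamd <- stats::rnorm(1, demo[[g]]$hamd[1], demo[[g]]$hamd[2])
      cesd <- stats::rnorm(1, demo[[g]]$cesd[1], demo[[g]]$cesd[2])
    }
    # Clip to each scale's plausible range (PHQ-9 0-27, HAMD >= 0, CES-D >= 0).
    phq <- round(clamp(phq, 0, 27)); hamd <- round(clamp(hamd, 0, Inf))
    cesd <- round(clamp(cesd, 0, Inf))

    arr <- array(dat, dim = c(gs, Tn))
    native_lesion <- lesion
    if (identical(side, "right")) {
      arr <- flip_to_ipsilesional(arr, "right")  # involution: mirror to native
      native_lesion <- flip_to_ipsilesional(lesion * 1L, "right") > 0
    }
    bold[[i]] <- bold_series(arr, spec$tr_seconds, subject_id = ids[i],
                             group = g, lesion_side = side, flipped = FALSE)
    motion[[i]] <- mot
    lag_maps[[i]] <- lag_map
    lesions[[i]] <- lesion
    attr(bold[[i]], "native_lesion") <- native_lesion
    factors[[i]] <- fac
    rec[[i]] <- data.frame(
      subject_id = ids[i], group = g, age = age, gender = gender,
      lesion_side = side, lesion_size_vox = sum(lesion),
      onset_days = onset, NIHSS = nihss, PHQ9 = phq, HAMD = hamd,
      CESD = cesd, ADL = adl, stringsAsFactors = FALSE)
  }

  names(bold) <- names(motion) <- names(lag_maps) <- names(lesions) <-
    names(factors) <- ids
  records <- do.call(rbind, rec)
  rownames(records) <- NULL
  truth <- list(hub_blocks = spec$hub_blocks, blocks = blocks,
                lag_maps = lag_maps, lesions = lesions,
                sides = stats::setNames(records$lesion_side, ids),
                factors = factors, realized_coupling = stats::setNames(coupling, ids),
                behavior_slopes = vapply(spec$behavior_coupling, `[[`,
                                         numeric(1), "slope"),
                z_reference = z_ref)
  list(bold = bold, records = records, motion = motion, truth = truth)
}

# Lesion = box around a center drawn in the left-hemisphere gray matter;
# centers falling inside a network block are re-drawn (bounded retries).
draw_lesion <- function(spec, left_gray, block_vox, max_retries = 100L) {
  gs <- spec$grid_shape
  size <- sample(seq(spec$lesion_size_range[1], spec$lesion_size_range[2]), 1L)
  for (try in seq_len(max_retries)) {
    ctr <- sample(left_gray, 1L)
    if (!(ctr %in% block_vox)) {
      cxyz <- arrayInd(ctr, gs)[1, ]
      edge <- max(1L, round(size^(1 / 3)))
      half <- (edge - 1L) %/% 2L
      # unilateral: the lesion never crosses the midsagittal plane
      rx <- clamp((cxyz[1] - half):(cxyz[1] + half + (edge - 1L) %% 2L), 1L,
                  floor(gs[1] / 2))
      ry <- clamp((cxyz[2] - half):(cxyz[2] + half + (edge - 1L) %% 2L), 1L, gs[2])
      rz <- clamp((cxyz[3] - half):(cxyz[3] + half + (edge - 1L) %% 2L), 1L, gs[3])
      lesion <- array(FALSE, gs)
      lesion[unique(rx), unique(ry), unique(rz)] <- TRUE
      lesion <- lesion & ellipsoid_mask(gs)
      if (any(lesion)) return(lesion)
    }
  }
  stop_psd("could not place a lesion avoiding network blocks after %d retries",
           max_retries)
}

# Mean pairwise Fisher z across hub-block voxel pairs (lesioned voxels
# excluded); this is the "realized hub coupling" behavior scores see.
realized_hub_coupling <- function(dat, spec, lesion) {
  zs <- vapply(spec$hub_blocks, function(b) {
    idx <- setdiff(spec$network_blocks[[b]], mask_indices(lesion))
    if (length(idx) < 2L) return(NA_real_)
    r <- stats::cor(t(dat[idx, , drop = FALSE]))
    mean(atanh(clamp(r[upper.tri(r)], -1 + 1e-7, 1 - 1e-7)))
  }, numeric(1))
  mean(zs, na.rm = TRUE)
}

# Stationary AR(1) series with unit marginal variance.
ar1_series <- function(Tn, phi) {
  e <- stats::rnorm(Tn)
  x <- numeric(Tn)
  x[1] <- e[1]
  s <- sqrt(1 - phi^2)
  for (t in 2:Tn) x[t] <- phi * x[t - 1] + s * e[t]
  x
}

# AR(1) rigid-body motion traces: 3 translations (mm), 3 rotations (rad).
ar1_motion <- function(Tn, sd_mm, phi = 0.95) {
  par <- matrix(0, Tn, 6L)
  sds <- c(rep(sd_mm, 3L), rep(sd_mm / 50, 3L))
  for (j in 1:6) {
    e <- stats::rnorm(Tn, 0, sds[j])
    p <- numeric(Tn)
    for (t in 2:Tn) p[t] <- phi * p[t - 1] + e[t]
    par[, j] <- p
  }
  colnames(par) <- c("trans_x_mm", "trans_y_mm", "trans_z_mm",
                     "rot_x_rad", "rot_y_rad", "rot_z_rad")
  par
}
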