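#' Flip a volume so the ipsilesional hemisphere is on the left
#'
#' Volumes from subjects with a right-sided lesion are mirrored along the
#' left-right axis (axis 1) so that the left hemisphere is ipsilesional for
#' every patient; left-lesion volumes pass through unchanged. The operation
#' is an involution.
#'
#' @param volume 3D or 4D array (or a [bold_series()]); axis 1 must be the
#'   left-right axis.
#' @param lesion_side `"left"` or `"right"`.
#' @return Array (or `bold_series`) of the same shape; for a `bold_series`
#'   the `flipped` flag is set.
#' @export
flip_to_ipsilesional <- function(volume, lesion_side) {
  if (inherits(volume, "bold_series")) {
    out <- volume
    out$data <- flip_to_ipsilesional(volume$data, lesion_side)
    out$flipped <- TRUE
    return(out)
  }
  if (!lesion_side %in% c("left", "right"))
    stop_psd("unknown lesion side '%s'", lesion_side)
  if (lesion_side == "left") return(volume)
  d <- dim(volume)
  if (is.null(d) || !length(d) %in% c(3L, 4L))
    stop_psd("flip_to_ipsilesional expects a 3D or 4D array")
  idx <- rev(seq_len(d[1]))
  if (length(d) == 3L) volume[idx, , , drop = FALSE]
  else volume[idx, , , , drop = FALSE]
}

#' Enantiomorphic filling of lesioned voxels
#'
#' Replaces each lesioned voxel's value by the value of its mirror voxel
#' across the midsagittal plane of the grid (axis 1 index `i` maps to
#' `nx + 1 - i`). If the mirror voxel is itself lesioned, the original value
#' is kept and a warning is issued.
#'
#' @param structural 3D numeric array.
#' @param lesion 3D logical (or 0/1) array on the same grid.
#' @return Filled 3D array; non-lesion voxels are untouched.
#' @export
enantiomorphic_fill <- function(structural, lesion) {
  d <- dim(structural)
  if (!identical(d, dim(lesion) * 1L) && !identical(d, dim(lesion)))
    stop_psd("structural and lesion grids differ")
  lesion <- array(as.logical(lesion), d)
  if (!any(lesion)) return(structural)
  mirrored <- structural[rev(seq_len(d[1])), , , drop = FALSE]
  mlesion <- lesion[rev(seq_len(d[1])), , , drop = FALSE]
  out <- structural
  fill <- lesion & !mlesion
  keep <- lesion & mlesion
  out[fill] <- mirrored[fill]
  if (any(keep))
    warn_psd("%d lesioned voxel(s) have lesioned mirrors; original values kept",
             sum(keep))
  out
}

#' Framewise displacement (Power convention)
#'
#' `fd[t] = sum(|delta translations|) + 50 mm * sum(|delta rotations (rad)|)`,
#' rotations converted to arc length on a 50 mm sphere; `fd[1] = 0`.
#'
#' @param params motion parameters: a T x 6 matrix (columns: 3 translations
#'   in mm, then 3 rotations in rad) or its 6 x T transpose.
#' @return Numeric vector of length T.
#' @export
compute_fd <- function(params) {
  params <- as_motion_matrix(params)
  tt <- nrow(params)
  if (tt < 2L) stop_psd("need at least 2 timepoints for FD")
  d <- abs(diff(params))
  fd <- c(0, rowSums(d[, 1:3, drop = FALSE]) + 50 * rowSums(d[, 4:6, drop = FALSE]))
  fd
}

as_motion_matrix <- function(params) {
  params <- as.matrix(params)
  if (ncol(params) == 6L) return(params)
  if (nrow(params) == 6L) return(t(params))
  stop_psd("motion parameters must be T x 6 or 6 x T")
}

#' Motion quality control decision
#'
#' A subject is excluded iff any criterion is strictly exceeded: maximal
#' absolute displacement on any translation axis > `max_disp_mm`, maximal
#' absolute rotation > `max_rot_deg`, or mean framewise displacement >
#' `max_mean_fd`. Values exactly at a threshold are kept.
#'
#' @param params motion parameters (see [compute_fd()]).
#' @param max_disp_mm,max_rot_deg,max_mean_fd exclusion thresholds.
#' @return List with `keep` (logical), `reason` (`NA` or the first failing
#'   criterion among `"max_disp"`, `"max_rot"`, `"mean_fd"`), and the three
#'   measured values.
#' @export
qc_exclude <- function(params, max_disp_mm = 3, max_rot_deg = 3,
                       max_mean_fd = 0.5) {
  params <- as_motion_matrix(params)
  max_disp <- max(abs(params[, 1:3]))
  max_rot <- max(abs(params[, 4:6])) * 180 / pi
  mean_fd <- mean(compute_fd(params))
  reason <- NA_character_
  if (max_disp > max_disp_mm) reason <- "max_disp"
  else if (max_rot > max_rot_deg) reason <- "max_rot"
  else if (mean_fd > max_mean_fd) reason <- "mean_fd"
  list(keep = is.na(reason), reason = reason, max_disp_mm = max_disp,
       max_rot_deg = max_rot, mean_fd = mean_fd)
}

#' Friston 24-parameter motion regressor set
#'
#' Expands 6 rigid-body parameters into the 24-regressor set: the
#' parameters, their one-volume lags (zero-padded at t = 1), and the squares
#' of both.
#'
#' @param params motion parameters (see [compute_fd()]).
#' @return A 24 x T matrix, rows ordered as `[p; lag(p); p^2; lag(p)^2]`.
#' @export
build_friston24 <- function(params) {
  params <- as_motion_matrix(params)
  tt <- nrow(params)
  if (tt < 2L) stop_psd("need at least 2 timepoints")
  p <- t(params)                                  # 6 x T
  plag <- cbind(0, p[, -tt, drop = FALSE])        # lagged, zero at t = 1
  rbind(p, plag, p^2, plag^2)
}

#' Regress nuisance signals out of a BOLD series
#'
#' Per-voxel ordinary-least-squares residualization against the supplied
#' regressors (an intercept is always included; `add_trend = TRUE` also adds
#' a linear trend so detrending and nuisance removal happen in a single
#' design). Collinear columns are dropped via the pivoted QR with a message.
#'
#' @param bold a [bold_series()] or 4D array.
#' @param regressors k x T matrix (rows = regressors) or T x k; may be
#'   `NULL` for intercept(/trend)-only regression.
#' @param add_trend include a linear trend column.
#' @param mask optional 3D logical array restricting the voxels processed;
#'   voxels outside are zeroed.
#' @return Same type as `bold`, containing residuals.
#' @export
nuisance_regress <- function(bold, regressors = NULL, add_trend = FALSE,
                             mask = NULL) {
  arr <- if (inherits(bold, "bold_series")) bold$data else bold
  d <- dim(arr)
  tt <- d[4]
  X <- matrix(1, tt, 1L)
  colnames(X) <- "intercept"
  if (add_trend) X <- cbind(X, trend = seq_len(tt) - (tt + 1) / 2)
  if (!is.null(regressors)) {
    R <- as.matrix(regressors)
    if (ncol(R) == tt && nrow(R) != tt) R <- t(R)
    if (nrow(R) != tt) stop_psd("regressor rows must have length T = %d", tt)
    colnames(R) <- colnames(R) %||% paste0("reg", seq_len(ncol(R)))
    X <- cbind(X, R)
  }
  qx <- qr(X)
  if (qx$rank < ncol(X))
    message(sprintf("nuisance_regress: dropped %d collinear column(s)",
                    ncol(X) - qx$rank))
  Y <- bold_matrix(arr, mask)
  res <- qr.resid(qx, Y)
  out_arr <- matrix_to_bold(res, d[1:3], mask)
  if (inherits(bold, "bold_series")) { bold$data <- out_arr; bold } else out_arr
}

#' Remove per-voxel linear trends
#'
#' Ordinary least squares on an intercept plus linear ramp; residuals have
#' mean zero and no linear component. Idempotent.
#'
#' @inheritParams nuisance_regress
#' @return Same type as `bold`.
#' @export
detrend_linear <- function(bold, mask = NULL) {
  nuisance_regress(bold, regressors = NULL, add_trend = TRUE, mask = mask)
}

#' Ideal band-pass filter in the DFT domain
#'
#' Retains discrete-Fourier components whose frequency lies in
#' `[low_hz, high_hz]` (inclusive, with a tiny tolerance for exact bins) and
#' zeroes all others, then inverts; the 0 Hz (mean) component is removed
#' whenever `low_hz > 0`. This is the rectangular frequency-mask filter of
#' the REST family of toolboxes.
#'
#' @param bold a [bold_series()] (TR taken from the object) or 4D array
#'   (then `tr_seconds` is required).
#' @param low_hz,high_hz pass band in Hz.
#' @param tr_seconds repetition time, for plain arrays.
#' @param mask optional 3D logical mask.
#' @return Same type as `bold`, filtered.
#' @export
bandpass <- function(bold, low_hz = 0.01, high_hz = 0.08, tr_seconds = NULL,
                     mask = NULL) {
  arr <- if (inherits(bold, "bold_series")) bold$data else bold
  tr <- if (inherits(bold, "bold_series")) bold$tr_seconds else tr_seconds
  if (is.null(tr)) stop_psd("tr_seconds required for a plain array")
  d <- dim(arr)
  tt <- d[4]
  nyq <- 1 / (2 * tr)
  if (high_hz >= nyq + 1e-12)
    stop_psd("high_hz (%g) must be below the Nyquist frequency (%g Hz)",
             high_hz, nyq)
  k <- 0:(tt - 1)
  freq <- pmin(k, tt - k) / (tt * tr)
  keep <- freq >= low_hz - 1e-12 & freq <= high_hz + 1e-12
  if (!any(keep)) {
    tmin <- ceiling(1 / (high_hz * tr))
    while (!any({kk <- 0:(tmin - 1); ff <- pmin(kk, tmin - kk) / (tmin * tr)
                 ff >= low_hz - 1e-12 & ff <= high_hz + 1e-12}))
      tmin <- tmin + 1L
    stop_psd(paste0("no DFT bin falls inside [%g, %g] Hz at T = %d, TR = %gs; ",
                    "smallest usable T is %d"), low_hz, high_hz, tt, tr, tmin)
  }
  Y <- bold_matrix(arr, mask)
  spec_t <- stats::mvfft(Y)
  spec_t[!keep, ] <- 0
  Yf <- Re(stats::mvfft(spec_t, inverse = TRUE)) / tt
  out_arr <- matrix_to_bold(Yf, d[1:3], mask)
  if (inherits(bold, "bold_series")) { bold$data <- out_arr; bold } else out_arr
}

#' Estimate and correct per-voxel hemodynamic lags by time-shift analysis
#'
#' For each voxel, the lag is the integer shift `s` in
#' `[-max_lag_tr, max_lag_tr]` maximizing the Pearson correlation between
#' the voxel series advanced by `s` and the reference series (computed over
#' the overlapping samples). A positive lag means the voxel runs behind the
#' reference. Ties go to the smaller `|s|`, then to the negative `s`. The
#' corrected series is the voxel series shifted by `-lag` with edge samples
#' repeated. Zero-variance voxels get lag 0 and are flagged.
#'
#' With `min_r > 0`, voxels whose peak cross-correlation does not reach
#' `min_r` keep lag 0: a shift estimated from an uninformative
#' cross-correlogram is noise, and applying it would jitter the series.
#'
#' @param bold a [bold_series()] or 4D array.
#' @param reference length-T reference series; defaults to the mean series
#'   over `mask` (or over all voxels with nonzero variance).
#' @param max_lag_tr maximum absolute lag searched, in TR units.
#' @param mask optional 3D logical mask of voxels to process.
#' @param min_r minimum peak correlation required before a nonzero lag is
#'   accepted (default 0: pure argmax).
#' @return List with `lag_map` (3D integer array, 0 outside the mask),
#'   `corrected` (same type as `bold`), and `flagged` (3D logical array of
#'   zero-variance voxels).
#' @export
estimate_and_correct_lag <- function(bold, reference = NULL, max_lag_tr = 4L,
                                     mask = NULL, min_r = 0) {
  if (max_lag_tr < 1L) stop_psd("max_lag_tr must be >= 1")
  arr <- if (inherits(bold, "bold_series")) bold$data else bold
  d <- dim(arr)
  tt <- d[4]
  Y <- bold_matrix(arr, mask)
  vsd <- apply(Y, 2L, stats::sd)
  zero_var <- !is.finite(vsd) | vsd == 0
  if (is.null(reference)) {
    src <- Y[, !zero_var, drop = FALSE]
    if (ncol(src) == 0L) stop_psd("no voxels with variance to build a reference")
    reference <- rowMeans(src)
  }
  if (length(reference) != tt) stop_psd("reference must have length T = %d", tt)
  # Candidate shifts ordered by (|s|, s negative first): ties resolved by
  # taking the first strict improvement in this order.
  shifts <- unique(as.integer(unlist(
    lapply(0:max_lag_tr, function(a) c(-a, a)))))
  best_r <- rep(-Inf, ncol(Y))
  best_s <- integer(ncol(Y))
  for (s in shifts) {
    if (s >= 0) { vr <- (1 + s):tt; rr <- 1:(tt - s) }
    else { vr <- 1:(tt + s); rr <- (1 - s):tt }
    r <- cor_with_reference(Y[vr, , drop = FALSE], reference[rr])
    r[is.na(r)] <- -Inf
    upd <- r > best_r + 1e-12
    best_r[upd] <- r[upd]
    best_s[upd] <- s
  }
  best_s[zero_var] <- 0L
  if (min_r > 0) best_s[best_r < min_r] <- 0L
  # Shift each voxel by -lag, repeating edge samples.
  Yc <- Y
  for (s in setdiff(unique(best_s), 0L)) {
    cols <- which(best_s == s)
    if (s > 0) idx <- c((1 + s):tt, rep(tt, s)) else idx <- c(rep(1, -s), 1:(tt + s))
    Yc[, cols] <- Y[idx, cols, drop = FALSE]
  }
  lag_map <- array(0L, d[1:3])
  flag <- array(FALSE, d[1:3])
  if (is.null(mask)) { lag_map[] <- best_s; flag[] <- zero_var }
  else { lag_map[as.logical(mask)] <- best_s; flag[as.logical(mask)] <- zero_var }
  out_arr <- matrix_to_bold(Yc, d[1:3], mask)
  corrected <- if (inherits(bold, "bold_series")) { b <- bold; b$data <- out_arr; b }
               else out_arr
  list(lag_map = lag_map, corrected = corrected, flagged = flag)
}

#' Separable Gaussian smoothing
#'
#' Convolves each axis with a normalized Gaussian kernel,
#' `sigma = fwhm / (2 sqrt(2 ln 2))` converted to voxel units per axis,
#' under a reflective (half-sample symmetric) boundary. Constants are
#' preserved and total sum is conserved.
#'
#' @param x 3D map, 4D series, or a [bold_series()].
#' @param fwhm_mm full width at half maximum in mm.
#' @param voxel_mm voxel size per axis (taken from a `bold_series`).
#' @return Same type as `x`.
#' @export
smooth_gaussian <- function(x, fwhm_mm = 6, voxel_mm = c(3, 3, 3)) {
  if (inherits(x, "bold_series")) {
    out <- x
    out$data <- smooth_gaussian(x$data, fwhm_mm, x$voxel_mm)
    return(out)
  }
  d <- dim(x)
  if (fwhm_mm <= 0) return(x)
  sig_vox <- (fwhm_mm / (2 * sqrt(2 * log(2)))) / voxel_mm
  mats <- lapply(1:3, function(ax) smoothing_matrix(d[ax], sig_vox[ax]))
  sm3 <- function(vol) {
    dd <- dim(vol)
    v <- mats[[1]] %*% matrix(vol, dd[1])
    vol <- array(v, dd)
    vol <- aperm(vol, c(2, 1, 3))
    v <- mats[[2]] %*% matrix(vol, dd[2])
    vol <- aperm(array(v, dd[c(2, 1, 3)]), c(2, 1, 3))
    vol <- aperm(vol, c(3, 2, 1))
    v <- mats[[3]] %*% matrix(vol, dd[3])
    aperm(array(v, dd[c(3, 2, 1)]), c(3, 2, 1))
  }
  if (length(d) == 3L) return(sm3(x))
  out <- x
  for (t in seq_len(d[4])) out[, , , t] <- sm3(x[, , , t, drop = TRUE])
  out
}

# Dense n x n smoothing operator with reflective boundary folding; rows sum
# to 1 (constant-preserving) and columns sum to 1 (mass-conserving).
smoothing_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  r <- max(1L, ceiling(4 * sigma))
  w <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  w <- w / sum(w)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (k in seq(-r, r)) {
      j <- i + k
      while (j < 1L || j > n) j <- ifelse(j < 1L, 1L - j, 2L * n + 1L - j)
      S[i, j] <- S[i, j] + w[k + r + 1L]
    }
  }
  S
}

#' Build the group-analysis gray-matter mask
#'
#' Intersection of all subject brain masks with the atlas gray-matter mask,
#' minus the union of all lesions.
#'
#' @param subject_masks list of 3D logical arrays (may be empty).
#' @param atlas_mask 3D logical atlas/gray-matter mask.
#' @param lesions list of 3D logical lesion masks (canonical orientation).
#' @return 3D logical array; errors if the result is empty.
#' @export
build_group_mask <- function(subject_masks, atlas_mask, lesions = list()) {
  out <- array(as.logical(atlas_mask), dim(atlas_mask))
  for (m in subject_masks) {
    if (!identical(dim(m), dim(out))) stop_psd("mask grids differ")
    out <- out & as.logical(m)
  }
  for (l in lesions) {
    if (!identical(dim(l), dim(out))) stop_psd("lesion grids differ")
    out <- out & !as.logical(l)
  }
  if (!any(out)) stop_psd("group mask is empty")
  out
}

#' Slice-timing correction hook
#'
#' Registered no-op: synthetic volumes carry no slice structure, so this
#' stage passes data through unchanged while keeping its place in the
#' pipeline order for real acquisitions.
#'
#' @param bold a [bold_series()] or 4D array.
#' @return `bold`, unchanged.
#' @export
slice_timing <- function(bold) bold
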