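test_that("hemisphere flip is an identity for left lesions and an involution", {
  arr <- rand_bold_array(c(3, 4, 2, 5), seed = 1)
  expect_identical(flip_to_ipsilesional(arr, "left"), arr)
  expect_identical(flip_to_ipsilesional(flip_to_ipsilesional(arr, "right"),
                                        "right"), arr)
  # index arithmetic on a 3-voxel-wide grid: index 1 -> index 3
  vol <- array(0, c(3, 1, 1)); vol[1, 1, 1] <- 7
  expect_equal(flip_to_ipsilesional(vol, "right")[3, 1, 1], 7)
  expect_error(flip_to_ipsilesional(vol, "up"), "unknown lesion side")
})

test_that("enantiomorphic fill mirrors lesioned voxels across the midline", {
  vol <- rand_bold_array(c(4, 3, 3), seed = 2)
  les <- array(FALSE, c(4, 3, 3))
  expect_identical(enantiomorphic_fill(vol, les), vol)
  # single lesioned voxel at x=1 on an x-extent-4 grid takes x=4's value
  les[1, 2, 2] <- TRUE
  out <- enantiomorphic_fill(vol, les)
  expect_equal(out[1, 2, 2], vol[4, 2, 2])
  out[1, 2, 2] <- vol[1, 2, 2]
  expect_identical(out, vol)
  # left-right symmetric image is a fixed point
  sym <- vol + vol[4:1, , ]
  expect_equal(enantiomorphic_fill(sym, les), sym)
  # lesioned mirror: fall back to original value with a warning
  les2 <- les; les2[4, 2, 2] <- TRUE
  expect_warning(out2 <- enantiomorphic_fill(vol, les2), "mirror")
  expect_equal(out2[1, 2, 2], vol[1, 2, 2])
  expect_equal(out2[4, 2, 2], vol[4, 2, 2])
})

test_that("framewise displacement follows the Power 50 mm convention", {
  p <- matrix(0, 10, 6)
  expect_equal(compute_fd(p), rep(0, 10))
  p1 <- p; p1[5:10, 1] <- 0.5      # one 0.5 mm translation step at frame 5
  fd <- compute_fd(p1)
  expect_equal(fd[5], 0.5)
  expect_equal(fd[-5], rep(0, 9))
  p2 <- p; p2[3:10, 4] <- 0.02     # one 0.02 rad rotation step -> 1.0 mm
  expect_equal(compute_fd(p2)[3], 1.0)
  expect_equal(compute_fd(t(p2)), compute_fd(p2))  # 6 x T accepted too
})

test_that("motion QC uses strict thresholds and names the failing criterion", {
  calm <- matrix(0, 20, 6)
  expect_true(qc_exclude(calm)$keep)
  # mean FD ~ 0.63: alternate 0 / 0.33 translations on two axes
  wob <- calm; wob[, 1] <- rep(c(0, 0.33), 10); wob[, 2] <- rep(c(0, 0.33), 10)
  res <- qc_exclude(wob)
  expect_false(res$keep)
  expect_equal(res$reason, "mean_fd")
  # rotation exactly 3 degrees is kept (strict inequality)
  rot <- calm; rot[10, 5] <- 3 * pi / 180
  expect_true(qc_exclude(rot)$keep)
  rot[10, 5] <- 3.0001 * pi / 180
  expect_equal(qc_exclude(rot)$reason, "max_rot")
  disp <- calm; disp[4, 2] <- 3.5
  expect_equal(qc_exclude(disp)$reason, "max_disp")
})

test_that("Friston-24 expansion matches its symbolic construction", {
  z <- matrix(0, 8, 6)
  expect_equal(build_friston24(z), matrix(0, 24, 8))
  p <- matrix(seq_len(5 * 6), 5, 6)   # p_t = t + 5(j-1)
  f24 <- build_friston24(p)
  expect_equal(dim(f24), c(24L, 5L))
  expect_equal(f24[1, ], p[, 1])                    # p
  expect_equal(f24[7, ], c(0, p[1:4, 1]))           # lag
  expect_equal(f24[13, ], p[, 1]^2)                 # square
  expect_equal(f24[19, ], c(0, p[1:4, 1]^2))        # lagged square
  expect_equal(f24[6, ], p[, 6])
})

test_that("nuisance regression is an OLS projection", {
  set.seed(3)
  tt <- 40
  arr <- rand_bold_array(c(2, 2, 1, tt), seed = 3)
  # regressor orthogonal to every centered voxel series: residual = centered
  r_orth <- rep(1, tt)   # intercept direction only
  out <- nuisance_regress(arr, matrix(r_orth, 1, tt))
  cent <- apply(arr, 1:3, function(v) v - mean(v))
  expect_equal(aperm(cent, c(2, 3, 4, 1)), out, tolerance = 1e-12)
  # voxel equal to a regressor -> residual ~ 0
  reg <- rnorm(tt)
  arr2 <- arr; arr2[1, 1, 1, ] <- 3 * reg + 2
  out2 <- nuisance_regress(arr2, matrix(reg, 1, tt))
  expect_lt(max(abs(out2[1, 1, 1, ])), 1e-10)
  # 3-timepoint fixture vs explicit normal-equations solution
  y <- c(1, 4, 2); x <- c(0.5, -1, 2)
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  arr3 <- array(y, c(1, 1, 1, 3))
  out3 <- nuisance_regress(arr3, matrix(x, 1, 3))
  expect_equal(as.numeric(out3), as.numeric(y - X %*% beta), tolerance = 1e-12)
  # collinear regressors are dropped with a message, not an error
  expect_message(nuisance_regress(arr, rbind(reg, reg)), "collinear")
})

test_that("linear detrending removes ramps exactly and is idempotent", {
  tt <- 50
  const <- array(5, c(1, 1, 1, tt))
  expect_equal(as.numeric(detrend_linear(const)), rep(0, tt))
  ramp <- array(seq_len(tt) * 2 + 3, c(1, 1, 1, tt))
  expect_equal(as.numeric(detrend_linear(ramp)), rep(0, tt), tolerance = 1e-10)
  # ramp + sinusoid: sinusoid recovered (explicit 2-column regression oracle)
  s <- sin(2 * pi * 5 * seq_len(tt) / tt)
  y <- 0.3 * seq_len(tt) + s
  X <- cbind(1, seq_len(tt))
  oracle <- y - X %*% solve(t(X) %*% X, t(X) %*% y)
  got <- as.numeric(detrend_linear(array(y, c(1, 1, 1, tt))))
  expect_equal(got, as.numeric(oracle), tolerance = 1e-10)
  expect_equal(detrend_linear(array(got, c(1, 1, 1, tt))),
               array(got, c(1, 1, 1, tt)), tolerance = 1e-10)
})

test_that("ideal band-pass keeps exact in-band bins and kills the rest", {
  tr <- 2; tt <- 100                    # bins at k/(T*TR) = k * 0.005 Hz
  tgrid <- seq_len(tt)
  # 0.04 Hz = bin 8: preserved to 1e-9
  s_in <- sin(2 * pi * 0.04 * tgrid * tr)
  out <- bandpass(array(s_in, c(1, 1, 1, tt)), 0.01, 0.08, tr_seconds = tr)
  expect_lt(max(abs(as.numeric(out) - s_in)), 1e-9)
  # 0.2 Hz = bin 40: annihilated
  s_out <- sin(2 * pi * 0.2 * tgrid * tr)
  out2 <- bandpass(array(s_out, c(1, 1, 1, tt)), 0.01, 0.08, tr_seconds = tr)
  expect_lt(max(abs(as.numeric(out2))), 1e-9)
  # constant -> zero (0 Hz outside the band)
  out3 <- bandpass(array(4, c(1, 1, 1, tt)), 0.01, 0.08, tr_seconds = tr)
  expect_lt(max(abs(as.numeric(out3))), 1e-12)
  # empty band names the smallest usable T
  expect_error(bandpass(array(1, c(1, 1, 1, 8)), 0.01, 0.02, tr_seconds = 2),
               "smallest usable T")
  expect_error(bandpass(array(1, c(1, 1, 1, 50)), 0.01, 0.3, tr_seconds = 2),
               "Nyquist")
})

test_that("time-shift analysis recovers known integer lags", {
  set.seed(9)
  tt <- 120
  ref <- rnorm(tt)
  arr <- array(0, c(3, 1, 1, tt))
  arr[1, 1, 1, ] <- ref                              # lag 0
  arr[2, 1, 1, ] <- c(ref[3:tt], ref[1:2])           # advanced...
  arr[3, 1, 1, ] <- c(ref[tt - 1:0], ref[1:(tt - 2)])# delayed by 2
  res <- estimate_and_correct_lag(arr, reference = ref, max_lag_tr = 4)
  expect_equal(res$lag_map[1, 1, 1], 0L)
  expect_equal(res$lag_map[2, 1, 1], -2L)
  expect_equal(res$lag_map[3, 1, 1], 2L)
  # corrected series re-aligns with the reference away from the edges
  cor_after <- cor(res$corrected[3, 1, 1, 5:(tt - 5)], ref[5:(tt - 5)])
  expect_gt(cor_after, 0.99)
  # zero-variance voxel: lag 0 and flagged
  arr[2, 1, 1, ] <- 0
  res2 <- estimate_and_correct_lag(arr, reference = ref, max_lag_tr = 4)
  expect_equal(res2$lag_map[2, 1, 1], 0L)
  expect_true(res2$flagged[2, 1, 1])
})

test_that("noiseless shifted-factor cohort yields exact lag recovery", {
  gs <- c(10, 10, 8)
  blk <- default_network_blocks(gs)
  spec <- cohort_spec(n_per_group = c(HC = 2, Stroke = 3, PSD = 2),
                      grid_shape = gs, n_timepoints = 80,
                      network_blocks = blk["L1"], within_block_r = 1,
                      hub_blocks = "L1", effect_delta_r = 0,
                      lag_range_tr = 2, lag_mode = "voxel", rng_seed = 13)
  co <- generate_cohort(spec)
  rec <- co$records
  for (s in rec$subject_id[rec$group == "Stroke"]) {
    arr <- co$bold[[s]]$data
    if (identical(rec$lesion_side[rec$subject_id == s], "right"))
      arr <- flip_to_ipsilesional(arr, "right")
    roi <- array(FALSE, gs); roi[spec$network_blocks$L1] <- TRUE
    roi[co$truth$lesions[[s]]] <- FALSE
    res <- estimate_and_correct_lag(arr, reference = co$truth$factors[[s]][, "L1"],
                                    max_lag_tr = 2, mask = roi)
    expect_identical(res$lag_map[roi], co$truth$lag_maps[[s]][roi])
  }
})

test_that("Gaussian smoothing preserves constants, mass, and the delta kernel", {
  vol <- array(3.5, c(8, 8, 6))
  sm <- smooth_gaussian(vol, fwhm_mm = 6, voxel_mm = c(3, 3, 3))
  expect_equal(sm, vol, tolerance = 1e-12)
  # delta: central value is the product of the normalized 1D kernel peaks
  delta <- array(0, c(9, 9, 9)); delta[5, 5, 5] <- 1
  sig <- (6 / (2 * sqrt(2 * log(2)))) / 3
  r <- max(1, ceiling(4 * sig))
  w <- exp(-(-r:r)^2 / (2 * sig^2)); w <- w / sum(w)
  peak <- max(w)^3
  smd <- smooth_gaussian(delta, fwhm_mm = 6, voxel_mm = c(3, 3, 3))
  expect_equal(smd[5, 5, 5], peak, tolerance = 1e-12)
  # total mass conserved under the reflective boundary
  noisy <- rand_bold_array(c(7, 6, 5), seed = 4)
  expect_equal(sum(smooth_gaussian(noisy, 6)), sum(noisy), tolerance = 1e-10)
  # anisotropic voxels honored per axis
  smx <- smooth_gaussian(delta, fwhm_mm = 6, voxel_mm = c(6, 3, 3))
  expect_gt(smx[5, 5, 5], smd[5, 5, 5])
})

test_that("group mask is the masked intersection minus lesions", {
  atlas <- array(TRUE, c(4, 4, 4))
  lesA <- array(FALSE, c(4, 4, 4)); lesA[1, 1, 1] <- TRUE
  lesB <- array(FALSE, c(4, 4, 4)); lesB[2, , ] <- TRUE
  out <- build_group_mask(list(), atlas, list(lesA, lesB))
  expect_identical(out, atlas & !lesA & !lesB)
  # one subject missing a slab removes the slab
  sub <- array(TRUE, c(4, 4, 4)); sub[, , 4] <- FALSE
  out2 <- build_group_mask(list(sub), atlas, list())
  expect_false(any(out2[, , 4]))
  # brute-force set algebra on a random fixture
  set.seed(6)
  subs <- replicate(3, array(runif(64) > 0.2, c(4, 4, 4)), simplify = FALSE)
  les <- replicate(2, array(runif(64) > 0.8, c(4, 4, 4)), simplify = FALSE)
  got <- build_group_mask(subs, atlas, les)
  want <- apply(array(unlist(subs), c(4, 4, 4, 3)), 1:3, all) &
    !apply(array(unlist(les), c(4, 4, 4, 2)), 1:3, any)
  expect_identical(got, want)
  expect_error(build_group_mask(list(), atlas, list(array(TRUE, c(4, 4, 4)))),
               "empty")
})

test_that("preprocessing never propagates non-finite values", {
  spec <- tiny_spec(n_per_group = c(HC = 2, Stroke = 2, PSD = 2),
                    n_timepoints = 60, rng_seed = 8)
  co <- generate_cohort(spec)
  masks <- cohort_masks(spec)
  cfg <- pipeline_config(preprocess = list(drop_initial = 5L))
  for (s in co$records$subject_id[c(1, 3, 5)]) {
    pr <- preprocess_subject(co$bold[[s]], co$motion[[s]], masks,
                             attr(co$bold[[s]], "native_lesion"), cfg)
    expect_true(pr$kept)
    expect_true(all(is.finite(pr$unsmoothed$data)))
    expect_true(all(is.finite(pr$smoothed$data)))
    expect_equal(dim(pr$unsmoothed$data)[4], 55L)
  }
})
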