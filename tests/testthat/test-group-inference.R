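make_design <- function(groups, seed = 1) {
  set.seed(seed)
  data.frame(subject_id = sprintf("s%02d", seq_along(groups)), group = groups,
             age = round(rnorm(length(groups), 60, 5), 1),
             gender = sample(c("M", "F"), length(groups), replace = TRUE),
             NIHSS = ifelse(groups == "HC", NA, rpois(length(groups), 3)),
             stringsAsFactors = FALSE)
}

test_that("pairwise t is zero with identical group data", {
  groups <- rep(c("PSD", "HC"), each = 5)
  des <- make_design(groups)
  y <- rnorm(5)
  Y <- matrix(rep(c(y, y), 3), nrow = 10)   # identical data in both groups
  mask <- array(TRUE, c(3, 1, 1))
  fit <- fit_voxelwise_glm(Y, des, contrast = "pair_t", pair = c("PSD", "HC"),
                           covariates = character(0), mask = mask)
  expect_equal(as.numeric(fit$stat$data[mask]), rep(0, 3))
  expect_equal(as.numeric(fit$p$data[mask]), rep(1, 3))
})

test_that("partial F matches an explicit residual-sum-of-squares oracle", {
  set.seed(20)
  groups <- rep(c("HC", "Stroke", "PSD"), each = 4)
  des <- make_design(groups, seed = 20)
  y <- rnorm(12) + (groups == "PSD") * 1.5
  mask <- array(TRUE, c(1, 1, 1))
  fit <- fit_voxelwise_glm(matrix(y, 12, 1), des, contrast = "three_group_F",
                           mask = mask)
  # oracle: explicit projections via normal equations
  gind <- stats::model.matrix(~ factor(groups))[, -1]
  covs <- cbind(des$age, as.numeric(factor(des$gender)) - 1)
  Xf <- cbind(1, gind, covs); Xr <- cbind(1, covs)
  rss <- function(X) {
    beta <- solve(t(X) %*% X, t(X) %*% y)
    sum((y - X %*% beta)^2)
  }
  df1 <- 2; df2 <- 12 - ncol(Xf)
  f_oracle <- ((rss(Xr) - rss(Xf)) / df1) / (rss(Xf) / df2)
  expect_equal(fit$stat$data[1, 1, 1], f_oracle, tolerance = 1e-10)
  expect_equal(fit$p$data[1, 1, 1], pf(f_oracle, df1, df2, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_equal(unname(fit$df), c(df1, df2))
})

test_that("pairwise t matches a direct lm fit and subject order is irrelevant", {
  set.seed(21)
  groups <- rep(c("Stroke", "PSD"), times = c(7, 6))
  des <- make_design(groups, seed = 21)
  Y <- matrix(rnorm(13 * 4), 13, 4)
  mask <- array(TRUE, c(4, 1, 1))
  fit <- fit_voxelwise_glm(Y, des, contrast = "pair_t", mask = mask)
  gender_num <- as.numeric(factor(des$gender)) - 1
  lmfit <- lm(Y[, 2] ~ I(groups == "PSD") + des$age + gender_num + des$NIHSS)
  tval <- summary(lmfit)$coefficients[2, "t value"]
  expect_equal(fit$stat$data[2, 1, 1], tval, tolerance = 1e-10)
  perm <- sample(13)
  fit_p <- fit_voxelwise_glm(Y[perm, ], des[perm, ], contrast = "pair_t",
                             mask = mask)
  expect_equal(fit_p$stat$data, fit$stat$data, tolerance = 1e-12)
})

test_that("NIHSS covariate policy is enforced by design validation", {
  groups <- rep(c("HC", "Stroke", "PSD"), each = 4)
  des <- make_design(groups)
  Y <- matrix(rnorm(12), 12, 1)
  mask <- array(TRUE, c(1, 1, 1))
  expect_error(fit_voxelwise_glm(Y, des, contrast = "pair_t",
                                 pair = c("PSD", "Stroke"),
                                 covariates = c("age", "gender"), mask = mask),
               "requires NIHSS")
  expect_error(fit_voxelwise_glm(Y, des, contrast = "pair_t",
                                 pair = c("PSD", "HC"),
                                 covariates = c("age", "gender", "NIHSS"),
                                 mask = mask),
               "only the PSD vs Stroke")
  expect_error(fit_voxelwise_glm(Y, des, contrast = "three_group_F",
                                 covariates = c("age", "gender", "NIHSS"),
                                 mask = mask),
               "only the PSD vs Stroke")
})

test_that("collinear designs fail naming the offending column", {
  groups <- rep(c("Stroke", "PSD"), each = 5)
  des <- make_design(groups)
  des$age <- 55                  # constant: collinear with the intercept
  Y <- matrix(rnorm(10), 10, 1)
  expect_error(fit_voxelwise_glm(Y, des, contrast = "pair_t",
                                 pair = c("PSD", "Stroke"), mask = array(TRUE, c(1, 1, 1))),
               "collinear")
})

test_that("BH-FDR reproduces the hand-evaluated step-up rule", {
  p <- c(0.001, 0.01, 0.02, 0.03, 0.2)
  # by hand: largest i with p(i) <= i q / m is 4 -> reject the first four
  expect_equal(fdr_bh(p, 0.05), c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(fdr_bh(rep(1, 6), 0.05), rep(FALSE, 6))
  expect_equal(fdr_bh(rep(0, 6), 0.05), rep(TRUE, 6))
  # independent hand implementation on random vectors + monotonicity in q
  set.seed(22)
  for (i in 1:20) {
    pv <- runif(sample(5:50, 1))^sample(1:3, 1)
    m <- length(pv)
    o <- order(pv)
    for (q in c(0.01, 0.05, 0.2)) {
      kmax <- max(c(0, which(sort(pv) <= seq_len(m) * q / m)))
      manual <- rep(FALSE, m)
      if (kmax > 0) manual[o[seq_len(kmax)]] <- TRUE
      expect_identical(fdr_bh(pv, q), manual)
    }
    expect_true(all(fdr_bh(pv, 0.01) <= fdr_bh(pv, 0.05)))
    expect_true(all(fdr_bh(pv, 0.05) <= fdr_bh(pv, 0.2)))
  }
  expect_error(fdr_bh(numeric(0)), "no p-values")
  expect_error(fdr_bh(c(0.5, 1.2)), "0, 1")
})

test_that("cluster extraction honors extent and connectivity conventions", {
  d <- c(8, 8, 8)
  stat <- array(1, d)
  m <- array(FALSE, d); m[4, 4, 4] <- TRUE
  expect_equal(nrow(extract_clusters(m, stat)), 0L)       # singleton dropped
  # 21-voxel blob passes (strict > 20), a 20-voxel blob does not
  blob21 <- array(FALSE, d); blob21[1:7, 1:3, 1][seq_len(21)] <- TRUE
  blob21 <- array(FALSE, d); blob21[cbind(rep(1:7, 3), rep(1:3, each = 7), 1)] <- TRUE
  tab <- extract_clusters(blob21, stat, min_extent = 20)
  expect_equal(tab$extent, 21L)
  blob20 <- blob21; blob20[7, 3, 1] <- FALSE
  expect_equal(nrow(extract_clusters(blob20, stat, min_extent = 20)), 0L)
  # corner-touching blobs: separate under 6-connectivity, one under 26
  corner <- array(FALSE, c(3, 3, 3))
  corner[1, 1, 1] <- TRUE; corner[2, 2, 2] <- TRUE
  expect_equal(nrow(extract_clusters(corner, array(1, c(3, 3, 3)),
                                     min_extent = 0, connectivity = 6)), 2L)
  expect_equal(nrow(extract_clusters(corner, array(1, c(3, 3, 3)),
                                     min_extent = 0, connectivity = 26)), 1L)
  # peak = max |stat|, ties to the lowest linear index
  st <- array(0, d); st[blob21] <- 2; st[5, 2, 1] <- -5
  tab2 <- extract_clusters(blob21, st, min_extent = 20)
  expect_equal(tab2$peak_stat, -5)
  expect_equal(tab2$sign, -1)
  st[blob21] <- 2
  tab3 <- extract_clusters(blob21, st, min_extent = 20)
  expect_equal(tab3$peak_index, which(blob21)[1])
})

test_that("specificity conjunction verdicts follow the Bonferroni predicate", {
  set.seed(23)
  groups <- rep(c("HC", "Stroke", "PSD"), each = 8)
  base <- rnorm(24)
  # identical distributions: never specific
  res <- detect_specific_rois(cbind(roiA = base), groups)
  expect_equal(res$verdict, "not_specific")
  # strong PSD elevation: specific up
  up <- base + (groups == "PSD") * 3
  res_up <- detect_specific_rois(cbind(roiB = up), groups)
  expect_equal(res_up$verdict, "psd_specific_up")
  down <- base - (groups == "PSD") * 3
  expect_equal(detect_specific_rois(cbind(r = down), groups)$verdict,
               "psd_specific_down")
  # PSD between the other two group means: never flagged
  betw <- base + (groups == "Stroke") * 3 - (groups == "HC") * 3
  expect_equal(detect_specific_rois(cbind(r = betw), groups)$verdict,
               "not_specific")
  # verdict always consistent with the recomputed predicate
  for (i in 1:30) {
    x <- rnorm(24) + rnorm(1) * (groups == "PSD") + rnorm(1) * (groups == "HC")
    r <- detect_specific_rois(cbind(r = x), groups)
    both_sig <- r$p_psd_stroke * 3 < 0.05 && r$p_psd_hc * 3 < 0.05
    want <- if (both_sig && r$dir_psd_stroke == 1 && r$dir_psd_hc == 1)
      "psd_specific_up"
    else if (both_sig && r$dir_psd_stroke == -1 && r$dir_psd_hc == -1)
      "psd_specific_down"
    else "not_specific"
    expect_identical(r$verdict, want)
  }
  # Bonferroni boundary arithmetic: 0.016 * 3 < 0.05 < 0.017 * 3
  expect_true(0.016 * 3 < 0.05)
  expect_false(0.017 * 3 < 0.05)
})

test_that("demographic tests reproduce printed contingency-table p-values", {
  # three-group gender table (counts M: 50/21/43, F: 32/18/31)
  rec <- records_from_counts(male = c(50, 21, 43), female = c(32, 18, 31))
  out <- demographic_tests(rec)
  g <- out[out$variable == "gender", ]
  expect_equal(g$test, "chi_square")
  expect_lt(abs(g$p - 0.756), 5e-4)
  # two-group lesion hemisphere table (L/R: 44/38 vs 23/16)
  rec2 <- data.frame(
    group = rep(rep(c("Stroke", "PSD"), 2), c(44, 23, 38, 16)),
    lesion_side = rep(c("left", "right"), c(67, 54)), stringsAsFactors = FALSE)
  out2 <- demographic_tests(rec2)
  h <- out2[out2$variable == "lesion_side", ]
  expect_lt(abs(h$p - 0.582), 5e-4)
  # identical group proportions: statistic 0, p = 1
  rec3 <- records_from_counts(male = c(10, 10, 10), female = c(5, 5, 5))
  out3 <- demographic_tests(rec3)
  expect_equal(out3$statistic[out3$variable == "gender"], 0)
  expect_equal(out3$p[out3$variable == "gender"], 1)
})

test_that("demographic tests route variables through the required families", {
  spec <- tiny_spec(n_per_group = c(HC = 12, Stroke = 12, PSD = 12),
                    rng_seed = 41)
  co <- generate_cohort(spec)
  out <- demographic_tests(co$records)
  expect_true(all(c("gender", "age", "PHQ9", "NIHSS", "lesion_side") %in%
                  out$variable))
  expect_equal(out$test[out$variable == "gender"], "chi_square")
  expect_true(out$test[out$variable == "age"] %in% c("anova", "kruskal_wallis"))
  # ADL is constant in HC: the normality gate must fall back to Kruskal-Wallis
  expect_equal(out$test[out$variable == "ADL"], "kruskal_wallis")
  expect_equal(out$test[out$variable == "NIHSS"], "mann_whitney_u")
  expect_true(all(out$p >= 0 & out$p <= 1))
})
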