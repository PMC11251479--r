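#' Voxel-wise general linear model across subjects
#'
#' Fits, at every in-mask voxel, `value ~ group + covariates` across the
#' subject stack and returns either the partial F statistic for the group
#' factor (covariates retained in both models) or the t statistic for a
#' pairwise group contrast, with two-sided p-values.
#'
#' Covariate policy follows the three-group stroke design: age and gender
#' accompany every contrast; NIHSS is included exactly when the contrast is
#' PSD versus Stroke (design validation enforces this).
#'
#' @param maps list of [scalar_map()] with a common mask, or an
#'   n-subjects x V matrix (then `mask` is required for map output).
#' @param design data.frame with one row per subject: `group`
#'   (`HC`/`Stroke`/`PSD`), `age`, `gender`, and `NIHSS` when required.
#' @param contrast `"three_group_F"` or `"pair_t"`.
#' @param pair for `"pair_t"`, the two group labels (tested as
#'   `pair[1] - pair[2]`).
#' @param covariates covariate column names; default age + gender, plus
#'   NIHSS for the PSD-Stroke pair.
#' @param mask 3D logical mask when `maps` is a matrix.
#' @return List with `stat` ([scalar_map()] of kind `"t"` or `"F"`), `p`
#'   ([scalar_map()] of kind `"p"`), `df`, and the subject count `n`.
#' @export
fit_voxelwise_glm <- function(maps, design,
                              contrast = c("three_group_F", "pair_t"),
                              pair = c("PSD", "Stroke"),
                              covariates = NULL, mask = NULL) {
  contrast <- match.arg(contrast)
  if (is.null(covariates)) {
    covariates <- c("age", "gender")
    if (contrast == "pair_t" && setequal(pair, c("PSD", "Stroke")))
      covariates <- c(covariates, "NIHSS")
  }
  if (contrast == "pair_t" && setequal(pair, c("PSD", "Stroke")) &&
      !"NIHSS" %in% covariates)
    stop_psd("the PSD vs Stroke contrast requires NIHSS as a covariate")
  if (!(contrast == "pair_t" && setequal(pair, c("PSD", "Stroke"))) &&
      "NIHSS" %in% covariates)
    stop_psd("NIHSS enters only the PSD vs Stroke contrast")
  covariates <- intersect(covariates, names(design))

  if (is.list(maps) && inherits(maps[[1]], "scalar_map")) {
    mask <- maps[[1]]$mask
    vm <- maps[[1]]$voxel_mm
    Y <- do.call(rbind, lapply(maps, map_values))
  } else {
    Y <- as.matrix(maps)
    vm <- c(3, 3, 3)
    if (is.null(mask)) stop_psd("mask required when maps is a matrix")
  }
  if (nrow(Y) != nrow(design)) stop_psd("maps and design rows differ")

  grp <- as.character(design$group)
  if (contrast == "pair_t") {
    keep <- grp %in% pair
    if (sum(grp[keep] == pair[1]) < 2L || sum(grp[keep] == pair[2]) < 2L)
      stop_psd("need >= 2 subjects in each group of the pair")
    Y <- Y[keep, , drop = FALSE]
    design <- design[keep, , drop = FALSE]
    grp <- grp[keep]
  } else if (any(table(factor(grp)) < 2L)) {
    stop_psd("need >= 2 subjects per group")
  }

  Xcov <- covariate_matrix(design, covariates)
  if (contrast == "three_group_F") {
    G <- stats::model.matrix(~ factor(grp))[, -1, drop = FALSE]
    Xf <- cbind(Intercept = 1, G, Xcov)
    Xr <- cbind(Intercept = 1, Xcov)
    check_rank(Xf)
    n <- nrow(Xf); pfull <- ncol(Xf); df1 <- ncol(G); df2 <- n - pfull
    if (df2 < 1L) stop_psd("not enough residual degrees of freedom")
    rss_f <- resid_ss(Xf, Y)
    rss_r <- resid_ss(Xr, Y)
    num <- (rss_r - rss_f) / df1
    den <- rss_f / df2
    stat <- ifelse(den > 0, num / den, ifelse(num <= 0, 0, Inf))
    p <- stats::pf(stat, df1, df2, lower.tail = FALSE)
    kind <- "F"; df <- c(df1 = df1, df2 = df2)
  } else {
    ind <- as.numeric(grp == pair[1])
    X <- cbind(Intercept = 1, contrast_ind = ind, Xcov)
    check_rank(X)
    n <- nrow(X); df2 <- n - ncol(X)
    if (df2 < 1L) stop_psd("not enough residual degrees of freedom")
    xtx_inv <- chol2inv(chol(crossprod(X)))
    B <- xtx_inv %*% crossprod(X, Y)
    res <- Y - X %*% B
    sigma2 <- colSums(res^2) / df2
    se <- sqrt(sigma2 * xtx_inv[2, 2])
    b <- B[2, ]
    stat <- ifelse(se > 0, b / se, ifelse(b == 0, 0, sign(b) * Inf))
    p <- 2 * stats::pt(abs(stat), df2, lower.tail = FALSE)
    kind <- "t"; df <- c(df = df2)
  }
  stat_arr <- array(0, dim(mask)); stat_arr[mask] <- stat
  p_arr <- array(1, dim(mask)); p_arr[mask] <- p
  list(stat = scalar_map(stat_arr, mask, kind = kind, voxel_mm = vm),
       p = scalar_map(p_arr, mask, kind = "p", voxel_mm = vm),
       df = df, n = nrow(Y))
}

covariate_matrix <- function(design, covariates) {
  if (length(covariates) == 0L) return(NULL)
  cols <- lapply(covariates, function(cv) {
    x <- design[[cv]]
    if (any(is.na(x))) stop_psd("covariate '%s' has missing values", cv)
    if (is.character(x) || is.factor(x)) as.numeric(factor(x)) - 1 else as.numeric(x)
  })
  m <- do.call(cbind, cols)
  colnames(m) <- covariates
  m
}

check_rank <- function(X) {
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop_psd("design matrix is collinear; offending column(s): %s",
             paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

resid_ss <- function(X, Y) {
  qx <- qr(X)
  colSums(qr.resid(qx, Y)^2)
}

#' Benjamini-Hochberg FDR thresholding
#'
#' Step-up procedure over the in-mask p-values at level `q`; rejections are
#' monotone in `q`.
#'
#' @param p a [scalar_map()] of kind `"p"`, or a numeric vector of p-values.
#' @param q FDR level.
#' @return For a map input, a 3D logical array of rejected voxels; for a
#'   vector, a logical vector.
#' @export
fdr_bh <- function(p, q = 0.05) {
  if (inherits(p, "scalar_map")) {
    pv <- map_values(p)
    if (length(pv) == 0L) stop_psd("empty mask")
    rej <- stats::p.adjust(pv, method = "BH") <= q
    out <- array(FALSE, dim(p$data))
    out[p$mask] <- rej
    return(out)
  }
  if (length(p) == 0L) stop_psd("no p-values supplied")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop_psd("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH") <= q
}

#' Extract suprathreshold clusters
#'
#' Labels connected components of a significance mask at the configured 3D
#' neighborhood and keeps components whose extent strictly exceeds
#' `min_extent` (the conventional `k > 20` reading). The peak voxel is the
#' maximum of `|statistic|` within the cluster, ties resolved toward the
#' lowest linear index.
#'
#' @param sig_mask 3D logical array of significant voxels.
#' @param stat_map [scalar_map()] (or 3D array) of the underlying statistic.
#' @param min_extent clusters must have extent `> min_extent` voxels.
#' @param connectivity 6 (faces), 18 (faces+edges) or 26
#'   (faces+edges+corners, default).
#' @return A `cluster_table` data.frame with columns `cluster_id`,
#'   `peak_index`, `peak_x`, `peak_y`, `peak_z`, `extent`, `peak_stat`,
#'   `sign`, plus a `voxels` list-column of linear indices.
#' @export
extract_clusters <- function(sig_mask, stat_map, min_extent = 20L,
                             connectivity = 26L) {
  d <- dim(sig_mask)
  stat <- if (inherits(stat_map, "scalar_map")) stat_map$data else stat_map
  labels <- label_components(sig_mask, connectivity)
  ids <- setdiff(unique(as.integer(labels)), 0L)
  rows <- list()
  vox_list <- list()
  for (id in ids) {
    vox <- which(labels == id)
    if (length(vox) <= min_extent) next
    sv <- stat[vox]
    peak_local <- which(abs(sv) == max(abs(sv)))
    peak <- vox[min(peak_local)]          # ties: lowest linear index
    pxyz <- arrayInd(peak, d)[1, ]
    rows[[length(rows) + 1L]] <- data.frame(
      cluster_id = length(rows) + 1L, peak_index = peak,
      peak_x = pxyz[1], peak_y = pxyz[2], peak_z = pxyz[3],
      extent = length(vox), peak_stat = stat[peak],
      sign = sign(stat[peak]))
    vox_list[[length(rows)]] <- vox
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster_id = integer(), peak_index = integer(),
               peak_x = integer(), peak_y = integer(), peak_z = integer(),
               extent = integer(), peak_stat = numeric(), sign = numeric())
  tab$voxels <- vox_list
  class(tab) <- c("cluster_table", "data.frame")
  tab
}

# Connected-component labeling by flood fill on a 3D logical array.
label_components <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  offsets <- neighbor_offsets(connectivity)
  labels <- array(0L, d)
  idx_all <- which(mask)
  cur <- 0L
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  for (start in idx_all) {
    if (labels[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    labels[start] <- cur
    while (length(queue)) {
      v <- queue[length(queue)]
      queue <- queue[-length(queue)]
      vz <- (v - 1L) %/% (nx * ny)
      rem <- (v - 1L) %% (nx * ny)
      vy <- rem %/% nx
      vx <- rem %% nx
      for (k in seq_len(nrow(offsets))) {
        x <- vx + offsets[k, 1]; y <- vy + offsets[k, 2]; z <- vz + offsets[k, 3]
        if (x < 0L || x >= nx || y < 0L || y >= ny || z < 0L || z >= nz) next
        w <- 1L + x + y * nx + z * nx * ny
        if (mask[w] && labels[w] == 0L) {
          labels[w] <- cur
          queue <- c(queue, w)
        }
      }
    }
  }
  labels
}

neighbor_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  nd <- rowSums(abs(g) > 0)
  if (connectivity == 6L) g[nd == 1, , drop = FALSE]
  else if (connectivity == 18L) g[nd <= 2, , drop = FALSE]
  else if (connectivity == 26L) g
  else stop_psd("connectivity must be 6, 18 or 26")
}

#' Three-group PSD-specificity conjunction on ROI means
#'
#' For each ROI, runs pairwise two-sided Welch t-tests on the per-subject
#' ROI means (PSD-Stroke, PSD-HC, Stroke-HC) and issues a verdict:
#' `psd_specific_up` iff the PSD mean exceeds both other group means and
#' both corresponding Bonferroni-corrected p-values
#' (`p * n_comparisons`) fall below `alpha`; `psd_specific_down`
#' symmetrically; otherwise `not_specific`.
#'
#' @param roi_means n-subjects x n-ROIs numeric matrix (ROI names as column
#'   names) or data.frame.
#' @param groups character vector of group labels, length n-subjects.
#' @param alpha nominal level (default 0.05).
#' @param n_comparisons Bonferroni family size (default 3, the pairwise
#'   tests per ROI).
#' @return A `specificity_result` data.frame: one row per ROI with group
#'   means, the three pairwise p-values, direction signs, and the verdict.
#' @export
detect_specific_rois <- function(roi_means, groups, alpha = 0.05,
                                 n_comparisons = 3L) {
  m <- as.matrix(roi_means)
  if (is.null(colnames(m))) colnames(m) <- paste0("roi", seq_len(ncol(m)))
  groups <- as.character(groups)
  if (length(groups) != nrow(m)) stop_psd("groups must match roi_means rows")
  for (g in c("HC", "Stroke", "PSD"))
    if (sum(groups == g) < 2L) stop_psd("need >= 2 subjects in group %s", g)
  pair_p <- function(a, b, x) {
    xa <- x[groups == a]; xb <- x[groups == b]
    if (stats::sd(xa) == 0 && stats::sd(xb) == 0)
      return(if (mean(xa) == mean(xb)) 1 else 0)
    stats::t.test(xa, xb)$p.value                # Welch
  }
  rows <- lapply(colnames(m), function(roi) {
    x <- m[, roi]
    if (stats::sd(x) == 0) stop_psd("ROI '%s' has zero variance", roi)
    mu <- vapply(c("HC", "Stroke", "PSD"), function(g) mean(x[groups == g]),
                 numeric(1))
    p_ps <- pair_p("PSD", "Stroke", x)
    p_ph <- pair_p("PSD", "HC", x)
    p_sh <- pair_p("Stroke", "HC", x)
    sig_ps <- p_ps * n_comparisons < alpha
    sig_ph <- p_ph * n_comparisons < alpha
    verdict <- "not_specific"
    if (mu["PSD"] > mu["Stroke"] && mu["PSD"] > mu["HC"] && sig_ps && sig_ph)
      verdict <- "psd_specific_up"
    if (mu["PSD"] < mu["Stroke"] && mu["PSD"] < mu["HC"] && sig_ps && sig_ph)
      verdict <- "psd_specific_down"
    data.frame(roi = roi, mean_HC = mu[["HC"]], mean_Stroke = mu[["Stroke"]],
               mean_PSD = mu[["PSD"]], p_psd_stroke = p_ps, p_psd_hc = p_ph,
               p_stroke_hc = p_sh,
               dir_psd_stroke = sign(mu[["PSD"]] - mu[["Stroke"]]),
               dir_psd_hc = sign(mu[["PSD"]] - mu[["HC"]]),
               verdict = verdict, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("specificity_result", "data.frame")
  out
}

#' Demographic and clinical group-difference tests
#'
#' Reproduces the conventional mixed testing scheme for a three-group
#' stroke table: three-group continuous variables pass a Shapiro-Wilk
#' normality gate per group (all normal at p > 0.05 -> one-way ANOVA,
#' otherwise Kruskal-Wallis); two-group continuous variables use the
#' Mann-Whitney U test; categorical variables use the Pearson chi-square
#' test without continuity correction.
#'
#' @param records subject metadata data.frame (see [generate_cohort()]);
#'   recognised variables: `age`, `PHQ9`, `ADL` (three-group continuous),
#'   `gender`, `lesion_side` (categorical), `onset_days`, `NIHSS`, `HAMD`,
#'   `CESD`, `lesion_size_vox` (two-group continuous, Stroke vs PSD).
#' @return data.frame with one row per variable: `variable`, `test`,
#'   `statistic`, `df`, `p`.
#' @export
demographic_tests <- function(records) {
  grp <- as.character(records$group)
  out <- list()
  emit <- function(variable, test, statistic, df, p) {
    out[[length(out) + 1L]] <<- data.frame(
      variable = variable, test = test, statistic = statistic,
      df = df, p = p, stringsAsFactors = FALSE)
  }
  cont3 <- function(var) {
    x <- records[[var]]
    ok <- is.finite(x)
    g <- factor(grp[ok])
    normal <- vapply(levels(g), function(l) {
      xs <- x[ok][g == l]
      if (length(unique(xs)) < 3L) return(FALSE)
      tryCatch(stats::shapiro.test(xs)$p.value > 0.05, error = function(e) FALSE)
    }, logical(1))
    if (all(normal)) {
      fit <- stats::aov(x[ok] ~ g)
      s <- summary(fit)[[1]]
      emit(var, "anova", s[["F value"]][1], s[["Df"]][1], s[["Pr(>F)"]][1])
    } else {
      k <- stats::kruskal.test(x[ok], g)
      emit(var, "kruskal_wallis", unname(k$statistic), unname(k$parameter),
           k$p.value)
    }
  }
  cont2 <- function(var, a = "Stroke", b = "PSD") {
    x <- records[[var]]
    sel <- grp %in% c(a, b) & is.finite(x)
    w <- stats::wilcox.test(x[sel & grp == a], x[sel & grp == b], exact = FALSE,
                            correct = FALSE)
    emit(var, "mann_whitney_u", unname(w$statistic), NA_real_, w$p.value)
  }
  cat_test <- function(var, groups_used) {
    sel <- grp %in% groups_used & !is.na(records[[var]])
    tab <- table(factor(records[[var]][sel]), factor(grp[sel]))
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected == 0)) stop_psd("zero expected cell count for '%s'", var)
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    emit(var, "chi_square", unname(ct$statistic), unname(ct$parameter),
         ct$p.value)
  }
  if ("gender" %in% names(records)) cat_test("gender", c("HC", "Stroke", "PSD"))
  if ("age" %in% names(records)) cont3("age")
  if ("onset_days" %in% names(records)) cont2("onset_days")
  if ("lesion_side" %in% names(records)) cat_test("lesion_side", c("Stroke", "PSD"))
  if ("lesion_size_vox" %in% names(records)) cont2("lesion_size_vox")
  if ("PHQ9" %in% names(records)) cont3("PHQ9")
  if ("ADL" %in% names(records)) cont3("ADL")
  if ("NIHSS" %in% names(records)) cont2("NIHSS")
  if ("HAMD" %in% names(records)) cont2("HAMD")
  if ("CESD" %in% names(records)) cont2("CESD")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
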