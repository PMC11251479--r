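#' Build a pipeline configuration
#'
#' Assembles (and defaults) the full configuration of the end-to-end
#' analysis: cohort source, preprocessing constants, degree-centrality
#' settings, inference thresholds, and behavior-analysis settings. The
#' configuration is validated before any compute and echoed verbatim into
#' the run's provenance record.
#'
#' @param input_dir directory with a cohort written by [write_cohort()], or
#'   `NULL` to simulate.
#' @param synthetic named list of [cohort_spec()] arguments used when
#'   `input_dir` is `NULL`.
#' @param out_dir output directory.
#' @param rng_seed root seed; all stage randomness derives from it via
#'   named substreams.
#' @param preprocess,dc,inference,behavior named lists overriding individual
#'   defaults (unknown keys are errors).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL, synthetic = list(),
                            out_dir = "psdconn-out", rng_seed = 1L,
                            preprocess = list(), dc = list(),
                            inference = list(), behavior = list()) {
  defaults <- list(
    preprocess = list(drop_initial = 10L, max_disp_mm = 3, max_rot_deg = 3,
                      max_mean_fd = 0.5, band_low_hz = 0.01, band_high_hz = 0.08,
                      max_lag_tr = 4L, lag_min_r = 0.3, fwhm_mm = 6),
    dc = list(r_threshold = 0.32, binary = TRUE, normalize = TRUE),
    inference = list(q = 0.05, min_extent = 20L, alpha = 0.05,
                     n_comparisons = 3L, connectivity = 26L,
                     pairwise_threshold = "uncorrected", pairwise_p = 0.05,
                     posthoc_in_anova_mask = TRUE),
    behavior = list(lambda_grid = 10^seq(-3, 3, length.out = 17), n_tests = 3L))
  merge_section <- function(name, user) {
    base <- defaults[[name]]
    unknown <- setdiff(names(user), names(base))
    if (length(unknown))
      stop_psd("unknown %s config key(s): %s", name, paste(unknown, collapse = ", "))
    base[names(user)] <- user
    base
  }
  cfg <- list(schema_version = 1L, input_dir = input_dir,
              synthetic = synthetic, out_dir = out_dir,
              rng_seed = as.integer(rng_seed),
              preprocess = merge_section("preprocess", preprocess),
              dc = merge_section("dc", dc),
              inference = merge_section("inference", inference),
              behavior = merge_section("behavior", behavior))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from structured text (YAML)
#'
#' @param path YAML file whose top-level keys mirror the arguments of
#'   [pipeline_config()]; `schema_version: 1` is required and unknown keys
#'   are errors.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!identical(as.integer(raw$schema_version %||% -1L), 1L))
    stop_psd("config must declare schema_version: 1")
  known <- c("schema_version", "input_dir", "synthetic", "out_dir", "rng_seed",
             "preprocess", "dc", "inference", "behavior")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop_psd("unknown config key(s): %s", paste(unknown, collapse = ", "))
  pipeline_config(input_dir = raw$input_dir,
                  synthetic = raw$synthetic %||% list(),
                  out_dir = raw$out_dir %||% "psdconn-out",
                  rng_seed = raw$rng_seed %||% 1L,
                  preprocess = raw$preprocess %||% list(),
                  dc = raw$dc %||% list(),
                  inference = raw$inference %||% list(),
                  behavior = raw$behavior %||% list())
}

#' Validate a pipeline configuration
#'
#' @param config a `pipeline_config`.
#' @return Character vector of problems, each naming the field and the
#'   violated constraint; empty when the configuration is runnable.
#' @export
validate_config <- function(config) {
  problems <- character()
  add <- function(msg) problems <<- c(problems, msg)
  pp <- config$preprocess; inf <- config$inference; dc <- config$dc
  bh <- config$behavior
  if (pp$drop_initial < 0) add("preprocess.drop_initial: must be >= 0")
  if (pp$max_mean_fd <= 0) add("preprocess.max_mean_fd: must be > 0")
  if (pp$band_low_hz < 0) add("preprocess.band_low_hz: must be >= 0")
  if (pp$band_high_hz <= pp$band_low_hz)
    add("preprocess.band_high_hz: must exceed band_low_hz")
  if (pp$max_lag_tr < 1) add("preprocess.max_lag_tr: must be >= 1")
  if (pp$lag_min_r < 0 || pp$lag_min_r >= 1)
    add("preprocess.lag_min_r: must lie in [0, 1)")
  if (pp$fwhm_mm < 0) add("preprocess.fwhm_mm: must be >= 0")
  if (abs(dc$r_threshold) >= 1) add("dc.r_threshold: must lie in (-1, 1)")
  if (inf$q <= 0 || inf$q > 1) add("inference.q: must lie in (0, 1]")
  if (inf$alpha <= 0 || inf$alpha > 1) add("inference.alpha: must lie in (0, 1]")
  if (inf$min_extent < 0) add("inference.min_extent: must be >= 0")
  if (!inf$connectivity %in% c(6L, 18L, 26L))
    add("inference.connectivity: must be 6, 18 or 26")
  if (!inf$pairwise_threshold %in% c("uncorrected", "fdr"))
    add("inference.pairwise_threshold: must be 'uncorrected' or 'fdr'")
  if (any(bh$lambda_grid <= 0)) add("behavior.lambda_grid: all values must be > 0")
  if (bh$n_tests < 1) add("behavior.n_tests: must be >= 1")
  tr <- NULL
  if (is.null(config$input_dir)) {
    sp <- tryCatch(do.call(cohort_spec, config$synthetic),
                   error = function(e) {add(paste0("synthetic: ", conditionMessage(e))); NULL})
    if (!is.null(sp)) tr <- sp$tr_seconds
  }
  if (!is.null(tr) && pp$band_high_hz >= 1 / (2 * tr))
    add(sprintf("preprocess.band_high_hz: %g is at/above Nyquist (%g Hz)",
                pp$band_high_hz, 1 / (2 * tr)))
  problems
}

#' Lesion-aware preprocessing of one subject
#'
#' Applies the per-subject pipeline in fixed order: flip to ipsilesional-left
#' (right-sided lesions only), slice-timing hook (no-op), dropping of the
#' initial volumes, motion QC, one-pass nuisance regression (Friston-24
#' motion set, WM and CSF mean signals, intercept and linear trend; the
#' global signal is intentionally not removed), hemodynamic lag correction
#' for stroke patients, and ideal band-pass filtering. Spatial smoothing is
#' applied to a separate copy: degree centrality is computed on unsmoothed
#' data and seed FC on smoothed data.
#'
#' @param bold a [bold_series()].
#' @param motion T x 6 motion-parameter matrix (full length; the initial
#'   rows are dropped together with the volumes).
#' @param masks list with `gray_matter`, `wm`, `csf` logical arrays.
#' @param lesion native-orientation lesion mask or `NULL`.
#' @param config a `pipeline_config` (its `preprocess` section is used).
#' @return List: `unsmoothed` and `smoothed` [bold_series()], `qc` (QC row),
#'   `lag_map`, `lesion` (canonical orientation), `kept` (logical).
#' @export
preprocess_subject <- function(bold, motion, masks, lesion = NULL,
                               config = pipeline_config()) {
  pp <- config$preprocess
  is_patient <- isTRUE(bold$group %in% c("Stroke", "PSD"))
  if (is_patient && identical(bold$lesion_side, "right")) {
    bold <- flip_to_ipsilesional(bold, "right")
    if (!is.null(lesion)) lesion <- flip_to_ipsilesional(lesion * 1L, "right") > 0
  } else {
    bold$flipped <- TRUE   # already in canonical orientation
  }
  bold <- slice_timing(bold)
  drop <- pp$drop_initial
  tt <- dim(bold$data)[4]
  if (drop >= tt - 1L) stop_psd("drop_initial leaves fewer than 2 volumes")
  if (drop > 0L) {
    bold$data <- bold$data[, , , (drop + 1L):tt, drop = FALSE]
    motion <- as_motion_matrix(motion)[(drop + 1L):tt, , drop = FALSE]
  }
  qc <- qc_exclude(motion, pp$max_disp_mm, pp$max_rot_deg, pp$max_mean_fd)
  qc_row <- data.frame(subject_id = bold$subject_id,
                       max_disp = qc$max_disp_mm, max_rot_deg = qc$max_rot_deg,
                       mean_fd = qc$mean_fd,
                       decision = if (qc$keep) "keep" else "exclude",
                       reason = qc$reason, stringsAsFactors = FALSE)
  if (!qc$keep)
    return(list(unsmoothed = NULL, smoothed = NULL, qc = qc_row,
                lag_map = NULL, lesion = lesion, kept = FALSE))
  gm <- masks$gray_matter
  if (!is.null(lesion)) gm <- gm & !lesion
  wm_mean <- rowMeans(bold_matrix(bold$data, masks$wm))
  csf_mean <- rowMeans(bold_matrix(bold$data, masks$csf))
  reg <- rbind(build_friston24(motion), wm = wm_mean, csf = csf_mean)
  bold <- nuisance_regress(bold, reg, add_trend = TRUE, mask = gm)
  lag_map <- NULL
  if (is_patient && pp$max_lag_tr >= 1) {
    lc <- estimate_and_correct_lag(bold, reference = NULL,
                                   max_lag_tr = pp$max_lag_tr, mask = gm,
                                   min_r = pp$lag_min_r)
    bold <- lc$corrected
    lag_map <- lc$lag_map
  }
  bold <- bandpass(bold, pp$band_low_hz, pp$band_high_hz, mask = gm)
  smoothed <- smooth_gaussian(bold, pp$fwhm_mm)
  list(unsmoothed = bold, smoothed = smoothed, qc = qc_row,
       lag_map = lag_map, lesion = lesion, kept = TRUE)
}

#' Run the full analysis pipeline
#'
#' Executes the end-to-end analysis from one validated configuration:
#' cohort simulation (or loading), per-subject lesion-aware preprocessing
#' and QC, group-mask construction, voxel-wise degree centrality (smoothed
#' afterwards), three-group ANOVA with FDR and cluster-extent control,
#' PSD-vs-Stroke post-hoc mapping, the three-group specificity conjunction
#' that selects seeds, seed-based FC with the same inference path, and the
#' brain-behavior stage (Spearman with Bonferroni control; ridge-LOOCV
#' prediction of the three depression scales from PSD-specific FC features).
#' Every output file is recorded in `manifest.json` together with the
#' configuration, its hash, and the seed; re-running an identical
#' configuration reproduces identical outputs.
#'
#' @param config a `pipeline_config`.
#' @return The run report (invisibly also written to disk): QC table,
#'   cluster tables, specificity tables, seed list, behavior results, and
#'   the manifest.
#' @export
run_pipeline <- function(config) {
  problems <- validate_config(config)
  if (length(problems))
    stop_psd("invalid config:\n  %s", paste(problems, collapse = "\n  "))
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_lines <- character()
  note <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }
  files <- character()
  reg_file <- function(path) files <<- c(files, path)

  stage <- "simulate"
  res <- tryCatch({
    inf <- config$inference
    pp <- config$preprocess

    # --- cohort -----------------------------------------------------------
    if (is.null(config$input_dir)) {
      syn <- config$synthetic
      if (is.null(syn$rng_seed))
        syn$rng_seed <- derive_seed(config$rng_seed, "simulate")
      spec <- do.call(cohort_spec, syn)
      cohort <- generate_cohort(spec)
      masks <- cohort_masks(spec)
      lesions_native <- lapply(cohort$bold, attr, "native_lesion")
      note("simulate: %d subjects, grid %s, seed %d", nrow(cohort$records),
           paste(spec$grid_shape, collapse = "x"), spec$rng_seed)
    } else {
      cohort <- read_cohort(config$input_dir)
      gs <- dim(cohort$bold[[1]]$data)[1:3]
      masks <- cohort_masks(gs)
      lesions_native <- lapply(cohort$bold, function(b)
        cohort$lesions[[b$subject_id]])
      note("load: %d subjects from %s", nrow(cohort$records), config$input_dir)
    }
    records <- cohort$records

    # --- preprocessing + QC ----------------------------------------------
    stage <- "preprocess"
    note("preprocess: drop_initial=%d, QC disp>%g mm rot>%g deg meanFD>%g, band=[%g,%g] Hz, max_lag=%d TR, fwhm=%g mm",
         pp$drop_initial, pp$max_disp_mm, pp$max_rot_deg, pp$max_mean_fd,
         pp$band_low_hz, pp$band_high_hz, pp$max_lag_tr, pp$fwhm_mm)
    prep <- list(); qc_rows <- list()
    for (sid in names(cohort$bold)) {
      pr <- tryCatch(
        preprocess_subject(cohort$bold[[sid]], cohort$motion[[sid]], masks,
                           lesions_native[[sid]], config),
        error = function(e) stop_psd("stage preprocess, subject %s: %s", sid,
                                     conditionMessage(e)))
      qc_rows[[sid]] <- pr$qc
      if (pr$kept) prep[[sid]] <- pr
    }
    qc_table <- do.call(rbind, qc_rows); rownames(qc_table) <- NULL
    utils::write.table(qc_table, file.path(out_dir, "qc.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "n/a")
    reg_file("qc.tsv")
    kept <- names(prep)
    records <- records[records$subject_id %in% kept, , drop = FALSE]
    note("qc: kept %d of %d subjects", length(kept), nrow(qc_table))

    # --- group mask -------------------------------------------------------
    stage <- "group_mask"
    lesions_canon <- lapply(prep, function(p) p$lesion)
    lesions_canon <- Filter(Negate(is.null), lesions_canon)
    group_mask <- build_group_mask(list(), masks$atlas, lesions_canon)
    write_nifti_vol(group_mask * 1L, file.path(out_dir, "group_mask.nii.gz"))
    reg_file("group_mask.nii.gz")
    note("group_mask: %d voxels", sum(group_mask))

    # --- degree centrality ------------------------------------------------
    stage <- "dc"
    dc_dir <- file.path(out_dir, "dc"); dir.create(dc_dir, showWarnings = FALSE)
    note("dc: r_threshold=%g (strict >), binary=%s, normalized=%s",
         config$dc$r_threshold, config$dc$binary, config$dc$normalize)
    dc_maps <- list()
    for (sid in kept) {
      m <- compute_dc(prep[[sid]]$unsmoothed, group_mask,
                      r_threshold = config$dc$r_threshold,
                      binary = config$dc$binary, normalize = config$dc$normalize)
      m$data <- smooth_gaussian(m$data, pp$fwhm_mm,
                                prep[[sid]]$unsmoothed$voxel_mm)
      dc_maps[[sid]] <- m
      write_scalar_map(m, file.path(dc_dir, sprintf("%s_dc.nii.gz", sid)))
      reg_file(file.path("dc", sprintf("%s_dc.nii.gz", sid)))
    }

    # --- DC inference and seed selection ---------------------------------
    stage <- "dc_inference"
    design <- records[, c("subject_id", "group", "age", "gender", "NIHSS")]
    dc_inf <- metric_inference(dc_maps, design, group_mask, config, out_dir,
                               prefix = "dc", reg_file, note)
    seeds <- dc_inf$specific_rois
    seed_json <- lapply(seeds, function(s)
      list(roi_id = s$roi_id, provenance = "dc_specificity",
           verdict = s$verdict, n_voxels = length(s$voxels),
           voxels = s$voxels))
    jsonlite::write_json(seed_json, file.path(out_dir, "seeds.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    reg_file("seeds.json")
    note("seeds: %d PSD-specific DC region(s)", length(seeds))

    # --- seed-based FC ----------------------------------------------------
    stage <- "fc"
    fc_specific <- list()
    fc_roi_features <- list()
    for (s in seeds) {
      sdir <- file.path(out_dir, sprintf("fc_%s", s$roi_id))
      dir.create(sdir, showWarnings = FALSE)
      fc_maps <- list()
      for (sid in kept) {
        fm <- compute_seed_fc(prep[[sid]]$smoothed, s$voxels, group_mask)
        fc_maps[[sid]] <- fm
        write_scalar_map(fm, file.path(sdir, sprintf("%s_fc.nii.gz", sid)))
        reg_file(file.path(sprintf("fc_%s", s$roi_id),
                           sprintf("%s_fc.nii.gz", sid)))
      }
      fi <- metric_inference(fc_maps, design, group_mask, config, out_dir,
                             prefix = sprintf("fc_%s", s$roi_id), reg_file, note)
      for (r in fi$specific_rois) {
        rid <- sprintf("%s__%s", s$roi_id, r$roi_id)
        fc_specific[[rid]] <- r
        fc_roi_features[[rid]] <- vapply(kept, function(sid)
          extract_roi_mean(fc_maps[[sid]], r$voxels), numeric(1))
      }
    }
    note("fc: %d PSD-specific FC region(s) across %d seed(s)",
         length(fc_specific), length(seeds))

    # --- behavior ---------------------------------------------------------
    stage <- "behavior"
    psd_ids <- records$subject_id[records$group == "PSD"]
    psd_sel <- match(psd_ids, kept)
    scales <- c("PHQ9", "HAMD", "CESD")
    corr_rows <- list()
    add_corr <- function(metric, roi, scale, sres) {
      corr_rows[[length(corr_rows) + 1L]] <<- data.frame(
        metric = metric, roi = roi, scale = scale, n = sres$n,
        rho = sres$rho, p = sres$p, significant = sres$significant,
        stringsAsFactors = FALSE)
    }
    for (s in seeds) {
      vals <- vapply(psd_ids, function(sid)
        extract_roi_mean(dc_maps[[sid]], s$voxels), numeric(1))
      for (sc in scales) {
        y <- records[[sc]][match(psd_ids, records$subject_id)]
        add_corr("dc", s$roi_id, sc,
                 spearman_bonferroni(vals, y, config$behavior$n_tests,
                                     inf$alpha))
      }
    }
    for (rid in names(fc_specific)) {
      vals <- fc_roi_features[[rid]][psd_sel]
      for (sc in scales) {
        y <- records[[sc]][match(psd_ids, records$subject_id)]
        add_corr("fc", rid, sc,
                 spearman_bonferroni(vals, y, config$behavior$n_tests,
                                     inf$alpha))
      }
    }
    corr_table <- if (length(corr_rows)) do.call(rbind, corr_rows) else
      data.frame(metric = character(), roi = character(), scale = character(),
                 n = integer(), rho = numeric(), p = numeric(),
                 significant = logical())
    utils::write.table(corr_table, file.path(out_dir, "behavior_spearman.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE, na = "n/a")
    reg_file("behavior_spearman.tsv")

    predictions <- list()
    if (length(fc_specific) >= 1L && length(psd_ids) >= 5L) {
      feat <- do.call(cbind, lapply(fc_roi_features, function(v) v[psd_sel]))
      colnames(feat) <- names(fc_specific)
      feat_tab <- data.frame(subject_id = psd_ids, feat, check.names = FALSE)
      utils::write.table(feat_tab, file.path(out_dir, "fc_features.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      reg_file("fc_features.tsv")
      for (sc in scales) {
        y <- records[[sc]][match(psd_ids, records$subject_id)]
        pr <- ridge_loocv_predict(feat, y, config$behavior$lambda_grid,
                                  n_tests = config$behavior$n_tests,
                                  alpha = inf$alpha)
        predictions[[sc]] <- pr
        jsonlite::write_json(
          list(scale = sc, chosen_lambda = pr$chosen_lambda, rho = pr$rho,
               p = pr$p, significant = pr$significant,
               n_features = pr$n_features,
               subject_id = psd_ids, predicted = pr$predictions,
               observed = y),
          file.path(out_dir, sprintf("prediction_%s.json", sc)),
          auto_unbox = TRUE, digits = NA, pretty = TRUE)
        reg_file(sprintf("prediction_%s.json", sc))
        note("behavior: %s prediction rho=%.3f p=%.4g (lambda=%g)", sc,
             pr$rho, pr$p, pr$chosen_lambda)
      }
    } else {
      note("behavior: prediction skipped (%d FC region(s), %d PSD subject(s))",
           length(fc_specific), length(psd_ids))
    }

    # --- demographics -----------------------------------------------------
    stage <- "demographics"
    demo <- demographic_tests(records)
    utils::write.table(demo, file.path(out_dir, "demographics.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "n/a")
    reg_file("demographics.tsv")

    list(qc = qc_table, records = records, group_mask = group_mask,
         dc = dc_inf, seeds = seeds, fc_specific = fc_specific,
         behavior_correlations = corr_table, predictions = predictions,
         demographics = demo)
  }, error = function(e) {
    stop_psd("pipeline failed at stage '%s': %s", stage, conditionMessage(e))
  })

  # --- provenance + manifest ---------------------------------------------
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  reg_file("run_log.txt")
  cfg_plain <- unclass(config)
  tmp <- file.path(out_dir, "config_echo.json")
  jsonlite::write_json(cfg_plain, tmp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  reg_file("config_echo.json")
  manifest <- list(tool = "psdconn", schema_version = config$schema_version,
                   rng_seed = config$rng_seed,
                   config_hash = unname(tools::md5sum(tmp)),
                   files = sort(unique(c(files, "manifest.json"))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}

# Shared inference path for a per-subject map stack: three-group ANOVA with
# FDR + extent control, PSD-vs-Stroke post-hoc map (within the ANOVA mask
# when configured), candidate clusters, and the specificity conjunction.
metric_inference <- function(map_stack, design, group_mask, config, out_dir,
                             prefix, reg_file, note) {
  inf <- config$inference
  fit <- fit_voxelwise_glm(map_stack, design, contrast = "three_group_F")
  write_scalar_map(fit$stat, file.path(out_dir, sprintf("%s_F.nii.gz", prefix)))
  reg_file(sprintf("%s_F.nii.gz", prefix))
  anova_sig <- fdr_bh(fit$p, inf$q)
  anova_clusters <- extract_clusters(anova_sig, fit$stat, inf$min_extent,
                                     inf$connectivity)
  write_cluster_table(anova_clusters,
                      file.path(out_dir, sprintf("%s_anova_clusters.tsv", prefix)))
  reg_file(sprintf("%s_anova_clusters.tsv", prefix))
  note("%s: ANOVA F df=(%d,%d), FDR q<%g, k>%d -> %d cluster(s)", prefix,
       fit$df[1], fit$df[2], inf$q, inf$min_extent, nrow(anova_clusters))

  posthoc_mask <- if (isTRUE(inf$posthoc_in_anova_mask)) {
    keep_mask <- array(FALSE, dim(group_mask))
    for (vox in anova_clusters$voxels) keep_mask[vox] <- TRUE
    keep_mask & group_mask
  } else group_mask
  specific <- list()
  spec_table <- NULL
  cand <- extract_clusters(array(FALSE, dim(group_mask)), fit$stat, 0L)
  if (any(posthoc_mask)) {
    sub_stack <- lapply(map_stack, function(m)
      scalar_map(m$data, posthoc_mask, kind = m$kind, voxel_mm = m$voxel_mm))
    tfit <- fit_voxelwise_glm(sub_stack, design, contrast = "pair_t",
                              pair = c("PSD", "Stroke"))
    write_scalar_map(tfit$stat,
                     file.path(out_dir, sprintf("%s_psd_stroke_t.nii.gz", prefix)))
    reg_file(sprintf("%s_psd_stroke_t.nii.gz", prefix))
    sig <- if (inf$pairwise_threshold == "fdr") fdr_bh(tfit$p, inf$q)
           else { s <- array(FALSE, dim(group_mask))
                  s[posthoc_mask] <- map_values(tfit$p) < inf$pairwise_p; s }
    note("%s: PSD vs Stroke t (NIHSS covaried), threshold=%s (p<%g)", prefix,
         inf$pairwise_threshold,
         if (inf$pairwise_threshold == "fdr") inf$q else inf$pairwise_p)
    cand <- extract_clusters(sig, tfit$stat, inf$min_extent, inf$connectivity)
    write_cluster_table(cand,
                        file.path(out_dir, sprintf("%s_psd_stroke_clusters.tsv", prefix)))
    reg_file(sprintf("%s_psd_stroke_clusters.tsv", prefix))
    if (nrow(cand) > 0L) {
      roi_means <- vapply(seq_len(nrow(cand)), function(i)
        vapply(map_stack, function(m) mean(m$data[cand$voxels[[i]]]), numeric(1)),
        numeric(length(map_stack)))
      colnames(roi_means) <- sprintf("%s_c%d", prefix, cand$cluster_id)
      spec_table <- detect_specific_rois(roi_means, design$group,
                                         alpha = inf$alpha,
                                         n_comparisons = inf$n_comparisons)
      utils::write.table(spec_table,
                         file.path(out_dir, sprintf("%s_specificity.tsv", prefix)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      reg_file(sprintf("%s_specificity.tsv", prefix))
      for (i in which(spec_table$verdict != "not_specific")) {
        specific[[spec_table$roi[i]]] <- list(
          roi_id = spec_table$roi[i], voxels = cand$voxels[[i]],
          verdict = spec_table$verdict[i])
      }
    }
  }
  list(anova = fit, anova_clusters = anova_clusters,
       candidate_clusters = cand, specificity = spec_table,
       specific_rois = specific)
}

write_cluster_table <- function(tab, path) {
  cols <- setdiff(names(tab), "voxels")
  utils::write.table(as.data.frame(tab)[, cols, drop = FALSE], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
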