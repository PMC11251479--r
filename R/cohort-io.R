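#' Write a synthetic cohort to disk
#'
#' Writes one 4D BOLD NIfTI per subject, one 3D lesion-mask NIfTI per
#' patient, one motion-parameter TSV per subject, a cohort metadata TSV
#' (`participants.tsv`), and a JSON manifest listing every file written.
#' Volumes are written in native orientation (axis 1 = left-right).
#'
#' @param cohort result of [generate_cohort()] (or a compatible list with
#'   `bold`, `records`, `motion`).
#' @param out_dir output directory (created if absent).
#' @return Invisibly, the manifest as a list (also written to
#'   `manifest.json`); `$files` is a data.frame with columns `path`, `type`,
#'   `subject_id`.
#' @export
write_cohort <- function(cohort, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop_psd("cannot create output directory '%s'", out_dir)
  bold <- cohort$bold
  records <- cohort$records
  d0 <- dim(bold[[1]]$data)
  files <- list()
  add <- function(path, type, sid) {
    files[[length(files) + 1L]] <<- data.frame(
      path = path, type = type, subject_id = sid, stringsAsFactors = FALSE)
  }
  for (i in seq_along(bold)) {
    bs <- bold[[i]]
    if (!identical(dim(bs$data)[1:3], d0[1:3]))
      stop_psd("inconsistent grid across subjects")
    sid <- bs$subject_id
    bpath <- sprintf("%s_bold.nii.gz", sid)
    write_nifti_vol(bs$data, file.path(out_dir, bpath), bs$voxel_mm, bs$tr_seconds)
    add(bpath, "bold", sid)
    les <- attr(bs, "native_lesion")
    if (!is.null(les) && any(les)) {
      lpath <- sprintf("%s_lesion.nii.gz", sid)
      write_nifti_vol(les * 1L, file.path(out_dir, lpath), bs$voxel_mm)
      add(lpath, "lesion", sid)
    }
    mpath <- sprintf("%s_motion.tsv", sid)
    utils::write.table(format(cohort$motion[[i]], digits = 10, trim = TRUE),
                       file.path(out_dir, mpath), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    add(mpath, "motion", sid)
  }
  utils::write.table(records, file.path(out_dir, "participants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "n/a")
  add("participants.tsv", "metadata", NA_character_)
  manifest <- list(
    format = "psdconn-cohort/1",
    grid_shape = d0[1:3], n_timepoints = d0[4],
    tr_seconds = bold[[1]]$tr_seconds, voxel_mm = bold[[1]]$voxel_mm,
    n_subjects = length(bold),
    files = do.call(rbind, files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing `manifest.json`.
#' @return List with `bold` (list of [bold_series()]), `records`
#'   (data.frame), `motion` (list of T x 6 matrices), `lesions` (named list
#'   of logical arrays, native orientation), and the `manifest`.
#' @export
read_cohort <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) stop_psd("no manifest.json in '%s'", dir)
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  files <- manifest$files
  records <- utils::read.table(file.path(dir, "participants.tsv"),
                               sep = "\t", header = TRUE, na.strings = "n/a",
                               stringsAsFactors = FALSE)
  bold <- list(); motion <- list(); lesions <- list()
  for (i in which(files$type == "bold")) {
    sid <- files$subject_id[i]
    arr <- array(as.numeric(RNifti::readNifti(file.path(dir, files$path[i]))),
                 dim = c(manifest$grid_shape, manifest$n_timepoints))
    rr <- records[records$subject_id == sid, ]
    bold[[sid]] <- bold_series(arr, manifest$tr_seconds, subject_id = sid,
                               group = rr$group, lesion_side = rr$lesion_side,
                               voxel_mm = manifest$voxel_mm)
  }
  for (i in which(files$type == "lesion")) {
    arr <- RNifti::readNifti(file.path(dir, files$path[i]))
    lesions[[files$subject_id[i]]] <- array(as.numeric(arr) > 0,
                                            dim = manifest$grid_shape)
  }
  for (i in which(files$type == "motion")) {
    motion[[files$subject_id[i]]] <- as.matrix(utils::read.table(
      file.path(dir, files$path[i]), sep = "\t", header = TRUE))
  }
  list(bold = bold, records = records, motion = motion, lesions = lesions,
       manifest = manifest)
}

# NIfTI writer: axis 1 is left-right with positive direction = subject
# right; TR recorded in the 4th pixdim slot.
write_nifti_vol <- function(arr, path, voxel_mm = c(3, 3, 3), tr = 1) {
  img <- RNifti::asNifti(arr)
  pd <- c(voxel_mm, tr)[seq_len(length(dim(arr)))]
  img <- RNifti::asNifti(img, pixdim = pd)
  RNifti::writeNifti(img, path)
  invisible(path)
}
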