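# On-disk artifacts: dynamic images + frame timing, masks, label volumes,
# TACs, plasma input. Frame timing on disk is in seconds; everything is
# converted to minutes at this boundary.

#' Read a frame timing file
#'
#' Two dialects are supported: a 2-column TSV with header (`start_s`,
#' `end_s`) and the Turku SIF dialect (first line a free-form header, then
#' one row per frame `start end counts1 counts2`, of which only the first
#' two columns are consumed).
#'
#' @param path timing file path.
#' @param format `"auto"`, `"tsv"` or `"sif"`.
#' @return A [frame_schedule()].
#' @export
read_frame_timing <- function(path, format = c("auto", "tsv", "sif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("read_frame_timing: no such file: ", path)
  first <- readLines(path, n = 1L)
  if (format == "auto") {
    format <- if (grepl("start", first, ignore.case = TRUE) &&
                  grepl("\t", first)) "tsv" else "sif"
  }
  if (format == "tsv") {
    d <- read.table(path, header = TRUE, sep = "\t")
    if (ncol(d) < 2L) stop("read_frame_timing: TSV needs >= 2 columns")
    return(frame_schedule(d[[1L]], d[[2L]]))
  }
  lines <- readLines(path)
  if (length(lines) < 2L) stop("read_frame_timing: SIF has no frame rows")
  rows <- lapply(strsplit(trimws(lines[-1L]), "[ \t]+"), function(x) {
    v <- suppressWarnings(as.numeric(x[1:2]))
    if (anyNA(v)) stop("read_frame_timing: unparseable SIF frame row")
    v
  })
  m <- do.call(rbind, rows)
  frame_schedule(m[, 1L], m[, 2L])
}

#' Write frame timing as TSV
#'
#' @param schedule a [frame_schedule()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_frame_timing <- function(schedule, path) {
  stopifnot(inherits(schedule, "frame_schedule"))
  d <- data.frame(start_s = schedule$start_s, end_s = schedule$end_s)
  write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load a dynamic PET image with its frame timing
#'
#' @param path NIfTI path of the 4D image (kBq/ml, decay-corrected).
#' @param timing_path timing TSV/SIF path; row count must equal the frame
#'   count.
#' @return A [dynamic_image()].
#' @export
load_dynamic_image <- function(path, timing_path) {
  nii <- read_nifti(path)
  if (length(dim(nii$data)) == 3L)
    dim(nii$data) <- c(dim(nii$data), 1L)
  sched <- read_frame_timing(timing_path)
  if (dim(nii$data)[4L] != length(sched))
    stop(sprintf(
      "load_dynamic_image: image has %d frames but timing file has %d rows",
      dim(nii$data)[4L], length(sched)))
  dynamic_image(nii$data, nii$affine, sched)
}

#' Write a dynamic PET image and its frame timing
#'
#' @param image a [dynamic_image()].
#' @param path NIfTI output path.
#' @param timing_path timing TSV output path (defaults to `path` with a
#'   `.tsv` extension).
#' @return `path`, invisibly.
#' @export
write_dynamic_image <- function(image, path,
                                timing_path = sub("\\.nii(\\.gz)?$", ".tsv", path)) {
  stopifnot(inherits(image, "dynamic_image"))
  write_nifti(image$voxels, image$affine, path, "float32")
  write_frame_timing(image$schedule, timing_path)
  invisible(path)
}

#' Load a binary mask from NIfTI
#' @param path NIfTI path (uint8 0/1).
#' @return A [voxel_mask()].
#' @export
load_mask <- function(path) {
  nii <- read_nifti(path)
  if (length(dim(nii$data)) != 3L) stop("load_mask: mask must be 3D")
  voxel_mask(nii$data != 0, nii$affine)
}

#' Write a binary mask to NIfTI (uint8 0/1)
#' @param mask a [voxel_mask()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "voxel_mask"))
  write_nifti(array(as.integer(mask$voxels), dim(mask$voxels)),
              mask$affine, path, "uint8")
  invisible(path)
}

#' Load an integer label volume from NIfTI
#' @param path NIfTI path.
#' @return A [label_volume()].
#' @export
load_labels <- function(path) {
  nii <- read_nifti(path)
  if (length(dim(nii$data)) != 3L) stop("load_labels: labels must be 3D")
  label_volume(nii$data, nii$affine)
}

#' Write an integer label volume to NIfTI (int32)
#' @param labels a [label_volume()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  stopifnot(inherits(labels, "label_volume"))
  write_nifti(labels$voxels, labels$affine, path, "int32")
  invisible(path)
}

#' Write a TAC as TSV
#'
#' Columns `t_mid_min`, `frame_dur_min`, `value`; the unit is recorded in a
#' leading comment line `# unit: <unit>`.
#'
#' @param tac a [tac()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tac <- function(tac, path) {
  stopifnot(inherits(tac, "tac"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# unit: %s", tac$unit), con)
  writeLines("t_mid_min\tframe_dur_min\tvalue", con)
  writeLines(sprintf("%.10g\t%.10g\t%.10g", tac$t_mid, tac$frame_dur, tac$value),
             con)
  invisible(path)
}

#' Read a TAC from TSV written by [write_tac()]
#' @param path TSV path.
#' @return A [tac()].
#' @export
read_tac <- function(path) {
  lines <- readLines(path)
  unit <- "kBq/ml"
  m <- grep("^#\\s*unit:", lines, value = TRUE)
  if (length(m)) unit <- trimws(sub("^#\\s*unit:\\s*", "", m[1L]))
  d <- read.table(text = lines[!grepl("^#", lines)], header = TRUE, sep = "\t")
  tac(d$t_mid_min, d$value, unit, d$frame_dur_min)
}

#' Write a plasma input curve as TSV (`time_min`, `activity_kBq_ml`)
#' @param plasma a [plasma_input()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_plasma <- function(plasma, path) {
  stopifnot(inherits(plasma, "plasma_input"))
  write.table(data.frame(time_min = plasma$t, activity_kBq_ml = plasma$cp),
              path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a plasma input curve from TSV
#' @param path TSV with time (min) and activity columns.
#' @return A [plasma_input()].
#' @export
read_plasma <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t")
  plasma_input(d[[1L]], d[[2L]])
}
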