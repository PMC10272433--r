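#' ROI time-series set
#'
#' Container for the T x 116 matrix of mean ROI signals extracted from a
#' parcellated 4D acquisition.
#'
#' @param data Numeric T x R matrix, one column per region in atlas order.
#' @param tr_seconds Repetition time in seconds.
#' @param region_names Character vector of region names (defaults to the
#'   AAL-116 names).
#' @return A `bg_roi_ts` object.
#' @export
roi_timeseries <- function(data, tr_seconds,
                           region_names = aal116_labels()$name) {
  data <- as.matrix(data)
  assert_that(is.numeric(data) && nrow(data) >= 2L,
              "data must be a numeric matrix with T >= 2")
  assert_that(ncol(data) == length(region_names),
              "data has %d columns but %d region names", ncol(data),
              length(region_names))
  assert_that(!anyNA(data), "ROI time series must not contain missing values")
  assert_that(is.numeric(tr_seconds) && tr_seconds > 0,
              "tr_seconds must be positive")
  colnames(data) <- region_names
  structure(list(data = data, tr_seconds = tr_seconds,
                 region_names = region_names),
            class = "bg_roi_ts")
}

#' @export
print.bg_roi_ts <- function(x, ...) {
  cat(sprintf("ROI time-series set: %d volumes x %d regions, TR = %g s\n",
              nrow(x$data), ncol(x$data), x$tr_seconds))
  invisible(x)
}

#' Confound set
#'
#' White-matter and CSF mean signals plus the six rigid-body motion
#' parameters, all of length T.
#'
#' @param wm,csf Numeric length-T vectors.
#' @param motion Numeric T x 6 matrix (3 translations mm, 3 rotations rad).
#' @return A `bg_confounds` object.
#' @export
confound_set <- function(wm, csf, motion) {
  motion <- as.matrix(motion)
  T <- length(wm)
  assert_that(length(csf) == T && nrow(motion) == T,
              "wm, csf and motion must all have the same length")
  assert_that(ncol(motion) == 6L, "motion must have 6 columns")
  assert_that(!anyNA(wm) && !anyNA(csf) && !anyNA(motion),
              "confounds must not contain missing values")
  colnames(motion) <- paste0("motion", 1:6)
  structure(list(wm = as.numeric(wm), csf = as.numeric(csf), motion = motion),
            class = "bg_confounds")
}

as_confound_matrix <- function(confounds) {
  cbind(wm = confounds$wm, csf = confounds$csf, confounds$motion)
}

#' Extract mean ROI time series from a 4D image
#'
#' Column j at time t is the arithmetic mean over all voxels carrying label j
#' at volume t. The image grid must equal the label grid exactly; volumes are
#' assumed to be in atlas space already (no resampling is performed).
#'
#' @param image4d 4D numeric array (or RNifti image), dimensions X,Y,Z,T.
#' @param parcellation A `bg_parcellation` from [parcellation()].
#' @param tr_seconds Repetition time in seconds.
#' @return A `bg_roi_ts`.
#' @export
extract_roi_timeseries <- function(image4d, parcellation, tr_seconds) {
  assert_that(inherits(parcellation, "bg_parcellation"),
              "parcellation must be built with parcellation()")
  dims <- dim(image4d)
  assert_that(length(dims) == 4L, "image4d must be 4-dimensional")
  ldim <- dim(parcellation$label_image)
  if (!identical(as.integer(dims[1:3]), as.integer(ldim))) {
    stopf("image grid (%s) does not match label grid (%s)",
          paste(dims[1:3], collapse = "x"), paste(ldim, collapse = "x"))
  }
  nvox <- prod(dims[1:3])
  mat <- matrix(as.numeric(image4d), nvox, dims[4])
  labels <- as.integer(parcellation$label_image)
  tab <- parcellation$label_table
  out <- matrix(NA_real_, dims[4], nrow(tab))
  for (j in seq_len(nrow(tab))) {
    sel <- which(labels == tab$label[j])
    if (length(sel) == 0L) stopf("ROI '%s' (label %d) is empty", tab$name[j],
                                 tab$label[j])
    out[, j] <- if (length(sel) == 1L) mat[sel, ] else colMeans(mat[sel, , drop = FALSE])
  }
  roi_timeseries(out, tr_seconds, region_names = tab$name)
}

#' Extract nuisance confound series from a 4D image
#'
#' White matter and CSF series are the mask-mean signal per volume; the
#' motion table is passed through unmodified.
#'
#' @param image4d 4D numeric array.
#' @param wm_mask,csf_mask Binary 3D arrays on the same grid.
#' @param motion_table T x 6 numeric matrix of motion parameters.
#' @return A `bg_confounds`.
#' @export
extract_confounds <- function(image4d, wm_mask, csf_mask, motion_table) {
  dims <- dim(image4d)
  assert_that(length(dims) == 4L, "image4d must be 4-dimensional")
  mask_mean <- function(mask, what) {
    assert_that(identical(as.integer(dim(mask)), as.integer(dims[1:3])),
                "%s mask grid does not match the image grid", what)
    mv <- as.numeric(mask)
    assert_that(all(mv %in% c(0, 1)), "%s mask must be binary", what)
    sel <- which(mv == 1)
    if (length(sel) == 0L) stopf("%s mask is empty", what)
    mat <- matrix(as.numeric(image4d), prod(dims[1:3]), dims[4])
    if (length(sel) == 1L) mat[sel, ] else colMeans(mat[sel, , drop = FALSE])
  }
  motion_table <- as.matrix(motion_table)
  assert_that(nrow(motion_table) == dims[4],
              "motion table has %d rows but image has %d volumes",
              nrow(motion_table), dims[4])
  confound_set(mask_mean(wm_mask, "white-matter"),
               mask_mean(csf_mask, "CSF"), motion_table)
}

#' Read SPM-style motion parameters
#'
#' Whitespace-delimited 6-column text (rp_*.txt dialect: three translations
#' in mm, three rotations in rad).
#'
#' @param path File path.
#' @return T x 6 numeric matrix.
#' @export
read_motion_params <- function(path) {
  mat <- as.matrix(utils::read.table(path, header = FALSE))
  assert_that(ncol(mat) == 6L, "motion parameter file must have 6 columns")
  unname(mat)
}

#' Read / write ROI time series as TSV
#'
#' T rows x 116 columns with a header of AAL region names.
#' @param path File path.
#' @param tr_seconds Repetition time used when reading.
#' @return [read_roi_tsv()] returns a `bg_roi_ts`.
#' @export
read_roi_tsv <- function(path, tr_seconds) {
  dat <- utils::read.delim(path, check.names = FALSE)
  roi_timeseries(as.matrix(dat), tr_seconds, region_names = colnames(dat))
}

#' @rdname read_roi_tsv
#' @param ts A `bg_roi_ts` to write.
#' @export
write_roi_tsv <- function(ts, path) {
  utils::write.table(ts$data, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write confounds as TSV (columns wm, csf, motion1..motion6)
#' @param path File path.
#' @return [read_confounds_tsv()] returns a `bg_confounds`.
#' @export
read_confounds_tsv <- function(path) {
  dat <- utils::read.delim(path)
  confound_set(dat$wm, dat$csf, as.matrix(dat[paste0("motion", 1:6)]))
}

#' @rdname read_confounds_tsv
#' @param confounds A `bg_confounds` to write.
#' @export
write_confounds_tsv <- function(confounds, path) {
  utils::write.table(as.data.frame(as_confound_matrix(confounds)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
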