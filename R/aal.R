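#' AAL-116 label table
#'
#' The 116-region automated anatomical labelling (AAL) parcellation used for
#' all connectivity analyses, shipped as a packaged text resource. Label
#' values index the label image; the row order fixes the column order of
#' every ROI time-series matrix and connectivity matrix in the package.
#'
#' @return A data.frame with columns `label` (integer label value) and
#'   `name` (region name), 116 rows in atlas order.
#' @export
#' @examples
#' head(aal116_labels())
aal116_labels <- function() {
  path <- system.file("extdata", "aal116_labels.tsv", package = "bgfc",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(nrow(tab) == 116L)
  tab
}

#' Basal ganglia region names
#'
#' The six bilateral basal-ganglia regions of the AAL atlas that define the
#' local and global connectivity statistics.
#'
#' @return Character vector of six region names.
#' @export
bg_region_names <- function() {
  c("Caudate_L", "Caudate_R", "Putamen_L", "Putamen_R",
    "Pallidum_L", "Pallidum_R")
}

#' Named basal ganglia structure pairs
#'
#' Each pair names two bilateral structures; its local connectivity is the
#' mean over the four cross-structure edges (L-L, L-R, R-L, R-R).
#'
#' @return Named list mapping pair name to a list with elements `a` and `b`,
#'   the two region-name pairs.
#' @export
bg_pairs <- function() {
  list(
    "Caudate-Putamen"  = list(a = c("Caudate_L", "Caudate_R"),
                              b = c("Putamen_L", "Putamen_R")),
    "Caudate-Pallidum" = list(a = c("Caudate_L", "Caudate_R"),
                              b = c("Pallidum_L", "Pallidum_R")),
    "Putamen-Pallidum" = list(a = c("Putamen_L", "Putamen_R"),
                              b = c("Pallidum_L", "Pallidum_R"))
  )
}

#' Basal ganglia seed definitions for global connectivity
#'
#' @return Named list mapping seed name (`Caudate`, `Putamen`, `Pallidum`,
#'   `BG-average`) to the region names it combines.
#' @export
bg_seeds <- function() {
  list(
    "Caudate"    = c("Caudate_L", "Caudate_R"),
    "Putamen"    = c("Putamen_L", "Putamen_R"),
    "Pallidum"   = c("Pallidum_L", "Pallidum_R"),
    "BG-average" = bg_region_names()
  )
}

#' Parcellation object
#'
#' Bundle a 3D integer label image with the AAL label table. The label image
#' must contain at least one voxel for every listed label; labels are matched
#' by value, not position, so sparse label numbering is supported.
#'
#' @param label_image 3D integer array of label values (0 = background).
#' @param label_table data.frame with columns `label`, `name`; defaults to
#'   [aal116_labels()].
#' @return An object of class `bg_parcellation`.
#' @export
parcellation <- function(label_image, label_table = aal116_labels()) {
  assert_that(length(dim(label_image)) == 3L,
              "label_image must be a 3D array")
  assert_that(all(c("label", "name") %in% names(label_table)),
              "label_table needs columns 'label' and 'name'")
  assert_that(!anyDuplicated(label_table$label) && !anyDuplicated(label_table$name),
              "label_table labels and names must be unique")
  assert_that(all(bg_region_names() %in% label_table$name),
              "label_table must contain the six basal ganglia regions")
  present <- unique(as.integer(label_image))
  missing <- setdiff(label_table$label, present)
  if (length(missing) > 0) {
    stopf("label image is missing labels: %s (regions %s)",
          paste(missing, collapse = ", "),
          paste(label_table$name[match(missing, label_table$label)],
                collapse = ", "))
  }
  extra <- setdiff(setdiff(present, 0L), label_table$label)
  if (length(extra) > 0) {
    stopf("label image contains labels not in the table: %s",
          paste(extra, collapse = ", "))
  }
  structure(list(label_image = label_image, label_table = label_table),
            class = "bg_parcellation")
}
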