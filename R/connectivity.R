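#' Functional connectivity matrix
#'
#' Symmetric region-by-region weighted connectivity matrix, on the Pearson r
#' or Fisher z scale. The diagonal carries no information (1 for r, 0 for z)
#' and is excluded from all statistics.
#'
#' @param values Symmetric numeric matrix.
#' @param scale `"pearson_r"` or `"fisher_z"`.
#' @param region_names Region names in atlas order.
#' @param task Optional task id the matrix belongs to.
#' @param block Optional block number for single-block matrices.
#' @return A `bg_fc_matrix`.
#' @export
fc_matrix <- function(values, scale = c("pearson_r", "fisher_z"),
                      region_names = colnames(values), task = NULL,
                      block = NULL) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  assert_that(nrow(values) == ncol(values), "values must be square")
  assert_that(max(abs(values - t(values))) == 0, "values must be symmetric")
  if (scale == "pearson_r") {
    assert_that(min(values) >= -1 && max(values) <= 1,
                "pearson_r entries must lie in [-1, 1]")
  }
  assert_that(!is.null(region_names) && length(region_names) == ncol(values),
              "region_names must label every column")
  dimnames(values) <- list(region_names, region_names)
  structure(list(values = values, scale = scale, region_names = region_names,
                 task = task, block = block),
            class = "bg_fc_matrix")
}

#' @export
print.bg_fc_matrix <- function(x, ...) {
  cat(sprintf("FC matrix: %d x %d, scale = %s%s%s\n", nrow(x$values),
              ncol(x$values), x$scale,
              if (is.null(x$task)) "" else paste0(", task ", x$task),
              if (is.null(x$block)) "" else paste0(", block ", x$block)))
  invisible(x)
}

#' Pearson correlation matrix of a task segment
#'
#' Pairwise Pearson correlation of the region columns over the concatenated
#' segment rows.
#'
#' @param segment A `bg_task_segment` from [segment_by_task()] or
#'   [segment_single_block()].
#' @return A `bg_fc_matrix` on the `pearson_r` scale.
#' @export
correlation_matrix <- function(segment) {
  assert_that(inherits(segment, "bg_task_segment"),
              "segment must be a bg_task_segment")
  X <- segment$data
  v <- apply(X, 2, stats::var)
  if (any(v <= 0)) {
    stopf("zero-variance region(s) in segment: %s",
          paste(segment$region_names[v <= 0], collapse = ", "))
  }
  m <- stats::cor(X)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  m[m > 1] <- 1; m[m < -1] <- -1
  fc_matrix(m, "pearson_r", segment$region_names, task = segment$task,
            block = segment$block %||% NULL)
}

#' Fisher z-transform of a correlation matrix
#'
#' Elementwise `z = atanh(r) = 0.5 * log((1+r)/(1-r))` off the diagonal,
#' with r clipped to +/-(1 - 1e-7) first; the diagonal is set to 0.
#'
#' @param m A `bg_fc_matrix` on the `pearson_r` scale.
#' @return A `bg_fc_matrix` on the `fisher_z` scale.
#' @export
fisher_z <- function(m) {
  assert_that(inherits(m, "bg_fc_matrix"), "m must be a bg_fc_matrix")
  assert_that(m$scale == "pearson_r",
              "fisher_z expects a pearson_r matrix, got %s", m$scale)
  r <- pmin(pmax(m$values, -(1 - 1e-7)), 1 - 1e-7)
  z <- atanh(r)
  diag(z) <- 0
  fc_matrix(z, "fisher_z", m$region_names, task = m$task, block = m$block)
}

bg_edge_indices <- function(region_names, pair) {
  p <- bg_pairs()[[pair]]
  if (is.null(p)) stopf("unknown basal ganglia pair '%s'", pair)
  ia <- match(p$a, region_names)
  ib <- match(p$b, region_names)
  assert_that(!anyNA(ia) && !anyNA(ib),
              "matrix is missing basal ganglia regions for pair %s", pair)
  cbind(rep(ia, each = length(ib)), rep(ib, times = length(ia)))
}

#' Local basal ganglia connectivity
#'
#' Mean Fisher-z connectivity over the four cross-structure edges (L-L, L-R,
#' R-L, R-R) of a named basal-ganglia structure pair. Within-structure
#' (homotopic) edges belong to no named pair and are excluded.
#'
#' @param m A `bg_fc_matrix` on the `fisher_z` scale.
#' @param pair One of `"Caudate-Putamen"`, `"Caudate-Pallidum"`,
#'   `"Putamen-Pallidum"`.
#' @return Scalar mean z.
#' @export
local_bg_fc <- function(m, pair) {
  assert_that(inherits(m, "bg_fc_matrix") && m$scale == "fisher_z",
              "local_bg_fc expects a fisher_z bg_fc_matrix")
  idx <- bg_edge_indices(m$region_names, pair)
  mean(m$values[idx])
}

#' Global basal ganglia connectivity
#'
#' Mean Fisher-z connectivity between a basal-ganglia seed (a bilateral
#' structure, or all six regions for `"BG-average"`) and the 110 non-basal-
#' ganglia regions of the atlas.
#'
#' @param m A `bg_fc_matrix` on the `fisher_z` scale.
#' @param seed One of `"Caudate"`, `"Putamen"`, `"Pallidum"`, `"BG-average"`.
#' @return Scalar mean z.
#' @export
global_bg_fc <- function(m, seed) {
  assert_that(inherits(m, "bg_fc_matrix") && m$scale == "fisher_z",
              "global_bg_fc expects a fisher_z bg_fc_matrix")
  s <- bg_seeds()[[seed]]
  if (is.null(s)) stopf("unknown basal ganglia seed '%s'", seed)
  is_ <- match(s, m$region_names)
  assert_that(!anyNA(is_), "matrix is missing seed regions for %s", seed)
  it <- which(!(m$region_names %in% bg_region_names()))
  idx <- cbind(rep(is_, each = length(it)), rep(it, times = length(is_)))
  mean(m$values[idx])
}

#' Write an FC matrix as TSV with region-name header and row names
#' @param m A `bg_fc_matrix`.
#' @param path File path.
#' @export
write_fc_matrix <- function(m, path) {
  df <- data.frame(region = m$region_names, m$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
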