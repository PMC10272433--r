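TASKS <- c("T1", "T2", "T3")

#' Paradigm schedule
#'
#' Ordered block schedule of the interleaved alertness-motor paradigm:
#' three tasks (T1 sensorimotor, T2 intrinsic alertness, T3 extrinsic
#' alertness), each repeated in four blocks, in a pseudorandomised but fixed
#' order.
#'
#' @param entries data.frame with columns `task` ("T1"/"T2"/"T3"), `block`
#'   (1..4, numbered by occurrence within task), `onset_s`, `duration_s`.
#' @param condition Condition arm of the subject the schedule applies to,
#'   `"handgrip_only"` or `"mental_imagery_first"`.
#' @return A `bg_schedule` object (data.frame with a `condition` attribute).
#' @export
paradigm_schedule <- function(entries, condition = "handgrip_only") {
  need <- c("task", "block", "onset_s", "duration_s")
  assert_that(all(need %in% names(entries)), "schedule needs columns %s",
              paste(need, collapse = ", "))
  assert_that(all(entries$task %in% TASKS), "tasks must be in {T1, T2, T3}")
  condition <- match.arg(condition, c("handgrip_only", "mental_imagery_first"))
  entries <- entries[order(entries$onset_s), , drop = FALSE]
  for (tk in unique(entries$task)) {
    blk <- sort(entries$block[entries$task == tk])
    assert_that(identical(as.integer(blk), 1:4),
                "task %s must have exactly blocks 1..4", tk)
  }
  ends <- entries$onset_s + entries$duration_s
  assert_that(all(entries$onset_s[-1] >= ends[-nrow(entries)] - 1e-9),
              "schedule blocks must not overlap")
  assert_that(all(entries$duration_s > 0), "durations must be positive")
  rownames(entries) <- NULL
  structure(entries, condition = condition, class = c("bg_schedule", "data.frame"))
}

#' Default paradigm schedule
#'
#' Twelve contiguous blocks (3 tasks x 4 repetitions) in a fixed
#' pseudorandomised order. With the default 80 volumes per block at
#' TR = 0.906 s the scan lasts 960 volumes (~14.5 min), consistent with an
#' approximately 15-minute acquisition.
#'
#' @param block_volumes Volumes per block (default 80).
#' @param tr_seconds Repetition time in seconds (default 0.906).
#' @param rest_volumes Volumes of rest inserted between blocks (default 0).
#' @param condition Condition arm label, see [paradigm_schedule()].
#' @return A `bg_schedule` object.
#' @export
default_schedule <- function(block_volumes = 80L, tr_seconds = 0.906,
                             rest_volumes = 0L,
                             condition = "handgrip_only") {
  order <- c("T1", "T2", "T3", "T2", "T3", "T1",
             "T3", "T1", "T2", "T1", "T2", "T3")
  dur <- block_volumes * tr_seconds
  step <- (block_volumes + rest_volumes) * tr_seconds
  entries <- data.frame(
    task = order,
    block = as.integer(stats::ave(seq_along(order), order, FUN = seq_along)),
    onset_s = (seq_along(order) - 1) * step,
    duration_s = dur
  )
  paradigm_schedule(entries, condition = condition)
}

#' Total scan length of a schedule, in volumes
#' @param schedule A `bg_schedule`.
#' @param tr_seconds Repetition time in seconds.
#' @return Integer number of volumes spanned by the schedule.
#' @export
schedule_volumes <- function(schedule, tr_seconds) {
  last <- nrow(schedule)
  as.integer(ceiling((schedule$onset_s[last] + schedule$duration_s[last]) /
                       tr_seconds - 1e-9))
}

#' Volume index range of one task block
#'
#' A volume belongs to a block iff its acquisition start falls inside the
#' block window shifted by `hrf_lag_seconds`: with 0-based volume indices the
#' half-open range is `[floor((onset+lag)/TR), floor((onset+lag+duration)/TR))`.
#' Returned as 1-based row indices into the time-series matrix.
#'
#' @param schedule A `bg_schedule`.
#' @param task Task id, one of "T1", "T2", "T3".
#' @param block Block number 1..4.
#' @param tr_seconds Repetition time in seconds.
#' @param hrf_lag_seconds Haemodynamic lag shift applied to the window
#'   (default 0; none is imposed by default).
#' @return Integer vector of 1-based volume indices.
#' @export
#' @examples
#' sch <- default_schedule()
#' head(volumes_for_block(sch, "T2", 1, 0.906))
volumes_for_block <- function(schedule, task, block, tr_seconds,
                              hrf_lag_seconds = 0) {
  row <- which(schedule$task == task & schedule$block == block)
  if (length(row) != 1L) {
    stopf("schedule has no block %s of task %s", as.character(block), task)
  }
  on <- schedule$onset_s[row] + hrf_lag_seconds
  first0 <- floor(on / tr_seconds + 1e-9)
  last0 <- floor((on + schedule$duration_s[row]) / tr_seconds + 1e-9)
  if (last0 <= first0) {
    stopf("block %d of task %s resolves to an empty volume range", block, task)
  }
  as.integer((first0 + 1):last0)
}

#' Concatenated task segment
#'
#' Extract the rows of all four blocks of one task from a cleaned ROI
#' time-series set and concatenate them in schedule order, recording the
#' block boundaries.
#'
#' @param ts A `bg_roi_ts` (see [roi_timeseries()]).
#' @param schedule A `bg_schedule`.
#' @param task Task id.
#' @param hrf_lag_seconds Window shift in seconds (default 0).
#' @return A `bg_task_segment`: list with `task`, `data` (T' x 116 matrix),
#'   `block_boundaries` (row indices where consecutive blocks join) and
#'   `block_rows` (list of source row ranges).
#' @export
segment_by_task <- function(ts, schedule, task, hrf_lag_seconds = 0) {
  assert_that(inherits(ts, "bg_roi_ts"), "ts must be a bg_roi_ts")
  rows <- lapply(1:4, function(b) {
    idx <- volumes_for_block(schedule, task, b, ts$tr_seconds, hrf_lag_seconds)
    if (max(idx) > nrow(ts$data)) {
      stopf("block %d of task %s extends past the end of the series (%d > %d)",
            b, task, max(idx), nrow(ts$data))
    }
    idx
  })
  lens <- vapply(rows, length, 1L)
  structure(list(
    task = task,
    data = ts$data[unlist(rows), , drop = FALSE],
    block_boundaries = cumsum(lens)[-4],
    block_rows = rows,
    tr_seconds = ts$tr_seconds,
    region_names = ts$region_names
  ), class = "bg_task_segment")
}

#' Single-block segment
#'
#' Rows of one block of one task, for block-1 vs block-4 contrasts. Blocks
#' shorter than `min_volumes` are rejected because correlations over very few
#' volumes are unstable.
#'
#' @inheritParams segment_by_task
#' @param block Block number 1..4.
#' @param min_volumes Minimum acceptable block length (default 30).
#' @return A `bg_task_segment` with a single block.
#' @export
segment_single_block <- function(ts, schedule, task, block,
                                 hrf_lag_seconds = 0, min_volumes = 30L) {
  assert_that(inherits(ts, "bg_roi_ts"), "ts must be a bg_roi_ts")
  idx <- volumes_for_block(schedule, task, block, ts$tr_seconds,
                           hrf_lag_seconds)
  if (max(idx) > nrow(ts$data)) {
    stopf("block %d of task %s extends past the end of the series", block, task)
  }
  if (length(idx) < min_volumes) {
    stopf("block %d of task %s has %d volumes; %d required for a stable block-level correlation",
          block, task, length(idx), min_volumes)
  }
  structure(list(
    task = task, block = block,
    data = ts$data[idx, , drop = FALSE],
    block_boundaries = integer(0),
    block_rows = list(idx),
    tr_seconds = ts$tr_seconds,
    region_names = ts$region_names
  ), class = "bg_task_segment")
}

#' Read / write a schedule TSV
#'
#' Columns: task, block, onset_s, duration_s.
#' @param path File path.
#' @param condition Condition label used when reading.
#' @return [read_schedule()] returns a `bg_schedule`.
#' @export
read_schedule <- function(path, condition = "handgrip_only") {
  paradigm_schedule(utils::read.delim(path, stringsAsFactors = FALSE),
                    condition = condition)
}

#' @rdname read_schedule
#' @param schedule A `bg_schedule` to write.
#' @export
write_schedule <- function(schedule, path) {
  utils::write.table(as.data.frame(schedule), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
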