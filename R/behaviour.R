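#' Trial reaction time
#'
#' RT is the difference between the onset of the force grip and the onset of
#' the stimulus (white square). Grips that precede their stimulus are
#' anticipations: they are flagged invalid (NA) and excluded from block
#' means.
#'
#' @param grip_onset_ms,stimulus_onset_ms Numeric vectors of onsets in ms.
#' @return Numeric vector of RTs in ms, NA for invalid trials.
#' @export
#' @examples
#' trial_rt(c(1400, 900), c(1000, 1000))  # 400, NA
trial_rt <- function(grip_onset_ms, stimulus_onset_ms) {
  assert_that(length(grip_onset_ms) == length(stimulus_onset_ms),
              "onset vectors must have equal length")
  rt <- grip_onset_ms - stimulus_onset_ms
  rt[rt < 0] <- NA_real_
  rt
}

#' Block mean reaction time over valid trials
#' @param rt_ms Numeric vector of trial RTs (NA = invalid).
#' @return Mean RT of the valid trials.
#' @export
block_rt <- function(rt_ms) {
  ok <- rt_ms[!is.na(rt_ms)]
  assert_that(length(ok) >= 1L, "no valid trials in block")
  mean(ok)
}

#' Block force summary
#'
#' The force measure of a block is the average of the per-trial peak forces.
#'
#' @param peak_forces Numeric vector of per-trial peak forces.
#' @return Mean peak force.
#' @export
block_force <- function(peak_forces) {
  ok <- peak_forces[!is.na(peak_forces)]
  assert_that(length(ok) >= 1L, "no valid force peaks in block")
  mean(ok)
}

subject_grand_rt <- function(behaviour) {
  b <- behaviour[behaviour$task %in% c("T2", "T3") & !is.na(behaviour$mean_rt_ms), ]
  stats::aggregate(mean_rt_ms ~ subject + group, data = b, FUN = mean)
}

#' Reaction-time outlier filter
#'
#' A subject is removed iff their grand-mean RT (pooled over the T2 and T3
#' blocks) lies strictly outside group mean +/- `k_sd` group SD. Statistics
#' are computed once, per diagnostic group, before any removal (single
#' pass).
#'
#' @param behaviour Cohort behaviour table (long format with columns
#'   `subject`, `group`, `task`, `block`, `mean_rt_ms`, ...).
#' @param k_sd SD multiple defining the outlier band (default 2).
#' @return List with `retained` and `removed` behaviour tables and a
#'   `report` data.frame (subject, group, mean_rt, group_mean, group_sd, z,
#'   removed).
#' @export
filter_rt_outliers <- function(behaviour, k_sd = 2) {
  gm <- subject_grand_rt(behaviour)
  report <- do.call(rbind, lapply(split(gm, gm$group), function(g) {
    assert_that(nrow(g) >= 3L, "need at least 3 subjects per group, got %d",
                nrow(g))
    mu <- mean(g$mean_rt_ms)
    s <- stats::sd(g$mean_rt_ms)
    if (s == 0) {
      warning("zero RT standard deviation in group ", g$group[1],
              "; no removals")
      z <- rep(0, nrow(g))
    } else {
      z <- (g$mean_rt_ms - mu) / s
    }
    data.frame(subject = g$subject, group = g$group, mean_rt = g$mean_rt_ms,
               group_mean = mu, group_sd = s, z = z,
               removed = abs(z) > k_sd)
  }))
  rownames(report) <- NULL
  out <- report$subject[report$removed]
  list(retained = behaviour[!(behaviour$subject %in% out), , drop = FALSE],
       removed = behaviour[behaviour$subject %in% out, , drop = FALSE],
       report = report)
}

#' Inclusion screening
#'
#' MS participants are included iff FSS >= 36; healthy controls are excluded
#' at FSS >= 36. Either group is excluded when a HADS subscale exceeds 12
#' (mental-health comorbidity).
#'
#' @param subjects data.frame with columns `group` ("HC"/"MS"), `fss_total`,
#'   `hads_anxiety`, `hads_depression` (one row per subject).
#' @return The input with added columns `include` (logical) and `reason`.
#' @export
screen_inclusion <- function(subjects) {
  assert_that(all(c("group", "fss_total", "hads_anxiety", "hads_depression")
                  %in% names(subjects)), "missing screening columns")
  assert_that(all(subjects$group %in% c("HC", "MS")),
              "group must be HC or MS")
  reason <- rep("", nrow(subjects))
  inc <- rep(TRUE, nrow(subjects))
  fatigue_fail <- ifelse(subjects$group == "MS", subjects$fss_total < 36,
                         subjects$fss_total >= 36)
  inc[fatigue_fail] <- FALSE
  reason[fatigue_fail] <- ifelse(subjects$group[fatigue_fail] == "MS",
                                 "FSS below fatigue cut-off (36)",
                                 "HC at or above FSS cut-off (36)")
  mh <- subjects$hads_anxiety > 12 | subjects$hads_depression > 12
  inc[mh] <- FALSE
  reason[mh] <- "mental-health comorbidity (HADS subscale > 12)"
  subjects$include <- inc
  subjects$reason <- reason
  subjects
}

#' Operational fatigue measures
#'
#' Cognitive fatigue is the increase in mean RT from block 1 to block 4 of
#' an alertness task (`rt_block4 - rt_block1`); physical fatigue is the
#' decrease in high-level average peak force (`force_block1 - force_block4`).
#' Defined for the alertness tasks T2 and T3 only.
#'
#' @param behaviour Behaviour table for one or more subjects (long format).
#' @return data.frame with columns `subject`, `group`, `task`,
#'   `cognitive_fatigue_ms`, `physical_fatigue`.
#' @export
#' @examples
#' b <- data.frame(subject = "s1", group = "MS", task = "T2",
#'                 block = c(1, 4), mean_rt_ms = c(600, 650),
#'                 mean_peak_force = c(11.90, 11.01))
#' fatigue_measures(b)
fatigue_measures <- function(behaviour) {
  b <- behaviour[behaviour$task %in% c("T2", "T3"), , drop = FALSE]
  out <- do.call(rbind, lapply(split(b, list(b$subject, b$task), drop = TRUE),
    function(d) {
      b1 <- d[d$block == 1, ]; b4 <- d[d$block == 4, ]
      assert_that(nrow(b1) == 1L && nrow(b4) == 1L,
                  "subject %s task %s must have blocks 1 and 4",
                  d$subject[1], d$task[1])
      data.frame(subject = d$subject[1], group = d$group[1], task = d$task[1],
                 cognitive_fatigue_ms = b4$mean_rt_ms - b1$mean_rt_ms,
                 physical_fatigue = b1$mean_peak_force - b4$mean_peak_force)
    }))
  rownames(out) <- NULL
  out[order(out$subject, out$task), ]
}
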