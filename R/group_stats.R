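#' Two-sample t-test from group summaries
#'
#' Pooled-variance (Student) t by default, with Cohen's d based on the
#' pooled SD; Welch's unequal-variance form by flag. Operates on group
#' summaries (n, mean, SD) so printed report tables can be re-derived
#' exactly.
#'
#' @param n1,m1,s1 Size, mean and SD of group 1.
#' @param n2,m2,s2 Size, mean and SD of group 2.
#' @param welch Use Welch's t with Satterthwaite df (default FALSE).
#' @return List with `t`, `df`, `p` (two-sided), `d` (signed Cohen's d).
#' @export
#' @examples
#' two_sample_t(36, 1.18, 0.21, 37, 1.05, 0.23)
two_sample_t <- function(n1, m1, s1, n2, m2, s2, welch = FALSE) {
  assert_that(n1 >= 2 && n2 >= 2, "need n >= 2 in both groups")
  assert_that(s1 >= 0 && s2 >= 0, "SDs must be non-negative")
  if (welch) {
    v1 <- s1^2 / n1; v2 <- s2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  } else {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  }
  if (se == 0) {
    if (m1 == m2) {
      return(list(t = 0, df = df, p = 1, d = 0))
    }
    stopf("zero pooled variance with unequal means: t overflows")
  }
  tval <- (m1 - m2) / se
  sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
  d <- if (sp == 0) 0 else (m1 - m2) / sp
  list(t = tval, df = df, p = 2 * stats::pt(-abs(tval), df), d = d)
}

#' Paired t-test
#'
#' One-sample t on the paired differences, df = n - 1, two-sided p.
#'
#' @param x,y Paired numeric vectors of equal length >= 2.
#' @return List with `t`, `df`, `p`, `mean_diff`.
#' @export
paired_t <- function(x, y) {
  assert_that(length(x) == length(y) && length(x) >= 2,
              "x and y must be paired with length >= 2")
  d <- x - y
  sd_d <- stats::sd(d)
  if (sd_d <= 1e-12 * max(1, abs(mean(d)))) {
    if (mean(d) == 0) {
      return(list(t = 0, df = length(d) - 1, p = 1, mean_diff = 0))
    }
    stopf("constant nonzero paired difference: t overflows")
  }
  ht <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_diff = mean(d))
}

#' 2x2 mixed-design ANOVA
#'
#' Between-subject factor `group` (two diagnostic groups), within-subject
#' factor `task` (two alertness tasks), one observation per cell. The
#' between effect is tested against subjects-within-groups, the within and
#' interaction effects against the task-by-subject residual. Partial eta
#' squared is `SS_effect / (SS_effect + SS_error)` with each effect's own
#' error stratum.
#'
#' @param rt_table data.frame with columns `subject`, `group` (2 levels),
#'   `task` (2 levels) and `value`; complete cases required.
#' @return List with per-effect `F`, `df`, `p`, `partial_eta_sq`, and the
#'   sums of squares decomposition `ss`.
#' @export
mixed_anova_2x2 <- function(rt_table) {
  need <- c("subject", "group", "task", "value")
  assert_that(all(need %in% names(rt_table)), "rt_table needs columns %s",
              paste(need, collapse = ", "))
  rt_table$subject <- factor(rt_table$subject)
  rt_table$group <- factor(rt_table$group)
  rt_table$task <- factor(rt_table$task)
  assert_that(nlevels(rt_table$group) == 2L && nlevels(rt_table$task) == 2L,
              "group and task must each have exactly 2 levels")
  counts <- table(rt_table$subject, rt_table$task)
  if (any(counts != 1L)) {
    stopf("each subject needs exactly one observation per task; offending subjects: %s",
          paste(utils::head(rownames(counts)[rowSums(counts != 1) > 0], 5),
                collapse = ", "))
  }
  fit <- stats::aov(value ~ group * task + Error(subject), data = rt_table)
  sm <- summary(fit)
  btw <- as.data.frame(sm[["Error: subject"]][[1]])
  wth <- as.data.frame(sm[["Error: Within"]][[1]])
  rn_b <- trimws(rownames(btw)); rn_w <- trimws(rownames(wth))
  ss <- list(
    group = btw$`Sum Sq`[rn_b == "group"],
    subjects_within_groups = btw$`Sum Sq`[rn_b == "Residuals"],
    task = wth$`Sum Sq`[rn_w == "task"],
    group_task = wth$`Sum Sq`[rn_w == "group:task"],
    task_subjects = wth$`Sum Sq`[rn_w == "Residuals"]
  )
  eff <- function(name, err_name, stratum, rn) {
    row <- stratum[rn == name, ]
    err <- stratum[rn == err_name, ]
    list(F = row$`F value`, df = c(row$Df, err$Df), p = row$`Pr(>F)`,
         partial_eta_sq = row$`Sum Sq` / (row$`Sum Sq` + err$`Sum Sq`))
  }
  list(
    diagnosis = eff("group", "Residuals", btw, rn_b),
    task = eff("task", "Residuals", wth, rn_w),
    interaction = eff("group:task", "Residuals", wth, rn_w),
    ss = ss
  )
}

#' Pearson correlation table
#'
#' Pairwise-complete Pearson correlations with two-sided p-values for a list
#' of variable pairs, optionally computed within levels of a grouping
#' column.
#'
#' @param measures Per-subject data.frame of variables.
#' @param pairs List of length-2 character vectors naming the variable pairs.
#' @param group_by Optional name of a grouping column; `NULL` = overall.
#' @return data.frame with columns `group`, `variable_x`, `variable_y`, `r`,
#'   `p`, `n`.
#' @export
correlation_table <- function(measures, pairs, group_by = NULL) {
  groups <- if (is.null(group_by)) list(overall = measures) else
    split(measures, measures[[group_by]])
  out <- do.call(rbind, lapply(names(groups), function(gname) {
    g <- groups[[gname]]
    do.call(rbind, lapply(pairs, function(pr) {
      ok <- stats::complete.cases(g[[pr[1]]], g[[pr[2]]])
      n <- sum(ok)
      if (n < 3L || stats::sd(g[[pr[1]]][ok]) == 0 ||
          stats::sd(g[[pr[2]]][ok]) == 0) {
        return(data.frame(group = gname, variable_x = pr[1],
                          variable_y = pr[2], r = NA_real_, p = NA_real_,
                          n = n))
      }
      ct <- stats::cor.test(g[[pr[1]]][ok], g[[pr[2]]][ok])
      data.frame(group = gname, variable_x = pr[1], variable_y = pr[2],
                 r = unname(ct$estimate), p = ct$p.value, n = n)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg FDR rejection flags
#'
#' Step-up procedure: sort p ascending, find the largest k with
#' `p_(k) <= k q / m`, reject hypotheses 1..k. Flags are returned in the
#' original order.
#'
#' @param p_values Numeric vector of p-values.
#' @param q FDR level (default 0.10, the a-priori threshold of the
#'   connectivity analyses).
#' @return Logical vector of rejection flags.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.04, 0.30, 0.50), q = 0.10)
bh_fdr <- function(p_values, q = 0.10) {
  assert_that(q > 0 && q < 1, "q must be in (0, 1)")
  if (length(p_values) == 0L) return(logical(0))
  stats::p.adjust(p_values, method = "BH") <= q
}
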