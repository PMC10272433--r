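test_that("summary t-test agrees with t.test on raw data", {
  set.seed(51)
  x <- rnorm(14, 1, 0.5); y <- rnorm(19, 0.7, 0.7)
  mine <- two_sample_t(length(x), mean(x), sd(x), length(y), mean(y), sd(y))
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(mine$t, unname(ref$statistic))
  expect_equal(mine$df, unname(ref$parameter))
  expect_equal(mine$p, ref$p.value)
  minew <- two_sample_t(length(x), mean(x), sd(x), length(y), mean(y),
                        sd(y), welch = TRUE)
  refw <- t.test(x, y)
  expect_equal(minew$t, unname(refw$statistic))
  expect_equal(minew$df, unname(refw$parameter))
})

test_that("t-test degenerate cases behave per contract", {
  out <- two_sample_t(10, 2, 1, 12, 2, 1)
  expect_equal(out$t, 0)
  expect_equal(out$d, 0)
  expect_error(two_sample_t(5, 1, 0, 5, 2, 0), "overflow")
})

test_that("retained two-group sample sizes give df = 71", {
  expect_equal(two_sample_t(36, 1, 1, 37, 1.1, 1)$df, 71)
})

test_that("paired t matches the difference-score oracle", {
  set.seed(52)
  x <- rnorm(20); y <- x + rnorm(20, 0.3, 0.4)
  out <- paired_t(x, y)
  d <- x - y
  t_oracle <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(out$t, t_oracle)
  expect_equal(out$df, length(d) - 1)
  expect_equal(out$p, 2 * pt(-abs(t_oracle), length(d) - 1))
  expect_equal(paired_t(x, x)$t, 0)
  expect_error(paired_t(x, x + 1), "overflow")
})

test_that("mixed ANOVA matches an explicit sums-of-squares oracle", {
  # hand-built 4-subject balanced table
  tab <- data.frame(
    subject = rep(c("s1", "s2", "s3", "s4"), each = 2),
    group = rep(c("A", "A", "B", "B"), each = 2),
    task = rep(c("T2", "T3"), 4),
    value = c(10, 12, 14, 18, 20, 21, 26, 29))
  out <- mixed_anova_2x2(tab)
  # oracle: explicit split-plot decomposition
  y <- tab$value
  gm <- mean(y)
  subj_m <- tapply(y, tab$subject, mean)
  grp_m <- tapply(y, tab$group, mean)
  task_m <- tapply(y, tab$task, mean)
  cell_m <- tapply(y, list(tab$group, tab$task), mean)
  ss_total <- sum((y - gm)^2)
  ss_between_subj <- 2 * sum((subj_m - gm)^2)
  ss_group <- 4 * sum((grp_m - gm)^2)
  ss_subj_within <- ss_between_subj - ss_group
  ss_task <- 4 * sum((task_m - gm)^2)
  ss_cells <- 2 * sum((cell_m - gm)^2)
  ss_inter <- ss_cells - ss_group - ss_task
  ss_task_subj <- ss_total - ss_between_subj - ss_task - ss_inter
  expect_equal(out$ss$group, ss_group, tolerance = 1e-10)
  expect_equal(out$ss$subjects_within_groups, ss_subj_within,
               tolerance = 1e-10)
  expect_equal(out$ss$task, ss_task, tolerance = 1e-10)
  expect_equal(out$ss$group_task, ss_inter, tolerance = 1e-10)
  expect_equal(out$ss$task_subjects, ss_task_subj, tolerance = 1e-10)
  expect_equal(out$diagnosis$F, (ss_group / 1) / (ss_subj_within / 2),
               tolerance = 1e-10)
  expect_equal(out$task$partial_eta_sq, ss_task / (ss_task + ss_task_subj),
               tolerance = 1e-10)
})

test_that("mixed ANOVA degrees of freedom and null behaviour", {
  set.seed(53)
  n <- c(36, 37)
  tab <- data.frame(
    subject = rep(sprintf("s%02d", 1:73), each = 2),
    group = rep(rep(c("HC", "MS"), n), each = 2),
    task = rep(c("T2", "T3"), 73),
    value = rnorm(146))
  out <- mixed_anova_2x2(tab)
  expect_equal(out$diagnosis$df, c(1, 71))
  expect_equal(out$task$df, c(1, 71))
  expect_lt(out$diagnosis$partial_eta_sq, 0.15)  # null data
  # SS identity: total = sum of effect and error strata
  tot <- sum((tab$value - mean(tab$value))^2)
  expect_equal(Reduce(`+`, out$ss), tot, tolerance = 1e-8)
  # missing cell errors
  expect_error(mixed_anova_2x2(tab[-1, ]), "exactly one observation")
})

test_that("correlation table matches the covariance-formula oracle", {
  set.seed(54)
  d <- data.frame(g = rep(c("HC", "MS"), each = 15),
                  x = rnorm(30), y = rnorm(30))
  d$y[5] <- NA
  out <- correlation_table(d, list(c("x", "y")), group_by = "g")
  for (gg in c("HC", "MS")) {
    sub <- d[d$g == gg & complete.cases(d$x, d$y), ]
    r_oracle <- sum((sub$x - mean(sub$x)) * (sub$y - mean(sub$y))) /
      sqrt(sum((sub$x - mean(sub$x))^2) * sum((sub$y - mean(sub$y))^2))
    row <- out[out$group == gg, ]
    expect_equal(row$r, r_oracle)
    expect_equal(row$n, nrow(sub))
  }
  self <- correlation_table(d, list(c("x", "x")))
  expect_equal(self$r, 1)
})

test_that("BH step-up rule matches a hand implementation", {
  bh_oracle <- function(p, q) {
    m <- length(p)
    ord <- order(p)
    k <- max(c(0, which(p[ord] <= seq_len(m) * q / m)))
    flags <- logical(m)
    if (k > 0) flags[ord[seq_len(k)]] <- TRUE
    flags
  }
  expect_identical(bh_fdr(rep(0.001, 10)), rep(TRUE, 10))
  expect_identical(bh_fdr(c(0.01, 0.04, 0.30, 0.50), q = 0.10),
                   c(TRUE, TRUE, FALSE, FALSE))
  expect_identical(bh_fdr(numeric(0)), logical(0))
  set.seed(55)
  for (i in 1:20) {
    p <- runif(sample(3:25, 1))^2
    q <- runif(1, 0.02, 0.3)
    expect_identical(bh_fdr(p, q), bh_oracle(p, q))
  }
  # monotone in q: lowering q never adds rejections
  set.seed(56)
  p <- runif(15)^1.5
  expect_true(all(bh_fdr(p, 0.05) <= bh_fdr(p, 0.10)))
})
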