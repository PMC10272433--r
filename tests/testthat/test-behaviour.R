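test_that("trial RT is grip minus stimulus with anticipations invalid", {
  expect_equal(trial_rt(1400, 1000), 400)
  expect_true(is.na(trial_rt(900, 1000)))
  expect_equal(block_rt(trial_rt(c(1300, 1500, 900), c(1000, 1000, 1000))),
               400)
  expect_error(block_rt(c(NA_real_, NA_real_)), "no valid trials")
})

test_that("block force is the mean peak force", {
  expect_equal(block_force(c(10, 12)), 11)
  expect_equal(block_force(7.3), 7.3)
  set.seed(41)
  x <- runif(17, 5, 15)
  expect_equal(block_force(x), sum(x) / length(x))
})

make_behaviour <- function(rts, group = "HC") {
  # one T2 and one T3 row per subject, block 1 (enough for the filter)
  do.call(rbind, lapply(seq_along(rts), function(i) {
    data.frame(subject = sprintf("%s%03d", group, i), group = group,
               condition = "handgrip_only", task = c("T2", "T3"),
               block = 1L, mean_rt_ms = rts[i], mean_peak_force = 10,
               fss = 40, hads_anxiety = 5, hads_depression = 5)
  }))
}

test_that("RT outlier filter matches brute-force z-scores, single pass", {
  set.seed(42)
  rts <- c(rnorm(18, 450, 30), 700, 120)
  beh <- make_behaviour(rts)
  out <- filter_rt_outliers(beh)
  z <- (rts - mean(rts)) / sd(rts)
  expect_setequal(out$report$subject[out$report$removed],
                  sprintf("HC%03d", which(abs(z) > 2)))
  expect_equal(sort(unique(out$retained$subject)),
               sort(sprintf("HC%03d", which(abs(z) <= 2))))
  # statistics are the pre-removal ones (single pass)
  expect_equal(unique(out$report$group_mean), mean(rts))
  expect_equal(unique(out$report$group_sd), sd(rts))
})

test_that("a clean cohort passes the filter untouched", {
  beh <- make_behaviour(seq(430, 470, length.out = 10))
  out <- filter_rt_outliers(beh)
  expect_identical(nrow(out$removed), 0L)
  expect_identical(sum(out$report$removed), 0L)
})

test_that("the filter uses pre-removal statistics: masked outliers stay", {
  # one extreme value inflates the SD enough to shelter a milder deviant;
  # a second (iterative) pass would remove it, a single pass must not
  rts <- c(rep(450, 12), 480, 1500)
  beh <- make_behaviour(rts)
  out <- filter_rt_outliers(beh)
  expect_identical(out$report$subject[out$report$removed], "HC014")
  z2 <- abs(480 - mean(rts[-14])) / sd(rts[-14])
  expect_gt(z2, 2)  # the sheltered subject would fail a second pass
})

test_that("degenerate SD warns and removes nobody", {
  beh <- make_behaviour(rep(450, 5))
  expect_warning(out <- filter_rt_outliers(beh), "zero RT")
  expect_identical(sum(out$report$removed), 0L)
})

test_that("inclusion screening applies the FSS and HADS cut-offs", {
  subj <- data.frame(
    group = c("MS", "MS", "HC", "HC", "MS", "HC"),
    fss_total = c(36, 35, 36, 35, 50, 20),
    hads_anxiety = c(5, 5, 5, 5, 5, 13),
    hads_depression = c(5, 5, 5, 5, 13, 5))
  out <- screen_inclusion(subj)
  expect_identical(out$include, c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE))
  expect_match(out$reason[2], "FSS below")
  expect_match(out$reason[3], "cut-off")
  expect_match(out$reason[5], "comorbidity")
})

test_that("fatigue measures are block-4 minus block-1 deltas", {
  beh <- data.frame(subject = "s1", group = "MS",
                    condition = "handgrip_only",
                    task = rep(c("T2", "T3"), each = 4), block = rep(1:4, 2),
                    mean_rt_ms = c(600, 610, 630, 650, 500, 500, 500, 500),
                    mean_peak_force = c(11.90, 11.5, 11.2, 11.01,
                                        10, 10, 10, 10))
  fm <- fatigue_measures(beh)
  expect_equal(fm$cognitive_fatigue_ms[fm$task == "T2"], 50)
  expect_equal(fm$physical_fatigue[fm$task == "T2"], 0.89)
  expect_equal(fm$cognitive_fatigue_ms[fm$task == "T3"], 0)
  expect_equal(fm$physical_fatigue[fm$task == "T3"], 0)
  # antisymmetry under swapping blocks 1 and 4
  swapped <- beh
  swapped$block <- c(4, 2, 3, 1, 4, 2, 3, 1)
  fs <- fatigue_measures(swapped)
  expect_equal(fs$cognitive_fatigue_ms, -fm$cognitive_fatigue_ms)
  expect_equal(fs$physical_fatigue, -fm$physical_fatigue)
})
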