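test_that("generation is deterministic given (spec, seed)", {
  spec <- tiny_spec()
  a <- generate_cohort(spec, 7)
  b <- generate_cohort(spec, 7)
  expect_identical(a$behaviour, b$behaviour)
  expect_identical(a$subjects$HC001$roi_timeseries$data,
                   b$subjects$HC001$roi_timeseries$data)
  expect_identical(a$subjects$MS002$confounds$wm,
                   b$subjects$MS002$confounds$wm)
  c <- generate_cohort(spec, 8)
  expect_false(identical(a$behaviour$mean_rt_ms, c$behaviour$mean_rt_ms))
  # behaviour-only generation leaves behavioural values identical
  d <- generate_cohort(spec, 7, components = "behaviour")
  expect_identical(a$behaviour, d$behaviour)
  expect_null(d$subjects$HC001$roi_timeseries)
})

test_that("null coupling produces near-zero local connectivity", {
  zero_pair <- list(hc_mean = 0, hc_sd = 0.05, ms_mean = 0, ms_sd = 0.05)
  null_spec <- cohort_spec(overrides = list(
    cohort = list(n_hc = 60, n_ms = 2),
    outliers = no_outliers,
    coupling = list(
      intrinsic = list("Caudate-Putamen" = zero_pair,
                       "Caudate-Pallidum" = zero_pair,
                       "Putamen-Pallidum" = zero_pair),
      extrinsic = list("Caudate-Putamen" = zero_pair,
                       "Caudate-Pallidum" = zero_pair,
                       "Putamen-Pallidum" = zero_pair)),
    background = list(homotopic_bg_z = 0, bg_cortex_z = 0,
                      bg_cortex_sd = 0.02, cortex_cortex_z = 0,
                      cortex_cortex_sd = 0.02),
    behaviour = list(fc_behaviour_corr = list(
      hc = list(fss = 0, t2_rt = 0), ms = list(fss = 0, t2_rt = 0)))))
  coh <- generate_cohort(null_spec, 9)
  hc <- coh$subjects[grep("^HC", names(coh$subjects))]
  zs <- vapply(hc, function(s) {
    st <- subject_fc_stats(s, coh$schedule, null_spec$cleaning,
                           tasks = "T2", blocks = integer(0))
    st$local$z[st$local$pair == "Putamen-Pallidum"]
  }, 1)
  expect_lt(abs(mean(zs)), 0.05)
})

test_that("infeasible coupling targets are rejected with a clear error", {
  hot <- cohort_spec(overrides = list(
    cohort = list(n_hc = 2, n_ms = 2), outliers = no_outliers,
    coupling = list(intrinsic = list("Putamen-Pallidum" = list(
      hc_mean = 2.3, hc_sd = 0.3, ms_mean = 2.3, ms_sd = 0.3)))))
  expect_error(generate_cohort(hot, 1), "\\|r\\| >= 1|positive definite")
})

test_that("outlier planting is exact and brute-force verifiable", {
  spec <- tiny_spec(10)
  coh <- generate_cohort(spec, 5, components = "behaviour")
  beh <- coh$behaviour
  # n = 0 leaves the table unchanged
  expect_identical(plant_rt_outliers(beh, c(HC = 0, MS = 0)),
                   structure(beh, planted = list(HC = character(0),
                                                 MS = character(0))),
                   ignore_attr = TRUE)
  planted <- plant_rt_outliers(beh, c(HC = 2, MS = 1), seed = 3)
  who <- attr(planted, "planted")
  expect_length(who$HC, 2)
  expect_length(who$MS, 1)
  # brute-force: recompute per-group mean/SD directly and check |z| > 2 for
  # exactly the planted subjects
  gm <- aggregate(mean_rt_ms ~ subject + group,
                  data = planted[planted$task %in% c("T2", "T3"), ], FUN = mean)
  for (g in c("HC", "MS")) {
    x <- gm[gm$group == g, ]
    z <- abs(x$mean_rt_ms - mean(x$mean_rt_ms)) / sd(x$mean_rt_ms)
    expect_setequal(x$subject[z > 2], who[[g]])
  }
  # the filter removes exactly the planted subjects
  out <- filter_rt_outliers(planted)
  expect_setequal(out$report$subject[out$report$removed],
                  c(who$HC, who$MS))
  # infeasible: cannot plant as many outliers as there are subjects
  expect_error(plant_rt_outliers(beh, c(HC = 10, MS = 0), seed = 1),
               "cannot plant")
})

test_that("the default fixture filters down to 37 MS and 36 HC", {
  coh <- generate_cohort(cohort_spec(), 42, components = "behaviour")
  out <- filter_rt_outliers(coh$behaviour)
  counts <- table(unique(out$retained[c("subject", "group")])$group)
  expect_identical(as.integer(counts[["MS"]]), 37L)
  expect_identical(as.integer(counts[["HC"]]), 36L)
  # retained condition arms mirror the reported split
  meta <- unique(out$retained[c("subject", "group", "condition")])
  expect_identical(sum(meta$group == "HC" & meta$condition == "handgrip_only"), 19L)
  expect_identical(sum(meta$group == "HC" & meta$condition == "mental_imagery_first"), 17L)
  expect_identical(sum(meta$group == "MS" & meta$condition == "handgrip_only"), 19L)
  expect_identical(sum(meta$group == "MS" & meta$condition == "mental_imagery_first"), 18L)
})

test_that("behaviour tables respect instrument ranges and structure", {
  coh <- generate_cohort(tiny_spec(8), 12, components = "behaviour")
  beh <- coh$behaviour
  expect_true(all(beh$fss >= 9 & beh$fss <= 63))
  expect_true(all(beh$fss[beh$group == "MS"] >= 36))
  expect_true(all(beh$fss[beh$group == "HC"] < 36))
  expect_true(all(beh$hads_anxiety >= 0 & beh$hads_anxiety <= 12))
  expect_true(all(beh$mean_peak_force > 0))
  expect_true(all(is.na(beh$mean_rt_ms[beh$task == "T1"])))
  expect_true(all(!is.na(beh$mean_rt_ms[beh$task != "T1"])))
  # one record per subject x task x block
  expect_identical(nrow(beh), 16L * 3L * 4L)
  # time-series length equals the schedule length in volumes
  coh2 <- generate_cohort(tiny_spec(), 12)
  expect_identical(nrow(coh2$subjects$HC001$roi_timeseries$data),
                   schedule_volumes(coh2$schedule, coh2$spec$tr_seconds))
})

test_that("NIfTI fixture round trips exactly at zero voxel noise", {
  coh <- generate_cohort(tiny_spec(), 13)
  s <- coh$subjects$MS001
  fx <- render_nifti_fixture(s)
  expect_identical(dim(fx$image4d)[4], nrow(s$roi_timeseries$data))
  ts2 <- extract_roi_timeseries(fx$image4d, fx$parcellation,
                                coh$spec$tr_seconds)
  expect_equal(ts2$data, s$roi_timeseries$data, tolerance = 1e-12)
  cf2 <- extract_confounds(fx$image4d, fx$wm_mask, fx$csf_mask, fx$motion)
  expect_equal(cf2$wm, s$confounds$wm, tolerance = 1e-12)
  expect_equal(cf2$csf, s$confounds$csf, tolerance = 1e-12)
  # with voxel noise the round trip is close but not exact
  set.seed(99)
  fxn <- render_nifti_fixture(s, voxel_noise_sd = 0.1)
  ts3 <- extract_roi_timeseries(fxn$image4d, fxn$parcellation,
                                coh$spec$tr_seconds)
  expect_gt(max(abs(ts3$data - s$roi_timeseries$data)), 0)
  expect_lt(max(abs(ts3$data - s$roi_timeseries$data)), 1)
})

test_that("cohorts round trip through the TSV representation", {
  coh <- generate_cohort(tiny_spec(), 14)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_identical(names(back$subjects), names(coh$subjects))
  expect_equal(back$subjects$HC002$roi_timeseries$data,
               coh$subjects$HC002$roi_timeseries$data, tolerance = 1e-6)
  expect_equal(back$behaviour$mean_rt_ms, coh$behaviour$mean_rt_ms,
               tolerance = 1e-6)
  expect_identical(back$subjects$MS001$group, "MS")
})
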