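#' Cohort specification
#'
#' Builds the full specification of a synthetic two-group (HC / MS) cohort:
#' sample sizes, paradigm schedule, connectivity coupling targets (Fisher-z
#' group means and SDs per basal-ganglia pair and task), behavioural
#' calibration (FSS distributions, pooled FSS-RT correlation, FC-behaviour
#' correlations, per-block RT and grip-force means, planted RT outliers) and
#' the confound/noise model. Defaults are read from the packaged calibration
#' file `extdata/default_calibration.yaml`.
#'
#' @param config Path to a YAML calibration file, or a list in the same
#'   structure; `NULL` uses the packaged defaults.
#' @param overrides Optional named list merged over the configuration
#'   (nested lists merge recursively), e.g.
#'   `list(cohort = list(n_hc = 200))`.
#' @return A `bg_cohort_spec` object.
#' @export
#' @examples
#' spec <- cohort_spec()
#' spec$n_hc
cohort_spec <- function(config = NULL, overrides = NULL) {
  cfg <- yaml::read_yaml(system.file("extdata", "default_calibration.yaml",
                                     package = "bgfc", mustWork = TRUE))
  if (!is.null(config)) {
    user <- if (is.character(config)) yaml::read_yaml(config) else config
    cfg <- utils::modifyList(cfg, user)
  }
  if (!is.null(overrides)) cfg <- utils::modifyList(cfg, overrides)

  n_hc <- cfg$cohort$n_hc; n_ms <- cfg$cohort$n_ms
  assert_that(is_count(n_hc) && n_hc >= 2, "n_hc must be an integer >= 2")
  assert_that(is_count(n_ms) && n_ms >= 2, "n_ms must be an integer >= 2")
  tr <- cfg$cohort$tr_seconds
  assert_that(is.numeric(tr) && tr > 0, "tr_seconds must be positive")

  # condition arm counts: rescale proportionally if they do not sum to n
  conds <- cfg$conditions
  for (g in c("hc", "ms")) {
    n <- if (g == "hc") n_hc else n_ms
    hg <- conds$handgrip_only[[g]]; im <- conds$mental_imagery_first[[g]]
    if (hg + im != n) {
      hg <- round(n * hg / (hg + im)); im <- n - hg
      conds$handgrip_only[[g]] <- hg
      conds$mental_imagery_first[[g]] <- im
    }
    for (cd in names(cfg$outliers[[g]])) {
      assert_that(cfg$outliers[[g]][[cd]] < conds[[cd]][[g]] ||
                    cfg$outliers[[g]][[cd]] == 0,
                  "planted outliers must be fewer than the %s %s arm size",
                  g, cd)
    }
  }

  for (tk in names(cfg$coupling)) for (p in names(cfg$coupling[[tk]])) {
    cp <- cfg$coupling[[tk]][[p]]
    assert_that(all(is.finite(unlist(cp))), "coupling targets must be finite")
    assert_that(cp$hc_sd >= 0 && cp$ms_sd >= 0, "coupling SDs must be >= 0")
  }

  cleaning <- cleaning_config(
    band_low_hz = cfg$cleaning$band_low_hz,
    band_high_hz = cfg$cleaning$band_high_hz,
    filter_order = cfg$cleaning$filter_order,
    detrend = cfg$cleaning$detrend
  )
  schedule <- default_schedule(block_volumes = cfg$schedule$block_volumes,
                               tr_seconds = tr,
                               rest_volumes = cfg$schedule$rest_volumes)
  structure(list(
    n_hc = as.integer(n_hc), n_ms = as.integer(n_ms), tr_seconds = tr,
    conditions = conds, outliers = cfg$outliers, coupling = cfg$coupling,
    background = cfg$background, behaviour = cfg$behaviour,
    noise = cfg$noise, schedule_cfg = cfg$schedule, cleaning = cleaning,
    schedule = schedule
  ), class = "bg_cohort_spec")
}

#' @export
print.bg_cohort_spec <- function(x, ...) {
  cat(sprintf("Synthetic cohort spec: %d HC + %d MS, TR = %g s, %d volumes\n",
              x$n_hc, x$n_ms, x$tr_seconds,
              schedule_volumes(x$schedule, x$tr_seconds)))
  invisible(x)
}

subject_ids <- function(spec) {
  c(sprintf("HC%03d", seq_len(spec$n_hc)),
    sprintf("MS%03d", seq_len(spec$n_ms)))
}

# Subject-level correlation-matrix target for one task, from the subject's
# coupling draws (Fisher-z scale). Returns the Cholesky factor of the
# noise-inflated covariance used to draw the latent signal.
subject_signal_chol <- function(z_pairs, z_gc, z_cc, z_hom, noise_sd,
                                region_names) {
  n <- length(region_names)
  bg_idx <- match(bg_region_names(), region_names)
  R <- matrix(tanh(z_cc), n, n)
  R[bg_idx, ] <- tanh(z_gc)
  R[, bg_idx] <- tanh(z_gc)
  for (p in names(bg_pairs())) {
    idx <- bg_edge_indices(region_names, p)
    R[idx] <- tanh(z_pairs[[p]])
    R[idx[, c(2, 1)]] <- tanh(z_pairs[[p]])
  }
  for (s in c("Caudate", "Putamen", "Pallidum")) {
    i <- match(paste0(s, c("_L", "_R")), region_names)
    R[i[1], i[2]] <- R[i[2], i[1]] <- tanh(z_hom)
  }
  diag(R) <- 1
  # inflate the off-diagonal so that adding iid measurement noise of SD
  # noise_sd on top of the unit-variance latent signal returns the observed
  # correlation to the target: corr = (1+sd^2) r / (1+sd^2) = r
  if (max(abs(R[upper.tri(R)])) * (1 + noise_sd^2) >= 1 - 1e-9) {
    stopf("subject coupling draw implies |r| >= 1 after jitter (max %.4f); reduce coupling_sd or targets",
          max(abs(R[upper.tri(R)])))
  }
  Ri <- (1 + noise_sd^2) * R
  diag(Ri) <- 1
  ch <- tryCatch(chol(Ri), error = function(e) NULL)
  if (is.null(ch)) {
    stopf("subject-level correlation target is not positive definite; coupling draw too extreme")
  }
  ch
}

draw_subject_latents <- function(spec, cal, group) {
  lat <- cal$latents[[group]]
  f <- spec$behaviour$fss[[tolower(group)]]
  trip <- NULL
  for (it in 1:1000) {
    cand <- as.numeric(rnorm(3) %*% lat$chol)  # (xi, eta, kappa)
    fss_raw <- f$mean + f$sd * cand[1]
    if (fss_raw >= f$min && fss_raw <= f$max) { trip <- cand; break }
  }
  assert_that(!is.null(trip), "FSS rejection sampling failed; check fss calibration")
  nu <- rnorm(2)
  # one shared background tone drives both the BG-cortex and cortex-cortex
  # coupling so that their joint draw stays inside the positive-definite
  # region (a strong seed-to-cortex coupling is only feasible when the
  # cortex background is strong too); likewise one shared caudate factor
  # drives Caudate-Putamen and Caudate-Pallidum, because when the
  # putamen-pallidum coupling is near its upper extreme the two caudate
  # couplings must be nearly equal for the joint target to remain a valid
  # correlation matrix
  zeta <- rtrunc_norm(1, 0, 1, -2, 2)
  rho_pf <- cal$pair_factor_corr
  clamp3 <- function(x) pmin(pmax(x, -3), 3)
  caud <- clamp3(rho_pf * trip[3] + sqrt(1 - rho_pf^2) * nu[1])
  factors <- c(
    "Caudate-Putamen" = caud,
    "Caudate-Pallidum" = caud,
    "Putamen-Pallidum" = clamp3(trip[3])
  )
  list(xi = trip[1], eta = trip[2], kappa = trip[3],
       fss = min(max(round(f$mean + f$sd * trip[1]), f$min), f$max),
       pair_factors = factors, zeta_gc = zeta, zeta_cc = zeta)
}

subject_behaviour_rows <- function(spec, id, group, condition, lat) {
  beh <- spec$behaviour
  g <- tolower(group)
  u <- beh$rt$subject_sd_ms * lat$eta
  f_i <- rnorm(1, 0, beh$force$subject_sd)
  hads <- round(rtrunc_norm(2, beh$hads$mean, beh$hads$sd, 0, beh$hads$max))
  rows <- list()
  for (task in TASKS) {
    task_name <- switch(task, T1 = NA, T2 = "intrinsic", T3 = "extrinsic")
    rt_means <- if (task == "T1") rep(NA_real_, 4) else
      interp_blocks(beh$rt$block_means_ms[[g]][[condition]][[task_name]]) +
        u + rnorm(4, 0, beh$rt$block_sd_ms)
    force_name <- if (task == "T1") "intrinsic" else task_name
    force <- interp_blocks(beh$force$block_means_high[[g]][[condition]][[force_name]]) +
      f_i + rnorm(4, 0, beh$force$block_sd)
    force <- pmax(force, 0.5)
    rows[[task]] <- data.frame(
      subject = id, group = group, condition = condition, task = task,
      block = 1:4, mean_rt_ms = rt_means, mean_peak_force = force,
      fss = lat$fss, hads_anxiety = hads[1], hads_depression = hads[2]
    )
  }
  do.call(rbind, rows)
}

subject_coupling_z <- function(cal, group, task, lat) {
  z <- list()
  for (p in names(bg_pairs())) {
    row <- cal$coupling[cal$coupling$group == group &
                          cal$coupling$pair == p & cal$coupling$task == task, ]
    z[[p]] <- row$mu_lat + row$sigma_lat * lat$pair_factors[[p]]
  }
  z
}

simulate_subject_imaging <- function(spec, cal, group, lat) {
  region_names <- aal116_labels()$name
  nR <- length(region_names)
  T <- schedule_volumes(spec$schedule, spec$tr_seconds)
  noise_sd <- spec$noise$white_noise_sd

  z_gc <- cal$bg_cortex_mu_lat + cal$bg_cortex_sd * lat$zeta_gc
  # equicorrelation below -1/(n-1) is not a valid correlation matrix, so
  # the cortical background is floored just above zero
  z_cc <- max(cal$cortex_cortex_z + cal$cortex_cortex_sd * lat$zeta_cc,
              atanh(0.01))
  # rare tail draws of the pair couplings can leave the feasible set of
  # correlation matrices (e.g. a negative caudate coupling jointly with a
  # strong seed-to-cortex background); such draws are shrunk toward the
  # group mean until the joint target is a valid correlation matrix, which
  # truncates the jitter distribution at the feasibility boundary
  chols <- NULL
  for (attempt in 1:6) {
    chols <- tryCatch(
      lapply(setNames(TASKS, TASKS), function(tk) {
        subject_signal_chol(subject_coupling_z(cal, group, tk, lat),
                            z_gc, z_cc, cal$homotopic_bg_z, noise_sd,
                            region_names)
      }),
      error = function(e) e)
    if (!inherits(chols, "error")) break
    lat$pair_factors <- lat$pair_factors * 0.7
  }
  if (inherits(chols, "error")) stop(chols)

  # confounds: AR(1) tissue signals, random-walk motion
  phi <- 0.9
  ar1 <- function(T) as.numeric(stats::filter(rnorm(T, 0, sqrt(1 - phi^2)),
                                              phi, method = "recursive"))
  wm <- ar1(T); csf <- ar1(T)
  motion <- cbind(
    sapply(1:3, function(i) cumsum(rnorm(T, 0, 0.02))),
    sapply(1:3, function(i) cumsum(rnorm(T, 0, 5e-4)))
  )
  conf <- confound_set(wm, csf, motion)
  Cstd <- scale(as_confound_matrix(conf))
  tau <- spec$noise$confound_amplitude * sqrt(1 + noise_sd^2) / sqrt(8)
  Gamma <- matrix(rnorm(nR * 8, 0, tau), nR, 8)

  X <- matrix(NA_real_, T, nR)
  step <- spec$schedule_cfg$block_volumes + spec$schedule_cfg$rest_volumes
  rest_chol <- NULL
  for (i in seq_len(nrow(spec$schedule))) {
    tk <- spec$schedule$task[i]
    first <- (i - 1L) * step + 1L
    rows <- first:(first + spec$schedule_cfg$block_volumes - 1L)
    X[rows, ] <- matrix(rnorm(length(rows) * nR), length(rows)) %*% chols[[tk]]
    if (spec$schedule_cfg$rest_volumes > 0) {
      if (is.null(rest_chol)) {
        rest_chol <- (chols$T1 + chols$T2 + chols$T3) / 3
      }
      rrows <- (first + spec$schedule_cfg$block_volumes):
        min(first + step - 1L, T)
      X[rrows, ] <- matrix(rnorm(length(rrows) * nR), length(rrows)) %*% rest_chol
    }
  }
  X <- X + matrix(rnorm(T * nR, 0, noise_sd), T, nR) + Cstd %*% t(Gamma)
  list(ts = roi_timeseries(X, spec$tr_seconds, region_names),
       confounds = conf)
}

#' Generate a synthetic cohort
#'
#' Deterministically (given `seed`) generates a cohort of synthetic subjects
#' whose ROI time series, confounds and behavioural tables carry the
#' statistical structure the downstream analysis assumes: after the standard
#' cleaning/segmentation/connectivity pipeline the expected Fisher-z
#' connectivity of each calibrated basal-ganglia pair equals the group
#' target; FSS, reaction time and connectivity realise the calibrated
#' correlations; and exactly the specified number of RT outliers per group
#' are planted beyond the 2 SD filter band.
#'
#' @param spec A `bg_cohort_spec` from [cohort_spec()].
#' @param seed Integer RNG seed; every source of randomness derives from it
#'   via per-subject substreams.
#' @param components Character subset of `c("behaviour", "imaging")`;
#'   dropping "imaging" skips the (comparatively expensive) ROI time-series
#'   simulation and leaves behavioural values identical.
#' @return A `bg_cohort`: list with `subjects` (list of `bg_subject`),
#'   `behaviour` (long table), `schedule`, `spec`, `seed`, `calibration`.
#' @export
generate_cohort <- function(spec, seed,
                            components = c("behaviour", "imaging")) {
  assert_that(inherits(spec, "bg_cohort_spec"), "spec must be a bg_cohort_spec")
  components <- match.arg(components, several.ok = TRUE)
  cal <- generator_calibration(spec)
  ids <- subject_ids(spec)
  groups <- rep(c("HC", "MS"), c(spec$n_hc, spec$n_ms))

  set.seed(derive_seed(seed, 0L))
  condition <- character(length(ids))
  planted <- list(HC = character(0), MS = character(0))
  for (g in c("HC", "MS")) {
    gl <- tolower(g)
    sel <- which(groups == g)
    arms <- sample(rep(c("handgrip_only", "mental_imagery_first"),
                       c(spec$conditions$handgrip_only[[gl]],
                         spec$conditions$mental_imagery_first[[gl]])))
    condition[sel] <- arms
    for (cd in c("handgrip_only", "mental_imagery_first")) {
      k <- spec$outliers[[gl]][[cd]]
      if (k > 0) {
        pool <- ids[sel][arms == cd]
        planted[[g]] <- c(planted[[g]], sample(pool, k))
      }
    }
  }

  latents <- vector("list", length(ids))
  beh_rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    set.seed(derive_seed(seed, 2L * i))
    latents[[i]] <- draw_subject_latents(spec, cal, groups[i])
    beh_rows[[i]] <- subject_behaviour_rows(spec, ids[i], groups[i],
                                            condition[i], latents[[i]])
  }
  behaviour <- do.call(rbind, beh_rows)
  rownames(behaviour) <- NULL
  n_out <- c(HC = length(planted$HC), MS = length(planted$MS))
  if (sum(n_out) > 0) {
    behaviour <- plant_rt_outliers(behaviour, n_out, subjects = planted)
  } else {
    attr(behaviour, "planted") <- planted
  }

  subjects <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    img <- NULL
    if ("imaging" %in% components) {
      set.seed(derive_seed(seed, 2L * i + 1L))
      img <- simulate_subject_imaging(spec, cal, groups[i], latents[[i]])
    }
    subjects[[i]] <- structure(list(
      subject_id = ids[i], group = groups[i], condition = condition[i],
      roi_timeseries = img$ts, confounds = img$confounds,
      behaviour = behaviour[behaviour$subject == ids[i], , drop = FALSE],
      latents = latents[[i]]
    ), class = "bg_subject")
  }
  names(subjects) <- ids
  structure(list(subjects = subjects, behaviour = behaviour,
                 schedule = spec$schedule, spec = spec, seed = seed,
                 calibration = cal, planted = attr(behaviour, "planted")),
            class = "bg_cohort")
}

#' @export
print.bg_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects (%d HC, %d MS), seed %d\n",
              length(x$subjects), sum(grepl("^HC", names(x$subjects))),
              sum(grepl("^MS", names(x$subjects))), x$seed))
  invisible(x)
}

#' Plant reaction-time outliers
#'
#' Shifts the grand-mean RT of selected subjects far enough beyond their
#' group mean that the 2 SD outlier filter — with group statistics
#' recomputed after planting — flags exactly those subjects and no others.
#' Planted subjects alternate between the high and low side of the band.
#'
#' @param behaviour Cohort behaviour table (long format).
#' @param n_outliers_per_group Named vector/list, e.g. `c(HC = 4, MS = 3)`.
#' @param seed RNG seed used when `subjects` is not given.
#' @param subjects Optional named list of pre-chosen subject ids per group.
#' @param k_sd Filter band width in SDs (default 2).
#' @return The behaviour table with shifted RTs and a `planted` attribute.
#' @export
plant_rt_outliers <- function(behaviour, n_outliers_per_group, seed = NULL,
                              subjects = NULL, k_sd = 2) {
  n_out <- n_outliers_per_group
  groups <- intersect(c("HC", "MS"), unique(behaviour$group))
  gm <- subject_grand_rt(behaviour)
  if (is.null(subjects)) {
    if (!is.null(seed)) set.seed(seed)
    subjects <- lapply(setNames(groups, groups), function(g) {
      k <- n_out[[g]] %||% 0
      pool <- gm$subject[gm$group == g]
      assert_that(k < length(pool),
                  "cannot plant %d outliers in a group of %d", k, length(pool))
      if (k == 0) character(0) else sample(pool, k)
    })
  }
  if (sum(lengths(subjects)) == 0) {
    attr(behaviour, "planted") <- subjects
    return(behaviour)
  }
  base <- lapply(setNames(groups, groups), function(g) {
    x <- gm$mean_rt_ms[gm$group == g]
    assert_that(length(x) - length(subjects[[g]]) >= 3,
                "too few non-outlier subjects remain in group %s", g)
    list(mean = mean(x), sd = stats::sd(x))
  })
  mult <- 4
  for (iter in 1:20) {
    shifted <- behaviour
    for (g in groups) {
      ss <- subjects[[g]]
      if (length(ss) == 0) next
      signs <- rep(c(1, -1), length.out = length(ss))
      for (j in seq_along(ss)) {
        cur <- gm$mean_rt_ms[gm$subject == ss[j]]
        target <- base[[g]]$mean + signs[j] * mult * base[[g]]$sd
        rows <- shifted$subject == ss[j] & shifted$task %in% c("T2", "T3")
        shifted$mean_rt_ms[rows] <- shifted$mean_rt_ms[rows] + (target - cur)
      }
    }
    gm2 <- subject_grand_rt(shifted)
    ok <- all(vapply(groups, function(g) {
      x <- gm2[gm2$group == g, ]
      z <- (x$mean_rt_ms - mean(x$mean_rt_ms)) / stats::sd(x$mean_rt_ms)
      flagged <- sort(x$subject[abs(z) > k_sd])
      identical(flagged, sort(subjects[[g]]))
    }, TRUE))
    if (ok) {
      attr(shifted, "planted") <- subjects
      return(shifted)
    }
    mult <- mult * 1.5
  }
  stopf("could not place RT outliers so that the %g SD filter flags exactly the chosen subjects; group too small or too dispersed",
        k_sd)
}

#' Default voxel layout for NIfTI fixtures
#'
#' A minimal 3D grid assigning each of the 116 atlas labels a contiguous run
#' of `voxels_per_label` voxels, plus two white-matter and two CSF voxels.
#'
#' @param voxels_per_label Voxels per region (default 1).
#' @return Layout list used by [render_nifti_fixture()].
#' @export
fixture_layout <- function(voxels_per_label = 1L) {
  need <- 116L * voxels_per_label + 4L
  nx <- ceiling(need / 20)
  list(dim = c(5L, 4L, as.integer(nx)), voxels_per_label = voxels_per_label)
}

#' Render a subject as a small 4D NIfTI fixture
#'
#' Writes the subject's ROI time series into a tiny volumetric image: every
#' voxel of a label carries that ROI's series plus optional iid voxel noise,
#' and dedicated voxels carry the white-matter and CSF confound series, so a
#' round trip through [extract_roi_timeseries()] / [extract_confounds()]
#' recovers the stored series exactly at zero voxel noise.
#'
#' @param subject A `bg_subject` with imaging data.
#' @param layout Layout from [fixture_layout()].
#' @param voxel_noise_sd SD of iid voxel noise (default 0).
#' @param dir Optional directory; when given, writes `func.nii.gz`,
#'   `labels.nii.gz`, `wm_mask.nii.gz`, `csf_mask.nii.gz`, `motion.txt`.
#' @return List with `image4d`, `parcellation`, `wm_mask`, `csf_mask`,
#'   `motion` and (if written) `paths`.
#' @export
render_nifti_fixture <- function(subject, layout = fixture_layout(),
                                 voxel_noise_sd = 0, dir = NULL) {
  assert_that(inherits(subject, "bg_subject"), "subject must be a bg_subject")
  assert_that(!is.null(subject$roi_timeseries),
              "subject has no imaging data (generate with components = 'imaging')")
  ts <- subject$roi_timeseries
  nvox <- prod(layout$dim)
  vpl <- layout$voxels_per_label
  tab <- aal116_labels()
  assert_that(nvox >= 116L * vpl + 4L,
              "layout too small: %d voxels for %d needed", nvox,
              116L * vpl + 4L)
  T <- nrow(ts$data)
  labels <- integer(nvox)
  mat <- matrix(0, nvox, T)
  for (j in seq_len(116L)) {
    vox <- ((j - 1L) * vpl + 1L):(j * vpl)
    labels[vox] <- tab$label[j]
    base <- matrix(rep(ts$data[, j], each = vpl), vpl, T)
    if (voxel_noise_sd > 0) {
      base <- base + matrix(rnorm(vpl * T, 0, voxel_noise_sd), vpl, T)
    }
    mat[vox, ] <- base
  }
  wm_vox <- 116L * vpl + 1:2
  csf_vox <- 116L * vpl + 3:4
  mat[wm_vox, ] <- rep(subject$confounds$wm, each = 2)
  mat[csf_vox, ] <- rep(subject$confounds$csf, each = 2)
  wm_mask <- csf_mask <- array(0L, layout$dim)
  wm_mask[wm_vox] <- 1L; csf_mask[csf_vox] <- 1L
  image4d <- array(mat, c(layout$dim, T))
  parc <- parcellation(array(labels, layout$dim), tab)
  out <- list(image4d = image4d, parcellation = parc, wm_mask = wm_mask,
              csf_mask = csf_mask, motion = subject$confounds$motion)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- file.path(dir, c("func.nii.gz", "labels.nii.gz",
                              "wm_mask.nii.gz", "csf_mask.nii.gz",
                              "motion.txt"))
    RNifti::writeNifti(RNifti::asNifti(image4d), paths[1])
    RNifti::writeNifti(RNifti::asNifti(array(labels, layout$dim)), paths[2])
    RNifti::writeNifti(RNifti::asNifti(wm_mask), paths[3])
    RNifti::writeNifti(RNifti::asNifti(csf_mask), paths[4])
    utils::write.table(subject$confounds$motion, paths[5],
                       row.names = FALSE, col.names = FALSE)
    out$paths <- paths
  }
  out
}

#' Write a cohort to disk as plain-text tables
#'
#' One ROI time-series TSV and one confound TSV per subject, a cohort
#' behaviour TSV, the schedule TSV and a JSON manifest.
#'
#' @param cohort A `bg_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in cohort$subjects) {
    if (!is.null(s$roi_timeseries)) {
      write_roi_tsv(s$roi_timeseries,
                    file.path(dir, paste0(s$subject_id, "_roi.tsv")))
      write_confounds_tsv(s$confounds,
                          file.path(dir, paste0(s$subject_id, "_confounds.tsv")))
    }
  }
  utils::write.table(cohort$behaviour, file.path(dir, "behaviour.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_schedule(cohort$schedule, file.path(dir, "schedule.tsv"))
  meta <- data.frame(
    subject = names(cohort$subjects),
    group = vapply(cohort$subjects, `[[`, "", "group"),
    condition = vapply(cohort$subjects, `[[`, "", "condition")
  )
  utils::write.table(meta, file.path(dir, "subjects.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(tr_seconds = cohort$spec$tr_seconds,
                            seed = cohort$seed),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a cohort previously written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @return A `bg_cohort` (without generator calibration metadata).
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  tr <- manifest$tr_seconds
  meta <- utils::read.delim(file.path(dir, "subjects.tsv"),
                            stringsAsFactors = FALSE)
  behaviour <- utils::read.delim(file.path(dir, "behaviour.tsv"),
                                 stringsAsFactors = FALSE)
  schedule <- read_schedule(file.path(dir, "schedule.tsv"))
  subjects <- lapply(seq_len(nrow(meta)), function(i) {
    id <- meta$subject[i]
    roi_path <- file.path(dir, paste0(id, "_roi.tsv"))
    ts <- if (file.exists(roi_path)) read_roi_tsv(roi_path, tr) else NULL
    cf <- if (file.exists(roi_path))
      read_confounds_tsv(file.path(dir, paste0(id, "_confounds.tsv"))) else NULL
    structure(list(subject_id = id, group = meta$group[i],
                   condition = meta$condition[i], roi_timeseries = ts,
                   confounds = cf,
                   behaviour = behaviour[behaviour$subject == id, , drop = FALSE],
                   latents = NULL), class = "bg_subject")
  })
  names(subjects) <- meta$subject
  structure(list(subjects = subjects, behaviour = behaviour,
                 schedule = schedule, spec = NULL,
                 seed = manifest$seed, calibration = NULL, planted = NULL),
            class = "bg_cohort")
}
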