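#' Per-subject connectivity analysis
#'
#' Cleans a subject's ROI time series (nuisance regression then bandpass),
#' segments by task, and computes the Fisher-z connectivity matrix plus the
#' local and global basal-ganglia statistics, for the full task segments and
#' for single blocks.
#'
#' @param subject A `bg_subject` with imaging data.
#' @param schedule A `bg_schedule`.
#' @param cleaning A `bg_cleaning_config`.
#' @param tasks Tasks to analyse (default the alertness tasks T2, T3).
#' @param blocks Block numbers for single-block statistics (default 1 and 4).
#' @param hrf_lag_seconds Segmentation window shift (default 0).
#' @return List of data.frames `local`, `global`, `block_global`.
#' @export
subject_fc_stats <- function(subject, schedule, cleaning = cleaning_config(),
                             tasks = c("T2", "T3"), blocks = c(1L, 4L),
                             hrf_lag_seconds = 0) {
  clean <- clean_roi_timeseries(subject$roi_timeseries, subject$confounds,
                                cleaning)
  id <- subject$subject_id
  loc <- list(); glob <- list(); blk <- list()
  for (tk in tasks) {
    seg <- segment_by_task(clean, schedule, tk, hrf_lag_seconds)
    z <- fisher_z(correlation_matrix(seg))
    for (p in names(bg_pairs())) {
      loc[[length(loc) + 1L]] <- data.frame(
        subject = id, group = subject$group, condition = subject$condition,
        task = tk, pair = p, z = local_bg_fc(z, p))
    }
    for (s in names(bg_seeds())) {
      glob[[length(glob) + 1L]] <- data.frame(
        subject = id, group = subject$group, condition = subject$condition,
        task = tk, seed = s, z = global_bg_fc(z, s))
    }
    for (b in blocks) {
      zb <- fisher_z(correlation_matrix(
        segment_single_block(clean, schedule, tk, b, hrf_lag_seconds)))
      for (s in names(bg_seeds())) {
        blk[[length(blk) + 1L]] <- data.frame(
          subject = id, group = subject$group, condition = subject$condition,
          task = tk, block = b, seed = s, z = global_bg_fc(zb, s))
      }
    }
  }
  list(local = do.call(rbind, loc), global = do.call(rbind, glob),
       block_global = do.call(rbind, blk))
}

#' Behavioural summary measures per subject
#'
#' Task-mean reaction time and high-force summaries plus FSS/HADS and the
#' block-1 vs block-4 fatigue deltas, one row per subject.
#'
#' @param behaviour Cohort behaviour table.
#' @return data.frame with one row per subject.
#' @export
behaviour_measures <- function(behaviour) {
  fm <- fatigue_measures(behaviour)
  per_subject <- function(d) {
    tmean <- function(task, col) {
      v <- d[[col]][d$task == task]
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }
    fms <- fm[fm$subject == d$subject[1], ]
    data.frame(
      subject = d$subject[1], group = d$group[1], condition = d$condition[1],
      fss = d$fss[1], hads_anxiety = d$hads_anxiety[1],
      hads_depression = d$hads_depression[1],
      t2_rt = tmean("T2", "mean_rt_ms"), t3_rt = tmean("T3", "mean_rt_ms"),
      t2_force = tmean("T2", "mean_peak_force"),
      t3_force = tmean("T3", "mean_peak_force"),
      t2_cognitive_fatigue = fms$cognitive_fatigue_ms[fms$task == "T2"],
      t3_cognitive_fatigue = fms$cognitive_fatigue_ms[fms$task == "T3"],
      t2_physical_fatigue = fms$physical_fatigue[fms$task == "T2"],
      t3_physical_fatigue = fms$physical_fatigue[fms$task == "T3"]
    )
  }
  out <- do.call(rbind, lapply(split(behaviour, behaviour$subject),
                               per_subject))
  rownames(out) <- NULL
  out
}

group_summary_t <- function(d, value = "z", welch = FALSE) {
  hc <- d[[value]][d$group == "HC"]
  ms <- d[[value]][d$group == "MS"]
  tt <- two_sample_t(length(hc), mean(hc), stats::sd(hc),
                     length(ms), mean(ms), stats::sd(ms), welch = welch)
  data.frame(hc_n = length(hc), hc_mean = mean(hc), hc_sd = stats::sd(hc),
             ms_n = length(ms), ms_mean = mean(ms), ms_sd = stats::sd(ms),
             t = tt$t, df = tt$df, p = tt$p, cohens_d = abs(tt$d),
             method = if (welch) "welch" else "pooled")
}

report_local_fc <- function(local, fdr_q) {
  out <- do.call(rbind, lapply(split(local, list(local$task, local$pair)),
    function(d) cbind(data.frame(task = d$task[1], pair = d$pair[1]),
                      group_summary_t(d))))
  out <- out[order(out$task, match(out$pair, names(bg_pairs()))), ]
  out$fdr_significant <- bh_fdr(out$p, fdr_q)
  rownames(out) <- NULL
  out
}

report_global_group_tests <- function(global, fdr_q) {
  # unequal-variance (Welch) form for the seed-to-cortex contrasts
  out <- do.call(rbind, lapply(split(global, list(global$task, global$seed)),
    function(d) cbind(data.frame(task = d$task[1], seed = d$seed[1]),
                      group_summary_t(d, welch = TRUE))))
  out <- out[order(out$task, match(out$seed, names(bg_seeds()))), ]
  out$fdr_significant <- bh_fdr(out$p, fdr_q)
  rownames(out) <- NULL
  out
}

report_correlations <- function(local, measures, fdr_q) {
  behav <- correlation_table(measures,
                             list(c("fss", "t2_rt"), c("fss", "t3_rt"),
                                  c("fss", "t2_force"), c("fss", "t3_force")))
  behav <- cbind(data.frame(task = "pooled", pair = "behaviour"), behav)
  wide <- merge(measures,
                stats::reshape(local[, c("subject", "task", "pair", "z")],
                               direction = "wide",
                               idvar = c("subject", "pair"),
                               timevar = "task"),
                by = "subject")
  fc_rows <- do.call(rbind, lapply(c("T2", "T3"), function(tk) {
    zcol <- paste0("z.", tk)
    do.call(rbind, lapply(names(bg_pairs()), function(p) {
      d <- wide[wide$pair == p, ]
      d$fc <- d[[zcol]]
      ct <- correlation_table(
        d, list(c("fc", "fss"), c("fc", "t2_rt"), c("fc", "t3_rt"),
                c("fc", "t2_force"), c("fc", "t3_force")),
        group_by = "group")
      cbind(data.frame(task = tk, pair = p), ct)
    }))
  }))
  out <- rbind(behav, fc_rows)
  out$fdr_significant <- bh_fdr(out$p, fdr_q)
  rownames(out) <- NULL
  out
}

report_block_global <- function(block_global) {
  combos <- list(c("HC", "T2"), c("MS", "T2"), c("MS", "T3"))
  out <- do.call(rbind, lapply(combos, function(cm) {
    d <- block_global[block_global$group == cm[1] & block_global$task == cm[2], ]
    do.call(rbind, lapply(split(d, list(d$condition, d$seed)), function(e) {
      w <- stats::reshape(e[, c("subject", "block", "z")],
                          direction = "wide", idvar = "subject",
                          timevar = "block")
      pt <- paired_t(w$z.1, w$z.4)
      data.frame(group = cm[1], task = cm[2], condition = e$condition[1],
                 seed = e$seed[1], n = nrow(w),
                 block1_mean = mean(w$z.1), block1_sd = stats::sd(w$z.1),
                 block4_mean = mean(w$z.4), block4_sd = stats::sd(w$z.4),
                 t = pt$t, df = pt$df, p = pt$p)
    }))
  }))
  out <- out[order(out$group, out$task, out$condition,
                   match(out$seed, names(bg_seeds()))), ]
  rownames(out) <- NULL
  out
}

report_rt_anova <- function(measures) {
  long <- rbind(
    data.frame(subject = measures$subject, group = measures$group,
               task = "T2", value = measures$t2_rt),
    data.frame(subject = measures$subject, group = measures$group,
               task = "T3", value = measures$t3_rt)
  )
  long <- long[stats::complete.cases(long), ]
  an <- mixed_anova_2x2(long)
  data.frame(
    effect = c("task", "diagnosis", "interaction"),
    F = c(an$task$F, an$diagnosis$F, an$interaction$F),
    df1 = c(an$task$df[1], an$diagnosis$df[1], an$interaction$df[1]),
    df2 = c(an$task$df[2], an$diagnosis$df[2], an$interaction$df[2]),
    p = c(an$task$p, an$diagnosis$p, an$interaction$p),
    partial_eta_sq = c(an$task$partial_eta_sq, an$diagnosis$partial_eta_sq,
                       an$interaction$partial_eta_sq)
  )
}

read_nifti_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  tr <- manifest$tr_seconds
  meta <- utils::read.delim(file.path(dir, "subjects.tsv"),
                            stringsAsFactors = FALSE)
  behaviour <- utils::read.delim(file.path(dir, "behaviour.tsv"),
                                 stringsAsFactors = FALSE)
  schedule <- read_schedule(file.path(dir, "schedule.tsv"))
  parc <- NULL
  subjects <- lapply(seq_len(nrow(meta)), function(i) {
    sd_ <- file.path(dir, meta$subject[i])
    img <- RNifti::readNifti(file.path(sd_, "func.nii.gz"))
    if (is.null(parc)) {
      parc <<- parcellation(array(as.integer(
        RNifti::readNifti(file.path(sd_, "labels.nii.gz"))),
        dim(img)[1:3]))
    }
    ts <- extract_roi_timeseries(img, parc, tr)
    cf <- extract_confounds(
      img,
      array(as.integer(RNifti::readNifti(file.path(sd_, "wm_mask.nii.gz"))),
            dim(img)[1:3]),
      array(as.integer(RNifti::readNifti(file.path(sd_, "csf_mask.nii.gz"))),
            dim(img)[1:3]),
      read_motion_params(file.path(sd_, "motion.txt")))
    structure(list(subject_id = meta$subject[i], group = meta$group[i],
                   condition = meta$condition[i], roi_timeseries = ts,
                   confounds = cf,
                   behaviour = behaviour[behaviour$subject == meta$subject[i], ],
                   latents = NULL), class = "bg_subject")
  })
  names(subjects) <- meta$subject
  structure(list(subjects = subjects, behaviour = behaviour,
                 schedule = schedule, spec = NULL, seed = manifest$seed,
                 calibration = NULL, planted = NULL), class = "bg_cohort")
}

#' Run the full analysis pipeline
#'
#' Acquires a cohort (synthetic generation, a TSV cohort directory, or a
#' NIfTI cohort directory), applies the reaction-time outlier filter, cleans
#' and segments each retained subject's time series, computes connectivity
#' statistics, and produces the group-level report tables: local FC group
#' contrasts, global FC group contrasts, FC/behaviour correlation table,
#' block-1 vs block-4 global FC contrasts, and the 2x2 mixed RT ANOVA.
#'
#' @param mode `"synthetic"`, `"tsv"` or `"nifti"`.
#' @param seed Integer seed (synthetic mode).
#' @param input_dir Cohort directory (tsv/nifti modes).
#' @param spec `bg_cohort_spec` for synthetic mode (default
#'   `cohort_spec()`).
#' @param cleaning A `bg_cleaning_config`; defaults to the spec's (synthetic
#'   mode) or the package default.
#' @param fdr_q FDR level for report tables (default 0.10).
#' @param hrf_lag_seconds Segmentation window shift (default 0).
#' @param out_dir Optional output directory for report TSVs and manifest.
#' @return A `bg_report`: list with `tables` (named list of data.frames),
#'   `subject_stats`, `measures`, `outlier_report`, `screening`, `manifest`.
#' @export
run_pipeline <- function(mode = c("synthetic", "tsv", "nifti"), seed = 1L,
                         input_dir = NULL, spec = NULL, cleaning = NULL,
                         fdr_q = 0.10, hrf_lag_seconds = 0, out_dir = NULL) {
  mode <- match.arg(mode)
  assert_that(fdr_q > 0 && fdr_q < 1, "fdr_q must be in (0, 1)")
  cohort <- switch(mode,
    synthetic = {
      if (is.null(spec)) spec <- cohort_spec()
      generate_cohort(spec, seed)
    },
    tsv = {
      assert_that(!is.null(input_dir), "tsv mode requires input_dir")
      read_cohort(input_dir)
    },
    nifti = {
      assert_that(!is.null(input_dir), "nifti mode requires input_dir")
      read_nifti_cohort(input_dir)
    })
  if (is.null(cleaning)) {
    cleaning <- if (!is.null(cohort$spec)) cohort$spec$cleaning else
      cleaning_config()
  }

  filt <- filter_rt_outliers(cohort$behaviour)
  retained_ids <- unique(filt$retained$subject)
  measures <- behaviour_measures(filt$retained)
  screening <- screen_inclusion(data.frame(
    subject = measures$subject, group = measures$group,
    fss_total = measures$fss, hads_anxiety = measures$hads_anxiety,
    hads_depression = measures$hads_depression))

  subjects <- cohort$subjects[retained_ids]
  has_img <- vapply(subjects, function(s) !is.null(s$roi_timeseries), TRUE)
  stats_list <- lapply(subjects[has_img], function(s) {
    tryCatch(
      subject_fc_stats(s, cohort$schedule, cleaning,
                       hrf_lag_seconds = hrf_lag_seconds),
      error = function(e) stopf("connectivity stage failed for subject %s: %s",
                                s$subject_id, conditionMessage(e)))
  })
  bindf <- function(name) do.call(rbind, c(lapply(stats_list, `[[`, name),
                                           list(make.row.names = FALSE)))
  tables <- list(outlier_report = filt$report, screening = screening)
  local <- global <- block_global <- NULL
  if (any(has_img)) {
    local <- bindf("local"); global <- bindf("global")
    block_global <- bindf("block_global")
    tables$local_fc <- report_local_fc(local, fdr_q)
    tables$global_fc_group <- report_global_group_tests(global, fdr_q)
    tables$correlations <- report_correlations(local, measures, fdr_q)
    tables$block_global_fc <- report_block_global(block_global)
  }
  tables$rt_anova <- report_rt_anova(measures)

  manifest <- list(
    mode = mode, seed = if (mode == "synthetic") seed else cohort$seed,
    package_version = as.character(utils::packageVersion("bgfc")),
    n_subjects = length(cohort$subjects),
    n_retained = length(retained_ids),
    n_with_imaging = sum(has_img),
    fdr_q = fdr_q,
    cleaning = unclass(cleaning),
    stage_rows = lapply(tables, nrow)
  )
  report <- structure(list(tables = tables,
                           subject_stats = list(local = local, global = global,
                                                block_global = block_global),
                           measures = measures,
                           outlier_report = filt$report,
                           screening = screening, manifest = manifest),
                      class = "bg_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.bg_report <- function(x, ...) {
  cat(sprintf("bgfc report: %d subjects retained (%d with imaging)\n",
              x$manifest$n_retained, x$manifest$n_with_imaging))
  cat("tables:", paste(names(x$tables), collapse = ", "), "\n")
  invisible(x)
}

#' Write report tables to a directory
#' @param report A `bg_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(report$tables)) {
    utils::write.table(report$tables[[nm]],
                       file.path(dir, paste0(nm, ".tsv")), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(report$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
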