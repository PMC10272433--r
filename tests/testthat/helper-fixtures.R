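# Shared fixtures, built in code at test time.

# A task segment wrapper around an arbitrary matrix (for connectivity tests
# that do not need a schedule).
make_segment <- function(X, region_names = paste0("R", seq_len(ncol(X))),
                         task = "T2", tr = 0.906) {
  colnames(X) <- region_names
  structure(list(task = task, data = X, block_boundaries = integer(0),
                 block_rows = list(seq_len(nrow(X))), tr_seconds = tr,
                 region_names = region_names),
            class = "bg_task_segment")
}

# A symmetric fisher-z FC matrix over the full atlas with constant value.
constant_z_matrix <- function(value, task = "T2") {
  nm <- aal116_labels()$name
  m <- matrix(value, 116, 116)
  diag(m) <- 0
  fc_matrix(m, "fisher_z", nm, task = task)
}

# Overrides that switch off outlier planting.
no_outliers <- list(
  hc = list(handgrip_only = 0, mental_imagery_first = 0),
  ms = list(handgrip_only = 0, mental_imagery_first = 0)
)

# Small cohort spec for pipeline tests: 4 + 4 subjects, no planted outliers.
tiny_spec <- function(n = 4L) {
  cohort_spec(overrides = list(cohort = list(n_hc = n, n_ms = n),
                               outliers = no_outliers))
}

# ROI time-series set filled with random data.
random_ts <- function(T = 120, R = 8, tr = 0.906, seed = 1) {
  set.seed(seed)
  roi_timeseries(matrix(rnorm(T * R), T, R), tr,
                 region_names = paste0("R", seq_len(R)))
}

random_confounds <- function(T = 120, seed = 2) {
  set.seed(seed)
  confound_set(rnorm(T), rnorm(T), matrix(rnorm(T * 6), T, 6))
}
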