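#' Cleaning configuration
#'
#' Parameters of the temporal cleaning applied to ROI time series: least
#' squares nuisance regression followed by a zero-phase Butterworth bandpass.
#' The passband (0.01-0.08) is read in Hz, the convention of the
#' functional-connectivity literature. `filter_order` is the Butterworth
#' order per band edge, so the default 2 yields a 4-pole bandpass.
#'
#' @param band_low_hz Lower passband edge in Hz (default 0.01).
#' @param band_high_hz Upper passband edge in Hz (default 0.08).
#' @param filter_order Butterworth order per band edge (default 2).
#' @param detrend Remove a linear trend before filtering (default TRUE).
#' @return A `bg_cleaning_config` list.
#' @export
cleaning_config <- function(band_low_hz = 0.01, band_high_hz = 0.08,
                            filter_order = 2L, detrend = TRUE) {
  assert_that(band_low_hz > 0 && band_high_hz > band_low_hz,
              "need 0 < band_low_hz < band_high_hz")
  assert_that(is_count(filter_order) && filter_order >= 1,
              "filter_order must be a positive integer")
  structure(list(band_low_hz = band_low_hz, band_high_hz = band_high_hz,
                 filter_order = as.integer(filter_order),
                 detrend = isTRUE(detrend)),
            class = "bg_cleaning_config")
}

butter_coefficients <- function(cfg, tr_seconds) {
  nyq <- 1 / (2 * tr_seconds)
  assert_that(cfg$band_high_hz < nyq,
              "band_high_hz (%g) must be below the Nyquist frequency (%g Hz)",
              cfg$band_high_hz, nyq)
  bt <- signal::butter(cfg$filter_order,
                       c(cfg$band_low_hz, cfg$band_high_hz) / nyq,
                       type = "pass")
  list(b = bt$b / bt$a[1], a = bt$a / bt$a[1])
}

# Steady-state filter state for a unit step input (direct form II transposed).
lfilter_zi <- function(b, a) {
  n <- length(a) - 1L
  A <- rbind(-a[-1], cbind(diag(1, n - 1L), 0))
  B <- b[-1] - a[-1] * b[1]
  as.numeric(solve(diag(n) - t(A), B))
}

filter_pad_length <- function(cfg, tr_seconds, T) {
  # two time constants of the high-pass corner, clamped to the series length
  as.integer(min(T - 1L, ceiling(2 / (cfg$band_low_hz * tr_seconds))))
}

filtfilt_matrix <- function(X, cfg, tr_seconds) {
  co <- butter_coefficients(cfg, tr_seconds)
  pad <- filter_pad_length(cfg, tr_seconds, nrow(X))
  cpp_filtfilt(co$b, co$a, X, pad, lfilter_zi(co$b, co$a))
}

#' Regress nuisance signals out of ROI time series
#'
#' Each output column is the least-squares residual of the input column on
#' an intercept plus the eight confound regressors (white matter, CSF, six
#' motion parameters). Residuals are orthogonal to every regressor. The
#' regression operates at ROI level; because ROI averaging and least squares
#' projection are both linear and all voxels of an ROI share the confounds,
#' this equals voxel-level regression followed by averaging.
#'
#' @param ts A `bg_roi_ts`.
#' @param confounds A `bg_confounds` of matching length.
#' @return A cleaned `bg_roi_ts`.
#' @export
regress_nuisance <- function(ts, confounds) {
  assert_that(inherits(ts, "bg_roi_ts"), "ts must be a bg_roi_ts")
  C <- as_confound_matrix(confounds)
  assert_that(nrow(C) == nrow(ts$data),
              "confound length (%d) does not match series length (%d)",
              nrow(C), nrow(ts$data))
  X <- cbind(intercept = 1, C)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stopf("confound design matrix is rank deficient; collinear columns: %s",
          paste(bad, collapse = ", "))
  }
  res <- qr.resid(qrX, ts$data)
  roi_timeseries(res, ts$tr_seconds, ts$region_names)
}

#' Zero-phase bandpass filter
#'
#' Butterworth bandpass applied forward and backward (zero phase). Columns
#' are extended by odd reflection and each pass starts from the steady-state
#' response to the first sample, so there is no edge transient: a constant
#' series maps to (numerically) zero. An optional linear detrend is applied
#' first.
#'
#' @param ts A `bg_roi_ts`.
#' @param cfg A `bg_cleaning_config`.
#' @return A filtered `bg_roi_ts`.
#' @export
bandpass <- function(ts, cfg = cleaning_config()) {
  assert_that(inherits(ts, "bg_roi_ts"), "ts must be a bg_roi_ts")
  T <- nrow(ts$data)
  min_len <- 9L * (2L * cfg$filter_order + 1L)
  if (T < min_len) {
    stopf("series too short for stable filtering (%d volumes; need >= %d)",
          T, min_len)
  }
  X <- ts$data
  if (cfg$detrend) {
    X <- qr.resid(qr(cbind(1, seq_len(T))), X)
  }
  roi_timeseries(filtfilt_matrix(X, cfg, ts$tr_seconds), ts$tr_seconds,
                 ts$region_names)
}

#' Full cleaning pipeline
#'
#' Nuisance regression followed by bandpass filtering, in that fixed order.
#'
#' @inheritParams regress_nuisance
#' @inheritParams bandpass
#' @return A cleaned `bg_roi_ts`.
#' @export
clean_roi_timeseries <- function(ts, confounds, cfg = cleaning_config()) {
  bandpass(regress_nuisance(ts, confounds), cfg)
}

# Lag autocorrelation of white noise passed through the zero-phase filter
# (power transfer |H|^4), via FFT of the squared power response.
filter_lag_autocorrelation <- function(cfg, tr_seconds, n_lags) {
  co <- butter_coefficients(cfg, tr_seconds)
  nfft <- 2^ceiling(log2(max(4 * (n_lags + 1L), 4096)))
  w <- 2 * pi * (seq_len(nfft) - 1) / nfft
  resp <- function(coef) {
    vapply(w, function(om) sum(coef * exp(-1i * om * (seq_along(coef) - 1))),
           complex(1))
  }
  p <- Mod(resp(co$b) / resp(co$a))^4
  acf <- Re(stats::fft(p, inverse = TRUE))
  (acf / acf[1])[seq_len(n_lags + 1L)]
}

# Effective number of independent samples for a correlation computed over
# n_blocks concatenated blocks of block_len filtered volumes (Bartlett).
effective_samples <- function(cfg, tr_seconds, block_len, n_blocks) {
  rho <- filter_lag_autocorrelation(cfg, tr_seconds, block_len - 1L)
  k <- seq_len(block_len - 1L)
  denom <- 1 + 2 * sum((1 - k / block_len) * rho[k + 1L]^2)
  block_len * n_blocks / denom
}
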