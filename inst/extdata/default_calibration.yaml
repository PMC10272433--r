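# Default synthetic-cohort calibration.
# Connectivity targets (Fisher z, group mean and observed between-subject SD)
# and force block means are transcribed from the source study's report
# tables; quantities the study does not print (RT levels in ms, FSS/HADS
# distribution parameters, background coupling) are package defaults chosen
# once as field-realistic values and documented in the methods vignette.
cohort:
  n_hc: 40
  n_ms: 40
  tr_seconds: 0.906
conditions:                 # per-group condition arm counts (pre-filter)
  handgrip_only:        {hc: 21, ms: 21}
  mental_imagery_first: {hc: 19, ms: 19}
outliers:                   # planted RT outliers (removed by the 2 SD filter)
  hc: {handgrip_only: 2, mental_imagery_first: 2}
  ms: {handgrip_only: 2, mental_imagery_first: 1}
coupling:                   # local BG coupling, Fisher z mean / observed SD
  intrinsic:
    Caudate-Putamen:  {hc_mean: 0.25, hc_sd: 0.15, ms_mean: 0.30, ms_sd: 0.23}
    Caudate-Pallidum: {hc_mean: 0.28, hc_sd: 0.14, ms_mean: 0.30, ms_sd: 0.21}
    Putamen-Pallidum: {hc_mean: 1.21, hc_sd: 0.21, ms_mean: 1.05, ms_sd: 0.21}
  extrinsic:
    Caudate-Putamen:  {hc_mean: 0.29, hc_sd: 0.19, ms_mean: 0.29, ms_sd: 0.17}
    Caudate-Pallidum: {hc_mean: 0.27, hc_sd: 0.17, ms_mean: 0.30, ms_sd: 0.17}
    Putamen-Pallidum: {hc_mean: 1.18, hc_sd: 0.21, ms_mean: 1.05, ms_sd: 0.23}
background:                 # uncalibrated couplings (package defaults)
  homotopic_bg_z: 1.80      # L-R edge within each BG structure; must exceed
                            # the strongest cross-structure coupling draw for
                            # the joint correlation target to stay feasible
  bg_cortex_z: 0.40         # BG seed to non-BG regions (global FC level)
  bg_cortex_sd: 0.05
  cortex_cortex_z: 0.50     # non-BG to non-BG background
  cortex_cortex_sd: 0.05
  pair_factor_corr: 0.5     # correlation of per-pair subject coupling factors
behaviour:
  fss:
    hc: {mean: 23.5, sd: 5.5, min: 9,  max: 35}
    ms: {mean: 48.0, sd: 5.5, min: 36, max: 63}
  fss_rt_corr_t2_pooled: 0.476
  fc_behaviour_corr:        # Putamen-Pallidum intrinsic z-FC vs behaviour
    hc: {fss: -0.36, t2_rt: -0.38}
    ms: {fss: -0.38, t2_rt: -0.42}
  rt:
    subject_sd_ms: 70
    block_sd_ms: 35
    block_means_ms:         # [block 1, block 4]; blocks 2-3 interpolated
      hc:
        handgrip_only:        {intrinsic: [400, 440], extrinsic: [385, 395]}
        mental_imagery_first: {intrinsic: [420, 417], extrinsic: [390, 392]}
      ms:
        handgrip_only:        {intrinsic: [480, 520], extrinsic: [455, 475]}
        mental_imagery_first: {intrinsic: [495, 510], extrinsic: [460, 495]}
  force:
    subject_sd: 2.5
    block_sd: 2.0
    block_means_high:       # high-force M1, M4 per group x condition x task
      hc:
        handgrip_only:        {intrinsic: [11.01, 10.95], extrinsic: [11.90, 11.01]}
        mental_imagery_first: {intrinsic: [11.65, 10.95], extrinsic: [11.58, 11.02]}
      ms:
        handgrip_only:        {intrinsic: [9.83, 9.31],   extrinsic: [10.68, 9.76]}
        mental_imagery_first: {intrinsic: [7.30, 6.85],   extrinsic: [6.71, 6.05]}
  hads: {mean: 5, sd: 3, max: 12}
noise:
  confound_amplitude: 0.20  # confound contribution, fraction of signal SD
  white_noise_sd: 0.20      # iid measurement noise, fraction of signal SD
schedule:
  block_volumes: 80
  rest_volumes: 0
cleaning:
  band_low_hz: 0.01
  band_high_hz: 0.08
  filter_order: 2
  detrend: true
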