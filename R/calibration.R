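# Internal calibration machinery of the synthetic-cohort generator.
#
# The generator is calibrated so that quantities measured AFTER the standard
# cleaning/segmentation/connectivity pipeline hit their target values: the
# finite filtered segment makes each subject's sample Fisher-z FC a noisy,
# slightly biased estimate of the subject's generative coupling, so target
# means are bias-corrected and target SDs/correlations are decomposed into a
# latent component plus estimation noise. Estimation noise is predicted
# analytically from (i) the effective number of independent samples in a
# bandpassed task segment (Bartlett) and (ii) the asymptotic covariance of
# sample correlations sharing regions (Olkin-Siotani), both validated against
# simulation in the test suite.

TASK_OF <- c(intrinsic = "T2", extrinsic = "T3")

# Asymptotic covariance of sample correlations r_ij, r_kl (times n).
corr_estimator_cov <- function(R, i, j, k, l, n) {
  (0.5 * R[i, j] * R[k, l] * (R[i, k]^2 + R[i, l]^2 + R[j, k]^2 + R[j, l]^2) +
     R[i, k] * R[j, l] + R[i, l] * R[j, k] -
     R[i, j] * (R[j, k] * R[j, l] + R[i, k] * R[i, l]) -
     R[k, l] * (R[i, k] * R[j, k] + R[i, l] * R[j, l])) / n
}

# SD of the 4-edge-mean Fisher z estimate for one bilateral structure pair.
edge_mean_z_sd <- function(r_cross, r_homotopic, n_eff) {
  R4 <- matrix(r_cross, 4, 4)
  diag(R4) <- 1
  R4[1, 2] <- R4[2, 1] <- r_homotopic
  R4[3, 4] <- R4[4, 3] <- r_homotopic
  edges <- list(c(1, 3), c(1, 4), c(2, 3), c(2, 4))
  S <- matrix(NA_real_, 4, 4)
  for (u in 1:4) for (v in 1:4) {
    e1 <- edges[[u]]; e2 <- edges[[v]]
    S[u, v] <- corr_estimator_cov(R4, e1[1], e1[2], e2[1], e2[2], n_eff) /
      ((1 - R4[e1[1], e1[2]]^2) * (1 - R4[e2[1], e2[2]]^2))
  }
  sqrt(mean(S))
}

# First-order upward bias of the sample Fisher z for true correlation r.
fisher_mean_bias <- function(r, n_eff) r / (2 * (n_eff - 1))

# Linear interpolation of the four block means from the (block1, block4) pair.
interp_blocks <- function(m14) {
  m14[1] + (m14[2] - m14[1]) * (0:3) / 3
}

# Non-planted subject counts per condition arm, used as calibration weights.
retained_condition_counts <- function(spec, group) {
  g <- tolower(group)
  vapply(c("handgrip_only", "mental_imagery_first"), function(cd) {
    spec$conditions[[cd]][[g]] - spec$outliers[[g]][[cd]]
  }, 1)
}

# Observed T2 mean-RT moments for the non-outlier population of one group
# (subject effect eta enters via var_eta_post, set by the caller).
rt_observed_moments <- function(spec, group, task_name = "intrinsic") {
  beh <- spec$behaviour$rt
  g <- tolower(group)
  w <- retained_condition_counts(spec, group)
  w <- w / sum(w)
  cond_means <- vapply(names(w), function(cd) {
    mean(interp_blocks(beh$block_means_ms[[g]][[cd]][[task_name]]))
  }, 1)
  mu <- sum(w * cond_means)
  var_cond <- sum(w * (cond_means - mu)^2)
  list(mu = mu, var_cond = var_cond,
       var_block = beh$block_sd_ms^2 / 4)
}

# Solve the latent correlation structure linking FSS, the subject RT effect
# and the Putamen-Pallidum coupling factor so that the OBSERVED (post
# truncation, post estimation-noise) correlations hit their calibrated
# targets. Returns per-group latent 3x3 correlation matrices and scales.
solve_behaviour_latents <- function(spec, coupling_cal, n_eff) {
  beh <- spec$behaviour
  groups <- c("HC", "MS")
  tm <- lapply(groups, function(g) {
    f <- beh$fss[[tolower(g)]]
    truncnorm_moments(f$min, f$max, f$mean, f$sd)
  })
  names(tm) <- groups
  rtm <- lapply(groups, function(g) rt_observed_moments(spec, g))
  names(rtm) <- groups
  su <- beh$rt$subject_sd_ms
  n_ret <- vapply(groups, function(g) sum(retained_condition_counts(spec, g)), 1)
  p_g <- n_ret / sum(n_ret)

  # pooled FSS vs T2 mean RT correlation as a function of the common latent
  # FSS-RT correlation rho
  pooled_corr <- function(rho) {
    st <- lapply(groups, function(g) {
      v <- tm[[g]]$v
      f <- beh$fss[[tolower(g)]]
      list(muF = tm[[g]]$mean, varF = tm[[g]]$var,
           muR = rtm[[g]]$mu,
           varR = su^2 * (1 - rho^2 * (1 - v)) + rtm[[g]]$var_cond +
             rtm[[g]]$var_block,
           covFR = f$sd * su * rho * v)
    })
    names(st) <- groups
    muF <- sum(p_g * vapply(st, `[[`, 1, "muF"))
    muR <- sum(p_g * vapply(st, `[[`, 1, "muR"))
    cv <- sum(p_g * vapply(groups, function(g)
      st[[g]]$covFR + (st[[g]]$muF - muF) * (st[[g]]$muR - muR), 1))
    vF <- sum(p_g * vapply(groups, function(g)
      st[[g]]$varF + (st[[g]]$muF - muF)^2, 1))
    vR <- sum(p_g * vapply(groups, function(g)
      st[[g]]$varR + (st[[g]]$muR - muR)^2, 1))
    cv / sqrt(vF * vR)
  }
  target <- beh$fss_rt_corr_t2_pooled
  f <- function(rho) pooled_corr(rho) - target
  assert_that(f(-0.995) < 0 && f(0.995) > 0,
              "pooled FSS-RT correlation target %g is infeasible under the calibration",
              target)
  rho_xe <- stats::uniroot(f, c(-0.995, 0.995), tol = 1e-12)$root

  # per-group latent correlations of the Putamen-Pallidum coupling factor
  out <- lapply(groups, function(g) {
    v <- tm[[g]]$v
    fssd <- beh$fss[[tolower(g)]]$sd
    row <- coupling_cal[coupling_cal$group == g &
                          coupling_cal$pair == "Putamen-Pallidum" &
                          coupling_cal$task == "T2", ]
    sZ <- row$z_sd_obs
    sig_e <- row$sigma_e
    alpha <- beh$fc_behaviour_corr[[tolower(g)]]$fss
    bet <- beh$fc_behaviour_corr[[tolower(g)]]$t2_rt
    if (sZ^2 - sig_e^2 <= 0.02^2) {
      # estimation noise uses up the whole calibrated dispersion; only
      # feasible when no FC-behaviour correlation is being calibrated
      assert_that(alpha == 0 && bet == 0,
                  "estimation noise (%.3f) exhausts the calibrated coupling SD (%.3f) for %s; FC-behaviour targets are unreachable",
                  sig_e, sZ, g)
      sZ <- sqrt(sig_e^2 + 0.02^2)
    }
    sF_obs <- fssd * sqrt(v)
    sRT_obs <- sqrt(su^2 * (1 - rho_xe^2 * (1 - v)) + rtm[[g]]$var_cond +
                      rtm[[g]]$var_block)
    rho_xk <- 0; rho_ek <- 0; sc <- sqrt(sZ^2 - sig_e^2)
    for (it in 1:50) {
      var_k <- 1 - rho_xk^2 * (1 - v)
      sc <- sqrt((sZ^2 - sig_e^2) / var_k)
      rho_xk_new <- alpha * sZ * sF_obs / (sc * fssd * v)
      rho_ek_new <- bet * sZ * sRT_obs / (sc * su) +
        rho_xe * rho_xk_new * (1 - v)
      if (max(abs(rho_xk_new - rho_xk), abs(rho_ek_new - rho_ek)) < 1e-12) {
        rho_xk <- rho_xk_new; rho_ek <- rho_ek_new
        break
      }
      rho_xk <- rho_xk_new; rho_ek <- rho_ek_new
    }
    L <- matrix(c(1, rho_xe, rho_xk,
                  rho_xe, 1, rho_ek,
                  rho_xk, rho_ek, 1), 3, 3)
    ch <- tryCatch(chol(L), error = function(e) NULL)
    if (is.null(ch)) {
      stopf("latent FSS/RT/coupling correlation matrix for %s is not positive definite (%.2f, %.2f, %.2f); calibration targets jointly infeasible",
            g, rho_xe, rho_xk, rho_ek)
    }
    list(rho_xe = rho_xe, rho_xk = rho_xk, rho_ek = rho_ek, chol = ch,
         trunc = tm[[g]], sigma_c_pp = sc, sRT_obs = sRT_obs,
         sF_obs = sF_obs)
  })
  names(out) <- groups
  out
}

# Full calibration of the generator for a cohort spec: effective sample
# size, bias-corrected latent coupling table, behavioural latent structure,
# background coupling.
generator_calibration <- function(spec) {
  blk <- spec$schedule_cfg$block_volumes
  n_eff <- effective_samples(spec$cleaning, spec$tr_seconds, blk, 4L)
  r_hom <- tanh(spec$background$homotopic_bg_z)

  rows <- list()
  for (tk_name in names(TASK_OF)) {
    for (pair in names(bg_pairs())) {
      cp <- spec$coupling[[tk_name]][[pair]]
      for (g in c("HC", "MS")) {
        zm <- if (g == "HC") cp$hc_mean else cp$ms_mean
        zs <- if (g == "HC") cp$hc_sd else cp$ms_sd
        rows[[length(rows) + 1L]] <- data.frame(
          group = g, pair = pair, task = TASK_OF[[tk_name]],
          z_mean_obs = zm, z_sd_obs = zs)
      }
    }
  }
  cal <- do.call(rbind, rows)
  # sensorimotor control task: not calibrated by the report tables; use the
  # per-group mean of the two alertness tasks so that adjacent blocks have
  # near-identical coupling (limits filter leakage across block boundaries)
  t1 <- do.call(rbind, lapply(split(cal, list(cal$group, cal$pair)),
    function(d) data.frame(group = d$group[1], pair = d$pair[1], task = "T1",
                           z_mean_obs = mean(d$z_mean_obs),
                           z_sd_obs = mean(d$z_sd_obs))))
  cal <- rbind(cal, t1)
  cal$sigma_e <- mapply(function(zm) {
    edge_mean_z_sd(tanh(zm), r_hom, n_eff)
  }, cal$z_mean_obs)
  cal$sigma_lat <- sqrt(pmax(cal$z_sd_obs^2 - cal$sigma_e^2, 0.02^2))
  cal$mu_lat <- cal$z_mean_obs - fisher_mean_bias(tanh(cal$z_mean_obs), n_eff)
  rownames(cal) <- NULL

  latents <- solve_behaviour_latents(spec, cal, n_eff)
  # override the Putamen-Pallidum latent SD with the truncation-consistent
  # solve (T2; T3 keeps the same coupling factor with its own scale)
  for (g in c("HC", "MS")) {
    i <- cal$group == g & cal$pair == "Putamen-Pallidum" & cal$task == "T2"
    cal$sigma_lat[i] <- latents[[g]]$sigma_c_pp
  }

  bgc <- spec$background
  list(
    n_eff = n_eff,
    coupling = cal,
    latents = latents,
    bg_cortex_mu_lat = bgc$bg_cortex_z -
      fisher_mean_bias(tanh(bgc$bg_cortex_z), n_eff),
    bg_cortex_sd = bgc$bg_cortex_sd,
    cortex_cortex_z = bgc$cortex_cortex_z,
    cortex_cortex_sd = bgc$cortex_cortex_sd,
    homotopic_bg_z = bgc$homotopic_bg_z,
    pair_factor_corr = bgc$pair_factor_corr
  )
}
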