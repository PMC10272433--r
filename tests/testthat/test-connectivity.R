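test_that("correlation matrix matches the pairwise-loop oracle", {
  set.seed(31)
  X <- matrix(rnorm(40 * 5), 40, 5)
  m <- correlation_matrix(make_segment(X))
  # independent oracle: naive pairwise Pearson with explicit sums
  oracle <- matrix(1, 5, 5)
  for (i in 1:5) for (j in 1:5) {
    xi <- X[, i] - mean(X[, i]); xj <- X[, j] - mean(X[, j])
    oracle[i, j] <- sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
  }
  expect_lt(max(abs(m$values - oracle)), 1e-12)
  expect_equal(max(abs(m$values - t(m$values))), 0)
})

test_that("duplicated and negated columns give r = +/-1", {
  set.seed(32)
  x <- rnorm(30)
  X <- cbind(x, x, -(x - mean(x)))
  m <- correlation_matrix(make_segment(X))
  expect_equal(m$values[1, 2], 1)
  expect_equal(m$values[1, 3], -1)
  expect_equal(diag(m$values), rep(1, 3), ignore_attr = TRUE)
})

test_that("zero-variance columns are rejected by name", {
  X <- cbind(rnorm(20), rep(2, 20))
  expect_error(correlation_matrix(make_segment(X, c("good", "flat"))),
               "flat")
})

test_that("fisher_z applies atanh off-diagonal with clipping", {
  set.seed(33)
  X <- matrix(rnorm(50 * 4), 50, 4)
  m <- correlation_matrix(make_segment(X))
  z <- fisher_z(m)
  r <- m$values
  expect_equal(z$values[1, 2], 0.5 * log((1 + r[1, 2]) / (1 - r[1, 2])))
  expect_equal(diag(z$values), rep(0, 4), ignore_attr = TRUE)
  # r = 0 -> z = 0; hand value at r = 0.8365
  expect_equal(atanh(0), 0)
  expect_equal(round(0.5 * log((1 + 0.8365) / (1 - 0.8365)), 3), 1.209)
  # antisymmetry: z(-r) = -z(r)
  mneg <- fc_matrix(-r + diag(2, 4), "pearson_r", m$region_names)
  expect_equal(fisher_z(mneg)$values, -z$values)
  # perfectly correlated columns are clipped, not infinite
  mdup <- correlation_matrix(make_segment(cbind(X[, 1], X[, 1])))
  expect_true(all(is.finite(fisher_z(mdup)$values)))
  expect_error(fisher_z(z), "pearson_r")
})

test_that("local BG connectivity is the mean of the four cross edges", {
  m <- constant_z_matrix(0.7)
  for (p in names(bg_pairs())) expect_equal(local_bg_fc(m, p), 0.7)
  # hand-set edges (1.0, 1.2, 1.1, 1.3) -> mean 1.15
  nm <- aal116_labels()$name
  v <- matrix(0, 116, 116)
  put <- match(c("Putamen_L", "Putamen_R"), nm)
  pal <- match(c("Pallidum_L", "Pallidum_R"), nm)
  vals <- matrix(c(1.0, 1.2, 1.1, 1.3), 2, 2, byrow = TRUE)
  v[put, pal] <- vals
  v[pal, put] <- t(vals)
  m2 <- fc_matrix(v, "fisher_z", nm)
  expect_equal(local_bg_fc(m2, "Putamen-Pallidum"), 1.15)
  # within-structure homotopic edges do not contribute
  v[put[1], put[2]] <- v[put[2], put[1]] <- 9
  expect_equal(local_bg_fc(fc_matrix(v, "fisher_z", nm),
                           "Putamen-Pallidum"), 1.15)
  expect_error(local_bg_fc(m, "Putamen-Thalamus"), "unknown")
})

test_that("global BG connectivity averages seed-to-110-regions edges", {
  m <- constant_z_matrix(0.42)
  for (s in names(bg_seeds())) expect_equal(global_bg_fc(m, s), 0.42)
  nm <- aal116_labels()$name
  expect_identical(sum(!(nm %in% bg_region_names())), 110L)
  # brute-force edge-loop oracle on a random symmetric matrix
  set.seed(34)
  v <- matrix(rnorm(116^2), 116)
  v <- (v + t(v)) / 2
  diag(v) <- 0
  m2 <- fc_matrix(v, "fisher_z", nm)
  for (s in names(bg_seeds())) {
    seed_regions <- bg_seeds()[[s]]
    acc <- c()
    for (a in seed_regions) for (b in nm[!(nm %in% bg_region_names())]) {
      acc <- c(acc, v[match(a, nm), match(b, nm)])
    }
    expect_equal(global_bg_fc(m2, s), mean(acc))
    expect_identical(length(acc),
                     if (s == "BG-average") 660L else 220L)
  }
  expect_error(global_bg_fc(m, "Thalamus"), "unknown")
})

test_that("BG statistics are linear and label-permutation invariant", {
  set.seed(35)
  v <- matrix(rnorm(116^2), 116)
  v <- (v + t(v)) / 2
  diag(v) <- 0
  nm <- aal116_labels()$name
  m <- fc_matrix(v, "fisher_z", nm)
  m3 <- fc_matrix(3 * v, "fisher_z", nm)
  for (p in names(bg_pairs())) {
    expect_equal(local_bg_fc(m3, p), 3 * local_bg_fc(m, p))
  }
  for (s in names(bg_seeds())) {
    expect_equal(global_bg_fc(m3, s), 3 * global_bg_fc(m, s))
  }
  # permuting the non-seed regions leaves the global statistic unchanged
  others <- which(!(nm %in% bg_region_names()))
  perm <- seq_len(116)
  set.seed(36)
  perm[others] <- sample(others)
  mp <- fc_matrix(v[perm, perm], "fisher_z", nm[perm])
  for (s in names(bg_seeds())) {
    expect_equal(global_bg_fc(mp, s), global_bg_fc(m, s))
  }
})
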