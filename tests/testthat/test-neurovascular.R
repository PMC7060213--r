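test_that("parametric design has the documented structure", {
  n <- 100
  mod <- sin(seq_len(n) / 5)
  des <- build_parametric_design(mod, tr_s = 2, n_scans = n)
  expect_identical(
    colnames(des$X),
    c("base", "mod_canonical", "mod_temporal", "mod_dispersion", "intercept")
  )
  expect_lt(abs(sum(des$modulator)), 1e-9)

  z <- build_parametric_design(rep(0.7, n), tr_s = 2, n_scans = n)
  expect_equal(max(abs(z$X[, 2:4])), 0)

  # a single unit impulse at scan 1 peaks ~6 s later (scan index 4 at TR 2)
  imp <- c(1, rep(0, n - 1))
  d1 <- build_parametric_design(imp, tr_s = 2, n_scans = n)
  expect_equal(which.max(d1$X[, "mod_canonical"]), 4)

  expect_error(build_parametric_design(c(NA, mod[-1]), 2, n), "NaN|NA")
  expect_error(build_parametric_design(mod[-1], 2, n), "length")
})

test_that("first-level GLM recovers planted betas with calibrated F test", {
  set.seed(10)
  n <- 205
  mod <- rnorm(n)
  des <- build_parametric_design(mod, tr_s = 2, n_scans = n)

  y <- 0.8 * des$X[, "mod_canonical"] + rnorm(n, sd = 0.05)
  fl <- fit_first_level_glm(cbind(y), des)
  expect_equal(unname(fl$betas["mod_canonical", 1]), 0.8, tolerance = 0.125)
  expect_lt(fl$pvalue[1], 0.001)
  expect_gt(fl$amplitude[1], 0)

  # F statistic invariant to adding a constant
  fl2 <- fit_first_level_glm(cbind(y + 100), des)
  expect_equal(fl$fstat[1], fl2$fstat[1], tolerance = 1e-9)

  # null type-I rate at alpha = 0.05 over 1000 pure-noise voxels
  noise <- matrix(rnorm(n * 1000), n)
  fn <- fit_first_level_glm(noise, des)
  rate <- mean(fn$pvalue < 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)

  # amplitude sign follows the canonical beta for strong signals
  signs <- sample(c(-1, 1), 200, replace = TRUE)
  ys <- des$X[, "mod_canonical"] %o% (0.8 * signs) +
    matrix(rnorm(n * 200, sd = 0.05), n)
  fs <- fit_first_level_glm(ys, des)
  expect_gte(mean(sign(fs$amplitude) == signs), 0.99)

  bad <- des
  bad$X[, "base"] <- bad$X[, "intercept"]
  expect_error(fit_first_level_glm(cbind(y), bad), "rank")
})

test_that("robust group regression resists outliers, flags them by weight", {
  set.seed(11)
  y <- rnorm(30)
  g <- group_robust_regression(cbind(y))
  # robust location agrees with the mean well within one standard error
  expect_lt(abs(g$estimate[1] - mean(y)), sd(y) / sqrt(30))
  expect_true(all(g$weights > 0 & g$weights <= 1))

  # 20% gross outliers: robust beats the plain mean in >= 90% of voxels
  nvox <- 200
  n <- 20
  truth <- 1
  ys <- matrix(rnorm(n * nvox, mean = truth), n)
  ys[1:4, ] <- ys[1:4, ] + 10
  gr <- group_robust_regression(ys)
  ols <- colMeans(ys)
  better <- mean(abs(gr$estimate - truth) < abs(ols - truth))
  expect_gte(better, 0.9)

  # an injected outlier subject is strongly downweighted
  yo <- c(rnorm(14, sd = 0.5), 25)
  go <- group_robust_regression(cbind(yo))
  expect_lt(go$weights[15, 1], 0.2)

  expect_error(group_robust_regression(cbind(y[1:2])), "3 subjects")
})

test_that("BH-FDR with the cluster-extent rule", {
  # step-up worked example
  res <- fdr_threshold(c(0.01, 0.02, 0.03, 0.5), q = 0.05, min_cluster = 0)
  expect_equal(sum(res$mask), 3)
  expect_identical(which(res$mask), 1:3)

  expect_equal(sum(fdr_threshold(rep(1, 50))$mask), 0)

  # cluster rule: a 20-voxel component dies, a 21-voxel one survives
  dims <- c(30, 5, 3)
  p <- array(0.9, dims)
  p[1:20, 1, 1] <- 1e-8 # 20-voxel line
  p[1:21, 3, 3] <- 1e-8 # 21-voxel line
  out <- fdr_threshold(p, q = 0.05, min_cluster = 20)
  expect_equal(sum(out$mask[, 1, 1]), 0)
  expect_equal(sum(out$mask[, 3, 3]), 21)

  # mean false-discovery proportion under the null stays below q
  set.seed(12)
  fdp <- replicate(500, {
    pv <- runif(1000)
    m <- fdr_threshold(pv, q = 0.05)$mask
    if (any(m)) 1 else 0 # all rejections are false under the global null
  })
  expect_lte(mean(fdp), 0.05 + 2 * sqrt(0.05 * 0.95 / 500))

  expect_error(fdr_threshold(numeric(0)), "empty")
  expect_error(fdr_threshold(c(0.5, 2)), "outside")
})

test_that("blind deconvolution recovers planted response heights", {
  tr <- 2
  n <- 205
  basis <- canonical_hrf_basis(tr)
  expect_equal(max(basis$canonical), 1) # unit peak by construction

  expect_true(deconvolve_hrf(rep(0, n), tr)$flagged)

  set.seed(13)
  ev <- numeric(n)
  ev[seq(5, 190, by = 15)] <- 1
  y <- 1.5 * convolve(ev, rev(basis$canonical), type = "open")[1:n] +
    rnorm(n, sd = 0.02)
  est <- deconvolve_hrf(y, tr)
  expect_false(est$flagged)
  expect_equal(est$amplitude, 1.5, tolerance = 0.25 / 1.5)

  est2 <- deconvolve_hrf(2 * y, tr)
  expect_equal(est2$amplitude, 2 * est$amplitude, tolerance = 0.05)

  expect_error(deconvolve_hrf(y[1:30], tr), "50 scans")
})

test_that("HLI is the right-left difference of median amplitudes", {
  dims <- c(10, 5, 2)
  amp <- array(1.3, dims)
  left <- array(FALSE, dims)
  right <- array(FALSE, dims)
  left[1:5, 1:5, 1] <- TRUE
  right[6:10, 1:5, 1] <- TRUE
  masks <- list(region = list(left = left, right = right))

  expect_equal(compute_hli(amp, masks)$hli, 0)

  amp2 <- amp
  amp2[left] <- 1
  amp2[right] <- 2
  h <- compute_hli(amp2, masks)
  expect_equal(h$hli, 1)
  expect_equal(h$median_amp_left, 1)
  expect_equal(h$median_amp_right, 2)

  # one corrupted voxel among many leaves the median unchanged
  amp3 <- amp2
  idx <- which(right)[1]
  amp3[idx] <- 100
  expect_equal(compute_hli(amp3, masks)$hli, 1)

  # flagged (NA) voxels are excluded; an all-NA hemisphere errors
  amp4 <- amp2
  amp4[right] <- NA
  expect_error(compute_hli(amp4, masks), "zero valid")
})

test_that("pipeline-scale HLI recovery from synthetic BOLD", {
  bd <- generate_bold_dataset(
    n_voxels_per_region = 8, noise_sd = 0.05,
    amp_right = 2, amp_left = 1, seed = 21
  )
  dec <- deconvolve_mask(bd$bold, bd$masks$left | bd$masks$right, 2)
  h <- compute_hli(dec$amplitude, list(frontal = bd$masks))
  expect_gt(h$hli, 0)
  expect_equal(h$hli, bd$truth$planted_hli, tolerance = 0.3)
})
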