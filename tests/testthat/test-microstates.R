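make_rec <- function(data, sfreq = 250, reference = "other") {
  labs <- standard_montage_32()$label[seq_len(nrow(data))]
  eeg_recording(data, sfreq = sfreq, channel_labels = labs, reference = reference)
}

test_that("GFP equals the channel-wise population SD", {
  r <- make_rec(matrix(c(1, -1), 2, 1))
  expect_equal(compute_gfp(r)$values, 1)

  r2 <- make_rec(matrix(5, 8, 3))
  expect_equal(unname(compute_gfp(r2)$values), rep(0, 3))

  set.seed(4)
  x <- matrix(rnorm(32 * 1000), 32)
  r3 <- make_rec(x)
  oracle <- apply(x, 2, function(v) sqrt(mean((v - mean(v))^2)))
  expect_lt(max(abs(compute_gfp(r3)$values - oracle)), 1e-12)
})

test_that("GFP peak selection honors spacing and the SD floor", {
  sfreq <- 250
  flat <- make_rec(matrix(1e-3 * rep(c(1, -1), 16), 32, 500))
  gf <- select_gfp_peaks(compute_gfp(flat))
  expect_length(gf$peak_indices, 0)

  # planted impulse peaks well above threshold, > 20 ms apart
  base <- matrix(0.01 * rep(c(1, -1), 16), 32, 1000)
  at <- c(100, 300, 500, 900)
  base[, at] <- outer(rep(c(1, -1), 16), rep(10, 4))
  gf2 <- select_gfp_peaks(compute_gfp(make_rec(base, sfreq)))
  expect_identical(gf2$peak_indices, as.integer(at))

  # two peaks 10 ms apart at 250 Hz: only the larger survives
  b2 <- matrix(0.01 * rep(c(1, -1), 16), 32, 200)
  b2[, 50] <- rep(c(8, -8), 16)
  b2[, 52] <- rep(c(10, -10), 16) # 2 samples = 8 ms away
  gf3 <- select_gfp_peaks(compute_gfp(make_rec(b2, sfreq)))
  expect_identical(gf3$peak_indices, 52L)

  # spacing invariant
  g <- generate_microstate_eeg(duration_s = 4, noise_sd = 1, seed = 2)
  gf4 <- select_gfp_peaks(compute_gfp(g$recording))
  min_gap <- ceiling(20 * 250 / 1000)
  expect_true(all(diff(gf4$peak_indices) >= min_gap))
})

test_that("peak-map concatenation preserves counts and order", {
  g1 <- generate_microstate_eeg(duration_s = 2, seed = 1)
  g2 <- generate_microstate_eeg(duration_s = 2, seed = 2)
  p1 <- c(10L, 50L, 90L)
  p2 <- c(20L, 70L)
  chi <- concatenate_peak_maps(list(g1$recording, g2$recording), list(p1, p2))
  expect_equal(nrow(chi), 5)
  expect_equal(attr(chi, "subject"), c(1, 1, 1, 2, 2))
  expect_equal(chi[2, ], g1$recording$data[, 50])
  expect_equal(chi[5, ], g2$recording$data[, 70])

  solo <- concatenate_peak_maps(list(g1$recording), list(p1))
  expect_equal(unname(solo), unname(t(g1$recording$data[, p1])),
    ignore_attr = TRUE
  )

  short <- g1$recording
  short$data <- short$data[1:16, ]
  short$channel_labels <- short$channel_labels[1:16]
  expect_error(
    concatenate_peak_maps(list(g1$recording, short), list(p1, p2)),
    "montage"
  )
})

test_that("modified K-means recovers planted orthonormal prototypes", {
  g <- generate_microstate_eeg(duration_s = 8, noise_sd = 0, k_true = 4, seed = 5)
  gf <- select_gfp_peaks(compute_gfp(g$recording))
  chi <- concatenate_peak_maps(list(g$recording), list(gf$peak_indices))
  fit <- fit_modified_kmeans(chi, k = 4, n_restarts = 5, seed = 1)
  m <- match_prototypes(fit$prototypes, g$truth$prototypes)
  expect_gte(m$min, 0.999)
  expect_true(all(abs(rowMeans(fit$prototypes)) < 1e-12))
  expect_true(all(abs(rowSums(fit$prototypes^2) - 1) < 1e-12))
  # objective is non-increasing across iterations
  expect_true(all(diff(fit$objective_trace) <= 1e-9))

  # k = 1 on copies of one map returns that map up to sign
  map <- g$truth$prototypes[1, ]
  chi1 <- matrix(rep(map, 10), 10, byrow = TRUE) * rep(seq(1, 10), each = 1)
  f1 <- fit_modified_kmeans(chi1, k = 1, n_restarts = 2, seed = 1)
  expect_gt(abs(sum(f1$prototypes[1, ] * map)), 0.999999)

  # polarity invariance: flipped copies of every row assign identically
  f2 <- fit_modified_kmeans(rbind(chi, -chi), k = 4, n_restarts = 3, seed = 2)
  n <- nrow(chi)
  expect_identical(f2$labels[seq_len(n)], f2$labels[n + seq_len(n)])

  expect_error(fit_modified_kmeans(chi, k = 0), "k")
  expect_error(fit_modified_kmeans(chi[1:3, ], k = 4), "clusters")
})

test_that("GEV, sigma^2 and CV match a brute-force transcription", {
  g <- generate_microstate_eeg(duration_s = 8, noise_sd = 0, k_true = 4, seed = 6)
  gf <- select_gfp_peaks(compute_gfp(g$recording))
  chi <- concatenate_peak_maps(list(g$recording), list(gf$peak_indices))
  fit <- fit_modified_kmeans(chi, k = 4, n_restarts = 5, seed = 1)
  ev <- evaluate_segmentation(chi, fit, fit$labels)
  # noiseless data: perfect fit
  expect_equal(ev$gev_total, 1, tolerance = 1e-6)
  expect_lt(ev$sigma2, 1e-12)
  expect_equal(sum(ev$gev_per_cluster), ev$gev_total, tolerance = 1e-9)

  # random 50-map set against the independent oracle
  set.seed(9)
  chi_r <- matrix(rnorm(50 * 32), 50, 32)
  fit_r <- fit_modified_kmeans(chi_r, k = 5, n_restarts = 3, seed = 3)
  ev_r <- evaluate_segmentation(chi_r, fit_r, fit_r$labels)
  or <- oracle_gev_cv(chi_r - rowMeans(chi_r), fit_r$prototypes, fit_r$labels)
  expect_equal(ev_r$gev_total, or$gev_total, tolerance = 1e-9)
  expect_equal(ev_r$sigma2, or$sigma2, tolerance = 1e-9)
  expect_equal(ev_r$cv, or$cv, tolerance = 1e-9)

  # CV undefined once K >= C - 1
  chi_small <- matrix(rnorm(40 * 6), 40, 6)
  fit_s <- suppressWarnings(
    fit_modified_kmeans(chi_small, k = 5, n_restarts = 2, seed = 1)
  )
  expect_warning(
    ev_s <- evaluate_segmentation(chi_small, fit_s, fit_s$labels),
    "undefined"
  )
  expect_true(is.na(ev_s$cv))
})

test_that("gev_total is non-decreasing in K on the same data", {
  g <- generate_microstate_eeg(duration_s = 10, noise_sd = 2, k_true = 4, seed = 12)
  gf <- select_gfp_peaks(compute_gfp(g$recording))
  chi <- concatenate_peak_maps(list(g$recording), list(gf$peak_indices))
  gevs <- vapply(2:6, function(k) {
    fit_modified_kmeans(chi, k = k, n_restarts = 10, seed = 4)$gev_total
  }, numeric(1))
  expect_true(all(diff(gevs) >= -1e-6))
})

test_that("back-fitting assigns by GMD with the documented geometry", {
  g <- generate_microstate_eeg(duration_s = 4, noise_sd = 0, k_true = 4, seed = 8)
  gf <- select_gfp_peaks(compute_gfp(g$recording))
  chi <- concatenate_peak_maps(list(g$recording), list(gf$peak_indices))
  fit <- fit_modified_kmeans(chi, k = 4, n_restarts = 5, seed = 1)

  # a sample equal to a prototype gets its label with GMD = 0
  rec1 <- make_rec(cbind(fit$prototypes[2, ], fit$prototypes[3, ]))
  lab1 <- backfit(rec1, fit)
  expect_identical(lab1$labels, c(2L, 3L))
  expect_lt(max(lab1$gmd), 1e-9)

  # polarity-flipped prototype: same label, GMD 0 in invariant mode
  recn <- make_rec(cbind(-fit$prototypes[2, ]))
  labn <- backfit(recn, fit, polarity_invariant = TRUE)
  expect_identical(labn$labels, 2L)
  expect_lt(labn$gmd, 1e-9)
  expect_equal(labn$polarity_sign, -1)

  # polarity-sensitive GMD of a map against its negation is exactly 2
  one_proto <- fit
  one_proto$prototypes <- fit$prototypes[1, , drop = FALSE]
  one_proto$k <- 1L
  neg <- make_rec(cbind(-fit$prototypes[1, ]))
  labs <- backfit(neg, one_proto, polarity_invariant = FALSE)
  expect_equal(labs$gmd, 2, tolerance = 1e-9)

  # GMD range and invariance to positive rescaling
  gr <- generate_microstate_eeg(duration_s = 2, noise_sd = 3, seed = 9)
  lab_a <- backfit(gr$recording, fit)
  expect_true(all(lab_a$gmd >= 0 & lab_a$gmd <= 2, na.rm = TRUE))
  scaled <- gr$recording
  scaled$data <- scaled$data * 7
  lab_b <- backfit(scaled, fit)
  expect_identical(lab_a$labels, lab_b$labels)
  expect_equal(lab_a$gmd, lab_b$gmd, tolerance = 1e-9)

  # zero-GFP samples get the sentinel
  zrec <- make_rec(cbind(fit$prototypes[1, ], rep(0, 32)))
  labz <- backfit(zrec, fit)
  expect_identical(labz$labels[2], NA_integer_)
})

test_that("zero-noise back-fit recovers the planted labels exactly", {
  g <- generate_microstate_eeg(duration_s = 8, noise_sd = 0, k_true = 4, seed = 10)
  gf <- select_gfp_peaks(compute_gfp(g$recording))
  chi <- concatenate_peak_maps(list(g$recording), list(gf$peak_indices))
  fit <- fit_modified_kmeans(chi, k = 4, n_restarts = 5, seed = 1)
  lab <- backfit(g$recording, fit)
  expect_equal(label_accuracy(lab$labels, g$truth$label_sequence, 4), 1.0)
})

test_that("re-expression is the prototype scaled by GFP and preserves GFP", {
  g <- generate_microstate_eeg(duration_s = 4, noise_sd = 0, k_true = 4, seed = 13)
  rec <- g$recording
  gf <- select_gfp_peaks(compute_gfp(rec))
  chi <- concatenate_peak_maps(list(rec), list(gf$peak_indices))
  fit <- fit_modified_kmeans(chi, k = 4, n_restarts = 5, seed = 1)
  lab <- backfit(rec, fit)
  rex <- reexpress(rec, lab, fit)

  expect_identical(dim(rex$data), dim(rec$data))
  # constructive definition at an arbitrary sample
  n0 <- 101
  gfp0 <- compute_gfp(rec)$values[n0]
  expected <- fit$prototypes[lab$labels[n0], ] * gfp0 * sqrt(32) *
    lab$polarity_sign[n0]
  expect_equal(rex$data[, n0], expected, tolerance = 1e-12)

  # GFP preservation
  expect_lt(max(abs(compute_gfp(rex)$values - compute_gfp(rec)$values)), 1e-9)

  # noiseless synthetic data: re-expressed equals the original
  expect_lt(max(abs(rex$data - rec$data)), 1e-6)

  # sentinel samples become zero vectors
  rec0 <- rec
  rec0$data[, 7] <- 0
  lab0 <- backfit(rec0, fit)
  rex0 <- reexpress(rec0, lab0, fit)
  expect_equal(rex0$data[, 7], rep(0, 32))

  bad <- lab
  bad$labels <- bad$labels[-1]
  expect_error(reexpress(rec, bad, fit), "length")
})
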