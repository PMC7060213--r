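#' Synthetic microstate EEG with a planted frontal asymmetry
#'
#' Generates a resting EEG whose topography alternates among `k_true`
#' quasi-stable prototype maps while a shared alpha-band carrier modulates
#' global field power, plus optional white sensor noise. Segment durations
#' are geometric with mean `mean_segment_ms` (the tens-of-milliseconds scale
#' of quasi-stable microstates). Prototypes are random orthonormalized
#' zero-mean topographies whose F4/F3 and F8/F7 entries are rescaled so the
#' clean signal's alpha-power log-ratios ln(P_F4/P_F3) and ln(P_F8/P_F7)
#' equal the planted values exactly: the same carrier drives every channel,
#' so the band-power ratio reduces to the squared-entry ratio of the
#' prototypes, which is enforced uniformly across prototypes.
#'
#' The carrier is an amplitude-modulated alpha oscillation
#' s(t) = A (1 + 0.5 sin(2 pi 0.2 t)) sin(2 pi f t + phi), with a small
#' phase offset so no sample is exactly zero; the stored non-negative GFP
#' envelope is |s(t)| (prototypes are unit-norm, so the clean per-sample GFP
#' is |s|/sqrt(C)).
#'
#' @param n_channels number of channels (<= 32; uses the first rows of
#'   [standard_montage_32()], which always include F3, F4, F7, F8).
#' @param sfreq sampling rate, Hz.
#' @param duration_s recording length, seconds.
#' @param k_true number of planted prototypes.
#' @param mean_segment_ms mean quasi-stable segment duration, ms.
#' @param alpha_freq_hz carrier frequency, Hz.
#' @param noise_sd white noise SD (microvolts) added per channel/sample.
#' @param planted_log_ratios named numeric: `F4F3`, `F8F7` target
#'   ln(power right / power left) of the clean signal.
#' @param amplitude carrier amplitude A, microvolts.
#' @param prototypes optional K x C zero-mean unit-norm matrix of planted
#'   topographies to reuse (e.g. one shared set across a synthetic cohort);
#'   its frontal entries are expected to already encode the planted ratios,
#'   as produced by a previous call's truth.
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return list with `recording` (an [eeg_recording()], average reference)
#'   and `truth` (class `synthetic_eeg_truth`: `prototypes`,
#'   `label_sequence`, `gfp_envelope`, `planted_log_ratio_F4F3`,
#'   `planted_log_ratio_F8F7`, `seed`).
#' @examples
#' g <- generate_microstate_eeg(duration_s = 2, seed = 1)
#' g$recording
#' @export
generate_microstate_eeg <- function(n_channels = 32, sfreq = 250,
                                    duration_s = 60, k_true = 4,
                                    mean_segment_ms = 80,
                                    alpha_freq_hz = 10, noise_sd = 0,
                                    planted_log_ratios = c(F4F3 = 0, F8F7 = 0),
                                    amplitude = 10, prototypes = NULL,
                                    seed = 1) {
  if (k_true < 1) stop("k_true must be >= 1")
  if (duration_s <= 0) stop("duration_s must be positive")
  if (sfreq <= 0) stop("sfreq must be positive")
  montage <- standard_montage_32()
  if (n_channels > nrow(montage)) stop("at most 32 channels supported")
  montage <- montage[seq_len(n_channels), , drop = FALSE]
  required <- c("F3", "F4", "F7", "F8")
  if (!all(required %in% montage$label)) {
    stop("montage must include F3, F4, F7, F8 (need n_channels >= 7)")
  }
  r_fa <- if ("F4F3" %in% names(planted_log_ratios)) planted_log_ratios[["F4F3"]] else 0
  r_fta <- if ("F8F7" %in% names(planted_log_ratios)) planted_log_ratios[["F8F7"]] else 0

  n <- round(duration_s * sfreq)
  with_seed(seed, {
    z <- if (is.null(prototypes)) {
      synth_prototypes(k_true, montage$label, r_fa, r_fta)
    } else {
      stopifnot(nrow(prototypes) == k_true, ncol(prototypes) == n_channels)
      prototypes
    }
    labels <- synth_label_sequence(n, k_true, mean_segment_ms, sfreq)
    t <- (seq_len(n) - 1) / sfreq
    carrier <- amplitude * (1 + 0.5 * sin(2 * pi * 0.2 * t)) *
      sin(2 * pi * alpha_freq_hz * t + 0.123)
    clean <- t(z[labels, , drop = FALSE]) * rep(carrier, each = n_channels)
    noisy <- clean + if (noise_sd > 0) {
      matrix(stats::rnorm(n_channels * n, sd = noise_sd), n_channels, n)
    } else {
      0
    }
    rec <- eeg_recording(noisy,
      sfreq = sfreq, channel_labels = montage$label,
      positions = montage, reference = "other"
    )
    rec <- average_reference(rec)
    truth <- structure(
      list(
        prototypes = z, label_sequence = labels,
        gfp_envelope = abs(carrier) / sqrt(n_channels),
        planted_log_ratio_F4F3 = r_fa, planted_log_ratio_F8F7 = r_fta,
        seed = seed
      ),
      class = "synthetic_eeg_truth"
    )
    list(recording = rec, truth = truth)
  })
}

# K x C random orthonormal zero-mean prototypes with frontal entries pinned
# so that |z[,F4]| = exp(r_fa/2) |z[,F3]| and |z[,F8]| = exp(r_fta/2) |z[,F7]|
# in every row (band-power log-ratios then equal r exactly for any carrier)
synth_prototypes <- function(k, labels, r_fa, r_fta) {
  C <- length(labels)
  z <- matrix(stats::rnorm(k * C), k, C)
  z <- center_rows(z)
  # Gram-Schmidt within the zero-mean subspace
  for (i in seq_len(k)) {
    if (i > 1) {
      for (j in seq_len(i - 1)) {
        z[i, ] <- z[i, ] - sum(z[i, ] * z[j, ]) * z[j, ]
      }
    }
    z[i, ] <- z[i, ] / sqrt(sum(z[i, ]^2))
  }
  iF3 <- match("F3", labels)
  iF4 <- match("F4", labels)
  iF7 <- match("F7", labels)
  iF8 <- match("F8", labels)
  frontal <- c(iF3, iF4, iF7, iF8)
  floor_mag <- 0.2 / sqrt(C)
  for (i in seq_len(k)) {
    a3 <- z[i, iF3]
    a7 <- z[i, iF7]
    if (abs(a3) < floor_mag) a3 <- floor_mag * ifelse(a3 >= 0, 1, -1)
    if (abs(a7) < floor_mag) a7 <- floor_mag * ifelse(a7 >= 0, 1, -1)
    # right channel is an exact signed multiple of its left partner so the
    # per-channel time courses are proportional and every band's power
    # ratio equals the planted ratio exactly
    z[i, iF3] <- a3
    z[i, iF4] <- exp(r_fa / 2) * a3
    z[i, iF7] <- a7
    z[i, iF8] <- exp(r_fta / 2) * a7
    # restore zero mean using non-frontal channels only (ratios untouched)
    rest <- setdiff(seq_len(C), frontal)
    z[i, rest] <- z[i, rest] - sum(z[i, ]) / length(rest)
    z[i, ] <- z[i, ] / sqrt(sum(z[i, ]^2)) # uniform rescale keeps ratios
  }
  z
}

# geometric segment durations (mean mean_ms), prototype drawn uniformly with
# no immediate repeats when k > 1
synth_label_sequence <- function(n, k, mean_ms, sfreq) {
  mean_samples <- max(1, mean_ms * sfreq / 1000)
  labels <- integer(n)
  pos <- 1L
  cur <- sample.int(k, 1)
  while (pos <= n) {
    len <- 1L + stats::rgeom(1, prob = 1 / mean_samples)
    end <- min(n, pos + len - 1L)
    labels[pos:end] <- cur
    pos <- end + 1L
    if (k > 1) {
      nxt <- sample.int(k - 1, 1)
      cur <- if (nxt >= cur) nxt + 1L else nxt
    }
  }
  labels
}

#' @export
print.synthetic_eeg_truth <- function(x, ...) {
  cat(sprintf(
    "<synthetic_eeg_truth> K = %d, %d samples, planted ln-ratios F4/F3 = %.3f, F8/F7 = %.3f\n",
    nrow(x$prototypes), length(x$label_sequence),
    x$planted_log_ratio_F4F3, x$planted_log_ratio_F8F7
  ))
  invisible(x)
}

#' Synthetic BOLD dataset with planted hemispheric lateralization
#'
#' Builds a 4D BOLD array containing two homologous regions (left and right
#' blocks of voxels) responding to a common sparse pseudo-event train
#' convolved with the canonical double-gamma HRF (unit peak height), with
#' region-specific response amplitudes, plus AR(1) Gaussian noise everywhere.
#' The planted hemodynamic lateralization index is `amp_right - amp_left`
#' by construction.
#'
#' @param n_voxels_per_region voxels in each hemisphere region.
#' @param tr_s repetition time, seconds.
#' @param n_volumes number of volumes (>= 50).
#' @param amp_right,amp_left HRF response heights (BOLD units).
#' @param noise_sd AR(1) innovation SD.
#' @param ar1_coef AR(1) coefficient in [0, 1).
#' @param mean_event_interval_s mean spacing of the pseudo-event train,
#'   seconds; sparse events keep individual responses resolvable.
#' @param seed integer seed.
#' @return list: `bold` (4D array x,y,z,t), `masks` (list of logical 3D
#'   arrays `left`, `right`), `truth` (class `synthetic_bold_truth`).
#' @export
generate_bold_dataset <- function(n_voxels_per_region = 20, tr_s = 2,
                                  n_volumes = 205, amp_right = 2,
                                  amp_left = 1, noise_sd = 0.1,
                                  ar1_coef = 0.3,
                                  mean_event_interval_s = 24, seed = 1) {
  if (tr_s <= 0) stop("tr_s must be positive")
  if (n_volumes < 50) stop("need at least 50 volumes")
  if (n_voxels_per_region < 1) stop("empty region masks")
  if (!is.finite(amp_right) || !is.finite(amp_left)) stop("amplitudes must be finite")
  nx <- 2 * ceiling(sqrt(n_voxels_per_region))
  ny <- ceiling(n_voxels_per_region / ceiling(sqrt(n_voxels_per_region)))
  nz <- 2
  dims <- c(nx, ny, nz)
  mask_left <- array(FALSE, dims)
  mask_right <- array(FALSE, dims)
  half <- nx / 2
  # fill voxel slots column-major within each hemisphere slab (z = 1)
  slots <- cbind(
    rep(seq_len(half), times = ny),
    rep(seq_len(ny), each = half)
  )[seq_len(n_voxels_per_region), , drop = FALSE]
  mask_left[cbind(slots[, 1], slots[, 2], 1L)] <- TRUE
  mask_right[cbind(slots[, 1] + half, slots[, 2], 1L)] <- TRUE

  with_seed(seed, {
    scan_t <- (seq_len(n_volumes) - 1) * tr_s
    duration <- n_volumes * tr_s
    n_events <- max(3, stats::rpois(1, duration / mean_event_interval_s))
    event_times <- sort(stats::runif(n_events, 0, duration - 16))
    events <- numeric(n_volumes)
    events[pmin(n_volumes, floor(event_times / tr_s) + 1)] <- 1
    h <- canonical_hrf_basis(tr_s, span_s = 32)$canonical
    resp <- stats::convolve(events, rev(h), type = "open")[seq_len(n_volumes)]

    nvox <- prod(dims)
    bold <- array(0, c(dims, n_volumes))
    noise <- matrix(stats::rnorm(nvox * n_volumes, sd = noise_sd), nvox, n_volumes)
    if (ar1_coef > 0) {
      noise <- t(apply(noise, 1, function(e) {
        as.numeric(stats::filter(e, ar1_coef, method = "recursive"))
      }))
    }
    flat <- noise
    amp_vec <- numeric(nvox)
    amp_vec[as.vector(mask_left)] <- amp_left
    amp_vec[as.vector(mask_right)] <- amp_right
    flat <- flat + outer(amp_vec, resp)
    bold <- array(flat, c(dims, n_volumes))
    truth <- structure(
      list(
        event_times = event_times, amp_right = amp_right,
        amp_left = amp_left, noise_sd = noise_sd, ar1_coef = ar1_coef,
        planted_hli = amp_right - amp_left, seed = seed
      ),
      class = "synthetic_bold_truth"
    )
    list(
      bold = bold, masks = list(left = mask_left, right = mask_right),
      truth = truth
    )
  })
}

#' @export
print.synthetic_bold_truth <- function(x, ...) {
  cat(sprintf(
    "<synthetic_bold_truth> %d events, amp R/L = %.2f/%.2f, planted HLI = %.2f\n",
    length(x$event_times), x$amp_right, x$amp_left, x$planted_hli
  ))
  invisible(x)
}

#' Synthetic behavioral scores with a planted correlation
#'
#' Produces a score vector whose in-sample Pearson correlation with `x`
#' equals `target_rho` exactly before any outlier injection: the Gaussian
#' noise component is projected orthogonal to the standardized `x` and
#' restandardized, so y = rho * z_x + sqrt(1 - rho^2) * z_noise realizes the
#' target as the sample correlation rather than only in expectation. Gross
#' outliers (if requested) then replace the last `n_outliers` entries with
#' values 10 SD away, for contamination studies.
#'
#' @param x numeric driver (length >= 3, non-degenerate).
#' @param target_rho target correlation in [-1, 1].
#' @param noise_model `"gaussian"` (reserved for alternatives).
#' @param n_outliers number of gross outliers to inject.
#' @param seed integer seed.
#' @return numeric vector of scores, same length as `x`.
#' @export
generate_behavioral_scores <- function(x, target_rho, noise_model = "gaussian",
                                       n_outliers = 0, seed = 1) {
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  if (abs(target_rho) > 1) stop("|target_rho| must be <= 1")
  if (stats::sd(x) == 0) stop("x has zero variance")
  with_seed(seed, {
    zx <- as.numeric(scale(x))
    e <- stats::rnorm(n)
    e <- e - zx * sum(e * zx) / sum(zx^2) # orthogonal to x
    if (stats::sd(e) > 0) e <- as.numeric(scale(e))
    y <- target_rho * zx + sqrt(1 - target_rho^2) * e
    if (n_outliers > 0) {
      idx <- n - seq_len(min(n_outliers, n)) + 1
      y[idx] <- 10 * sign(stats::rnorm(length(idx)))
    }
    y
  })
}

#' Write a synthetic cohort's behavioral scores as CSV
#'
#' @param scores data.frame with columns subject_id, positive_affect,
#'   negative_affect, bis, bas.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_scores_csv <- function(scores, path) {
  utils::write.csv(scores, path, row.names = FALSE)
  invisible(path)
}
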