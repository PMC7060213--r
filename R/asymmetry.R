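#' Current-source-density (surface Laplacian) re-reference
#'
#' Spherical-spline CSD estimate: potentials are interpolated on the unit
#' sphere with an m-th order spline through the electrode positions and the
#' surface Laplacian of the interpolant is evaluated at the electrodes.
#' The transform is reference-free (insensitive to adding a constant to all
#' channels), linear, and sharpens topographies by suppressing distant
#' sources - the conventional pre-step for standard frontal-asymmetry
#' indices.
#'
#' @param recording an [eeg_recording()] with 3D positions.
#' @param spline_order spline flexibility m (>= 2); 4 is the common default.
#' @param lambda Tikhonov regularization added to the interpolation matrix.
#' @param n_legendre number of Legendre terms in the kernel expansions.
#' @return the recording with CSD data and `reference = "csd"`.
#' @export
csd_transform <- function(recording, spline_order = 4, lambda = 1e-5,
                          n_legendre = 50) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (is.null(recording$positions)) stop("csd_transform: electrode positions required")
  pos <- as.matrix(recording$positions[, c("x", "y", "z")])
  pos <- pos / sqrt(rowSums(pos^2))
  C <- nrow(pos)
  if (C < 8) warning("csd_transform: spline ill-conditioned below 8 electrodes")
  cosang <- tcrossprod(pos)
  cosang[cosang > 1] <- 1
  cosang[cosang < -1] <- -1
  G <- csd_kernel(cosang, spline_order, n_legendre, laplacian = FALSE)
  H <- csd_kernel(cosang, spline_order, n_legendre, laplacian = TRUE)
  # spline system with the zero-sum constraint on the coefficients
  A <- rbind(cbind(G + lambda * diag(C), rep(1, C)), c(rep(1, C), 0))
  rhs <- rbind(recording$data, rep(0, ncol(recording$data)))
  sol <- solve(A, rhs)
  recording$data <- H %*% sol[seq_len(C), , drop = FALSE]
  recording$reference <- "csd"
  recording
}

# spline kernels g (interpolation) and h (surface Laplacian) as truncated
# Legendre series over cos(angular distance)
csd_kernel <- function(x, m, n_terms, laplacian = FALSE) {
  n <- seq_len(n_terms)
  coef <- if (laplacian) {
    -(2 * n + 1) / (n * (n + 1))^(m - 1) / (4 * pi)
  } else {
    (2 * n + 1) / (n * (n + 1))^m / (4 * pi)
  }
  legendre_series(x, coef)
}

# sum_n coef[n] * P_n(x) by the three-term recurrence, elementwise over x
legendre_series <- function(x, coef) {
  p_prev <- array(1, dim = dim(x)) # P_0
  p_cur <- x # P_1
  out <- coef[1] * p_cur
  for (n in 2:length(coef)) {
    p_next <- ((2 * n - 1) * x * p_cur - (n - 1) * p_prev) / n
    out <- out + coef[n] * p_next
    p_prev <- p_cur
    p_cur <- p_next
  }
  out
}

#' Welch power spectral density
#'
#' Hann-windowed segment-averaged one-sided PSD (density scaling: the
#' integral over frequency approximates the signal variance). Used by
#' [alpha_band_power()]; exported for diagnostics.
#'
#' @param x numeric vector.
#' @param sfreq sampling rate, Hz.
#' @param window_s segment length, seconds.
#' @param overlap fractional segment overlap in [0, 1).
#' @return list with `freq` (Hz) and `psd` (power / Hz).
#' @export
welch_psd <- function(x, sfreq, window_s = 2, overlap = 0.5) {
  L <- round(window_s * sfreq)
  if (length(x) < L) stop("welch_psd: signal shorter than one window")
  step <- max(1, round(L * (1 - overlap)))
  starts <- seq(1, length(x) - L + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(L) / (L + 1)) # Hann
  u <- sum(w^2)
  nfreq <- floor(L / 2) + 1
  segs <- vapply(starts, function(s) {
    seg <- x[s:(s + L - 1)]
    (seg - mean(seg)) * w
  }, numeric(L))
  sp <- abs(stats::mvfft(segs))^2 / (sfreq * u)
  half <- rowMeans(sp)[seq_len(nfreq)]
  if (L %% 2 == 0) {
    half[2:(nfreq - 1)] <- 2 * half[2:(nfreq - 1)]
  } else {
    half[2:nfreq] <- 2 * half[2:nfreq]
  }
  list(freq = (seq_len(nfreq) - 1) * sfreq / L, psd = half)
}

#' Alpha-band power per channel
#'
#' Welch PSD per channel, integrated (trapezoid) over the alpha band to give
#' band power in microvolts squared. The natural-log of a right/left pair of
#' these powers is the asymmetry index; `log_display` carries the
#' 10*log10 values conventionally used for topographic display.
#'
#' @param recording an [eeg_recording()].
#' @param band two-element numeric, band edges in Hz (default 8-12).
#' @param welch_window_s Welch segment length, seconds.
#' @param overlap Welch segment overlap.
#' @return object of class `alpha_power_map`: `power` (named per-channel
#'   band power), `band`, `method_tag` (the recording's reference),
#'   `log_display`.
#' @export
alpha_band_power <- function(recording, band = c(8, 12), welch_window_s = 2,
                             overlap = 0.5) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (band[1] >= band[2]) stop("band must satisfy low < high")
  if (band[2] > recording$sfreq / 2) stop("band exceeds the Nyquist frequency")
  if (ncol(recording$data) < welch_window_s * recording$sfreq) {
    stop("recording shorter than one Welch window")
  }
  power <- apply(recording$data, 1, function(ch) {
    sp <- welch_psd(ch, recording$sfreq, welch_window_s, overlap)
    band_integral(sp$freq, sp$psd, band)
  })
  names(power) <- recording$channel_labels
  structure(
    list(
      power = power, band = band,
      method_tag = recording$reference,
      log_display = 10 * log10(pmax(power, .Machine$double.xmin))
    ),
    class = "alpha_power_map"
  )
}

# trapezoidal integral of psd over [band[1], band[2]] with interpolated edges
band_integral <- function(freq, psd, band) {
  f <- stats::approxfun(freq, psd, rule = 2)
  grid <- sort(unique(c(band, freq[freq > band[1] & freq < band[2]])))
  pracma::trapz(grid, f(grid))
}

#' @export
print.alpha_power_map <- function(x, ...) {
  cat(sprintf(
    "<alpha_power_map> %d channels, band %g-%g Hz, reference: %s\n",
    length(x$power), x$band[1], x$band[2], x$method_tag
  ))
  invisible(x)
}

# channel pairs: right channel first, left second
asym_pairs <- list(FA = c("F4", "F3"), FTA = c("F8", "F7"))

#' Frontal alpha asymmetry index
#'
#' value = ln(alpha power at the right channel) - ln(alpha power at the left
#' channel) for the mid-frontal pair F4/F3 ("FA") or the lateral-frontal
#' pair F8/F7 ("FTA"). Positive values indicate relatively higher
#' right-hemisphere alpha power (conventionally read as relatively greater
#' left-hemisphere activation).
#'
#' @param power_map an `alpha_power_map` (or named power vector).
#' @param pair `"FA"` (F4/F3) or `"FTA"` (F8/F7).
#' @return scalar asymmetry value (dimensionless), with attributes `pair`
#'   and `method_tag`.
#' @export
asymmetry_index <- function(power_map, pair = c("FA", "FTA")) {
  pair <- match.arg(pair)
  pw <- if (inherits(power_map, "alpha_power_map")) power_map$power else power_map
  chans <- asym_pairs[[pair]]
  for (ch in chans) {
    if (!ch %in% names(pw)) stop(sprintf("channel %s missing from power map", ch))
    if (!is.finite(pw[[ch]]) || pw[[ch]] <= 0) {
      stop(sprintf("non-positive alpha power at channel %s", ch))
    }
  }
  val <- log(pw[[chans[1]]]) - log(pw[[chans[2]]])
  attr(val, "pair") <- pair
  attr(val, "method_tag") <- if (inherits(power_map, "alpha_power_map")) {
    power_map$method_tag
  } else {
    NA_character_
  }
  val
}

#' TR-locked per-scan alpha power and asymmetry
#'
#' Downsamples instantaneous per-channel alpha power to the fMRI acquisition
#' grid by taking the median within each TR window, then computes the
#' per-scan asymmetry ln(right) - ln(left). Instantaneous alpha power is the
#' squared Hilbert envelope of the 8-12 Hz band-passed signal when a
#' recording is supplied. Partial trailing windows are rejected: the EEG
#' must cover `n_scans * tr_s` seconds.
#'
#' @param x an [eeg_recording()], or a channels-x-samples matrix of
#'   per-sample alpha power with rownames as channel labels.
#' @param sfreq sampling rate (taken from the recording if given).
#' @param tr_s scan repetition time, seconds.
#' @param n_scans number of scans to produce.
#' @param pair asymmetry channel pair, as in [asymmetry_index()].
#' @param band band-pass edges for the envelope (recording input only).
#' @return list: `per_scan_power` (channels x n_scans matrix of window
#'   medians), `asymmetry` (length-`n_scans` per-scan index).
#' @export
alpha_to_tr_series <- function(x, sfreq = NULL, tr_s = 2, n_scans,
                               pair = c("FA", "FTA"), band = c(8, 12)) {
  pair <- match.arg(pair)
  if (inherits(x, "eeg_recording")) {
    sfreq <- x$sfreq
    pw <- instantaneous_alpha_power(x, band)
  } else {
    if (is.null(sfreq)) stop("sfreq required with matrix input")
    pw <- as.matrix(x)
  }
  win <- round(tr_s * sfreq)
  if (ncol(pw) < n_scans * win) {
    stop("EEG does not cover the requested number of scans")
  }
  per_scan <- vapply(seq_len(n_scans), function(s) {
    idx <- ((s - 1) * win + 1):(s * win)
    apply(pw[, idx, drop = FALSE], 1, stats::median)
  }, numeric(nrow(pw)))
  rownames(per_scan) <- rownames(pw)
  chans <- asym_pairs[[pair]]
  if (!all(chans %in% rownames(per_scan))) {
    stop("pair channels missing from the power matrix")
  }
  asym <- log(per_scan[chans[1], ]) - log(per_scan[chans[2], ])
  list(per_scan_power = per_scan, asymmetry = as.numeric(asym))
}

# squared Hilbert envelope of the band-passed signal, per channel
instantaneous_alpha_power <- function(recording, band = c(8, 12)) {
  ny <- recording$sfreq / 2
  bf <- signal::butter(4, band / ny, type = "pass")
  out <- t(apply(recording$data, 1, function(ch) {
    filt <- signal::filtfilt(bf, ch)
    Mod(analytic_signal(filt))^2
  }))
  rownames(out) <- recording$channel_labels
  out
}
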