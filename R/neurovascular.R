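#' Canonical HRF basis (double-gamma + temporal and dispersion derivatives)
#'
#' The canonical hemodynamic response is the conventional double-gamma
#' difference, peak at 6 s, undershoot at 16 s, undershoot ratio 1/6,
#' supported on 0-`span_s` seconds, and scaled here to unit peak height so
#' that a regression beta on the canonical column reads directly as response
#' height in BOLD units. The temporal derivative is d/dt of the canonical;
#' the dispersion derivative is the sensitivity to the peak-dispersion
#' parameter (finite difference at +1%). Both derivatives share the
#' canonical's scaling.
#'
#' @param tr_s sampling interval of the basis, seconds.
#' @param span_s support length, seconds.
#' @return list: `time`, `canonical`, `temporal`, `dispersion` (equal-length
#'   numeric vectors).
#' @export
canonical_hrf_basis <- function(tr_s, span_s = 32) {
  t <- seq(0, span_s, by = tr_s)
  raw <- function(disp) {
    stats::dgamma(t, shape = 6 / disp, rate = 1 / disp) -
      stats::dgamma(t, shape = 16, rate = 1) / 6
  }
  h <- raw(1)
  scale <- max(h)
  h <- h / scale
  # temporal derivative by central differences on a fine grid
  eps <- 1e-3
  hp <- (stats::dgamma(t + eps, 6, 1) - stats::dgamma(t + eps, 16, 1) / 6 -
    (stats::dgamma(pmax(t - eps, 0), 6, 1) -
      stats::dgamma(pmax(t - eps, 0), 16, 1) / 6)) / (2 * eps) / scale
  hd <- (raw(1.01) / scale - h) / 0.01
  list(time = t, canonical = h, temporal = hp, dispersion = hd)
}

#' Parametric-modulation design matrix for resting EEG-informed fMRI
#'
#' Resting acquisitions have no task events, so the base regressor treats
#' every scan as an event: unit impulses at each scan convolved with the
#' canonical HRF. The EEG asymmetry series, mean-centered, weights the same
#' impulse train and is convolved with the canonical HRF and its temporal
#' and dispersion derivatives to give the three parametric-modulation
#' columns; an intercept completes the design.
#'
#' @param per_scan_modulator numeric length-`n_scans` asymmetry series.
#' @param tr_s repetition time, seconds.
#' @param n_scans number of scans.
#' @return object of class `design_matrix_spec`: `X` (n_scans x 5 matrix
#'   with columns base, mod_canonical, mod_temporal, mod_dispersion,
#'   intercept), `tr_s`, `modulator` (centered).
#' @export
build_parametric_design <- function(per_scan_modulator, tr_s, n_scans) {
  if (length(per_scan_modulator) != n_scans) {
    stop("modulator length must equal n_scans")
  }
  if (anyNA(per_scan_modulator)) stop("NaN/NA in modulator")
  basis <- canonical_hrf_basis(tr_s)
  mod <- per_scan_modulator - mean(per_scan_modulator)
  conv_scan <- function(w, h) {
    stats::convolve(w, rev(h), type = "open")[seq_len(n_scans)]
  }
  ones <- rep(1, n_scans)
  X <- cbind(
    base = conv_scan(ones, basis$canonical),
    mod_canonical = conv_scan(mod, basis$canonical),
    mod_temporal = conv_scan(mod, basis$temporal),
    mod_dispersion = conv_scan(mod, basis$dispersion),
    intercept = ones
  )
  structure(
    list(X = X, tr_s = tr_s, n_scans = n_scans, modulator = mod),
    class = "design_matrix_spec"
  )
}

#' First-level GLM with an F test over the modulated columns
#'
#' Ordinary least squares per voxel, a partial F statistic over the three
#' parametric-modulation columns (canonical + temporal + dispersion), and an
#' amplitude summary per voxel: the signed root-sum-of-squares of the three
#' modulation betas, sign taken from the canonical beta. The amplitude
#' summary is what carries to the robust group stage.
#'
#' @param bold n_scans x V matrix (or 4D array, time last; it is flattened
#'   voxel-major).
#' @param design a `design_matrix_spec`.
#' @return object of class `first_level_result`: `betas` (p x V), `fstat`,
#'   `pvalue`, `amplitude`, `sigma2`, `df` and, for array input, `dims`.
#' @export
fit_first_level_glm <- function(bold, design) {
  stopifnot(inherits(design, "design_matrix_spec"))
  dims <- NULL
  if (is.array(bold) && length(dim(bold)) == 4) {
    dims <- dim(bold)[1:3]
    bold <- t(matrix(bold, prod(dims), dim(bold)[4]))
  }
  bold <- as.matrix(bold)
  if (nrow(bold) != design$n_scans) stop("BOLD time length must equal n_scans")
  X <- design$X
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("rank-deficient design matrix")
  n <- nrow(X)
  p <- ncol(X)
  betas <- qr.coef(qrX, bold)
  res <- bold - X %*% betas
  rss_full <- colSums(res^2)
  mod_cols <- c("mod_canonical", "mod_temporal", "mod_dispersion")
  keep <- !(colnames(X) %in% mod_cols)
  X0 <- X[, keep, drop = FALSE]
  qr0 <- qr(X0)
  res0 <- bold - X0 %*% qr.coef(qr0, bold)
  rss_red <- colSums(res0^2)
  df <- n - p
  q <- length(mod_cols)
  fstat <- pmax(0, (rss_red - rss_full) / q / (rss_full / df))
  pval <- stats::pf(fstat, q, df, lower.tail = FALSE)
  b <- betas[mod_cols, , drop = FALSE]
  amp <- sign(b["mod_canonical", ]) * sqrt(colSums(b^2))
  structure(
    list(
      betas = betas, fstat = fstat, pvalue = pval, amplitude = amp,
      sigma2 = rss_full / df, df = df, dims = dims
    ),
    class = "first_level_result"
  )
}

#' Robust one-sample group statistics per voxel
#'
#' Intercept-only iteratively re-weighted least squares (Tukey bisquare,
#' tuning constant 4.685) over subjects at each voxel: a robust group mean,
#' its t statistic (estimate / robust SE) with two-sided p, and the final
#' IRLS weights, which downweight outlying subjects toward zero.
#'
#' @param per_subject_amplitude_maps subjects x V matrix of first-level
#'   amplitude summaries.
#' @return object of class `group_stat_map`: `estimate`, `t`, `p`,
#'   `weights` (subjects x V), `n_subjects`.
#' @export
group_robust_regression <- function(per_subject_amplitude_maps) {
  y <- as.matrix(per_subject_amplitude_maps)
  n <- nrow(y)
  if (n < 3) stop("need at least 3 subjects")
  V <- ncol(y)
  est <- tstat <- pval <- numeric(V)
  wts <- matrix(1, n, V)
  for (v in seq_len(V)) {
    fit <- tryCatch(
      suppressWarnings(
        MASS::rlm(y[, v] ~ 1, psi = MASS::psi.bisquare, c = 4.685, maxit = 200)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      est[v] <- mean(y[, v])
      se <- stats::sd(y[, v]) / sqrt(n)
    } else {
      est[v] <- unname(stats::coef(fit)[1])
      se <- sqrt(diag(stats::vcov(fit)))[1]
      wts[, v] <- fit$w
    }
    tstat[v] <- est[v] / se
    pval[v] <- 2 * stats::pt(-abs(tstat[v]), df = n - 1)
  }
  structure(
    list(estimate = est, t = tstat, p = pval, weights = wts, n_subjects = n),
    class = "group_stat_map"
  )
}

#' FDR threshold with a cluster-extent rule
#'
#' Benjamini-Hochberg step-up over all supplied p-values; voxels with
#' adjusted p below `q` form the initial mask, from which connected
#' components of `min_cluster` voxels or fewer are removed (strictly more
#' than `min_cluster` voxels must survive). With a 3D p-value array the
#' components use face adjacency by default; a plain vector skips the
#' cluster rule.
#'
#' @param p_values numeric vector or 3D array of p-values in [0, 1].
#' @param q FDR level.
#' @param min_cluster cluster-extent threshold (components must exceed it).
#' @param connectivity 6 (faces) or 26 (faces+edges+corners).
#' @return list: `mask` (logical, same shape as input), `q_values`
#'   (BH-adjusted p), `n_rejected_fdr` (before the cluster rule).
#' @export
fdr_threshold <- function(p_values, q = 0.05, min_cluster = 20,
                          connectivity = 6) {
  if (!length(p_values)) stop("empty p-value map")
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) stop("p-values outside [0,1]")
  qv <- stats::p.adjust(as.vector(p_values), method = "BH")
  mask <- qv < q & !is.na(qv)
  n_fdr <- sum(mask)
  if (is.array(p_values) && length(dim(p_values)) == 3 && n_fdr > 0) {
    m3 <- array(mask, dim(p_values))
    lab <- label_components_3d(m3, connectivity)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes > min_cluster)
    m3 <- array(lab %in% keep, dim(p_values))
    mask <- m3
    qv <- array(qv, dim(p_values))
  } else if (is.array(p_values)) {
    mask <- array(mask, dim(p_values))
    qv <- array(qv, dim(p_values))
  }
  list(mask = mask, q_values = qv, n_rejected_fdr = n_fdr)
}

# integer labeling of connected components in a logical 3D array
label_components_3d <- function(mask, connectivity = 6) {
  dims <- dim(mask)
  offs <- if (connectivity == 6) {
    rbind(
      c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
      c(0, -1, 0), c(0, 0, 1), c(0, 0, -1)
    )
  } else {
    g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    g[rowSums(abs(g)) > 0, , drop = FALSE]
  }
  lab <- array(0L, dims)
  nextlab <- 0L
  idx_all <- which(mask)
  for (start in idx_all) {
    if (lab[start] != 0L) next
    nextlab <- nextlab + 1L
    queue <- start
    lab[start] <- nextlab
    while (length(queue)) {
      cur <- queue[1]
      queue <- queue[-1]
      ci <- arrayInd(cur, dims)
      nb <- sweep(offs, 2, as.numeric(ci), `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
        nb[, 2] >= 1 & nb[, 2] <= dims[2] &
        nb[, 3] >= 1 & nb[, 3] <= dims[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + (nb[, 2] - 1) * dims[1] + (nb[, 3] - 1) * dims[1] * dims[2]
      lin <- lin[mask[lin] & lab[lin] == 0L]
      if (length(lin)) {
        lab[lin] <- nextlab
        queue <- c(queue, lin)
      }
    }
  }
  lab
}

#' Blind HRF deconvolution of a resting BOLD series
#'
#' Point-process deconvolution: the series is standardized and its local
#' maxima exceeding `event_threshold_sd` are taken as pseudo-events (the
#' spontaneous excursions assumed to mark neural events). A neural-event
#' onset lag relative to the detected BOLD peaks is chosen within
#' `lag_range_s` by least squares, and the HRF is fitted on the original
#' scale as canonical + temporal + dispersion basis regression on the lagged
#' event train. The amplitude is the fitted curve's response height (value
#' at its absolute peak; the canonical basis has unit peak, so a pure
#' canonical response of height a returns a).
#'
#' @param voxel_series numeric BOLD time series (>= 50 scans).
#' @param tr_s repetition time, seconds.
#' @param event_threshold_sd pseudo-event threshold in SD units of the
#'   standardized series.
#' @param lag_range_s two-element search window for the peak-to-onset lag.
#' @param span_s HRF support, seconds.
#' @return object of class `hrf_estimate`: `curve`, `time`, `amplitude`,
#'   `lag_s`, `event_scans`, `flagged` (TRUE when no pseudo-events were
#'   found; amplitude is NA and the voxel is excluded from medians).
#' @export
deconvolve_hrf <- function(voxel_series, tr_s, event_threshold_sd = 1.0,
                           lag_range_s = c(0, 8), span_s = 32) {
  y <- as.numeric(voxel_series)
  n <- length(y)
  if (n < 50) stop("need at least 50 scans")
  sdy <- stats::sd(y)
  flagged_result <- structure(
    list(
      curve = NULL, time = NULL, amplitude = NA_real_, lag_s = NA_real_,
      event_scans = integer(0), flagged = TRUE
    ),
    class = "hrf_estimate"
  )
  if (sdy == 0) {
    return(flagged_result)
  }
  z <- (y - mean(y)) / sdy
  peaks <- which(diff(sign(diff(z))) < 0) + 1L
  peaks <- peaks[z[peaks] > event_threshold_sd]
  if (!length(peaks)) {
    return(flagged_result)
  }
  basis <- canonical_hrf_basis(tr_s, span_s)
  B <- cbind(basis$canonical, basis$temporal, basis$dispersion)
  lags <- seq(floor(lag_range_s[1] / tr_s), ceiling(lag_range_s[2] / tr_s))
  best <- NULL
  for (lg in lags) {
    onsets <- peaks - lg
    onsets <- onsets[onsets >= 1]
    if (!length(onsets)) next
    ev <- numeric(n)
    ev[onsets] <- 1
    X <- cbind(1, apply(B, 2, function(h) {
      stats::convolve(ev, rev(h), type = "open")[seq_len(n)]
    }))
    fit <- stats::lm.fit(X, y)
    rss <- sum(fit$residuals^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(rss = rss, beta = fit$coefficients[-1], lag = lg, onsets = onsets)
    }
  }
  if (is.null(best)) {
    return(flagged_result)
  }
  beta <- best$beta
  beta[is.na(beta)] <- 0
  curve <- as.numeric(B %*% beta)
  amp <- curve[which.max(abs(curve))]
  structure(
    list(
      curve = curve, time = basis$time, amplitude = amp,
      lag_s = best$lag * tr_s, event_scans = best$onsets, flagged = FALSE
    ),
    class = "hrf_estimate"
  )
}

#' @export
print.hrf_estimate <- function(x, ...) {
  if (x$flagged) {
    cat("<hrf_estimate> flagged: no pseudo-events\n")
  } else {
    cat(sprintf(
      "<hrf_estimate> amplitude %.3f, lag %.1f s, %d pseudo-events\n",
      x$amplitude, x$lag_s, length(x$event_scans)
    ))
  }
  invisible(x)
}

#' Deconvolve every voxel inside a mask
#'
#' @param bold 4D BOLD array (x, y, z, t).
#' @param mask logical 3D array selecting voxels.
#' @param tr_s repetition time, seconds.
#' @param ... passed to [deconvolve_hrf()].
#' @return list: `amplitude` (3D array, NA outside mask / flagged voxels),
#'   `flagged` (logical 3D array).
#' @export
deconvolve_mask <- function(bold, mask, tr_s, ...) {
  dims <- dim(bold)[1:3]
  amp <- array(NA_real_, dims)
  flg <- array(FALSE, dims)
  idx <- which(mask)
  flat <- matrix(bold, prod(dims), dim(bold)[4])
  for (v in idx) {
    est <- deconvolve_hrf(flat[v, ], tr_s, ...)
    amp[v] <- est$amplitude
    flg[v] <- est$flagged
  }
  list(amplitude = amp, flagged = flg)
}

#' Hemodynamic lateralization index per paired region
#'
#' HLI = median HRF amplitude over the right-hemisphere voxels minus the
#' median over the homologous left-hemisphere voxels. Flagged voxels
#' (no pseudo-events) are excluded from the medians.
#'
#' @param amplitudes 3D array (or vector) of per-voxel HRF amplitudes; NA
#'   entries are treated as flagged.
#' @param region_masks named list of regions, each a list with logical
#'   `left` and `right` masks conformable with `amplitudes`.
#' @return data.frame with one row per region: `region`,
#'   `median_amp_left`, `median_amp_right`, `hli`, `n_left`, `n_right`.
#' @export
compute_hli <- function(amplitudes, region_masks) {
  rows <- lapply(names(region_masks), function(nm) {
    rm <- region_masks[[nm]]
    al <- amplitudes[rm$left]
    ar <- amplitudes[rm$right]
    al <- al[is.finite(al)]
    ar <- ar[is.finite(ar)]
    if (!length(al) || !length(ar)) {
      stop(sprintf("region %s: a hemisphere has zero valid voxels", nm))
    }
    data.frame(
      region = nm,
      median_amp_left = stats::median(al),
      median_amp_right = stats::median(ar),
      hli = stats::median(ar) - stats::median(al),
      n_left = length(al), n_right = length(ar),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
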