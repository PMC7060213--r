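#' Global field power
#'
#' GFP at sample t is the population standard deviation of the potential
#' across the montage, sqrt(sum_i (X_i - X_mean)^2 / C): a reference-free
#' per-sample measure of momentary map strength. The recording is
#' re-referenced to the common average internally if it is not already.
#'
#' @param recording an [eeg_recording()].
#' @return an object of class `gfp_series` with fields `values` (per-sample
#'   GFP, microvolts), `sfreq`, and (after [select_gfp_peaks()]) peak
#'   bookkeeping.
#' @export
compute_gfp <- function(recording) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (nrow(recording$data) < 2) stop("compute_gfp: single-channel input")
  # always center across channels: idempotent on average-referenced data and
  # guards against a stale reference tag
  d <- sweep(recording$data, 2, colMeans(recording$data))
  C <- nrow(d)
  values <- sqrt(colSums(d^2) / C)
  structure(
    list(
      values = values, sfreq = recording$sfreq,
      peak_indices = integer(0), threshold_sd = NA_real_,
      min_peak_distance_ms = NA_real_
    ),
    class = "gfp_series"
  )
}

#' @export
print.gfp_series <- function(x, ...) {
  cat(sprintf(
    "<gfp_series> %d samples @ %g Hz, %d peaks selected\n",
    length(x$values), x$sfreq, length(x$peak_indices)
  ))
  invisible(x)
}

#' Select prominent GFP peaks
#'
#' Local maxima of the GFP curve, thinned so that retained peaks are at least
#' `min_peak_distance_ms` apart (greedy, keeping the larger of two close
#' peaks), and kept only if they exceed `threshold_sd` standard deviations of
#' the GFP series. The threshold acts as a floor: only prominent, high-SNR
#' maps enter clustering. Maps at GFP peaks are the classic input to
#' microstate clustering because topography is most stable and best defined
#' where field strength is maximal.
#'
#' @param gfp_series a `gfp_series` from [compute_gfp()].
#' @param min_peak_distance_ms minimum separation between retained peaks (ms).
#' @param threshold_sd amplitude floor in SD units of the GFP series.
#' @param direction `"floor"` keeps peaks above the threshold (default);
#'   `"ceiling"` keeps peaks below it (artifact-exclusion reading).
#' @return the series with `peak_indices` set (strictly increasing, possibly
#'   empty).
#' @export
select_gfp_peaks <- function(gfp_series, min_peak_distance_ms = 20,
                             threshold_sd = 1.0,
                             direction = c("floor", "ceiling")) {
  stopifnot(inherits(gfp_series, "gfp_series"))
  direction <- match.arg(direction)
  v <- gfp_series$values
  n <- length(v)
  cand <- which(diff(sign(diff(v))) < 0) + 1L # strict local maxima (interior)
  # plateaus: sign(diff) == 0 runs are not counted as peaks; fine for
  # continuous-valued GFP
  if (length(cand)) {
    thr <- threshold_sd * stats::sd(v)
    keep <- if (direction == "floor") v[cand] > thr else v[cand] <= thr
    cand <- cand[keep]
  }
  min_gap <- max(1, ceiling(min_peak_distance_ms * gfp_series$sfreq / 1000))
  if (length(cand) > 1) {
    # greedy by descending amplitude: a peak survives unless a larger,
    # already-retained peak lies within min_gap samples
    ord <- cand[order(v[cand], decreasing = TRUE)]
    taken <- integer(0)
    for (p in ord) {
      if (!length(taken) || all(abs(taken - p) >= min_gap)) taken <- c(taken, p)
    }
    cand <- sort(taken)
  }
  gfp_series$peak_indices <- as.integer(cand)
  gfp_series$threshold_sd <- threshold_sd
  gfp_series$min_peak_distance_ms <- min_peak_distance_ms
  gfp_series
}

#' Concatenate peak maps across subjects
#'
#' Stacks the average-referenced EEG maps at each subject's selected GFP
#' peaks into one group matrix (rows = maps) for group-level clustering.
#' Row order is subject order, then time order within subject.
#'
#' @param recordings list of [eeg_recording()] sharing one montage.
#' @param peak_lists list of integer peak-index vectors, parallel to
#'   `recordings`.
#' @return matrix with `sum(lengths(peak_lists))` rows and C columns;
#'   attribute `subject` gives the source subject of each row.
#' @export
concatenate_peak_maps <- function(recordings, peak_lists) {
  stopifnot(length(recordings) == length(peak_lists))
  labs <- recordings[[1]]$channel_labels
  for (r in recordings) {
    if (!identical(r$channel_labels, labs)) {
      stop("concatenate_peak_maps: montage mismatch across recordings")
    }
  }
  blocks <- vector("list", length(recordings))
  for (i in seq_along(recordings)) {
    rec <- recordings[[i]]
    if (rec$reference != "average") rec <- average_reference(rec)
    blocks[[i]] <- t(rec$data[, peak_lists[[i]], drop = FALSE])
  }
  out <- do.call(rbind, blocks)
  attr(out, "subject") <- rep(seq_along(recordings), lengths(peak_lists))
  attr(out, "channel_labels") <- labs
  out
}

# rows centered to zero mean (average reference of each map)
center_rows <- function(x) x - rowMeans(x)

# unit-norm rows; zero rows left untouched
normalize_rows <- function(x) {
  nrm <- sqrt(rowSums(x^2))
  nrm[nrm == 0] <- 1
  x / nrm
}

#' Modified K-means microstate clustering
#'
#' Clusters GFP-peak maps into K prototype topographies with the
#' polarity-invariant distance D^2_kn = x_n' x_n - (x_n' z_k)^2 (prototypes
#' unit-norm, maps average-referenced). Assignment takes the arg-min over
#' prototypes; the update re-estimates each prototype as the sign-aligned
#' average of its assigned maps, re-centered and renormalized. Iteration
#' stops when the relative change of the total residual sum(D^2) falls below
#' `tol` or after `max_iter` iterations. The best of `n_restarts` random
#' initializations (lowest CV, equivalently lowest residual at fixed K) is
#' returned.
#'
#' @param chi maps matrix (rows = maps, columns = channels), e.g. from
#'   [concatenate_peak_maps()].
#' @param k number of prototypes.
#' @param max_iter iteration cap.
#' @param tol relative convergence threshold on the residual.
#' @param n_restarts random restarts.
#' @param seed integer seed for the restarts.
#' @param update `"mean"` (sign-aligned averaging, default) or
#'   `"eigen"` (first principal axis of the assigned maps).
#' @return an object of class `microstate_prototypes`: `prototypes` (K x C,
#'   unit-norm zero-mean rows), `labels` (training assignment), `gev_per_cluster`,
#'   `gev_total`, `sigma2`, `cv`, `n_iter`, `converged`, `restart_seed`,
#'   `channel_labels`.
#' @export
fit_modified_kmeans <- function(chi, k = 8, max_iter = 1000, tol = 1e-6,
                                n_restarts = 10, seed = 1,
                                update = c("mean", "eigen")) {
  update <- match.arg(update)
  chi <- center_rows(as.matrix(chi))
  n <- nrow(chi)
  if (k < 1) stop("fit_modified_kmeans: k must be >= 1")
  if (k > n) stop("fit_modified_kmeans: more clusters than maps")
  best <- NULL
  for (r in seq_len(n_restarts)) {
    rs <- derive_seed(seed, r)
    fit <- with_seed(rs, kmeans_single(chi, k, max_iter, tol, update))
    fit$restart_seed <- rs
    if (is.null(best) || fit$residual < best$residual) best <- fit
  }
  ev <- segmentation_stats(chi, best$prototypes, best$labels)
  structure(
    list(
      prototypes = best$prototypes, k = k, labels = best$labels,
      gev_per_cluster = ev$gev_per_cluster, gev_total = ev$gev_total,
      sigma2 = ev$sigma2, cv = ev$cv,
      n_iter = best$n_iter, converged = best$converged,
      objective_trace = best$objective_trace,
      restart_seed = best$restart_seed,
      channel_labels = attr(chi, "channel_labels") %||% colnames(chi)
    ),
    class = "microstate_prototypes"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.microstate_prototypes <- function(x, ...) {
  cat(sprintf(
    "<microstate_prototypes> K = %d over %d channels | GEV = %.4f, CV = %.4g, %s in %d iter\n",
    x$k, ncol(x$prototypes), x$gev_total, x$cv,
    if (x$converged) "converged" else "not converged", x$n_iter
  ))
  invisible(x)
}

kmeans_single <- function(chi, k, max_iter, tol, update) {
  n <- nrow(chi)
  z <- normalize_rows(chi[sample.int(n, k), , drop = FALSE])
  xx <- rowSums(chi^2)
  prev <- Inf
  labels <- integer(n)
  converged <- FALSE
  iter <- 0
  trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    proj <- chi %*% t(z) # n x k, x_n' z_k
    d2 <- xx - proj^2
    labels <- max.col(-d2, ties.method = "first")
    resid <- sum(d2[cbind(seq_len(n), labels)])
    trace <- c(trace, resid)
    for (j in seq_len(k)) {
      idx <- which(labels == j)
      if (!length(idx)) {
        # empty cluster: reseed on the worst-fit map
        z[j, ] <- chi[which.max(d2[cbind(seq_len(n), labels)]), ]
      } else if (update == "mean") {
        s <- sign(proj[idx, j])
        s[s == 0] <- 1
        z[j, ] <- colSums(chi[idx, , drop = FALSE] * s)
      } else {
        m <- crossprod(chi[idx, , drop = FALSE])
        z[j, ] <- eigen(m, symmetric = TRUE)$vectors[, 1]
      }
    }
    z <- normalize_rows(center_rows(z))
    floor_resid <- .Machine$double.eps * sum(xx)
    if (resid <= floor_resid ||
      (is.finite(prev) && abs(prev - resid) <= tol * max(prev, floor_resid))) {
      converged <- TRUE
      prev <- resid
      break
    }
    prev <- resid
  }
  # final assignment consistent with the returned prototypes
  proj <- chi %*% t(z)
  d2 <- rowSums(chi^2) - proj^2
  labels <- max.col(-d2, ties.method = "first")
  list(
    prototypes = z, labels = labels,
    residual = sum(d2[cbind(seq_len(n), labels)]),
    n_iter = iter, converged = converged, objective_trace = trace
  )
}

# shared GEV / sigma^2 / CV computation on an assigned set of maps
segmentation_stats <- function(chi, z, labels, cv_squared_correction = FALSE) {
  chi <- center_rows(as.matrix(chi))
  C <- ncol(chi)
  k <- nrow(z)
  n <- nrow(chi)
  valid <- which(rowSums(chi^2) > 0 & !is.na(labels))
  gfp <- sqrt(rowSums(chi^2) / C)
  # Pearson spatial correlation between map and its assigned prototype
  zc <- center_rows(z)
  gev_n <- numeric(n)
  dot <- numeric(n)
  for (j in seq_len(k)) {
    idx <- valid[labels[valid] == j]
    if (!length(idx)) next
    xs <- chi[idx, , drop = FALSE]
    co <- as.numeric(xs %*% zc[j, ]) /
      (sqrt(rowSums(xs^2)) * sqrt(sum(zc[j, ]^2)))
    gev_n[idx] <- (co * gfp[idx])^2
    dot[idx] <- as.numeric(xs %*% z[j, ])
  }
  denom <- sum(gfp[valid]^2)
  gev_n <- gev_n / denom
  gev_per_cluster <- vapply(
    seq_len(k),
    function(j) sum(gev_n[valid[labels[valid] == j]]),
    numeric(1)
  )
  sigma2 <- sum(rowSums(chi[valid, , drop = FALSE]^2) - dot[valid]^2) /
    (length(valid) * (C - 1))
  cv <- if (C - k - 1 <= 0) {
    warning("CV undefined: K >= C - 1")
    NA_real_
  } else if (cv_squared_correction) {
    sigma2 * ((C - 1) / (C - k - 1))^2
  } else {
    sigma2 * ((C - 1) / (C - k - 1))
  }
  list(
    gev_per_cluster = gev_per_cluster, gev_total = sum(gev_per_cluster),
    sigma2 = sigma2, cv = cv
  )
}

#' Goodness of fit of a microstate segmentation
#'
#' Global explained variance and the cross-validation criterion for a set of
#' labeled maps. Per sample, GEV_n = (Corr(x_n, z_tau_n) * GFP_n)^2 /
#' sum(GFP^2); a cluster's GEV is the sum over its members and `gev_total`
#' the sum over clusters. The residual variance is sigma^2 =
#' sum_n (x_n' x_n - (x_n' z_tau_n)^2) / (N (C - 1)) and the model-selection
#' score CV = sigma^2 * (C - 1)/(C - K - 1) penalizes K relative to the
#' channel count (set `cv_squared_correction = TRUE` for the classic squared
#' penalty). Flat (zero-GFP) maps are excluded from all sums.
#'
#' @param chi maps matrix (rows = maps).
#' @param prototype_set a `microstate_prototypes` object.
#' @param labels integer assignment of each row to a prototype (NA allowed
#'   for sentinel rows).
#' @param cv_squared_correction square the (C-1)/(C-K-1) factor.
#' @return list with `gev_per_cluster`, `gev_total`, `sigma2`, `cv`.
#' @export
evaluate_segmentation <- function(chi, prototype_set, labels,
                                  cv_squared_correction = FALSE) {
  stopifnot(inherits(prototype_set, "microstate_prototypes"))
  if (length(labels) != nrow(chi)) stop("labels length must match rows of chi")
  lv <- labels[!is.na(labels)]
  if (length(lv) && (min(lv) < 1 || max(lv) > prototype_set$k)) {
    stop("labels outside [1, K]")
  }
  segmentation_stats(chi, prototype_set$prototypes, labels, cv_squared_correction)
}

#' Back-fit microstate prototypes onto a recording
#'
#' Labels every EEG sample with the prototype of minimal global map
#' dissimilarity, GMD_kn = ||x_n / GFP_n - z_k / GFP(z_k)|| / sqrt(C)
#' (both maps average-referenced and scaled to unit GFP). GMD is 0 for
#' identical topographies and 2 for polarity-inverted ones. In
#' polarity-invariant mode (default, consistent with the clustering
#' distance) the minimum is also taken over the flipped prototype -z_k and
#' the winning sign is recorded. Zero-GFP samples get the sentinel label NA
#' and are excluded downstream.
#'
#' @param recording an [eeg_recording()] on the prototypes' montage.
#' @param prototype_set a `microstate_prototypes` object.
#' @param polarity_invariant minimize over both polarities of each prototype.
#' @return an object of class `microstate_labeling`: `labels` (per sample,
#'   NA sentinel), `gmd` (winning dissimilarity), `polarity_sign` (+1/-1),
#'   `source_k`.
#' @export
backfit <- function(recording, prototype_set, polarity_invariant = TRUE) {
  stopifnot(
    inherits(recording, "eeg_recording"),
    inherits(prototype_set, "microstate_prototypes")
  )
  if (!is.null(prototype_set$channel_labels) &&
    !identical(recording$channel_labels, prototype_set$channel_labels)) {
    stop("backfit: recording montage does not match prototypes")
  }
  if (recording$reference != "average") recording <- average_reference(recording)
  x <- recording$data # C x N, zero-mean columns
  C <- nrow(x)
  n <- ncol(x)
  gfp <- sqrt(colSums(x^2) / C)
  z <- prototype_set$prototypes # K x C, unit-norm zero-mean
  # unit-GFP maps: x/GFP has norm sqrt(C); z/GFP(z) = z*sqrt(C)
  labels <- rep(NA_integer_, n)
  gmd <- rep(NA_real_, n)
  sign_out <- rep(NA_real_, n)
  ok <- which(gfp > 0)
  if (length(ok)) {
    u <- x[, ok, drop = FALSE] / rep(gfp[ok], each = C) # C x n_ok, norm sqrt(C)
    # GMD^2 = (2C - 2 * s * (z_k . u_n) * sqrt(C)) / C
    proj <- z %*% u # K x n_ok
    if (polarity_invariant) {
      best <- apply(abs(proj), 2, which.max)
      pb <- proj[cbind(best, seq_along(ok))]
      s <- ifelse(pb >= 0, 1, -1)
      gmd2 <- (2 * C - 2 * abs(pb) * sqrt(C)) / C
    } else {
      best <- apply(proj, 2, which.max)
      pb <- proj[cbind(best, seq_along(ok))]
      s <- rep(1, length(ok))
      gmd2 <- (2 * C - 2 * pb * sqrt(C)) / C
    }
    labels[ok] <- as.integer(best)
    gmd[ok] <- sqrt(pmax(gmd2, 0))
    sign_out[ok] <- s
  }
  structure(
    list(
      labels = labels, gmd = gmd, polarity_sign = sign_out,
      source_k = prototype_set$k
    ),
    class = "microstate_labeling"
  )
}

#' @export
print.microstate_labeling <- function(x, ...) {
  cat(sprintf(
    "<microstate_labeling> %d samples, K = %d, %d sentinel\n",
    length(x$labels), x$source_k, sum(is.na(x$labels))
  ))
  invisible(x)
}

#' Re-express a recording through its microstate sequence
#'
#' Replaces each sample by its assigned prototype topography scaled by the
#' sample's GFP: channel c at sample n becomes z[mu_n, c] * GFP_n. The
#' result has the shape of the input, preserves each sample's GFP exactly
#' (prototypes are unit-norm and zero-mean), and discards within-state
#' topographic fluctuation - the "quasi-stable" version of the recording
#' from which microstate alpha power is computed. Sentinel samples become
#' zero vectors. With `scale = "prototype"` the raw prototype amplitude is
#' used instead of GFP scaling.
#'
#' @param recording the [eeg_recording()] the labeling was derived from.
#' @param labeling a `microstate_labeling` from [backfit()].
#' @param prototype_set the `microstate_prototypes` used for the labeling.
#' @param scale `"gfp"` (default) or `"prototype"` (unscaled topography).
#' @param use_polarity multiply by the recorded polarity sign.
#' @return an [eeg_recording()] (average reference).
#' @export
reexpress <- function(recording, labeling, prototype_set,
                      scale = c("gfp", "prototype"), use_polarity = TRUE) {
  scale <- match.arg(scale)
  stopifnot(
    inherits(recording, "eeg_recording"),
    inherits(labeling, "microstate_labeling"),
    inherits(prototype_set, "microstate_prototypes")
  )
  if (length(labeling$labels) != ncol(recording$data)) {
    stop("reexpress: labeling length does not match recording")
  }
  if (recording$reference != "average") recording <- average_reference(recording)
  C <- nrow(recording$data)
  n <- ncol(recording$data)
  gfp <- sqrt(colSums(recording$data^2) / C)
  out <- matrix(0, C, n)
  ok <- which(!is.na(labeling$labels))
  if (length(ok)) {
    # prototypes are unit-norm zero-mean, so z * GFP_n * sqrt(C) has GFP
    # exactly GFP_n: the re-expressed sample preserves the original field
    # strength
    amp <- if (scale == "gfp") gfp[ok] * sqrt(C) else rep(1, length(ok))
    s <- if (use_polarity) labeling$polarity_sign[ok] else rep(1, length(ok))
    out[, ok] <- t(prototype_set$prototypes[labeling$labels[ok], , drop = FALSE]) *
      rep(amp * s, each = C)
  }
  res <- recording
  res$data <- out
  res$reference <- "average"
  res
}

#' Choose the number of active microstates by minimum CV
#'
#' Fits the modified K-means at each candidate K and returns the fit with
#' the lowest cross-validation criterion, the classic residual-noise-based
#' selection of the active microstate count.
#'
#' @param chi maps matrix.
#' @param k_range candidate cluster counts.
#' @param ... passed to [fit_modified_kmeans()].
#' @return list: `best` (`microstate_prototypes` at the CV-optimal K),
#'   `cv_by_k` (named numeric), `fits` (all fits).
#' @export
select_active_k <- function(chi, k_range = 2:8, ...) {
  fits <- lapply(k_range, function(k) fit_modified_kmeans(chi, k = k, ...))
  cvs <- vapply(fits, function(f) f$cv, numeric(1))
  names(cvs) <- k_range
  list(best = fits[[which.min(cvs)]], cv_by_k = cvs, fits = fits)
}
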