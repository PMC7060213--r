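#' EEG recording container
#'
#' A light S3 container for multichannel EEG: a channels-by-samples matrix in
#' microvolts plus the sampling rate, channel labels, 3D electrode positions
#' and a reference tag. Downstream stages assert on the reference tag so that
#' the standard-asymmetry branch runs on CSD-referenced data while the
#' microstate branch runs on average-referenced data.
#'
#' @param data numeric matrix, channels x samples (microvolts).
#' @param sfreq sampling frequency in Hz (> 0).
#' @param channel_labels character vector of unique 10-20 labels, one per row.
#' @param positions data.frame with `label`, `x`, `y`, `z` unit-sphere
#'   coordinates; defaults to the subset of [standard_montage_32()] matching
#'   `channel_labels`.
#' @param reference one of `"average"`, `"csd"`, `"other"`.
#' @return an object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, sfreq, channel_labels,
                          positions = NULL,
                          reference = c("other", "average", "csd")) {
  reference <- match.arg(reference)
  data <- as.matrix(data)
  if (nrow(data) < 2) stop("eeg_recording: need at least 2 channels")
  if (!is.numeric(sfreq) || length(sfreq) != 1 || sfreq <= 0) {
    stop("eeg_recording: sfreq must be a positive scalar")
  }
  if (length(channel_labels) != nrow(data)) {
    stop("eeg_recording: one label per channel row required")
  }
  if (anyDuplicated(channel_labels)) stop("eeg_recording: duplicate channel labels")
  if (any(!is.finite(data))) stop("eeg_recording: non-finite samples")
  if (is.null(positions)) {
    m <- standard_montage_32()
    idx <- match(channel_labels, m$label)
    positions <- if (anyNA(idx)) NULL else m[idx, , drop = FALSE]
  }
  structure(
    list(
      data = data, sfreq = sfreq,
      channel_labels = as.character(channel_labels),
      positions = positions, reference = reference
    ),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), reference: %s\n",
    nrow(x$data), ncol(x$data), x$sfreq, ncol(x$data) / x$sfreq, x$reference
  ))
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)

#' Re-reference a recording to the common average
#'
#' Subtracts the instantaneous mean across channels from every sample, the
#' canonical reference for microstate analysis (topographic quantities such
#' as GFP and GMD are defined on average-referenced maps).
#'
#' @param recording an [eeg_recording()].
#' @return the recording with zero-mean columns and `reference = "average"`.
#' @export
average_reference <- function(recording) {
  stopifnot(inherits(recording, "eeg_recording"))
  recording$data <- sweep(recording$data, 2, colMeans(recording$data))
  recording$reference <- "average"
  recording
}

#' Read a channels-by-samples EEG table from TSV
#'
#' Plain-text ingestion: first column channel label, remaining columns
#' samples. Intended for small fixtures and interoperability with exported
#' data; recordings from acquisition systems should be converted to this
#' layout (or passed as matrices to [eeg_recording()]).
#'
#' @param path TSV file path.
#' @param sfreq sampling frequency in Hz.
#' @param reference reference tag of the stored data.
#' @return an [eeg_recording()].
#' @export
read_eeg_tsv <- function(path, sfreq, reference = "other") {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  labels <- as.character(tab[[1]])
  data <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(data) <- "double"
  dimnames(data) <- NULL
  eeg_recording(data, sfreq = sfreq, channel_labels = labels, reference = reference)
}

#' Write a recording as a channels-by-samples TSV
#'
#' @param recording an [eeg_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_eeg_tsv <- function(recording, path) {
  stopifnot(inherits(recording, "eeg_recording"))
  tab <- data.frame(recording$channel_labels, recording$data)
  utils::write.table(tab, path,
    sep = "\t", row.names = FALSE,
    col.names = FALSE, quote = FALSE
  )
  invisible(path)
}
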