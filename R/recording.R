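#' Multichannel LFP recording container
#'
#' A raw recording holds a channels-by-time sample matrix in millivolts plus
#' its sampling rate and channel labels. The four default channels are the
#' bilateral nucleus accumbens shell and medial prefrontal cortex sites:
#' `lNAcSh`, `rNAcSh`, `lmPFC`, `rmPFC`.
#'
#' @param samples Numeric matrix, channels x time, in mV.
#' @param fs Sampling rate in Hz.
#' @param channel_labels Character vector of unique channel names, one per
#'   row of `samples`.
#' @param subject_id,session_id Identifiers carried through the pipeline.
#' @param artifact_truth Optional data frame of injected ground-truth
#'   artifact events (columns `time_s`, `channel`); used by tests.
#' @return An object of class `lfp_recording`.
#' @export
lfp_recording <- function(samples, fs, channel_labels = lfp_channels(),
                          subject_id = "s1", session_id = "ses1",
                          artifact_truth = NULL) {
  if (!is.matrix(samples)) samples <- matrix(samples, nrow = 1)
  stopifnot(is.numeric(samples), is.numeric(fs), length(fs) == 1, fs > 0)
  if (length(channel_labels) != nrow(samples)) {
    stop("need one channel label per row of samples", call. = FALSE)
  }
  if (anyDuplicated(channel_labels)) {
    stop("channel labels must be unique", call. = FALSE)
  }
  rownames(samples) <- channel_labels
  structure(
    list(samples = samples, fs = fs, channel_labels = channel_labels,
         subject_id = subject_id, session_id = session_id,
         artifact_truth = artifact_truth),
    class = "lfp_recording"
  )
}

#' Default channel labels
#'
#' Bilateral NAcSh and mPFC electrode sites in the fixed order used for
#' feature naming.
#' @return Character vector of four channel labels.
#' @export
lfp_channels <- function() c("lNAcSh", "rNAcSh", "lmPFC", "rmPFC")

#' Channel pairs in canonical order
#'
#' All unordered channel pairs, enumerated in the fixed channel order, used
#' for coherence feature naming (`chanA-chanB`).
#' @param channels Character vector of channel labels.
#' @return Character vector of `"A-B"` pair names.
#' @export
lfp_channel_pairs <- function(channels = lfp_channels()) {
  cmb <- utils::combn(channels, 2)
  paste(cmb[1, ], cmb[2, ], sep = "-")
}

#' @export
print.lfp_recording <- function(x, ...) {
  cat(sprintf("<lfp_recording> %s / %s: %d channels x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, x$session_id, nrow(x$samples), ncol(x$samples),
              x$fs, ncol(x$samples) / x$fs))
  invisible(x)
}

#' Convert a recording to a long tibble
#'
#' One row per (channel, sample): columns `time_s`, `channel`, `mv`.
#' @param x An `lfp_recording`.
#' @param ... Unused.
#' @return A tibble.
#' @method as_tibble lfp_recording
#' @export
as_tibble.lfp_recording <- function(x, ...) {
  n <- ncol(x$samples)
  tibble::tibble(
    time_s = rep(seq_len(n) - 1, times = nrow(x$samples)) / x$fs,
    channel = rep(x$channel_labels, each = n),
    mv = as.vector(t(x$samples))
  )
}

#' Write / read a recording as CSV
#'
#' Plain-text interchange format: a wide CSV with a `time_s` column and one
#' column per channel (mV). The sampling rate is recovered from the time
#' column on read.
#'
#' @param rec An `lfp_recording`.
#' @param path File path.
#' @return `write_recording_csv` returns `path` invisibly;
#'   `read_recording_csv` returns an `lfp_recording`.
#' @export
write_recording_csv <- function(rec, path) {
  df <- data.frame(time_s = (seq_len(ncol(rec$samples)) - 1) / rec$fs,
                   t(rec$samples), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_recording_csv
#' @param subject_id,session_id Identifiers to attach on read.
#' @export
read_recording_csv <- function(path, subject_id = "s1", session_id = "ses1") {
  df <- utils::read.csv(path, check.names = FALSE)
  fs <- 1 / stats::median(diff(df$time_s))
  chans <- setdiff(names(df), "time_s")
  lfp_recording(t(as.matrix(df[chans])), fs = round(fs), channel_labels = chans,
                subject_id = subject_id, session_id = session_id)
}
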