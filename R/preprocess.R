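#' Notch-filter a recording
#'
#' Applies a Chebyshev type I band-stop filter centered on the line-noise
#' frequency to every channel. The default is a fourth-order design with a
#' 59-61 Hz stop band, applied forward-backward (zero phase). The design
#' ripple is 0.5 dB so that the doubled passband ripple of the two-pass
#' application stays within 1 dB.
#'
#' @param rec An [lfp_recording()].
#' @param center Stop-band center frequency in Hz; must be below Nyquist.
#' @param order Chebyshev prototype order.
#' @param ripple_db Passband ripple in dB.
#' @param half_width Half-width of the stop band in Hz.
#' @return A filtered [lfp_recording()] with the same shape and labels.
#' @export
notch_filter <- function(rec, center = 60, order = 4, ripple_db = 0.5,
                         half_width = 1) {
  nyq <- rec$fs / 2
  if (center <= 0 || center >= nyq) {
    stop("notch center must lie in (0, Nyquist)", call. = FALSE)
  }
  flt <- signal::cheby1(order, ripple_db,
                        c(center - half_width, center + half_width) / nyq,
                        type = "stop")
  out <- rec$samples
  for (i in seq_len(nrow(out))) {
    out[i, ] <- signal::filtfilt(flt, rec$samples[i, ])
  }
  lfp_recording(out, fs = rec$fs, channel_labels = rec$channel_labels,
                subject_id = rec$subject_id, session_id = rec$session_id,
                artifact_truth = rec$artifact_truth)
}

#' Decimate a recording
#'
#' Reduces the sampling rate by an integer factor with an anti-alias
#' low-pass filter applied before sample selection (the standard
#' IIR decimator). The default factor 5 takes 2 kHz to 400 Hz.
#'
#' @param rec An [lfp_recording()].
#' @param factor Integer decimation factor; `fs` must be divisible by it.
#' @return An [lfp_recording()] at `fs / factor`.
#' @export
decimate_recording <- function(rec, factor = 5) {
  stopifnot(factor >= 1, factor == round(factor))
  if (factor == 1) return(rec)
  if (rec$fs %% factor != 0) {
    stop("sampling rate must be divisible by the decimation factor", call. = FALSE)
  }
  out <- NULL
  for (i in seq_len(nrow(rec$samples))) {
    y <- signal::decimate(rec$samples[i, ], q = factor, ftype = "iir")
    if (is.null(out)) out <- matrix(0, nrow(rec$samples), length(y))
    out[i, ] <- y
  }
  lfp_recording(out, fs = rec$fs / factor, channel_labels = rec$channel_labels,
                subject_id = rec$subject_id, session_id = rec$session_id,
                artifact_truth = rec$artifact_truth)
}

#' Detect amplitude artifacts and build a removal mask
#'
#' Any sample on any channel whose absolute value reaches `threshold` marks
#' an artifact event; the removal interval extends `pre_window` seconds
#' before and `post_window` seconds after the event, clipped to the
#' recording bounds. Overlapping intervals are merged. A single mask is
#' applied jointly to all channels so that coherence is always computed on
#' time-aligned clean data.
#'
#' @param rec An [lfp_recording()].
#' @param threshold Detection threshold in mV (default 2).
#' @param pre_window Seconds removed before each event (default 0.0125).
#' @param post_window Seconds removed after each event (default 1).
#' @return An object of class `artifact_mask`: a tibble of half-open
#'   sample-index intervals (`start`, `end`, 0-based) with attributes `fs`,
#'   `n_samples` and `total_removed_s`.
#' @export
find_artifact_mask <- function(rec, threshold = 2, pre_window = 0.0125,
                               post_window = 1) {
  stopifnot(threshold > 0, pre_window >= 0, post_window >= 0)
  n <- ncol(rec$samples)
  hits <- which(apply(abs(rec$samples) >= threshold, 2, any)) - 1L  # 0-based
  ivals <- tibble::tibble(start = integer(0), end = integer(0))
  if (length(hits)) {
    pre <- round(pre_window * rec$fs)
    post <- round(post_window * rec$fs)
    starts <- pmax(0L, hits - pre)
    ends <- pmin(n, hits + post + 1L)  # half-open
    o <- order(starts)
    starts <- starts[o]; ends <- ends[o]
    ms <- starts[1]; me <- ends[1]
    outs <- integer(0); oute <- integer(0)
    for (k in seq_along(starts)[-1]) {
      if (starts[k] <= me) {
        me <- max(me, ends[k])
      } else {
        outs <- c(outs, ms); oute <- c(oute, me)
        ms <- starts[k]; me <- ends[k]
      }
    }
    ivals <- tibble::tibble(start = c(outs, ms), end = c(oute, me))
  }
  structure(ivals,
            fs = rec$fs, n_samples = n,
            total_removed_s = sum(ivals$end - ivals$start) / rec$fs,
            class = c("artifact_mask", class(ivals)))
}

#' Segment the unmasked signal into fixed-length epochs
#'
#' The complement of the mask is decomposed into maximal contiguous runs;
#' each run at least `epoch_length` long yields `floor(run / epoch_length)`
#' non-overlapping epochs starting at the run's first sample, and the
#' remainder is dropped. Epochs are time-aligned across channels.
#'
#' @param rec An [lfp_recording()].
#' @param mask An `artifact_mask` from [find_artifact_mask()], or `NULL`
#'   for a clean recording.
#' @param epoch_length Epoch length in seconds (default 3).
#' @param max_epochs Optional cap on the number of epochs kept (earliest
#'   first), for equalizing analyzed time across recordings; `Inf` keeps
#'   all epochs.
#' @return An object of class `epoch_set`: list with `epochs` (list of
#'   channels x samples matrices), `epoch_length`, `fs`, `channel_labels`,
#'   `subject_id`, `session_id`, `starts` (0-based start samples).
#' @export
segment_epochs <- function(rec, mask = NULL, epoch_length = 3,
                           max_epochs = Inf) {
  stopifnot(epoch_length > 0, max_epochs >= 1)
  n <- ncol(rec$samples)
  el <- round(epoch_length * rec$fs)
  keep <- rep(TRUE, n)
  if (!is.null(mask) && nrow(mask) > 0) {
    for (k in seq_len(nrow(mask))) {
      keep[(mask$start[k] + 1L):mask$end[k]] <- FALSE
    }
  }
  r <- rle(keep)
  run_ends <- cumsum(r$lengths)
  run_starts <- run_ends - r$lengths + 1L
  starts <- integer(0)
  for (k in which(r$values)) {
    n_ep <- r$lengths[k] %/% el
    if (n_ep > 0) {
      starts <- c(starts, run_starts[k] + el * (seq_len(n_ep) - 1L) - 1L)  # 0-based
    }
  }
  if (!length(starts)) {
    warning("no artifact-free run long enough for a single epoch")
  }
  if (length(starts) > max_epochs) starts <- starts[seq_len(max_epochs)]
  epochs <- lapply(starts, function(s) rec$samples[, (s + 1L):(s + el), drop = FALSE])
  structure(
    list(epochs = epochs, epoch_length = epoch_length, fs = rec$fs,
         channel_labels = rec$channel_labels, subject_id = rec$subject_id,
         session_id = rec$session_id, starts = starts),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs of %g s @ %g Hz (%d channels)\n",
              length(x$epochs), x$epoch_length, x$fs, length(x$channel_labels)))
  invisible(x)
}

#' Run the full preprocessing chain
#'
#' notch filter, then decimation, then artifact detection on the decimated
#' signal, then epoch segmentation — the narrative order of the recording
#' methods this pipeline follows.
#'
#' @param rec An [lfp_recording()] (typically 2 kHz).
#' @param config A [pipeline_config()].
#' @return An `epoch_set`, with the artifact mask attached as attribute
#'   `"mask"`.
#' @export
preprocess_recording <- function(rec, config = pipeline_config()) {
  p <- config$preprocessing
  rec <- notch_filter(rec, center = p$notch_center, order = p$notch_order,
                      ripple_db = p$notch_ripple_db,
                      half_width = p$notch_half_width)
  rec <- decimate_recording(rec, factor = p$decimation_factor)
  mask <- find_artifact_mask(rec, threshold = p$artifact_threshold,
                             pre_window = p$artifact_pre_window,
                             post_window = p$artifact_post_window)
  eps <- segment_epochs(rec, mask, epoch_length = p$epoch_length)
  attr(eps, "mask") <- mask
  eps
}
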