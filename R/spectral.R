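# Welch averaged-periodogram engine.
#
# No installed R package exposes pwelch/mscohere-style estimators, so the
# segmenting, windowing and averaging are implemented here directly on
# stats::fft with a Hamming window, following the standard one-sided
# density convention (power doubled except at DC and Nyquist, normalised by
# fs * sum(w^2)). Cross-spectra use the same segmentation so coherence is
# consistent with the auto-spectra.

# Segment a vector into windows of `nw` samples advancing by `step`.
welch_segments <- function(x, nw, step) {
  n <- length(x)
  n_seg <- (n - nw) %/% step + 1L
  if (n_seg < 1) stop("signal shorter than one window", call. = FALSE)
  starts <- (seq_len(n_seg) - 1L) * step + 1L
  vapply(starts, function(s) x[s:(s + nw - 1L)], numeric(nw))
}

# Windowed FFTs of all segments of all channels: list (per channel) of
# complex nfreq x n_seg matrices, plus the frequency grid.
welch_ffts <- function(mat, fs, nw, step) {
  w <- signal::hamming(nw)
  n_keep <- nw %/% 2 + 1L
  ffts <- lapply(seq_len(nrow(mat)), function(i) {
    seg <- welch_segments(mat[i, ], nw, step) * w
    f <- stats::mvfft(seg)
    f[seq_len(n_keep), , drop = FALSE]
  })
  list(ffts = ffts, freqs = (seq_len(n_keep) - 1L) * fs / nw,
       scale = 1 / (fs * sum(w^2)), n_keep = n_keep, nfft = nw)
}

one_sided <- function(s, nfft, n_keep) {
  # double all bins except DC (and Nyquist when nfft is even)
  dbl <- rep(2, n_keep)
  dbl[1] <- 1
  if (nfft %% 2 == 0) dbl[n_keep] <- 1
  s * dbl
}

#' Welch power spectral density of an epoch set
#'
#' Per epoch, each channel is cut into Hamming-windowed segments of
#' `window_length` seconds with the given overlap; the averaged one-sided
#' periodogram gives the epoch PSD, and epoch PSDs are averaged (in the
#' linear domain) across epochs before conversion to dB. The dB reference
#' is 1 microvolt^2/Hz, which keeps broadband dB values positive for
#' physiological millivolt-scale signals so the percent-of-total
#' normalization in [band_power_features()] preserves the direction of
#' power changes. The defaults — 1.28 s windows with 50% overlap — give a
#' 0.78125 Hz grid at 400 Hz.
#'
#' @param epochs An `epoch_set` from [segment_epochs()].
#' @param window_length Welch window length in seconds; must not exceed the
#'   epoch length.
#' @param overlap_fraction Fractional overlap between consecutive windows,
#'   in [0, 1).
#' @return An object of class `spectral_estimate`: `freqs` (Hz), `psd_db`
#'   (channels x freqs matrix, dB re 1 microvolt^2/Hz), `psd` (linear,
#'   mV^2/Hz), `n_epochs`, `fs`, `channel_labels`.
#' @export
epoch_psd <- function(epochs, window_length = 1.28, overlap_fraction = 0.5) {
  check_epochs(epochs, window_length, overlap_fraction)
  nw <- round(window_length * epochs$fs)
  step <- max(1L, round(nw * (1 - overlap_fraction)))
  acc <- NULL
  for (ep in epochs$epochs) {
    wf <- welch_ffts(ep, epochs$fs, nw, step)
    p <- vapply(wf$ffts, function(f) {
      one_sided(rowMeans(Mod(f)^2) * wf$scale, wf$nfft, wf$n_keep)
    }, numeric(wf$n_keep))
    acc <- if (is.null(acc)) p else acc + p
  }
  psd <- t(acc / length(epochs$epochs))
  rownames(psd) <- epochs$channel_labels
  freqs <- (seq_len(ncol(psd)) - 1L) * epochs$fs / nw
  structure(
    list(freqs = freqs, psd = psd, psd_db = 10 * log10(psd / 1e-6),
         n_epochs = length(epochs$epochs), fs = epochs$fs,
         channel_labels = epochs$channel_labels,
         subject_id = epochs$subject_id, session_id = epochs$session_id),
    class = "spectral_estimate"
  )
}

#' Magnitude-squared coherence between two channels of an epoch set
#'
#' Per epoch, Welch cross- and auto-spectra over Hamming-windowed segments
#' give the magnitude-squared coherence
#' `|<Sxy>|^2 / (<Sxx> <Syy>)` (angle brackets: average over segments);
#' per-epoch coherence spectra are then averaged across epochs. Values lie
#' in [0, 1]. With few segments per epoch the estimator has the classical
#' positive small-sample bias (about 1/L for L segments under
#' independence).
#'
#' @param epochs An `epoch_set`.
#' @param pair Length-2 character vector or `"A-B"` string naming the two
#'   channels.
#' @param window_length,overlap_fraction As in [epoch_psd()].
#' @return List: `freqs`, `coherence` (vector in [0, 1]), `n_epochs`.
#' @export
epoch_coherence <- function(epochs, pair, window_length = 1.28,
                            overlap_fraction = 0.5) {
  check_epochs(epochs, window_length, overlap_fraction)
  if (length(pair) == 1) pair <- strsplit(pair, "-", fixed = TRUE)[[1]]
  if (!all(pair %in% epochs$channel_labels)) {
    stop("both channels of the pair must be present", call. = FALSE)
  }
  ia <- match(pair[1], epochs$channel_labels)
  ib <- match(pair[2], epochs$channel_labels)
  nw <- round(window_length * epochs$fs)
  step <- max(1L, round(nw * (1 - overlap_fraction)))
  acc <- NULL
  for (ep in epochs$epochs) {
    wf <- welch_ffts(ep[c(ia, ib), , drop = FALSE], epochs$fs, nw, step)
    fa <- wf$ffts[[1]]; fb <- wf$ffts[[2]]
    sxx <- rowMeans(Mod(fa)^2)
    syy <- rowMeans(Mod(fb)^2)
    sxy <- rowMeans(fa * Conj(fb))
    coh <- Mod(sxy)^2 / (sxx * syy)
    acc <- if (is.null(acc)) coh else acc + coh
  }
  freqs <- (seq_len(length(acc)) - 1L) * epochs$fs / nw
  list(freqs = freqs, coherence = acc / length(epochs$epochs),
       n_epochs = length(epochs$epochs))
}

check_epochs <- function(epochs, window_length, overlap_fraction) {
  if (!length(epochs$epochs)) {
    stop("epoch set is empty: no artifact-free epochs to analyse", call. = FALSE)
  }
  if (window_length > epochs$epoch_length) {
    stop("window_length must not exceed the epoch length", call. = FALSE)
  }
  if (overlap_fraction < 0 || overlap_fraction >= 1) {
    stop("overlap_fraction must be in [0, 1)", call. = FALSE)
  }
  invisible(TRUE)
}

#' Normalized band power features
#'
#' For each channel and band: the mean dB PSD over the band's frequency
#' bins (exclusion bins dropped), expressed as a percent of the mean dB PSD
#' over the broadband normalization range (same exclusion). A flat spectrum
#' therefore scores 100 in every band. `domain = "linear"` averages the
#' linear-scale PSD instead of dB values before taking the percent.
#'
#' @param est A `spectral_estimate` from [epoch_psd()].
#' @param scheme A [band_scheme()].
#' @param domain Average `"db"` (default) or `"linear"` PSD values within
#'   bands.
#' @return Tibble: `channel`, `band`, `power_pct`.
#' @export
band_power_features <- function(est, scheme = band_scheme(),
                                domain = c("db", "linear")) {
  domain <- match.arg(domain)
  p <- if (domain == "db") est$psd_db else est$psd
  norm_sel <- band_bins(est$freqs, scheme$norm_range, scheme$exclusion)
  if (!any(norm_sel)) stop("no frequency bins inside norm_range", call. = FALSE)
  purrr::map_dfr(names(scheme$bands), function(bn) {
    sel <- band_bins(est$freqs, scheme$bands[[bn]], scheme$exclusion)
    if (!any(sel)) {
      stop("band '", bn, "' contains no frequency bins (resolution too coarse)",
           call. = FALSE)
    }
    tibble::tibble(
      channel = est$channel_labels,
      band = bn,
      power_pct = 100 * rowMeans(p[, sel, drop = FALSE]) /
        rowMeans(p[, norm_sel, drop = FALSE])
    )
  })
}

#' Normalized band coherence features
#'
#' For each channel pair and band: mean magnitude-squared coherence over
#' the band's bins as a percent of the pair's mean coherence over the
#' broadband range, with exclusion bins dropped from both.
#'
#' @param epochs An `epoch_set`.
#' @param scheme A [band_scheme()].
#' @param window_length,overlap_fraction As in [epoch_coherence()].
#' @param pairs Character vector of `"A-B"` pair names.
#' @return Tibble: `pair`, `band`, `coherence_pct`.
#' @export
band_coherence_features <- function(epochs, scheme = band_scheme(),
                                    window_length = 1.28,
                                    overlap_fraction = 0.5,
                                    pairs = lfp_channel_pairs(epochs$channel_labels)) {
  purrr::map_dfr(pairs, function(p) {
    coh <- epoch_coherence(epochs, p, window_length, overlap_fraction)
    norm_sel <- band_bins(coh$freqs, scheme$norm_range, scheme$exclusion)
    normalizer <- mean(coh$coherence[norm_sel])
    if (!is.finite(normalizer) || normalizer <= 0) {
      stop("degenerate coherence spectrum: zero broadband normalizer", call. = FALSE)
    }
    purrr::map_dfr(names(scheme$bands), function(bn) {
      sel <- band_bins(coh$freqs, scheme$bands[[bn]], scheme$exclusion)
      if (!any(sel)) {
        stop("band '", bn, "' contains no frequency bins", call. = FALSE)
      }
      tibble::tibble(pair = p, band = bn,
                     coherence_pct = 100 * mean(coh$coherence[sel]) / normalizer)
    })
  })
}

#' Canonical names of the 60 LFP features
#'
#' 24 power features (`<channel>_<band>_pow`; channels in fixed label
#' order) followed by 36 coherence features (`<chanA>-<chanB>_<band>_coh`;
#' pairs in canonical order), bands in scheme order within each block.
#'
#' @param channels Channel labels.
#' @param scheme A [band_scheme()].
#' @return Character vector of feature names.
#' @export
feature_names <- function(channels = lfp_channels(), scheme = band_scheme()) {
  bands <- names(scheme$bands)
  pow <- as.vector(t(outer(channels, bands, function(c, b) paste0(c, "_", b, "_pow"))))
  coh <- as.vector(t(outer(lfp_channel_pairs(channels), bands,
                           function(p, b) paste0(p, "_", b, "_coh"))))
  c(pow, coh)
}

#' Assemble the per-subject feature vector
#'
#' Joins band power and band coherence tables into the fixed-order feature
#' vector (24 power + 36 coherence = 60 features for 4 channels and 6
#' bands), validating completeness.
#'
#' @param power Tibble from [band_power_features()].
#' @param coherence Tibble from [band_coherence_features()].
#' @param subject_id Subject identifier.
#' @param channels,scheme Define the expected feature set.
#' @return One-row tibble: `subject_id` plus one column per feature, all
#'   finite.
#' @export
build_feature_vector <- function(power, coherence, subject_id,
                                 channels = lfp_channels(),
                                 scheme = band_scheme()) {
  vals <- c(
    stats::setNames(power$power_pct,
                    paste0(power$channel, "_", power$band, "_pow")),
    stats::setNames(coherence$coherence_pct,
                    paste0(coherence$pair, "_", coherence$band, "_coh"))
  )
  expected <- feature_names(channels, scheme)
  missing <- setdiff(expected, names(vals))
  if (length(missing)) {
    stop("missing features: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  vals <- vals[expected]
  if (!all(is.finite(vals))) {
    stop("non-finite feature values: ",
         paste(expected[!is.finite(vals)], collapse = ", "), call. = FALSE)
  }
  dplyr::bind_cols(tibble::tibble(subject_id = subject_id),
                   tibble::as_tibble(as.list(vals)))
}

#' Average feature vectors across recording sessions
#'
#' Entrywise arithmetic mean of several one-row feature tibbles from the
#' same subject (e.g. the two recording sessions).
#'
#' @param vectors List of one-row feature tibbles from
#'   [build_feature_vector()].
#' @return One-row tibble in the same format.
#' @export
combine_session_features <- function(vectors) {
  stopifnot(length(vectors) >= 1)
  ids <- unique(vapply(vectors, function(v) v$subject_id, character(1)))
  stopifnot(length(ids) == 1)
  num <- purrr::map(vectors, ~ as.numeric(.x[-1]))
  avg <- Reduce(`+`, num) / length(num)
  out <- vectors[[1]]
  out[-1] <- as.list(avg)
  out
}

#' Extract the 60-feature vector from a raw recording
#'
#' Convenience wrapper: [preprocess_recording()], [epoch_psd()],
#' [band_power_features()], [band_coherence_features()] and
#' [build_feature_vector()] with parameters drawn from the config.
#'
#' @param rec An [lfp_recording()].
#' @param config A [pipeline_config()].
#' @return One-row feature tibble.
#' @export
extract_features <- function(rec, config = pipeline_config()) {
  s <- config$spectral
  eps <- preprocess_recording(rec, config)
  est <- epoch_psd(eps, s$window_length, s$overlap_fraction)
  pow <- band_power_features(est, config$scheme)
  coh <- band_coherence_features(eps, config$scheme, s$window_length,
                                 s$overlap_fraction)
  build_feature_vector(pow, coh, rec$subject_id, rec$channel_labels,
                       config$scheme)
}
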