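#' Subject specification for the synthetic cohort generator
#'
#' Describes one simulated animal: its drinking phenotype group, per-channel
#' band power offsets (dB), inter-channel coherence coupling weights, the
#' artifact rate, and the drinking distribution. Offsets and couplings that
#' are not named default to zero.
#'
#' @param subject_id Subject identifier.
#' @param group `"HD"` or `"LD"` (high / low drinker).
#' @param band_power_offsets Named list: `offsets[[channel]][[band]]` = dB
#'   offset applied to that channel's band-limited process amplitude.
#' @param coherence_coupling Named list: `coupling[[ "A-B" ]][[band]]` =
#'   mixing weight in [0, 1] of a shared band-limited source in both
#'   channels of the pair.
#' @param artifact_rate Artifact events per minute (>= 0).
#' @param drinking_mean,drinking_sd Per-session alcohol intake distribution
#'   in g/kg.
#' @return An object of class `subject_spec`.
#' @export
subject_spec <- function(subject_id, group = c("LD", "HD"),
                         band_power_offsets = list(),
                         coherence_coupling = list(),
                         artifact_rate = 0,
                         drinking_mean = 1, drinking_sd = 0.25) {
  group <- match.arg(group)
  stopifnot(artifact_rate >= 0, drinking_sd >= 0)
  if (drinking_mean < 0) stop("drinking_mean must be nonnegative", call. = FALSE)
  for (p in coherence_coupling) {
    w <- unlist(p)
    if (any(w < 0 | w > 1)) stop("coupling weights must be in [0, 1]", call. = FALSE)
  }
  structure(
    list(subject_id = subject_id, group = group,
         band_power_offsets = band_power_offsets,
         coherence_coupling = coherence_coupling,
         artifact_rate = artifact_rate,
         drinking_mean = drinking_mean, drinking_sd = drinking_sd),
    class = "subject_spec"
  )
}

#' Cohort specification
#'
#' Study-level parameters of the simulated cohort. Defaults reflect the
#' study design the pipeline targets: 13 subjects, two 30-minute recording
#' sessions per subject sampled at 2 kHz, and 12 drinking sessions.
#' `recording_duration` defaults to a desk-scale 60 s; full-length 1800 s
#' sessions are supported but rarely needed since spectral estimates
#' stabilise quickly.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param n_sessions_recording Recording sessions per subject.
#' @param recording_duration Seconds per recording session.
#' @param sampling_rate Hz; must exceed twice the highest band edge.
#' @param n_drinking_sessions Drinking sessions per subject (>= 3).
#' @param drinking_group_effect Difference in mean g/kg added to HD
#'   subjects' drinking relative to LD.
#' @param hd_gamma_offset_db dB added to gamma-band (low and high gamma)
#'   power on `hd_gamma_channels` in HD subjects; 0 gives a null cohort.
#' @param hd_gamma_coupling Coherence coupling weight added in gamma bands
#'   for `hd_gamma_pairs` in HD subjects.
#' @param hd_gamma_channels,hd_gamma_pairs Channels and channel pairs
#'   carrying the HD group effect. The defaults place it on the right
#'   hemisphere sites and their pair, the lateralization reported for
#'   gamma-band differences between drinking phenotypes.
#' @param subject_sd_db Between-subject standard deviation, in dB, of
#'   per-channel per-band power offsets: a single number or a named
#'   per-band vector. This is what makes cohort members statistically
#'   distinct individuals; with it at zero, group effects separate
#'   subjects deterministically through the spectral estimates. The
#'   default declines with frequency — low-frequency (delta through beta)
#'   power varies far more across animals with behavioral state than
#'   gamma power does.
#' @param subject_coupling_mean,subject_coupling_sd Mean and between-subject
#'   standard deviation of the baseline coherence coupling weight drawn per
#'   subject, pair and band (clamped to [0, 0.95]): single numbers or named
#'   per-band vectors. The defaults decline with frequency — inter-regional
#'   LFP coherence is strongest and most variable at low frequencies
#'   (global states, volume conduction) and low and focal in the gamma
#'   bands. This gives coherence features the same kind of individual
#'   variability as power features.
#' @param artifact_rate Artifact events per minute for every subject.
#' @param drinking_mean,drinking_sd Baseline (LD) drinking distribution,
#'   g/kg per session.
#' @param scheme A [band_scheme()].
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 13, n_sessions_recording = 2,
                        recording_duration = 60, sampling_rate = 2000,
                        n_drinking_sessions = 12,
                        drinking_group_effect = 1,
                        hd_gamma_offset_db = 0, hd_gamma_coupling = 0,
                        hd_gamma_channels = c("rNAcSh", "rmPFC"),
                        hd_gamma_pairs = "rNAcSh-rmPFC",
                        subject_sd_db = c(delta = 4, theta = 4, alpha = 3.5,
                                          beta = 3, lgamma = 1.5, hgamma = 1.5),
                        subject_coupling_mean = c(delta = 0.45, theta = 0.4,
                                                  alpha = 0.35, beta = 0.3,
                                                  lgamma = 0.2, hgamma = 0.2),
                        subject_coupling_sd = c(delta = 0.15, theta = 0.15,
                                                alpha = 0.15, beta = 0.15,
                                                lgamma = 0.08, hgamma = 0.08),
                        artifact_rate = 1,
                        drinking_mean = 1, drinking_sd = 0.25,
                        scheme = band_scheme()) {
  stopifnot(n_subjects >= 2, recording_duration > 0, n_drinking_sessions >= 3)
  top <- max(vapply(scheme$bands, max, numeric(1)))
  if (sampling_rate <= 2 * top) {
    stop("sampling_rate must exceed twice the highest band edge", call. = FALSE)
  }
  structure(
    list(n_subjects = n_subjects, n_sessions_recording = n_sessions_recording,
         recording_duration = recording_duration, sampling_rate = sampling_rate,
         n_drinking_sessions = n_drinking_sessions,
         drinking_group_effect = drinking_group_effect,
         hd_gamma_offset_db = hd_gamma_offset_db,
         hd_gamma_coupling = hd_gamma_coupling,
         hd_gamma_channels = hd_gamma_channels,
         hd_gamma_pairs = hd_gamma_pairs,
         subject_sd_db = subject_sd_db,
         subject_coupling_mean = subject_coupling_mean,
         subject_coupling_sd = subject_coupling_sd,
         artifact_rate = artifact_rate,
         drinking_mean = drinking_mean, drinking_sd = drinking_sd,
         scheme = scheme),
    class = "cohort_spec"
  )
}

# FFT-domain band-limited unit-variance Gaussian process: white noise whose
# spectrum is zeroed outside [low, high] Hz. Zero-phase and numerically
# stable at narrow low-frequency bands where IIR band-passes are not.
band_limited_noise <- function(n, fs, low, high) {
  x <- stats::rnorm(n)
  xf <- stats::fft(x)
  freqs <- seq(0, n - 1) * fs / n
  freqs <- pmin(freqs, fs - freqs)  # two-sided frequency magnitude
  xf[freqs < low | freqs > high] <- 0
  y <- Re(stats::fft(xf, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s == 0) return(y)
  y / s
}

# 1/f (pink) background: white noise shaped by 1/sqrt(f), unit variance.
pink_noise <- function(n, fs, f_floor = 0.5) {
  x <- stats::rnorm(n)
  xf <- stats::fft(x)
  freqs <- seq(0, n - 1) * fs / n
  freqs <- pmin(freqs, fs - freqs)
  amp <- 1 / sqrt(pmax(freqs, f_floor))
  amp[1] <- 0
  y <- Re(stats::fft(xf * amp, inverse = TRUE)) / n
  y / stats::sd(y)
}

# Baseline component scales in mV RMS. Chosen so the combined signal sits
# around 0.2 mV RMS: well inside the +-2 mV artifact threshold, so
# thresholding fires only on injected artifacts.
.synth_scales <- list(pink = 0.12, white = 0.03, band = 0.05)

#' Generate one multichannel synthetic LFP recording
#'
#' Each channel is the sum of a 1/f (pink) background, a white-noise floor,
#' and one band-limited Gaussian process per frequency band whose amplitude
#' is scaled by the subject's dB offset for that channel and band.
#' Coherence between channel pairs in a band is induced by mixing shared
#' band-limited sources (one per coupled pair) into both channels: a
#' channel belonging to pairs with weights `w_p` receives
#' `sum(w_p * s_p) + sqrt(1 - sum(w_p^2)) * own`, so measured band
#' coherence for a pair rises monotonically from the independent-noise
#' floor at weight 0 toward 1 at weight 1. If a channel's summed squared
#' weights exceed 1 they are rescaled to unit total shared variance.
#'
#' @param spec A [subject_spec()].
#' @param duration Recording length in seconds (>= 10).
#' @param fs Sampling rate in Hz (>= 200).
#' @param seed Integer seed; identical `(spec, duration, fs, seed)` give
#'   bit-identical output.
#' @param scheme A [band_scheme()] defining the band-limited components.
#' @param channels Channel labels.
#' @param session_id Session identifier stored in the recording.
#' @param noise_scales Named list of component RMS amplitudes in mV:
#'   `pink` (1/f background), `white` (broadband floor), `band` (each
#'   band-limited process at 0 dB offset). The defaults put the combined
#'   signal near 0.2 mV RMS. Setting `pink` and `white` to zero isolates
#'   the band-limited processes (useful for calibration checks).
#' @return An [lfp_recording()] in mV.
#' @export
generate_recording <- function(spec, duration, fs, seed,
                               scheme = band_scheme(),
                               channels = lfp_channels(),
                               session_id = "ses1",
                               noise_scales = .synth_scales) {
  if (duration < 10) stop("duration must be at least 10 s", call. = FALSE)
  if (fs < 200) stop("fs must be at least 200 Hz", call. = FALSE)
  n <- round(duration * fs)
  bands <- scheme$bands
  pairs <- lfp_channel_pairs(channels)
  withr::with_seed(seed, {
    # shared sources per pair x band (drawn unconditionally so the random
    # stream, hence the background realisation, is invariant to couplings)
    shared <- lapply(pairs, function(p) {
      lapply(bands, function(b) band_limited_noise(n, fs, b[1], b[2]))
    })
    names(shared) <- pairs
    samples <- matrix(0, nrow = length(channels), ncol = n)
    for (ci in seq_along(channels)) {
      ch <- channels[ci]
      x <- noise_scales$pink * pink_noise(n, fs) +
        noise_scales$white * stats::rnorm(n)
      for (bi in seq_along(bands)) {
        bn <- names(bands)[bi]
        own <- band_limited_noise(n, fs, bands[[bn]][1], bands[[bn]][2])
        # superpose the shared sources of every coupled pair this channel
        # belongs to
        my_pairs <- pairs[vapply(pairs, function(p)
          ch %in% strsplit(p, "-", fixed = TRUE)[[1]], logical(1))]
        w <- vapply(my_pairs, function(p) {
          wp <- spec$coherence_coupling[[p]][[bn]]
          if (is.null(wp)) 0 else wp
        }, numeric(1))
        if (sum(w^2) > 1) w <- w / sqrt(sum(w^2))
        proc <- sqrt(max(0, 1 - sum(w^2))) * own
        for (k in which(w > 0)) {
          proc <- proc + w[k] * shared[[my_pairs[k]]][[bn]]
        }
        off_db <- spec$band_power_offsets[[ch]][[bn]]
        if (is.null(off_db)) off_db <- 0
        x <- x + noise_scales$band * 10^(off_db / 20) * proc
      }
      samples[ci, ] <- x
    }
    lfp_recording(samples, fs = fs, channel_labels = channels,
                  subject_id = spec$subject_id, session_id = session_id)
  })
}

#' Inject large-amplitude artifacts into a recording
#'
#' Adds Poisson-placed half-sine transients (20 ms wide) of the given peak
#' amplitude onto randomly chosen channels. Ground-truth event times and
#' channels are recorded in the returned object's `artifact_truth` field so
#' downstream detection can be validated.
#'
#' @param rec An [lfp_recording()].
#' @param rate Events per minute (>= 0). Rate 0 returns the input unchanged.
#' @param amplitude Peak amplitude in mV. Amplitudes at or below the 2 mV
#'   detection threshold are allowed but raise a warning, since such events
#'   would be invisible to threshold-based detection.
#' @param seed Integer seed.
#' @param width Transient width in seconds.
#' @return A copy of `rec` with artifacts added and `artifact_truth` set.
#' @export
inject_artifacts <- function(rec, rate, amplitude = 3, seed = 1,
                             width = 0.02) {
  stopifnot(rate >= 0)
  if (amplitude <= 2) {
    warning("artifact amplitude <= 2 mV: events will not cross the detection threshold")
  }
  if (rate == 0) return(rec)
  n <- ncol(rec$samples)
  duration_min <- n / rec$fs / 60
  withr::with_seed(seed, {
    n_events <- stats::rpois(1, rate * duration_min)
    wl <- max(2L, round(width * rec$fs))
    pulse <- amplitude * sin(pi * seq(0, 1, length.out = wl))
    out <- rec$samples
    truth <- tibble::tibble(time_s = numeric(0), channel = character(0))
    if (n_events > 0) {
      starts <- sort(sample.int(n - wl, n_events, replace = TRUE))
      chans <- sample(rec$channel_labels, n_events, replace = TRUE)
      for (k in seq_len(n_events)) {
        idx <- starts[k]:(starts[k] + wl - 1)
        out[chans[k], idx] <- out[chans[k], idx] + pulse
      }
      truth <- tibble::tibble(time_s = (starts - 1) / rec$fs, channel = chans)
    }
    lfp_recording(out, fs = rec$fs, channel_labels = rec$channel_labels,
                  subject_id = rec$subject_id, session_id = rec$session_id,
                  artifact_truth = truth)
  })
}

#' Simulate per-subject drinking trajectories
#'
#' Draws `n_drinking_sessions` per-session alcohol intakes (g/kg) per
#' subject from a normal distribution truncated at zero, with HD subjects'
#' mean raised by the cohort's `drinking_group_effect`.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed.
#' @param groups Optional character vector of group assignments
#'   (`"HD"`/`"LD"`), one per subject. Defaults to the first
#'   `ceiling(n/2)` subjects HD and the rest LD.
#' @return A tibble with columns `subject_id`, `group` (ground truth),
#'   `session_index`, `session_type` (all `"training"`), `g_per_kg`.
#' @export
generate_drinking_table <- function(spec, seed, groups = NULL) {
  n <- spec$n_subjects
  if (spec$drinking_mean < 0) stop("drinking_mean must be nonnegative", call. = FALSE)
  if (is.null(groups)) {
    groups <- rep(c("HD", "LD"), c(ceiling(n / 2), floor(n / 2)))
  }
  stopifnot(length(groups) == n, all(groups %in% c("HD", "LD")))
  ids <- sprintf("s%02d", seq_len(n))
  withr::with_seed(seed, {
    purrr::map2_dfr(ids, groups, function(id, g) {
      mu <- spec$drinking_mean + if (g == "HD") spec$drinking_group_effect else 0
      vals <- pmax(0, stats::rnorm(spec$n_drinking_sessions, mu, spec$drinking_sd))
      tibble::tibble(subject_id = id, group = g,
                     session_index = seq_len(spec$n_drinking_sessions),
                     session_type = "training", g_per_kg = vals)
    })
  })
}

#' Simulate a full cohort: recordings, features and drinking
#'
#' End-to-end generator: for each subject, simulates the configured number
#' of recording sessions (with artifacts), runs the preprocessing and
#' spectral stages, averages feature vectors across sessions, and simulates
#' the drinking table. HD subjects receive the cohort's gamma power offset
#' on every channel and gamma coherence coupling on every pair — the effect
#' direction reported for high drinkers.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed driving every stage.
#' @param config A [pipeline_config()] supplying preprocessing and spectral
#'   parameters.
#' @return A list with `features` (tibble: `subject_id`, `group`, 60 feature
#'   columns), `drinking` (tibble from [generate_drinking_table()]), and
#'   `groups` (named character vector of ground-truth labels).
#' @export
simulate_cohort <- function(spec, seed, config = pipeline_config()) {
  n <- spec$n_subjects
  groups <- rep(c("HD", "LD"), c(ceiling(n / 2), floor(n / 2)))
  ids <- sprintf("s%02d", seq_len(n))
  gbands <- intersect(c("lgamma", "hgamma"), names(spec$scheme$bands))
  sub_seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max, n))

  bands <- names(spec$scheme$bands)
  chans <- lfp_channels()
  prs <- lfp_channel_pairs(chans)
  per_band <- function(x) {
    if (length(x) == 1) x <- stats::setNames(rep(x, length(bands)), bands)
    stopifnot(all(bands %in% names(x)))
    x[bands]
  }
  sd_db <- per_band(spec$subject_sd_db)
  cp_mean <- per_band(spec$subject_coupling_mean)
  cp_sd <- per_band(spec$subject_coupling_sd)
  feat_rows <- purrr::map_dfr(seq_len(n), function(i) {
    draws <- withr::with_seed(sub_seeds[i], list(
      indiv = matrix(stats::rnorm(length(chans) * length(bands),
                                  sd = rep(sd_db[bands], each = length(chans))),
                     length(chans), length(bands),
                     dimnames = list(chans, bands)),
      coup = matrix(stats::rnorm(length(prs) * length(bands),
                                 rep(cp_mean, each = length(prs)),
                                 rep(cp_sd, each = length(prs))),
                    length(prs), length(bands),
                    dimnames = list(prs, bands)),
      ses_seeds = sample.int(.Machine$integer.max,
                             2 * spec$n_sessions_recording)
    ))
    # individual spectral profile plus the HD group's gamma shift
    offs <- lapply(chans, function(ch) {
      v <- draws$indiv[ch, ]
      if (groups[i] == "HD" && ch %in% spec$hd_gamma_channels) {
        v[gbands] <- v[gbands] + spec$hd_gamma_offset_db
      }
      as.list(v)
    })
    names(offs) <- chans
    # individual connectivity profile plus the HD group's gamma coupling
    coup <- lapply(prs, function(p) {
      w <- draws$coup[p, ]
      if (groups[i] == "HD" && p %in% spec$hd_gamma_pairs) {
        w[gbands] <- w[gbands] + spec$hd_gamma_coupling
      }
      as.list(pmin(pmax(w, 0), 0.95))
    })
    names(coup) <- prs
    sub <- subject_spec(ids[i], group = groups[i],
                        band_power_offsets = offs, coherence_coupling = coup,
                        artifact_rate = spec$artifact_rate,
                        drinking_mean = spec$drinking_mean,
                        drinking_sd = spec$drinking_sd)
    ses_seeds <- draws$ses_seeds
    vecs <- purrr::map(seq_len(spec$n_sessions_recording), function(s) {
      rec <- generate_recording(sub, spec$recording_duration, spec$sampling_rate,
                                seed = ses_seeds[2 * s - 1], scheme = spec$scheme,
                                session_id = sprintf("ses%d", s))
      if (spec$artifact_rate > 0) {
        rec <- inject_artifacts(rec, spec$artifact_rate, amplitude = 3,
                                seed = ses_seeds[2 * s])
      }
      extract_features(rec, config = config)
    })
    combine_session_features(vecs)
  })
  drinking <- generate_drinking_table(spec, seed = seed + 1L, groups = groups)
  list(features = dplyr::bind_cols(tibble::tibble(group = groups), feat_rows) |>
         dplyr::relocate("subject_id"),
       drinking = drinking,
       groups = stats::setNames(groups, ids))
}

#' Simulate a subjects-by-features table directly
#'
#' Draws a cohort feature table from per-feature normal distributions
#' without simulating time series — a fast stand-in for classifier-scale
#' experiments. With `effect_size = 0` the table carries no class signal;
#' otherwise the named features' means are shifted by `effect_size` (in SD
#' units) in the HD group.
#'
#' @param n_subjects Number of subjects; labels are split
#'   `ceiling(n/2)` HD / `floor(n/2)` LD.
#' @param n_features Number of feature columns; named after the standard
#'   60 LFP features when `n_features == 60`, else `f1..fk`.
#' @param effect_size Mean shift, in SD units, applied to HD subjects on
#'   `informative_features`.
#' @param informative_features Character vector of feature names to shift.
#' @param seed Integer seed.
#' @return A tibble: `subject_id`, `group`, one column per feature.
#' @export
simulate_feature_table <- function(n_subjects = 13, n_features = 60,
                                   effect_size = 0,
                                   informative_features = character(0),
                                   seed = 1) {
  fnames <- if (n_features == 60) feature_names() else paste0("f", seq_len(n_features))
  groups <- rep(c("HD", "LD"), c(ceiling(n_subjects / 2), floor(n_subjects / 2)))
  withr::with_seed(seed, {
    m <- matrix(stats::rnorm(n_subjects * n_features), n_subjects, n_features,
                dimnames = list(NULL, fnames))
    if (effect_size != 0 && length(informative_features)) {
      stopifnot(all(informative_features %in% fnames))
      m[groups == "HD", informative_features] <-
        m[groups == "HD", informative_features] + effect_size
    }
    dplyr::bind_cols(
      tibble::tibble(subject_id = sprintf("s%02d", seq_len(n_subjects)),
                     group = groups),
      tibble::as_tibble(m)
    )
  })
}
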