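# Shared fixtures, all generated in code.

# Single-channel recording holding a pure sinusoid.
sine_recording <- function(freq, fs = 400, duration = 10, amplitude = 1,
                           n_channels = 1) {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  x <- amplitude * sin(2 * pi * freq * t)
  lfp_recording(matrix(rep(x, n_channels), nrow = n_channels, byrow = TRUE),
                fs = fs, channel_labels = paste0("ch", seq_len(n_channels)))
}

# Four-channel white-noise recording at the analysis rate.
noise_recording <- function(fs = 400, duration = 30, sd = 0.2, seed = 1) {
  withr::with_seed(seed, {
    lfp_recording(matrix(stats::rnorm(4 * fs * duration, sd = sd), nrow = 4),
                  fs = fs)
  })
}

# Epoch set built directly from a channels x time matrix (clean, no mask).
epochs_from_matrix <- function(mat, fs, epoch_length = 3,
                               channel_labels = paste0("ch", seq_len(nrow(mat)))) {
  rec <- lfp_recording(mat, fs = fs, channel_labels = channel_labels)
  segment_epochs(rec, NULL, epoch_length)
}

# Deterministic two-channel fixture used for the frozen external
# cross-check of the Welch engine: tones plus chirps, no randomness.
welch_fixture <- function() {
  fs <- 400
  t <- (seq_len(1200) - 1) / fs
  x <- 0.5 * sin(2 * pi * 8 * t) + 0.2 * sin(2 * pi * 25 * t + 0.7) +
    0.1 * sin(2 * pi * 0.05 * t^2)
  y <- 0.4 * sin(2 * pi * 8 * t + 0.3) + 0.3 * sin(2 * pi * 55 * t) +
    0.1 * sin(2 * pi * 0.04 * t^2 + 1.1)
  epochs_from_matrix(rbind(x, y), fs = fs, epoch_length = 3,
                     channel_labels = c("chx", "chy"))
}

# A constant-dB spectral estimate on the standard analysis grid.
flat_spectral_estimate <- function(level_db = -30, fs = 400, nw = 512,
                                   channels = lfp_channels()) {
  freqs <- (seq_len(nw / 2 + 1) - 1) * fs / nw
  psd_db <- matrix(level_db, nrow = length(channels), ncol = length(freqs),
                   dimnames = list(channels, NULL))
  structure(
    list(freqs = freqs, psd = 10^(psd_db / 10), psd_db = psd_db,
         n_epochs = 1, fs = fs, channel_labels = channels,
         subject_id = "s1", session_id = "ses1"),
    class = "spectral_estimate"
  )
}
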