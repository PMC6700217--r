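test_that("Welch grid, peak location and guards behave as specified", {
  eps <- segment_epochs(sine_recording(8, fs = 400, duration = 30), NULL, 3)
  est <- epoch_psd(eps, 1.28, 0.5)
  # 1.28 s window at 400 Hz = 512 samples -> 0.78125 Hz resolution
  expect_equal(diff(est$freqs)[1], 0.78125)
  expect_equal(est$freqs[which.max(est$psd[1, ])], 7.8125)

  empty <- structure(list(epochs = list(), epoch_length = 3, fs = 400,
                          channel_labels = "c"), class = "epoch_set")
  expect_error(epoch_psd(empty), "empty")
  expect_error(epoch_psd(eps, window_length = 5), "epoch length")
  expect_error(epoch_psd(eps, overlap_fraction = 1), "overlap")
})

test_that("white-noise PSD integrates to the signal variance (Parseval)", {
  errs <- vapply(1:12, function(s) {
    eps <- withr::with_seed(s, epochs_from_matrix(
      matrix(stats::rnorm(400 * 30, sd = 0.5), nrow = 1), fs = 400))
    est <- epoch_psd(eps)
    total <- sum(est$psd[1, ]) * diff(est$freqs)[1]
    total / 0.25
  }, numeric(1))
  expect_lt(abs(mean(errs) - 1), 0.1)
})

test_that("Welch auto/cross spectra agree with an external reference", {
  # frozen oracle values computed with scipy.signal (welch / coherence,
  # symmetric Hamming window, nperseg 512, noverlap 256, no detrending) on
  # the deterministic tone-plus-chirp fixture
  oracle <- rbind(
    c(f = 7.8125,    pxx = 1.0710090007e-01, pyy = 6.8596096468e-02, cxy = 0.9999969027),
    c(f = 20.3125,   pxx = 4.3291267899e-07, pyy = 1.9170444197e-07, cxy = 0.6657277244),
    c(f = 50.0,      pxx = 4.8089167018e-08, pyy = 1.1909597461e-06, cxy = 0.7454541792),
    c(f = 54.6875,   pxx = 4.0002524356e-08, pyy = 3.2624648631e-02, cxy = 0.7321341167),
    c(f = 110.15625, pxx = 1.1295477290e-08, pyy = 5.7330513317e-08, cxy = 0.6296085115)
  )
  eps <- welch_fixture()
  est <- epoch_psd(eps)
  coh <- epoch_coherence(eps, c("chx", "chy"))
  idx <- match(oracle[, "f"], est$freqs)
  expect_false(anyNA(idx))
  expect_equal(est$psd["chx", idx], unname(oracle[, "pxx"]), tolerance = 1e-6)
  expect_equal(est$psd["chy", idx], unname(oracle[, "pyy"]), tolerance = 1e-6)
  expect_equal(coh$coherence[idx], unname(oracle[, "cxy"]), tolerance = 1e-6)
})

test_that("coherence is exact for identical and delayed signals", {
  x <- withr::with_seed(1, stats::rnorm(400 * 12))
  eps <- epochs_from_matrix(rbind(x, x), fs = 400)
  coh <- epoch_coherence(eps, c("ch1", "ch2"))
  expect_true(all(abs(coh$coherence - 1) < 1e-9))
  expect_true(all(coh$coherence >= 0 & coh$coherence <= 1 + 1e-12))

  # pure 10 ms delay leaves the magnitude untouched
  d <- round(0.01 * 400)
  y <- c(rep(0, d), x[seq_len(length(x) - d)])
  epsd <- epochs_from_matrix(rbind(x, y), fs = 400)
  cohd <- epoch_coherence(epsd, c("ch1", "ch2"))
  sel <- cohd$freqs >= 1 & cohd$freqs <= 90
  expect_gt(mean(cohd$coherence[sel]), 0.95)
})

test_that("independent-noise coherence shows the small-sample bias floor", {
  floor_for <- function(epoch_length) {
    mean(vapply(1:10, function(s) {
      eps <- withr::with_seed(s, epochs_from_matrix(
        matrix(stats::rnorm(2 * 400 * 36), nrow = 2), fs = 400,
        epoch_length = epoch_length))
      mean(epoch_coherence(eps, c("ch1", "ch2"))$coherence)
    }, numeric(1)))
  }
  f3 <- floor_for(3)    # 3 Hamming windows per epoch
  f9 <- floor_for(9)    # 13 windows per epoch
  expect_gt(f3, 0.15)   # far above zero
  expect_gt(f3, f9)     # bias shrinks with more windows per epoch
})

test_that("band power features normalize to percent of broadband power", {
  est <- flat_spectral_estimate(-30)
  pow <- band_power_features(est)
  expect_equal(nrow(pow), 24)
  expect_true(all(abs(pow$power_pct - 100) < 1e-12))

  # bins inside the 59-61 Hz exclusion never contribute, even in low gamma
  est2 <- flat_spectral_estimate(-30)
  contaminated <- est2$freqs > 59 & est2$freqs < 61
  expect_gt(sum(contaminated), 0)
  est2$psd_db[, contaminated] <- 1000
  pow2 <- band_power_features(est2)
  expect_equal(pow2$power_pct, pow$power_pct)

  # a uniform linear-power doubling rescales features by a closed form
  est3 <- flat_spectral_estimate(-30)
  shift <- 10 * log10(2)
  est3$psd_db <- est3$psd_db + shift
  pow3 <- band_power_features(est3)
  expect_true(all(abs(pow3$power_pct - 100) < 1e-12))
  # ordering across bands is preserved under the shift for a non-flat PSD
  est4 <- flat_spectral_estimate(-30)
  est4$psd_db <- est4$psd_db + outer(rep(1, 4), seq(-5, 5, length.out = ncol(est4$psd_db)))
  p4 <- band_power_features(est4)$power_pct
  est4$psd_db <- est4$psd_db + shift
  p4s <- band_power_features(est4)$power_pct
  expect_identical(order(p4), order(p4s))

  coarse <- flat_spectral_estimate(-30, fs = 400, nw = 16)  # 25 Hz bins
  expect_error(band_power_features(coarse), "no frequency bins")

  # linear-domain averaging: also 100 for a flat spectrum, but differs
  # from dB-domain averaging when the spectrum slopes
  expect_true(all(abs(band_power_features(est, domain = "linear")$power_pct
                      - 100) < 1e-12))
  est5 <- flat_spectral_estimate(-30)
  est5$psd_db <- est5$psd_db + outer(rep(1, 4), seq(0, 10, length.out = ncol(est5$psd_db)))
  est5$psd <- 10^(est5$psd_db / 10)
  expect_false(isTRUE(all.equal(band_power_features(est5)$power_pct,
                                band_power_features(est5, domain = "linear")$power_pct)))
})

test_that("band coherence features normalize per pair and count 36", {
  x <- withr::with_seed(2, matrix(stats::rnorm(4 * 400 * 12), nrow = 4))
  eps <- epochs_from_matrix(x, fs = 400, channel_labels = lfp_channels())
  coh <- band_coherence_features(eps)
  expect_equal(nrow(coh), 36)
  expect_equal(length(unique(coh$pair)), 6)
  expect_true(all(is.finite(coh$coherence_pct)))

  # identical channels: coherence 1 at every frequency -> every band 100
  same <- epochs_from_matrix(rbind(x[1, ], x[1, ]), fs = 400,
                             channel_labels = c("a", "b"))
  cs <- band_coherence_features(same, pairs = "a-b")
  expect_true(all(abs(cs$coherence_pct - 100) < 1e-9))
})

test_that("coupling injected in one band dominates that pair's features", {
  pair <- "rNAcSh-rmPFC"
  wins <- vapply(1:6, function(s) {
    sub <- subject_spec("s01", "HD",
                        coherence_coupling = stats::setNames(
                          list(list(lgamma = 0.9)), pair))
    rec <- generate_recording(sub, 30, 400, seed = s)
    eps <- segment_epochs(rec, NULL, 3)
    coh <- band_coherence_features(eps, pairs = pair)
    coh$band[which.max(coh$coherence_pct)] == "lgamma"
  }, logical(1))
  expect_gte(mean(wins), 5 / 6)
})

test_that("feature vectors carry 60 named entries in fixed order", {
  expect_length(feature_names(), 60)
  expect_equal(sum(grepl("_pow$", feature_names())), 24)
  expect_equal(sum(grepl("_coh$", feature_names())), 36)

  x <- withr::with_seed(3, matrix(stats::rnorm(4 * 400 * 12), nrow = 4))
  eps <- epochs_from_matrix(x, fs = 400, channel_labels = lfp_channels())
  pow <- band_power_features(epoch_psd(eps))
  coh <- band_coherence_features(eps)
  fv <- build_feature_vector(pow, coh, "s01")
  expect_equal(ncol(fv), 61)
  expect_identical(names(fv)[-1], feature_names())

  expect_error(build_feature_vector(pow, coh[-1, ], "s01"), "missing features")

  fv2 <- fv
  fv2[-1] <- as.list(as.numeric(fv[-1]) + 2)
  comb <- combine_session_features(list(fv, fv2))
  expect_equal(as.numeric(comb[-1]), as.numeric(fv[-1]) + 1)
})

test_that("cohorts with raised HD gamma power show the effect directionally", {
  hits <- vapply(1:4, function(s) {
    spec <- cohort_spec(n_subjects = 6, n_sessions_recording = 1,
                        recording_duration = 15, sampling_rate = 2000,
                        hd_gamma_offset_db = 6, artifact_rate = 0)
    sim <- simulate_cohort(spec, seed = s * 17)
    lg <- sim$features$rNAcSh_lgamma_pow
    mean(lg[sim$features$group == "HD"]) > mean(lg[sim$features$group == "LD"])
  }, logical(1))
  expect_gte(mean(hits), 3 / 4)
})
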