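test_that("generators are pure functions of spec and seed", {
  sub <- subject_spec("s01", "HD", artifact_rate = 2)
  r1 <- generate_recording(sub, 10, 400, seed = 42)
  r2 <- generate_recording(sub, 10, 400, seed = 42)
  expect_identical(r1$samples, r2$samples)
  r3 <- generate_recording(sub, 10, 400, seed = 43)
  expect_false(identical(r1$samples, r3$samples))

  spec <- cohort_spec(n_subjects = 4)
  expect_identical(generate_drinking_table(spec, seed = 7),
                   generate_drinking_table(spec, seed = 7))
})

test_that("generated recordings have the expected shape, scale and guards", {
  sub <- subject_spec("s01", "LD")
  rec <- generate_recording(sub, 12, 400, seed = 1)
  expect_identical(rec$channel_labels, c("lNAcSh", "rNAcSh", "lmPFC", "rmPFC"))
  expect_equal(ncol(rec$samples), 12 * 400)
  # baseline regime: comfortably inside the +-2 mV artifact threshold
  expect_lt(max(abs(rec$samples)), 1.5)
  expect_gt(stats::sd(rec$samples[1, ]), 0.05)
  expect_error(generate_recording(sub, 5, 400, seed = 1), "duration")
  expect_error(generate_recording(sub, 12, 100, seed = 1), "fs")
})

test_that("uncoupled channels sit at the independent-noise coherence floor", {
  # oracle: the empirical floor of mean broadband magnitude-squared
  # coherence between independent white-noise channels with the same
  # epoch/window layout
  floor_vals <- vapply(1:20, function(s) {
    eps <- withr::with_seed(s, epochs_from_matrix(
      matrix(stats::rnorm(2 * 400 * 30), nrow = 2), fs = 400))
    mean(epoch_coherence(eps, c("ch1", "ch2"))$coherence)
  }, numeric(1))

  sub <- subject_spec("s01", "LD")  # all coupling weights zero
  rec <- generate_recording(sub, 30, 400, seed = 5)
  eps <- segment_epochs(rec, NULL, 3)
  got <- mean(epoch_coherence(eps, c("lNAcSh", "lmPFC"))$coherence)
  expect_lt(abs(got - mean(floor_vals)), 4 * stats::sd(floor_vals) + 0.02)
})

test_that("a +6 dB band offset quadruples that band's measured power", {
  # background noise switched off so the band process is measured alone
  quiet <- list(pink = 0, white = 0, band = 0.05)
  theta_power <- function(offset_db, seed) {
    offs <- if (offset_db != 0) list(rNAcSh = list(theta = offset_db)) else list()
    sub <- subject_spec("s01", "HD", band_power_offsets = offs)
    rec <- generate_recording(sub, 30, 400, seed = seed, noise_scales = quiet)
    est <- epoch_psd(segment_epochs(rec, NULL, 3))
    sel <- est$freqs >= 5 & est$freqs <= 10
    mean(est$psd["rNAcSh", sel])
  }
  ratios <- vapply(1:8, function(s) theta_power(6, s) / theta_power(0, s),
                   numeric(1))
  expect_gt(mean(ratios), 3.5)
  expect_lt(mean(ratios), 4.5)
})

test_that("band power rises monotonically with the dB offset", {
  grid <- c(-6, -3, 0, 3, 6)
  mean_power <- vapply(grid, function(off) {
    mean(vapply(1:5, function(s) {
      sub <- subject_spec("s01", "HD",
                          band_power_offsets = list(rNAcSh = list(alpha = off)))
      rec <- generate_recording(sub, 20, 400, seed = s)
      est <- epoch_psd(segment_epochs(rec, NULL, 3))
      sel <- est$freqs >= 11 & est$freqs <= 14
      mean(est$psd["rNAcSh", sel])
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_power) > 0))
})

test_that("band coherence rises with the coupling weight and saturates", {
  pair <- "lNAcSh-rNAcSh"
  quiet <- list(pink = 0, white = 0, band = 0.05)
  coh_at <- function(w) {
    coup <- if (w > 0) stats::setNames(list(list(lgamma = w)), pair) else list()
    mean(vapply(1:4, function(s) {
      sub <- subject_spec("s01", "HD", coherence_coupling = coup)
      rec <- generate_recording(sub, 20, 400, seed = s, noise_scales = quiet)
      eps <- segment_epochs(rec, NULL, 3)
      coh <- epoch_coherence(eps, pair)
      mean(coh$coherence[coh$freqs >= 45 & coh$freqs <= 65])
    }, numeric(1)))
  }
  levels <- vapply(c(0, 0.5, 0.8, 1), coh_at, numeric(1))
  expect_true(all(diff(levels) > 0))
  # weight 1 with no independent background: near-perfect coherence
  expect_gt(levels[4], 0.95)
})

test_that("artifact injection bookkeeping matches the placed events", {
  sub <- subject_spec("s01", "LD")
  rec <- generate_recording(sub, 60, 400, seed = 3)
  expect_identical(inject_artifacts(rec, rate = 0, amplitude = 3, seed = 1), rec)

  reca <- inject_artifacts(rec, rate = 2, amplitude = 3, seed = 11)
  expect_s3_class(reca$artifact_truth, "tbl_df")
  expect_true(all(reca$artifact_truth$channel %in% rec$channel_labels))
  # peak reaches the requested amplitude at some ground-truth event
  if (nrow(reca$artifact_truth) > 0) {
    expect_gt(max(abs(reca$samples)), 2)
  }
  expect_warning(inject_artifacts(rec, rate = 1, amplitude = 1.5, seed = 1),
                 "threshold")
})

test_that("every injected artifact is caught by threshold detection", {
  sub <- subject_spec("s01", "LD")
  for (s in 1:10) {
    rec <- generate_recording(sub, 30, 400, seed = s)
    reca <- inject_artifacts(rec, rate = 4, amplitude = 3, seed = s + 100)
    mask <- find_artifact_mask(reca, threshold = 2)
    for (tt in reca$artifact_truth$time_s) {
      samp <- round(tt * reca$fs)
      inside <- any(mask$start <= samp + round(0.02 * reca$fs) &
                      mask$end > samp)
      expect_true(inside, info = sprintf("seed %d event at %.3f s", s, tt))
    }
  }
})

test_that("drinking tables honour their distribution parameters", {
  spec0 <- cohort_spec(n_subjects = 6, drinking_sd = 0, drinking_group_effect = 0)
  tab0 <- generate_drinking_table(spec0, seed = 1)
  expect_true(all(tab0$g_per_kg == spec0$drinking_mean))
  expect_equal(nrow(tab0), 6 * 12)

  bad <- cohort_spec(n_subjects = 4)
  bad$drinking_mean <- -1
  expect_error(generate_drinking_table(bad, seed = 1), "nonnegative")
})

test_that("null drinking cohorts show ~5% false-positive group differences", {
  spec <- cohort_spec(n_subjects = 13, drinking_group_effect = 0)
  pvals <- vapply(1:50, function(s) {
    tab <- generate_drinking_table(spec, seed = s)
    avg <- average_last_sessions(tab, 3)
    grp <- dplyr::distinct(tab, subject_id, group)
    m <- dplyr::inner_join(avg, grp, by = "subject_id")
    two_sample_t(m$mean_g_per_kg[m$group == "HD"],
                 m$mean_g_per_kg[m$group == "LD"])$p
  }, numeric(1))
  expect_gte(mean(pvals > 0.05), 0.9)
})

test_that("large drinking separation is fully recovered by the median split", {
  # 4 SD units of separation between the group means
  spec <- cohort_spec(n_subjects = 13, drinking_sd = 0.25,
                      drinking_group_effect = 1)
  hits <- vapply(1:25, function(s) {
    tab <- generate_drinking_table(spec, seed = s)
    avg <- average_last_sessions(tab, 3)
    labels <- median_split(avg)
    truth <- dplyr::distinct(tab, subject_id, group)
    joined <- dplyr::inner_join(labels, truth, by = "subject_id")
    all(joined$label == joined$group)
  }, logical(1))
  expect_true(all(hits))
})
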