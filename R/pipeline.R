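#' Pipeline configuration
#'
#' Collects every tunable parameter of the analysis. The defaults encode
#' the pipeline's canonical constants: 60 Hz fourth-order Chebyshev type I
#' notch; decimation factor 5 (2 kHz to 400 Hz); +-2 mV artifact threshold
#' with 12.5 ms pre / 1 s post removal windows; 3 s epochs; 1.28 s Hamming
#' Welch windows with 50% overlap; the six rodent bands normalized over
#' 1-90 Hz excluding 59-61 Hz; last-3-session drinking averages; 4-fold CV
#' with 100 repetitions and 100 label permutations.
#'
#' @param scheme A [band_scheme()].
#' @param preprocessing,spectral,phenotype,classification Named lists
#'   overriding individual defaults within each stage.
#' @param seed Default seed recorded in the config.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(scheme = band_scheme(),
                            preprocessing = list(), spectral = list(),
                            phenotype = list(), classification = list(),
                            seed = 1) {
  defaults <- list(
    preprocessing = list(
      notch_center = 60, notch_order = 4, notch_ripple_db = 0.5,
      notch_half_width = 1, decimation_factor = 5,
      artifact_threshold = 2, artifact_pre_window = 0.0125,
      artifact_post_window = 1, epoch_length = 3
    ),
    spectral = list(window_length = 1.28, overlap_fraction = 0.5),
    phenotype = list(k_last_sessions = 3),
    classification = list(folds = 4, repetitions = 100, n_permutations = 100,
                          lambda_rule = "lambda.min")
  )
  cfg <- list(
    scheme = scheme,
    preprocessing = utils::modifyList(defaults$preprocessing, preprocessing),
    spectral = utils::modifyList(defaults$spectral, spectral),
    phenotype = utils::modifyList(defaults$phenotype, phenotype),
    classification = utils::modifyList(defaults$classification, classification),
    seed = seed
  )
  class(cfg) <- "pipeline_config"
  cfg
}

#' Validate a pipeline configuration
#'
#' Checks every cross-parameter constraint at once (Welch window within the
#' epoch, bands below the post-decimation Nyquist, exclusion inside the
#' normalization range, overlap in [0, 1), positive thresholds, folds not
#' exceeding the planned cohort size) and returns all violations together.
#'
#' @param config A [pipeline_config()].
#' @param sampling_rate Input sampling rate in Hz used for the Nyquist
#'   checks.
#' @param n_subjects Planned cohort size for the fold check (optional).
#' @return Character vector of problems; empty when the config is valid.
#' @export
validate_config <- function(config, sampling_rate = 2000, n_subjects = NULL) {
  p <- config$preprocessing; s <- config$spectral; cl <- config$classification
  errs <- character(0)
  add <- function(msg) errs <<- c(errs, msg)
  if (s$window_length > p$epoch_length) {
    add("spectral window_length exceeds epoch_length")
  }
  if (s$overlap_fraction < 0 || s$overlap_fraction >= 1) {
    add("overlap_fraction must be in [0, 1)")
  }
  if (sampling_rate %% p$decimation_factor != 0) {
    add("sampling_rate not divisible by decimation_factor")
  }
  out_nyq <- sampling_rate / p$decimation_factor / 2
  top <- max(vapply(config$scheme$bands, max, numeric(1)))
  if (top >= out_nyq) {
    add(sprintf("highest band edge (%g Hz) is at or above the post-decimation Nyquist (%g Hz)",
                top, out_nyq))
  }
  if (p$notch_center >= out_nyq) add("notch center at or above post-decimation Nyquist")
  if (p$artifact_threshold <= 0) add("artifact_threshold must be positive")
  if (p$artifact_pre_window < 0 || p$artifact_post_window < 0) {
    add("artifact windows must be nonnegative")
  }
  ex <- config$scheme$exclusion; nr <- config$scheme$norm_range
  if (ex[1] <= nr[1] || ex[2] >= nr[2]) add("exclusion range not strictly inside norm_range")
  if (!is.null(n_subjects) && cl$folds > n_subjects) {
    add("classification folds exceed the number of subjects")
  }
  if (cl$repetitions < 1 || cl$n_permutations < 1) {
    add("repetitions and n_permutations must be at least 1")
  }
  errs
}

#' Write / read a configuration as YAML
#'
#' Round-trips a [pipeline_config()] losslessly through a YAML file.
#' @param config A `pipeline_config`.
#' @param path File path.
#' @return `write_config_yaml` returns `path` invisibly; `read_config_yaml`
#'   returns a `pipeline_config`.
#' @export
write_config_yaml <- function(config, path) {
  lst <- unclass(config)
  lst$scheme <- list(bands = config$scheme$bands,
                     norm_range = config$scheme$norm_range,
                     exclusion = config$scheme$exclusion)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  lst <- yaml::read_yaml(path)
  sch <- band_scheme(bands = lapply(lst$scheme$bands, as.numeric),
                     norm_range = as.numeric(lst$scheme$norm_range),
                     exclusion = as.numeric(lst$scheme$exclusion))
  pipeline_config(scheme = sch, preprocessing = lst$preprocessing,
                  spectral = lst$spectral, phenotype = lst$phenotype,
                  classification = lst$classification, seed = lst$seed)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Simulation, preprocessing, feature extraction, phenotype labelling and
#' permutation-validated classification in one call, writing each stage's
#' outputs (feature CSV, drinking CSV, labels CSV, JSON classification
#' summary, and a manifest echoing the configuration and seed) under
#' `out_dir`. Re-running with the same spec, config and seed reproduces
#' byte-identical outputs.
#'
#' @param spec A [cohort_spec()].
#' @param config A [pipeline_config()].
#' @param seed Integer seed.
#' @param out_dir Output directory, created if needed; `NULL` to skip
#'   writing.
#' @return List: `features`, `labels`, `classification`
#'   (`permutation_result`), `summary` (tibble from
#'   [compare_real_vs_null()]), `drinking`.
#' @export
run_pipeline <- function(spec, config = pipeline_config(), seed = config$seed,
                         out_dir = NULL) {
  errs <- validate_config(config, sampling_rate = spec$sampling_rate,
                          n_subjects = spec$n_subjects)
  if (length(errs)) {
    stop("invalid configuration:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  }
  message("stage simulate+features: ", spec$n_subjects, " subjects x ",
          spec$n_sessions_recording, " sessions of ",
          spec$recording_duration, " s")
  sim <- simulate_cohort(spec, seed = seed, config = config)

  message("stage phenotype: median split on last ",
          config$phenotype$k_last_sessions, " training sessions")
  avg <- average_last_sessions(sim$drinking, config$phenotype$k_last_sessions)
  labels <- median_split(avg)

  feat <- sim$features |>
    dplyr::select(-"group") |>
    dplyr::inner_join(dplyr::select(labels, "subject_id", group = "label"),
                      by = "subject_id") |>
    dplyr::relocate("subject_id", "group")

  cl <- config$classification
  message("stage classify: ", cl$folds, "-fold CV x ", cl$repetitions,
          " repetitions, ", cl$n_permutations, " permutations")
  perm <- permutation_null(feat, n_permutations = cl$n_permutations,
                           folds = cl$folds, repetitions = cl$repetitions,
                           seed = seed, lambda_rule = cl$lambda_rule)
  summary <- compare_real_vs_null(perm)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(feat, file.path(out_dir, "features.csv"), row.names = FALSE)
    utils::write.csv(sim$drinking, file.path(out_dir, "drinking.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(labels), file.path(out_dir, "labels.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(summary = summary,
           null_accuracies = perm$null_accuracies,
           per_repetition_accuracies = perm$real$per_repetition_accuracies,
           seed = seed,
           classification = config$classification),
      file.path(out_dir, "classification.json"),
      auto_unbox = TRUE, digits = NA)
    write_config_yaml(config, file.path(out_dir, "config.yaml"))
  }
  list(features = feat, labels = labels, classification = perm,
       summary = summary, drinking = sim$drinking)
}
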