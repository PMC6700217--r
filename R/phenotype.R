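#' Average each subject's last k training sessions
#'
#' The drinking phenotype is summarised by the mean g/kg consumed over the
#' final `k` training sessions (by `session_index`), default 3.
#'
#' @param table Drinking tibble with columns `subject_id`, `session_index`,
#'   `g_per_kg`, and optionally `session_type` (only `"training"` rows are
#'   used when present).
#' @param k Number of final sessions to average.
#' @return Tibble: `subject_id`, `mean_g_per_kg`.
#' @export
average_last_sessions <- function(table, k = 3) {
  stopifnot(k >= 1)
  if ("session_type" %in% names(table)) {
    table <- dplyr::filter(table, .data$session_type == "training")
  }
  counts <- dplyr::count(table, .data$subject_id)
  short <- counts$subject_id[counts$n < k]
  if (length(short)) {
    stop("subjects with fewer than ", k, " training sessions: ",
         paste(short, collapse = ", "), call. = FALSE)
  }
  table |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::arrange(.data$session_index, .by_group = TRUE) |>
    dplyr::slice_tail(n = k) |>
    dplyr::summarise(mean_g_per_kg = mean(.data$g_per_kg), .groups = "drop")
}

#' Label subjects HD or LD by a median split
#'
#' Subjects whose summary drinking value is at or above the cohort median
#' are labelled HD (high drinker), the rest LD. With an odd number of
#' distinct values the median subject falls in HD, giving e.g. a 7/6 split
#' for 13 subjects. Ties exactly at the median follow the same >= rule; a
#' message is emitted since the split is then unbalanced beyond the usual
#' one subject.
#'
#' @param values Tibble with columns `subject_id` and a value column
#'   (default `mean_g_per_kg`), or a named numeric vector.
#' @param value_col Name of the value column.
#' @return Tibble: `subject_id`, value column, `label` (`"HD"`/`"LD"`),
#'   with the split value as attribute `"split_value"`.
#' @export
median_split <- function(values, value_col = "mean_g_per_kg") {
  if (is.numeric(values) && !is.null(names(values))) {
    values <- tibble::tibble(subject_id = names(values),
                             mean_g_per_kg = unname(values))
    value_col <- "mean_g_per_kg"
  }
  v <- values[[value_col]]
  stopifnot(length(v) >= 2)
  m <- stats::median(v)
  ties <- sum(v == m)
  if (ties > 1) {
    message("median_split: ", ties,
            " subjects tie exactly at the median; all assigned HD by the >= rule")
  }
  out <- values
  out$label <- ifelse(v >= m, "HD", "LD")
  attr(out, "split_value") <- m
  out
}

#' Pooled-variance two-sample t test
#'
#' Student's t with pooled variance and `df = n_a + n_b - 2`, matching the
#' degrees of freedom convention of the phenotype comparison (df = 11 for
#' 7 vs 6 subjects). Two-sided p value.
#'
#' @param a,b Numeric vectors (each length >= 2).
#' @return One-row tibble: `t`, `df`, `p`, `mean_a`, `mean_b`.
#' @export
two_sample_t <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
    (length(a) + length(b) - 2)
  if (sp2 == 0) {
    # degenerate: no within-group variance
    t_stat <- if (mean(a) == mean(b)) 0 else sign(mean(a) - mean(b)) * Inf
    p <- if (t_stat == 0) 1 else 0
    return(tibble::tibble(t = t_stat, df = length(a) + length(b) - 2, p = p,
                          mean_a = mean(a), mean_b = mean(b)))
  }
  ht <- stats::t.test(a, b, var.equal = TRUE)
  tibble::tibble(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value, mean_a = mean(a), mean_b = mean(b))
}

#' Two-by-two mixed ANOVA (one within, one between factor)
#'
#' Repeated-measures ANOVA with two within-subject levels (e.g. average
#' consumption before vs. during stimulation) and two between-subject
#' groups (HD vs. LD). The sums of squares decompose into group,
#' subjects-within-group, time, time x group, and time x
#' subjects-within-group; each effect is tested against its own error term
#' with df (1, n - 2), and partial eta squared is
#' `SS_effect / (SS_effect + SS_error)`.
#'
#' @param data Tibble with one row per subject: columns `subject_id`,
#'   `label` (`"HD"`/`"LD"`), `pre` and `stim` (the two within-level
#'   values, g/kg).
#' @return An object of class `mixed_anova`: tibble with rows `group`,
#'   `time`, `time:group`; columns `effect`, `F`, `df1`, `df2`, `p`,
#'   `partial_eta_sq`.
#' @export
mixed_anova_2x2 <- function(data) {
  stopifnot(all(c("subject_id", "label", "pre", "stim") %in% names(data)))
  tab <- table(data$label)
  if (length(tab) < 2 || any(tab < 2)) {
    stop("each group needs at least 2 subjects", call. = FALSE)
  }
  y <- rbind(data$pre, data$stim)        # 2 x n, within levels in rows
  g <- data$label
  n <- ncol(y)
  n_g <- as.numeric(table(g)[unique(g)])
  grand <- mean(y)

  subj_means <- colMeans(y)              # across the 2 within levels
  grp_means <- tapply(subj_means, g, mean)
  time_means <- rowMeans(y)
  cell_means <- t(vapply(unique(g), function(gg) rowMeans(y[, g == gg, drop = FALSE]),
                         numeric(2)))    # group x time

  k <- 2  # within levels
  n_per_group <- as.numeric(table(g)[names(grp_means)])
  ss_group <- k * sum(n_per_group * (as.numeric(grp_means) - grand)^2)
  ss_subj_within <- k * sum((subj_means - grp_means[g])^2)
  ss_time <- n * sum((time_means - grand)^2)
  ng_cells <- as.numeric(table(g)[rownames(cell_means)])
  ss_cells <- sum(ng_cells * (cell_means - grand)^2)  # recycles over rows
  ss_interaction <- ss_cells - ss_group - ss_time
  ss_total <- sum((y - grand)^2)
  ss_time_subj <- ss_total - ss_group - ss_subj_within - ss_time - ss_interaction

  df_between <- n - length(unique(g))
  mk_row <- function(effect, ss, ss_err, df_err) {
    if (ss_err == 0) {
      # degenerate error term: no variance left to test against
      f <- if (ss == 0) 0 else Inf
    } else {
      f <- (ss / 1) / (ss_err / df_err)
    }
    eta <- if (ss == 0 && ss_err == 0) 0 else ss / (ss + ss_err)
    tibble::tibble(effect = effect, F = f, df1 = 1, df2 = df_err,
                   p = stats::pf(f, 1, df_err, lower.tail = FALSE),
                   partial_eta_sq = eta)
  }
  res <- dplyr::bind_rows(
    mk_row("group", ss_group, ss_subj_within, df_between),
    mk_row("time", ss_time, ss_time_subj, df_between),
    mk_row("time:group", ss_interaction, ss_time_subj, df_between)
  )
  class(res) <- c("mixed_anova", class(res))
  res
}

#' @export
print.mixed_anova <- function(x, ...) {
  cat("Two-by-two mixed ANOVA\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-11s F(%d,%d) = %.2f, p = %.3g, np2 = %.2f\n",
                x$effect[i], x$df1[i], x$df2[i], x$F[i], x$p[i],
                x$partial_eta_sq[i]))
  }
  invisible(x)
}

#' Stimulation-response analysis from drinking tables
#'
#' Computes per-subject averages for the pre-stimulation (last `k` training
#' sessions) and stimulation phases, then runs the 2x2 mixed ANOVA with
#' phenotype group as the between factor.
#'
#' @param training Drinking tibble of training sessions.
#' @param stimulation Drinking tibble of stimulation sessions (all sessions
#'   averaged per subject).
#' @param labels Tibble with `subject_id`, `label` from [median_split()].
#' @param k Final training sessions to average.
#' @return A `mixed_anova` result.
#' @export
stimulation_response <- function(training, stimulation, labels, k = 3) {
  pre <- average_last_sessions(training, k)
  stim <- stimulation |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(stim = mean(.data$g_per_kg), .groups = "drop")
  dat <- pre |>
    dplyr::rename(pre = "mean_g_per_kg") |>
    dplyr::inner_join(stim, by = "subject_id") |>
    dplyr::inner_join(dplyr::select(labels, "subject_id", "label"),
                      by = "subject_id")
  if (nrow(dat) != nrow(pre)) {
    stop("every subject needs a pre average, a stimulation average and a label",
         call. = FALSE)
  }
  mixed_anova_2x2(dat)
}
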