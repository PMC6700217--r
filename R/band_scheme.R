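#' Frequency band scheme for rodent LFP analysis
#'
#' A band scheme names the frequency bands used to summarise spectra, the
#' broadband range used to normalize band values, and an exclusion range
#' (around the line-noise notch) whose frequency bins are dropped from both
#' band and normalizer averages.
#'
#' The default encodes the canonical rodent bands: delta 1-4 Hz, theta
#' 5-10 Hz, alpha 11-14 Hz, beta 15-30 Hz, low gamma 45-65 Hz and high gamma
#' 70-90 Hz, normalized over 1-90 Hz with 59-61 Hz excluded to account for
#' the 60 Hz notch filter.
#'
#' @param bands Named list of two-element numeric vectors `c(low, high)` in
#'   Hz, ordered by increasing frequency and non-overlapping.
#' @param norm_range Two-element numeric vector, the broadband normalization
#'   range in Hz. All band edges must lie inside it.
#' @param exclusion Two-element numeric vector, an open interval in Hz whose
#'   bins are excluded from every average. Must lie strictly inside
#'   `norm_range`.
#' @return An object of class `band_scheme`.
#' @examples
#' sch <- band_scheme()
#' names(sch$bands)
#' @export
band_scheme <- function(bands = list(
                          delta  = c(1, 4),
                          theta  = c(5, 10),
                          alpha  = c(11, 14),
                          beta   = c(15, 30),
                          lgamma = c(45, 65),
                          hgamma = c(70, 90)
                        ),
                        norm_range = c(1, 90),
                        exclusion = c(59, 61)) {
  stopifnot(is.list(bands), length(bands) >= 1, !is.null(names(bands)))
  edges <- vapply(bands, function(b) {
    stopifnot(is.numeric(b), length(b) == 2, b[1] < b[2])
    b
  }, numeric(2))
  lows <- edges[1, ]
  highs <- edges[2, ]
  if (is.unsorted(lows, strictly = TRUE) || any(highs[-length(highs)] > lows[-1])) {
    stop("bands must be sorted ascending and non-overlapping", call. = FALSE)
  }
  stopifnot(length(norm_range) == 2, norm_range[1] < norm_range[2])
  if (min(lows) < norm_range[1] || max(highs) > norm_range[2]) {
    stop("all band edges must lie within norm_range", call. = FALSE)
  }
  stopifnot(length(exclusion) == 2, exclusion[1] < exclusion[2])
  if (exclusion[1] <= norm_range[1] || exclusion[2] >= norm_range[2]) {
    stop("exclusion range must lie strictly inside norm_range", call. = FALSE)
  }
  structure(
    list(bands = bands, norm_range = norm_range, exclusion = exclusion),
    class = "band_scheme"
  )
}

#' @export
print.band_scheme <- function(x, ...) {
  cat("<band_scheme>\n")
  for (nm in names(x$bands)) {
    cat(sprintf("  %-8s %g-%g Hz\n", nm, x$bands[[nm]][1], x$bands[[nm]][2]))
  }
  cat(sprintf("  normalized over %g-%g Hz, excluding %g-%g Hz\n",
              x$norm_range[1], x$norm_range[2], x$exclusion[1], x$exclusion[2]))
  invisible(x)
}

# Frequency-bin membership helpers. A grid frequency f belongs to band
# [low, high] iff low <= f <= high; bins inside the open exclusion interval
# never count, neither for bands nor for the broadband normalizer.
band_bins <- function(freqs, band, exclusion) {
  freqs >= band[1] & freqs <= band[2] &
    !(freqs > exclusion[1] & freqs < exclusion[2])
}
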