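#' Immunoreactivity score (IRS)
#'
#' The IRS is the classic semi-quantitative product score: a percentage-of-
#' positive-cells category (0-4) multiplied by a staining-intensity category
#' (0-3), giving a score in 0-12. The intensity category is a human judgment
#' (0 none, 1 weak, 2 moderate, 3 strong) and is always an input here, never
#' derived from pixels.
#'
#' `score_pct()` bins a %PC value: 0 for exactly 0% (no positive cells),
#' 1 for (0, 10)%, 2 for \[10, 50\]%, 3 for (50, 80\]%, 4 for > 80%. The
#' published bins leave (50, 51) unnamed ("10-50%", "51-80%"); this
#' implementation closes the gap by extending category 3 down to just above
#' 50 so the function is total and monotone on \[0, 100\].
#'
#' @param pct_positive Numeric vector of percentages in `[0, 100]`.
#' @return `score_pct()`: integer vector of categories 0-4.
#' @examples
#' score_pct(c(0, 5, 10, 50, 50.5, 80, 85))
#' compute_irs(4, 3) # maximum score, 12
#' @export
score_pct <- function(pct_positive) {
  if (any(!is.finite(pct_positive)) ||
    any(pct_positive < 0) || any(pct_positive > 100)) {
    stop("`pct_positive` must be finite and in [0, 100]", call. = FALSE)
  }
  out <- integer(length(pct_positive))
  out[pct_positive > 0 & pct_positive < 10] <- 1L
  out[pct_positive >= 10 & pct_positive <= 50] <- 2L
  out[pct_positive > 50 & pct_positive <= 80] <- 3L
  out[pct_positive > 80] <- 4L
  out
}

#' @rdname score_pct
#' @param pct_score Integer vector of %PC categories in 0-4.
#' @param intensity_score Integer vector of intensity categories in 0-3.
#' @return `compute_irs()`: integer vector of IRS values in 0-12.
#' @export
compute_irs <- function(pct_score, intensity_score) {
  if (any(pct_score != as.integer(pct_score)) ||
    any(pct_score < 0) || any(pct_score > 4)) {
    stop("`pct_score` must be an integer in 0-4", call. = FALSE)
  }
  if (any(intensity_score != as.integer(intensity_score)) ||
    any(intensity_score < 0) || any(intensity_score > 3)) {
    stop("`intensity_score` must be an integer in 0-3", call. = FALSE)
  }
  as.integer(pct_score) * as.integer(intensity_score)
}

#' Score a measurement table with the IRS
#'
#' Data-frame-first wrapper: adds `pct_score` (from `pct_positive` if a
#' `pct_score` column is not already present) and `irs` columns.
#'
#' @param data Data frame with `intensity_score` and either `pct_positive`
#'   or `pct_score`.
#' @return The input as a tibble with `pct_score` and `irs` columns added.
#' @export
score_irs <- function(data) {
  stopifnot(is.data.frame(data))
  data <- as_tibble(data)
  if (!"intensity_score" %in% names(data)) {
    stop("`data` needs an `intensity_score` column", call. = FALSE)
  }
  if (!"pct_score" %in% names(data)) {
    if (!"pct_positive" %in% names(data)) {
      stop("`data` needs a `pct_score` or `pct_positive` column", call. = FALSE)
    }
    data$pct_score <- score_pct(data$pct_positive)
  }
  data$irs <- compute_irs(data$pct_score, data$intensity_score)
  data
}
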