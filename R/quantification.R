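#' Field-level staining measures
#'
#' Computes the two measures used to quantify a field: the percentage of
#' positive cells, `%PC = 100 * n_positive / n_cells`, and the staining
#' intensity per unit area, `intensity/area = total_intensity / roi_area`,
#' where `total_intensity` sums the DAB channel over *all* ROI pixels
#' (stained and unstained) and `roi_area` is the number of analyzed pixels.
#' With the DAB channel normalized to `[0, 1]`, intensity/area ranges from 0
#' (no staining) to 1 (maximum staining) arbitrary units per pixel.
#'
#' A field with no detected cells reports `pct_positive` as `NA` (0/0 is not
#' "no positive cells"); such fields are excluded from the %PC mean at
#' aggregation but still contribute intensity/area.
#'
#' @param dab DAB channel matrix in `[0, 1]`.
#' @param roi Logical ROI mask, same shape; must contain at least one pixel.
#' @param positive Named logical vector of per-cell positivity from
#'   [classify_positive()] (the number of cells is its length).
#' @return One-row tibble: `n_cells`, `n_positive`, `total_intensity`,
#'   `roi_area`, `pct_positive`, `intensity_per_area`.
#' @examples
#' dab <- matrix(0.25, 10, 10)
#' roi <- matrix(TRUE, 10, 10)
#' compute_image_metrics(dab, roi, setNames(c(TRUE, FALSE), 1:2))
#' @export
compute_image_metrics <- function(dab, roi, positive) {
  stopifnot(is.matrix(dab))
  roi <- check_roi(roi, dab)
  if (min(dab) < 0 || max(dab) > 1) {
    stop("`dab` must lie in [0, 1]", call. = FALSE)
  }
  n_cells <- length(positive)
  n_pos <- sum(positive)
  total <- sum(dab[roi])
  area <- sum(roi)
  tibble(
    n_cells = n_cells,
    n_positive = n_pos,
    total_intensity = total,
    roi_area = area,
    pct_positive = if (n_cells > 0) 100 * n_pos / n_cells else NA_real_,
    intensity_per_area = total / area
  )
}

#' Aggregate field measures to sample level
#'
#' One sample is measured as the unweighted mean of its (up to four) field
#' images for each measure, per selector/analyzer combination. Fields with
#' undefined %PC (no cells) are dropped from the %PC mean only.
#'
#' @param metrics Data frame of per-image rows with at least `sample_id`,
#'   `selector`, `analyzer`, `pct_positive`, `intensity_per_area`.
#' @param max_images Maximum fields per (sample, selector, analyzer)
#'   combination; more is an error (default 4).
#' @return Tibble with one row per (sample_id, selector, analyzer):
#'   `n_images`, `pct_positive`, `intensity_per_area`.
#' @export
aggregate_sample <- function(metrics, max_images = 4L) {
  stopifnot(is.data.frame(metrics), nrow(metrics) > 0)
  req <- c("sample_id", "selector", "analyzer", "pct_positive", "intensity_per_area")
  missing_cols <- setdiff(req, names(metrics))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- metrics |>
    dplyr::group_by(.data$sample_id, .data$selector, .data$analyzer) |>
    dplyr::summarise(
      n_images = dplyr::n(),
      pct_positive = mean(.data$pct_positive, na.rm = TRUE),
      intensity_per_area = mean(.data$intensity_per_area),
      .groups = "drop"
    ) |>
    dplyr::mutate(pct_positive = ifelse(is.nan(.data$pct_positive), NA_real_,
      .data$pct_positive
    ))
  if (any(out$n_images > max_images)) {
    stop("more than ", max_images, " images for a (sample, selector, analyzer) ",
      "combination",
      call. = FALSE
    )
  }
  out
}

#' Average a sample's measures across observer combinations
#'
#' For each sample, the mean of the measurements of the available
#' selector/analyzer combinations (up to 4: S1A1, S1A2, S2A1, S2A2);
#' duplicated combinations are an error.
#'
#' @param samples Tibble from [aggregate_sample()].
#' @return Tibble with one row per sample: `n_combinations`, `pct_positive`,
#'   `intensity_per_area`.
#' @export
aggregate_combinations <- function(samples) {
  stopifnot(is.data.frame(samples), nrow(samples) > 0)
  dup <- samples |>
    dplyr::count(.data$sample_id, .data$selector, .data$analyzer) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop("duplicated (selector, analyzer) combination for sample ",
      paste(unique(dup$sample_id), collapse = ", "),
      call. = FALSE
    )
  }
  samples |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      n_combinations = dplyr::n(),
      pct_positive = mean(.data$pct_positive, na.rm = TRUE),
      intensity_per_area = mean(.data$intensity_per_area),
      .groups = "drop"
    ) |>
    dplyr::mutate(pct_positive = ifelse(is.nan(.data$pct_positive), NA_real_,
      .data$pct_positive
    ))
}

#' Quantify a single field image
#'
#' Full single-field pipeline: stain separation, segmentation, positivity
#' classification and measure computation.
#'
#' @param image RGB array (`height x width x 3`).
#' @param roi Logical ROI mask.
#' @param config Configuration list; see [default_config()].
#' @return List with `channels`, `segmentation` and `metrics` (one-row
#'   tibble).
#' @export
quantify_field <- function(image, roi, config = default_config()) {
  config <- utils::modifyList(default_config(), config)
  channels <- separate_stains(image,
    stains = config$stain_matrix,
    white_point = config$white_point, saturation_od = config$saturation_od
  )
  seg <- segment_field(channels, roi, config$segmentation)
  metrics <- compute_image_metrics(channels$dab, roi, seg$positive)
  list(channels = channels, segmentation = seg, metrics = metrics)
}
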