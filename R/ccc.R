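#' Lin's concordance correlation coefficient
#'
#' The CCC measures agreement between two measurements of the same quantity,
#' penalizing both imprecision (scatter about the best-fit line) and
#' inaccuracy (location/scale shift from the identity line):
#' \deqn{\rho_c = \frac{2 s_{xy}}{s_x^2 + s_y^2 + (\bar x - \bar y)^2}}
#' It ranges over \[-1, 1\] and equals 1 only when the two vectors are
#' identical. Moments use the 1/n (population) convention of the original
#' estimator; `bias_correction = TRUE` switches to 1/(n-1).
#'
#' The 95% confidence interval is obtained on the Fisher z scale,
#' `z = atanh(ccc)`, with Lin's asymptotic standard error, then transformed
#' back. Agreement is categorized as `"none"` below 0.800, `"acceptable"`
#' at 0.800 or higher, and `"strong"` at 0.950 or higher.
#'
#' @param x,y Numeric vectors of equal length (n >= 3), finite, with nonzero
#'   variance in at least one.
#' @param conf_level Confidence level (default 0.95).
#' @param bias_correction Use 1/(n-1) moments instead of 1/n.
#' @return An object of class `ccc_result` with elements `ccc`, `ci_low`,
#'   `ci_high`, `category`, `n`, `pearson`. Use [tidy()] or [glance()] for a
#'   tibble view.
#' @examples
#' concordance_correlation(1:10, 1:10 + rnorm(10, sd = 0.1))
#' @export
concordance_correlation <- function(x, y, conf_level = 0.95,
                                    bias_correction = FALSE) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length", call. = FALSE)
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("`x` and `y` must be finite", call. = FALSE)
  }
  denom_n <- if (bias_correction) n - 1 else n
  mx <- mean(x)
  my <- mean(y)
  sx2 <- sum((x - mx)^2) / denom_n
  sy2 <- sum((y - my)^2) / denom_n
  if (sx2 == 0 && sy2 == 0) {
    stop("both vectors are constant; CCC undefined", call. = FALSE)
  }
  sxy <- sum((x - mx) * (y - my)) / denom_n
  ccc <- 2 * sxy / (sx2 + sy2 + (mx - my)^2)

  # Fisher-z CI with Lin's asymptotic SE (needs nondegenerate r and |ccc|<1)
  r <- suppressWarnings(cor(x, y))
  ci <- c(NA_real_, NA_real_)
  if (is.finite(r) && abs(r) > 0 && abs(ccc) < 1 - 1e-12 && n > 2) {
    u <- (mx - my) / sqrt(sqrt(sx2) * sqrt(sy2))
    sez2 <- ((1 - r^2) * ccc^2 / ((1 - ccc^2) * r^2) +
      4 * ccc^3 * (1 - ccc) * u^2 / (r * (1 - ccc^2)^2) -
      2 * ccc^4 * u^4 / (r^2 * (1 - ccc^2)^2)) / (n - 2)
    if (is.finite(sez2) && sez2 >= 0) {
      zc <- atanh(ccc)
      q <- qnorm(1 - (1 - conf_level) / 2)
      ci <- tanh(zc + c(-1, 1) * q * sqrt(sez2))
    }
  } else if (abs(ccc) >= 1 - 1e-12) {
    ci <- c(ccc, ccc)
  }

  structure(
    list(
      ccc = ccc, ci_low = ci[1], ci_high = ci[2],
      category = ccc_category(ccc), n = n, pearson = r,
      conf_level = conf_level, bias_correction = bias_correction
    ),
    class = "ccc_result"
  )
}

#' Agreement category of a CCC value
#'
#' `"none"` below 0.800, `"acceptable"` from 0.800 (inclusive), `"strong"`
#' from 0.950 (inclusive).
#'
#' @param ccc Numeric vector of CCC values.
#' @return Character vector of categories.
#' @export
ccc_category <- function(ccc) {
  ifelse(ccc >= 0.950, "strong", ifelse(ccc >= 0.800, "acceptable", "none"))
}

#' @export
print.ccc_result <- function(x, ...) {
  cat(sprintf(
    "Lin's concordance correlation\n  CCC = %.3f (%d%% CI %.3f-%.3f), n = %d\n  agreement: %s\n",
    x$ccc, round(100 * x$conf_level), x$ci_low, x$ci_high, x$n, x$category
  ))
  invisible(x)
}

#' @method tidy ccc_result
#' @export
tidy.ccc_result <- function(x, ...) {
  tibble(
    estimate = x$ccc, ci_low = x$ci_low, ci_high = x$ci_high,
    category = x$category
  )
}

#' @method glance ccc_result
#' @export
glance.ccc_result <- function(x, ...) {
  tibble(
    ccc = x$ccc, ci_low = x$ci_low, ci_high = x$ci_high,
    category = x$category, pearson = x$pearson, n = x$n
  )
}

#' Pairwise CCC between observer combinations
#'
#' From a long-format measurement table (one row per sample x selector x
#' analyzer x measure), computes Lin's CCC for every pair of
#' selector/analyzer combinations, per measure — the all-pairs agreement
#' matrix of a two-selector, two-analyzer validation design (6 pairs for 4
#' combinations). Each pair is labeled by which observer index differs:
#' `"analyzer"` (same selector), `"selector"` (same analyzer), or `"both"`.
#'
#' @param data Data frame with columns `sample_id`, `selector`, `analyzer`,
#'   `measure`, `value`.
#' @param ... Passed to [concordance_correlation()].
#' @return Tibble with one row per (measure, combination pair): `measure`,
#'   `combo_a`, `combo_b`, `comparison`, `n`, `ccc`, `ci_low`, `ci_high`,
#'   `category`.
#' @export
pairwise_ccc <- function(data, ...) {
  req <- c("sample_id", "selector", "analyzer", "measure", "value")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  wide <- data |>
    dplyr::mutate(combo = paste(.data$selector, .data$analyzer, sep = "-")) |>
    dplyr::select("sample_id", "measure", "combo", "value") |>
    tidyr::pivot_wider(names_from = "combo", values_from = "value")
  combos <- setdiff(names(wide), c("sample_id", "measure"))
  if (length(combos) < 2) {
    stop("need at least two selector/analyzer combinations", call. = FALSE)
  }
  pairs <- utils::combn(sort(combos), 2, simplify = FALSE)
  purrr::map_dfr(split(wide, wide$measure), function(w) {
    purrr::map_dfr(pairs, function(p) {
      ok <- complete.cases(w[[p[1]]], w[[p[2]]])
      fit <- concordance_correlation(w[[p[1]]][ok], w[[p[2]]][ok], ...)
      sel <- sub("-.*", "", p)
      ana <- sub(".*-", "", p)
      tibble(
        measure = w$measure[1], combo_a = p[1], combo_b = p[2],
        comparison = if (sel[1] == sel[2]) {
          "analyzer"
        } else if (ana[1] == ana[2]) "selector" else "both",
        n = fit$n, ccc = fit$ccc, ci_low = fit$ci_low,
        ci_high = fit$ci_high, category = fit$category
      )
    })
  })
}
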