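#' Specification of a synthetic H-DAB field
#'
#' Parameters of the synthetic field generator. The defaults describe a
#' tumor-like field at desk scale: a 512x512 8-bit image with 300
#' well-separated nuclei of ~16 px diameter, moderate hematoxylin
#' counterstain, DAB deposited on positive cells at 60% of the saturation
#' ceiling, and mild Gaussian pixel noise.
#'
#' @param n_cells Number of nuclei to place (default 300).
#' @param frac_positive Fraction of DAB-positive cells in `[0, 1]`
#'   (default 0.5); the positive count is `round(frac_positive * n_cells)`.
#' @param dab_level DAB concentration of positive cells as a fraction of the
#'   saturation OD (default 0.6).
#' @param hema_level Hematoxylin concentration of nuclei (default 0.5).
#' @param nucleus_radius_mean,nucleus_radius_sd Nucleus radius distribution
#'   in pixels (defaults 8 and 1).
#' @param ring_px Width of the perinuclear DAB ring on positive cells
#'   (default 3), giving whole-cell rather than nucleus-only staining.
#' @param image_size `c(height, width)` (default `c(512, 512)`).
#' @param white_point Background intensity (default 255, 8-bit).
#' @param noise_sd Gaussian pixel noise sd in intensity counts (default 4).
#' @param roi_margin Inset of the rectangular ROI from the image border in
#'   pixels (default 12).
#' @param seed Integer seed; mandatory for reproducibility (default 1).
#' @return A `field_spec` list.
#' @export
field_spec <- function(n_cells = 300, frac_positive = 0.5, dab_level = 0.6,
                       hema_level = 0.5, nucleus_radius_mean = 8,
                       nucleus_radius_sd = 1, ring_px = 3,
                       image_size = c(512, 512), white_point = 255,
                       noise_sd = 4, roi_margin = 12, seed = 1) {
  stopifnot(
    n_cells >= 0, frac_positive >= 0, frac_positive <= 1,
    dab_level >= 0, dab_level <= 1, hema_level > 0, hema_level <= 1,
    noise_sd >= 0, length(image_size) == 2
  )
  structure(
    list(
      n_cells = n_cells, frac_positive = frac_positive,
      dab_level = dab_level, hema_level = hema_level,
      nucleus_radius_mean = nucleus_radius_mean,
      nucleus_radius_sd = nucleus_radius_sd, ring_px = ring_px,
      image_size = as.integer(image_size), white_point = white_point,
      noise_sd = noise_sd, roi_margin = roi_margin, seed = as.integer(seed)
    ),
    class = "field_spec"
  )
}

disk_offsets <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g[g$dr^2 + g$dc^2 <= radius^2, , drop = FALSE]
}

stamp_disk <- function(mat, row, col, radius, value) {
  off <- disk_offsets(radius)
  rr <- row + off$dr
  cc <- col + off$dc
  keep <- rr >= 1 & rr <= nrow(mat) & cc >= 1 & cc <= ncol(mat)
  mat[cbind(rr[keep], cc[keep])] <- pmax(mat[cbind(rr[keep], cc[keep])], value)
  mat
}

#' Generate a synthetic H-DAB field with ground truth
#'
#' Nuclei are placed by dart throwing without overlap (a small guard gap
#' keeps neighbors separable), hematoxylin is deposited on every nucleus,
#' and DAB on positive cells over the nucleus plus a perinuclear ring
#' (whole-cell staining). The RGB image is composed by the forward
#' Beer-Lambert model with the standard H-DAB stain matrix, then Gaussian
#' pixel noise is added, clipped and quantized. Fully deterministic for a
#' given seed.
#'
#' @param spec A [field_spec()].
#' @param max_attempts_per_cell Dart-throwing retry bound (default 200);
#'   exceeding it (infeasible density) is an error.
#' @return List with `image` (RGB array), `roi` (logical matrix), and
#'   `truth`: a list with `cells` (tibble of `row`, `col`, `radius`,
#'   `positive`), `true_pct_positive`, `true_intensity_per_area` (mean of
#'   the noiseless DAB concentration channel over the ROI), and the
#'   noiseless `dab`/`hematoxylin` concentration maps.
#' @export
generate_field <- function(spec = field_spec(), max_attempts_per_cell = 200) {
  stopifnot(inherits(spec, "field_spec"))
  withr::with_seed(spec$seed, generate_field_impl(spec, max_attempts_per_cell))
}

generate_field_impl <- function(spec, max_attempts_per_cell) {
  h <- spec$image_size[1]
  w <- spec$image_size[2]
  roi <- matrix(FALSE, h, w)
  m <- spec$roi_margin
  roi[(m + 1):(h - m), (m + 1):(w - m)] <- TRUE

  # dart-throwing placement with a 3 px guard gap between nucleus borders
  rows <- cols <- radii <- numeric(0)
  attempts <- 0L
  max_attempts <- max_attempts_per_cell * max(spec$n_cells, 1L)
  while (length(rows) < spec$n_cells) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop("could not place ", spec$n_cells, " non-overlapping nuclei; ",
        "density infeasible",
        call. = FALSE
      )
    }
    r <- max(3, rnorm(1, spec$nucleus_radius_mean, spec$nucleus_radius_sd))
    pad <- m + r + spec$ring_px + 1
    cy <- runif(1, pad, h - pad)
    cx <- runif(1, pad, w - pad)
    if (length(rows) == 0 ||
      all((rows - cy)^2 + (cols - cx)^2 >= (radii + r + 3)^2)) {
      rows <- c(rows, cy)
      cols <- c(cols, cx)
      radii <- c(radii, r)
    }
  }

  n <- spec$n_cells
  n_pos <- round(spec$frac_positive * n)
  positive <- rep(FALSE, n)
  if (n_pos > 0) positive[sample.int(n, n_pos)] <- TRUE

  hema <- matrix(0, h, w)
  dab <- matrix(0, h, w)
  for (i in seq_len(n)) {
    hema <- stamp_disk(hema, round(rows[i]), round(cols[i]), radii[i], spec$hema_level)
    if (positive[i]) {
      dab <- stamp_disk(
        dab, round(rows[i]), round(cols[i]),
        radii[i] + spec$ring_px, spec$dab_level
      )
    }
  }

  img <- recombine(hema, dab,
    white_point = spec$white_point,
    quantize = FALSE
  )
  if (spec$noise_sd > 0) {
    img <- img + array(rnorm(length(img), 0, spec$noise_sd), dim = dim(img))
  }
  img <- round(img)
  img[img < 0] <- 0
  img[img > spec$white_point] <- spec$white_point

  truth <- list(
    cells = tibble(
      row = rows, col = cols, radius = radii,
      positive = positive
    ),
    true_pct_positive = if (n > 0) 100 * sum(positive) / n else NA_real_,
    true_intensity_per_area = mean(dab[roi]),
    dab = dab, hematoxylin = hema
  )
  list(image = img, roi = roi, truth = truth, spec = spec)
}

#' Simulate a multi-observer measurement table
#'
#' Emulates a two-selector, two-analyzer validation design with additive
#' Gaussian observer effects: each sample has a latent true value, each
#' (sample, selector) and (sample, analyzer) pair draws an effect, and every
#' selector/analyzer combination measures
#' `truth + selector effect + analyzer effect + residual`. Under this model
#' the population CCC between two combinations has the closed form given by
#' [theoretical_ccc()], so generator and estimator form a parameter-recovery
#' loop.
#'
#' @param n_samples Number of samples.
#' @param truth_mean,truth_sd Latent truth distribution (Gaussian).
#' @param selector_sd,analyzer_sd,measurement_sd Effect scales (>= 0).
#' @param measure Name written into the `measure` column.
#' @param range Optional `c(lo, hi)`; measurements are clipped to it after
#'   noise addition (mildly attenuates agreement for extreme truths).
#' @param seed Integer seed.
#' @return Long tibble: `sample_id`, `selector`, `analyzer`, `measure`,
#'   `value`.
#' @export
generate_observer_tables <- function(n_samples, truth_mean = 50,
                                     truth_sd = 20, selector_sd = 2,
                                     analyzer_sd = 2, measurement_sd = 2,
                                     measure = "pct_positive", range = NULL,
                                     seed = 1) {
  stopifnot(
    n_samples >= 1, truth_sd >= 0, selector_sd >= 0,
    analyzer_sd >= 0, measurement_sd >= 0
  )
  withr::with_seed(seed, {
    truth <- rnorm(n_samples, truth_mean, truth_sd)
    grid <- tidyr::expand_grid(
      sample_id = sprintf("sample_%03d", seq_len(n_samples)),
      selector = c("S1", "S2"), analyzer = c("A1", "A2")
    )
    sel_eff <- matrix(rnorm(2 * n_samples, 0, selector_sd), n_samples, 2)
    ana_eff <- matrix(rnorm(2 * n_samples, 0, analyzer_sd), n_samples, 2)
    i <- rep(seq_len(n_samples), each = 4)
    si <- as.integer(factor(grid$selector))
    ai <- as.integer(factor(grid$analyzer))
    value <- truth[i] + sel_eff[cbind(i, si)] + ana_eff[cbind(i, ai)] +
      rnorm(nrow(grid), 0, measurement_sd)
    if (!is.null(range)) value <- pmin(pmax(value, range[1]), range[2])
    dplyr::mutate(grid, measure = measure, value = value)
  })
}

#' Closed-form CCC of the additive-Gaussian observer model
#'
#' Population concordance between two selector/analyzer combinations under
#' the [generate_observer_tables()] model. Shared effects contribute to the
#' covariance; the means are equal, so there is no shift term.
#'
#' @param truth_sd,selector_sd,analyzer_sd,measurement_sd Model scales.
#' @param differ Which observer indices differ between the two combinations:
#'   `"both"`, `"selector"`, or `"analyzer"`.
#' @return Theoretical CCC value.
#' @export
theoretical_ccc <- function(truth_sd, selector_sd, analyzer_sd,
                            measurement_sd,
                            differ = c("both", "selector", "analyzer")) {
  differ <- match.arg(differ)
  vt <- truth_sd^2
  vs <- selector_sd^2
  va <- analyzer_sd^2
  vm <- measurement_sd^2
  cov <- vt + switch(differ,
    both = 0,
    selector = va,
    analyzer = vs
  )
  cov / (vt + vs + va + vm)
}

#' Simulate score/outcome tables for response prediction
#'
#' Generates paired (staining measure, biochemical response) data with a
#' controlled negative Spearman correlation through a Gaussian copula
#' (Pearson latent correlation `2 sin(pi rho / 6)` matches the target
#' Spearman rho). The response is a positive IGF-1 multiple of the upper
#' limit of normal (log-normal, median 1), and `normalized` flags values at
#' or below 1.
#'
#' @param n_patients Number of patients.
#' @param rho_target Target Spearman correlation in `(-1, 0]`.
#' @param sst2_max Upper end of the uniform-margin staining measure
#'   (default 0.6, an intensity/area-like scale).
#' @param igf1_sdlog Log-sd of the IGF-1 margin (default 0.5).
#' @param seed Integer seed.
#' @return Tibble: `patient_id`, `sst2_measure`, `igf1_xuln`, `normalized`.
#' @export
generate_response_tables <- function(n_patients, rho_target = -0.5,
                                     sst2_max = 0.6, igf1_sdlog = 0.5,
                                     seed = 1) {
  stopifnot(rho_target > -1, rho_target <= 0, n_patients >= 2)
  r <- 2 * sin(pi * rho_target / 6)
  withr::with_seed(seed, {
    z1 <- rnorm(n_patients)
    z2 <- r * z1 + sqrt(1 - r^2) * rnorm(n_patients)
    igf1 <- qlnorm(pnorm(z2), meanlog = 0, sdlog = igf1_sdlog)
    tibble(
      patient_id = sprintf("pt_%03d", seq_len(n_patients)),
      sst2_measure = sst2_max * pnorm(z1),
      igf1_xuln = igf1,
      normalized = igf1 <= 1.0
    )
  })
}
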