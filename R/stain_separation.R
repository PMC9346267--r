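#' Standard H-DAB stain matrix
#'
#' Optical-density vectors for hematoxylin, DAB and a residual channel, as
#' published by Ruifrok and Johnston for brightfield H-DAB
#' immunohistochemistry. Rows are unit-length OD vectors in (R, G, B) order;
#' the residual row is the normalized cross product of the first two, so the
#' matrix is always invertible.
#'
#' @param hematoxylin,dab Optional length-3 replacement OD vectors (they are
#'   normalized internally). Defaults are the published H-DAB values.
#' @return A 3x3 numeric matrix with rownames `c("hematoxylin", "dab",
#'   "residual")` and colnames `c("R", "G", "B")`.
#' @examples
#' hdab_stain_matrix()
#' @export
hdab_stain_matrix <- function(hematoxylin = c(0.650, 0.704, 0.286),
                              dab = c(0.269, 0.568, 0.778)) {
  h <- hematoxylin / sqrt(sum(hematoxylin^2))
  d <- dab / sqrt(sum(dab^2))
  r <- c(
    h[2] * d[3] - h[3] * d[2],
    h[3] * d[1] - h[1] * d[3],
    h[1] * d[2] - h[2] * d[1]
  )
  r <- r / sqrt(sum(r^2))
  m <- rbind(h, d, r)
  dimnames(m) <- list(c("hematoxylin", "dab", "residual"), c("R", "G", "B"))
  m
}

check_stain_matrix <- function(stains) {
  if (!is.matrix(stains) || !all(dim(stains) == c(3L, 3L))) {
    stop("`stains` must be a 3x3 matrix of stain OD vectors (rows)",
      call. = FALSE
    )
  }
  norms <- sqrt(rowSums(stains^2))
  if (any(abs(norms - 1) > 1e-6)) {
    stop("stain matrix rows must be unit length (tolerance 1e-6)",
      call. = FALSE
    )
  }
  if (!is.finite(kappa(stains)) || abs(det(stains)) < 1e-8) {
    stop("stain matrix is singular or ill-conditioned", call. = FALSE)
  }
  invisible(stains)
}

#' Convert an RGB brightfield image to optical density
#'
#' Applies the Beer-Lambert relation per channel:
#' `OD = -log10((pixel + eps) / (white_point + eps))`, where `white_point` is
#' the unstained background intensity (by default the nominal maximum of the
#' integer range, e.g. 255 for 8-bit). `eps = 1 / white_point` guards the
#' logarithm at zero; it sits below quantization noise.
#'
#' @param image Numeric array `height x width x 3` with values in
#'   `[0, white_point]`.
#' @param white_point Background (unstained) intensity; scalar or length 3.
#' @return Array of the same shape with nonnegative optical densities
#'   (pixels brighter than `white_point` would give small negative OD and are
#'   clamped at 0).
#' @examples
#' img <- array(255, dim = c(2, 2, 3))
#' range(rgb_to_od(img)) # background -> 0 OD
#' @export
rgb_to_od <- function(image, white_point = 255) {
  if (length(dim(image)) != 3L || dim(image)[3] != 3L) {
    stop("`image` must be a height x width x 3 array", call. = FALSE)
  }
  if (any(white_point <= 0)) stop("`white_point` must be positive", call. = FALSE)
  wp <- rep_len(white_point, 3L)
  eps <- 1 / wp
  od <- image
  for (k in 1:3) {
    od[, , k] <- -log10((image[, , k] + eps[k]) / (wp[k] + eps[k]))
  }
  od[od < 0] <- 0
  od
}

#' Separate an H-DAB image into per-stain channels
#'
#' Unmixes the optical-density image into per-pixel stain concentrations by
#' the inverse of the stain matrix, clips negative concentrations to zero and
#' rescales by a fixed saturation OD so each channel lives on `[0, 1]` with 1
#' meaning maximum (saturated) staining. The orientation follows the
#' convention that stronger staining maps to higher channel values, so an
#' unstained white pixel is 0 in both channels.
#'
#' A fixed saturation constant (rather than per-image max normalization)
#' keeps channel values, and hence the intensity/area measure, comparable
#' across images.
#'
#' @param image Numeric `height x width x 3` RGB array.
#' @param stains 3x3 stain matrix, rows = unit OD vectors
#'   (hematoxylin, DAB, residual); default [hdab_stain_matrix()].
#' @param white_point Background intensity (see [rgb_to_od()]).
#' @param saturation_od Concentration (in OD units along the stain vector)
#'   mapped to channel value 1. Default 2.0.
#' @return List with matrices `hematoxylin` and `dab` in `[0, 1]`, plus the
#'   attributes-free `residual` channel for diagnostics.
#' @seealso [recombine()] for the forward model.
#' @export
separate_stains <- function(image, stains = hdab_stain_matrix(),
                            white_point = 255, saturation_od = 2.0) {
  check_stain_matrix(stains)
  od <- rgb_to_od(image, white_point = white_point)
  d <- dim(od)
  odm <- matrix(od, ncol = 3L) # pixels x RGB
  conc <- odm %*% solve(stains) # pixels x stain
  conc[conc < 0] <- 0
  conc <- conc / saturation_od
  conc[conc > 1] <- 1
  list(
    hematoxylin = matrix(conc[, 1], d[1], d[2]),
    dab = matrix(conc[, 2], d[1], d[2]),
    residual = matrix(conc[, 3], d[1], d[2])
  )
}

#' Synthesize an RGB image from stain channels (forward Beer-Lambert model)
#'
#' The inverse of [separate_stains()]: channel values in `[0, 1]` are scaled
#' back to OD by `saturation_od`, mixed through the stain matrix, and
#' converted to transmitted intensities. Used to build synthetic fields and
#' as the round-trip oracle in tests.
#'
#' @param hematoxylin,dab Numeric matrices in `[0, 1]`, same shape.
#' @param residual Optional residual channel (default 0).
#' @param stains,white_point,saturation_od As in [separate_stains()].
#' @param quantize Round to integer intensities (default `TRUE`).
#' @return `height x width x 3` array with values in `[0, white_point]`.
#' @export
recombine <- function(hematoxylin, dab, residual = NULL,
                      stains = hdab_stain_matrix(), white_point = 255,
                      saturation_od = 2.0, quantize = TRUE) {
  check_stain_matrix(stains)
  stopifnot(all(dim(hematoxylin) == dim(dab)))
  if (is.null(residual)) residual <- matrix(0, nrow(dab), ncol(dab))
  conc <- cbind(as.vector(hematoxylin), as.vector(dab), as.vector(residual))
  if (any(conc < 0) || any(conc > 1)) {
    stop("stain channels must lie in [0, 1]", call. = FALSE)
  }
  od <- (conc * saturation_od) %*% stains # pixels x RGB
  px <- white_point * 10^(-od)
  if (quantize) px <- round(px)
  px[px < 0] <- 0
  px[px > white_point] <- white_point
  array(px, dim = c(nrow(dab), ncol(dab), 3L))
}
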