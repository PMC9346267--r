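#' Otsu threshold of a sample of intensities
#'
#' Between-class-variance-maximizing threshold computed from a vector of
#' values, used so the nuclei threshold can be computed from ROI pixels only
#' rather than the full rectangular frame.
#'
#' @param values Numeric vector in `[0, 1]`.
#' @param levels Number of histogram bins (default 256).
#' @return Threshold on the `[0, 1]` scale; pixels `>=` the threshold are
#'   foreground.
#' @keywords internal
otsu_threshold <- function(values, levels = 256L) {
  values <- values[is.finite(values)]
  if (length(values) == 0L) stop("no finite values for thresholding", call. = FALSE)
  breaks <- seq(0, 1, length.out = levels + 1L)
  h <- tabulate(findInterval(values, breaks, rightmost.closed = TRUE),
    nbins = levels
  )
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[levels]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  # threshold above the optimal bin so that bin's pixels stay background
  breaks[which.max(between) + 1L]
}

check_roi <- function(roi, ref = NULL, require_nonempty = TRUE) {
  if (!is.matrix(roi) || !is.logical(roi)) {
    storage.mode(roi) <- "logical"
    roi <- as.matrix(roi)
  }
  if (!is.null(ref) && !all(dim(roi) == dim(ref)[1:2])) {
    stop("ROI mask shape does not match the image", call. = FALSE)
  }
  if (require_nonempty && !any(roi)) {
    stop("ROI mask is empty (no TRUE pixel)", call. = FALSE)
  }
  roi
}

label_centroids <- function(labels) {
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids) == 0L) {
    return(tibble(label = integer(), row = numeric(), col = numeric()))
  }
  idx <- which(labels > 0)
  lab <- labels[idx]
  rr <- ((idx - 1L) %% nrow(labels)) + 1L
  cc <- ((idx - 1L) %/% nrow(labels)) + 1L
  tibble(
    label = as.integer(ids),
    row = as.numeric(tapply(rr, lab, mean)[as.character(ids)]),
    col = as.numeric(tapply(cc, lab, mean)[as.character(ids)])
  )
}

#' Detect nuclei in the hematoxylin channel
#'
#' Gaussian smoothing, Otsu thresholding restricted to ROI pixels, area
#' filtering, and splitting of touching nuclei by a distance-transform
#' watershed — the standard declumping route for brightfield nuclei.
#' Only objects whose centroid lies inside the ROI are kept, and the
#' thresholded mask itself is confined to the ROI, so no nucleus pixel lies
#' outside the analyst's outline. Labels are consecutive positive integers
#' ordered by centroid position (row, then column), which makes the labeling
#' deterministic.
#'
#' @param hematoxylin Matrix in `[0, 1]`, higher = stronger nuclear stain.
#' @param roi Logical matrix, same shape; `TRUE` inside the region of
#'   interest.
#' @param sigma Gaussian smoothing sigma in pixels (default 2).
#' @param min_area,max_area Object area bounds in pixels (defaults 40 and
#'   `Inf`); objects outside the bounds are removed before declumping.
#' @param watershed_h Height tolerance of the watershed declumping, in
#'   pixels of distance-map depth (default 2): shallower splits are merged.
#' @return Integer label matrix (0 = background). A field with no detected
#'   nuclei returns an all-zero map with a warning.
#' @export
detect_nuclei <- function(hematoxylin, roi, sigma = 2, min_area = 40,
                          max_area = Inf, watershed_h = 2) {
  stopifnot(is.matrix(hematoxylin))
  if (min(hematoxylin) < 0 || max(hematoxylin) > 1) {
    stop("`hematoxylin` must lie in [0, 1]", call. = FALSE)
  }
  roi <- check_roi(roi, hematoxylin)
  sm <- as.matrix(EBImage::gblur(EBImage::Image(hematoxylin), sigma = sigma))
  thr <- otsu_threshold(sm[roi])
  mask <- (sm >= thr) & roi
  if (!any(mask)) {
    warning("no nuclei detected in the ROI")
    return(matrix(0L, nrow(hematoxylin), ncol(hematoxylin)))
  }
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  areas <- tabulate(lab[lab > 0])
  bad <- which(areas < min_area | areas > max_area)
  if (length(bad)) mask[lab %in% bad] <- FALSE
  if (!any(mask)) {
    warning("no nuclei detected in the ROI")
    return(matrix(0L, nrow(hematoxylin), ncol(hematoxylin)))
  }
  dm <- EBImage::distmap(EBImage::Image(mask * 1))
  ws <- EBImage::watershed(dm, tolerance = watershed_h, ext = 1)
  labels <- matrix(as.integer(ws), nrow(hematoxylin), ncol(hematoxylin))
  # keep objects whose centroid falls inside the ROI, relabel deterministically
  cent <- label_centroids(labels)
  if (nrow(cent) == 0L) {
    warning("no nuclei detected in the ROI")
    return(matrix(0L, nrow(hematoxylin), ncol(hematoxylin)))
  }
  ri <- pmin(pmax(round(cent$row), 1L), nrow(roi))
  ci <- pmin(pmax(round(cent$col), 1L), ncol(roi))
  keep <- cent$label[roi[cbind(ri, ci)]]
  if (length(keep) == 0L) {
    warning("no nuclei detected in the ROI")
    return(matrix(0L, nrow(hematoxylin), ncol(hematoxylin)))
  }
  ord <- order(cent$row[match(keep, cent$label)], cent$col[match(keep, cent$label)])
  keep <- keep[ord]
  out <- matrix(0L, nrow(labels), ncol(labels))
  for (i in seq_along(keep)) out[labels == keep[i]] <- i
  out
}

#' Delimit whole cells around nuclei by distance-limited expansion
#'
#' Each nucleus is expanded outward by at most `expansion_px` pixels
#' (Euclidean distance to the nearest pixel of the nucleus); contested pixels
#' go to the nearest nucleus, with exact ties resolved to the lower label id.
#' Cells are clipped to the ROI. This emulates the "secondary object by
#' distance" delimitation familiar from CellProfiler-style pipelines and
#' guarantees cell count equals nucleus count.
#'
#' @param nuclei Integer nucleus label matrix from [detect_nuclei()].
#' @param roi Logical ROI mask, same shape.
#' @param expansion_px Maximum outward expansion in pixels (default 10);
#'   0 returns the nucleus map unchanged (clipped to ROI).
#' @return Integer cell label matrix with the same label set as `nuclei`.
#' @export
delimit_cells <- function(nuclei, roi, expansion_px = 10) {
  stopifnot(is.matrix(nuclei), expansion_px >= 0)
  roi <- check_roi(roi, nuclei)
  ids <- sort(unique(nuclei[nuclei > 0]))
  cells <- nuclei
  if (length(ids) && expansion_px > 0) {
    nr <- nrow(nuclei)
    nc <- ncol(nuclei)
    best <- matrix(Inf, nr, nc)
    best[nuclei > 0] <- 0
    pad <- as.integer(ceiling(expansion_px)) + 1L
    idx_all <- which(nuclei > 0)
    rr_all <- ((idx_all - 1L) %% nr) + 1L
    cc_all <- ((idx_all - 1L) %/% nr) + 1L
    for (l in ids) {
      sel <- nuclei[idx_all] == l
      r0 <- max(1L, min(rr_all[sel]) - pad)
      r1 <- min(nr, max(rr_all[sel]) + pad)
      c0 <- max(1L, min(cc_all[sel]) - pad)
      c1 <- min(nc, max(cc_all[sel]) + pad)
      sub <- nuclei[r0:r1, c0:c1, drop = FALSE]
      d <- as.matrix(EBImage::distmap(EBImage::Image((sub != l) * 1)))
      win <- which(d <= expansion_px & d < best[r0:r1, c0:c1, drop = FALSE])
      if (length(win)) {
        sr <- ((win - 1L) %% nrow(d)) + r0
        sc <- ((win - 1L) %/% nrow(d)) + c0
        gi <- cbind(sr, sc)
        best[gi] <- d[win]
        cells[gi] <- l
      }
    }
  }
  cells[!roi] <- 0L
  cells
}

#' Classify cells as DAB-positive
#'
#' A cell is positive when at least `min_frac` of its pixels have a DAB
#' channel value at or above `threshold`. Both parameters are on the
#' normalized `[0, 1]` stain scale; the defaults (0.15 and 0.10) are a fixed
#' global criterion, so a truly unstained field yields zero positive cells.
#'
#' @param cells Integer cell label matrix.
#' @param dab DAB channel matrix in `[0, 1]`, same shape.
#' @param threshold Pixel-level DAB positivity threshold (default 0.15).
#' @param min_frac Minimum fraction of positive pixels per cell
#'   (default 0.10).
#' @return Named logical vector, one element per cell id (names are the cell
#'   ids in increasing order); empty if there are no cells.
#' @export
classify_positive <- function(cells, dab, threshold = 0.15, min_frac = 0.10) {
  stopifnot(is.matrix(cells), is.matrix(dab), all(dim(cells) == dim(dab)))
  if (min(dab) < 0 || max(dab) > 1) {
    stop("`dab` must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(threshold >= 0, threshold <= 1, min_frac >= 0, min_frac <= 1)
  inside <- cells > 0
  if (!any(inside)) {
    return(setNames(logical(0), character(0)))
  }
  frac <- tapply(dab[inside] >= threshold, cells[inside], mean)
  ids <- sort(as.integer(names(frac)))
  setNames(as.vector(frac[as.character(ids)] >= min_frac), ids)
}

#' Segment one field end to end
#'
#' Convenience wrapper running [detect_nuclei()], [delimit_cells()] and
#' [classify_positive()] with one parameter list.
#'
#' @param channels List with `hematoxylin` and `dab` matrices (output of
#'   [separate_stains()]).
#' @param roi Logical ROI mask.
#' @param params List of segmentation parameters; see
#'   [default_config()]. Missing entries take the defaults.
#' @return List with `nucleus_labels`, `cell_labels`, `cell_ids` and
#'   `positive` (named logical vector).
#' @export
segment_field <- function(channels, roi, params = list()) {
  p <- utils::modifyList(default_config()$segmentation, params)
  nuc <- detect_nuclei(channels$hematoxylin, roi,
    sigma = p$sigma, min_area = p$min_area, max_area = p$max_area,
    watershed_h = p$watershed_h
  )
  cells <- delimit_cells(nuc, roi, expansion_px = p$expansion_px)
  pos <- classify_positive(cells, channels$dab,
    threshold = p$positivity_threshold, min_frac = p$positivity_min_frac
  )
  list(
    nucleus_labels = nuc, cell_labels = cells,
    cell_ids = as.integer(names(pos)), positive = pos
  )
}
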