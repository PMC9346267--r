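# Independent brute-force oracles used across the suite. These are written
# from the textbook definitions and deliberately share no code with the
# package implementations they check.

# Lin's concordance: direct moment sums (1/n convention)
oracle_ccc <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sx2 <- sum((x - mx)^2) / n
  sy2 <- sum((y - my)^2) / n
  sxy <- sum((x - mx) * (y - my)) / n
  2 * sxy / (sx2 + sy2 + (mx - my)^2)
}

# AUC as the probability a random positive outscores a random negative
# (ties count half)
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# exhaustive Youden scan over midpoint thresholds (higher score = positive);
# ties go to the lower threshold
oracle_youden <- function(scores, labels) {
  s <- sort(unique(scores))
  thr <- c(-Inf, (head(s, -1) + tail(s, -1)) / 2, Inf)
  best <- NULL
  for (t in thr) {
    sens <- mean(scores[labels == 1] >= t)
    spec <- mean(scores[labels == 0] < t)
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-12) {
      best <- list(threshold = t, j = j, sens = sens, spec = spec)
    }
  }
  best
}

# Spearman rho via explicit mid-rank computation
oracle_spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  mx <- mean(rx)
  my <- mean(ry)
  sum((rx - mx) * (ry - my)) / sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# per-pixel nearest-nucleus assignment limited to `expansion` (Euclidean
# distance to the nearest pixel of each nucleus; ties to the lower label)
oracle_expand_labels <- function(nuclei, expansion) {
  nr <- nrow(nuclei)
  nc <- ncol(nuclei)
  ids <- sort(unique(nuclei[nuclei > 0]))
  coords <- lapply(ids, function(l) which(nuclei == l, arr.ind = TRUE))
  out <- matrix(0L, nr, nc)
  for (r in seq_len(nr)) {
    for (cc in seq_len(nc)) {
      bestd <- Inf
      bestl <- 0L
      for (k in seq_along(ids)) {
        d <- sqrt(min((coords[[k]][, 1] - r)^2 + (coords[[k]][, 2] - cc)^2))
        if (d < bestd - 1e-9) {
          bestd <- d
          bestl <- ids[k]
        }
      }
      if (bestd <= expansion) out[r, cc] <- bestl
    }
  }
  out
}

# small noiseless field spec used by several tests
quick_field <- function(n_cells = 60, frac_positive = 0.5, seed = 11,
                        noise_sd = 0, size = 256, ...) {
  field_spec(
    n_cells = n_cells, frac_positive = frac_positive,
    image_size = c(size, size), noise_sd = noise_sd, seed = seed, ...
  )
}
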