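test_that("nuclei are counted exactly on clean synthetic fields", {
  f <- generate_field(quick_field(n_cells = 100, seed = 3, size = 512))
  ch <- separate_stains(f$image)
  nuc <- detect_nuclei(ch$hematoxylin, f$roi)
  expect_equal(max(nuc), 100)
  # labels are consecutive 1..n
  expect_equal(sort(unique(nuc[nuc > 0])), 1:100)
})

test_that("a blank field yields zero nuclei with a warning", {
  blank <- matrix(0, 64, 64)
  roi <- matrix(TRUE, 64, 64)
  expect_warning(nuc <- detect_nuclei(blank, roi), "no nuclei")
  expect_equal(max(nuc), 0)
  expect_error(detect_nuclei(blank, matrix(FALSE, 64, 64)), "empty")
  expect_error(detect_nuclei(blank + 2, roi), "\\[0, 1\\]")
})

test_that("nuclei counts survive moderate noise within 5%", {
  f <- generate_field(field_spec(
    n_cells = 100, image_size = c(512, 512),
    seed = 5
  )) # generator default noise
  ch <- separate_stains(f$image)
  nuc <- detect_nuclei(ch$hematoxylin, f$roi)
  expect_gte(max(nuc), 95)
  expect_lte(max(nuc), 105)
})

test_that("segmentation is deterministic and confined to the ROI", {
  f <- generate_field(quick_field(n_cells = 40, seed = 9))
  ch <- separate_stains(f$image)
  a <- detect_nuclei(ch$hematoxylin, f$roi)
  b <- detect_nuclei(ch$hematoxylin, f$roi)
  expect_identical(a, b)
  expect_true(all(a[!f$roi] == 0))
  cells <- delimit_cells(a, f$roi, expansion_px = 8)
  expect_true(all(cells[!f$roi] == 0))
})

test_that("cell delimitation preserves counts and contains nuclei", {
  f <- generate_field(quick_field(n_cells = 50, seed = 21))
  ch <- separate_stains(f$image)
  nuc <- detect_nuclei(ch$hematoxylin, f$roi)
  cells <- delimit_cells(nuc, f$roi, expansion_px = 10)
  expect_setequal(unique(cells[cells > 0]), unique(nuc[nuc > 0]))
  # every nucleus pixel keeps its own label in the cell map
  idx <- which(nuc > 0)
  expect_identical(cells[idx], nuc[idx])
  # zero expansion is the identity
  expect_identical(delimit_cells(nuc, f$roi, expansion_px = 0), nuc)
})

test_that("expansion matches the brute-force nearest-nucleus oracle", {
  nuclei <- matrix(0L, 40, 40)
  nuclei[8:11, 8:11] <- 1L
  nuclei[8:11, 21:24] <- 2L # 10 px gap to nucleus 1
  nuclei[28:30, 14:16] <- 3L
  roi <- matrix(TRUE, 40, 40)
  for (expansion in c(3, 7, 10)) {
    got <- delimit_cells(nuclei, roi, expansion_px = expansion)
    expect_identical(got, oracle_expand_labels(nuclei, expansion),
      label = paste("expansion", expansion)
    )
  }
  # contested midline: assigned, disjoint, and to the nearer nucleus
  got <- delimit_cells(nuclei, roi, expansion_px = 10)
  expect_true(all(got[, 1:14][got[, 1:14] > 0 & row(got[, 1:14]) < 20] != 2L))
})

test_that("isolated nucleus expands by a morphological disc ring", {
  nuclei <- matrix(0L, 51, 51)
  nuclei[24:28, 24:28] <- 1L # 5x5 square nucleus
  roi <- matrix(TRUE, 51, 51)
  cells <- delimit_cells(nuclei, roi, expansion_px = 5)
  # oracle: pixels within Euclidean distance 5 of the square
  d <- as.matrix(EBImage::distmap(EBImage::Image((nuclei == 0) * 1)))
  expect_equal(sum(cells > 0), sum(d <= 5))
})

test_that("positivity classification follows threshold and fraction rules", {
  cells <- matrix(rep(1:2, each = 32), 8, 8)
  expect_equal(
    unname(classify_positive(cells, matrix(0, 8, 8))),
    c(FALSE, FALSE)
  )
  expect_equal(
    unname(classify_positive(cells, matrix(1, 8, 8))),
    c(TRUE, TRUE)
  )
  # cell 1: 20% of pixels at 0.5; cell 2: 5% -> below min_frac
  dab <- matrix(0, 8, 8)
  dab[1:7, 1] <- 0.5
  dab[1:2, 5] <- 0.5
  flags <- classify_positive(cells, dab, threshold = 0.15, min_frac = 0.10)
  expect_equal(unname(flags), c(TRUE, FALSE))
  # raising the threshold never increases positives
  thresholds <- seq(0, 1, by = 0.1)
  n_pos <- vapply(
    thresholds,
    function(t) sum(classify_positive(cells, dab, threshold = t)), 1
  )
  expect_true(all(diff(n_pos) <= 0))
  # no cells -> empty flags
  expect_length(classify_positive(matrix(0L, 4, 4), matrix(0, 4, 4)), 0)
})

test_that("positive fraction is recovered within 5 points at strong DAB", {
  f <- generate_field(field_spec(
    n_cells = 200, frac_positive = 0.6,
    image_size = c(512, 512), seed = 13
  ))
  q <- quantify_field(f$image, f$roi)
  expect_lt(abs(q$metrics$pct_positive - 60), 5)
})
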