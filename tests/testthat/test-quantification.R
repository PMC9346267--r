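test_that("field measures follow their printed formulas", {
  # ROI of 1000 px, dab 0.25 on 400 px, 10 cells of which 4 positive
  dab <- matrix(0, 25, 40)
  dab[1:10, 1:40] <- 0.25
  roi <- matrix(TRUE, 25, 40)
  flags <- setNames(rep(c(TRUE, FALSE), c(4, 6)), 1:10)
  m <- compute_image_metrics(dab, roi, flags)
  expect_equal(m$intensity_per_area, 0.1)
  expect_equal(m$pct_positive, 40.0)
  expect_equal(m$roi_area, 1000L)
  expect_equal(m$total_intensity, 100)

  # saturated DAB everywhere -> the intensity/area ceiling of 1
  sat <- compute_image_metrics(matrix(1, 10, 10), roi = matrix(TRUE, 10, 10), flags)
  expect_equal(sat$intensity_per_area, 1.0)

  # no staining -> both measures zero
  z <- compute_image_metrics(matrix(0, 10, 10), matrix(TRUE, 10, 10),
    setNames(rep(FALSE, 5), 1:5)
  )
  expect_equal(z$intensity_per_area, 0)
  expect_equal(z$pct_positive, 0)

  # no cells -> %PC missing, not zero
  none <- compute_image_metrics(matrix(0.2, 10, 10), matrix(TRUE, 10, 10),
    logical(0)
  )
  expect_true(is.na(none$pct_positive))
  expect_equal(none$intensity_per_area, 0.2)

  expect_error(
    compute_image_metrics(matrix(0.2, 4, 4), matrix(FALSE, 4, 4), logical(0)),
    "empty"
  )
})

test_that("sample aggregation is the unweighted mean of up to four fields", {
  per_image <- tibble::tibble(
    sample_id = "s1", selector = "S1", analyzer = "A1",
    pct_positive = c(20, 40, 60, 80),
    intensity_per_area = c(0.1, 0.2, 0.3, 0.4)
  )
  s <- aggregate_sample(per_image)
  expect_equal(s$pct_positive, 50)
  expect_equal(s$intensity_per_area, 0.25)
  expect_equal(s$n_images, 4L)

  # idempotent on identical fields
  same <- aggregate_sample(per_image[rep(1, 4), ])
  expect_equal(same$pct_positive, 20)

  # three fields (small tissue) is allowed
  three <- aggregate_sample(per_image[1:3, ])
  expect_equal(three$n_images, 3L)
  expect_equal(three$pct_positive, 40)

  # undefined %PC fields excluded from that mean only
  withna <- per_image
  withna$pct_positive[2] <- NA
  s2 <- aggregate_sample(withna)
  expect_equal(s2$pct_positive, mean(c(20, 60, 80)))
  expect_equal(s2$intensity_per_area, 0.25)

  expect_error(aggregate_sample(per_image[rep(1, 5), ]), "more than 4")
  expect_error(aggregate_sample(per_image[0, ]))
})

test_that("combination means average the available observer pairs", {
  samples <- tibble::tibble(
    sample_id = "s1",
    selector = c("S1", "S1", "S2", "S2"),
    analyzer = c("A1", "A2", "A1", "A2"),
    n_images = 4L,
    pct_positive = c(40, 42, 44, 46),
    intensity_per_area = c(0.1, 0.2, 0.3, 0.4)
  )
  cm <- aggregate_combinations(samples)
  expect_equal(cm$intensity_per_area, 0.25)
  expect_equal(cm$pct_positive, 43)
  expect_equal(cm$n_combinations, 4L)

  # single combination is the identity
  one <- aggregate_combinations(samples[1, ])
  expect_equal(one$pct_positive, 40)

  expect_error(aggregate_combinations(samples[c(1, 1), ]), "duplicated")
})

test_that("%PC is recovered across positive fractions and is expansion-stable", {
  for (p in c(0.2, 0.8)) {
    f <- generate_field(field_spec(
      n_cells = 200, frac_positive = p,
      image_size = c(512, 512), seed = 31 + round(100 * p)
    ))
    q <- quantify_field(f$image, f$roi)
    expect_lt(abs(q$metrics$pct_positive - 100 * p), 5)

    cfg <- default_config()
    cfg$segmentation$expansion_px <- 20
    q2 <- quantify_field(f$image, f$roi, cfg)
    expect_lt(abs(q2$metrics$pct_positive - q$metrics$pct_positive), 2)
  }
})

test_that("intensity/area is linear in DAB concentration below saturation", {
  levels <- seq(0.1, 0.8, by = 0.1)
  ipa <- vapply(levels, function(dl) {
    f <- generate_field(field_spec(
      n_cells = 60, frac_positive = 1, dab_level = dl,
      image_size = c(256, 256), noise_sd = 0, seed = 99
    ))
    quantify_field(f$image, f$roi)$metrics$intensity_per_area
  }, 1)
  fit <- summary(stats::lm(ipa ~ levels))
  expect_gt(fit$r.squared, 0.99)
})
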