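test_that("stigma area is the scaled pixel count, with degenerate handling", {
  m <- matrix(1, 200, 200)                     # 40,000 px
  a <- stigma_area(m, 0.005)
  expect_equal(as.numeric(a), 1.0)
  expect_equal(attr(a, "px"), 40000)

  e <- stigma_area(matrix(0, 10, 10), 0.01)
  expect_equal(as.numeric(e), 0)
  expect_equal(attr(e, "flags"), "empty_stigma")

  m2 <- disc_mask(64, 64, 32, 32, 20)
  expect_equal(as.numeric(stigma_area(m2, 0.02)),
               4 * as.numeric(stigma_area(m2, 0.01)))
  expect_error(stigma_area(m2, 0), "positive")
})

test_that("a circle's centroid-perpendicular chord is its diameter", {
  H <- 256
  ov <- disc_mask(H, H, 150, 128, 100)
  st <- blob_mask(H, H, 30, 128)
  d <- ovary_diameter(ov, st, 0.01)
  expect_equal(d$diameter_mm, 2.00, tolerance = 0.01)
  expect_length(d$flags, 0)
})

test_that("axis-aligned ellipse with stigma above yields the horizontal diameter", {
  # semi-axes: 80 along rows, 120 along cols; the centroid axis is vertical,
  # so the measured chord is the full horizontal axis
  ov <- ellipse_mask(300, 300, 160, 150, 80, 120)
  st <- blob_mask(300, 300, 40, 150)
  d <- ovary_diameter(ov, st, 0.01)
  expect_equal(d$diameter_mm, 2.40, tolerance = 0.024)
})

test_that("rotated ellipses match the closed-form central chord", {
  theta <- 30 * pi / 180
  ov <- ellipse_mask(300, 300, 150, 150, 70, 110, theta)
  # stigma centroid along the rotated minor-axis direction (the carpel axis)
  u <- c(cos(theta), sin(theta))               # minor axis direction
  st <- blob_mask(300, 300, round(150 - 130 * u[1]), round(150 - 130 * u[2]))
  d <- ovary_diameter(ov, st, 0.01)
  chord <- ellipse_chord(70, 110, theta, c(-u[2], u[1])) * 0.01
  expect_equal(d$diameter_mm, chord, tolerance = chord * 0.02)
})

test_that("50 random ellipses stay within 2% of the analytic chord", {
  set.seed(99)
  worst <- 0
  for (i in 1:50) {
    a <- runif(1, 40, 90); b <- runif(1, 40, 120)
    th <- runif(1, 0, pi)
    phi <- runif(1, 0, 2 * pi)                 # stigma direction, arbitrary
    u <- c(cos(phi), sin(phi))
    ov <- ellipse_mask(300, 300, 150, 150, a, b, th)
    st <- blob_mask(300, 300, round(150 - 135 * u[1]), round(150 - 135 * u[2]))
    sc <- asNamespace("carpelseg")$mask_centroid(st)
    dir <- (sc - c(150, 150)) / sqrt(sum((sc - c(150, 150))^2))
    d <- ovary_diameter(ov, st, 0.01)
    ref <- ellipse_chord(a, b, th, c(-dir[2], dir[1])) * 0.01
    rel <- abs(d$diameter_mm - ref) / ref
    worst <- max(worst, rel)
    # diameter can never exceed the major axis (plus rasterisation slack)
    expect_lte(d$diameter_mm, (2 * max(a, b) + 2) * 0.01)
  }
  expect_lt(worst, 0.02)
})

test_that("measurements are translation invariant and 90-degree rotation stable", {
  ov <- ellipse_mask(200, 200, 90, 100, 50, 70)
  st <- blob_mask(200, 200, 20, 100)
  base_a <- as.numeric(stigma_area(st, 0.01))
  base_d <- ovary_diameter(ov, st, 0.01)$diameter_mm

  shift <- function(m, dr, dc) {
    out <- matrix(0, nrow(m), ncol(m))
    out[(1 + dr):nrow(m), (1 + dc):ncol(m)] <-
      m[1:(nrow(m) - dr), 1:(ncol(m) - dc)]
    out
  }
  expect_identical(as.numeric(stigma_area(shift(st, 7, 5), 0.01)), base_a)
  expect_equal(ovary_diameter(shift(ov, 7, 5), shift(st, 7, 5),
                              0.01)$diameter_mm, base_d, tolerance = 1e-12)

  rot <- function(m) t(m[nrow(m):1, ])
  expect_equal(as.numeric(stigma_area(rot(st), 0.01)), base_a,
               tolerance = base_a * 0.005)
  expect_equal(ovary_diameter(rot(ov), rot(st), 0.01)$diameter_mm, base_d,
               tolerance = base_d * 0.01)
})

test_that("degenerate stigma triggers the principal-axis fallback", {
  ov <- ellipse_mask(200, 200, 100, 100, 40, 80)   # long axis horizontal
  empty <- matrix(0, 200, 200)
  d <- ovary_diameter(ov, empty, 0.01)
  expect_true(all(c("empty_stigma", "fallback_axis") %in% d$flags))
  # fallback axis = major axis (horizontal), so the chord is the minor axis
  expect_equal(d$diameter_mm, 0.80, tolerance = 0.02)

  # coincident centroids fall back the same way
  st_on_top <- blob_mask(200, 200, 100, 100, 3)
  d2 <- ovary_diameter(ov, st_on_top, 0.01)
  expect_true("fallback_axis" %in% d2$flags)
  expect_error(ovary_diameter(empty, empty, 0.01), "empty")
})

test_that("a mask truncated by the frame is flagged off_edge", {
  # ovary spills past the right border; the stigma sits above it, so the
  # measurement line runs horizontally into the frame edge
  ov <- disc_mask(100, 100, 50, 95, 30)
  st <- blob_mask(100, 100, 12, 95)
  d <- ovary_diameter(ov, st, 0.01)
  expect_true("off_edge" %in% d$flags)
})

test_that("measure_batch keeps manifest order, records errors, and reproduces", {
  ov <- disc_mask(80, 80, 45, 40, 20)
  st <- blob_mask(80, 80, 12, 40)
  masks <- list(
    list(stigma = st, ovary = ov),
    list(stigma = st, ovary = ov),
    list(stigma = matrix(0, 80, 80), ovary = ov),   # empty stigma
    list(stigma = st, ovary = ov)
  )
  manifest <- data.frame(
    image_id = c("a", "b", "c", "d"),
    cultivar = "CV1", timepoint_days = c(0, 3, 7, 13),
    fixation = "non_fixed",
    mm_per_px = c(0.01, 0.01, 0.01, NA),
    stringsAsFactors = FALSE
  )
  res <- measure_batch(masks, manifest)
  expect_equal(nrow(res$measurements), 3)
  expect_equal(res$measurements$image_id, c("a", "b", "c"))
  expect_equal(res$errors$image_id, "d")
  expect_match(res$errors$message, "mm_per_px")
  crow <- res$measurements[res$measurements$image_id == "c", ]
  expect_match(crow$flags, "empty_stigma")
  expect_match(crow$flags, "fallback_axis")
  expect_false(is.na(crow$ovary_diameter_mm))
  expect_equal(crow$stigma_area_mm2, crow$stigma_px * 0.01^2)

  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_measurements(res$measurements, f1)
  write_measurements(measure_batch(masks, manifest)$measurements, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})
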