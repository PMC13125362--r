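test_that("denoise removes speckles but leaves clean drawings unchanged", {
  clean <- matrix(0, 32, 32)
  clean[10:20, 14:16] <- 1            # 3-px-wide stroke
  expect_identical(denoise(clean), clean)
  speck <- clean
  speck[3, 3] <- 1                    # isolated impulse pixel
  out <- denoise(speck)
  expect_equal(out, clean, ignore_attr = TRUE)
  # the 3x3 median-filter oracle removes the same isolated pixel
  med <- EBImage::medianFilter(speck, 1L)
  expect_equal(med[3, 3], 0)
  expect_true(all(out >= 0 & out <= 1))
  noisy <- matrix(runif(64), 8, 8)
  expect_true(all(denoise(noisy) >= 0 & denoise(noisy) <= 1))
})

test_that("Otsu segmentation matches the brute-force variance scan", {
  set.seed(4)
  img <- matrix(sample(c(0.1, 0.9), 400, replace = TRUE), 20, 20)
  mask <- segment_ink(img)
  expect_true(all(mask %in% c(0, 1)))
  expect_equal(dim(mask), dim(img))
  expect_identical(mask == 1, img == 0.9)     # exact two-level separation
  th <- attr(mask, "threshold")
  expect_equal((img > otsu_oracle(img)) * 1, unclass(mask)[, ],
               ignore_attr = TRUE)
  # graded bimodal image: the induced mask matches the brute-force scan
  # (the variance is flat between the modes, so thresholds may differ
  # within the plateau while separating identically)
  img2 <- matrix(c(rnorm(200, 0.2, 0.05), rnorm(200, 0.8, 0.05)), 20, 20)
  img2 <- pmin(pmax(img2, 0), 1)
  expect_equal(unclass(segment_ink(img2))[, ] * 1,
               (img2 > otsu_oracle(img2)) * 1, ignore_attr = TRUE)
  expect_error(segment_ink(matrix(0.5, 4, 4)), "no ink")
})

test_that("crop_to_content agrees with an exhaustive min/max scan", {
  m <- matrix(0, 16, 16); m[5, 7] <- 1
  bb <- crop_to_content(m, 0)
  expect_equal(bb, list(row_start = 4, row_end = 5, col_start = 6,
                        col_end = 7))
  # margin clipped at the borders
  bb2 <- crop_to_content(m, 100)
  expect_equal(bb2, list(row_start = 0, row_end = 16, col_start = 0,
                         col_end = 16))
  set.seed(8)
  for (rep in 1:10) {
    m <- matrix(rbinom(15 * 12, 1, 0.05), 15, 12)
    if (!any(m == 1)) m[4, 4] <- 1
    bb <- crop_to_content(m, 1)
    w <- which(m == 1, arr.ind = TRUE)
    expect_equal(bb$row_start, max(min(w[, 1]) - 2, 0))
    expect_equal(bb$row_end, min(max(w[, 1]) + 1, 15))
    expect_equal(bb$col_start, max(min(w[, 2]) - 2, 0))
    expect_equal(bb$col_end, min(max(w[, 2]) + 1, 12))
  }
  expect_error(crop_to_content(matrix(0, 4, 4)), "empty mask")
})

rotate_about_center <- function(img, angle) {
  cs <- cos(angle); sn <- sin(angle)
  M <- matrix(c(cs, sn, -sn, cs), 2, 2, byrow = TRUE)
  ctr <- (dim(img) + 1) / 2
  spiralnet:::warp_affine(img, M, ctr, dim(img))
}

test_that("normalize_geometry aligns, scales and centres content", {
  # elongated bar rotated by 10 degrees comes back within 1 degree
  bar <- matrix(0, 64, 64); bar[30:34, 10:54] <- 1
  tilted <- rotate_about_center(bar, 10 * pi / 180)
  out <- normalize_geometry(tilted)
  expect_equal(dim(out), c(64, 64))
  ax <- spiralnet:::ink_axis(out > 0.5)
  expect_lt(abs(ax$angle) * 180 / pi, 1)
  # longer side fills ~90% of the canvas
  w <- which(out > 0.5, arr.ind = TRUE)
  expect_gt((diff(range(w[, 2])) + 1) / 64, 0.85)
  # idempotence within interpolation tolerance
  again <- normalize_geometry(out)
  expect_lt(mean(abs(again - out)), 0.02)
})

test_that("normalization is stable under a 15-degree input rotation", {
  disk <- matrix(0, 96, 96)
  for (r in 1:96) for (c in 1:96)
    if ((r - 48)^2 / 900 + (c - 48)^2 / 100 < 1) disk[r, c] <- 1
  a <- normalize_geometry(disk)
  b <- normalize_geometry(rotate_about_center(disk, 15 * pi / 180))
  expect_lt(mean(abs(a - b)), 0.05)
})

test_that("fuse_to_rgb obeys the channel contract", {
  set.seed(2)
  ims <- list(spiral = matrix(runif(64^2), 64),
              meander = matrix(runif(64^2), 64),
              wave = matrix(runif(64^2), 64))
  f <- fuse_to_rgb(ims, "multitask", size = 256)
  expect_equal(dim(f), c(256, 256, 3))
  expect_true(all(f >= 0 & f <= 1))
  expect_equal(attr(f, "channels"), c("spiral", "meander", "wave"))
  g <- fuse_to_rgb(ims["spiral"], "single_filtered", size = 32)
  expect_equal(dim(g), c(32, 32, 3))
  expect_equal(g[, , 1], spiralnet:::resize_bilinear(ims$spiral, 32, 32))
  expect_error(fuse_to_rgb(ims[c("spiral", "wave")], "multitask"),
               "missing task")
  expect_error(fuse_to_rgb(list(), "multitask"), "non-empty")
})

test_that("the full preprocessing pipeline is deterministic with valid shapes", {
  man <- synthesize_cohort(2, 2, seed = 9, canvas = 128, n_points = 400,
                           stroke_width = 2)
  d1 <- preprocess_cohort(man, size = 64)
  d2 <- preprocess_cohort(man, size = 64)
  expect_identical(d1, d2)
  expect_length(d1$inputs, 4)
  for (x in d1$inputs) {
    expect_equal(dim(x), c(64, 64, 3))
    expect_true(all(is.finite(x)) && all(x >= 0 & x <= 1))
  }
  expect_equal(sort(unique(d1$labels)), c(0, 1))
})
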