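test_that("count normalization maps extremes to 0/255 and inverts exactly", {
  m <- matrix(c(10, 20, 30, 25), 2)
  r <- normalize_counts(m)
  expect_equal(r$normalized[1:3], c(0, 127.5, 255))
  expect_equal(r$record$x_min, 10)
  expect_equal(r$record$x_max, 30)
  expect_equal(min(r$normalized), 0)
  expect_equal(max(r$normalized), 255)
  back <- denormalize(r$normalized, r$record)
  expect_lt(max(abs(back - m)) / max(abs(m)), 1e-10)
  # idempotence on an already-normalized image
  again <- normalize_counts(r$normalized)
  expect_lt(max(abs(again$normalized - r$normalized)), 1e-10)
  # identity record
  idr <- structure(list(x_min = 0, x_max = 255), class = "normalization_record")
  expect_equal(denormalize(r$normalized, idr), r$normalized)
  expect_error(normalize_counts(matrix(5, 3, 3)), "constant")
})

test_that("CT windowing uses WW 2500 / WL 250", {
  expect_equal(window_ct(matrix(-1000)), matrix(0))
  expect_equal(window_ct(matrix(1500)), matrix(255))
  expect_equal(window_ct(matrix(250)), matrix(127.5))
  expect_equal(window_ct(matrix(-2000)), matrix(0))   # clamped
  hu <- matrix(seq(-900, 1400, length.out = 16), 4)
  expect_lt(max(abs(window_ct_inverse(window_ct(hu)) - hu)), 1e-9)
})

test_that("resampling preserves extent, constants and smooth content", {
  m <- matrix(rnorm(64 * 64), 64)
  expect_lt(max(abs(resample_to_grid(m, 1, 64, 1) - m)), 1e-12)
  cst <- matrix(3.5, 32, 32)
  up <- resample_to_grid(cst, 2, 64, 1)
  expect_lt(max(abs(up - 3.5)), 1e-12)
  # smooth blob survives a down-then-up round trip
  coord <- seq(-1, 1, length.out = 64)
  blob <- exp(-(outer(coord^2, coord^2, `+`)) * 8)
  down <- resample_to_grid(blob, 1, 32, 2)
  back <- resample_to_grid(down, 2, 64, 1)
  expect_lt(nmse(blob, back, rescale_target = FALSE), 0.01)
  expect_error(resample_to_grid(m, -1, 64, 1), "positive")
})

test_that("augmentation transforms compose as a group", {
  set.seed(9)
  img <- matrix(runif(64 * 64), 64)
  r4 <- petac:::rot90_mat(petac:::rot90_mat(petac:::rot90_mat(
    petac:::rot90_mat(img, 1), 1), 1), 1)
  expect_identical(r4, img)
  expect_identical(img[, 64:1][, 64:1], img)
  tr <- petac:::translate_mat(img, 8, 8)
  expect_equal(tr[9:64, 9:64], img[1:56, 1:56])
  expect_true(all(tr[1:8, ] == 0))
  expect_error(augment32(matrix(0, 4, 6)), "square")
  expect_error(augmentation_spec(translations = list(c(1, 1), c(2, 2),
                                                     c(3, 3), c(4, 4))),
               "identity")
})

test_that("PNG round-trip restores native counts within quantization", {
  set.seed(11)
  native <- matrix(rexp(64 * 64, rate = 0.1), 64)
  nr <- normalize_counts(native)
  bytes <- to_png(nr$normalized)
  restored <- from_png(bytes, nr$record)
  bound <- (nr$record$x_max - nr$record$x_min) / 255 / 2 + 1e-9
  expect_lte(max(abs(restored - native)), bound)
  # all-zero image decodes to zeros
  expect_true(all(png::readPNG(to_png(matrix(0, 8, 8))) == 0))
  # missing sidecar: display units with a warning
  expect_warning(disp <- from_png(bytes), "record")
  expect_equal(disp, round(nr$normalized), tolerance = 1e-6)
  expect_error(to_png(matrix(-1, 2, 2)), "range")
})

test_that("PNG files round-trip through disk with their sidecar records", {
  dir <- withr::local_tempdir()
  native <- matrix(seq(2, 50, length.out = 256), 16)
  nr <- normalize_counts(native)
  p <- file.path(dir, "img.png")
  write_png_with_record(nr$normalized, p, nr$record)
  expect_true(file.exists(paste0(p, ".json")))
  back <- read_png_with_record(p)
  expect_lte(max(abs(back - native)), (nr$record$x_max - nr$record$x_min) / 510 + 1e-9)
})
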