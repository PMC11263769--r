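test_that("phantoms satisfy their anatomical invariants across seeds", {
  for (s in c(1, 7, 19)) {
    ph <- generate_head_phantom(shape = 64, seed = s)
    expect_true(validate_phantom(ph))
  }
  # larger grid once
  expect_true(validate_phantom(generate_head_phantom(shape = 128, seed = 2)))
})

test_that("phantom generation is deterministic and seed-sensitive", {
  a <- generate_head_phantom(shape = 64, seed = 5)
  b <- generate_head_phantom(shape = 64, seed = 5)
  c <- generate_head_phantom(shape = 64, seed = 6)
  expect_identical(a, b)
  expect_false(identical(a$ct_hu, c$ct_hu))
})

test_that("gray/white mean activity ratio stays near the configured 4:1", {
  ratios <- vapply(1:20, function(s) {
    ph <- generate_head_phantom(shape = 128, seed = s)
    mean(ph$activity[ph$labels == phantom_labels[["gray"]]]) /
      mean(ph$activity[ph$labels == phantom_labels[["white"]]])
  }, numeric(1))
  expect_true(all(ratios >= 3.5 & ratios <= 4.5))
})

test_that("MRI intensity is not a fixed function of HU across seeds", {
  cors <- vapply(1:12, function(s) {
    ph <- generate_head_phantom(shape = 64, seed = s)
    brain <- ph$labels %in% phantom_labels[c("gray", "white", "ventricle", "striatum")]
    cor(rank(ph$mri_t1[brain]), rank(ph$ct_hu[brain]))
  }, numeric(1))
  expect_gt(diff(range(cors)), 0.02)
})

test_that("undersized grids are rejected", {
  expect_error(generate_head_phantom(shape = 32, seed = 1), "at least 64")
  expect_error(generate_head_phantom(shape = 64, seed = 1, pixel_size_mm = 0.5),
               "too small")
})

test_that("cohorts are ordered, unique and prefix-stable", {
  co10 <- generate_cohort(10, seed = 7, shape = 64)
  co5 <- generate_cohort(5, seed = 7, shape = 64)
  ids <- vapply(co10, `[[`, character(1), "case_id")
  expect_length(unique(ids), 10)
  expect_identical(co5, co10[1:5])
  expect_error(generate_cohort(0), "count")
})
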