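test_that("Richardson-Lucy sharpens a blurred phantom monotonically", {
  ph <- small_case()
  px <- ph$pixel_size_mm
  psf <- psf_model(5)
  blurred <- apply_psf(ph$activity, psf, px)
  rmse <- vapply(1:10, function(k) {
    dec <- richardson_lucy(blurred, hrc_config(k, psf), px)
    expect_true(all(dec >= 0))
    sqrt(mean((dec - ph$activity)^2))
  }, numeric(1))
  expect_true(all(diff(rmse) < 0))
  expect_lt(rmse[10], sqrt(mean((blurred - ph$activity)^2)))
})

test_that("flux is conserved for an interior object", {
  ph <- small_case()
  px <- ph$pixel_size_mm
  blurred <- apply_psf(ph$activity, psf_model(5), px)
  dec <- richardson_lucy(blurred, hrc_config(10, psf_model(5)), px)
  expect_lt(abs(sum(dec) - sum(blurred)) / sum(blurred), 0.001)
})

test_that("degenerate and invalid configurations are handled", {
  expect_error(hrc_config(0), "iterations")
  expect_error(richardson_lucy(matrix(-1, 4, 4)), "nonnegative")
  # near-delta PSF leaves the image essentially unchanged
  img <- small_case()$activity
  out <- richardson_lucy(img, hrc_config(5, psf_model(1e-6)), 4)
  expect_lt(max(abs(out - img)), 1e-8)
})

test_that("the HRC reference is a deterministic, sharpened CTAC transform", {
  ph <- small_case()
  px <- ph$pixel_size_mm
  g <- default_geometry(64, px, 48)
  mm <- hu_to_mu(ph$ct_hu, pixel_size_mm = px)
  em <- simulate_emission(ph$activity, mm, psf_model(5), g, 0, pixel_size_mm = px)
  ctac <- ctac_correct(em, attenuation_factors(mm, g), g, 64, pixel_size_mm = px)
  cfg <- hrc_config(10, psf_model(5))
  h1 <- make_hrc_reference(ctac, cfg, px)
  h2 <- make_hrc_reference(ctac, cfg, px)
  expect_identical(h1, h2)
  grad_energy <- function(m) sum(diff(m)^2) + sum(t(diff(t(m)))^2)
  expect_gt(grad_energy(h1), grad_energy(ctac))
})

test_that("TV regularization damps the deconvolution", {
  ph <- small_case()
  px <- ph$pixel_size_mm
  blurred <- apply_psf(ph$activity, psf_model(5), px)
  plain <- richardson_lucy(blurred, hrc_config(10, psf_model(5)), px)
  tv <- richardson_lucy(blurred, hrc_config(10, psf_model(5),
                                            regularization = "tv",
                                            lambda = 0.02), px)
  grad_energy <- function(m) sum(diff(m)^2) + sum(t(diff(t(m)))^2)
  expect_lt(grad_energy(tv), grad_energy(plain))
  expect_true(all(tv >= 0))
})
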