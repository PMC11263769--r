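test_that("forward projection is linear and matches disk chord lengths", {
  d <- disk_fixture()
  g <- default_geometry(d$n, d$px, 24)
  ctr <- (g$n_bins + 1) / 2
  sg <- forward_project(d$img, g, d$px)
  # central-bin integral = 2 * r * v = 20 cm at every angle
  expect_true(all(abs(sg$data[, ctr] - 20) / 20 < 0.02))
  # exact linearity on random images
  set.seed(4)
  A <- matrix(rnorm(32 * 32), 32); B <- matrix(rnorm(32 * 32), 32)
  g2 <- default_geometry(32, 1, 16)
  lhs <- forward_project(2 * A + 3 * B, g2, 1)$data
  rhs <- 2 * forward_project(A, g2, 1)$data + 3 * forward_project(B, g2, 1)$data
  expect_lt(max(abs(lhs - rhs)), 1e-10)
  # zero image -> zero sinogram
  expect_true(all(forward_project(matrix(0, 32, 32), g2, 1)$data == 0))
  # too-few bins rejected
  expect_error(forward_project(d$img, scan_geometry(24, 32, d$px), d$px),
               "n_bins")
})

test_that("attenuation factors obey Beer-Lambert closed forms", {
  d <- disk_fixture()
  g <- default_geometry(d$n, d$px, 24)
  ctr <- (g$n_bins + 1) / 2
  mm <- mu_map(d$img * 0.096, d$px)
  af <- attenuation_factors(mm, g)
  expect_true(all(af$data > 0 & af$data <= 1))
  expect_true(all(abs(af$data[, ctr] - exp(-1.92)) / exp(-1.92) < 0.02))
  # zero mu-map -> all ones
  af0 <- attenuation_factors(mu_map(matrix(0, 32, 32), 1),
                             default_geometry(32, 1, 16))
  expect_true(all(af0$data == 1))
  # doubling mu squares the factors
  af2 <- attenuation_factors(mu_map(d$img * 0.192, d$px), g)
  expect_lt(max(abs(af2$data - af$data^2)), 1e-8)
  # negative mu rejected at construction
  expect_error(mu_map(matrix(-0.1, 4, 4), 1), "nonnegative")
})

test_that("hu_to_mu applies the three-class rule in both threshold modes", {
  thr <- mu_map_thresholds()
  lit <- mu_map_thresholds(printed_rule = TRUE)
  hu <- matrix(c(-500, 40, 1000, 249), 2)
  m <- hu_to_mu(hu, thr)$mu
  expect_equal(m[1, 1], 0)      # deep air
  expect_equal(m[2, 1], 0.096)  # brain tissue is soft in sign-corrected mode
  expect_equal(m[1, 2], 0.151)  # bone in both modes
  expect_equal(m[2, 2], 0.096)  # just under the bone threshold
  ml <- hu_to_mu(hu, lit)$mu
  expect_equal(ml[2, 1], 0)     # +200 HU boundary sends brain tissue to air
  expect_equal(ml[1, 2], 0.151)
  expect_error(mu_map_thresholds(air_upper_hu = 300, bone_lower_hu = 250))
})

test_that("emission simulation conserves counts and reproduces under seed", {
  ph <- small_case()
  px <- ph$pixel_size_mm
  g <- default_geometry(64, px, 24)
  mm <- hu_to_mu(ph$ct_hu, pixel_size_mm = px)
  em0 <- simulate_emission(ph$activity, mm, psf_model(5), g, 1e5,
                           pixel_size_mm = px, poisson = FALSE)
  expect_equal(sum(em0$data), 1e5, tolerance = 1e-6)
  e1 <- simulate_emission(ph$activity, mm, psf_model(5), g, 1e5, seed = 3,
                          pixel_size_mm = px)
  e2 <- simulate_emission(ph$activity, mm, psf_model(5), g, 1e5, seed = 3,
                          pixel_size_mm = px)
  e3 <- simulate_emission(ph$activity, mm, psf_model(5), g, 1e5, seed = 4,
                          pixel_size_mm = px)
  expect_identical(e1$data, e2$data)
  expect_false(identical(e1$data, e3$data))
  # zero activity -> zero sinogram; negatives rejected
  expect_true(all(simulate_emission(matrix(0, 64, 64), mm, NULL, g, 0,
                                    pixel_size_mm = px)$data == 0))
  expect_error(simulate_emission(matrix(-1, 4, 4), NULL, NULL, g, 0),
               "nonnegative")
})

test_that("FBP round-trips a disk and is linear before clipping", {
  d <- disk_fixture()
  g <- default_geometry(d$n, d$px, 180)
  sg <- forward_project(d$img, g, d$px)
  rec <- reconstruct_fbp(sg, g, d$n, d$px)
  expect_lt(nmse(d$img, rec), 0.02)
  # zero sinogram -> zero image
  z <- sinogram(matrix(0, g$n_angles, g$n_bins), "emission")
  expect_true(all(reconstruct_fbp(z, g, d$n, d$px) == 0))
  # doubling the sinogram doubles the (unclipped) reconstruction
  r1 <- reconstruct_fbp(sg, g, d$n, d$px, clip_negative = FALSE)
  sg2 <- sinogram(2 * sg$data, "emission")
  r2 <- reconstruct_fbp(sg2, g, d$n, d$px, clip_negative = FALSE)
  expect_lt(max(abs(r2 - 2 * r1)), 1e-8)
  # geometry mismatch rejected
  expect_error(reconstruct_fbp(z, default_geometry(64, 1, 24), 64, 1),
               "geometry")
})

test_that("OSEM honours its contracts and improves with iterations", {
  n <- 32; px <- 2
  coord <- (seq_len(n) - (n + 1) / 2) * px
  xg <- matrix(coord, n, n, byrow = TRUE); yg <- matrix(coord, n, n)
  disk <- (xg^2 + yg^2 <= 20^2) * 1.0
  g <- default_geometry(n, px, 24)
  expect_error(reconstruct_osem(sinogram(matrix(0, 24, g$n_bins)), g, n,
                                subsets = 7), "divide")
  # EM fixed point: data that exactly matches a uniform image's projection
  ones <- matrix(1, n, n)
  y1 <- forward_project(ones, g, px)
  f1 <- reconstruct_osem(y1, g, n, iterations = 1, subsets = 4,
                         pixel_size_mm = px)
  expect_lt(max(abs(f1 - 1)), 1e-8)
  # noise-free disk with attenuation folded into the model: the Poisson
  # log-likelihood rises monotonically (the EM guarantee) and the image
  # error improves over continued iteration
  mm <- mu_map(disk * 0.096, px)
  att <- attenuation_factors(mm, g)
  y <- sinogram(forward_project(disk, g, px)$data * att$data, "emission")
  stats <- vapply(1:5, function(it) {
    f <- reconstruct_osem(y, g, n, att = att, iterations = it,
                          subsets = 4, pixel_size_mm = px)
    proj <- forward_project(f, g, px)$data * att$data
    c(ll = sum(y$data * log(pmax(proj, 1e-12)) - proj), err = nmse(disk, f))
  }, numeric(2))
  expect_true(all(diff(stats["ll", ]) > 0))
  expect_lt(stats["err", 5], stats["err", 1])
  expect_true(all(reconstruct_osem(y, g, n, att = att, iterations = 1,
                                   subsets = 4, pixel_size_mm = px) >= 0))
})

test_that("CTAC correction removes the attenuation bias", {
  ph <- small_case()
  px <- ph$pixel_size_mm
  g <- default_geometry(64, px, 96)
  mm <- hu_to_mu(ph$ct_hu, pixel_size_mm = px)
  psf <- psf_model(5)
  blurred <- apply_psf(ph$activity, psf, px)
  em <- simulate_emission(ph$activity, mm, psf, g, 0, pixel_size_mm = px)
  att <- attenuation_factors(mm, g)
  ct <- ctac_correct(em, att, g, 64, pixel_size_mm = px)
  non_ac <- reconstruct_fbp(em, g, 64, px)
  expect_lt(nmse(blurred, ct), 0.02)
  expect_gt(nmse(blurred, non_ac), nmse(blurred, ct))
  # all-ones factors leave the reconstruction unchanged
  ones <- sinogram(matrix(1, g$n_angles, g$n_bins), "attenuation_factor")
  expect_equal(ctac_correct(em, ones, g, 64, pixel_size_mm = px), non_ac)
  # nonpositive factors rejected
  bad <- sinogram(matrix(1e-3, g$n_angles, g$n_bins), "attenuation_factor")
  bad$data[1, 1] <- 0
  expect_error(ctac_correct(em, bad, g, 64, pixel_size_mm = px),
               "division-safety")
})
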