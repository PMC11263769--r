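test_that("NMSE matches its printed-definition example and edge cases", {
  X <- matrix(c(1, 3, 2, 4), 2)   # [[1,2],[3,4]] row-wise
  Y <- matrix(c(1, 3, 2, 0), 2)
  expect_equal(nmse(X, Y, rescale_target = FALSE), 16 / 14)
  expect_equal(nmse(X, X), 0)
  # literal and reference denominators agree when target = reference
  expect_equal(nmse(X, X, denominator = "target"),
               nmse(X, X, denominator = "reference"))
  expect_error(nmse(X, matrix(0, 2, 2), rescale_target = FALSE), "denominator")
})

test_that("PSNR matches closed forms and is scale-aware", {
  ref <- matrix(255, 16, 16); ref[1, 1] <- 0
  tgt <- ref + 1; tgt[1, 1] <- 1   # MSE = 1
  expect_equal(psnr(ref, tgt), 10 * log10(65025), tolerance = 1e-12)
  expect_identical(psnr(ref, ref), Inf)
  # doubling both images (peak scales too) leaves PSNR unchanged
  expect_equal(psnr(2 * ref, 2 * tgt), psnr(ref, tgt), tolerance = 1e-12)
  expect_error(psnr(matrix(0, 2, 2), matrix(0, 2, 2)), "zero reference")
})

test_that("SSIM hits its closed-form and identity values", {
  set.seed(2)
  m <- matrix(runif(256, 0, 255), 16)
  expect_equal(ssim(m, m), 1)
  a <- matrix(0, 8, 8); b <- matrix(255, 8, 8)
  got <- ssim(a, b, ssim_params(window = "global"))
  c1 <- (0.01 * 255)^2
  expect_equal(got, c1 / (255^2 + c1), tolerance = 1e-12)
  expect_error(ssim(a, b, ssim_params(window_size = 16)), "window")
})

test_that("metrics agree with brute-force double-loop oracles", {
  set.seed(7)
  for (i in 1:20) {
    X <- matrix(runif(256, 0, 255), 16)
    Y <- matrix(runif(256, 0, 255), 16)
    expect_equal(nmse(X, Y, rescale_target = FALSE), nmse_oracle(X, Y),
                 tolerance = 1e-10)
    expect_equal(psnr(X, Y), psnr_oracle(X, Y), tolerance = 1e-10)
    expect_equal(ssim(X, Y), ssim_oracle(X, Y), tolerance = 1e-10)
  }
})

test_that("extra noise raises median NMSE", {
  set.seed(5)
  base <- matrix(runif(64, 50, 200), 8)
  n1 <- n2 <- numeric(50)
  for (i in 1:50) {
    y1 <- base + matrix(rnorm(64, 0, 5), 8)
    y2 <- y1 + matrix(rnorm(64, 0, 5), 8)
    n1[i] <- nmse(base, y1); n2[i] <- nmse(base, y2)
  }
  expect_gt(median(n2), median(n1))
})

test_that("Wilcoxon rank-sum: exact enumeration, ties, and approximation", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_equal(wilcoxon_rank_sum(c(2, 2, 2), c(2, 2, 2)), 1)
  # cross-check the exact path against wilcox.test where it is exact
  set.seed(3)
  a <- rnorm(6); b <- rnorm(7, 1)
  expect_equal(wilcoxon_rank_sum(a, b),
               stats::wilcox.test(a, b, exact = TRUE)$p.value,
               tolerance = 1e-12)
  # exact vs normal approximation agree for moderate n
  a <- rnorm(10); b <- rnorm(10, 0.5)
  p_exact <- wilcoxon_rank_sum(a, b)
  p_approx <- wilcoxon_rank_sum(a, b, exact_limit = 0)
  expect_lt(abs(p_exact - p_approx), 0.02)
  expect_error(wilcoxon_rank_sum(1, c(1, 2)), "at least two")
})

test_that("cohort evaluation summarizes and recomputes correctly", {
  set.seed(8)
  mk <- function(id, method, noise) {
    ref <- matrix(runif(256, 10, 200), 16)
    list(case_id = id, method = method,
         predicted_ac = ref + matrix(rnorm(256, 0, noise), 16),
         reference_ac = ref)
  }
  res <- c(lapply(1:4, function(i) mk(paste0("c", i), "direct", 0)),
           lapply(1:4, function(i) mk(paste0("c", i), "direct_hrc", 20)))
  rep <- evaluate_cohort(res)
  d <- rep$per_case[rep$per_case$method == "direct", ]
  expect_true(all(d$nmse == 0))
  expect_true(all(d$ssim == 1))
  # medians recompute from the per-case rows
  h <- rep$per_case[rep$per_case$method == "direct_hrc", ]
  expect_equal(rep$summary$nmse_median[rep$summary$method == "direct_hrc"],
               median(h$nmse))
  expect_true(all(rep$pairwise$p_nmse >= 0 & rep$pairwise$p_nmse <= 1))
  # identical distributions give a null p-value
  res2 <- c(lapply(1:3, function(i) mk(paste0("a", i), "m1", 0)),
            lapply(1:3, function(i) mk(paste0("b", i), "m2", 0)))
  rep2 <- evaluate_cohort(res2)
  expect_gt(rep2$pairwise$p_nmse, 0.05)
  expect_error(evaluate_cohort(list()), "empty")
})
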