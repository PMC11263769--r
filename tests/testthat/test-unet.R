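test_that("the built network has 13 conv layers over 5 depth levels", {
  m <- build_unet(unet_config(base_channels = 2), seed = 1)
  expect_equal(count_conv_layers(m), 13)
  expect_equal(m$config$depth, 5)
  # every layer but the last carries batch-norm + ReLU; the last is linear
  flags <- vapply(m$config$layers, function(l) l$bn && l$act, logical(1))
  expect_true(all(flags[-13]))
  expect_false(flags[13])
  expect_equal(m$config$layers$fin$kernel, 1)
})

test_that("shape contracts: output matches input, bad sizes rejected", {
  m <- build_unet(unet_config(base_channels = 2), seed = 2)
  img <- matrix(runif(64 * 64, 0, 255), 64)
  out <- unet_predict(m, img)
  expect_equal(dim(out), c(64, 64))
  expect_true(all(out >= 0 & out <= 255))
  expect_error(unet_predict(m, matrix(0, 100, 100)), "shape error")
})

test_that("initialization and inference are seed-reproducible", {
  m1 <- build_unet(unet_config(base_channels = 2), seed = 9)
  m2 <- build_unet(unet_config(base_channels = 2), seed = 9)
  m3 <- build_unet(unet_config(base_channels = 2), seed = 10)
  expect_identical(m1$params, m2$params)
  expect_false(identical(m1$params, m3$params))
  img <- matrix(runif(32 * 32, 0, 255), 32)
  expect_identical(unet_predict(m1, img), unet_predict(m2, img))
  expect_identical(unet_predict(m1, img), unet_predict(m1, img))
})

test_that("backpropagation matches finite-difference gradients", {
  set.seed(1)
  m <- build_unet(unet_config(base_channels = 2), seed = 5)
  x <- array(runif(16 * 16 * 2), c(16, 16, 1, 2))
  y <- array(runif(16 * 16 * 2), c(16, 16, 1, 2))
  fw <- petac:::unet_forward(m, x, training = TRUE)
  loss0 <- mean((fw$out - y)^2)
  grads <- petac:::unet_backward(m, fw, 2 * (fw$out - y) / length(y))
  eps <- 1e-6
  for (nm in c("enc2", "bott1", "dec3", "fin")) {
    for (pn in intersect(names(grads[[nm]]), c("W", "gamma", "beta"))) {
      m2 <- m
      m2$params[[nm]][[pn]][1] <- m2$params[[nm]][[pn]][1] + eps
      fw2 <- petac:::unet_forward(m2, x, training = TRUE)
      num <- (mean((fw2$out - y)^2) - loss0) / eps
      ana <- grads[[nm]][[pn]][1]
      expect_equal(num, ana, tolerance = 1e-3)
    }
  }
})

test_that("training descends on an identity task and is deterministic", {
  set.seed(4)
  imgs <- lapply(1:12, function(i) matrix(runif(32 * 32, 0, 255), 32))
  m <- build_unet(unet_config(base_channels = 4), seed = 3)
  tcfg <- train_config(epochs = 3, batch_size = 4, seed = 6)
  t1 <- unet_train(m, imgs, imgs, tcfg = tcfg)
  expect_length(t1$loss_curve, 3)
  expect_lt(t1$loss_curve[3], t1$loss_curve[1])
  t2 <- unet_train(m, imgs, imgs, tcfg = tcfg)
  expect_identical(t1$loss_curve, t2$loss_curve)
  expect_identical(t1$params, t2$params)
  expect_error(unet_train(m, list(), list(), tcfg = tcfg), "empty|must be")
})

test_that("k-fold assignment balances sizes and is seeded by case", {
  ids <- sprintf("case_%02d", 1:53)
  f <- kfold_split(ids, 6, seed = 2)
  expect_equal(sort(unname(table(f)), decreasing = TRUE), c(9, 9, 9, 9, 9, 8),
               ignore_attr = TRUE)
  expect_setequal(names(f), ids)
  expect_identical(f, kfold_split(ids, 6, seed = 2))
  expect_false(identical(f, kfold_split(ids, 6, seed = 3)))
  expect_error(kfold_split(ids[1:4], 6), "more folds")
})
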