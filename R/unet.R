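# U-net image-to-image model: 13 convolutional layers over 5 depth levels,
# ReLU + batch normalization on every conv layer except the final linear
# 1x1 convolution. Encoder downsamples by 2x2 max-pooling, decoder
# upsamples by nearest-neighbour and concatenates skip connections.
# Forward/backward passes are hand-rolled on Rcpp conv/pool kernels.

#' U-net configuration
#'
#' Fixed 13-layer, five-level topology: one conv per encoder level (4), two
#' bottleneck convs, one conv per decoder level after up-concat (4), two
#' refinement convs, and a final linear 1x1 conv. Channel widths double per
#' level from `base_channels`.
#'
#' @param base_channels channels of the first level (default 16).
#' @param kernel spatial kernel size of the main convolutions (odd).
#' @export
unet_config <- function(base_channels = 16, kernel = 3) {
  stopifnot(base_channels >= 1, kernel %% 2 == 1)
  cc <- base_channels
  layer <- function(cin, cout, k = kernel, bn = TRUE, act = TRUE)
    list(cin = cin, cout = cout, kernel = k, bn = bn, act = act)
  layers <- list(
    enc1 = layer(1, cc),         enc2 = layer(cc, 2 * cc),
    enc3 = layer(2 * cc, 4 * cc), enc4 = layer(4 * cc, 8 * cc),
    bott1 = layer(8 * cc, 16 * cc), bott2 = layer(16 * cc, 16 * cc),
    dec4 = layer(24 * cc, 8 * cc), dec3 = layer(12 * cc, 4 * cc),
    dec2 = layer(6 * cc, 2 * cc),  dec1 = layer(3 * cc, cc),
    ref1 = layer(cc, cc), ref2 = layer(cc, cc),
    fin = layer(cc, 1, k = 1, bn = FALSE, act = FALSE)
  )
  structure(list(depth = 5L, total_conv_layers = length(layers),
                 base_channels = as.integer(base_channels),
                 kernel = as.integer(kernel), layers = layers),
            class = "unet_config")
}

#' Build a U-net with seeded initialization
#'
#' He-normal weight initialization; batch-norm scales start at 1, shifts at
#' 0. Identical `(config, seed)` give bit-identical models.
#'
#' @param config a [unet_config()].
#' @param seed integer seed.
#' @return object of class `petac_unet`.
#' @export
build_unet <- function(config = unet_config(), seed = 1) {
  stopifnot(inherits(config, "unet_config"))
  params <- with_seed(seed, lapply(config$layers, function(ly) {
    k <- ly$kernel
    sdw <- sqrt(2 / (k * k * ly$cin))
    p <- list(W = array(rnorm(k * k * ly$cin * ly$cout, 0, sdw),
                        c(k, k, ly$cin, ly$cout)),
              b = numeric(ly$cout))
    if (ly$bn) {
      p$gamma <- rep(1, ly$cout); p$beta <- numeric(ly$cout)
      p$run_mean <- numeric(ly$cout); p$run_var <- rep(1, ly$cout)
      p$run_n <- 0
    }
    p
  }))
  structure(list(config = config, params = params, seed = seed,
                 trained = FALSE),
            class = "petac_unet")
}

#' Count the convolutional layers of a built model
#'
#' @param model a `petac_unet`.
#' @export
count_conv_layers <- function(model) {
  stopifnot(inherits(model, "petac_unet"))
  length(model$params)
}

#' @export
print.petac_unet <- function(x, ...) {
  np <- sum(vapply(x$params, function(p)
    length(p$W) + length(p$b) + length(p$gamma) + length(p$beta), numeric(1)))
  cat(sprintf("<petac_unet: %d conv layers, %d depth levels, %s parameters%s>\n",
              length(x$params), x$config$depth, format(np, big.mark = ","),
              if (isTRUE(x$trained)) ", trained" else ""))
  invisible(x)
}

# ---- layer primitives ---------------------------------------------------

bn_channel_index <- function(d) rep(rep(seq_len(d[3]), each = d[1] * d[2]), d[4])

bn_fwd <- function(z, p, training, eps = 1e-5) {
  d <- dim(z); C <- d[3]
  chidx <- bn_channel_index(d)
  if (training) {
    zp <- matrix(aperm(z, c(1, 2, 4, 3)), ncol = C)
    mu <- colMeans(zp)
    v <- colMeans(zp * zp) - mu^2
    # cumulative (debiased) average of batch statistics: stable inference
    # statistics even after very few updates
    k <- if (is.null(p$run_n)) 0 else p$run_n
    run_mean <- (k * p$run_mean + mu) / (k + 1)
    run_var <- (k * p$run_var + v) / (k + 1)
    run_n <- k + 1
  } else {
    mu <- p$run_mean; v <- p$run_var
    run_mean <- p$run_mean; run_var <- p$run_var
    run_n <- p$run_n
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- (z - mu[chidx]) * inv[chidx]
  out <- p$gamma[chidx] * xhat + p$beta[chidx]
  list(out = out, xhat = xhat, inv = inv, chidx = chidx,
       run_mean = run_mean, run_var = run_var, run_n = run_n)
}

bn_bwd <- function(dout, cache, p) {
  d <- dim(dout); C <- d[3]
  m <- d[1] * d[2] * d[4]
  chidx <- cache$chidx
  per_channel <- function(x) {
    colSums(matrix(aperm(x, c(1, 2, 4, 3)), ncol = C))
  }
  dgamma <- per_channel(dout * cache$xhat)
  dbeta <- per_channel(dout)
  dxhat <- dout * p$gamma[chidx]
  s1 <- per_channel(dxhat)
  s2 <- per_channel(dxhat * cache$xhat)
  dx <- (cache$inv[chidx] / m) *
    (m * dxhat - s1[chidx] - cache$xhat * s2[chidx])
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

conv_layer_fwd <- function(p, ly, x, training) {
  z <- conv2d_fwd(x, p$W, p$b)
  cache <- list(x = x)
  if (ly$bn) {
    bn <- bn_fwd(z, p, training)
    cache$bn <- bn[c("xhat", "inv", "chidx")]
    cache$run <- bn[c("run_mean", "run_var", "run_n")]
    z <- bn$out
  }
  if (ly$act) {
    mask <- z > 0
    z <- z * mask
    cache$mask <- mask
  }
  list(out = z, cache = cache)
}

conv_layer_bwd <- function(p, ly, cache, dout) {
  if (ly$act) dout <- dout * cache$mask
  g <- list()
  if (ly$bn) {
    bb <- bn_bwd(dout, c(cache$bn, list()), p)
    dout <- bb$dx
    g$gamma <- bb$dgamma; g$beta <- bb$dbeta
  }
  cb <- conv2d_bwd(cache$x, p$W, dout)
  g$W <- cb$dw; g$b <- cb$db
  list(dx = cb$dx, grads = g)
}

up2 <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , ,
    drop = FALSE]
}

up2_bwd <- function(dy) {
  d <- dim(dy)
  o1 <- seq(1, d[1], 2); e1 <- o1 + 1
  o2 <- seq(1, d[2], 2); e2 <- o2 + 1
  dy[o1, o2, , , drop = FALSE] + dy[e1, o2, , , drop = FALSE] +
    dy[o1, e2, , , drop = FALSE] + dy[e1, e2, , , drop = FALSE]
}

concat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

# ---- full network forward / backward -----------------------------------

unet_forward <- function(model, x, training = FALSE) {
  P <- model$params; L <- model$config$layers
  d <- dim(x)
  if (d[1] %% 16 != 0 || d[2] %% 16 != 0)
    stop("shape error: input sides must be divisible by 16 (2^(depth-1))",
         call. = FALSE)
  cc <- list()
  step <- function(name, inp) {
    r <- conv_layer_fwd(P[[name]], L[[name]], inp, training)
    cc[[name]] <<- r$cache
    r$out
  }
  a1 <- step("enc1", x);  p1 <- maxpool2_fwd(a1)
  a2 <- step("enc2", p1$out); p2 <- maxpool2_fwd(a2)
  a3 <- step("enc3", p2$out); p3 <- maxpool2_fwd(a3)
  a4 <- step("enc4", p3$out); p4 <- maxpool2_fwd(a4)
  b1 <- step("bott1", p4$out); b2 <- step("bott2", b1)
  d4 <- step("dec4", concat_ch(up2(b2), a4))
  d3 <- step("dec3", concat_ch(up2(d4), a3))
  d2 <- step("dec2", concat_ch(up2(d3), a2))
  d1 <- step("dec1", concat_ch(up2(d2), a1))
  r1 <- step("ref1", d1); r2 <- step("ref2", r1)
  out <- step("fin", r2)
  list(out = out,
       caches = cc,
       pools = list(p1 = p1, p2 = p2, p3 = p3, p4 = p4),
       dims = list(a1 = dim(a1), a2 = dim(a2), a3 = dim(a3), a4 = dim(a4)))
}

unet_backward <- function(model, fw, dout) {
  P <- model$params; L <- model$config$layers
  grads <- list()
  back <- function(name, dy) {
    r <- conv_layer_bwd(P[[name]], L[[name]], fw$caches[[name]], dy)
    grads[[name]] <<- r$grads
    r$dx
  }
  split_ch <- function(dz, c_up) {
    list(up = dz[, , seq_len(c_up), , drop = FALSE],
         skip = dz[, , -seq_len(c_up), , drop = FALSE])
  }
  d <- back("fin", dout)
  d <- back("ref2", d); d <- back("ref1", d)
  dz <- back("dec1", d)
  sp <- split_ch(dz, dim(dz)[3] - fw$dims$a1[3])
  da1 <- sp$skip; d <- up2_bwd(sp$up)
  dz <- back("dec2", d)
  sp <- split_ch(dz, dim(dz)[3] - fw$dims$a2[3])
  da2 <- sp$skip; d <- up2_bwd(sp$up)
  dz <- back("dec3", d)
  sp <- split_ch(dz, dim(dz)[3] - fw$dims$a3[3])
  da3 <- sp$skip; d <- up2_bwd(sp$up)
  dz <- back("dec4", d)
  sp <- split_ch(dz, dim(dz)[3] - fw$dims$a4[3])
  da4 <- sp$skip; d <- up2_bwd(sp$up)
  d <- back("bott2", d); d <- back("bott1", d)
  d <- maxpool2_bwd(d, fw$pools$p4$which, fw$dims$a4)
  d <- back("enc4", d + da4)
  d <- maxpool2_bwd(d, fw$pools$p3$which, fw$dims$a3)
  d <- back("enc3", d + da3)
  d <- maxpool2_bwd(d, fw$pools$p2$which, fw$dims$a2)
  d <- back("enc2", d + da2)
  d <- maxpool2_bwd(d, fw$pools$p1$which, fw$dims$a1)
  back("enc1", d + da1)
  grads
}

# merge freshly computed batch-norm running stats back into the params
merge_running_stats <- function(model, caches) {
  for (nm in names(caches)) {
    run <- caches[[nm]]$run
    if (!is.null(run)) {
      model$params[[nm]]$run_mean <- run$run_mean
      model$params[[nm]]$run_var <- run$run_var
      model$params[[nm]]$run_n <- run$run_n
    }
  }
  model
}

#' Predict an output image
#'
#' Deterministic inference: batch normalization uses running statistics and
#' the output is clipped to the 0-255 display range. For convenience in
#' oracle-substitution experiments, `model` may also be a plain function
#' `image -> image`, which is called directly.
#'
#' @param model a trained `petac_unet` (or a function).
#' @param image matrix on the 0-255 display scale; sides must be divisible
#'   by 16.
#' @return matrix on the display scale.
#' @export
unet_predict <- function(model, image) {
  if (is.function(model)) return(model(image))
  stopifnot(inherits(model, "petac_unet"))
  x <- array(image / 255, c(nrow(image), ncol(image), 1, 1))
  fw <- unet_forward(model, x, training = FALSE)
  clamp(matrix(fw$out[, , 1, 1] * 255, nrow(image), ncol(image)), 0, 255)
}
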