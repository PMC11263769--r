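# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded simulation code does not
#' disturb the caller's RNG stream.
#'
#' @param seed integer scalar.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Mix a global seed with a per-item index into a derived 31-bit seed.
# Deterministic in (seed, i) only, so cohort prefixes are stable.
derive_seed <- function(seed, i) {
  v <- (as.numeric(seed) %% 2147483647) * 48271 + as.numeric(i) * 1000003
  as.integer(v %% 2147483647)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

assert_square <- function(img, what = "image") {
  if (!is.matrix(img) || nrow(img) != ncol(img))
    stop(sprintf("%s must be a square matrix", what), call. = FALSE)
  invisible(img)
}

# Bilinear sampling of matrix `img` at fractional positions (row, col),
# 1-based; positions outside the grid contribute zero. Linear in `img`.
bilinear_sample <- function(img, row, col) {
  H <- nrow(img); W <- ncol(img)
  r0 <- floor(row); c0 <- floor(col)
  fr <- row - r0;   fc <- col - c0
  out <- numeric(length(row))
  corners <- list(
    list(r = r0,      c = c0,      w = (1 - fr) * (1 - fc)),
    list(r = r0 + 1L, c = c0,      w = fr       * (1 - fc)),
    list(r = r0,      c = c0 + 1L, w = (1 - fr) * fc),
    list(r = r0 + 1L, c = c0 + 1L, w = fr       * fc)
  )
  for (cr in corners) {
    ok <- cr$r >= 1 & cr$r <= H & cr$c >= 1 & cr$c <= W & cr$w != 0
    if (any(ok)) {
      idx <- cbind(cr$r[ok], cr$c[ok])
      out[ok] <- out[ok] + cr$w[ok] * img[idx]
    }
  }
  out
}

# Adjoint of bilinear_sample: scatter `values` at fractional positions into
# an H x W accumulator with the same bilinear weights.
bilinear_scatter <- function(values, row, col, H, W) {
  r0 <- floor(row); c0 <- floor(col)
  fr <- row - r0;   fc <- col - c0
  acc <- numeric(H * W)
  corners <- list(
    list(r = r0,      c = c0,      w = (1 - fr) * (1 - fc)),
    list(r = r0 + 1L, c = c0,      w = fr       * (1 - fc)),
    list(r = r0,      c = c0 + 1L, w = (1 - fr) * fc),
    list(r = r0 + 1L, c = c0 + 1L, w = fr       * fc)
  )
  for (cr in corners) {
    ok <- cr$r >= 1 & cr$r <= H & cr$c >= 1 & cr$c <= W & cr$w != 0
    if (any(ok)) {
      lin <- (cr$c[ok] - 1) * H + cr$r[ok]
      rs <- rowsum(values[ok] * cr$w[ok], lin)
      at <- as.integer(rownames(rs))
      acc[at] <- acc[at] + rs[, 1L]
    }
  }
  matrix(acc, H, W)
}

# 1-D Gaussian kernel, normalized to sum 1, truncated at `truncate` sigma.
gaussian_kernel_1d <- function(sigma, truncate = 4) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(1)
  r <- max(1L, ceiling(truncate * sigma))
  k <- exp(-0.5 * ((-r:r) / sigma)^2)
  k / sum(k)
}

# Separable Gaussian blur with reflective boundary padding.
gaussian_blur <- function(img, sigma_px, truncate = 4) {
  if (sigma_px == 0) return(img)
  k <- gaussian_kernel_1d(sigma_px, truncate)
  r <- (length(k) - 1L) / 2L
  blur_cols <- function(m) {
    n <- nrow(m)
    pad <- rbind(m[pmin(r:1, n), , drop = FALSE], m,
                 m[pmax(n - seq_len(r) + 1L, 1L), , drop = FALSE])
    out <- 0
    for (j in seq_along(k)) out <- out + k[j] * pad[(j - 1L) + seq_len(n), , drop = FALSE]
    out
  }
  t(blur_cols(t(blur_cols(img))))
}

# Fill an ellipse mask on the pixel grid: centre (cy, cx) and semi-axes
# (ry, rx) in mm; `yg`, `xg` are mm coordinate grids of pixel centres.
ellipse_mask <- function(yg, xg, cy, cx, ry, rx, theta = 0) {
  dy <- yg - cy; dx <- xg - cx
  if (theta != 0) {
    co <- cos(theta); si <- sin(theta)
    tmp <- dx * co + dy * si
    dy <- -dx * si + dy * co
    dx <- tmp
  }
  (dx / rx)^2 + (dy / ry)^2 <= 1
}
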