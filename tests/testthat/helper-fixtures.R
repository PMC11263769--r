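# Shared fixtures, built lazily and cached for the session.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

small_case <- function(seed = 3) {
  fixture(paste0("case", seed), function() generate_head_phantom(shape = 64, seed = seed))
}

# a 128-px disk image in a 2 mm grid: radius 100 mm, unit value
disk_fixture <- function() {
  fixture("disk", function() {
    n <- 128; px <- 2
    coord <- (seq_len(n) - (n + 1) / 2) * px
    xg <- matrix(coord, n, n, byrow = TRUE)
    yg <- matrix(coord, n, n)
    list(img = (xg^2 + yg^2 <= 100^2) * 1.0, n = n, px = px)
  })
}

# brute-force double-loop metric oracles (kept independent of the package
# implementations)
nmse_oracle <- function(X, Y) {
  num <- 0; den <- 0
  for (i in seq_len(nrow(X))) for (j in seq_len(ncol(X))) {
    num <- num + (X[i, j] - Y[i, j])^2
    den <- den + Y[i, j]^2
  }
  num / den
}

psnr_oracle <- function(X, Y) {
  mse <- 0
  for (i in seq_len(nrow(X))) for (j in seq_len(ncol(X)))
    mse <- mse + (X[i, j] - Y[i, j])^2
  mse <- mse / length(X)
  10 * log10(max(X)^2 / mse)
}

ssim_oracle <- function(X, Y, w = 8, L = 255) {
  c1 <- (0.01 * L)^2; c2 <- (0.03 * L)^2
  vals <- numeric(0)
  for (i in seq_len(nrow(X) - w + 1)) for (j in seq_len(ncol(X) - w + 1)) {
    x <- as.vector(X[i:(i + w - 1), j:(j + w - 1)])
    y <- as.vector(Y[i:(i + w - 1), j:(j + w - 1)])
    mx <- mean(x); my <- mean(y)
    vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
    cxy <- mean((x - mx) * (y - my))
    vals <- c(vals, ((2 * mx * my + c1) * (2 * cxy + c2)) /
                ((mx^2 + my^2 + c1) * (vx + vy + c2)))
  }
  mean(vals)
}
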