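# Image-agreement metrics (NMSE, PSNR, SSIM) and the Wilcoxon rank-sum
# comparison used to contrast correction methods.

#' Normalized mean squared error
#'
#' `sum((X - Y)^2) / sum(Y^2)` where X is the reference and Y the target
#' after rescaling so its maximum matches the reference maximum. The
#' default denominator sums the rescaled *target* squared (the literal
#' definition used by the clinical analysis software this mirrors);
#' `denominator = "reference"` gives the conventional form. Both agree
#' whenever target equals reference.
#'
#' @param reference,target equal-shape numeric matrices.
#' @param denominator `"target"` (default) or `"reference"`.
#' @param rescale_target rescale the target so its maximum equals the
#'   reference maximum before comparison (default TRUE).
#' @return scalar >= 0; 0 iff the images agree.
#' @export
nmse <- function(reference, target, denominator = c("target", "reference"),
                 rescale_target = TRUE) {
  denominator <- match.arg(denominator)
  stopifnot(all(dim(reference) == dim(target)))
  y <- target
  if (rescale_target && max(y) != 0 && max(reference) != 0)
    y <- y * (max(reference) / max(y))
  den <- if (denominator == "target") sum(y^2) else sum(reference^2)
  if (den == 0) stop("metric error: all-zero denominator image", call. = FALSE)
  sum((reference - y)^2) / den
}

#' Peak signal-to-noise ratio (dB)
#'
#' `10 * log10(max(K)^2 / MSE(K, K'))` with K the reference; identical
#' images give `Inf`.
#'
#' @param reference,target equal-shape numeric matrices.
#' @export
psnr <- function(reference, target) {
  stopifnot(all(dim(reference) == dim(target)))
  peak <- max(reference)
  if (peak == 0) stop("metric error: zero reference maximum", call. = FALSE)
  mse <- mean((reference - target)^2)
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}

#' SSIM parameters
#'
#' @param k1,k2 stabilization constants (0.01 and 0.03).
#' @param L dynamic range of pixel values (default 255).
#' @param window `"sliding"` (default: w x w windows, stride 1, mean over
#'   windows) or `"global"` (one window covering the whole image).
#' @param window_size side of the sliding window (default 8).
#' @export
ssim_params <- function(k1 = 0.01, k2 = 0.03, L = 255,
                        window = c("sliding", "global"), window_size = 8) {
  window <- match.arg(window)
  stopifnot(L > 0, k1 > 0, k2 > 0, window_size >= 2)
  structure(list(k1 = k1, k2 = k2, L = L, window = window,
                 window_size = as.integer(window_size),
                 c1 = (k1 * L)^2, c2 = (k2 * L)^2),
            class = "ssim_params")
}

# window sums of all w x w windows (stride 1) via an integral image
win_sums <- function(x, w) {
  H <- nrow(x); W <- ncol(x)
  cs <- apply(x, 2, cumsum)
  cs <- t(apply(cs, 1, cumsum))
  P <- matrix(0, H + 1, W + 1)
  P[-1, -1] <- cs
  i <- seq_len(H - w + 1); j <- seq_len(W - w + 1)
  P[i + w, j + w, drop = FALSE] - P[i, j + w, drop = FALSE] -
    P[i + w, j, drop = FALSE] + P[i, j, drop = FALSE]
}

#' Structural similarity index
#'
#' `(2 mu_x mu_y + c1)(2 sigma_xy + c2) /
#'  ((mu_x^2 + mu_y^2 + c1)(sigma_x^2 + sigma_y^2 + c2))`, computed per
#' window with population moments and averaged. Identical images score
#' exactly 1.
#'
#' @param reference,target equal-shape numeric matrices.
#' @param params an [ssim_params()].
#' @export
ssim <- function(reference, target, params = ssim_params()) {
  stopifnot(all(dim(reference) == dim(target)), inherits(params, "ssim_params"))
  w <- if (params$window == "global") NULL else params$window_size
  if (!is.null(w) && (w > nrow(reference) || w > ncol(reference)))
    stop("argument error: SSIM window larger than image", call. = FALSE)
  c1 <- params$c1; c2 <- params$c2
  if (params$window == "global") {
    n <- length(reference)
    mx <- mean(reference); my <- mean(target)
    vx <- mean(reference^2) - mx^2
    vy <- mean(target^2) - my^2
    cxy <- mean(reference * target) - mx * my
    return(((2 * mx * my + c1) * (2 * cxy + c2)) /
             ((mx^2 + my^2 + c1) * (vx + vy + c2)))
  }
  n <- w * w
  mx <- win_sums(reference, w) / n
  my <- win_sums(target, w) / n
  vx <- win_sums(reference^2, w) / n - mx^2
  vy <- win_sums(target^2, w) / n - my^2
  cxy <- win_sums(reference * target, w) / n - mx * my
  smap <- ((2 * mx * my + c1) * (2 * cxy + c2)) /
    ((mx^2 + my^2 + c1) * (vx + vy + c2))
  mean(smap)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Midranks throughout. For combined sample size up to `exact_limit` the
#' p-value is computed by exhaustive enumeration of all rank assignments;
#' beyond that a normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param a,b numeric samples, each of length >= 2.
#' @param exact_limit switch-over combined size for exact enumeration.
#' @return p-value in \[0, 1\].
#' @export
wilcoxon_rank_sum <- function(a, b, exact_limit = 20) {
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2)
    stop("argument error: need at least two observations per sample",
         call. = FALSE)
  n <- na + nb
  r <- rank(c(a, b))                     # midranks
  W <- sum(r[seq_len(na)])
  mu <- na * (n + 1) / 2
  if (n <= exact_limit) {
    cmb <- combn(n, na)
    ws <- colSums(matrix(r[cmb], nrow = na))
    return(mean(abs(ws - mu) >= abs(W - mu) - 1e-9))
  }
  ties <- table(r)
  tiecorr <- sum(ties^3 - ties) / (n * (n - 1))
  sig2 <- na * nb / 12 * ((n + 1) - tiecorr)
  if (sig2 <= 0) return(1)
  z <- (abs(W - mu) - 0.5) / sqrt(sig2)
  min(1, 2 * pnorm(-max(z, 0)))
}

#' Score a set of case results and compare methods
#'
#' Computes per-case NMSE, PSNR and SSIM of each prediction against its
#' reference, per-method medians and ranges, and pairwise two-sided
#' Wilcoxon rank-sum p-values between methods (significance conventionally
#' read at p < 0.05).
#'
#' Predicted and reference images may live on different native count
#' scales (the direct methods restore counts through the input's record),
#' so each pair is first brought onto a common 0-255 display scale: the
#' prediction is rescaled to the reference maximum and both are mapped by
#' `255 / max(reference)`. NMSE is invariant to this; PSNR and SSIM
#' (`L = 255`) become comparable across cases.
#'
#' @param results list of case results, each a list with `case_id`,
#'   `method`, `predicted_ac`, `reference_ac` (as produced by the pipeline
#'   runners).
#' @param ssim_parameters an [ssim_params()].
#' @param nmse_denominator passed to [nmse()].
#' @return object of class `metrics_report`: `per_case` data frame,
#'   `summary` data frame, `pairwise` data frame of p-values.
#' @export
evaluate_cohort <- function(results, ssim_parameters = ssim_params(),
                            nmse_denominator = "target") {
  if (!length(results))
    stop("argument error: empty result set", call. = FALSE)
  rows <- do.call(rbind, lapply(results, function(r) {
    ref <- r$reference_ac
    tgt <- r$predicted_ac
    if (max(ref) <= 0)
      stop("metric error: nonpositive reference image", call. = FALSE)
    if (max(tgt) > 0) tgt <- tgt * (max(ref) / max(tgt))
    s <- 255 / max(ref)
    ref <- ref * s; tgt <- tgt * s
    data.frame(case_id = r$case_id, method = r$method,
               nmse = nmse(ref, tgt, denominator = nmse_denominator),
               psnr = psnr(ref, tgt),
               ssim = ssim(ref, tgt, ssim_parameters),
               stringsAsFactors = FALSE)
  }))
  summ <- do.call(rbind, lapply(split(rows, rows$method), function(d) {
    data.frame(method = d$method[1], n = nrow(d),
               nmse_median = median(d$nmse), nmse_min = min(d$nmse),
               nmse_max = max(d$nmse),
               psnr_median = median(d$psnr[is.finite(d$psnr)]),
               ssim_median = median(d$ssim), ssim_min = min(d$ssim),
               ssim_max = max(d$ssim), stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  methods <- unique(rows$method)
  pairwise <- NULL
  if (length(methods) >= 2) {
    prs <- combn(methods, 2)
    pairwise <- do.call(rbind, lapply(seq_len(ncol(prs)), function(i) {
      m1 <- prs[1, i]; m2 <- prs[2, i]
      d1 <- rows[rows$method == m1, ]; d2 <- rows[rows$method == m2, ]
      if (nrow(d1) < 2 || nrow(d2) < 2) return(NULL)
      data.frame(method_a = m1, method_b = m2,
                 p_nmse = wilcoxon_rank_sum(d1$nmse, d2$nmse),
                 p_psnr = wilcoxon_rank_sum(d1$psnr, d2$psnr),
                 p_ssim = wilcoxon_rank_sum(d1$ssim, d2$ssim),
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(per_case = rows, summary = summ, pairwise = pairwise),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Per-method summary:\n")
  print(x$summary, row.names = FALSE)
  if (!is.null(x$pairwise)) {
    cat("\nPairwise Wilcoxon rank-sum p-values:\n")
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}
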