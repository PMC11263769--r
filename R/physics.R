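# 2-D parallel-beam PET physics: projection, 511-keV attenuation, Poisson
# emission simulation, FBP and OSEM reconstruction, and the CT-based
# attenuation-correction (CTAC) pathway.

#' Parallel-beam scan geometry
#'
#' @param n_angles number of projection angles, evenly spaced over \[0, pi).
#' @param n_bins number of detector bins; must cover the image diagonal.
#' @param bin_size_mm detector bin width.
#' @return object of class `scan_geometry`.
#' @export
scan_geometry <- function(n_angles = 180, n_bins = 367, bin_size_mm = 1) {
  stopifnot(n_angles >= 8, n_bins >= 8, bin_size_mm > 0)
  structure(list(n_angles = as.integer(n_angles),
                 angles = (seq_len(n_angles) - 1) * pi / n_angles,
                 n_bins = as.integer(n_bins),
                 bin_size_mm = bin_size_mm),
            class = "scan_geometry")
}

#' Default geometry covering a square image
#'
#' Bins match the pixel size and cover the image diagonal.
#'
#' @param shape image side length in pixels.
#' @param pixel_size_mm pixel size.
#' @param n_angles number of angles.
#' @export
default_geometry <- function(shape, pixel_size_mm = 1, n_angles = 180) {
  nb <- 2L * ceiling(sqrt(2) * shape / 2) + 3L
  scan_geometry(n_angles, nb, pixel_size_mm)
}

#' Sinogram container
#'
#' Projection-domain data, `n_angles` rows by `n_bins` columns. Emission
#' sinograms are nonnegative; attenuation-factor sinograms lie in (0, 1].
#'
#' @param data numeric matrix `n_angles x n_bins`.
#' @param kind `"emission"` or `"attenuation_factor"`.
#' @param validate check the kind-specific range invariant.
#' @export
sinogram <- function(data, kind = c("emission", "attenuation_factor"),
                     validate = TRUE) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(data))
  if (validate) {
    if (kind == "emission" && any(data < 0))
      stop("emission sinogram must be nonnegative", call. = FALSE)
    if (kind == "attenuation_factor" && (any(data <= 0) || any(data > 1)))
      stop("attenuation factors must lie in (0, 1]", call. = FALSE)
  }
  structure(list(data = data, kind = kind), class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  cat(sprintf("<sinogram %s: %d angles x %d bins>\n", x$kind,
              nrow(x$data), ncol(x$data)))
  invisible(x)
}

#' Linear attenuation map at 511 keV
#'
#' @param mu numeric matrix of attenuation coefficients (cm^-1), in
#'   \[0, 0.5\].
#' @param pixel_size_mm pixel size.
#' @export
mu_map <- function(mu, pixel_size_mm = 1) {
  stopifnot(is.matrix(mu), pixel_size_mm > 0)
  if (any(mu < 0)) stop("mu must be nonnegative", call. = FALSE)
  if (any(mu > 0.5)) stop("mu above 0.5 cm^-1 is not physical at 511 keV",
                          call. = FALSE)
  structure(list(mu = mu, pixel_size_mm = pixel_size_mm), class = "mu_map")
}

#' Scanner point-spread-function model
#'
#' Isotropic Gaussian PSF applied in the image domain before projection;
#' this same kernel is the one inverted by the Richardson-Lucy
#' high-resolution correction.
#'
#' @param fwhm_mm full width at half maximum (default 5 mm, typical for a
#'   clinical brain PET system).
#' @param truncate kernel truncation radius in multiples of sigma.
#' @export
psf_model <- function(fwhm_mm = 5, truncate = 4) {
  stopifnot(fwhm_mm > 0, truncate > 0)
  structure(list(fwhm_mm = fwhm_mm, truncate = truncate), class = "psf_model")
}

psf_sigma_px <- function(psf, pixel_size_mm) {
  psf$fwhm_mm / (2 * sqrt(2 * log(2))) / pixel_size_mm
}

#' Apply the scanner point-spread function to an image
#'
#' Separable Gaussian blur with reflective boundaries; the same operator
#' used inside [simulate_emission()] and inverted by [richardson_lucy()].
#'
#' @param image numeric matrix.
#' @param psf a [psf_model()].
#' @param pixel_size_mm pixel size of `image`.
#' @export
apply_psf <- function(image, psf = psf_model(), pixel_size_mm = 1) {
  stopifnot(inherits(psf, "psf_model"))
  gaussian_blur(image, psf_sigma_px(psf, pixel_size_mm), psf$truncate)
}

# ---- projection operators ----------------------------------------------

ray_samples <- function(geometry, shape, pixel_size_mm) {
  n <- shape
  sc <- (seq_len(geometry$n_bins) - (geometry$n_bins + 1) / 2) * geometry$bin_size_mm
  half_diag <- sqrt(2) / 2 * n * pixel_size_mm
  tt <- seq(-half_diag, half_diag, by = pixel_size_mm)
  list(s = sc, t = tt, step_cm = pixel_size_mm / 10)
}

#' Forward projection (discrete Radon transform)
#'
#' Length-weighted line integrals (in cm) of a square image along parallel
#' rays, by bilinear sampling at pixel-size steps; exactly linear in the
#' image.
#'
#' @param image square numeric matrix.
#' @param geometry a [scan_geometry()].
#' @param pixel_size_mm pixel size of `image`.
#' @param kind kind tag of the returned [sinogram()].
#' @return a `sinogram` (validation off: projections of signed images are
#'   permitted for operator-level use).
#' @export
forward_project <- function(image, geometry, pixel_size_mm = 1,
                            kind = "emission") {
  assert_square(image)
  n <- nrow(image)
  need <- sqrt(2) * n * pixel_size_mm / geometry$bin_size_mm
  if (geometry$n_bins < need)
    stop("geometry error: n_bins too small to cover the image diagonal",
         call. = FALSE)
  rs <- ray_samples(geometry, n, pixel_size_mm)
  ns <- length(rs$s); nt <- length(rs$t)
  ctr <- (n + 1) / 2
  out <- matrix(0, geometry$n_angles, geometry$n_bins)
  svec <- rep(rs$s, times = nt)
  tvec <- rep(rs$t, each = ns)
  for (a in seq_len(geometry$n_angles)) {
    th <- geometry$angles[a]
    x <- svec * cos(th) - tvec * sin(th)
    y <- svec * sin(th) + tvec * cos(th)
    v <- bilinear_sample(image, y / pixel_size_mm + ctr, x / pixel_size_mm + ctr)
    out[a, ] <- .rowSums(v, ns, nt) * rs$step_cm
  }
  sinogram(out, kind, validate = FALSE)
}

# Adjoint of forward_project (scatter form), used by OSEM.
back_project_adjoint <- function(sino_data, geometry, shape, pixel_size_mm,
                                 angle_idx = seq_len(geometry$n_angles)) {
  n <- shape
  rs <- ray_samples(geometry, n, pixel_size_mm)
  ns <- length(rs$s); nt <- length(rs$t)
  ctr <- (n + 1) / 2
  svec <- rep(rs$s, times = nt)
  tvec <- rep(rs$t, each = ns)
  acc <- matrix(0, n, n)
  for (a in angle_idx) {
    th <- geometry$angles[a]
    x <- svec * cos(th) - tvec * sin(th)
    y <- svec * sin(th) + tvec * cos(th)
    vals <- rep(sino_data[a, ], times = nt) * rs$step_cm
    acc <- acc + bilinear_scatter(vals, y / pixel_size_mm + ctr,
                                  x / pixel_size_mm + ctr, n, n)
  }
  acc
}

#' Attenuation factor sinogram from a mu-map
#'
#' Beer-Lambert survival probability exp(-integral of mu dl) along each
#' ray; values in (0, 1], all ones for a zero mu-map.
#'
#' @param mu a [mu_map()].
#' @param geometry a [scan_geometry()].
#' @export
attenuation_factors <- function(mu, geometry) {
  stopifnot(inherits(mu, "mu_map"))
  proj <- forward_project(mu$mu, geometry, mu$pixel_size_mm)
  sinogram(exp(-proj$data), "attenuation_factor")
}

#' Simulate an emission sinogram
#'
#' The activity is blurred by the scanner PSF, forward projected, multiplied
#' by the attenuation factors, scaled so the expected total equals
#' `total_counts`, and Poisson sampled under `seed`. `total_counts = 0` is
#' the noise-free sentinel: the unscaled exact expectation is returned.
#' `poisson = FALSE` returns the scaled expectation without noise.
#'
#' @param activity nonnegative square matrix.
#' @param mu a [mu_map()] (matching pixel size) or `NULL` for no attenuation.
#' @param psf a [psf_model()] or `NULL` to skip blurring.
#' @param geometry a [scan_geometry()].
#' @param total_counts expected total counts; 0 for noise-free native scale.
#' @param seed integer seed for the Poisson draw.
#' @param pixel_size_mm pixel size of `activity`.
#' @param poisson draw Poisson noise (ignored when `total_counts` is 0).
#' @export
simulate_emission <- function(activity, mu, psf, geometry, total_counts,
                              seed = 1, pixel_size_mm = NULL, poisson = TRUE) {
  if (any(activity < 0)) stop("activity must be nonnegative", call. = FALSE)
  if (is.null(pixel_size_mm)) {
    pixel_size_mm <- if (inherits(mu, "mu_map")) mu$pixel_size_mm else 1
  }
  blurred <- if (!is.null(psf)) apply_psf(activity, psf, pixel_size_mm)
             else activity
  proj <- forward_project(blurred, geometry, pixel_size_mm)$data
  if (!is.null(mu)) {
    stopifnot(inherits(mu, "mu_map"))
    proj <- proj * attenuation_factors(mu, geometry)$data
  }
  proj[proj < 0] <- 0
  if (total_counts > 0) {
    tot <- sum(proj)
    if (tot <= 0) return(sinogram(proj, "emission"))
    proj <- proj * (total_counts / tot)
    if (poisson)
      proj <- with_seed(seed, matrix(rpois(length(proj), proj), nrow(proj)))
  }
  sinogram(proj, "emission")
}

# ---- reconstruction -----------------------------------------------------

# Ramp (Ram-Lak) filter of sinogram rows, spatial-domain kernel evaluated
# via FFT; tau is the bin size in cm.
ramp_filter_rows <- function(data, bin_size_cm) {
  nb <- ncol(data)
  L <- 2^ceiling(log2(2 * nb))
  k <- c(0:(L / 2), (-(L / 2 - 1)):(-1))
  h <- numeric(L)
  h[k == 0] <- 1 / (4 * bin_size_cm^2)
  odd <- k %% 2 != 0
  h[odd] <- -1 / (pi^2 * k[odd]^2 * bin_size_cm^2)
  H <- fft(h)
  pad <- matrix(0, nrow(data), L)
  pad[, seq_len(nb)] <- data
  ft <- t(mvfft(t(pad)))
  ft <- sweep(ft, 2, H, `*`)
  q <- Re(t(mvfft(t(ft), inverse = TRUE))) / L
  q[, seq_len(nb), drop = FALSE] * bin_size_cm
}

#' Filtered back-projection reconstruction
#'
#' Ramp-filtered pixel-driven back-projection; recovers an image in the
#' native units of the projected activity. Negative pixels are clipped to
#' zero unless `clip_negative = FALSE` (the raw operator is linear in the
#' sinogram).
#'
#' @param sino an emission [sinogram()].
#' @param geometry a [scan_geometry()].
#' @param shape output side length in pixels.
#' @param pixel_size_mm output pixel size.
#' @param clip_negative clip negative pixels to 0 (default).
#' @export
reconstruct_fbp <- function(sino, geometry, shape, pixel_size_mm = 1,
                            clip_negative = TRUE) {
  stopifnot(inherits(sino, "sinogram"))
  if (nrow(sino$data) != geometry$n_angles || ncol(sino$data) != geometry$n_bins)
    stop("geometry error: sinogram shape does not match geometry", call. = FALSE)
  q <- ramp_filter_rows(sino$data, geometry$bin_size_mm / 10)
  n <- shape
  coord <- (seq_len(n) - (n + 1) / 2) * pixel_size_mm
  xg <- matrix(coord, n, n, byrow = TRUE)
  yg <- matrix(coord, n, n)
  ctr <- (geometry$n_bins + 1) / 2
  acc <- matrix(0, n, n)
  for (a in seq_len(geometry$n_angles)) {
    th <- geometry$angles[a]
    s <- (xg * cos(th) + yg * sin(th)) / geometry$bin_size_mm + ctr
    s0 <- floor(s); fs <- s - s0
    row <- q[a, ]
    v <- matrix(0, n, n)
    ok0 <- s0 >= 1 & s0 <= geometry$n_bins
    ok1 <- s0 + 1 >= 1 & s0 + 1 <= geometry$n_bins
    v[ok0] <- v[ok0] + (1 - fs[ok0]) * row[s0[ok0]]
    v[ok1] <- v[ok1] + fs[ok1] * row[s0[ok1] + 1]
    acc <- acc + v
  }
  out <- acc * pi / geometry$n_angles
  if (clip_negative) out[out < 0] <- 0
  out
}

#' Ordered-subsets expectation-maximization reconstruction
#'
#' Standard multiplicative OSEM update over angle-interleaved subsets; when
#' `att` is supplied its factors are folded into the system model so that
#' reconstruction and attenuation correction happen simultaneously.
#' Defaults (3 iterations, 15 subsets) mirror a clinical brain protocol.
#'
#' @param sino an emission [sinogram()].
#' @param geometry a [scan_geometry()].
#' @param shape output side length.
#' @param att optional attenuation-factor [sinogram()].
#' @param iterations full passes over all subsets (>= 1).
#' @param subsets number of subsets; must divide `n_angles`.
#' @param pixel_size_mm output pixel size.
#' @return nonnegative reconstruction matrix.
#' @export
reconstruct_osem <- function(sino, geometry, shape, att = NULL,
                             iterations = 3, subsets = 15,
                             pixel_size_mm = 1) {
  stopifnot(inherits(sino, "sinogram"), iterations >= 1)
  if (geometry$n_angles %% subsets != 0)
    stop("argument error: subsets must divide n_angles", call. = FALSE)
  if (!is.null(att)) {
    stopifnot(inherits(att, "sinogram"))
    if (att$kind != "attenuation_factor")
      stop("att must be an attenuation_factor sinogram", call. = FALSE)
  }
  a_dat <- if (is.null(att)) matrix(1, geometry$n_angles, geometry$n_bins)
           else att$data
  y <- sino$data
  n <- shape
  eps <- 1e-12
  subset_idx <- lapply(seq_len(subsets), function(i)
    seq(i, geometry$n_angles, by = subsets))
  sens <- lapply(subset_idx, function(ai)
    back_project_adjoint(a_dat, geometry, n, pixel_size_mm, ai))
  f <- matrix(1, n, n)
  for (it in seq_len(iterations)) {
    for (si in seq_len(subsets)) {
      ai <- subset_idx[[si]]
      proj <- forward_project(f, geometry, pixel_size_mm)$data[ai, , drop = FALSE]
      proj <- proj * a_dat[ai, , drop = FALSE]
      ratio <- matrix(0, geometry$n_angles, geometry$n_bins)
      ratio[ai, ] <- a_dat[ai, , drop = FALSE] *
        (y[ai, , drop = FALSE] / pmax(proj, eps))
      bp <- back_project_adjoint(ratio, geometry, n, pixel_size_mm, ai)
      f <- f * bp / pmax(sens[[si]], eps)
      f[sens[[si]] <= eps] <- 0
    }
  }
  f
}

# ---- mu-map rules and CTAC ---------------------------------------------

#' Segmentation thresholds for HU to mu conversion
#'
#' Piecewise-constant three-class rule: air below `air_upper_hu`, bone at
#' or above `bone_lower_hu`, soft tissue in between. The sign-corrected
#' default (`air_upper_hu = -200`) keeps brain tissue (~0-60 HU) in the
#' soft-tissue class; `printed_rule = TRUE` applies the printed clinical
#' rule with the air/soft boundary at +200 HU instead.
#'
#' @param air_upper_hu HU below which pixels are air.
#' @param bone_lower_hu HU at or above which pixels are bone.
#' @param mu_air,mu_soft,mu_bone class attenuation coefficients (cm^-1) at
#'   511 keV; defaults 0 / 0.096 / 0.151 are standard values.
#' @param printed_rule use the literally printed +200 HU air boundary.
#' @export
mu_map_thresholds <- function(air_upper_hu = -200, bone_lower_hu = 250,
                              mu_air = 0, mu_soft = 0.096, mu_bone = 0.151,
                              printed_rule = FALSE) {
  if (printed_rule) air_upper_hu <- 200
  if (!(air_upper_hu < bone_lower_hu))
    stop("air_upper_hu must be below bone_lower_hu", call. = FALSE)
  if (!(mu_air >= 0 && mu_air < mu_soft && mu_soft < mu_bone))
    stop("need 0 <= mu_air < mu_soft < mu_bone", call. = FALSE)
  structure(list(air_upper_hu = air_upper_hu, bone_lower_hu = bone_lower_hu,
                 mu_air = mu_air, mu_soft = mu_soft, mu_bone = mu_bone),
            class = "mu_map_thresholds")
}

#' Convert a CT image in HU to a 511-keV mu-map
#'
#' @param ct_hu CT matrix in Hounsfield units.
#' @param thresholds a [mu_map_thresholds()].
#' @param pixel_size_mm pixel size of `ct_hu`.
#' @return a [mu_map()].
#' @export
hu_to_mu <- function(ct_hu, thresholds = mu_map_thresholds(),
                     pixel_size_mm = 1) {
  stopifnot(inherits(thresholds, "mu_map_thresholds"))
  mu <- matrix(thresholds$mu_soft, nrow(ct_hu), ncol(ct_hu))
  mu[ct_hu < thresholds$air_upper_hu] <- thresholds$mu_air
  mu[ct_hu >= thresholds$bone_lower_hu] <- thresholds$mu_bone
  mu_map(mu, pixel_size_mm)
}

#' CT-based attenuation correction
#'
#' Produces the attenuation-corrected PET image that serves as the training
#' reference. For FBP the emission sinogram is divided by the attenuation
#' factors before reconstruction; for OSEM the factors enter the system
#' model.
#'
#' @param emission emission [sinogram()].
#' @param att attenuation-factor [sinogram()]; entries must be positive.
#' @param geometry a [scan_geometry()].
#' @param shape output side length.
#' @param recon `"fbp"` (default) or `"osem"`.
#' @param pixel_size_mm output pixel size.
#' @param iterations,subsets OSEM parameters.
#' @export
ctac_correct <- function(emission, att, geometry, shape, recon = c("fbp", "osem"),
                         pixel_size_mm = 1, iterations = 3, subsets = 15) {
  recon <- match.arg(recon)
  stopifnot(inherits(emission, "sinogram"), inherits(att, "sinogram"))
  if (!all(dim(emission$data) == dim(att$data)))
    stop("emission and attenuation sinogram shapes differ", call. = FALSE)
  if (any(att$data <= 0))
    stop("division-safety error: attenuation factors must be positive",
         call. = FALSE)
  if (recon == "fbp") {
    corrected <- sinogram(emission$data / att$data, "emission", validate = FALSE)
    reconstruct_fbp(corrected, geometry, shape, pixel_size_mm)
  } else {
    reconstruct_osem(emission, geometry, shape, att = att,
                     iterations = iterations, subsets = subsets,
                     pixel_size_mm = pixel_size_mm)
  }
}
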