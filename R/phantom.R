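# Digital head phantom generator: randomized, co-registered CT (HU),
# T1-like MRI and FDG-like activity slices with a region label map.

#' Region labels used by the phantom generator
#'
#' Integer codes of the label grid: background 0, soft (scalp) 1, skull 2,
#' ventricle 3, gray matter 4, white matter 5, striatum 6.
#'
#' @export
phantom_labels <- c(background = 0L, soft = 1L, skull = 2L, ventricle = 3L,
                    gray = 4L, white = 5L, striatum = 6L)

#' Phantom generator parameters
#'
#' Controls the randomized geometry and tissue properties of the synthetic
#' head slices. Defaults emulate an adult head on a 256 mm field of view:
#' an elliptical skull ring of high HU encloses a brain with a gray-matter
#' rim, white-matter core, paired ventricles and striata; activity contrast
#' is gray:white = 4:1 with a striatal boost; the MRI channel is assigned
#' per-region T1-like intensities with per-case jitter so that its scale is
#' not a fixed function of HU.
#'
#' @param head_radii_range range (mm) of the skull outer transverse
#'   semi-axis; the anteroposterior semi-axis is 1.15-1.30 times larger.
#' @param skull_thickness_range range (mm) of the skull ring thickness.
#' @param scalp_thickness_range range (mm) of the soft-tissue layer outside
#'   the skull.
#' @param ventricle_scale_range ventricle semi-axes as a fraction of the
#'   brain semi-axes.
#' @param gray_white_activity_ratio mean gray:white activity ratio
#'   (default 4, typical FDG contrast).
#' @param striatum_activity_boost striatal activity as a multiple of gray
#'   matter (default 1.25, i.e. 5 when gray is 4).
#' @param white_activity white-matter activity level (arbitrary units).
#' @param ventricle_activity ventricle (CSF) activity level.
#' @param activity_texture_sd relative s.d. of multiplicative activity
#'   texture noise.
#' @param hu_noise_sd s.d. (HU) of soft-tissue CT noise.
#' @param mri_contrast_map named vector of mean T1-like display intensities
#'   (0-255) per region.
#' @param mri_noise_sd s.d. of additive MRI noise (display units).
#' @return an object of class `phantom_params`.
#' @export
phantom_params <- function(head_radii_range = c(72, 82),
                           skull_thickness_range = c(4, 8),
                           scalp_thickness_range = c(4, 7),
                           ventricle_scale_range = c(0.10, 0.16),
                           gray_white_activity_ratio = 4,
                           striatum_activity_boost = 1.25,
                           white_activity = 1,
                           ventricle_activity = 0.2,
                           activity_texture_sd = 0.03,
                           hu_noise_sd = 10,
                           mri_contrast_map = c(background = 0, soft = 150,
                                                skull = 30, ventricle = 40,
                                                gray = 110, white = 160,
                                                striatum = 125),
                           mri_noise_sd = 8) {
  stopifnot(all(head_radii_range > 0), all(skull_thickness_range > 0),
            all(scalp_thickness_range > 0), all(ventricle_scale_range > 0),
            gray_white_activity_ratio > 1, striatum_activity_boost > 0,
            white_activity > 0, ventricle_activity >= 0)
  if (!all(names(phantom_labels) %in% names(mri_contrast_map)))
    stop("mri_contrast_map must name every region", call. = FALSE)
  structure(as.list(environment()), class = "phantom_params")
}

#' Generate one synthetic head phantom slice
#'
#' Draws a randomized head geometry (nested ellipses) and returns
#' co-registered CT, MRI and activity grids plus a label map. The skull is
#' a closed high-HU ring enclosing all brain tissue; activity is zero on
#' background, scalp and skull. Fully deterministic in `(params, shape,
#' seed)`.
#'
#' @param params a [phantom_params()] object.
#' @param shape grid side length (scalar) or `c(n, n)`; at least 64.
#' @param seed integer seed.
#' @param pixel_size_mm pixel size; default scales so the field of view is
#'   always 256 mm regardless of grid size.
#' @return an object of class `phantom_case` with elements `ct_hu`,
#'   `mri_t1`, `activity`, `labels`, `pixel_size_mm`, `case_id`, `seed`.
#' @examples
#' ph <- generate_head_phantom(shape = 128, seed = 1)
#' table(ph$labels)
#' @export
generate_head_phantom <- function(params = phantom_params(), shape = 256,
                                  seed = 1, pixel_size_mm = NULL,
                                  case_id = sprintf("case_seed%d", seed)) {
  stopifnot(inherits(params, "phantom_params"))
  if (length(shape) == 1L) shape <- c(shape, shape)
  if (shape[1] != shape[2]) stop("phantom grids must be square", call. = FALSE)
  n <- as.integer(shape[1])
  if (n < 64L) stop("shape too small: need at least 64x64 to contain a skull ring",
                    call. = FALSE)
  if (is.null(pixel_size_mm)) pixel_size_mm <- 256 / n

  fov_half <- n * pixel_size_mm / 2
  with_seed(seed, {
    a_out <- runif(1, params$head_radii_range[1], params$head_radii_range[2])
    b_out <- a_out * runif(1, 1.15, 1.30)
    t_sk  <- runif(1, params$skull_thickness_range[1], params$skull_thickness_range[2])
    t_sc  <- runif(1, params$scalp_thickness_range[1], params$scalp_thickness_range[2])
    # guarantee the rasterized ring is at least ~1.6 px thick so it stays closed
    t_sk <- max(t_sk, 1.6 * pixel_size_mm)
    if (b_out + t_sc + 2 * pixel_size_mm > fov_half)
      stop("shape too small to contain the skull ring at this pixel size",
           call. = FALSE)
    cx <- runif(1, -3, 3); cy <- runif(1, -3, 3)

    px <- pixel_size_mm
    coord <- (seq_len(n) - (n + 1) / 2) * px
    xg <- matrix(coord, n, n, byrow = TRUE)
    yg <- matrix(coord, n, n)

    scalp  <- ellipse_mask(yg, xg, cy, cx, b_out + t_sc, a_out + t_sc)
    sk_out <- ellipse_mask(yg, xg, cy, cx, b_out, a_out)
    brain  <- ellipse_mask(yg, xg, cy, cx, b_out - t_sk, a_out - t_sk)
    skull  <- sk_out & !brain

    a_br <- a_out - t_sk; b_br <- b_out - t_sk
    white <- ellipse_mask(yg, xg, cy, cx, 0.74 * b_br, 0.72 * a_br)
    vsc <- runif(1, params$ventricle_scale_range[1], params$ventricle_scale_range[2])
    vent <- ellipse_mask(yg, xg, cy - 0.05 * b_br, cx - 0.18 * a_br,
                         2.2 * vsc * b_br, vsc * a_br, theta = 0.15) |
            ellipse_mask(yg, xg, cy - 0.05 * b_br, cx + 0.18 * a_br,
                         2.2 * vsc * b_br, vsc * a_br, theta = -0.15)
    stri <- ellipse_mask(yg, xg, cy - 0.02 * b_br, cx - 0.38 * a_br,
                         0.22 * b_br, 0.10 * a_br, theta = 0.35) |
            ellipse_mask(yg, xg, cy - 0.02 * b_br, cx + 0.38 * a_br,
                         0.22 * b_br, 0.10 * a_br, theta = -0.35)
    vent <- vent & white
    stri <- stri & white & !vent

    lab <- matrix(phantom_labels[["background"]], n, n)
    lab[scalp] <- phantom_labels[["soft"]]
    lab[skull] <- phantom_labels[["skull"]]
    lab[brain] <- phantom_labels[["gray"]]
    lab[brain & white] <- phantom_labels[["white"]]
    lab[vent] <- phantom_labels[["ventricle"]]
    lab[stri] <- phantom_labels[["striatum"]]

    # CT channel (HU)
    hu_mean <- c(soft = 40, ventricle = 8, gray = 38, white = 28, striatum = 32)
    ct <- matrix(-1000, n, n)
    for (rg in names(hu_mean)) {
      m <- lab == phantom_labels[[rg]]
      ct[m] <- clamp(hu_mean[[rg]] + rnorm(sum(m), 0, params$hu_noise_sd), 0, 80)
    }
    msk <- lab == phantom_labels[["skull"]]
    ct[msk] <- clamp(rnorm(sum(msk), 1000, 100), 700, 2000)

    # MRI channel: per-case multiplicative jitter per region decouples the
    # MRI scale from HU across seeds
    mri <- matrix(0, n, n)
    for (rg in setdiff(names(phantom_labels), "background")) {
      m <- lab == phantom_labels[[rg]]
      jit <- exp(rnorm(1, 0, 0.12))
      mri[m] <- clamp(params$mri_contrast_map[[rg]] * jit +
                        rnorm(sum(m), 0, params$mri_noise_sd), 0, 255)
    }

    # Activity channel
    gray_act <- params$white_activity * params$gray_white_activity_ratio
    act_mean <- c(ventricle = params$ventricle_activity,
                  gray = gray_act,
                  white = params$white_activity,
                  striatum = gray_act * params$striatum_activity_boost)
    act <- matrix(0, n, n)
    for (rg in names(act_mean)) {
      m <- lab == phantom_labels[[rg]]
      act[m] <- pmax(act_mean[[rg]] *
                       (1 + rnorm(sum(m), 0, params$activity_texture_sd)), 0)
    }

    structure(list(ct_hu = ct, mri_t1 = mri, activity = act, labels = lab,
                   pixel_size_mm = px, case_id = case_id, seed = seed),
              class = "phantom_case")
  })
}

#' Generate an ordered cohort of phantoms
#'
#' Case seeds are derived from `(seed, index)` only, so the first `m` cases
#' of an `n`-case cohort equal the `m`-case cohort for the same seed.
#'
#' @param n number of cases (>= 1).
#' @inheritParams generate_head_phantom
#' @return a list of `phantom_case` objects with unique `case_id`s.
#' @export
generate_cohort <- function(n, params = phantom_params(), seed = 1,
                            shape = 256, pixel_size_mm = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("n must be a count >= 1", call. = FALSE)
  lapply(seq_len(n), function(i) {
    generate_head_phantom(params, shape, seed = derive_seed(seed, i),
                          pixel_size_mm = pixel_size_mm,
                          case_id = sprintf("case_%03d", i))
  })
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf("<phantom_case %s: %dx%d, %.2f mm/px, seed %d>\n",
              x$case_id, nrow(x$ct_hu), ncol(x$ct_hu), x$pixel_size_mm, x$seed))
  invisible(x)
}

# Masks commonly needed downstream
phantom_mask <- function(case, regions) {
  codes <- phantom_labels[regions]
  matrix(case$labels %in% codes, nrow(case$labels), ncol(case$labels))
}

#' Check the phantom type invariants
#'
#' Verifies grid-shape agreement, activity support, HU ranges and skull-ring
#' closure (every brain pixel enclosed by skull pixels along both grid axes).
#' Used by the test suite; exported because phantom consumers may want the
#' same audit on external data.
#'
#' @param case a `phantom_case`.
#' @return `TRUE` invisibly, or an error describing the violated invariant.
#' @export
validate_phantom <- function(case) {
  stopifnot(inherits(case, "phantom_case"))
  dims <- vapply(case[c("ct_hu", "mri_t1", "activity", "labels")], dim,
                 integer(2))
  if (!all(dims == dims[, 1])) stop("phantom grids differ in shape")
  lab <- case$labels
  if (any(case$activity < 0)) stop("negative activity")
  off <- lab %in% phantom_labels[c("background", "skull", "soft")]
  if (any(case$activity[off] != 0)) stop("activity outside brain tissue")
  if (any(case$ct_hu[lab == phantom_labels[["skull"]]] < 700))
    stop("skull HU below 700")
  softish <- lab %in% phantom_labels[c("soft", "ventricle", "gray", "white", "striatum")]
  if (any(case$ct_hu[softish] < 0 | case$ct_hu[softish] > 80))
    stop("soft-tissue HU outside [0, 80]")
  if (any(case$ct_hu[lab == phantom_labels[["background"]]] != -1000))
    stop("background HU must be -1000")
  # ring closure along both axes
  brain <- lab %in% phantom_labels[c("ventricle", "gray", "white", "striatum")]
  brain <- matrix(brain, nrow(lab))
  sk <- lab == phantom_labels[["skull"]]
  closed_1d <- function(b, s) {
    # every TRUE run of b must have a TRUE of s on both sides
    idx <- which(b)
    if (!length(idx)) return(TRUE)
    lo <- min(idx); hi <- max(idx)
    if (lo == 1L || hi == length(b)) return(FALSE)
    any(s[1:(lo - 1L)]) && any(s[(hi + 1L):length(b)])
  }
  for (i in seq_len(nrow(lab))) {
    if (!closed_1d(brain[i, ], sk[i, ])) stop("skull ring open along a row")
  }
  for (j in seq_len(ncol(lab))) {
    if (!closed_1d(brain[, j], sk[, j])) stop("skull ring open along a column")
  }
  invisible(TRUE)
}
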