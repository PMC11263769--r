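# Data preparation: per-case count normalization, CT display windowing,
# grid resampling, PNG round-trip with exact count restoration, and the
# 32-fold rotation/translation/flip augmentation.

#' Normalize image counts to the 0-255 display scale
#'
#' Per-case min-max normalization: `(X - X_min) / (X_max - X_min) * 255`.
#' The returned record holds the native-unit extremes so the mapping can be
#' inverted exactly. Records are computed per image/case, never pooled.
#'
#' @param image numeric matrix in native units; must not be constant.
#' @return list with `normalized` (matrix in \[0, 255\]) and `record`
#'   (class `normalization_record`, fields `x_min`, `x_max`).
#' @export
normalize_counts <- function(image) {
  x_min <- min(image); x_max <- max(image)
  if (x_max <= x_min)
    stop("normalization error: constant image has no count range", call. = FALSE)
  list(normalized = (image - x_min) / (x_max - x_min) * 255,
       record = structure(list(x_min = x_min, x_max = x_max),
                          class = "normalization_record"))
}

#' Invert count normalization
#'
#' Exact algebraic inverse of [normalize_counts()] on real-valued inputs.
#'
#' @param normalized matrix on the 0-255 scale.
#' @param record a `normalization_record`.
#' @export
denormalize <- function(normalized, record) {
  stopifnot(inherits(record, "normalization_record"))
  normalized / 255 * (record$x_max - record$x_min) + record$x_min
}

#' Window a CT image for display
#'
#' Window width 2500 HU, level 250 HU (a bone-emphasis setting): HU are
#' clamped to \[-1000, 1500\] and mapped affinely to \[0, 255\].
#'
#' @param ct_hu CT matrix in Hounsfield units.
#' @param ww,wl window width and level.
#' @export
window_ct <- function(ct_hu, ww = 2500, wl = 250) {
  lo <- wl - ww / 2; hi <- wl + ww / 2
  (clamp(ct_hu, lo, hi) - lo) / (hi - lo) * 255
}

#' Invert the CT display window
#'
#' Maps display values back to HU on the window support; information
#' outside the window was clamped and cannot be recovered.
#'
#' @param display matrix in \[0, 255\].
#' @inheritParams window_ct
#' @export
window_ct_inverse <- function(display, ww = 2500, wl = 250) {
  lo <- wl - ww / 2; hi <- wl + ww / 2
  display / 255 * (hi - lo) + lo
}

#' Resample an image onto a new grid
#'
#' Bilinear resampling that preserves the physical extent: source and
#' destination grids share a common centre and each destination pixel
#' centre is sampled at its physical location (edge-clamped).
#'
#' @param image source matrix.
#' @param src_pixel_mm source pixel size.
#' @param dst_shape destination side length (scalar) or `c(n, n)`.
#' @param dst_pixel_mm destination pixel size.
#' @export
resample_to_grid <- function(image, src_pixel_mm, dst_shape, dst_pixel_mm) {
  if (src_pixel_mm <= 0 || dst_pixel_mm <= 0)
    stop("argument error: pixel sizes must be positive", call. = FALSE)
  if (length(dst_shape) == 1L) dst_shape <- c(dst_shape, dst_shape)
  H <- nrow(image); W <- ncol(image)
  rows <- ((seq_len(dst_shape[1]) - (dst_shape[1] + 1) / 2) * dst_pixel_mm) /
    src_pixel_mm + (H + 1) / 2
  cols <- ((seq_len(dst_shape[2]) - (dst_shape[2] + 1) / 2) * dst_pixel_mm) /
    src_pixel_mm + (W + 1) / 2
  rows <- clamp(rows, 1, H); cols <- clamp(cols, 1, W)
  rg <- matrix(rows, dst_shape[1], dst_shape[2])
  cg <- matrix(cols, dst_shape[1], dst_shape[2], byrow = TRUE)
  matrix(bilinear_sample(image, as.vector(rg), as.vector(cg)),
         dst_shape[1], dst_shape[2])
}

#' Augmentation specification
#'
#' Four rotations (0/90/180/270 degrees), four integer pixel translations
#' including the identity, and an optional horizontal flip: 4 x 4 x 2 = 32
#' combinations. Rotations are exact multiples of 90 degrees so every
#' transform is lossless.
#'
#' @param translations list of 4 integer `(dy, dx)` offsets; must contain
#'   `(0, 0)`.
#' @export
augmentation_spec <- function(translations = list(c(0L, 0L), c(8L, 0L),
                                                  c(0L, 8L), c(8L, 8L))) {
  if (length(translations) != 4L)
    stop("exactly four translation offsets are required", call. = FALSE)
  if (!any(vapply(translations, function(t) all(t == 0L), logical(1))))
    stop("translations must include the identity (0, 0)", call. = FALSE)
  structure(list(rotations = c(0L, 90L, 180L, 270L),
                 translations = translations, flips = c(FALSE, TRUE)),
            class = "augmentation_spec")
}

rot90_mat <- function(m, times) {
  times <- times %% 4L
  for (i in seq_len(times)) m <- t(m)[ncol(m):1, , drop = FALSE]
  m
}

translate_mat <- function(m, dy, dx) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0, H, W)
  src_r <- seq_len(H) - dy; src_c <- seq_len(W) - dx
  ok_r <- src_r >= 1 & src_r <= H; ok_c <- src_c >= 1 & src_c <= W
  out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c], drop = FALSE]
  out
}

#' Expand one image 32-fold
#'
#' Applies every (rotation, translation, flip) combination in that order,
#' returning 32 images. The first combination is the identity and
#' reproduces the input bit-exactly; translations zero-fill vacated pixels.
#'
#' @param image square matrix.
#' @param spec an [augmentation_spec()].
#' @return list of 32 matrices, named by the transform applied.
#' @export
augment32 <- function(image, spec = augmentation_spec()) {
  if (!is.matrix(image) || nrow(image) != ncol(image))
    stop("argument error: augmentation requires a square image", call. = FALSE)
  stopifnot(inherits(spec, "augmentation_spec"))
  out <- vector("list", 32L)
  nm <- character(32L)
  i <- 0L
  for (fl in spec$flips) for (tr in spec$translations) for (rot in spec$rotations) {
    i <- i + 1L
    m <- rot90_mat(image, rot / 90L)
    m <- translate_mat(m, tr[1], tr[2])
    if (fl) m <- m[, ncol(m):1, drop = FALSE]
    out[[i]] <- m
    nm[i] <- sprintf("rot%d_t%d.%d_f%d", rot, tr[1], tr[2], as.integer(fl))
  }
  names(out) <- nm
  out
}

#' Encode a display image as 8-bit grayscale PNG
#'
#' Values are rounded to the nearest of the 256 display levels; the sidecar
#' normalization record (from [normalize_counts()]) allows native counts to
#' be restored to within half a quantization step.
#'
#' @param image matrix with values in \[0, 255\].
#' @return raw vector of PNG bytes.
#' @export
to_png <- function(image) {
  if (any(image < 0) || any(image > 255))
    stop("range error: PNG encoding requires values in [0, 255]", call. = FALSE)
  png::writePNG(round(image) / 255)
}

#' Decode an 8-bit grayscale PNG back to native units
#'
#' @param bytes raw PNG bytes from [to_png()].
#' @param record the sidecar `normalization_record`; if `NULL`, display
#'   units are returned unchanged with a warning.
#' @export
from_png <- function(bytes, record = NULL) {
  img <- png::readPNG(bytes) * 255
  if (length(dim(img)) == 3L) img <- img[, , 1]
  if (is.null(record)) {
    warning("no normalization record: returning display units")
    return(img)
  }
  denormalize(img, record)
}

#' Write a display image and its sidecar record to disk
#'
#' @param image matrix in \[0, 255\].
#' @param path PNG file path; the record is written to `<path>.json`.
#' @param record optional `normalization_record`.
#' @export
write_png_with_record <- function(image, path, record = NULL) {
  writeBin(to_png(image), path)
  if (!is.null(record))
    jsonlite::write_json(unclass(record), paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a display image written by [write_png_with_record()]
#'
#' @param path PNG file path.
#' @export
read_png_with_record <- function(path) {
  sidecar <- paste0(path, ".json")
  record <- NULL
  if (file.exists(sidecar)) {
    r <- jsonlite::read_json(sidecar)
    record <- structure(list(x_min = r$x_min, x_max = r$x_max),
                        class = "normalization_record")
  }
  from_png(readBin(path, "raw", file.info(path)$size), record)
}

# Head mask for ingesting external (clinical) slices: threshold plus
# largest connected component; phantoms are already bed-free.
head_mask <- function(image, threshold = NULL) {
  if (is.null(threshold)) threshold <- min(image) + 0.05 * diff(range(image))
  fg <- image > threshold
  lab <- label_components(fg)
  if (max(lab) == 0L) return(fg)
  keep <- which.max(tabulate(lab[lab > 0]))
  lab == keep
}

# 4-connected component labelling (two-pass with union-find), small and
# dependency-free.
label_components <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  parent <- integer(0)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  nxt <- 0L
  for (j in seq_len(W)) for (i in seq_len(H)) {
    if (!mask[i, j]) next
    up <- if (i > 1L) lab[i - 1L, j] else 0L
    lf <- if (j > 1L) lab[i, j - 1L] else 0L
    if (up == 0L && lf == 0L) {
      nxt <- nxt + 1L; parent[nxt] <- nxt; lab[i, j] <- nxt
    } else if (up != 0L && lf != 0L) {
      ru <- find(up); rl <- find(lf)
      parent[max(ru, rl)] <- min(ru, rl)
      lab[i, j] <- min(ru, rl)
    } else lab[i, j] <- max(up, lf)
  }
  if (nxt == 0L) return(lab)
  roots <- vapply(seq_len(nxt), find, integer(1))
  remap <- match(roots, sort(unique(roots)))
  lab[lab > 0L] <- remap[lab[lab > 0L]]
  lab
}
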