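#' Extraction parameters
#'
#' Controls how annotated lesions are turned into network-ready images:
#' the working magnification, the stromal border drawn around the lesion
#' bounding box, the patch side length, and the fill colour used outside the
#' image or around small lesions. Defaults follow the grading pipeline:
#' x10 working magnification, a 90 um border (to include tumour-associated
#' stroma), 512-px patches (about 450 um at x10), and white padding
#' (approximating slide background).
#'
#' @param target_magnification Working magnification (unitless, default 10).
#' @param border_um Border around the lesion bounding box, in microns.
#' @param patch_size Patch side length in pixels at the working magnification.
#' @param pad_value RGB triple in \[0, 255\] used for out-of-image fill.
#' @return Object of class `extraction_params`.
#' @export
extraction_params <- function(target_magnification = 10, border_um = 90,
                              patch_size = 512L, pad_value = c(255, 255, 255)) {
  stopifnot(target_magnification > 0, border_um >= 0, patch_size > 0,
            length(pad_value) == 3L, all(pad_value >= 0 & pad_value <= 255))
  structure(list(target_magnification = target_magnification,
                 border_um = border_um, patch_size = as.integer(patch_size),
                 pad_value = as.numeric(pad_value)),
            class = "extraction_params")
}

#' Pixel size at a target magnification
#'
#' Microns per pixel when working at `target_magnification`, given the scan
#' resolution at the base magnification. Multiplicative: halving the target
#' magnification doubles the pixel size. At the defaults (0.22 um/px at x40)
#' the x10 working resolution is 0.88 um/px, so a 512-px patch spans
#' 450.56 um.
#'
#' @param meta A [slide_meta()].
#' @param target_magnification Target magnification, in (0, base].
#' @return Microns per pixel at the target magnification.
#' @export
pixel_size_at <- function(meta, target_magnification) {
  if (!is.numeric(target_magnification) || target_magnification <= 0)
    stop("target magnification must be > 0")
  if (target_magnification > meta$base_magnification)
    stop("target magnification exceeds the base magnification")
  meta$base_resolution * meta$base_magnification / target_magnification
}

#' Lesion bounding box with stromal border
#'
#' Axis-aligned bounding rectangle of the annotation polygon, expanded on
#' all four sides by `round(border_um / base_resolution)` level-0 pixels
#' (round half up). Returned as a half-open rectangle in level-0 pixel
#' coordinates; it may extend beyond the image and is clipped (with padding)
#' only at extraction time.
#'
#' @param lesion A [lesion_annotation()].
#' @param meta A [slide_meta()].
#' @param params An [extraction_params()].
#' @return Named numeric vector `c(x0, y0, x1, y1)`, half-open.
#' @export
lesion_box <- function(lesion, meta, params = extraction_params()) {
  p <- lesion$polygon
  b <- round_half_up(params$border_um / meta$base_resolution)
  c(x0 = floor(min(p[, 1])) - b, y0 = floor(min(p[, 2])) - b,
    x1 = ceiling(max(p[, 1])) + b, y1 = ceiling(max(p[, 2])) + b)
}

#' Lesion image container
#'
#' An extracted RGB lesion crop at the working magnification. Pixels are
#' held as an 8-bit raw array (height x width x 3) to keep whole-cohort
#' memory small; use [lesion_pixels()] to obtain a numeric array.
#'
#' @param pixels Numeric (values in \[0, 255\]) or raw array, H x W x 3.
#' @param resolution Microns per pixel at the working magnification.
#' @param origin Level-0 pixel offset `c(x, y)` of the crop's top-left corner.
#' @param lesion_id Lesion identifier.
#' @return Object of class `lesion_image`.
#' @export
lesion_image <- function(pixels, resolution, origin = c(0, 0),
                         lesion_id = NA_character_) {
  d <- dim(pixels)
  if (length(d) != 3L || d[3] != 3L || d[1] < 1L || d[2] < 1L)
    stop("pixels must be a height x width x 3 array")
  if (!is.raw(pixels)) {
    pixels <- as.raw(clamp(round(pixels), 0, 255))
    dim(pixels) <- d
  }
  if (resolution <= 0) stop("resolution must be > 0")
  structure(list(pixels = pixels, resolution = resolution,
                 origin = as.numeric(origin), lesion_id = lesion_id),
            class = "lesion_image")
}

#' Numeric pixel array of a lesion image
#'
#' @param img A [lesion_image()].
#' @return Numeric array H x W x 3 with values in \[0, 255\].
#' @export
lesion_pixels <- function(img) {
  x <- as.numeric(as.integer(img$pixels))
  dim(x) <- dim(img$pixels)
  x
}

#' Extract a lesion image at the working magnification
#'
#' Crops the (half-open, level-0) box from the slide image, filling pixels
#' outside the image with `pad_value`, then downscales to the target
#' magnification by area averaging over square blocks of side
#' `base_magnification / target_magnification` (which must be a whole
#' number; it is 4 for the x40 -> x10 default). The crop is padded on the
#' right/bottom with `pad_value` to a block multiple before averaging.
#'
#' @param pixels Slide RGB array (H x W x 3, values in \[0, 255\]) at base
#'   magnification.
#' @param meta A [slide_meta()].
#' @param box Half-open level-0 rectangle `c(x0, y0, x1, y1)`, e.g. from
#'   [lesion_box()].
#' @param params An [extraction_params()].
#' @param lesion_id Identifier stored on the result.
#' @return A [lesion_image()].
#' @export
extract_lesion_image <- function(pixels, meta, box,
                                 params = extraction_params(),
                                 lesion_id = NA_character_) {
  d <- dim(pixels)
  x0 <- box[["x0"]]; y0 <- box[["y0"]]; x1 <- box[["x1"]]; y1 <- box[["y1"]]
  if (x1 <= x0 || y1 <= y0) stop("empty extraction box")
  if (x1 <= 0 || y1 <= 0 || x0 >= d[2] || y0 >= d[1])
    stop("extraction box lies entirely outside the image")
  w <- x1 - x0; h <- y1 - y0
  crop <- array(rep(params$pad_value, each = h * w), c(h, w, 3L))
  sx <- max(x0, 0); sy <- max(y0, 0)
  ex <- min(x1, d[2]); ey <- min(y1, d[1])
  crop[(sy - y0 + 1):(ey - y0), (sx - x0 + 1):(ex - x0), ] <-
    pixels[(sy + 1):ey, (sx + 1):ex, , drop = FALSE]
  f <- meta$base_magnification / params$target_magnification
  if (abs(f - round(f)) > 1e-9)
    stop("base/target magnification ratio must be a whole number")
  f <- as.integer(round(f))
  if (f > 1L) {
    crop <- pad_to_multiple(crop, f, params$pad_value)
    crop <- downscale_mean(crop, f)
  }
  lesion_image(crop, resolution = pixel_size_at(meta, params$target_magnification),
               origin = c(x0, y0), lesion_id = lesion_id)
}

# Pad right/bottom so both spatial dims are multiples of f.
pad_to_multiple <- function(x, f, pad_value) {
  d <- dim(x)
  nh <- ceiling(d[1] / f) * f; nw <- ceiling(d[2] / f) * f
  if (nh == d[1] && nw == d[2]) return(x)
  out <- array(rep(pad_value, each = nh * nw), c(nh, nw, 3L))
  out[seq_len(d[1]), seq_len(d[2]), ] <- x
  out
}

# Area-average downscaling by an integer factor, via block means.
downscale_mean <- function(x, f) {
  d <- dim(x)
  h <- d[1] %/% f; w <- d[2] %/% f; ch <- d[3]
  y <- colMeans(array(x, c(f, h, d[2] * ch)))        # pool rows -> h x (W*C)
  y <- aperm(array(y, c(h, d[2], ch)), c(2L, 1L, 3L)) # W x h x C
  y <- colMeans(array(y, c(f, w, h * ch)))            # pool cols -> w x (h*C)
  aperm(array(y, c(w, h, ch)), c(2L, 1L, 3L))
}

#' Sample a square patch from a lesion image
#'
#' Draws a `patch_size` square uniformly over all valid top-left positions.
#' A lesion image smaller than `patch_size` in either dimension is first
#' symmetrically padded to `patch_size` with `pad_value` (white by default,
#' approximating slide background). Uses the current R random stream, so it
#' is reproducible under `set.seed()`.
#'
#' @param img A [lesion_image()].
#' @param params An [extraction_params()].
#' @return List of class `patch`: `pixels` (numeric patch_size^2 x 3 array,
#'   values in \[0, 255\]), `lesion_id`, `offset` (0-based `c(x, y)` of the
#'   patch within the possibly padded lesion image).
#' @export
sample_patch <- function(img, params = extraction_params()) {
  ps <- params$patch_size
  d <- dim(img$pixels)
  i0 <- if (d[1] > ps) sample.int(d[1] - ps + 1L, 1L) else 1L
  j0 <- if (d[2] > ps) sample.int(d[2] - ps + 1L, 1L) else 1L
  rows <- i0:min(i0 + ps - 1L, d[1])
  cols <- j0:min(j0 + ps - 1L, d[2])
  sl <- img$pixels[rows, cols, , drop = FALSE]
  sl <- as.numeric(as.integer(sl))
  dim(sl) <- c(length(rows), length(cols), 3L)
  if (length(rows) == ps && length(cols) == ps) {
    px <- sl
  } else {
    px <- array(rep(params$pad_value, each = ps * ps), c(ps, ps, 3L))
    oi <- (ps - length(rows)) %/% 2L
    oj <- (ps - length(cols)) %/% 2L
    px[oi + seq_along(rows), oj + seq_along(cols), ] <- sl
  }
  structure(list(pixels = px, lesion_id = img$lesion_id,
                 offset = c(x = j0 - 1L, y = i0 - 1L)),
            class = "patch")
}

#' Augmentation parameters
#'
#' Training-time augmentation emulating stain-appearance variability plus
#' orientation invariance: independent horizontal/vertical flips, 90-degree
#' rotations, and hue/saturation/brightness/contrast jitter in HSV/RGB
#' space. Setting every probability to zero and every range to the identity
#' makes [augment()] the identity map. No augmentation is used at test time.
#'
#' @param hue Maximum absolute hue shift (fraction of the hue circle).
#' @param saturation Multiplicative saturation range `c(lo, hi)`.
#' @param brightness Multiplicative brightness range `c(lo, hi)`.
#' @param contrast Multiplicative contrast range `c(lo, hi)`.
#' @param flip_p Probability of each of the horizontal and vertical flips.
#' @param rot_p Probability of applying a rotation by k * 90 degrees
#'   (k uniform in 0..3).
#' @return Object of class `augment_params`.
#' @export
augment_params <- function(hue = 0.05, saturation = c(0.7, 1.3),
                           brightness = c(0.8, 1.2), contrast = c(0.8, 1.2),
                           flip_p = 0.5, rot_p = 1.0) {
  stopifnot(hue >= 0, length(saturation) == 2L, length(brightness) == 2L,
            length(contrast) == 2L, flip_p >= 0, flip_p <= 1,
            rot_p >= 0, rot_p <= 1)
  structure(list(hue = hue, saturation = saturation, brightness = brightness,
                 contrast = contrast, flip_p = flip_p, rot_p = rot_p),
            class = "augment_params")
}

#' Augment a patch
#'
#' Applies, each independently from the current R random stream: horizontal
#' and vertical flips, a rotation by a random multiple of 90 degrees, and
#' hue/saturation/brightness/contrast jitter. Output values are clipped to
#' \[0, 255\]; shape is preserved.
#'
#' @param patch A `patch` (see [sample_patch()]).
#' @param params An [augment_params()].
#' @return The augmented `patch`.
#' @export
augment <- function(patch, params = augment_params()) {
  x <- patch$pixels
  do_h <- stats::runif(1) < params$flip_p
  do_v <- stats::runif(1) < params$flip_p
  do_r <- stats::runif(1) < params$rot_p
  k <- if (do_r) sample.int(4L, 1L) - 1L else 0L
  dh <- if (params$hue > 0) stats::runif(1, -params$hue, params$hue) else 0
  fs <- stats::runif(1, params$saturation[1], params$saturation[2])
  fb <- stats::runif(1, params$brightness[1], params$brightness[2])
  fc <- stats::runif(1, params$contrast[1], params$contrast[2])
  x <- dihedral_transform(x, do_h, do_v, k)
  if (dh != 0 || fs != 1) x <- jitter_hsv(x, dh, fs)
  if (fb != 1) x <- x * fb
  if (fc != 1) {
    mu <- mean(x)
    x <- (x - mu) * fc + mu
  }
  patch$pixels <- clamp(x, 0, 255)
  patch
}

# Rotate an H x W x C array by 90 degrees counter-clockwise.
rot90_array <- function(x) {
  y <- aperm(x, c(2L, 1L, 3L))
  y[rev(seq_len(dim(y)[1])), , , drop = FALSE]
}

# Apply horizontal flip, vertical flip and k x 90-degree rotation as one
# composed dihedral transform (at most one transpose plus one indexed
# reversal, instead of up to five array copies).  The composition is
# computed on 2x2 signed permutation matrices; ops compose in the order
# hflip, vflip, then k rotations.
dihedral_transform <- function(x, do_h, do_v, k) {
  M <- diag(2)
  if (do_h) M <- diag(c(1, -1)) %*% M
  if (do_v) M <- diag(c(-1, 1)) %*% M
  R <- diag(c(-1, 1)) %*% matrix(c(0, 1, 1, 0), 2)  # rot90 = transpose + row flip
  for (i in seq_len(k)) M <- R %*% M
  swap <- M[1, 1] == 0
  fr <- sum(M[1, ]) < 0
  fc <- sum(M[2, ]) < 0
  if (swap) x <- aperm(x, c(2L, 1L, 3L))
  d <- dim(x)
  if (fr && fc) x[d[1]:1, d[2]:1, , drop = FALSE]
  else if (fr) x[d[1]:1, , , drop = FALSE]
  else if (fc) x[, d[2]:1, , drop = FALSE]
  else x
}

# Hue shift (wrapping) and saturation scaling in HSV space; x in [0, 255].
jitter_hsv <- function(x, dh, fs) {
  d <- dim(x)
  m <- t(matrix(x, ncol = 3L))           # 3 x n, channels as rows
  hsv <- grDevices::rgb2hsv(m, maxColorValue = 255)
  h <- (hsv[1L, ] + dh) %% 1
  s <- clamp(hsv[2L, ] * fs, 0, 1)
  v <- hsv[3L, ]
  rgb <- hsv_to_rgb_mat(h, s, v) * 255
  array(t(rgb), d)
}

# Vectorized HSV -> RGB (h, s, v in [0, 1]); returns 3 x n matrix in [0, 1].
# Branch-free "K-function" form: channel(n) = v * (1 - s * max(0, min(K, 4-K, 1)))
# with K = (n + 6h) mod 6.
hsv_to_rgb_mat <- function(h, s, v) {
  h6 <- h * 6
  vs <- v * s
  chan <- function(n) {
    k <- (n + h6) %% 6
    v - vs * pmax(0, pmin(k, 4 - k, 1))
  }
  rbind(chan(5), chan(3), chan(1))
}
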