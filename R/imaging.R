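# ---- ImageArray ------------------------------------------------------------

#' Construct an image array
#'
#' Images are stored as `height x width x 3` numeric arrays with 8-bit
#' channel values in `[0, 255]`, origin top-left, row-major semantics
#' (first index = row). Floating-point work buffers are used internally by
#' the processing functions; storage is always re-quantized to this range.
#'
#' @param values numeric array of dimension `c(h, w, 3)`, values in
#'   `[0, 255]`.
#' @return an `image_array` object.
#' @export
image_array <- function(values) {
  d <- dim(values)
  if (is.null(d) || length(d) != 3L || d[3] != 3L)
    stop("image_array: values must be an h x w x 3 array")
  if (d[1] < 1L || d[2] < 1L)
    stop("image_array: height and width must be >= 1")
  if (anyNA(values) || min(values) < 0 || max(values) > 255)
    stop("image_array: values must lie in [0, 255]")
  structure(values, class = "image_array")
}

#' @export
print.image_array <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<image_array %d x %d x %d, range [%g, %g]>\n",
              d[1], d[2], d[3], min(x), max(x)))
  invisible(x)
}

as_image_array <- function(x) {
  if (inherits(x, "image_array")) return(x)
  image_array(x)
}

#' Read an RGB image from PNG or JPEG
#'
#' @param path file path ending in .png, .jpg or .jpeg.
#' @return an [image_array()] with values in `[0, 255]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("read_image: file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png  = png::readPNG(path),
    jpg  = ,
    jpeg = jpeg::readJPEG(path),
    stop("read_image: unsupported extension '", ext, "'"))
  if (length(dim(raw)) == 2L) raw <- array(raw, c(dim(raw), 1L))
  if (dim(raw)[3] == 1L) raw <- raw[, , c(1L, 1L, 1L), drop = FALSE]
  if (dim(raw)[3] == 4L) raw <- raw[, , 1:3, drop = FALSE]
  image_array(round(raw * 255))
}

#' Write an image to PNG or JPEG
#'
#' @param img an [image_array()].
#' @param path output file path; format chosen from the extension.
#' @export
write_image <- function(img, path) {
  img <- as_image_array(img)
  x <- unclass(img) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png  = png::writePNG(x, path),
    jpg  = ,
    jpeg = jpeg::writeJPEG(x, path, quality = 0.95),
    stop("write_image: unsupported extension '", ext, "'"))
  invisible(path)
}

# ---- Bicubic interpolation -------------------------------------------------

#' Keys cubic interpolation kernel
#'
#' Piecewise-cubic convolution kernel `W(x)` used by bicubic resampling:
#' for `|x| <= 1`, `(a+2)|x|^3 - (a+3)|x|^2 + 1`; for `1 < |x| < 2`,
#' `a|x|^3 - 5a|x|^2 + 8a|x| - 4a`; zero beyond. The default sharpness
#' `a = -0.5` gives the Catmull-Rom member of the family, which is exact on
#' linear ramps and satisfies `W(0) = 1`, `W(1) = W(2) = 0`.
#'
#' @param x numeric vector of signed offsets in source-pixel units.
#' @param a kernel sharpness coefficient (default -0.5).
#' @return numeric vector of kernel weights.
#' @export
cubic_kernel_weight <- function(x, a = -0.5) {
  ax <- abs(x)
  w <- numeric(length(x))
  near <- ax <= 1
  mid  <- ax > 1 & ax < 2
  w[near] <- (a + 2) * ax[near]^3 - (a + 3) * ax[near]^2 + 1
  w[mid]  <- a * ax[mid]^3 - 5 * a * ax[mid]^2 + 8 * a * ax[mid] - 4 * a
  w
}

# Resampling matrix mapping n_in samples to n_out along one axis.
# Align-centers convention: output pixel i (1-based) samples source
# coordinate (i - 0.5) * n_in / n_out + 0.5; the 4 nearest source pixels
# contribute with Keys weights, source indices clamped at the borders.
# Rows sum to 1 (partition of unity is preserved under clamping).
bicubic_weight_matrix <- function(n_out, n_in, a = -0.5) {
  W <- matrix(0, n_out, n_in)
  scale <- n_in / n_out
  for (i in seq_len(n_out)) {
    src <- (i - 0.5) * scale + 0.5
    base <- floor(src)
    for (j in (base - 1):(base + 2)) {
      w <- cubic_kernel_weight(src - j, a)
      jc <- min(max(j, 1), n_in)
      W[i, jc] <- W[i, jc] + w
    }
  }
  W
}

#' Bicubic image resize
#'
#' Resamples an image to `target_h x target_w` with separable Keys cubic
#' convolution: every output pixel is a weighted average of its 16 nearest
#' source neighbors with weights `W(a - u) W(b - v)`. Pixel centers sit at
#' half-integer positions (align-centers); border source indices are
#' clamped. Output is re-quantized to 8-bit `[0, 255]`.
#'
#' @param img an [image_array()].
#' @param target_h,target_w output size in pixels, each >= 1.
#' @param a kernel sharpness coefficient (default -0.5).
#' @return resized [image_array()].
#' @export
resize_bicubic <- function(img, target_h, target_w, a = -0.5) {
  img <- as_image_array(img)
  if (target_h < 1 || target_w < 1)
    stop("resize_bicubic: target size must be >= 1")
  d <- dim(img)
  Wh <- bicubic_weight_matrix(target_h, d[1], a)
  Ww <- bicubic_weight_matrix(target_w, d[2], a)
  out <- array(0, c(target_h, target_w, 3L))
  for (ch in 1:3)
    out[, , ch] <- Wh %*% unclass(img)[, , ch] %*% t(Ww)
  image_array(pmin(pmax(round(out), 0), 255))
}

# ---- Augmentation primitives ----------------------------------------------

#' Rotate an image by 90 or 180 degrees
#'
#' Lossless pixel permutation. 90 degrees rotates clockwise and swaps
#' height and width; only 90 and 180 are supported.
#'
#' @param img an [image_array()].
#' @param degrees 90 or 180.
#' @return rotated [image_array()].
#' @export
rotate_image <- function(img, degrees) {
  img <- as_image_array(img)
  x <- unclass(img)
  h <- dim(x)[1]; w <- dim(x)[2]
  out <- switch(as.character(degrees),
    "90"  = aperm(x[h:1, , , drop = FALSE], c(2, 1, 3)),
    "180" = x[h:1, w:1, , drop = FALSE],
    stop("rotate_image: degrees must be 90 or 180"))
  image_array(out)
}

#' Mirror an image left-right
#'
#' @param img an [image_array()].
#' @return horizontally flipped [image_array()].
#' @export
mirror_image <- function(img) {
  img <- as_image_array(img)
  x <- unclass(img)
  image_array(x[, dim(x)[2]:1, , drop = FALSE])
}

#' Scale image brightness
#'
#' Multiplies every channel value by `factor`, rounds, and clamps to
#' `[0, 255]`. The augmentation set uses 0.9 (dim) and 1.5 (brighten).
#'
#' @param img an [image_array()].
#' @param factor positive brightness multiplier.
#' @return brightness-scaled [image_array()].
#' @export
scale_brightness <- function(img, factor) {
  if (factor <= 0) stop("scale_brightness: factor must be > 0")
  img <- as_image_array(img)
  image_array(pmin(pmax(round(unclass(img) * factor), 0), 255))
}

# 1-D normalized Gaussian taps for a centered odd-length kernel.
gaussian_taps <- function(sigma, kernel_size) {
  if (kernel_size %% 2 == 0) stop("gaussian_taps: kernel_size must be odd")
  if (sigma <= 0) stop("gaussian_taps: sigma must be > 0")
  k <- (kernel_size - 1) / 2
  t <- exp(-((-k:k)^2) / (2 * sigma^2))
  t / sum(t)
}

# Reflect out-of-range 1-based indices back into [1, n] (edge included:
# 0 -> 1, -1 -> 2, n+1 -> n).
reflect_index <- function(i, n) {
  i[i < 1] <- 1 - i[i < 1]
  i[i > n] <- 2 * n + 1 - i[i > n]
  i
}

#' Gaussian blur
#'
#' Separable discrete Gaussian convolution with reflected borders; the
#' kernel is normalized to sum 1 so constant images pass through
#' unchanged. Emulates the dust / windblown-sand degradation applied
#' during dataset expansion.
#'
#' @param img an [image_array()].
#' @param sigma Gaussian standard deviation in pixels (> 0).
#' @param kernel_size odd kernel width in pixels.
#' @return blurred [image_array()].
#' @export
gaussian_blur <- function(img, sigma = 1.0, kernel_size = 5L) {
  img <- as_image_array(img)
  taps <- gaussian_taps(sigma, kernel_size)
  k <- (kernel_size - 1) / 2
  x <- unclass(img)
  h <- dim(x)[1]; w <- dim(x)[2]
  for (ch in 1:3) {
    plane <- x[, , ch]
    tmp <- matrix(0, h, w)
    for (o in -k:k)
      tmp <- tmp + taps[o + k + 1] * plane[reflect_index(seq_len(h) + o, h), , drop = FALSE]
    out <- matrix(0, h, w)
    for (o in -k:k)
      out <- out + taps[o + k + 1] * tmp[, reflect_index(seq_len(w) + o, w), drop = FALSE]
    x[, , ch] <- out
  }
  image_array(pmin(pmax(round(x), 0), 255))
}

#' Additive Gaussian pixel noise
#'
#' Alternative degradation model, off by default in the augmentation set
#' (the standard set applies [gaussian_blur()]).
#'
#' @param img an [image_array()].
#' @param sigma noise standard deviation in intensity levels.
#' @return noisy [image_array()].
#' @export
gaussian_noise <- function(img, sigma = 8) {
  img <- as_image_array(img)
  x <- unclass(img) + stats::rnorm(length(img), sd = sigma)
  image_array(pmin(pmax(round(x), 0), 255))
}

# ---- Augmentation op set ---------------------------------------------------

#' The default six-transform augmentation set
#'
#' Rotation by 90 and 180 degrees, horizontal mirroring, brightness
#' dimming by 0.9, brightening by 1.5, and Gaussian blur. Applying all six
#' to a dataset multiplies its size by exactly 6.
#'
#' @param gauss_sigma,gauss_kernel Gaussian blur parameters.
#' @return named list of augment op descriptors (`name`, `factor`, `sigma`,
#'   `kernel_size` as applicable).
#' @export
default_augment_ops <- function(gauss_sigma = 1.0, gauss_kernel = 5L) {
  list(
    rot90    = list(name = "rot90"),
    rot180   = list(name = "rot180"),
    mirror   = list(name = "mirror"),
    dim      = list(name = "dim", factor = 0.9),
    brighten = list(name = "brighten", factor = 1.5),
    gauss    = list(name = "gauss", sigma = gauss_sigma,
                    kernel_size = gauss_kernel)
  )
}

#' Apply one augmentation op to an image
#'
#' @param img an [image_array()].
#' @param op one element of [default_augment_ops()], or its name.
#' @return transformed [image_array()].
#' @export
apply_augment <- function(img, op) {
  if (is.character(op)) op <- default_augment_ops()[[op]]
  if (is.null(op)) stop("apply_augment: unknown op")
  switch(op$name,
    rot90    = rotate_image(img, 90),
    rot180   = rotate_image(img, 180),
    mirror   = mirror_image(img),
    dim      = scale_brightness(img, op$factor %||% 0.9),
    brighten = scale_brightness(img, op$factor %||% 1.5),
    gauss    = gaussian_blur(img, op$sigma %||% 1.0, op$kernel_size %||% 5L),
    stop("apply_augment: unknown op '", op$name, "'"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
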