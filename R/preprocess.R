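#' @name preprocess
#' @title Image conditioning before pose detection
#' @description
#' Four conditioning steps applied to scene images before any pose
#' detection: brightening (gamma mapping), cropping to a region of
#' interest, denoising (box low-pass filter) and edge detection (Sobel
#' gradient magnitude). Images are plain numeric matrices (grayscale,
#' H x W) or arrays (H x W x 3), with intensities in \[0, 255\]; every
#' operation clips its output back to that range and uses symmetric
#' border reflection where a neighbourhood is needed.
NULL

.check_image <- function(image) {
  if (!(is.matrix(image) || (is.array(image) && length(dim(image)) == 3 &&
                             dim(image)[3] == 3))) {
    stop("image must be an H x W matrix or H x W x 3 array")
  }
  if (any(dim(image)[1:2] < 1)) stop("image dimensions must be >= 1")
  invisible(TRUE)
}

.clip255 <- function(x) pmin(pmax(x, 0), 255)

.per_channel <- function(image, f) {
  if (is.matrix(image)) return(f(image))
  out <- image
  for (ch in 1:3) out[, , ch] <- f(image[, , ch])
  out
}

# luminance as plain channel average
.to_gray <- function(image) {
  if (is.matrix(image)) image else (image[, , 1] + image[, , 2] + image[, , 3]) / 3
}

# symmetric (edge-inclusive) reflection padding by h pixels on each side
.pad_reflect <- function(m, h) {
  if (h == 0) return(m)
  nr <- nrow(m); nc <- ncol(m)
  if (h > nr || h > nc) stop("kernel larger than image")
  ri <- c(rev(seq_len(min(h, nr))), seq_len(nr),
          rev(seq_len(nr))[seq_len(min(h, nr))])
  ci <- c(rev(seq_len(min(h, nc))), seq_len(nc),
          rev(seq_len(nc))[seq_len(min(h, nc))])
  m[ri, ci, drop = FALSE]
}

# 2D convolution-style neighbourhood sum with reflective border,
# implemented as shifted-slab accumulation over the padded image
.shift_sum <- function(m, kernel) {
  kh <- (nrow(kernel) - 1) / 2
  kw <- (ncol(kernel) - 1) / 2
  h <- max(kh, kw)
  p <- .pad_reflect(m, h)
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nrow(kernel))) {
    for (j in seq_len(ncol(kernel))) {
      w <- kernel[i, j]
      if (w == 0) next
      out <- out + w * p[(i - 1 - kh + h) + seq_len(nr),
                         (j - 1 - kw + h) + seq_len(nc), drop = FALSE]
    }
  }
  out
}

#' Brighten an image with a gamma mapping
#'
#' Output intensity is `255 * (input/255)^(1/gamma)`; `gamma > 1` brightens,
#' `gamma = 1` is the identity.
#'
#' @param image Grayscale matrix or H x W x 3 array in \[0, 255\].
#' @param gamma Positive gamma value.
#' @return Image of the same shape.
#' @export
brighten <- function(image, gamma = 1.5) {
  .check_image(image)
  if (!is.numeric(gamma) || length(gamma) != 1 || gamma <= 0) {
    stop("gamma must be a single positive number")
  }
  .clip255(.per_channel(image, function(m) 255 * (m / 255)^(1 / gamma)))
}

#' Crop an image to a region of interest
#'
#' Coordinates are 0-based pixels, half-open on the max edges, so the
#' output has dimensions `(y_max - y_min) x (x_max - x_min)`.
#'
#' @param image Grayscale matrix or H x W x 3 array.
#' @param roi Numeric `c(x_min, y_min, x_max, y_max)`.
#' @return The cropped image.
#' @export
crop_image <- function(image, roi) {
  .check_image(image)
  stopifnot(length(roi) == 4)
  roi <- as.numeric(roi)
  h <- dim(image)[1]; w <- dim(image)[2]
  if (roi[1] < 0 || roi[2] < 0 || roi[3] > w || roi[4] > h ||
      roi[3] <= roi[1] || roi[4] <= roi[2]) {
    stop(sprintf("roi (%g,%g,%g,%g) degenerate or outside %dx%d image bounds",
                 roi[1], roi[2], roi[3], roi[4], w, h))
  }
  rows <- (roi[2] + 1):roi[4]
  cols <- (roi[1] + 1):roi[3]
  if (is.matrix(image)) image[rows, cols, drop = FALSE]
  else image[rows, cols, , drop = FALSE]
}

#' Denoise an image with a box (mean) low-pass filter
#'
#' Neighbourhood mean over a `kernel_size x kernel_size` window with
#' symmetric border reflection; `kernel_size = 1` is the identity. The
#' filter never increases per-image variance.
#'
#' @param image Grayscale matrix or H x W x 3 array.
#' @param kernel_size Odd window width in pixels (>= 1).
#' @return Filtered image of the same shape.
#' @export
denoise <- function(image, kernel_size = 3) {
  .check_image(image)
  if (kernel_size < 1 || kernel_size %% 2 == 0) {
    stop("kernel_size must be an odd integer >= 1")
  }
  if (kernel_size == 1) return(image)
  k <- matrix(1 / kernel_size^2, kernel_size, kernel_size)
  .clip255(.per_channel(image, function(m) .shift_sum(m, k)))
}

#' Sobel edge detection
#'
#' Gradient magnitude from the two 3x3 Sobel kernels, computed on the
#' luminance (channel average) of the input and rescaled so the strongest
#' edge maps to 255. A constant image maps to all zeros.
#'
#' @param image Grayscale matrix or H x W x 3 array.
#' @return Grayscale edge-magnitude matrix in \[0, 255\].
#' @export
edge_detect <- function(image) {
  .check_image(image)
  g <- .to_gray(image)
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  ky <- t(kx)
  gx <- .shift_sum(g, kx)
  gy <- .shift_sum(g, ky)
  mag <- sqrt(gx^2 + gy^2)
  mx <- max(mag)
  if (mx > 0) mag <- mag / mx * 255
  mag
}

#' Read a PNG image as a \[0, 255\] intensity grid
#'
#' @param path PNG file path.
#' @return Grayscale matrix or H x W x 3 array.
#' @export
read_image_png <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) {
    if (dim(a)[3] >= 3) a <- a[, , 1:3] else a <- a[, , 1]
  }
  a * 255
}

#' Write a \[0, 255\] intensity grid to PNG
#'
#' @param image Grayscale matrix or H x W x 3 array.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(image, path) {
  .check_image(image)
  png::writePNG(.clip255(image) / 255, path)
  invisible(path)
}
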