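#' @name image-containers
#' @title Image containers
#'
#' @description
#' Images are plain base-R arrays in row/column orientation: an RGB image is
#' an `H x W x 3` array of integers in 0..255, a grayscale image an `H x W`
#' integer matrix in 0..255, and a binary mask an `H x W` matrix of 0/1
#' with 1 marking lesion pixels.  The helpers below validate and coerce.
NULL

as_rgb_image <- function(img) {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L) {
    stop("an RGB image must be an H x W x 3 array")
  }
  if (any(is.na(img)) || any(img < 0) || any(img > 255)) {
    stop("RGB intensities must lie in 0..255")
  }
  storage.mode(img) <- "integer"
  img
}

as_gray_image <- function(img) {
  if (is.array(img) && length(dim(img)) == 3L) stop("expected a single-channel image")
  if (!is.matrix(img)) stop("a grayscale image must be an H x W matrix")
  if (any(is.na(img)) || any(img < 0) || any(img > 255)) {
    stop("grayscale intensities must lie in 0..255")
  }
  storage.mode(img) <- "integer"
  img
}

as_binary_mask <- function(mask) {
  if (!is.matrix(mask)) stop("a binary mask must be an H x W matrix")
  if (any(is.na(mask)) || !all(mask %in% c(0L, 1L))) {
    stop("a binary mask may contain only 0 and 1")
  }
  storage.mode(mask) <- "integer"
  mask
}

#' Select the red channel of an RGB dermoscopy image
#'
#' Lesions have the strongest contrast against skin in the red channel, so
#' the whole pipeline operates on channel 1, unchanged.
#'
#' @param img `H x W x 3` integer array in 0..255.
#' @return Grayscale `H x W` integer matrix.
#' @export
select_red_channel <- function(img) {
  img <- as_rgb_image(img)
  img[, , 1L]
}

# Reflect-pad a matrix by k rows/columns on every side.
pad_reflect <- function(m, k) {
  nr <- nrow(m); nc <- ncol(m)
  if (k >= nr || k >= nc) stop("padding exceeds image size")
  ri <- c(rev(seq_len(k) + 1L), seq_len(nr), nr - seq_len(k))
  ci <- c(rev(seq_len(k) + 1L), seq_len(nc), nc - seq_len(k))
  m[ri, ci, drop = FALSE]
}

#' Median filter with reflect padding
#'
#' Each output pixel is the median of its `kernel x kernel` neighborhood;
#' the image is reflect-padded so the same window applies at the edges.
#' Removes salt-and-pepper outliers smaller than half the kernel.  The
#' heavy lifting is done by `EBImage::medianFilter` (constant-time median),
#' which is exact for 8-bit data.
#'
#' @param img Grayscale `H x W` integer matrix in 0..255.
#' @param kernel Odd positive window size, at most `min(H, W)`; the
#'   default 25 matches the reference pipeline.
#' @return Filtered grayscale image of the same size.
#' @export
median_smooth <- function(img, kernel = 25L) {
  img <- as_gray_image(img)
  kernel <- as.integer(kernel)
  if (kernel < 1L || kernel %% 2L == 0L) stop("'kernel' must be an odd positive integer")
  if (kernel > min(dim(img))) stop("'kernel' must not exceed the image size")
  if (kernel == 1L) return(img)
  k <- (kernel - 1L) %/% 2L
  padded <- pad_reflect(img, k) / 255
  out <- EBImage::medianFilter(padded, size = k)
  out <- round(as.matrix(out) * 255)
  m <- out[(k + 1L):(k + nrow(img)), (k + 1L):(k + ncol(img)), drop = FALSE]
  storage.mode(m) <- "integer"
  m
}

#' Gaussian smoothing with reflect padding
#'
#' Convolution with a normalized 2-D Gaussian kernel (radius
#' `ceiling(3 sigma)`), rounded back to 8 bits.  The unit-sum kernel
#' preserves the mean intensity up to rounding.
#'
#' @param img Grayscale `H x W` integer matrix in 0..255.
#' @param sigma Positive standard deviation in pixels (default 5).
#' @return Smoothed grayscale image of the same size.
#' @export
gaussian_smooth <- function(img, sigma = 5) {
  img <- as_gray_image(img)
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma <= 0) {
    stop("'sigma' must be a positive number")
  }
  r <- as.integer(ceiling(3 * sigma))
  g1 <- stats::dnorm(seq(-r, r), sd = sigma)
  kern <- outer(g1, g1)
  kern <- kern / sum(kern)
  padded <- pad_reflect(img, r)
  out <- EBImage::filter2(padded / 255, kern)
  out <- round(as.matrix(out) * 255)
  m <- out[(r + 1L):(r + nrow(img)), (r + 1L):(r + ncol(img)), drop = FALSE]
  m[m < 0L] <- 0L; m[m > 255L] <- 255L
  storage.mode(m) <- "integer"
  m
}
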