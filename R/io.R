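#' Read an 8-bit image file
#'
#' PNG (via the png package) and TIFF (via the tiff package, if installed)
#' are read into the package's array convention: `H x W x 3` integers in
#' 0..255 for color, `H x W` for grayscale.
#'
#' @param path File path ending in .png, .tif or .tiff.
#' @return An integer array (RGB) or matrix (grayscale).
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop(sprintf("image file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) stop("the 'tiff' package is required for TIFF input")
      tiff::readTIFF(path)
    },
    stop(sprintf("unsupported image format '%s' for %s", ext, path))
  )
  img <- round(raw * 255)
  if (length(dim(img)) == 3L) {
    img <- img[, , seq_len(min(3L, dim(img)[3])), drop = FALSE]
    if (dim(img)[3] == 1L) img <- img[, , 1L]
  }
  if (length(dim(img)) == 3L && dim(img)[3] == 2L) img <- img[, , 1L]  # gray+alpha
  storage.mode(img) <- "integer"
  img
}

#' Write a binary mask as an 8-bit PNG
#'
#' Foreground (1) is written white (255), background black.
#'
#' @param mask Binary mask.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  mask <- as_binary_mask(mask)
  png::writePNG(mask * 1.0, path)
  invisible(path)
}

#' Write an RGB overlay of a mask contour on an image
#'
#' The mask boundary (foreground pixels with a background 4-neighbor) is
#' painted green on the original image.
#'
#' @param img `H x W x 3` RGB array.
#' @param mask Binary mask of matching size.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_overlay <- function(img, mask, path) {
  img <- as_rgb_image(img); mask <- as_binary_mask(mask)
  if (!identical(dim(img)[1:2], dim(mask))) stop("image and mask shapes differ")
  h <- nrow(mask); w <- ncol(mask)
  grown <- mask
  grown[-1, ] <- pmax(grown[-1, ], mask[-h, ])
  grown[-h, ] <- pmax(grown[-h, ], mask[-1, ])
  grown[, -1] <- pmax(grown[, -1], mask[, -w])
  grown[, -w] <- pmax(grown[, -w], mask[, -1])
  edge <- grown == 1L & mask == 0L
  out <- img / 255
  r <- out[, , 1L]; g <- out[, , 2L]; b <- out[, , 3L]
  r[edge] <- 0; g[edge] <- 1; b[edge] <- 0
  out[, , 1L] <- r; out[, , 2L] <- g; out[, , 3L] <- b
  png::writePNG(out, path)
  invisible(path)
}

#' Read a binary mask from an image file
#'
#' Any pixel above half intensity is foreground.
#'
#' @param path Image path.
#' @return Binary mask.
#' @export
read_mask <- function(path) {
  img <- read_image(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  m <- (img > 127L) * 1L
  mode(m) <- "integer"
  m
}
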