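#' Pipeline configuration
#'
#' @param median_kernel Odd positive median window (default 25).
#' @param gaussian_sigma Positive Gaussian sigma in pixels (default 5).
#' @param corner_mask_radius_fraction Radius of the circular field of view
#'   as a fraction of the half-diagonal (default 0.9): pixels outside the
#'   disc are treated as dermoscope corner shadow and forced to background.
#' @param lesion_polarity `"dark_lesion"` (default; lesion is the
#'   below-threshold class) or `"bright_lesion"`.
#' @param keep_largest_component Retain only the largest connected
#'   foreground component (default `TRUE`).
#' @return An object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(median_kernel = 25L, gaussian_sigma = 5,
                            corner_mask_radius_fraction = 0.9,
                            lesion_polarity = c("dark_lesion", "bright_lesion"),
                            keep_largest_component = TRUE) {
  median_kernel <- as.integer(median_kernel)
  if (median_kernel < 1L || median_kernel %% 2L == 0L) stop("'median_kernel' must be odd and positive")
  if (gaussian_sigma <= 0) stop("'gaussian_sigma' must be positive")
  if (corner_mask_radius_fraction <= 0 || corner_mask_radius_fraction > 1) {
    stop("'corner_mask_radius_fraction' must lie in (0, 1]")
  }
  structure(list(median_kernel = median_kernel,
                 gaussian_sigma = as.numeric(gaussian_sigma),
                 corner_mask_radius_fraction = as.numeric(corner_mask_radius_fraction),
                 lesion_polarity = match.arg(lesion_polarity),
                 keep_largest_component = isTRUE(keep_largest_component)),
            class = "pipeline_config")
}

#' Threshold a grayscale image into a lesion mask
#'
#' With `dark_lesion` polarity the lesion class is `intensity <= t`; with
#' `bright_lesion` it is `intensity > t`.  The classical white/black
#' rendering (above-threshold pixels white) is the complement of the
#' dark-lesion mask and is available from [render_bw()].
#'
#' @param img Grayscale `H x W` integer matrix.
#' @param t Integer threshold in 0..255.
#' @param polarity Lesion polarity (see [pipeline_config()]).
#' @return Binary mask, 1 = lesion.
#' @export
binarize <- function(img, t, polarity = c("dark_lesion", "bright_lesion")) {
  img <- as_gray_image(img)
  polarity <- match.arg(polarity)
  t <- as.integer(t)
  if (t < 0L || t > 255L) stop("threshold must lie in 0..255")
  m <- if (polarity == "dark_lesion") (img <= t) else (img > t)
  mode(m) <- "integer"
  m
}

#' Black/white rendering of a thresholded image
#'
#' Pixels above the threshold become white (255), others black (0).
#'
#' @inheritParams binarize
#' @return `H x W` integer matrix of 0/255.
#' @export
render_bw <- function(img, t) {
  img <- as_gray_image(img)
  m <- (img > as.integer(t)) * 255L
  mode(m) <- "integer"
  m
}

#' Zero a mask outside the circular field of view
#'
#' The dermoscope eyepiece leaves dark corners; everything outside the
#' centered disc of radius `radius_fraction * half_diagonal` is forced to
#' background.  Idempotent.
#'
#' @param mask Binary mask.
#' @param radius_fraction Disc radius as a fraction of the half-diagonal,
#'   in (0, 1].
#' @return Binary mask of the same size.
#' @export
apply_corner_mask <- function(mask, radius_fraction = 0.9) {
  mask <- as_binary_mask(mask)
  if (radius_fraction <= 0 || radius_fraction > 1) {
    stop("'radius_fraction' must lie in (0, 1]")
  }
  mask * fov_disc(nrow(mask), ncol(mask), radius_fraction)
}

# 0/1 matrix of the centered field-of-view disc.  The half-diagonal is
# measured center-to-corner-pixel-center and membership is strict, so a
# radius fraction of exactly 1 removes the corner pixels themselves.
fov_disc <- function(h, w, radius_fraction) {
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  r <- radius_fraction * sqrt(((h - 1) / 2)^2 + ((w - 1) / 2)^2)
  dy <- (seq_len(h) - cy)^2
  dx <- (seq_len(w) - cx)^2
  disc <- outer(dy, dx, "+") < r^2
  mode(disc) <- "integer"
  disc
}

#' Keep only the largest connected foreground component
#'
#' The lesion is a single adjacent region, so isolated fragments are
#' discarded.  Components are labeled 4-connected by `EBImage::bwlabel`;
#' for the default 8-connectivity, labels touching diagonally are merged by
#' union-find before areas are compared.  Ties in area are broken by raster
#' scan order (the component whose first pixel comes first).
#'
#' @param mask Binary mask.
#' @param connectivity 8 (default) or 4.
#' @return Binary mask containing one component (or empty if the input was
#'   empty).
#' @export
keep_largest_component <- function(mask, connectivity = 8L) {
  mask <- as_binary_mask(mask)
  if (!connectivity %in% c(4L, 8L)) stop("'connectivity' must be 4 or 8")
  if (!any(mask == 1L)) return(mask)
  lab <- label_components(mask, connectivity)
  areas <- tabulate(lab[lab > 0L])
  keep <- which(areas == max(areas))
  if (length(keep) > 1L) {
    # raster order: first foreground pixel (row-major) among tied labels
    first_pix <- vapply(keep, function(l) {
      idx <- which(lab == l)
      rr <- (idx - 1L) %% nrow(lab) + 1L
      cc <- (idx - 1L) %/% nrow(lab) + 1L
      min((rr - 1L) * ncol(lab) + cc)
    }, numeric(1))
    keep <- keep[which.min(first_pix)]
  }
  out <- (lab == keep) * 1L
  mode(out) <- "integer"
  out
}

# Connected-component labels; EBImage::bwlabel is 4-connected, diagonal
# adjacencies are merged with union-find to obtain 8-connectivity.
label_components <- function(mask, connectivity) {
  lab <- round(as.matrix(EBImage::bwlabel(mask)))
  storage.mode(lab) <- "integer"
  if (connectivity == 4L || max(lab) <= 1L) return(lab)
  n <- max(lab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i] <- parent[parent[i]]; i }
  union <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj) }
  h <- nrow(lab); w <- ncol(lab)
  for (shift in list(c(1L, 1L), c(1L, -1L))) {
    a <- lab[seq_len(h - 1L), , drop = FALSE]
    if (shift[2] == 1L) {
      a <- a[, seq_len(w - 1L), drop = FALSE]
      b <- lab[2L:h, 2L:w, drop = FALSE]
    } else {
      a <- a[, 2L:w, drop = FALSE]
      b <- lab[2L:h, seq_len(w - 1L), drop = FALSE]
    }
    pairs <- unique(cbind(as.vector(a), as.vector(b)))
    pairs <- pairs[pairs[, 1L] > 0L & pairs[, 2L] > 0L & pairs[, 1L] != pairs[, 2L], , drop = FALSE]
    if (nrow(pairs)) for (k in seq_len(nrow(pairs))) union(pairs[k, 1L], pairs[k, 2L])
  }
  roots <- vapply(seq_len(n), find, integer(1))
  relabel <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0L] <- relabel[lab[lab > 0L]]
  out
}

#' Does a mask touch the image border?
#'
#' A lesion mask reaching the border after corner masking indicates the
#' threshold swallowed surrounding skin, which is reported as a
#' segmentation failure.
#'
#' @param mask Binary mask.
#' @return `TRUE` iff any foreground pixel lies on the border.
#' @export
detect_edge_failure <- function(mask) {
  mask <- as_binary_mask(mask)
  any(mask[1L, ] == 1L) || any(mask[nrow(mask), ] == 1L) ||
    any(mask[, 1L] == 1L) || any(mask[, ncol(mask)] == 1L)
}

#' Segment a dermoscopic image
#'
#' End-to-end pipeline: red channel, median filter, Gaussian smoothing,
#' histogram, threshold search by the filled-function optimizer, lesion
#' binarization, field-of-view corner masking, largest-component selection,
#' and border-failure detection.  Deterministic given the configuration
#' seed.
#'
#' @param img `H x W x 3` RGB array in 0..255.
#' @param pcfg A [pipeline_config()] object.
#' @param p A [smoothing_params()] object.
#' @param cfg A [search_config()] object.
#' @return An object of class `"segmentation_result"`: a list with `mask`
#'   (binary), `threshold`, `fitness`, `failure_flag`, and the smoothed
#'   grayscale image `gray`.
#' @examples
#' \donttest{
#' im <- make_lesion_image(lesion_spec(seed = 1))
#' r <- segment_lesion(im$image)
#' r$threshold
#' }
#' @export
segment_lesion <- function(img, pcfg = pipeline_config(),
                           p = smoothing_params(), cfg = search_config()) {
  stopifnot(inherits(pcfg, "pipeline_config"))
  gray <- select_red_channel(img)
  gray <- median_smooth(gray, pcfg$median_kernel)
  gray <- gaussian_smooth(gray, pcfg$gaussian_sigma)
  h <- compute_histogram(gray)
  t <- optimize_threshold(h, p, cfg)
  mask <- binarize(gray, t, pcfg$lesion_polarity)
  mask <- apply_corner_mask(mask, pcfg$corner_mask_radius_fraction)
  if (pcfg$keep_largest_component) mask <- keep_largest_component(mask)
  structure(list(mask = mask, threshold = as.integer(t),
                 fitness = attr(t, "fitness"),
                 failure_flag = detect_edge_failure(mask),
                 gray = gray),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> threshold = %d, fitness = %.4f, lesion pixels = %d, failure: %s\n",
              x$threshold, x$fitness, sum(x$mask), x$failure_flag))
  invisible(x)
}
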