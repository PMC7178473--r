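#' Specification of a synthetic dermoscopy-like image
#'
#' The generator emulates the gross structure of a dermoscopic photograph:
#' a bright skin-toned background, a darker roughly elliptical lesion,
#' optional Gaussian sensor noise, salt-and-pepper corruption, dark
#' curvilinear hair artifacts, and corner vignetting from the dermoscope
#' field of view.  It does not attempt photorealism (no pigment networks,
#' bubbles, or color variegation).
#'
#' @param height,width Image size in pixels.
#' @param skin_level Mean red-channel intensity of skin (default 180).
#' @param lesion_level Mean red-channel intensity inside the lesion; must
#'   be below `skin_level` (default 90, i.e. contrast 90).
#' @param axes Ellipse semi-axes in pixels (length 2).
#' @param rotation Ellipse rotation in radians.
#' @param center Ellipse center (row, col); default image center.  The
#'   lesion must stay inside the field-of-view disc unless
#'   `edge_touching = TRUE`.
#' @param noise_sd Gaussian noise standard deviation (default 8).
#' @param salt_pepper_fraction Fraction of pixels replaced by 0/255
#'   impulses (default 0).
#' @param hair_count Number of dark hair-like polylines (default 0).
#' @param vignette Apply radial corner darkening (default `TRUE`).
#' @param edge_touching Allow (and by construction force) the lesion to
#'   overlap the image border, for failure-mode fixtures.
#' @param seed Integer seed; generation is fully deterministic given the
#'   spec.
#' @return An object of class `"lesion_spec"`.
#' @export
lesion_spec <- function(height = 192L, width = 192L, skin_level = 180,
                        lesion_level = 90, axes = c(45, 32), rotation = 0.5,
                        center = NULL, noise_sd = 8, salt_pepper_fraction = 0,
                        hair_count = 0L, vignette = TRUE,
                        edge_touching = FALSE, seed = 1L) {
  if (lesion_level >= skin_level) stop("'lesion_level' must be below 'skin_level'")
  if (salt_pepper_fraction < 0 || salt_pepper_fraction >= 1) {
    stop("'salt_pepper_fraction' must lie in [0, 1)")
  }
  if (noise_sd < 0) stop("'noise_sd' must be nonnegative")
  height <- as.integer(height); width <- as.integer(width)
  if (is.null(center)) {
    center <- if (edge_touching) c(height / 2, 2) else c((height + 1) / 2, (width + 1) / 2)
  }
  if (max(axes) * 2 > min(height, width)) stop("lesion larger than image")
  structure(list(height = height, width = width, skin_level = skin_level,
                 lesion_level = lesion_level, axes = as.numeric(axes),
                 rotation = as.numeric(rotation), center = as.numeric(center),
                 noise_sd = noise_sd, salt_pepper_fraction = salt_pepper_fraction,
                 hair_count = as.integer(hair_count), vignette = isTRUE(vignette),
                 edge_touching = isTRUE(edge_touching), seed = as.integer(seed)),
            class = "lesion_spec")
}

# Exact rasterized ellipse mask for a spec.
ellipse_mask <- function(spec) {
  rr <- matrix(seq_len(spec$height), spec$height, spec$width)
  cc <- matrix(seq_len(spec$width), spec$height, spec$width, byrow = TRUE)
  dy <- rr - spec$center[1]; dx <- cc - spec$center[2]
  co <- cos(spec$rotation); si <- sin(spec$rotation)
  u <- dy * co + dx * si
  v <- -dy * si + dx * co
  m <- (u / spec$axes[1])^2 + (v / spec$axes[2])^2 <= 1
  mode(m) <- "integer"
  m
}

#' Generate a synthetic lesion image with ground truth
#'
#' The truth mask is the exact rasterized ellipse; all degradations (noise,
#' impulses, hairs, vignetting) are applied to the image afterwards, so the
#' truth is uncontaminated.  The green and blue channels are scaled copies
#' of the red channel (0.55 and 0.40), giving a skin-like hue while keeping
#' the red channel authoritative.
#'
#' @param spec A [lesion_spec()].
#' @return A list with `image` (`H x W x 3` integer array) and `truth`
#'   (binary mask).
#' @examples
#' im <- make_lesion_image(lesion_spec(seed = 7))
#' dim(im$image); sum(im$truth)
#' @export
make_lesion_image <- function(spec) {
  stopifnot(inherits(spec, "lesion_spec"))
  truth <- ellipse_mask(spec)
  with_seed(spec$seed, {
    h <- spec$height; w <- spec$width
    red <- matrix(spec$skin_level, h, w)
    red[truth == 1L] <- spec$lesion_level
    if (spec$noise_sd > 0) red <- red + matrix(stats::rnorm(h * w, 0, spec$noise_sd), h, w)
    if (spec$hair_count > 0L) red <- draw_hairs(red, spec$hair_count)
    if (spec$vignette) {
      r0 <- 0.95 * min(h, w) / 2
      cy <- (h + 1) / 2; cx <- (w + 1) / 2
      d <- sqrt(outer((seq_len(h) - cy)^2, (seq_len(w) - cx)^2, "+"))
      fall <- pmax(0, d - r0) / (sqrt((h / 2)^2 + (w / 2)^2) - r0)
      red <- red * (1 - 0.5 * pmin(1, fall))
    }
    if (spec$salt_pepper_fraction > 0) {
      n <- round(spec$salt_pepper_fraction * h * w)
      idx <- sample.int(h * w, n)
      red[idx] <- sample(c(0, 255), n, replace = TRUE)
    }
    red <- round(pmin(pmax(red, 0), 255))
    img <- array(0L, dim = c(h, w, 3L))
    img[, , 1L] <- as.integer(red)
    img[, , 2L] <- as.integer(round(red * 0.55))
    img[, , 3L] <- as.integer(round(red * 0.40))
    list(image = img, truth = truth)
  })
}

# Dark anti-aliased-ish polylines of width 1-3 px emulating hairs.
draw_hairs <- function(red, count) {
  h <- nrow(red); w <- ncol(red)
  for (i in seq_len(count)) {
    y0 <- stats::runif(1, 1, h); x0 <- stats::runif(1, 1, w)
    ang <- stats::runif(1, 0, 2 * pi)
    curv <- stats::runif(1, -0.02, 0.02)
    len <- stats::runif(1, 0.4, 0.9) * min(h, w)
    width_px <- sample(1:3, 1)
    dark <- stats::runif(1, 20, 60)
    tt <- seq(0, len, by = 0.7)
    ys <- y0 + tt * sin(ang + curv * tt)
    xs <- x0 + tt * cos(ang + curv * tt)
    keep <- ys >= 1 & ys <= h & xs >= 1 & xs <= w
    ys <- ys[keep]; xs <- xs[keep]
    rad <- (width_px - 1) / 2
    for (j in seq_along(ys)) {
      r1 <- max(1L, floor(ys[j] - rad)); r2 <- min(h, ceiling(ys[j] + rad))
      c1 <- max(1L, floor(xs[j] - rad)); c2 <- min(w, ceiling(xs[j] + rad))
      red[r1:r2, c1:c2] <- pmin(red[r1:r2, c1:c2], dark)
    }
  }
  red
}

#' Seeded Gaussian-mixture intensity histogram
#'
#' Draws `n` intensities from the stated Gaussian mixture, clips to
#' `[0, 255]`, rounds, and bins.  The standard fixture for exercising the
#' threshold optimizer against the exhaustive oracle.
#'
#' @param means,sds,weights Mixture component parameters; `weights` must
#'   sum to 1.
#' @param n Number of draws (> 0).
#' @param seed Integer seed.
#' @return A [histogram256()] with total count `n`.
#' @export
make_mixture_histogram <- function(means, sds, weights, n, seed = 1L) {
  if (length(means) != length(sds) || length(means) != length(weights)) {
    stop("'means', 'sds' and 'weights' must have equal length")
  }
  if (abs(sum(weights) - 1) > 1e-9 || any(weights < 0)) {
    stop("'weights' must be nonnegative and sum to 1")
  }
  n <- as.integer(n)
  if (n <= 0L) stop("'n' must be positive")
  with_seed(seed, {
    comp <- sample.int(length(means), n, replace = TRUE, prob = weights)
    x <- stats::rnorm(n, means[comp], sds[comp])
    x <- pmin(pmax(round(x), 0), 255)
    histogram256(tabulate(x + 1L, nbins = 256L))
  })
}

#' Benchmark objectives with grid-oracle minima
#'
#' A fixed suite of multimodal box-constrained objectives used to validate
#' the global search: an asymmetric 1-D double well, the 1-D quartic
#' `d^4 - 4 d^2 + d` on `[-3, 3]`, the oscillatory `sin(3 d) + 0.1 d` on
#' `[0, 10]`, and a 2-D separable double well with linear tilt on
#' `[-2, 2]^2`.  Each oracle minimum is recomputed by dense grid scan at
#' suite-build time (spacing 1e-4 in 1-D, 1e-2 per axis in 2-D), never
#' hard-coded.
#'
#' @return A list of entries, each with `name`, `objective`
#'   ([objective()]), `oracle_minimum`, and `oracle_argmin`.
#' @examples
#' s <- benchmark_suite()
#' vapply(s, function(e) e$oracle_minimum, numeric(1))
#' @export
benchmark_suite <- function() {
  grid_oracle_1d <- function(fn, lo, hi, by = 1e-4) {
    g <- seq(lo, hi, by = by)
    v <- vapply(g, function(z) fn(z), numeric(1))
    i <- which.min(v)
    list(min = v[i], argmin = g[i])
  }
  entries <- list(
    list(name = "double_well_asym",
         fn = function(x) (x[1]^2 - 1)^2 + 0.1 * x[1],
         lo = -2, hi = 2, dims = 1L),
    list(name = "quartic_tilted",
         fn = function(x) x[1]^4 - 4 * x[1]^2 + x[1],
         lo = -3, hi = 3, dims = 1L),
    list(name = "sine_ramp",
         fn = function(x) sin(3 * x[1]) + 0.1 * x[1],
         lo = 0, hi = 10, dims = 1L),
    list(name = "double_well_2d",
         fn = function(x) (x[1]^2 - 1)^2 + (x[2]^2 - 1)^2 + 0.1 * x[1] + 0.1 * x[2],
         lo = -2, hi = 2, dims = 2L)
  )
  lapply(entries, function(e) {
    if (e$dims == 1L) {
      o <- grid_oracle_1d(function(z) e$fn(z), e$lo, e$hi)
      argmin <- o$argmin
    } else {
      g <- seq(e$lo, e$hi, by = 1e-2)
      u <- vapply(g, function(z) (z^2 - 1)^2 + 0.1 * z, numeric(1))
      grid2 <- outer(u, u, "+")  # vectorized evaluation of the separable form
      i <- arrayInd(which.min(grid2), dim(grid2))
      o <- list(min = grid2[i])
      argmin <- c(g[i[1]], g[i[2]])
    }
    list(name = e$name,
         objective = objective(e$fn, rep(e$lo, e$dims), rep(e$hi, e$dims), e$dims),
         oracle_minimum = o$min, oracle_argmin = argmin)
  })
}
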