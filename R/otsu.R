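#' Construct a 256-bin intensity histogram
#'
#' @param counts Integer vector of 256 nonnegative counts indexed by
#'   intensity 0..255 (element `i` holds the count of intensity `i - 1`).
#' @return An object of class `"histogram256"`.
#' @export
histogram256 <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) != 256L) stop("a histogram must have exactly 256 bins")
  if (any(is.na(counts)) || any(counts < 0)) stop("counts must be nonnegative")
  if (sum(counts) <= 0) stop("histogram must contain at least one pixel")
  structure(counts, class = "histogram256")
}

#' Histogram of an 8-bit grayscale image
#'
#' @param img Integer matrix with values in 0..255.
#' @return A [histogram256()] whose counts sum to the pixel count.
#' @export
compute_histogram <- function(img) {
  img <- as_gray_image(img)
  if (length(img) == 0L) stop("empty image")
  histogram256(tabulate(as.vector(img) + 1L, nbins = 256L))
}

# Class statistics for a split at threshold t (class 0: intensities <= t).
# Returns +Inf fitness when a class is empty so continuous sweeps of the
# optimizer never crash at the extremes.
otsu_class_stats <- function(h, t) {
  t <- as.integer(t)
  if (t < 0L || t > 255L) stop("threshold must lie in 0..255")
  p <- as.numeric(h) / sum(h)
  i <- 0:255
  idx0 <- i <= t
  w0 <- sum(p[idx0]); w1 <- 1 - w0
  if (w0 <= 0 || w1 <= 0) return(NULL)
  mu0 <- sum(i[idx0] * p[idx0]) / w0
  mu1 <- sum(i[!idx0] * p[!idx0]) / w1
  v0 <- sum((i[idx0] - mu0)^2 * p[idx0]) / w0
  v1 <- sum((i[!idx0] - mu1)^2 * p[!idx0]) / w1
  list(w0 = w0, w1 = w1, mu0 = mu0, mu1 = mu1, v0 = v0, v1 = v1)
}

#' Within-class variance of a histogram split
#'
#' The Otsu fitness `w0 * s0^2 + w1 * s1^2` from the normalized histogram
#' split at `t` (class 0: intensities `<= t`).  An empty class scores
#' `+Inf`, excluding that split from any argmin without raising.
#'
#' @param h A [histogram256()].
#' @param t Integer threshold in 0..255.
#' @return Numeric scalar fitness (possibly `+Inf`).
#' @export
within_class_variance <- function(h, t) {
  st <- otsu_class_stats(h, t)
  if (is.null(st)) return(Inf)
  st$w0 * st$v0 + st$w1 * st$v1
}

#' Between-class variance of a histogram split
#'
#' `w0 * w1 * (mu0 - mu1)^2`; complements [within_class_variance()] so that
#' the two sum to the total variance of the histogram at every split.
#'
#' @inheritParams within_class_variance
#' @return Numeric scalar (possibly `+Inf` for an empty class).
#' @export
between_class_variance <- function(h, t) {
  st <- otsu_class_stats(h, t)
  if (is.null(st)) return(Inf)
  st$w0 * st$w1 * (st$mu0 - st$mu1)^2
}

#' Exhaustive Otsu threshold
#'
#' Scans every split `t` in 0..254 and returns the argmin of the
#' within-class variance, ties broken toward the smallest `t`.  Serves as
#' the oracle against which the optimizer-driven threshold is validated.
#'
#' @param h A [histogram256()].
#' @return Integer threshold.
#' @export
brute_force_threshold <- function(h) {
  check_nondegenerate(h)
  v <- vapply(0:254, function(t) within_class_variance(h, t), numeric(1))
  as.integer(which.min(v) - 1L)  # which.min takes the first (smallest t) on ties
}

check_nondegenerate <- function(h) {
  if (sum(as.numeric(h) > 0) < 2L) {
    stop(degenerate_histogram_error("histogram has fewer than two distinct intensities"))
  }
  invisible(h)
}

degenerate_histogram_error <- function(msg) {
  structure(class = c("dermofill_degenerate_histogram", "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}

#' Otsu threshold by filled-function global search
#'
#' Minimizes the continuous relaxation `g(delta) =` within-class variance at
#' `t = round(25.5 * delta)` over `delta` in `[lower, upper]` (default
#' `[0, 10]`, so the affine factor 25.5 maps the search interval onto the
#' intensity range) using [global_minimize_1d()].  A final integer polish
#' walks to the smallest neighboring threshold of equal or lower fitness,
#' implementing the smallest-`t` tie-break convention.
#'
#' @param h A [histogram256()].
#' @param p A [smoothing_params()] object.
#' @param cfg A [search_config()] object; `lower`/`upper` give the search
#'   interval.
#' @return An integer threshold in 0..254 with attributes `fitness` (the
#'   within-class variance at the threshold) and `converged`.
#' @examples
#' h <- make_mixture_histogram(c(80, 170), c(10, 10), c(0.5, 0.5),
#'                             n = 4000, seed = 1)
#' optimize_threshold(h)
#' @export
optimize_threshold <- function(h, p = smoothing_params(), cfg = search_config()) {
  check_nondegenerate(h)
  scale <- 255 / (cfg$upper - cfg$lower)
  v <- rep(NA_real_, 255L)  # memo of integer-threshold fitness
  g_int <- function(t) {
    t <- min(max(t, 0L), 254L)
    if (is.na(v[t + 1L])) v[t + 1L] <<- within_class_variance(h, t)
    v[t + 1L]
  }
  g <- function(delta) g_int(as.integer(round((delta - cfg$lower) * scale)))
  r <- global_minimize_1d(g, c(cfg$lower, cfg$upper), p, cfg)
  t <- as.integer(round((r$delta - cfg$lower) * scale))
  t <- min(max(t, 0L), 254L)
  # integer polish: descend to the smallest equal-or-better neighbor
  repeat {
    moved <- FALSE
    if (t > 0L && g_int(t - 1L) <= g_int(t)) { t <- t - 1L; moved <- TRUE }
    else if (t < 254L && g_int(t + 1L) < g_int(t)) { t <- t + 1L; moved <- TRUE }
    if (!moved) break
  }
  structure(t, fitness = g_int(t), converged = r$converged)
}
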