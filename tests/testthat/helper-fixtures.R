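# Shared fixtures: everything is generated in code, nothing is stored.

# Seeded Gaussian-mixture histogram case used by the oracle-equivalence
# tests: alternates two- and three-component mixtures of varied separation.
mixture_case <- function(i) {
  k <- 2L + (i %% 2L)
  set.seed(i)
  means <- sort(runif(k, 30, 225))
  sds <- runif(k, 6, 20)
  w <- runif(k, 0.5, 1.5); w <- w / sum(w)
  list(h = make_mixture_histogram(means, sds, w, n = 4000, seed = 1000L + i),
       means = means)
}

# Random tilted quartic on [-2, 2]; always coercive with multiple basins
# for most draws.
rand_quartic <- function(seed) {
  set.seed(seed)
  c4 <- runif(1, 0.5, 2); c3 <- runif(1, -1, 1)
  c2 <- runif(1, -3, 0); c1 <- runif(1, -1, 1)
  function(d) c4 * d^4 + c3 * d^3 + c2 * d^2 + c1 * d
}

# All strict local minima of a 1-D function by dense-grid sign change of
# finite differences, refined with optimize().
find_local_minima_1d <- function(fn, lo, hi, n = 20001L) {
  g <- seq(lo, hi, length.out = n)
  v <- vapply(g, fn, numeric(1))
  dv <- diff(v)
  idx <- which(dv[-length(dv)] < 0 & dv[-1] > 0) + 1L
  lapply(idx, function(i) {
    o <- stats::optimize(fn, lower = g[max(1L, i - 2L)], upper = g[min(n, i + 2L)],
                         tol = 1e-10)
    list(x = o$minimum, f = o$objective)
  })
}

# Two-region test image: dark rectangle on bright background.
two_region_image <- function(h = 60L, w = 60L, dark = 60L, bright = 200L) {
  img <- matrix(bright, h, w)
  img[20:40, 20:40] <- dark
  storage.mode(img) <- "integer"
  img
}

# Logical matrix marking pixels of two_region_image() that are at least 6 px
# away from the rectangle boundary (rows/cols 20 and 40).
region_interior <- function(h = 60L, w = 60L, band = 6L) {
  interior <- matrix(TRUE, h, w)
  for (b in c(20L, 40L)) {
    interior[max(1, b - band):min(h, b + band), ] <- FALSE
    interior[, max(1, b - band):min(w, b + band)] <- FALSE
  }
  interior
}

# Dice between two masks, direct formula (independent of the metrics module).
plain_dice <- function(a, b) 2 * sum(a == 1 & b == 1) / (sum(a) + sum(b))

default_params <- function() smoothing_params()
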