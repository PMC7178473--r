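test_that("histogram construction counts every pixel once", {
  img <- matrix(c(0L, 0L, 255L, 255L), 2, 2)
  h <- compute_histogram(img)
  expect_identical(as.numeric(h)[c(1, 256)], c(2, 2))
  expect_identical(sum(as.numeric(h)), 4)

  h7 <- compute_histogram(matrix(7L, 10, 10))
  expect_identical(as.numeric(h7)[8], 100)

  set.seed(5)
  img2 <- matrix(sample(0:255, 300, replace = TRUE), 15, 20)
  expect_identical(sum(as.numeric(compute_histogram(img2))), 300)
  expect_error(histogram256(rep(0, 256)), "at least one pixel")
  expect_error(histogram256(1:10), "256 bins")
})

test_that("within-class variance matches a direct two-pass recomputation", {
  two_delta <- histogram256(replace(rep(0, 256), c(61, 181), c(40, 60)))
  expect_identical(within_class_variance(two_delta, 100), 0)
  expect_identical(within_class_variance(two_delta, 200), Inf)  # empty upper class

  set.seed(8)
  h <- histogram256(rpois(256, 5))
  xs <- rep(0:255, times = as.numeric(h))
  for (t in c(0, 31, 127, 200, 254)) {
    lo <- xs[xs <= t]; hi <- xs[xs > t]
    pop_var <- function(v) mean((v - mean(v))^2)
    direct <- length(lo) / length(xs) * pop_var(lo) +
              length(hi) / length(xs) * pop_var(hi)
    expect_equal(within_class_variance(h, t), direct, tolerance = 1e-10)
  }
})

test_that("within- and between-class variance sum to the total variance", {
  two_delta <- histogram256(replace(rep(0, 256), c(61, 181), c(40, 60)))
  w0 <- 0.4; w1 <- 0.6
  expect_equal(between_class_variance(two_delta, 100), w0 * w1 * (180 - 60)^2)

  set.seed(9)
  for (i in 1:5) {
    h <- histogram256(rpois(256, 3) + 1)
    xs <- rep(0:255, times = as.numeric(h))
    total <- mean((xs - mean(xs))^2)
    for (t in c(10, 100, 180)) {
      expect_equal(within_class_variance(h, t) + between_class_variance(h, t),
                   total, tolerance = 1e-9)
    }
  }
})

test_that("exhaustive threshold takes the smallest optimal split", {
  two_delta <- histogram256(replace(rep(0, 256), c(61, 181), c(40, 60)))
  expect_identical(brute_force_threshold(two_delta), 60L)

  h <- make_mixture_histogram(c(80, 170), c(10, 10), c(0.5, 0.5), 5000, seed = 2)
  t <- brute_force_threshold(h)
  expect_gt(t, 80); expect_lt(t, 170)

  # mirror symmetry up to tie sets: reversed histogram's optimum has the
  # same fitness as the mirrored split
  hr <- histogram256(rev(as.numeric(h)))
  tr <- brute_force_threshold(hr)
  expect_equal(within_class_variance(hr, tr),
               within_class_variance(hr, 254 - t), tolerance = 1e-9)

  expect_error(brute_force_threshold(histogram256(replace(rep(0, 256), 50, 10))),
               class = "dermofill_degenerate_histogram")
})

test_that("optimizer-driven threshold equals the exhaustive oracle", {
  expect_identical(as.integer(optimize_threshold(
    histogram256(replace(rep(0, 256), c(61, 181), c(40, 60))))), 60L)
  for (i in seq(1, 60, by = 2)) {
    case <- mixture_case(i)
    expect_identical(as.integer(optimize_threshold(case$h, cfg = search_config(seed = i))),
                     brute_force_threshold(case$h))
  }
  expect_error(optimize_threshold(histogram256(replace(rep(0, 256), 9, 5))),
               class = "dermofill_degenerate_histogram")
})

test_that("threshold is shift-equivariant and count-scale invariant", {
  h <- make_mixture_histogram(c(70, 150), c(8, 12), c(0.4, 0.6), 4000, seed = 3)
  counts <- as.numeric(h)
  expect_identical(sum(counts[1:31]), 0)   # room to shift without clipping
  expect_identical(sum(counts[227:256]), 0)
  t0 <- brute_force_threshold(h)
  shifted <- histogram256(c(rep(0, 30), counts)[1:256])
  expect_identical(brute_force_threshold(shifted), t0 + 30L)
  scaled <- histogram256(counts * 7)
  expect_identical(brute_force_threshold(scaled), t0)
})

test_that("package threshold agrees with an independent Otsu implementation", {
  # EBImage maximizes between-class variance over its own binning of the
  # unit interval; on tie plateaus (empty valley bins) or overlapping
  # components the two conventions may name different splits of equal or
  # near-equal fitness, so agreement is checked on the fitness scale.
  for (i in c(2, 11, 24)) {
    case <- mixture_case(i)
    img01 <- rep(0:255, times = as.numeric(case$h)) / 255
    m <- EBImage::Image(matrix(img01, nrow = 80))
    t_eb <- round(EBImage::otsu(m, range = c(0, 1), levels = 256) * 255)
    t_bf <- brute_force_threshold(case$h)
    v_eb <- within_class_variance(case$h, t_eb)
    v_bf <- within_class_variance(case$h, t_bf)
    expect_lte(v_bf, v_eb)                  # the exhaustive scan is optimal
    expect_lte(v_eb - v_bf, 0.005 * v_bf)   # and the two agree in fitness
  }
})
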