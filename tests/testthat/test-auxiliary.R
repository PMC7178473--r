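test_that("elimination function caps the objective at the incumbent level", {
  f <- objective(function(x) x[1]^2, lower = -5, upper = 5)
  rec <- minimizer_record(1, 1)
  expect_identical(elimination_value(f, 2, rec), 1)
  expect_identical(elimination_value(f, 0.5, rec), 0.25)

  # identity with the indicator form for a random polynomial
  set.seed(42)
  co <- rnorm(4)
  g <- objective(function(x) co[1] + co[2] * x[1] + co[3] * x[1]^2 + co[4] * x[1]^4,
                 lower = -3, upper = 3)
  xs <- runif(100, -3, 3)
  recg <- minimizer_record(0.7, eval_objective(g, 0.7))
  for (x in xs) {
    fx <- eval_objective(g, x)
    indicator_form <- recg$f_star - (recg$f_star - fx) * indicator_psi(fx - recg$f_star)
    expect_identical(elimination_value(g, x, recg), indicator_form)
  }
})

test_that("objective evaluation rejects out-of-box and non-finite values", {
  f <- objective(function(x) if (x[1] > 1) NaN else x[1], lower = -2, upper = 2)
  expect_error(eval_objective(f, 3), "outside the box")
  expect_error(eval_objective(f, 1.5), "non-finite")
  expect_error(objective(function(x) x, lower = 2, upper = 1), "lower < upper")
})

test_that("lower-region indicator is the strict-inequality membership", {
  expect_identical(indicator_psi(-0.3), 1)
  expect_identical(indicator_psi(0), 0)
  expect_identical(indicator_psi(2.5), 0)
  expect_error(indicator_psi(NA_real_))
})

test_that("bridge branches are continuous at all three knots", {
  for (p in list(smoothing_params(), smoothing_params(0.5, 0.2, 1),
                 smoothing_params(2, 0.8, 1))) {
    expect_equal(y_branches(-p$b2 / p$b1, p)$y1, 1, tolerance = 1e-6)
    expect_equal(y_branches(p$b2, p)$y2, 0, tolerance = 1e-6)
    br0 <- y_branches(0, p)
    expect_equal(br0$y1, br0$y2, tolerance = 1e-6)
  }
})

test_that("smoothed indicator dispatches piecewise, stays in [0,1], and decreases", {
  p <- smoothing_params()
  expect_identical(psi_tilde(p$b2 + 0.1, p), 0)
  expect_identical(psi_tilde(-p$b2 / p$b1 - 0.1, p), 1)
  tau <- seq(-2 * p$b2 / p$b1, 2 * p$b2, length.out = 4001)
  ps <- psi_tilde(tau, p)
  expect_true(all(ps >= 0 & ps <= 1))
  expect_true(all(diff(ps) <= 1e-12))
  # equals the exact indicator outside the smoothing window
  outside <- tau <= -p$b2 / p$b1 | tau > p$b2
  expect_identical(ps[outside], indicator_psi(tau[outside]))
})

test_that("smoothed elimination collapses exactly outside the window", {
  p <- smoothing_params()
  f <- objective(function(x) x[1]^2, lower = -10, upper = 10)
  rec <- minimizer_record(1, 1)
  # tau > b2: value is exactly f_star
  expect_identical(smoothed_gamma(f, 3, rec, p), 1)
  # tau <= -b2/b1 (here tau = -25 <= -4): value is exactly f(x)
  rec_hi <- minimizer_record(5, 25)
  expect_identical(smoothed_gamma(f, 0, rec_hi, p), 0)
})

test_that("smoothing gap is nonnegative and below the selected envelope", {
  p <- smoothing_params()
  f <- objective(function(x) x[1]^2, lower = -10, upper = 10)
  rec <- minimizer_record(1, 1)
  bound <- smoothing_gap_bound(p, case3 = "product")
  set.seed(7)
  for (x in runif(200, -10, 10)) {
    gap <- smoothed_gamma(f, x, rec, p) - elimination_value(f, x, rec)
    expect_gte(gap, -1e-9)
    expect_lte(gap, bound)
  }
})

test_that("escape kernel is positive, decreasing, and anchored at 1", {
  expect_identical(escape_zeta(0), 1)
  expect_identical(escape_zeta(1), 0.5)
  set.seed(3)
  t1 <- runif(100, 0, 50); t2 <- t1 + runif(100, 0.01, 10)
  expect_true(all(escape_zeta(t1) > escape_zeta(t2)))
  expect_error(escape_zeta(-0.1), "nonnegative")
})

test_that("auxiliary value composes smoothing and escape terms", {
  p <- smoothing_params()
  f <- objective(function(x) x[1]^4, lower = -3, upper = 3)
  rec <- minimizer_record(0, 0)
  expect_identical(auxiliary_value(f, 0, rec, p), rec$f_star + p$a)
  # x far from x* with f >= f* + b2: exactly f* + a/(1+d^2)
  expect_equal(auxiliary_value(f, 2, rec, p), 0 + 1 / (1 + 4), tolerance = 1e-12)
  expect_equal(auxiliary_value(f, 1, rec, p),
               smoothed_gamma(f, 1, rec, p) + 0.5, tolerance = 1e-12)
})

test_that("gap-bound readings give the documented envelopes and vanish with b2", {
  p <- smoothing_params()
  expect_equal(smoothing_gap_bound(p, "product"),
               max(p$b2^2, p$b2 - p$b2^2 * p$b1))
  expect_equal(smoothing_gap_bound(p, "quotient"),
               max(p$b2^2, p$b2 - p$b2^2 / p$b1))
  tiny <- smoothing_params(b2 = 1e-4)
  expect_lt(smoothing_gap_bound(tiny, "product"), 2e-4)
  sel <- select_case3_reading(p)
  expect_true("product" %in% sel$selected)
  expect_lte(sel$max_gap, smoothing_gap_bound(p, "product"))
})

test_that("the incumbent is a strict local maximizer of the auxiliary", {
  p <- smoothing_params()
  suite <- benchmark_suite()
  for (e in suite[1:3]) {
    obj <- e$objective
    mins <- find_local_minima_1d(function(d) obj$fn(d), obj$lower, obj$upper)
    for (m in mins) {
      rec <- minimizer_record(m$x, m$f)
      set.seed(11)
      got <- 0L
      while (got < 100L) {
        x <- m$x + runif(1, -0.4, 0.4)
        if (abs(x - m$x) < 1e-4 || !in_box(obj, x)) next
        if (eval_objective(obj, x) < m$f) next
        expect_lt(auxiliary_value(obj, x, rec, p), m$f + p$a)
        got <- got + 1L
      }
    }
  }
})

test_that("the auxiliary has no stationary point over the flattened region", {
  p <- smoothing_params()
  suite <- benchmark_suite()
  for (e in suite[1:3]) {
    obj <- e$objective
    m <- find_local_minima_1d(function(d) obj$fn(d), obj$lower, obj$upper)[[1]]
    rec <- minimizer_record(m$x, m$f)
    hstep <- 1e-5
    set.seed(13)
    got <- 0L
    while (got < 100L) {
      x <- runif(1, obj$lower + 2 * hstep, obj$upper - 2 * hstep)
      if (abs(x - m$x) < 0.05) next
      if (eval_objective(obj, x) < m$f) next
      grad <- (auxiliary_value(obj, x + hstep, rec, p) -
               auxiliary_value(obj, x - hstep, rec, p)) / (2 * hstep)
      expect_gt(abs(grad), 1e-8)
      got <- got + 1L
    }
  }
})

test_that("the auxiliary turns stationary inside a strictly lower basin", {
  # double well with a strictly lower right-hand well; incumbent at the
  # higher (left) well; the escape-weight condition |a| <= L/T holds
  p <- smoothing_params()
  fn <- function(d) (d^2 - 1)^2 - 0.5 * d
  obj <- objective(fn, lower = -2, upper = 2)
  mins <- find_local_minima_1d(fn, -2, 2)
  expect_length(mins, 2L)
  higher <- mins[[which.max(vapply(mins, `[[`, numeric(1), "f"))]]
  rec <- minimizer_record(higher$x, higher$f)
  # L = max |f'| on the box, T = max gradient factor of the escape kernel
  g <- seq(-2, 2, by = 1e-3)
  L <- max(abs(4 * g^3 - 4 * g - 0.5))
  Tz <- max(abs(2 * (g - higher$x) / (1 + (g - higher$x)^2)^2))
  expect_lte(abs(p$a), L / Tz)
  in_lower <- g[vapply(g, fn, numeric(1)) < higher$f]
  aux <- vapply(in_lower, function(x) auxiliary_value(obj, x, rec, p), numeric(1))
  sign_change <- any(diff(aux) < 0) && any(diff(aux) > 0)
  expect_true(sign_change)
})
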