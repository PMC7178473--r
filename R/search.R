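#' Configuration of the directional global search
#'
#' Defaults follow the reference configuration of the method: tolerance
#' `eps = 0.003`, iteration budget `G = 100`, `M = 15` directions, search
#' interval `[0, 10]`.  The `upsilon` field is carried for configuration
#' fidelity but is inert: it plays no role in any computation.
#'
#' @param n_directions Number of random search directions (`M`).
#' @param budget Cap on escape iterations per direction (`G`).
#' @param tol Positive tolerance of the one-dimensional minimizer (`eps`).
#' @param lower,upper Default scalar bounds of the one-dimensional search
#'   interval (used when no objective box is supplied).
#' @param seed Integer seed driving direction sampling; the only source of
#'   randomness in the optimizer.
#' @param escape_offset Perturbation used to leave an incumbent minimizer;
#'   defaults to `tol`.
#' @param upsilon Inert configuration field (kept at its reference value -1).
#' @return An object of class `"search_config"`.
#' @examples
#' search_config(seed = 1)
#' @export
search_config <- function(n_directions = 15L, budget = 100L, tol = 0.003,
                          lower = 0, upper = 10, seed = 1L,
                          escape_offset = tol, upsilon = -1) {
  stopifnot(n_directions >= 1L, budget >= 1L, tol > 0, lower < upper,
            escape_offset > 0)
  structure(list(n_directions = as.integer(n_directions),
                 budget = as.integer(budget), tol = as.numeric(tol),
                 lower = as.numeric(lower), upper = as.numeric(upper),
                 seed = as.integer(seed),
                 escape_offset = as.numeric(escape_offset),
                 upsilon = as.numeric(upsilon)),
            class = "search_config")
}

# Run code with a private RNG stream, restoring the caller's state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Sample unit search directions
#'
#' Directions are uniform on the unit sphere (normalized Gaussian draws) and
#' deterministic for a fixed seed.  In one dimension the only unit vectors
#' are +1 and -1, returned cyclically.
#'
#' @param dims Problem dimension (>= 1).
#' @param count Number of directions.
#' @param seed Integer seed.
#' @return A list of `count` numeric unit vectors of length `dims`.
#' @export
sample_directions <- function(dims, count, seed) {
  dims <- as.integer(dims); count <- as.integer(count)
  if (dims < 1L) stop("'dims' must be >= 1")
  if (count < 1L) stop("'count' must be >= 1")
  if (dims == 1L) {
    return(as.list(rep_len(c(1, -1), count)))
  }
  with_seed(seed, {
    out <- vector("list", count)
    for (i in seq_len(count)) {
      repeat {
        v <- stats::rnorm(dims)
        nv <- sqrt(sum(v^2))
        if (nv > 1e-8) break
      }
      out[[i]] <- v / nv
    }
    out
  })
}

#' Reduce an objective to one dimension along a direction
#'
#' Builds `F(delta) = f(x0 + delta * d)` together with the exact interval of
#' `delta` values keeping the point inside the box.
#'
#' @param f An [objective()].
#' @param x0 Base point inside the box.
#' @param d Unit direction vector.
#' @return A list with `F` (function of `delta`) and `interval`
#'   (`c(lo, hi)`).
#' @export
reduce_to_1d <- function(f, x0, d) {
  stopifnot(inherits(f, "objective"))
  x0 <- as.numeric(x0); d <- as.numeric(d)
  if (!in_box(f, x0)) stop("'x0' lies outside the box domain")
  lo <- -Inf; hi <- Inf
  for (i in seq_len(f$dims)) {
    if (d[i] == 0) next
    r <- sort(c((f$lower[i] - x0[i]) / d[i], (f$upper[i] - x0[i]) / d[i]))
    lo <- max(lo, r[1]); hi <- min(hi, r[2])
  }
  if (!is.finite(lo) || !is.finite(hi)) stop("direction must be nonzero")
  fn <- f$fn; bl <- f$lower; bu <- f$upper
  F1 <- function(delta) {
    x <- pmin(pmax(x0 + delta * d, bl), bu)  # clamp fp drift at the faces
    as.numeric(fn(x))
  }
  list(F = F1, interval = c(lo, hi))
}

# Wrap a 1-D function with an evaluation counter (environment-based).
counted <- function(F) {
  n <- 0L
  g <- function(delta) { n <<- n + 1L; F(delta) }
  attr(g, "count") <- function() n
  g
}

#' Derivative-free one-dimensional local minimization
#'
#' Bracket scan followed by golden-section/parabolic refinement
#' ([stats::optimize()]).  From `start`, probes of size `tol` pick a descent
#' direction; steps then grow geometrically, capped at
#' `max(tol, width/1000)` so that basins at the optimizer's resolution are
#' never stepped over, until the function value rises (bracket found) or the
#' interval edge is reached.  The result never exceeds the value at `start`
#' (descent property), and a flat scan is reported as degenerate.
#'
#' @param F Function of one numeric argument; may return `+Inf` (treated as
#'   a large value), never `NA`.
#' @param start Start point inside `interval`.
#' @param interval Numeric `c(lo, hi)` search interval.
#' @param tol Positive tolerance on the minimizer location.
#' @return A list with `delta` (the minimizer), `value`, and `degenerate`
#'   (`TRUE` when no descent direction was found at resolution `tol`).
#' @export
local_minimize_1d <- function(F, start, interval, tol) {
  stopifnot(tol > 0, length(interval) == 2L, interval[1] < interval[2])
  lo <- interval[1]; hi <- interval[2]
  if (start < lo - 1e-12 || start > hi + 1e-12) stop("'start' outside interval")
  start <- min(max(start, lo), hi)
  f0 <- F(start)
  if (is.na(f0)) stop("non-finite (NA) function value at start")

  probe <- function(x) if (x < lo || x > hi) Inf else F(x)
  fr <- probe(start + tol); fl <- probe(start - tol)
  sgn <- if (fr < f0 || fl < f0) { if (fr <= fl) 1 else -1 } else 0
  if (sgn == 0) {
    # flat or already locally minimal at this resolution
    degen <- is.finite(f0) && fr == f0 && fl == f0
    return(list(delta = start, value = f0, degenerate = degen))
  }

  hmax <- max(tol, (hi - lo) / 1000)
  h <- tol
  x_prev2 <- start; x_prev <- start + sgn * tol
  f_prev <- if (sgn == 1) fr else fl
  best_x <- if (f_prev < f0) x_prev else start
  best_f <- min(f_prev, f0)
  repeat {
    h <- min(h * 2, hmax)
    x_new <- x_prev + sgn * h
    at_edge <- FALSE
    if (x_new <= lo) { x_new <- lo; at_edge <- TRUE }
    if (x_new >= hi) { x_new <- hi; at_edge <- TRUE }
    f_new <- F(x_new)
    if (f_new < best_f) { best_f <- f_new; best_x <- x_new }
    if (f_new > f_prev || at_edge) {
      bracket <- sort(c(x_prev2, x_new))
      break
    }
    x_prev2 <- x_prev; x_prev <- x_new; f_prev <- f_new
  }
  if (diff(bracket) > 2 * tol) {
    opt <- stats::optimize(F, lower = bracket[1], upper = bracket[2], tol = tol)
    if (opt$objective < best_f) { best_f <- opt$objective; best_x <- opt$minimum }
  }
  if (f0 < best_f) { best_f <- f0; best_x <- start }  # descent guarantee
  list(delta = best_x, value = best_f, degenerate = FALSE)
}

#' One escape attempt from an incumbent one-dimensional minimizer
#'
#' Builds the one-dimensional auxiliary
#' `A(delta) = gamma~(delta) + a * zeta((delta - delta*)^2)` around the
#' incumbent, minimizes it starting from `delta* +/- escape_offset` in both
#' directions, then descends `F` from each auxiliary minimizer.  Returns the
#' best strictly improving point, or `NULL` when neither direction yields
#' `F(delta_new) < F(delta*)`.
#'
#' @param F Function of one numeric argument.
#' @param rec A [minimizer_record()] with the incumbent `delta*` and value.
#' @param p A [smoothing_params()] object.
#' @param cfg A [search_config()] object (supplies `tol` and
#'   `escape_offset`).
#' @param interval Numeric `c(lo, hi)` search interval.
#' @return `NULL`, or a list with `delta` and `value` of the improving
#'   point.
#' @export
escape_step <- function(F, rec, p, cfg, interval) {
  stopifnot(inherits(rec, "minimizer_record"), inherits(p, "smoothing_params"),
            inherits(cfg, "search_config"))
  d_star <- rec$x_star[1]; f_star <- rec$f_star
  aux <- function(delta) {
    smoothed_gamma_value(F(delta), f_star, p) +
      p$a * escape_zeta((delta - d_star)^2)
  }
  best <- NULL
  for (sgn in c(1, -1)) {
    s0 <- d_star + sgn * cfg$escape_offset
    if (s0 < interval[1] || s0 > interval[2]) next
    ra <- local_minimize_1d(aux, s0, interval, cfg$tol)
    rf <- local_minimize_1d(F, ra$delta, interval, cfg$tol)
    if (rf$value < f_star && (is.null(best) || rf$value < best$value)) {
      best <- list(delta = rf$delta, value = rf$value)
    }
  }
  best
}

#' One-dimensional global minimization by auxiliary-function escapes
#'
#' Alternates local minimization of `F` with [escape_step()] until no
#' improving point is found or the iteration budget is exhausted.  The
#' returned value is the lowest seen and never exceeds the value at the
#' first local minimizer.
#'
#' @inheritParams escape_step
#' @param start Start point; defaults to the interval midpoint.
#' @return A list with `delta`, `value`, `converged` (`FALSE` only when the
#'   budget ran out while escapes were still improving), and `n_iter`.
#' @export
global_minimize_1d <- function(F, interval, p, cfg, start = mean(interval)) {
  Fc <- counted(F)
  res <- local_minimize_1d(Fc, start, interval, cfg$tol)
  if (!is.finite(res$value)) {
    # start sits on an infeasible (+Inf) plateau: scan for a finite foothold
    grid <- seq(interval[1], interval[2],
                by = max(cfg$tol, diff(interval) / 1000))
    vals <- vapply(grid, Fc, numeric(1))
    if (!any(is.finite(vals))) stop("function has no finite values on the interval")
    res <- local_minimize_1d(Fc, grid[which.min(vals)], interval, cfg$tol)
  }
  best <- list(delta = res$delta, value = res$value)
  converged <- FALSE
  iters <- 0L
  for (i in seq_len(cfg$budget)) {
    iters <- i
    rec <- minimizer_record(best$delta, best$value)
    esc <- escape_step(Fc, rec, p, cfg, interval)
    if (is.null(esc)) { converged <- TRUE; break }
    res <- local_minimize_1d(Fc, esc$delta, interval, cfg$tol)
    if (res$value < best$value) best <- list(delta = res$delta, value = res$value)
    else { converged <- TRUE; break }
  }
  list(delta = best$delta, value = best$value, converged = converged,
       n_iter = iters, n_evaluations = attr(Fc, "count")())
}

#' Global minimization over a box by random-direction reduction
#'
#' The search reduces the objective to one-dimensional sections
#' `F(delta) = f(x0 + delta d)` along `M` seeded unit directions through
#' `x0`, globally minimizes each section with [global_minimize_1d()], and
#' keeps the lowest minimizer.  A single restart pass then repeats the
#' directional sweep through the incumbent best point, updating the
#' incumbent after every direction, which lets successive sections correct
#' components the first pass could not reach.  Deterministic given the
#' configuration seed.
#'
#' @param f An [objective()].
#' @param x0 Start point; defaults to the box center.
#' @param p A [smoothing_params()] object.
#' @param cfg A [search_config()] object.
#' @param restart Run the second (incumbent-updating) pass.
#' @return An object of class `"optimization_result"`: a list with
#'   `x_best`, `f_best`, `n_evaluations`, `per_direction_minima` (a
#'   data.frame with one row per line search), and `converged`.
#' @examples
#' f <- objective(function(x) (x[1]^2 - 1)^2 + 0.1 * x[1], lower = -2, upper = 2)
#' global_minimize(f, p = smoothing_params(), cfg = search_config(seed = 1))
#' @export
global_minimize <- function(f, x0 = NULL, p = smoothing_params(),
                            cfg = search_config(), restart = TRUE) {
  stopifnot(inherits(f, "objective"))
  if (is.null(x0)) x0 <- (f$lower + f$upper) / 2
  x0 <- as.numeric(x0)
  if (!in_box(f, x0)) stop("'x0' lies outside the box domain")
  if (cfg$n_directions < 1L) stop("configuration must supply at least one direction")

  dirs <- sample_directions(f$dims, cfg$n_directions, cfg$seed)
  n_eval <- 0L
  rows <- list()
  all_conv <- TRUE

  run_pass <- function(base, update_incumbent) {
    best_x <- base; best_f <- eval_objective(f, base)
    n_eval <<- n_eval + 1L
    for (k in seq_along(dirs)) {
      d <- dirs[[k]]
      origin <- if (update_incumbent) best_x else base
      line <- reduce_to_1d(f, origin, d)
      r <- global_minimize_1d(line$F, line$interval, p, cfg, start = 0)
      n_eval <<- n_eval + r$n_evaluations
      all_conv <<- all_conv && r$converged
      rows[[length(rows) + 1L]] <<- data.frame(
        direction = paste(signif(d, 6), collapse = ","),
        delta_star = r$delta, value = r$value)
      if (r$value < best_f) {
        best_f <- r$value
        best_x <- pmin(pmax(origin + r$delta * d, f$lower), f$upper)
      }
    }
    list(x = best_x, f = best_f)
  }

  pass1 <- run_pass(x0, update_incumbent = FALSE)
  final <- if (restart) run_pass(pass1$x, update_incumbent = TRUE) else pass1
  if (pass1$f < final$f) final <- pass1

  structure(list(x_best = final$x, f_best = final$f, n_evaluations = n_eval,
                 per_direction_minima = do.call(rbind, rows),
                 converged = all_conv),
            class = "optimization_result")
}

#' @export
print.optimization_result <- function(x, ...) {
  cat(sprintf("<optimization_result> f_best = %.6g at (%s); %d evaluations; converged: %s\n",
              x$f_best, paste(signif(x$x_best, 6), collapse = ", "),
              x$n_evaluations, x$converged))
  invisible(x)
}
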