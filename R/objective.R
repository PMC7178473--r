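#' Define an objective function on a box domain
#'
#' Wraps a real-valued function of an n-vector together with componentwise
#' box bounds.  This is the object the global optimizer minimizes.
#'
#' @param fn Function taking a numeric vector of length `dims` and returning
#'   a single finite numeric value for every point inside the box.
#' @param lower,upper Numeric vectors of box bounds; must satisfy
#'   `lower < upper` componentwise.  Scalars are recycled to `dims`.
#' @param dims Problem dimension.  Defaults to `length(lower)` after
#'   recycling.
#'
#' @return An object of class `"objective"`: a list with elements `fn`,
#'   `lower`, `upper`, `dims`.
#' @examples
#' f <- objective(function(x) sum(x^2), lower = -2, upper = 2, dims = 2)
#' eval_objective(f, c(1, 1))
#' @export
objective <- function(fn, lower, upper, dims = NULL) {
  stopifnot(is.function(fn), is.numeric(lower), is.numeric(upper))
  if (is.null(dims)) dims <- max(length(lower), length(upper))
  dims <- as.integer(dims)
  if (dims < 1L) stop("'dims' must be a positive integer")
  lower <- rep_len(as.numeric(lower), dims)
  upper <- rep_len(as.numeric(upper), dims)
  if (!all(lower < upper)) stop("box bounds must satisfy lower < upper componentwise")
  structure(list(fn = fn, lower = lower, upper = upper, dims = dims),
            class = "objective")
}

#' @export
print.objective <- function(x, ...) {
  cat(sprintf("<objective> %d-dimensional box [%s] x [%s]\n", x$dims,
              paste(signif(x$lower, 4), collapse = ", "),
              paste(signif(x$upper, 4), collapse = ", ")))
  invisible(x)
}

#' Evaluate an objective, checking domain membership and finiteness
#'
#' @param f An [objective()].
#' @param x Numeric vector of length `f$dims` inside the box.
#' @return The objective value, a finite numeric scalar.
#' @export
eval_objective <- function(f, x) {
  stopifnot(inherits(f, "objective"))
  x <- as.numeric(x)
  if (length(x) != f$dims) {
    stop(sprintf("point has length %d, objective expects %d", length(x), f$dims))
  }
  if (!in_box(f, x)) {
    stop(sprintf("point (%s) lies outside the box domain",
                 paste(signif(x, 6), collapse = ", ")))
  }
  v <- f$fn(x)
  if (!is.numeric(v) || length(v) != 1L || is.na(v) || !is.finite(v)) {
    stop(sprintf("objective returned a non-finite value at (%s)",
                 paste(signif(x, 6), collapse = ", ")))
  }
  as.numeric(v)
}

#' Test whether a point lies inside an objective's box
#'
#' A small tolerance absorbs floating-point drift on the boundary.
#'
#' @param f An [objective()].
#' @param x Numeric vector.
#' @param tol Boundary tolerance.
#' @return Logical scalar.
#' @export
in_box <- function(f, x, tol = 1e-9) {
  all(x >= f$lower - tol) && all(x <= f$upper + tol)
}

#' Smoothing and escape parameters of the auxiliary function
#'
#' `b1` and `b2` set the width of the Bernstein smoothing window
#' `(-b2/b1, b2]` around the incumbent level, and `a` weights the rational
#' escape term.  Defaults follow the reference configuration of the method
#' (`b1 = 0.1`, `b2 = 0.4`, `a = 1`).
#'
#' @param b1 Positive real; left window width is `b2/b1`.
#' @param b2 Real in (0, 1); right window width.
#' @param a Real escape weight.
#' @return An object of class `"smoothing_params"`.
#' @examples
#' smoothing_params()
#' @export
smoothing_params <- function(b1 = 0.1, b2 = 0.4, a = 1) {
  stopifnot(is.numeric(b1), length(b1) == 1L, is.finite(b1),
            is.numeric(b2), length(b2) == 1L, is.finite(b2),
            is.numeric(a), length(a) == 1L, is.finite(a))
  if (b1 <= 0) stop("'b1' must be > 0")
  if (b2 <= 0 || b2 >= 1) stop("'b2' must lie in the open interval (0, 1)")
  structure(list(b1 = as.numeric(b1), b2 = as.numeric(b2), a = as.numeric(a)),
            class = "smoothing_params")
}

#' Record of a local minimizer
#'
#' Pairs a point with its objective value; the auxiliary function is always
#' built around the best such record found so far.
#'
#' @param x_star Numeric vector, a (local) minimizer.
#' @param f_star Objective value at `x_star`.
#' @return An object of class `"minimizer_record"`.
#' @export
minimizer_record <- function(x_star, f_star) {
  stopifnot(is.numeric(x_star), is.numeric(f_star), length(f_star) == 1L,
            is.finite(f_star))
  structure(list(x_star = as.numeric(x_star), f_star = as.numeric(f_star)),
            class = "minimizer_record")
}
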