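#' Confusion counts between a predicted mask and ground truth
#'
#' @param mask,truth Binary masks of identical shape (1 = lesion).
#' @param fov_only Count only pixels inside the circular field of view of
#'   [apply_corner_mask()]; `radius_fraction` then sets the disc size.
#' @param radius_fraction Disc radius fraction used when `fov_only = TRUE`.
#' @return An object of class `"confusion_counts"`: a list with integer
#'   `tp`, `fp`, `tn`, `fn` summing to the number of compared pixels.
#' @export
confusion_counts <- function(mask, truth, fov_only = FALSE, radius_fraction = 0.9) {
  mask <- as_binary_mask(mask); truth <- as_binary_mask(truth)
  if (!identical(dim(mask), dim(truth))) stop("mask and truth shapes differ")
  if (fov_only) {
    disc <- fov_disc(nrow(mask), ncol(mask), radius_fraction) == 1L
    mask <- mask[disc]; truth <- truth[disc]
  }
  m <- mask == 1L; g <- truth == 1L
  structure(list(tp = sum(m & g), fp = sum(m & !g),
                 tn = sum(!m & !g), fn = sum(!m & g)),
            class = "confusion_counts")
}

#' Overlap and classification metrics from confusion counts
#'
#' Computes accuracy `AC = (tp+tn)/total`, Jaccard `JA = tp/(tp+fn+fp)`,
#' Dice `DI = 2tp/(2tp+fn+fp)`, sensitivity `SE = tp/(tp+fn)`, specificity
#' `SP = tn/(tn+fp)`, positive predictive value `PPV = tp/(tp+fp)`, and
#' negative predictive value `NPV = tn/(tn+fn)`.  (Published variants of
#' these formula sets occasionally misprint SE with `fp` in the
#' denominator, which is the PPV formula; the standard definitions above
#' are used throughout.)  A metric whose denominator is zero is reported as
#' `NA` and named, with its reason, in the `undefined` attribute rather
#' than silently coerced to 0.
#'
#' @param x A [confusion_counts()] object, or a mask when `truth` is given.
#' @param truth Optional ground-truth mask; when supplied, `x` is treated
#'   as the predicted mask and counts are formed first.
#' @return Named list with elements `AC`, `JA`, `DI`, `SE`, `SP`, `PPV`,
#'   `NPV`; attribute `undefined` names any `NA` metrics.
#' @examples
#' m <- matrix(c(1, 0, 0, 1), 2)
#' segmentation_metrics(confusion_counts(m, m))
#' @export
segmentation_metrics <- function(x, truth = NULL) {
  if (!is.null(truth)) x <- confusion_counts(x, truth)
  stopifnot(inherits(x, "confusion_counts"))
  tp <- x$tp; fp <- x$fp; tn <- x$tn; fn <- x$fn
  total <- tp + fp + tn + fn
  if (total == 0) stop("all confusion counts are zero")
  safe <- function(num, den, what) {
    if (den == 0) {
      structure(NA_real_, reason = sprintf("%s undefined: empty denominator", what))
    } else num / den
  }
  out <- list(AC  = safe(tp + tn, total, "AC"),
              JA  = safe(tp, tp + fn + fp, "JA"),
              DI  = safe(2 * tp, 2 * tp + fn + fp, "DI"),
              SE  = safe(tp, tp + fn, "SE"),
              SP  = safe(tn, tn + fp, "SP"),
              PPV = safe(tp, tp + fp, "PPV"),
              NPV = safe(tn, tn + fn, "NPV"))
  und <- vapply(out, function(v) !is.null(attr(v, "reason")), logical(1))
  reasons <- unlist(lapply(out[und], attr, "reason"), use.names = FALSE)
  out <- lapply(out, function(v) { attributes(v) <- NULL; v })
  if (any(und)) attr(out, "undefined") <- stats::setNames(reasons, names(which(und)))
  out
}
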