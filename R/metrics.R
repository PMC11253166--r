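# Error metrics and the transferability quantities. All energies in kcal/mol.

#' Mean absolute deviation
#'
#' @param pred,ref Equal-length numeric vectors of predicted and reference
#'   energies (kcal/mol).
#' @return Mean of `|pred - ref|`.
#' @export
mad_error <- function(pred, ref) {
  if (length(pred) != length(ref)) {
    stop("pred and ref must have equal length", call. = FALSE)
  }
  if (length(pred) == 0) stop("empty input", call. = FALSE)
  mean(abs(pred - ref))
}

#' Weighted mean absolute deviation
#'
#' Generic weighted-MAD hook: `sum(w |pred - ref|) / sum(w)`. With uniform
#' weights this equals [mad_error()]. Published weighting schemes (such as
#' WTMAD-2) can be plugged in by supplying their per-process weights.
#'
#' @param pred,ref Equal-length numeric vectors (kcal/mol).
#' @param weights Non-negative weights, not all zero.
#' @return Weighted MAD in kcal/mol.
#' @export
weighted_mad <- function(pred, ref, weights) {
  if (length(pred) != length(ref) || length(pred) != length(weights)) {
    stop("pred, ref and weights must have equal length", call. = FALSE)
  }
  if (length(pred) == 0) stop("empty input", call. = FALSE)
  if (any(weights < 0)) stop("negative weights", call. = FALSE)
  if (sum(weights) == 0) stop("all-zero weights", call. = FALSE)
  sum(weights * abs(pred - ref)) / sum(weights)
}

#' Transferability of a trained model to a test set
#'
#' The regularized ratio of the two-set error to the test set's own accuracy
#' limit:
#' \deqn{T_{B@A} = \frac{MAD_{B@A} + \eta}{MAD_{B@B} + \eta}}
#' with `eta` (default 0.01 kcal/mol) applied to both numerator and
#' denominator so that T = 1 whenever the two MADs coincide, including at 0.
#' T = 1 is perfect transferability; when the denominator is a global optimum,
#' minimization guarantees T >= 1 and larger values mean poorer transfer.
#'
#' @param mad_ba MAD on test set B of the model trained on A (kcal/mol).
#' @param mad_bb MAD on B of the model trained on B itself (kcal/mol).
#' @param eta Regularization for small energies, kcal/mol (> 0).
#' @return A list of class `transferability_entry` with fields `mad_ba`,
#'   `mad_bb`, `eta`, and the dimensionless ratio `t`.
#' @examples
#' transferability(1.91, 1.84) # ~1.038
#' @export
transferability <- function(mad_ba, mad_bb, eta = 0.01) {
  stopifnot(length(mad_ba) == 1, length(mad_bb) == 1, length(eta) == 1)
  if (mad_ba < 0 || mad_bb < 0) stop("MADs must be >= 0", call. = FALSE)
  if (eta <= 0) stop("eta must be > 0", call. = FALSE)
  structure(
    list(
      mad_ba = mad_ba, mad_bb = mad_bb, eta = eta,
      t = (mad_ba + eta) / (mad_bb + eta)
    ),
    class = "transferability_entry"
  )
}

#' @export
print.transferability_entry <- function(x, ...) {
  cat(sprintf(
    "T = (%.4g + %.3g)/(%.4g + %.3g) = %.6g\n",
    x$mad_ba, x$eta, x$mad_bb, x$eta, x$t
  ))
  invisible(x)
}

#' Transfer energy (excess error of training on the wrong set)
#'
#' `delta = MAD_B@A - MAD_B@B`, the energy cost in kcal/mol of using
#' parameters trained on A instead of B's own optimum. Non-negative whenever
#' `mad_bb` is a global optimum; a negative value is returned unclamped with a
#' warning, since it indicates the training optimizer failed to reach the
#' global minimum.
#'
#' @param mad_ba,mad_bb Non-negative MADs in kcal/mol.
#' @return A list of class `transfer_energy` with field `delta` (kcal/mol).
#' @export
delta_mad <- function(mad_ba, mad_bb) {
  stopifnot(length(mad_ba) == 1, length(mad_bb) == 1)
  if (mad_ba < 0 || mad_bb < 0) stop("MADs must be >= 0", call. = FALSE)
  delta <- mad_ba - mad_bb
  if (delta < 0) {
    warning("negative transfer energy: mad_bb is not a global optimum",
      call. = FALSE
    )
  }
  structure(list(delta = delta, mad_ba = mad_ba, mad_bb = mad_bb),
    class = "transfer_energy"
  )
}

#' @export
print.transfer_energy <- function(x, ...) {
  cat(sprintf("dMAD = %.4g - %.4g = %.6g kcal/mol\n", x$mad_ba, x$mad_bb, x$delta))
  invisible(x)
}

#' Fractions of good / ok / bad process errors
#'
#' Bins absolute errors into good (< 1 kcal/mol, chemical accuracy), ok
#' (1-7 kcal/mol, useful accuracy) and bad (> 7 kcal/mol). The middle bin is
#' closed, `[1, 7]`, so boundary values count as ok.
#'
#' @param abs_errors Non-negative numeric vector of absolute errors (kcal/mol).
#' @return Named numeric vector `c(good, ok, bad)` of fractions summing to 1.
#' @export
classify_errors <- function(abs_errors) {
  if (length(abs_errors) == 0) stop("empty input", call. = FALSE)
  if (any(abs_errors < 0)) stop("absolute errors must be >= 0", call. = FALSE)
  n <- length(abs_errors)
  c(
    good = sum(abs_errors < 1) / n,
    ok = sum(abs_errors >= 1 & abs_errors <= 7) / n,
    bad = sum(abs_errors > 7) / n
  )
}
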