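# Cross-set transferability analysis: the B@A grids of two-set errors,
# transferability ratios and transfer energies over a collection of benchsets.
# Orientation convention everywhere: column = training set (A), row = test
# set (B), matching the B@A = [test set]@[training set] reading.

#' Transferability matrix over a collection of benchsets
#'
#' Trains the p-parameter model once per set (column = training set), then
#' evaluates every trained model on every set (row = test set) and forms the
#' regularized transferability ratio
#' `t[B, A] = (MAD_B@A + eta) / (MAD_B@B + eta)`. The diagonal is 1 by
#' construction, and all entries are >= 1 (up to solver tolerance) whenever
#' every fit reaches its global optimum.
#'
#' @param sets A named list of `benchset` objects (>= 2, unique names), or an
#'   unnamed list (benchset names are used).
#' @param p Integer in 1..7.
#' @param opts A [fit_options()] list.
#' @param eta Regularization in kcal/mol (default 0.01).
#' @param cache If `TRUE` (default) each training set is fitted once and the
#'   fit reused across rows; if `FALSE` every (B, A) entry refits A. The two
#'   modes give bit-identical matrices (the fit is deterministic); the flag
#'   exists to make that checkable.
#' @return An object of class `tat_matrix`: fields `sets` (names), `mad`
#'   (matrix of MAD_B@A, kcal/mol), `t` (transferability matrix), `p`, `eta`,
#'   `fits` (the per-column fits when cached), `statuses` (per training set).
#' @export
tat_matrix <- function(sets, p, opts = fit_options(), eta = 0.01, cache = TRUE) {
  sets <- name_sets(sets)
  if (length(sets) < 2) stop("need at least 2 benchsets", call. = FALSE)
  nm <- names(sets)
  k <- length(sets)
  fit_one <- function(A) {
    tryCatch(fit_xyg(sets[[A]], p, opts), error = function(e) {
      stop(sprintf("fit failed for set '%s': %s", A, conditionMessage(e)),
        call. = FALSE
      )
    })
  }
  fits <- if (cache) lapply(nm, fit_one) else NULL
  if (cache) names(fits) <- nm
  mad <- matrix(NA_real_, k, k, dimnames = list(test = nm, train = nm))
  for (A in seq_len(k)) {
    fa <- if (cache) fits[[A]] else fit_one(nm[A])
    for (B in seq_len(k)) {
      mad[B, A] <- cross_mad(fa, sets[[B]])
    }
  }
  tmat <- (mad + eta) / matrix(diag(mad) + eta, k, k) # denominator: row's own MAD_B@B
  statuses <- if (cache) {
    vapply(fits, `[[`, "", "status")
  } else {
    vapply(nm, function(A) fit_one(A)$status, "")
  }
  structure(
    list(
      sets = nm, mad = mad, t = tmat, p = p, eta = eta,
      fits = fits, statuses = statuses
    ),
    class = "tat_matrix"
  )
}

name_sets <- function(sets) {
  stopifnot(is.list(sets), all(vapply(sets, inherits, TRUE, "benchset")))
  if (is.null(names(sets))) {
    names(sets) <- vapply(sets, `[[`, "", "name")
  }
  if (anyDuplicated(names(sets))) {
    stop("benchset names must be unique", call. = FALSE)
  }
  sets
}

#' @export
print.tat_matrix <- function(x, digits = 4, ...) {
  cat(sprintf(
    "tat_matrix: p = %d, eta = %g kcal/mol  (rows = test set B, cols = training set A)\n",
    x$p, x$eta
  ))
  cat("T_B@A:\n")
  print(round(x$t, digits))
  invisible(x)
}

#' Transfer-energy matrix over a collection of benchsets
#'
#' As [tat_matrix()] but with entries `dMAD[B, A] = MAD_B@A - MAD_B@B`, the
#' excess error (kcal/mol) of training on A instead of B's own optimum. The
#' diagonal is exactly 0 and off-diagonal entries are >= 0 when fits are
#' global.
#'
#' @inheritParams tat_matrix
#' @return A list of class `dmad_matrix` with fields `sets`, `dmad`, `mad`,
#'   `p`, `statuses`.
#' @export
transfer_energy_matrix <- function(sets, p, opts = fit_options(), cache = TRUE) {
  tm <- tat_matrix(sets, p, opts, cache = cache)
  dmad <- tm$mad - matrix(diag(tm$mad), length(tm$sets), length(tm$sets))
  diag(dmad) <- 0
  structure(
    list(sets = tm$sets, dmad = dmad, mad = tm$mad, p = tm$p, statuses = tm$statuses),
    class = "dmad_matrix"
  )
}

#' @export
print.dmad_matrix <- function(x, digits = 4, ...) {
  cat(sprintf(
    "dmad_matrix: p = %d (rows = test set B, cols = training set A), kcal/mol\n",
    x$p
  ))
  print(round(x$dmad, digits))
  invisible(x)
}

#' Accuracy limit of the model family on a benchset
#'
#' `MAD_A@A` at a given p: the smallest error the p-parameter family can
#' reach on the set, i.e. the training MAD of the set fitted on itself. At
#' p = 7 this is the accuracy limit of the full family. Non-increasing in p
#' by the nesting of the reduction rules.
#'
#' @param b A `benchset`.
#' @param p Integer in 1..7.
#' @param opts A [fit_options()] list.
#' @return MAD in kcal/mol.
#' @export
accuracy_limit <- function(b, p, opts = fit_options()) {
  fit_xyg(b, p, opts)$mad
}

#' Good / ok / bad error summary of a fit on a benchset
#'
#' Bins the per-process absolute errors of a trained model evaluated on a
#' benchset into good (< 1), ok (1-7) and bad (> 7 kcal/mol) fractions.
#'
#' @param fit An `xyg_fit`.
#' @param b A `benchset` to evaluate on (may differ from the training set).
#' @return A list of class `error_summary` with fields `set`, `trainset`,
#'   `frac_good`, `frac_ok`, `frac_bad`.
#' @export
error_summary <- function(fit, b) {
  validate_benchset(b)
  fr <- classify_errors(abs(predict_energies(fit$a, b) - b$processes$ref_kcal))
  structure(
    list(
      set = b$name, trainset = fit$trainset,
      frac_good = unname(fr["good"]), frac_ok = unname(fr["ok"]),
      frac_bad = unname(fr["bad"])
    ),
    class = "error_summary"
  )
}

#' @export
print.error_summary <- function(x, ...) {
  cat(sprintf(
    "errors on '%s' (trained on '%s'): good %.1f%%, ok %.1f%%, bad %.1f%%\n",
    x$set, x$trainset, 100 * x$frac_good, 100 * x$frac_ok, 100 * x$frac_bad
  ))
  invisible(x)
}

#' Write a transferability (or transfer-energy) matrix to CSV
#'
#' CSV layout: first column = test-set name (rows B), remaining columns =
#' training sets (A), values at 6 significant digits. A sidecar JSON with
#' full-precision values and metadata is written when `jsonlite` is
#' installed and `json_path` is given.
#'
#' @param x A `tat_matrix` or `dmad_matrix`.
#' @param path Output CSV path.
#' @param which `"t"`, `"mad"`, or `"dmad"` (must exist in `x`).
#' @param json_path Optional sidecar JSON path.
#' @return Invisibly, `path`.
#' @export
write_tat_csv <- function(x, path, which = if (inherits(x, "dmad_matrix")) "dmad" else "t",
                          json_path = NULL) {
  m <- x[[which]]
  stopifnot(is.matrix(m))
  df <- data.frame(test_set = x$sets, signif(m, 6), check.names = FALSE)
  names(df)[-1] <- paste0("train_", x$sets)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(json_path)) {
    if (!requireNamespace("jsonlite", quietly = TRUE)) {
      stop("jsonlite is required for the JSON sidecar", call. = FALSE)
    }
    meta <- list(
      sets = x$sets, p = x$p, eta = x$eta,
      orientation = "rows = test set B, cols = training set A"
    )
    meta[[which]] <- m
    jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
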