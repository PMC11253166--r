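# The XYG_p family: a double-hybrid DFA written as a linear combination of
# seven precomputed per-species energy components,
#   E = a1 E_x^HF + a2 E_x^aux + a3 E_x^(m)GGA + a4 E_c^aux + a5 E_c^(m)GGA
#     + a6 E_c^MP2,ss + a7 E_c^MP2,os,
# with p = 1..7 free parameters nested by fixed reduction rules. The slot
# labels for components 2 and 4 ("auxiliary" exchange/correlation) are
# conventional; nothing downstream depends on their physical identity, only
# on which slots the reduction rules zero or tie.

#' Names of the free parameters at each model size
#'
#' @param p Integer in 1..7.
#' @return Character vector of length `p`, in the canonical ordering used by
#'   [expand_params()] and [fit_xyg()].
#' @export
free_param_names <- function(p) {
  stopifnot(length(p) == 1, p %in% 1:7)
  switch(p,
    "alpha",
    c("alpha", "beta"),
    c("a1", "a3", "a6"),
    c("a1", "a2", "a3", "a6"),
    c("a1", "a2", "a3", "a5", "a6"),
    c("a1", "a2", "a3", "a4", "a5", "a6"),
    c("a1", "a2", "a3", "a4", "a5", "a6", "a7")
  )
}

#' Expand free parameters into the full seven-component vector
#'
#' Applies the reduction rule for the p-parameter member of the family:
#' \describe{
#'   \item{p = 1}{exact-exchange fraction `alpha`: a1 = alpha, a2 = a4 = 0,
#'     a3 = 1 - alpha, a5 = 1 - alpha^2, a6 = a7 = alpha^2}
#'   \item{p = 2}{`alpha` and MP2 fraction `beta`: a1 = alpha, a2 = a4 = 0,
#'     a3 = 1 - alpha, a5 = 1 - beta, a6 = a7 = beta}
#'   \item{p = 3}{free a1, a3, a6; a2 = a4 = 0, a5 = 1 - a6, a7 = a6}
#'   \item{p = 4}{free a1, a2, a3, a6; a4 = 0, a5 = 1 - a6, a7 = a6}
#'   \item{p = 5}{free all except a4 = 0 and a7 = a6}
#'   \item{p = 6}{free all except a7 = a6}
#'   \item{p = 7}{identity}
#' }
#'
#' @param p Integer in 1..7.
#' @param values Numeric vector of length `p` of free-parameter values, in
#'   [free_param_names()] order.
#' @return Named numeric vector `a1`...`a7`.
#' @examples
#' expand_params(1, 0.5)
#' expand_params(2, c(0.7, 0.9))
#' @export
expand_params <- function(p, values) {
  stopifnot(length(p) == 1, is.numeric(values), all(is.finite(values)))
  if (!p %in% 1:7) stop("p must be an integer in 1..7", call. = FALSE)
  if (length(values) != p) {
    stop(sprintf("expected %d free parameter(s), got %d", p, length(values)),
      call. = FALSE
    )
  }
  a <- switch(p,
    {
      al <- values[1]
      c(al, 0, 1 - al, 0, 1 - al^2, al^2, al^2)
    },
    {
      al <- values[1]
      be <- values[2]
      c(al, 0, 1 - al, 0, 1 - be, be, be)
    },
    c(values[1], 0, values[2], 0, 1 - values[3], values[3], values[3]),
    c(values[1], values[2], values[3], 0, 1 - values[4], values[4], values[4]),
    c(values[1], values[2], values[3], 0, values[4], values[5], values[5]),
    c(values[1:6], values[6]),
    values
  )
  names(a) <- paste0("a", 1:7)
  a
}

# Affine representation a = M f + c of the p >= 2 reduction rules; the p = 1
# rule is quadratic in alpha and handled separately by the fitter.
param_map <- function(p) {
  stopifnot(p %in% 2:7)
  M <- matrix(0, 7, p, dimnames = list(paste0("a", 1:7), free_param_names(p)))
  cc <- numeric(7)
  if (p == 2) {
    M[1, 1] <- 1
    M[3, 1] <- -1
    M[5, 2] <- -1
    M[6, 2] <- 1
    M[7, 2] <- 1
    cc[3] <- 1
    cc[5] <- 1
  } else if (p == 3) {
    M[1, 1] <- 1
    M[3, 2] <- 1
    M[5, 3] <- -1
    M[6, 3] <- 1
    M[7, 3] <- 1
    cc[5] <- 1
  } else if (p == 4) {
    M[1, 1] <- 1
    M[2, 2] <- 1
    M[3, 3] <- 1
    M[5, 4] <- -1
    M[6, 4] <- 1
    M[7, 4] <- 1
    cc[5] <- 1
  } else if (p == 5) {
    M[1, 1] <- 1
    M[2, 2] <- 1
    M[3, 3] <- 1
    M[5, 4] <- 1
    M[6, 5] <- 1
    M[7, 5] <- 1
  } else if (p == 6) {
    M[cbind(1:6, 1:6)] <- 1
    M[7, 6] <- 1
  } else {
    M[cbind(1:7, 1:7)] <- 1
  }
  list(M = M, c = cc)
}

#' Design matrix of a benchset
#'
#' Row j holds the seven stoichiometry-weighted component sums of process j,
#' converted to kcal/mol: `d_j = 627.509474 * sum_i nu_ij * c_i`. For any
#' parameter vector `a`, the model energy of process j is the inner product
#' `a . d_j`, so all fitting and prediction reduce to linear algebra on this
#' matrix.
#'
#' @param b A `benchset`.
#' @return A numeric matrix with `n_processes(b)` rows and 7 columns, row
#'   names = process ids.
#' @export
design_matrix <- function(b) {
  validate_benchset(b)
  comp <- as.matrix(b$species[, paste0("c", 1:7)])
  rownames(comp) <- b$species$id
  D <- t(vapply(
    b$processes$stoich,
    function(st) drop(crossprod(comp[names(st), , drop = FALSE], st)),
    numeric(7)
  )) * kcal_per_hartree
  dimnames(D) <- list(b$processes$id, paste0("d", 1:7))
  D
}

#' Model energies of a benchset under a parameter vector
#'
#' Evaluates the linear DFA for every process: `E_j = a . d_j` in kcal/mol.
#'
#' @param a Numeric length-7 parameter vector (see [expand_params()]).
#' @param b A `benchset`, or a design matrix precomputed by [design_matrix()].
#' @return Numeric vector of process energies in kcal/mol.
#' @export
predict_energies <- function(a, b) {
  stopifnot(is.numeric(a), length(a) == 7, all(is.finite(a)))
  D <- if (is.matrix(b)) b else design_matrix(b)
  unname(drop(D %*% a))
}
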