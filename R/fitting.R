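# Training: minimize the mean absolute deviation of the linear DFA over the
# p-constrained parameter space. For p >= 2 the free-parameter -> a map is
# affine, so MAD minimization is a least-absolute-deviations problem that a
# linear program solves exactly (Barrodale-Roberts simplex; Frisch-Newton
# interior point when box bounds bind). For p = 1 the rule is quadratic in
# alpha and a dense scan plus local refinement is used instead.

#' Fitting options
#'
#' @param box Length-2 numeric, bounds applied to every free parameter for
#'   p >= 2 (default `c(-3, 3)`; generous, since MP2 fractions above 1 are
#'   legitimate for HF-orbital double hybrids). A safety device against
#'   unbounded programs on degenerate designs; `status` reports when it binds.
#' @param p1_range Length-2 numeric, scan range for the p = 1 exact-exchange
#'   fraction alpha (default `c(-0.5, 1.5)`, physical mixing fractions with
#'   margin).
#' @param p1_grid_step Scan step for p = 1 (default `1e-3`).
#' @param tolerance Numerical tolerance in kcal/mol for optimality and
#'   bound-activity decisions (default `1e-8`).
#' @return A list of class `fit_options`.
#' @export
fit_options <- function(box = c(-3, 3), p1_range = c(-0.5, 1.5),
                        p1_grid_step = 1e-3, tolerance = 1e-8) {
  stopifnot(
    length(box) == 2, box[1] < box[2],
    length(p1_range) == 2, p1_range[1] < p1_range[2],
    p1_grid_step > 0, tolerance > 0
  )
  structure(
    list(
      box = box, p1_range = p1_range,
      p1_grid_step = p1_grid_step, tolerance = tolerance
    ),
    class = "fit_options"
  )
}

# Quadratic-in-alpha prediction basis for p = 1:
# pred(alpha) = base + alpha * lin + alpha^2 * quad  (per process).
p1_basis <- function(D) {
  list(
    base = D[, 3] + D[, 5],
    lin = D[, 1] - D[, 3],
    quad = D[, 6] + D[, 7] - D[, 5]
  )
}

# Exact LAD solve of min ||X f - z||_1 with optional box, handling rank
# deficiency (and n <= p) by solving in the top-rank singular subspace and
# taking the minimum-norm representative along null directions.
lad_solve <- function(X, z, box, tol) {
  n <- nrow(X)
  p <- ncol(X)
  sv <- svd(X)
  rank <- sum(sv$d > max(sv$d[1] * 1e-10, 1e-300))
  status <- "global"
  if (rank == 0) {
    f <- rep(0, p)
    status <- if (p > 0 && n > 0) "underdetermined" else "global"
  } else if (rank < p || n <= rank) {
    U <- sv$u[, seq_len(rank), drop = FALSE]
    V <- sv$v[, seq_len(rank), drop = FALSE]
    Xr <- sweep(U, 2, sv$d[seq_len(rank)], "*")
    g <- if (n == rank) {
      qr.solve(Xr, z)
    } else {
      suppressWarnings(quantreg::rq.fit.br(Xr, z, tau = 0.5)$coefficients)
    }
    f <- drop(V %*% g)
    if (rank < p) status <- "underdetermined"
  } else {
    f <- suppressWarnings(quantreg::rq.fit.br(X, z, tau = 0.5)$coefficients)
  }
  f <- unname(f)
  if (any(f < box[1] - tol) || any(f > box[2] + tol)) {
    r0 <- c(rep(box[1], p), rep(-box[2], p))
    f <- tryCatch(
      {
        if (rank == p && n > rank) {
          R <- rbind(diag(p), -diag(p))
          unname(suppressWarnings(
            quantreg::rq.fit.fnc(X, z, R = R, r = r0, tau = 0.5)$coefficients
          ))
        } else {
          # constrain in the top-rank subspace: f = V g, box on V g
          U <- sv$u[, seq_len(rank), drop = FALSE]
          V <- sv$v[, seq_len(rank), drop = FALSE]
          Xr <- sweep(U, 2, sv$d[seq_len(rank)], "*")
          g <- unname(suppressWarnings(
            quantreg::rq.fit.fnc(Xr, z,
              R = rbind(V, -V), r = r0, tau = 0.5
            )$coefficients
          ))
          drop(V %*% g)
        }
      },
      error = function(e) f # degenerate program: fall back to clipping
    )
    f <- pmin(pmax(f, box[1]), box[2])
    status <- "bounded"
  }
  list(f = f, status = status, rank = rank)
}

#' Fit the p-parameter model to a benchset
#'
#' Finds the free parameters minimizing the mean absolute deviation between
#' model energies and reference energies over the training benchset. For
#' p >= 2 the problem is solved exactly as a linear program (least absolute
#' deviations on the affine-reduced design); for p = 1 a dense alpha scan at
#' `p1_grid_step` is refined by local univariate optimization. Rank-deficient
#' or data-poor designs (fewer processes than parameters) yield the
#' minimum-norm interpolating solution with `status = "underdetermined"`.
#'
#' @param b A `benchset` (the training set).
#' @param p Integer in 1..7, number of free parameters.
#' @param opts A [fit_options()] list.
#' @return An object of class `xyg_fit`: fields `p`, `free` (named free
#'   parameters), `a` (expanded 7-vector), `mad` (kcal/mol on the training
#'   set), `status` (`"global"`, `"bounded"`, or `"underdetermined"`),
#'   `trainset` (name), and `diagnostics`.
#' @export
fit_xyg <- function(b, p, opts = fit_options()) {
  validate_benchset(b)
  out <- fit_design(design_matrix(b), b$processes$ref_kcal, p, opts)
  out$trainset <- b$name
  out
}

# Design-level fitter shared by fit_xyg and the curation machinery, which
# re-fits thousands of row subsets of one pooled design matrix.
fit_design <- function(D, y, p, opts = fit_options()) {
  stopifnot(length(p) == 1, is.matrix(D), ncol(D) == 7, nrow(D) == length(y))
  if (!p %in% 1:7) stop("p must be an integer in 1..7", call. = FALSE)
  if (p == 1) {
    bas <- p1_basis(D)
    alphas <- seq(opts$p1_range[1], opts$p1_range[2], by = opts$p1_grid_step)
    A <- cbind(1, alphas, alphas^2)
    B <- rbind(bas$base - y, bas$lin, bas$quad)
    mads <- rowMeans(abs(A %*% B))
    near <- which(mads <= min(mads) + 1e-12)
    best <- near[which.min(abs(alphas[near]))] # tie-break: smallest |alpha|
    obj <- function(al) mean(abs(bas$base + al * bas$lin + al^2 * bas$quad - y))
    lo <- max(opts$p1_range[1], alphas[best] - opts$p1_grid_step)
    hi <- min(opts$p1_range[2], alphas[best] + opts$p1_grid_step)
    ref <- stats::optimize(obj, c(lo, hi), tol = opts$tolerance)
    if (ref$objective <= mads[best]) {
      alpha <- ref$minimum
      mad <- ref$objective
    } else {
      alpha <- alphas[best]
      mad <- mads[best]
    }
    at_edge <- min(alpha - opts$p1_range[1], opts$p1_range[2] - alpha) <
      2 * opts$p1_grid_step
    free <- c(alpha = alpha)
    status <- if (at_edge) "bounded" else "global"
    diagnostics <- list(grid_points = length(alphas), rank = NA_integer_)
    a <- expand_params(1, alpha)
  } else {
    map <- param_map(p)
    X <- D %*% map$M
    off <- drop(D %*% map$c)
    z <- y - off
    sol <- lad_solve(X, z, opts$box, opts$tolerance)
    free <- stats::setNames(sol$f, free_param_names(p))
    a <- expand_params(p, sol$f)
    mad <- mean(abs(drop(X %*% sol$f) - z))
    status <- sol$status
    diagnostics <- list(rank = sol$rank, n = nrow(X))
    if (status == "underdetermined") {
      warning(sprintf(
        "fit at p = %d is underdetermined (design rank %d < %d); minimum-norm solution returned",
        p, sol$rank, p
      ), call. = FALSE)
    }
  }
  structure(
    list(
      p = p, free = free, a = a, mad = mad, status = status,
      trainset = NA_character_, diagnostics = diagnostics
    ),
    class = "xyg_fit"
  )
}

#' @export
print.xyg_fit <- function(x, ...) {
  cat(sprintf(
    "xyg_fit: p = %d trained on '%s'  (MAD = %.6g kcal/mol, status: %s)\n",
    x$p, x$trainset, x$mad, x$status
  ))
  cat("free:", paste(sprintf("%s = %.6g", names(x$free), x$free), collapse = ", "), "\n")
  cat("a   :", paste(sprintf("%.6g", x$a), collapse = " "), "\n")
  invisible(x)
}

#' Brute-force grid oracle for the fit
#'
#' Exhaustively evaluates the training MAD over a regular grid of free
#' parameters and returns the best grid point, optionally refining by zooming
#' a finer grid (step / 10 each round, window +/- 2 previous steps) around the
#' incumbent. Entirely independent of the LP fitting path; intended as a
#' verification oracle at small p.
#'
#' @param b A `benchset`.
#' @param p Integer in 1..7.
#' @param lower,upper Per-dimension grid bounds (recycled to length `p`).
#'   Defaults: the [fit_options()] p1 range for p = 1, the default box
#'   otherwise.
#' @param step Grid step (scalar, shared by all dimensions).
#' @param refine Number of zoom rounds (default 0).
#' @param polish If `TRUE`, finish with a derivative-free Nelder-Mead descent
#'   from the best grid point (useful when the optimum sits in a narrow
#'   diagonal valley that axis-aligned grids track slowly); the result is
#'   still clipped to `[lower, upper]` and independent of the LP fitting
#'   path.
#' @param max_points Guard on the total number of grid points per round
#'   (default 1e7).
#' @return An `xyg_fit`-shaped object with `status = "grid"`.
#' @export
grid_oracle <- function(b, p, lower = NULL, upper = NULL, step,
                        refine = 0, polish = FALSE, max_points = 1e7) {
  validate_benchset(b)
  stopifnot(p %in% 1:7, step > 0, refine >= 0)
  if (is.null(lower)) lower <- if (p == 1) -0.5 else -3
  if (is.null(upper)) upper <- if (p == 1) 1.5 else 3
  lower <- rep_len(lower, p)
  upper <- rep_len(upper, p)
  D <- design_matrix(b)
  y <- b$processes$ref_kcal
  if (p == 1) {
    bas <- p1_basis(D)
    eval_grid <- function(G) {
      al <- G[, 1]
      rowMeans(abs(cbind(1, al, al^2) %*% rbind(bas$base - y, bas$lin, bas$quad)))
    }
  } else {
    map <- param_map(p)
    X <- D %*% map$M
    shift <- drop(D %*% map$c) - y
    eval_grid <- function(G) {
      out <- numeric(nrow(G))
      chunk <- max(1L, floor(5e6 / length(y)))
      for (s in seq(1, nrow(G), by = chunk)) {
        i <- s:min(s + chunk - 1, nrow(G))
        R <- tcrossprod(G[i, , drop = FALSE], X)
        out[i] <- rowMeans(abs(sweep(R, 2, shift, "+")))
      }
      out
    }
  }
  lo <- lower
  hi <- upper
  st <- step
  total <- 0
  best_f <- NULL
  best_mad <- Inf
  for (round in 0:refine) {
    seqs <- lapply(seq_len(p), function(k) seq(lo[k], hi[k], by = st))
    npts <- prod(lengths(seqs))
    if (npts > max_points) {
      stop(sprintf("grid too large: %.3g points > %.3g", npts, max_points),
        call. = FALSE
      )
    }
    G <- as.matrix(expand.grid(seqs, KEEP.OUT.ATTRS = FALSE))
    mads <- eval_grid(G)
    total <- total + npts
    ib <- which.min(mads)
    if (mads[ib] < best_mad) {
      best_mad <- mads[ib]
      best_f <- G[ib, ]
    }
    lo <- pmax(lower, best_f - 2 * st)
    hi <- pmin(upper, best_f + 2 * st)
    st <- st / 10
  }
  if (polish && p == 1) {
    win <- c(max(lower, best_f - 10 * st), min(upper, best_f + 10 * st))
    ref <- stats::optimize(function(al) eval_grid(matrix(al, 1)), win, tol = 1e-12)
    if (ref$objective < best_mad) {
      best_mad <- ref$objective
      best_f <- ref$minimum
    }
  } else if (polish) {
    objective <- function(f) {
      f <- pmin(pmax(f, lower), upper)
      eval_grid(matrix(f, 1))
    }
    nm <- stats::optim(best_f, objective,
      method = "Nelder-Mead",
      control = list(
        reltol = 1e-14, maxit = 5000,
        parscale = rep(max(step, 1e-6), p)
      )
    )
    if (nm$value < best_mad) {
      best_mad <- nm$value
      best_f <- pmin(pmax(nm$par, lower), upper)
    }
    # Simplex descent stalls at the kinks of a piecewise-linear objective;
    # finish with exact line searches (1-D convex minimization) along axes
    # and diagonal directions, iterated until no direction improves.
    dirs <- diag(p)
    if (p >= 2) {
      cmb <- utils::combn(p, 2)
      for (jj in seq_len(ncol(cmb))) {
        for (sgn in c(1, -1)) {
          v <- numeric(p)
          v[cmb[1, jj]] <- 1
          v[cmb[2, jj]] <- sgn
          dirs <- rbind(dirs, v / sqrt(2))
        }
      }
    }
    if (p >= 3) {
      signs <- as.matrix(expand.grid(rep(list(c(1, -1)), p - 1)))
      dirs <- rbind(dirs, cbind(1, signs) / sqrt(p))
    }
    radius <- max(1e-3, 20 * st)
    line_search <- function(v) {
      ls <- stats::optimize(
        function(t) objective(best_f + t * v),
        c(-radius, radius), tol = 1e-12
      )
      if (ls$objective < best_mad - 1e-15) {
        best_mad <<- ls$objective
        best_f <<- pmin(pmax(best_f + ls$minimum * v, lower), upper)
        TRUE
      } else {
        FALSE
      }
    }
    # At a kink the descent cone can be needle-thin, so fixed or random
    # directions stall. The valley of a least-absolute-deviations surface
    # runs along the null space of the currently active (smallest-residual)
    # design rows; those directions follow from the objective's own residuals
    # and an SVD, independent of any LP machinery.
    valley_dirs <- function(f) {
      r <- drop(X %*% f) + shift
      ord <- order(abs(r))
      out <- list()
      for (k in seq_len(max(p - 1, 1))) {
        A <- X[ord[seq_len(k)], , drop = FALSE]
        sv2 <- svd(A, nu = 0, nv = p)
        dvals <- c(sv2$d, rep(0, p - length(sv2$d)))
        rank <- sum(dvals > max(dvals[1], 1e-300) * 1e-8)
        if (rank < p) {
          for (jj in seq(rank + 1, p)) {
            out[[length(out) + 1]] <- sv2$v[, jj]
          }
        }
      }
      out
    }
    for (pass in 1:100) {
      improved <- any(vapply(seq_len(nrow(dirs)), function(jj) {
        line_search(dirs[jj, ])
      }, FALSE))
      for (v in valley_dirs(best_f)) {
        improved <- line_search(v) || improved
      }
      if (!improved) break
    }
  }
  free <- stats::setNames(unname(best_f), free_param_names(p))
  structure(
    list(
      p = p, free = free, a = expand_params(p, unname(best_f)),
      mad = best_mad, status = "grid", trainset = b$name,
      diagnostics = list(step_final = st * 10, points_total = total)
    ),
    class = "xyg_fit"
  )
}

#' Two-set error: MAD of a trained model on a test benchset
#'
#' Evaluates `MAD_B@A`: the mean absolute deviation on test set `test` of the
#' model carried by `train_fit` (trained on some set A).
#'
#' @param train_fit An `xyg_fit` (or any list with a length-7 numeric `a`).
#' @param test A `benchset`.
#' @return MAD in kcal/mol.
#' @export
cross_mad <- function(train_fit, test) {
  stopifnot(is.numeric(train_fit$a), length(train_fit$a) == 7)
  validate_benchset(test)
  mad_error(predict_energies(train_fit$a, test), test$processes$ref_kcal)
}
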