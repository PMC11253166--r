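# Genetic curation of compact, transferable training subsets. A candidate is
# a fixed-size set of process indices into a pool benchset; breeding success
# is the (inverse) mean transferability from the candidate to a list of
# evaluation subsets at p = 7, and final selection balances transferability
# (averaged over p in {1, 4, 7} to avoid accidental single-p transferability)
# against the number of unique chemical elements the candidate spans.

#' Genetic-algorithm options for subset breeding
#'
#' Standard operator choices: tournament selection, uniform membership
#' crossover with random size repair, per-slot swap mutation, small elitism.
#'
#' @param population Population size (default 32).
#' @param generations Number of generations (default 200).
#' @param tournament_k Tournament size (default 2).
#' @param mutation_rate Per-slot probability of swapping a member for a
#'   random non-member (default 0.05).
#' @param elitism Number of best individuals copied unchanged (default 2).
#' @param stagnation Generations without best-ever improvement after which
#'   the non-elite population is reinitialized at random (default 25);
#'   escapes single-swap local optima on small pools.
#' @param fitness_p Model size used in the breeding fitness (default 7).
#' @param eta Transferability regularization, kcal/mol.
#' @param seed Master seed; independent GA runs use `seed + run` offsets.
#' @return A list of class `ga_options`.
#' @export
ga_options <- function(population = 32, generations = 200, tournament_k = 2,
                       mutation_rate = 0.05, elitism = 2, stagnation = 25,
                       fitness_p = 7, eta = 0.01, seed = 0) {
  stopifnot(
    population >= 2, generations >= 1, tournament_k >= 1,
    mutation_rate >= 0, mutation_rate <= 1, elitism >= 0,
    elitism < population, stagnation >= 1, fitness_p %in% 1:7, eta > 0
  )
  structure(
    list(
      population = population, generations = generations,
      tournament_k = tournament_k, mutation_rate = mutation_rate,
      elitism = elitism, stagnation = stagnation,
      fitness_p = fitness_p, eta = eta, seed = seed
    ),
    class = "ga_options"
  )
}

# Internal evaluator shared by fitness and scoring. Precomputes the pool
# design matrix, the evaluation-set designs and their per-p accuracy limits
# MAD_S@S, and per-process element sets, so candidate evaluation is pure
# linear algebra: fit the candidate rows, predict each evaluation set, form
# the mean transferability ratio.
curation_evaluator <- function(pool, eval_subsets, p_list, fit_opts, eta) {
  D <- design_matrix(pool)
  y <- pool$processes$ref_kcal
  eval_d <- lapply(eval_subsets, design_matrix)
  eval_y <- lapply(eval_subsets, function(s) s$processes$ref_kcal)
  mad_ss <- lapply(p_list, function(p) {
    vapply(seq_along(eval_subsets), function(i) {
      suppressWarnings(fit_design(eval_d[[i]], eval_y[[i]], p, fit_opts))$mad
    }, 0)
  })
  names(mad_ss) <- paste0("p", p_list)
  el_of <- lapply(pool$processes$stoich, function(st) {
    rows <- pool$species$formula[match(names(st), pool$species$id)]
    unique(unlist(lapply(parse_formula(rows), names)))
  })
  tbar <- function(indices, p) {
    fit <- suppressWarnings(fit_design(D[indices, , drop = FALSE], y[indices], p, fit_opts))
    tv <- vapply(seq_along(eval_d), function(i) {
      mad_ba <- mean(abs(drop(eval_d[[i]] %*% fit$a) - eval_y[[i]]))
      (mad_ba + eta) / (mad_ss[[paste0("p", p)]][i] + eta)
    }, 0)
    mean(tv)
  }
  n_el <- function(indices) length(unique(unlist(el_of[indices])))
  list(tbar = tbar, n_el = n_el)
}

#' Breed transferable fixed-size subsets of a pool by a genetic algorithm
#'
#' Runs `n_candidates` independent GA runs (seeded `opts$seed + run`), each
#' evolving fixed-size subsets of the pool's processes. The fitness of a
#' candidate is the reciprocal of its mean transferability at
#' `opts$fitness_p` to the evaluation subsets:
#' `1 / mean_S T_S@candidate`, so perfectly transferable candidates approach
#' fitness 1 from below. Each run returns its best-ever individual.
#'
#' @param pool A `benchset` to draw processes from.
#' @param eval_subsets Non-empty list of `benchset`s transfer is scored
#'   against.
#' @param n_candidates Number of independent runs (= returned candidates).
#' @param size Subset size (< number of pool processes).
#' @param opts A [ga_options()] list.
#' @param fit_opts A [fit_options()] list.
#' @return A list of `subset_candidate` objects: fields `indices` (sorted),
#'   `fitness`, `n_el`, `run`.
#' @export
ga_breed <- function(pool, eval_subsets, n_candidates, size,
                     opts = ga_options(), fit_opts = fit_options()) {
  validate_benchset(pool)
  npool <- n_processes(pool)
  if (size >= npool) stop("size must be smaller than the pool", call. = FALSE)
  if (length(eval_subsets) == 0) stop("empty eval_subsets", call. = FALSE)
  for (s in eval_subsets) validate_benchset(s)
  ev <- curation_evaluator(pool, eval_subsets, opts$fitness_p, fit_opts, opts$eta)
  cache <- new.env(parent = emptyenv())
  fitness_of <- function(idx) {
    key <- paste(sort(idx), collapse = ",")
    if (!is.null(cache[[key]])) {
      return(cache[[key]])
    }
    val <- 1 / ev$tbar(sort(idx), opts$fitness_p)
    cache[[key]] <- val
    val
  }
  repair <- function(idx) {
    idx <- unique(idx)
    if (length(idx) > size) {
      idx <- idx[sample.int(length(idx), size)]
    } else if (length(idx) < size) {
      idx <- c(idx, resample(setdiff(seq_len(npool), idx), size - length(idx)))
    }
    idx
  }
  run_one <- function(run) {
    set.seed(opts$seed + run)
    popn <- replicate(opts$population, sample.int(npool, size), simplify = FALSE)
    fit <- vapply(popn, fitness_of, 0)
    best_idx <- popn[[which.max(fit)]]
    best_fit <- max(fit)
    stagnant <- 0L
    for (gen in seq_len(opts$generations)) {
      ord <- order(fit, decreasing = TRUE)
      nextgen <- popn[ord[seq_len(opts$elitism)]]
      if (stagnant >= opts$stagnation) {
        # diversity collapse: restart the non-elite population
        while (length(nextgen) < opts$population) {
          nextgen[[length(nextgen) + 1]] <- sample.int(npool, size)
        }
        popn <- nextgen
        fit <- vapply(popn, fitness_of, 0)
        stagnant <- 0L
        if (max(fit) > best_fit) {
          best_fit <- max(fit)
          best_idx <- popn[[which.max(fit)]]
        }
        next
      }
      while (length(nextgen) < opts$population) {
        pick_parent <- function() {
          contenders <- sample.int(opts$population, opts$tournament_k, replace = TRUE)
          popn[[contenders[which.max(fit[contenders])]]]
        }
        p1 <- pick_parent()
        p2 <- pick_parent()
        shared <- intersect(p1, p2)
        only <- c(setdiff(p1, p2), setdiff(p2, p1))
        child <- c(shared, only[stats::runif(length(only)) < 0.5])
        child <- repair(child)
        mut <- stats::runif(size) < opts$mutation_rate
        if (any(mut)) {
          swaps <- resample(setdiff(seq_len(npool), child), sum(mut))
          child[mut] <- swaps
        }
        nextgen[[length(nextgen) + 1]] <- child
      }
      popn <- nextgen
      fit <- vapply(popn, fitness_of, 0)
      if (max(fit) > best_fit) {
        best_fit <- max(fit)
        best_idx <- popn[[which.max(fit)]]
        stagnant <- 0L
      } else {
        stagnant <- stagnant + 1L
      }
    }
    structure(
      list(
        indices = sort(best_idx), fitness = best_fit,
        n_el = ev$n_el(sort(best_idx)), run = run
      ),
      class = "subset_candidate"
    )
  }
  lapply(seq_len(n_candidates), run_one)
}

#' @export
print.subset_candidate <- function(x, ...) {
  cat(sprintf(
    "subset_candidate (run %s): %d processes, fitness %.4g, N_el %d\n",
    as.character(x$run %||% NA), length(x$indices), x$fitness, x$n_el
  ))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Transferable-diversity score of a candidate subset
#'
#' `score = N_el(candidate) / mean_p T_bar_p(candidate)`, where
#' `T_bar_p` is the mean transferability at model size p from the candidate
#' to all evaluation subsets, averaged over `p_list` (default {1, 4, 7}) to
#' avoid accidental transferability at any single parameter count, and
#' `N_el` is the number of unique elements the candidate spans (the
#' element-diversity bias). Higher is better. This functional form is a
#' reconstruction from the published textual constraints (see the methods
#' vignette), not a verbatim published formula.
#'
#' @param candidate A `subset_candidate`, or an integer vector of process
#'   indices into `pool`.
#' @param pool A `benchset`.
#' @param eval_subsets List of `benchset`s.
#' @param p_list Model sizes to average over (default `c(1, 4, 7)`).
#' @param fit_opts A [fit_options()] list.
#' @param eta Transferability regularization, kcal/mol.
#' @return The numeric score (attributes `n_el` and `tbar`, the per-p mean
#'   transferabilities).
#' @export
score_candidate <- function(candidate, pool, eval_subsets,
                            p_list = c(1, 4, 7), fit_opts = fit_options(),
                            eta = 0.01) {
  if (inherits(candidate, "subset_candidate")) candidate <- candidate$indices
  stopifnot(length(candidate) >= 1, length(p_list) >= 1)
  if (length(eval_subsets) == 0) stop("empty eval_subsets", call. = FALSE)
  ev <- curation_evaluator(pool, eval_subsets, p_list, fit_opts, eta)
  tbar <- vapply(p_list, function(p) ev$tbar(sort(candidate), p), 0)
  names(tbar) <- paste0("p", p_list)
  n_el <- ev$n_el(sort(candidate))
  structure(n_el / mean(tbar), n_el = n_el, tbar = tbar)
}

#' Select the best-scoring candidate as a benchset
#'
#' Scores every candidate with [score_candidate()] and materializes the
#' argmax as a `benchset`. Ties break toward higher element count, then
#' toward the earlier candidate in the list.
#'
#' @param candidates Non-empty list of `subset_candidate`s (or index
#'   vectors).
#' @param pool A `benchset`.
#' @param eval_subsets List of `benchset`s.
#' @param p_list,fit_opts,eta Passed to [score_candidate()].
#' @param name Name for the selected benchset.
#' @return The selected `benchset`, with attributes `scores` (all candidate
#'   scores) and `selected` (the winning candidate's index in the list).
#' @export
select_best <- function(candidates, pool, eval_subsets, p_list = c(1, 4, 7),
                        fit_opts = fit_options(), eta = 0.01,
                        name = "selected") {
  if (length(candidates) == 0) stop("empty candidate list", call. = FALSE)
  ev <- curation_evaluator(pool, eval_subsets, p_list, fit_opts, eta)
  idx_of <- lapply(candidates, function(cd) {
    sort(if (inherits(cd, "subset_candidate")) cd$indices else cd)
  })
  scores <- vapply(idx_of, function(idx) {
    ev$n_el(idx) / mean(vapply(p_list, function(p) ev$tbar(idx, p), 0))
  }, 0)
  n_els <- vapply(idx_of, function(idx) ev$n_el(idx), 0L)
  ord <- order(-scores, -n_els, seq_along(candidates))
  win <- ord[1]
  idx <- if (inherits(candidates[[win]], "subset_candidate")) {
    candidates[[win]]$indices
  } else {
    candidates[[win]]
  }
  out <- subset_benchset(pool, sort(idx), name = name)
  attr(out, "scores") <- scores
  attr(out, "selected") <- win
  out
}
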