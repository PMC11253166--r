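# Fixtures are built in code; nothing is read from disk except in the I/O
# round-trip tests, which write to tempdir().

# Minimal hand-built benchset: two species, two processes.
tiny_benchset <- function() {
  species <- data.frame(
    id = c("X", "Y"), formula = c("H2O", "CH4"),
    stringsAsFactors = FALSE
  )
  species[paste0("c", 1:7)] <- 0
  species$c1 <- c(1, 0.5)
  species$c3 <- c(0.2, -0.1)
  processes <- data.frame(
    id = c("r1", "r2"), subset = c("s", "s"),
    ref_kcal = c(100, -50), stringsAsFactors = FALSE
  )
  processes$stoich <- list(c(X = 1), c(X = -1, Y = 2))
  benchset("tiny", species, processes)
}

# Species with a single unit component c1 = 1 hartree; one process "1 X".
unit_benchset <- function() {
  species <- data.frame(id = "X", formula = "H", stringsAsFactors = FALSE)
  species[paste0("c", 1:7)] <- 0
  species$c1 <- 1
  processes <- data.frame(
    id = "u", subset = "s", ref_kcal = 0,
    stringsAsFactors = FALSE
  )
  processes$stoich <- list(c(X = 1))
  benchset("unit", species, processes)
}

# Single-regime synthetic benchset with a planted two-parameter model.
one_regime_benchset <- function(n_processes, seed, noise_sigma = 0.5,
                                n_species = 30, alpha = 0.65, beta = 0.8) {
  generate_benchset(synthetic_spec(
    n_species = n_species, n_processes = n_processes,
    regimes = list(list(
      name = "main", planted_a = expand_params(2, c(alpha, beta)),
      weight = 1, flatness = rep(1, 7)
    )),
    noise_sigma = noise_sigma, seed = seed
  ))
}

# Three seeded single-regime benchsets with distinct planted optima.
three_benchsets <- function(n = 40, seed = 0) {
  mk <- function(nm, al, be, s) {
    b <- generate_benchset(synthetic_spec(
      n_species = 30, n_processes = n,
      regimes = list(list(
        name = nm, planted_a = expand_params(2, c(al, be)),
        weight = 1, flatness = rep(1, 7)
      )),
      noise_sigma = 0.4, seed = s
    ))
    b$name <- nm
    b
  }
  list(
    A = mk("A", 0.55, 0.7, seed + 11),
    B = mk("B", 0.70, 1.0, seed + 22),
    C = mk("C", 0.62, 0.85, seed + 33)
  )
}

# Pool + per-regime evaluation subsets for small GA tests.
ga_test_pool <- function(seed = 10, n_processes = 12, n_species = 24) {
  pool <- generate_benchset(synthetic_spec(
    n_species = n_species, n_processes = n_processes,
    regimes = list(
      list(
        name = "main", planted_a = expand_params(2, c(0.6, 0.8)),
        weight = 2, flatness = rep(1, 7)
      ),
      list(
        name = "tm", planted_a = expand_params(2, c(0.8, 1.2)),
        weight = 1, flatness = rep(1, 7)
      )
    ),
    noise_sigma = 0.3, seed = seed
  ))
  list(pool = pool, evals = split_by_subset(pool))
}

# Exhaustive best GA fitness over all size-k subsets of the pool.
exhaustive_best_fitness <- function(pool, evals, size, p = 7,
                                    fit_opts = fit_options(), eta = 0.01) {
  combos <- utils::combn(n_processes(pool), size)
  D <- design_matrix(pool)
  y <- pool$processes$ref_kcal
  mad_ss <- vapply(evals, function(s) {
    suppressWarnings(fit_xyg(s, p, fit_opts))$mad
  }, 0)
  eval_d <- lapply(evals, design_matrix)
  eval_y <- lapply(evals, function(s) s$processes$ref_kcal)
  best <- -Inf
  for (jj in seq_len(ncol(combos))) {
    idx <- combos[, jj]
    fit <- suppressWarnings(tatkit:::fit_design(D[idx, , drop = FALSE], y[idx], p, fit_opts))
    tv <- vapply(seq_along(eval_d), function(i) {
      (mean(abs(drop(eval_d[[i]] %*% fit$a) - eval_y[[i]])) + eta) / (mad_ss[i] + eta)
    }, 0)
    best <- max(best, 1 / mean(tv))
  }
  best
}
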