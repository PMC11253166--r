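# Seeded synthetic benchmark generator. Plants a known parameter vector per
# "chemistry regime", draws per-species component vectors with a realistic
# magnitude hierarchy (exchange components much larger than MP2 components),
# builds random sparse integer-coefficient stoichiometries, and sets
# reference energies to planted-model predictions plus Gaussian noise. Every
# other module is testable against these fixtures without any real
# quantum-chemistry input.

#' Specification for a synthetic benchset
#'
#' @param n_species Total number of species, shared out over regimes in
#'   proportion to their weights.
#' @param n_processes Total number of processes, likewise.
#' @param regimes List of regimes; each is a list with fields `name`,
#'   `planted_a` (length-7 numeric, the parameter vector generating that
#'   regime's reference energies), `weight` (> 0), and `flatness` (length-7
#'   positive factors multiplying the regime's component magnitudes; factors
#'   much below 1 on the slots an MP2 fraction touches make the regime's MAD
#'   insensitive to that parameter, i.e. a flat error landscape). Defaults: a
#'   "sharp" regime (alpha = 0.65, beta = 0.7, unit flatness) and a "flat"
#'   regime (alpha = 0.65, beta = 1.3, flatness 0.1 on the correlation slots
#'   5-7 that the tied MP2 fraction multiplies), emulating the
#'   thermodynamics-vs-kinetics asymmetry of sharply and weakly curved cost
#'   landscapes with distinct planted optima.
#' @param noise_sigma Gaussian noise s.d. on reference energies, kcal/mol.
#' @param component_sd Length-7 positive s.d. of species components
#'   (hartree); the default hierarchy makes exchange components an order of
#'   magnitude larger than MP2 components, mimicking real energetics
#'   (stylized constants, not fitted to any real data).
#' @param element_pool Element symbols species draw from.
#' @param element_weights Optional sampling weights over `element_pool`
#'   (default uniform).
#' @param elements_per_species Length-2 integer range of distinct elements
#'   per species.
#' @param species_per_process Length-2 integer range of species per process.
#' @param coeff_values Stoichiometric coefficients sampled per term
#'   (integer-valued by default, mimicking reaction equations).
#' @param seed Master seed; all randomness flows from it via fixed per-phase
#'   offsets (+1 components, +2 elements, +3 stoichiometries, +4 noise), so
#'   e.g. changing only the noise phase never perturbs the species table.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_species = 60, n_processes = 120,
                           regimes = default_regimes(),
                           noise_sigma = 0.5,
                           component_sd = c(0.05, 0.02, 0.05, 0.01, 0.02, 0.004, 0.008),
                           element_pool = c(
                             "H", "C", "N", "O", "F", "P", "S", "Cl",
                             "Si", "B", "Ti", "Fe", "Ni", "Cu", "Zn", "Br"
                           ),
                           element_weights = NULL,
                           elements_per_species = c(2, 4),
                           species_per_process = c(2, 5),
                           coeff_values = c(-2, -1, 1, 2),
                           seed = 0) {
  stopifnot(
    n_species >= 2, n_processes >= 1, length(regimes) >= 1,
    noise_sigma >= 0, length(component_sd) == 7, all(component_sd > 0),
    length(elements_per_species) == 2, length(species_per_process) == 2,
    all(coeff_values != 0), length(element_pool) >= 1
  )
  for (r in regimes) {
    stopifnot(
      is.character(r$name), length(r$planted_a) == 7,
      all(is.finite(r$planted_a)), r$weight > 0,
      length(r$flatness) == 7, all(r$flatness > 0)
    )
  }
  if (!is.null(element_weights)) {
    stopifnot(length(element_weights) == length(element_pool), all(element_weights >= 0))
  }
  structure(
    list(
      n_species = n_species, n_processes = n_processes, regimes = regimes,
      noise_sigma = noise_sigma, component_sd = component_sd,
      element_pool = element_pool, element_weights = element_weights,
      elements_per_species = elements_per_species,
      species_per_process = species_per_process,
      coeff_values = coeff_values, seed = seed
    ),
    class = "synthetic_spec"
  )
}

#' Default two-regime structure for [synthetic_spec()]
#'
#' @return A list of two regimes, "sharp" and "flat" (see [synthetic_spec()]).
#' @export
default_regimes <- function() {
  list(
    list(
      name = "sharp", planted_a = expand_params(2, c(0.65, 0.7)),
      weight = 1, flatness = rep(1, 7)
    ),
    list(
      name = "flat", planted_a = expand_params(2, c(0.65, 1.3)),
      weight = 1, flatness = c(1, 1, 1, 1, 0.1, 0.1, 0.1)
    )
  )
}

# Largest-remainder apportionment of n items over weights (deterministic).
apportion <- function(n, weights) {
  q <- n * weights / sum(weights)
  base <- floor(q)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(q - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Generate a synthetic benchset
#'
#' Species are allocated to regimes by weight; their seven components are
#' zero-mean Gaussians scaled by `component_sd` and the regime's flatness
#' factors. Processes are random sparse stoichiometries over species of one
#' regime; reference energies are the regime's planted-model predictions plus
#' Gaussian noise; the subset label is the regime name. Fully determined by
#' `spec$seed`.
#'
#' The drawn noise vector is attached as `attr(b, "planted")$noise`, so
#' planted-model residuals can be reconstructed bitwise in tests.
#'
#' @param spec A [synthetic_spec()].
#' @return A `benchset`.
#' @export
generate_benchset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  k <- length(spec$regimes)
  if (spec$n_species < k * spec$species_per_process[2]) {
    stop("infeasible spec: too few species per regime for the largest stoichiometry",
      call. = FALSE
    )
  }
  w <- vapply(spec$regimes, `[[`, 1, "weight")
  nsp <- apportion(spec$n_species, w)
  npr <- apportion(spec$n_processes, w)
  if (any(npr == 0)) {
    stop("infeasible spec: a regime received zero processes", call. = FALSE)
  }
  regime_of_species <- rep(seq_len(k), nsp)
  sp_id <- sprintf("S%04d", seq_len(spec$n_species))

  # Phase 1: component vectors (seed + 1)
  set.seed(spec$seed + 1L)
  comp <- matrix(stats::rnorm(spec$n_species * 7), spec$n_species, 7)
  comp <- sweep(comp, 2, spec$component_sd, "*")
  for (j in seq_len(k)) {
    rows <- regime_of_species == j
    comp[rows, ] <- sweep(comp[rows, , drop = FALSE], 2, spec$regimes[[j]]$flatness, "*")
  }

  # Phase 2: element compositions (seed + 2)
  set.seed(spec$seed + 2L)
  formulas <- vapply(seq_len(spec$n_species), function(i) {
    ne <- resample(spec$elements_per_species[1]:spec$elements_per_species[2], 1)
    ne <- min(ne, length(spec$element_pool))
    els <- resample(spec$element_pool, ne, prob = spec$element_weights)
    counts <- resample(1:3, ne, replace = TRUE)
    names(counts) <- els
    format_formula(counts)
  }, "")

  # Phase 3: stoichiometries (seed + 3)
  set.seed(spec$seed + 3L)
  regime_of_process <- rep(seq_len(k), npr)
  stoich <- vector("list", spec$n_processes)
  for (j in seq_len(spec$n_processes)) {
    reg <- regime_of_process[j]
    pool_ids <- sp_id[regime_of_species == reg]
    ns <- resample(spec$species_per_process[1]:spec$species_per_process[2], 1)
    ns <- min(ns, length(pool_ids))
    ids <- resample(pool_ids, ns)
    co <- resample(spec$coeff_values, ns, replace = TRUE)
    names(co) <- ids
    stoich[[j]] <- co
  }

  # Phase 4: reference energies = planted prediction + noise (seed + 4)
  set.seed(spec$seed + 4L)
  noise <- stats::rnorm(spec$n_processes, 0, spec$noise_sigma)
  rownames(comp) <- sp_id
  planted_pred <- vapply(seq_len(spec$n_processes), function(j) {
    st <- stoich[[j]]
    d <- drop(crossprod(comp[names(st), , drop = FALSE], st)) * kcal_per_hartree
    sum(d * spec$regimes[[regime_of_process[j]]]$planted_a)
  }, 0)
  ref <- planted_pred + noise
  noise <- ref - planted_pred # store the exactly reconstructable residual

  species <- data.frame(id = sp_id, formula = formulas, stringsAsFactors = FALSE)
  species[paste0("c", 1:7)] <- as.data.frame(comp)
  processes <- data.frame(
    id = sprintf("P%04d", seq_len(spec$n_processes)),
    subset = vapply(spec$regimes, `[[`, "", "name")[regime_of_process],
    ref_kcal = ref, stringsAsFactors = FALSE
  )
  processes$stoich <- stoich
  b <- benchset("synthetic", species, processes)
  attr(b, "planted") <- list(
    noise = noise, planted_pred = planted_pred,
    regime_of_process = regime_of_process
  )
  b
}

#' Generate a sharp/flat benchset pair sharing one species table
#'
#' Builds the two-regime fixture emulating the asymmetry between sharply and
#' weakly curved error landscapes: one regime with near-unit flatness
#' ("sharp") and one with small factors on the MP2 components ("flat"),
#' planted at distinct optima. Both returned benchsets carry the full shared
#' species table bit-identically. At the default spec and seed 0 the
#' two-parameter transferability matrix satisfies
#' `t[flat, sharp] < t[sharp, flat]`: the flat set forgives a model trained
#' elsewhere, while the sharp set punishes the flat set's poorly pinned-down
#' parameters.
#'
#' @param spec A [synthetic_spec()] with exactly 2 regimes.
#' @return A named list of two `benchset`s, in regime order.
#' @export
generate_two_regime <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (length(spec$regimes) != 2) {
    stop("spec must have exactly 2 regimes", call. = FALSE)
  }
  split_by_subset(generate_benchset(spec))
}

#' Generate a curation pool with a planted high-quality subset
#'
#' Generates a pool benchset (typically with skewed regime weights, see
#' [curation_spec()]) and deterministically designates a planted subset of
#' `planted_size` processes with balanced regime coverage and greedily
#' maximal element coverage. Planted rows additionally get their reference
#' noise scaled by `planted_noise_factor` (default 0: benchmark-quality,
#' noise-free references), emulating a curated subset whose benchmarks are
#' more accurate than the pool at large. Together these make the planted
#' subset's mean transferability to the per-regime subsets and its element
#' count N_el beat random size-matched subsets — ground truth for testing
#' the curation machinery.
#'
#' @param spec A [synthetic_spec()] with >= 2 regimes.
#' @param planted_size Size of the planted subset (< `n_processes`).
#' @param planted_noise_factor Factor in `[0, 1]` applied to the noise of
#'   planted rows (default 0).
#' @return A list with fields `pool` (a `benchset`) and `planted` (sorted
#'   integer process indices into the pool). The pool's `"planted"`
#'   attribute reflects the rescaled noise, so residual reconstruction stays
#'   exact.
#' @export
generate_curation_pool <- function(spec, planted_size, planted_noise_factor = 0) {
  stopifnot(inherits(spec, "synthetic_spec"), length(spec$regimes) >= 2)
  if (planted_size >= spec$n_processes) {
    stop("planted_size must be smaller than n_processes", call. = FALSE)
  }
  pool <- generate_benchset(spec)
  reg <- pool$processes$subset
  regimes <- unique(reg)
  el_of <- lapply(pool$processes$stoich, function(st) {
    rows <- pool$species$formula[match(names(st), pool$species$id)]
    unique(unlist(lapply(parse_formula(rows), names)))
  })
  sel <- integer(0)
  covered <- character(0)
  # round-robin over regimes, rarest first, greedy on new-element gain
  order_reg <- regimes[order(table(reg)[regimes])]
  ri <- 0L
  while (length(sel) < planted_size) {
    r <- order_reg[(ri %% length(order_reg)) + 1L]
    ri <- ri + 1L
    cand <- setdiff(which(reg == r), sel)
    if (length(cand) == 0) next
    gain <- vapply(cand, function(j) length(setdiff(el_of[[j]], covered)), 0L)
    pick <- cand[which.max(gain)] # which.max: ties -> lowest index
    sel <- c(sel, pick)
    covered <- union(covered, el_of[[pick]])
  }
  sel <- sort(sel)
  pl <- attr(pool, "planted")
  pl$noise[sel] <- planted_noise_factor * pl$noise[sel]
  pool$processes$ref_kcal[sel] <- pl$planted_pred[sel] + pl$noise[sel]
  pl$noise[sel] <- pool$processes$ref_kcal[sel] - pl$planted_pred[sel]
  attr(pool, "planted") <- pl
  list(pool = pool, planted = sel)
}

#' Canonical study conditions for curation testing
#'
#' A [synthetic_spec()] tailored to exercising the curation machinery: one
#' dominant "main" regime whose species are nearly silent in the auxiliary
#' component slots 2 and 4 (so training sets drawn only from it cannot pin
#' those parameters at p >= 4), two rare full-component regimes ("tm", "bh"),
#' a common planted parameter vector, a 26-element pool in which elements
#' beyond H/C/N/O are rare, and moderate reference noise. Under these
#' conditions a subset with balanced regime coverage and wide element
#' coverage is structurally better training data than a typical random
#' subset — which is exactly what the planted subset of
#' [generate_curation_pool()] provides.
#'
#' @param seed Master seed (default 0).
#' @param n_species,n_processes,noise_sigma As in [synthetic_spec()].
#' @return A `synthetic_spec`.
#' @export
curation_spec <- function(seed = 0, n_species = 60, n_processes = 100,
                          noise_sigma = 0.3) {
  a0 <- expand_params(2, c(0.6, 0.8))
  synthetic_spec(
    n_species = n_species, n_processes = n_processes,
    regimes = list(
      list(
        name = "main", planted_a = a0, weight = 8,
        flatness = c(1, 0.05, 1, 0.05, 1, 1, 1)
      ),
      list(name = "tm", planted_a = a0, weight = 1, flatness = rep(1, 7)),
      list(name = "bh", planted_a = a0, weight = 1, flatness = rep(1, 7))
    ),
    noise_sigma = noise_sigma,
    element_pool = c(
      "H", "C", "N", "O", "F", "P", "S", "Cl", "Si", "B", "Br", "I",
      "Na", "K", "Mg", "Ca", "Al", "Ti", "V", "Cr", "Mn", "Fe", "Co",
      "Ni", "Cu", "Zn"
    ),
    element_weights = c(rep(12, 4), rep(0.4, 22)),
    elements_per_species = c(1, 3),
    seed = seed
  )
}
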