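test_that("GA runs are deterministic under the master seed", {
  gp <- ga_test_pool()
  o <- ga_options(generations = 10, seed = 7)
  c1 <- ga_breed(gp$pool, gp$evals, 2, 4, o)
  c2 <- ga_breed(gp$pool, gp$evals, 2, 4, o)
  expect_identical(
    lapply(c1, `[[`, "indices"),
    lapply(c2, `[[`, "indices")
  )
  expect_identical(
    vapply(c1, `[[`, 0, "fitness"),
    vapply(c2, `[[`, 0, "fitness")
  )
})

test_that("candidates always have exactly the requested size and valid indices", {
  gp <- ga_test_pool(seed = 12)
  cands <- ga_breed(
    gp$pool, gp$evals, 3, 5,
    ga_options(generations = 15, mutation_rate = 0.3, seed = 3)
  )
  for (cd in cands) {
    expect_length(cd$indices, 5)
    expect_false(anyDuplicated(cd$indices) > 0)
    expect_true(all(cd$indices >= 1 & cd$indices <= n_processes(gp$pool)))
  }
})

test_that("GA reaches the exhaustive optimum on a small pool", {
  gp <- ga_test_pool(seed = 10)
  best <- exhaustive_best_fitness(gp$pool, gp$evals, 4)
  cands <- ga_breed(
    gp$pool, gp$evals, 2, 4,
    ga_options(generations = 60, seed = 1)
  )
  for (cd in cands) {
    expect_gte(cd$fitness, 0.95 * best)
  }
})

test_that("score_candidate equals the decided N_el / mean-transferability formula", {
  gp <- ga_test_pool(seed = 14, n_processes = 16)
  idx <- c(2, 5, 9, 13)
  sc <- score_candidate(idx, gp$pool, gp$evals, p_list = c(1, 4, 7))
  # independent recomputation through the public fitting API
  cand <- subset_benchset(gp$pool, idx, name = "cand")
  tbar <- vapply(c(1, 4, 7), function(p) {
    fit <- suppressWarnings(fit_xyg(cand, p))
    mean(vapply(gp$evals, function(s) {
      mad_ss <- suppressWarnings(fit_xyg(s, p))$mad
      (cross_mad(fit, s) + 0.01) / (mad_ss + 0.01)
    }, 0))
  }, 0)
  n_el <- length(unique_elements(cand))
  expect_equal(as.numeric(sc), n_el / mean(tbar), tolerance = 1e-9)
  expect_equal(attr(sc, "n_el"), n_el)
  expect_equal(unname(attr(sc, "tbar")), tbar, tolerance = 1e-9)
  # fitness and score are invariant to the order of the indices
  expect_equal(
    as.numeric(score_candidate(rev(idx), gp$pool, gp$evals)),
    as.numeric(score_candidate(idx, gp$pool, gp$evals))
  )
})

test_that("select_best is the argmax of independent re-scoring", {
  gp <- ga_test_pool(seed = 16, n_processes = 14)
  set.seed(5)
  cands <- replicate(6, sort(sample.int(14, 4)), simplify = FALSE)
  sel <- select_best(cands, gp$pool, gp$evals, name = "picked")
  scores <- vapply(
    cands, function(i) as.numeric(score_candidate(i, gp$pool, gp$evals)), 0
  )
  expect_equal(attr(sel, "selected"), which.max(scores))
  expect_equal(
    sort(match(sel$processes$id, gp$pool$processes$id)),
    cands[[which.max(scores)]]
  )
  # a single candidate is returned as-is; duplicated scores break to the first
  one <- select_best(cands[1], gp$pool, gp$evals)
  expect_equal(attr(one, "selected"), 1L)
  dup <- select_best(c(cands[2], cands[2]), gp$pool, gp$evals)
  expect_equal(attr(dup, "selected"), 1L)
  expect_error(select_best(list(), gp$pool, gp$evals), "empty")
})

test_that("the planted curated subset outscores random subsets", {
  cp <- generate_curation_pool(curation_spec(seed = 0), 12)
  expect_true(all(cp$planted >= 1 & cp$planted <= n_processes(cp$pool)))
  evals <- split_by_subset(cp$pool)
  sc <- as.numeric(score_candidate(cp$planted, cp$pool, evals))
  set.seed(123)
  rand <- replicate(
    100,
    as.numeric(score_candidate(
      sort(sample.int(n_processes(cp$pool), 12)), cp$pool, evals
    ))
  )
  expect_gt(sc, stats::quantile(rand, 0.95))
})
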