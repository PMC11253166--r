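test_that("transferability matrix diagonal is exactly 1", {
  sets <- three_benchsets()
  for (p in c(1, 4)) {
    tm <- tat_matrix(sets, p)
    expect_equal(unname(diag(tm$t)), rep(1, 3), tolerance = 1e-9)
  }
})

test_that("identical sets give an all-ones matrix", {
  b <- one_regime_benchset(30, seed = 91)
  b2 <- b
  b2$name <- "copy"
  tm <- tat_matrix(list(a = b, b = b2), 3)
  expect_equal(unname(tm$t), matrix(1, 2, 2), tolerance = 1e-9)
})

test_that("every matrix entry matches an independent fit + ratio recomputation", {
  sets <- three_benchsets(seed = 5)
  p <- 4
  tm <- tat_matrix(sets, p)
  for (A in names(sets)) {
    fa <- fit_xyg(sets[[A]], p)
    for (B in names(sets)) {
      mad_ba <- mad_error(
        predict_energies(fa$a, sets[[B]]),
        sets[[B]]$processes$ref_kcal
      )
      expect_equal(tm$mad[B, A], mad_ba, tolerance = 1e-10)
      mad_bb <- fit_xyg(sets[[B]], p)$mad
      expect_equal(tm$t[B, A], (mad_ba + 0.01) / (mad_bb + 0.01), tolerance = 1e-9)
    }
  }
})

test_that("off-diagonal entries respect the minimization bound for global fits", {
  sets <- three_benchsets(seed = 9)
  for (p in c(2, 5, 7)) {
    tm <- tat_matrix(sets, p)
    expect_true(all(tm$statuses == "global"))
    expect_true(all(tm$t >= 1 - 1e-6))
  }
})

test_that("transfer-energy matrix has zero diagonal and consistent algebra", {
  sets <- three_benchsets(seed = 13)
  p <- 3
  dm <- transfer_energy_matrix(sets, p)
  expect_equal(unname(diag(dm$dmad)), rep(0, 3))
  expect_true(all(dm$dmad >= -1e-9))
  tm <- tat_matrix(sets, p)
  # dMAD = t * (mad_bb + eta) - eta - mad_bb entry by entry
  bb <- matrix(diag(tm$mad), 3, 3)
  expect_equal(dm$dmad, tm$t * (bb + 0.01) - 0.01 - bb, tolerance = 1e-9)
})

test_that("accuracy limit is non-increasing in p and matches the oracle at p = 2", {
  b <- one_regime_benchset(25, seed = 17)
  lims <- vapply(1:7, function(p) accuracy_limit(b, p), 0)
  expect_true(all(diff(lims) <= 1e-6))
  o <- grid_oracle(b, 2, step = 0.1, refine = 3, polish = TRUE)
  expect_lt(abs(lims[2] - o$mad), 1e-5)
})

test_that("error summaries bin per-process errors end to end", {
  b <- one_regime_benchset(30, seed = 23, noise_sigma = 0)
  f <- fit_xyg(b, 7)
  es <- error_summary(f, b)
  expect_equal(es$frac_good, 1)
  expect_equal(es$frac_bad, 0)
  shifted <- f
  shifted$a <- f$a
  b_off <- b
  b_off$processes$ref_kcal <- b$processes$ref_kcal + 10
  es2 <- error_summary(shifted, b_off)
  expect_equal(es2$frac_bad, 1)
  # manual binning on a noisy fixture
  bn <- one_regime_benchset(40, seed = 29, noise_sigma = 3)
  fn <- fit_xyg(bn, 2)
  err <- abs(predict_energies(fn$a, bn) - bn$processes$ref_kcal)
  es3 <- error_summary(fn, bn)
  expect_equal(es3$frac_good, mean(err < 1))
  expect_equal(es3$frac_ok, mean(err >= 1 & err <= 7))
  expect_equal(es3$frac_bad, mean(err > 7))
})

test_that("the sharp/flat fixture is asymmetric and not symmetrized", {
  pair <- generate_two_regime(synthetic_spec(seed = 0))
  tm <- tat_matrix(pair, 2)
  expect_lt(tm$t["flat", "sharp"], tm$t["sharp", "flat"])
  expect_false(isTRUE(all.equal(tm$t, t(tm$t))))
})

test_that("caching does not change the matrix", {
  sets <- three_benchsets(seed = 19)
  t1 <- tat_matrix(sets, 4, cache = TRUE)
  t2 <- tat_matrix(sets, 4, cache = FALSE)
  expect_identical(t1$t, t2$t)
  expect_identical(t1$mad, t2$mad)
})

test_that("matrices serialize to CSV with orientation in the header", {
  sets <- three_benchsets(seed = 25)
  tm <- tat_matrix(sets, 2)
  path <- file.path(tempdir(), "tat.csv")
  write_tat_csv(tm, path)
  got <- utils::read.csv(path, check.names = FALSE)
  expect_equal(got$test_set, tm$sets)
  expect_equal(names(got)[-1], paste0("train_", tm$sets))
  expect_equal(as.matrix(got[, -1]), unname(signif(tm$t, 6)), ignore_attr = TRUE)
})
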