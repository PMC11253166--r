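test_that("noise-free planted data are interpolated exactly at p = 7", {
  b <- one_regime_benchset(50, seed = 21, noise_sigma = 0)
  f <- fit_xyg(b, 7)
  expect_lt(f$mad, 1e-8)
  expect_equal(f$status, "global")
  expect_equal(predict_energies(f$a, b), b$processes$ref_kcal, tolerance = 1e-8)
})

test_that("the LP fit matches the refined grid oracle at small p", {
  for (s in 1:3) {
    b <- one_regime_benchset(20, seed = 100 + s)
    f1 <- fit_xyg(b, 1)
    o1 <- grid_oracle(b, 1, step = 1e-3, refine = 2, polish = TRUE)
    expect_lt(abs(f1$mad - o1$mad), 1e-5)
    for (p in 2:3) {
      f <- fit_xyg(b, p)
      o <- grid_oracle(b, p, step = 0.1, refine = 3, polish = TRUE)
      expect_lt(abs(f$mad - o$mad), 1e-5)
      # the LP optimum is certified: no grid point may beat it
      expect_gte(o$mad, f$mad - 1e-9)
    }
  }
})

test_that("grid_oracle is permutation-invariant and exact on planted points", {
  b <- one_regime_benchset(15, seed = 31, noise_sigma = 0, alpha = 0.6, beta = 0.9)
  planted <- c(0.6, 0.9)
  o <- grid_oracle(b, 2,
    lower = planted, upper = planted, step = 1,
    refine = 0
  ) # single-point grid at the planted parameters
  expect_lt(o$mad, 1e-9)
  perm <- subset_benchset(b, rev(seq_len(n_processes(b))), name = "rev")
  o1 <- grid_oracle(b, 2, step = 0.25)
  o2 <- grid_oracle(perm, 2, step = 0.25)
  expect_equal(o1$mad, o2$mad, tolerance = 1e-12)
  expect_equal(o1$free, o2$free)
  expect_error(grid_oracle(b, 3, step = 1e-4), "grid too large")
})

test_that("underdetermined designs yield zero MAD and a warning", {
  b <- one_regime_benchset(3, seed = 41, noise_sigma = 0.3, n_species = 12)
  expect_warning(f <- fit_xyg(b, 7), "underdetermined")
  expect_equal(f$status, "underdetermined")
  expect_lt(f$mad, 1e-8)
})

test_that("box bounds activate when the optimum lies outside", {
  # plant an exact-exchange fraction far outside the default [-3, 3] box
  b <- one_regime_benchset(30, seed = 51, noise_sigma = 0, alpha = 5, beta = 0.5)
  f <- fit_xyg(b, 2)
  expect_equal(f$status, "bounded")
  expect_true(all(f$free >= -3 - 1e-8 & f$free <= 3 + 1e-8))
  wide <- fit_xyg(b, 2, fit_options(box = c(-10, 10)))
  expect_equal(wide$status, "global")
  expect_equal(unname(wide$free), c(5, 0.5), tolerance = 1e-6)
  expect_lt(wide$mad, f$mad)
})

test_that("training error is non-increasing in the number of parameters", {
  for (s in 1:3) {
    b <- one_regime_benchset(40, seed = 200 + s)
    mads <- vapply(1:7, function(p) fit_xyg(b, p)$mad, 0)
    expect_true(all(diff(mads) <= 1e-6))
  }
})

test_that("cross_mad reduces to the training MAD when B = A", {
  b <- one_regime_benchset(30, seed = 61)
  for (p in c(1, 4, 7)) {
    f <- fit_xyg(b, p)
    expect_equal(cross_mad(f, b), f$mad, tolerance = 1e-10)
  }
})

test_that("cross_mad of all-zero design rows with zero references is zero", {
  species <- data.frame(id = c("X", "Y"), formula = c("H", "He"), stringsAsFactors = FALSE)
  species[paste0("c", 1:7)] <- 0
  species$c1 <- c(1, 1)
  processes <- data.frame(id = "z", subset = "s", ref_kcal = 0, stringsAsFactors = FALSE)
  processes$stoich <- list(c(X = 1, Y = -1))
  zero <- benchset("zero", species, processes)
  f <- fit_xyg(one_regime_benchset(20, seed = 71), 3)
  expect_equal(cross_mad(f, zero), 0)
})

test_that("identical fits come back from repeated invocations", {
  b <- one_regime_benchset(25, seed = 81)
  f1 <- fit_xyg(b, 4)
  f2 <- fit_xyg(b, 4)
  expect_identical(f1$free, f2$free)
  expect_identical(f1$mad, f2$mad)
})
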