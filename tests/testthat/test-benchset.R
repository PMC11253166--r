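test_that("formula parsing and formatting round-trip", {
  expect_equal(parse_formula("H2O")[[1]], c(H = 2L, O = 1L))
  expect_equal(parse_formula("C2H6O")[[1]], c(C = 2L, H = 6L, O = 1L))
  expect_equal(parse_formula("FeCl3")[[1]], c(Cl = 3L, Fe = 1L))
  expect_equal(format_formula(c(C = 2L, H = 6L, O = 1L)), "C2H6O")
  expect_equal(format_formula(c(O = 1L, H = 2L)), "H2O")
  for (f in c("H2O", "C6H12O6", "FeO3Ti", "CHBrClF")) {
    expect_equal(format_formula(parse_formula(f)[[1]]), f)
  }
  expect_error(parse_formula("h2o"), "malformed")
  expect_error(parse_formula(""), "empty")
})

test_that("benchset validation catches structural defects", {
  b <- tiny_benchset()
  expect_silent(validate_benchset(b))
  bad <- b
  bad$processes$stoich[[1]] <- c(Qz = 1)
  expect_error(validate_benchset(bad), "Qz")
  bad2 <- b
  bad2$species$c3[1] <- NaN
  expect_error(validate_benchset(bad2), "non-finite")
  bad3 <- b
  bad3$processes$stoich[[2]] <- c(X = 0)
  expect_error(validate_benchset(bad3), "zero")
  expect_error(benchset("e", b$species, b$processes[0, ]), "no processes")
})

test_that("CSV write/read round-trips a synthetic benchset", {
  b <- generate_benchset(synthetic_spec(
    n_species = 20, n_processes = 30,
    seed = 7
  ))
  sp <- file.path(tempdir(), "species.csv")
  pr <- file.path(tempdir(), "processes.csv")
  write_benchset(b, sp, pr)
  b2 <- read_benchset(sp, pr)
  expect_equal(b2$name, b$name)
  expect_equal(b2$species$id, b$species$id)
  expect_equal(b2$species$formula, b$species$formula)
  expect_equal(
    as.matrix(b2$species[paste0("c", 1:7)]),
    as.matrix(b$species[paste0("c", 1:7)]),
    tolerance = 1e-11
  )
  expect_equal(b2$processes$id, b$processes$id)
  expect_equal(b2$processes$subset, b$processes$subset) # labels preserved exactly
  expect_equal(b2$processes$ref_kcal, b$processes$ref_kcal, tolerance = 1e-11)
  for (j in seq_len(n_processes(b))) {
    expect_equal(b2$processes$stoich[[j]], b$processes$stoich[[j]], tolerance = 1e-11)
  }
  # second round trip is value-stable
  sp2 <- file.path(tempdir(), "species2.csv")
  pr2 <- file.path(tempdir(), "processes2.csv")
  write_benchset(b2, sp2, pr2)
  expect_equal(readLines(sp), readLines(sp2))
  expect_equal(readLines(pr), readLines(pr2))
})

test_that("read_benchset reports schema problems by file and column", {
  sp <- file.path(tempdir(), "bad_species.csv")
  pr <- file.path(tempdir(), "bad_processes.csv")
  b <- tiny_benchset()
  write_benchset(b, sp, pr)
  sp_df <- utils::read.csv(sp)
  sp_df$c7 <- NULL
  utils::write.csv(sp_df, sp, row.names = FALSE)
  expect_error(read_benchset(sp, pr), "c7")
  write_benchset(b, sp, pr)
  pr_lines <- readLines(pr)
  pr_lines[2] <- sub("X:1", "Qz:1", pr_lines[2])
  writeLines(pr_lines, pr)
  expect_error(read_benchset(sp, pr), "Qz")
})

test_that("unique_elements is the union over used species and monotone", {
  b <- tiny_benchset() # H2O and CH4 both used
  expect_equal(unique_elements(b), c("C", "H", "O"))
  only_x <- subset_benchset(b, 1, name = "x") # references species X only
  expect_equal(unique_elements(only_x), c("H", "O"))
  expect_true(all(unique_elements(only_x) %in% unique_elements(b)))
  # invariant to process order
  flipped <- subset_benchset(b, c(2, 1), name = "f")
  expect_equal(unique_elements(flipped), unique_elements(b))
  # two disjoint species sets combine
  species <- data.frame(
    id = c("M1", "M2"), formula = c("CH4", "FeO"),
    stringsAsFactors = FALSE
  )
  species[paste0("c", 1:7)] <- 1
  processes <- data.frame(
    id = c("p1", "p2"), subset = "s", ref_kcal = 0,
    stringsAsFactors = FALSE
  )
  processes$stoich <- list(c(M1 = 1), c(M2 = -1))
  expect_equal(
    unique_elements(benchset("two", species, processes)),
    c("C", "Fe", "H", "O")
  )
})

test_that("split and combine preserve processes and labels", {
  b <- generate_benchset(synthetic_spec(n_species = 20, n_processes = 24, seed = 3))
  parts <- split_by_subset(b)
  expect_setequal(names(parts), unique(b$processes$subset))
  expect_equal(sum(vapply(parts, n_processes, 0L)), n_processes(b))
  back <- combine_benchsets(parts[[1]], parts[[2]], name = "back")
  expect_equal(n_processes(back), n_processes(b))
  expect_setequal(back$processes$subset, b$processes$subset)
})
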