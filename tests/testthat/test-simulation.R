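test_that("run_scenario accounts for every replicate", {
  sc <- wmw_scenario("exponential", 0, 5, 5, decimals = 1)
  r <- run_scenario(sc, reps = 300, seed = 101)
  expect_equal(r$reps_total, 300L)
  rej <- r$rejection
  expect_equal(unique(rej$n_performed[rej$policy == "include"]), 300L)
  expect_equal(unique(rej$n_performed[rej$policy == "omit"]),
               300L - r$empty_group_count)
  expect_true(all(rej$rate >= 0 & rej$rate <= 1, na.rm = TRUE))
  expect_gte(r$mean_size_after_omission, 0)
  expect_lte(r$mean_size_after_omission, 10)
})

test_that("a nominal level above every p-value rejects always", {
  sc <- wmw_scenario("normal", 0, 6, 6, decimals = 2, alphas = 1.5)
  r <- run_scenario(sc, reps = 50, seed = 3)
  expect_true(all(r$rejection$rate == 1))
})

test_that("without ties the two policies coincide and nothing is skipped", {
  sc <- wmw_scenario("normal", 0.5, 8, 8, decimals = 12)
  r <- run_scenario(sc, reps = 200, seed = 7)
  expect_equal(r$empty_group_count, 0L)
  expect_equal(r$mean_size_after_omission, 16)
  rej <- r$rejection
  for (m in c("exact", "asymptotic")) for (a in c(0.05, 0.01))
    expect_equal(rejection_rate(r, m, "include", a),
                 rejection_rate(r, m, "omit", a))
})

test_that("scenario runs are deterministic given a seed", {
  sc <- wmw_scenario("laplace", 0.5, 7, 7, decimals = 1)
  r1 <- run_scenario(sc, reps = 150, seed = 13)
  r2 <- run_scenario(sc, reps = 150, seed = 13)
  expect_identical(r1$rejection, r2$rejection)
  expect_identical(r1$mean_size_after_omission, r2$mean_size_after_omission)
})

test_that("the exact test holds its level in a null scenario", {
  reps <- 400
  for (dist in c("normal", "cauchy")) {
    sc <- wmw_scenario(dist, 0, 10, 10, decimals = 2)
    r <- run_scenario(sc, reps = reps, seed = 17)
    for (a in c(0.05, 0.01))
      expect_lte(rejection_rate(r, "exact", "include", a),
                 a + 3 * sqrt(a * (1 - a) / reps))
  }
})

test_that("rejection rates increase with the location shift", {
  rates <- vapply(c(0, 0.75, 1.5), function(sh) {
    sc <- wmw_scenario("normal", sh, 10, 10, decimals = 2)
    rejection_rate(run_scenario(sc, reps = 300, seed = 23),
                   "exact", "include", 0.05)
  }, numeric(1))
  expect_true(all(diff(rates) > 0))
})

test_that("run_study is deterministic, order-invariant, and fault-tolerant", {
  grid <- list(wmw_scenario("normal", 0, 6, 6, decimals = 1),
               wmw_scenario("exponential", 1, 6, 6, decimals = 1))
  s1 <- run_study(grid, reps = 100, seed = 5, progress = FALSE)
  s2 <- run_study(grid, reps = 100, seed = 5, progress = FALSE)
  expect_identical(s1$results[[1]]$rejection, s2$results[[1]]$rejection)
  # scenario substreams do not depend on grid position of other cells
  solo <- run_scenario(grid[[2]], reps = 100,
                       seed = wmwties:::scenario_seed(5, 2))
  expect_identical(solo$rejection, s1$results[[2]]$rejection)
  expect_error(run_study(list(), reps = 10), "non-empty")
})

test_that("tables assemble in the report layout with explicit gaps", {
  grid <- list(wmw_scenario("normal", 0, 6, 6, decimals = 1),
               wmw_scenario("normal", 0.5, 6, 6, decimals = 1))
  study <- run_study(grid, reps = 60, seed = 29, progress = FALSE)
  tab <- build_table(study, design = c(6, 6), decimals = 1)
  expect_equal(dim(tab), c(16L, 11L))  # 4 distributions x 4 shifts
  expect_equal(tab$distribution[1:4], rep("normal", 4))
  filled <- tab$distribution == "normal" & tab$shift %in% c(0, 0.5)
  expect_true(all(!is.na(tab$exact_5_include[filled])))
  expect_true(all(is.na(tab$exact_5_include[!filled])))

  fmt <- format_study_table(tab)
  # null rows print 3 decimals, power rows 2, gaps stay empty
  expect_match(fmt$exact_5_include[tab$shift == 0 & filled], "^0\\.\\d{3}$")
  expect_match(fmt$exact_5_include[tab$shift == 0.5 & filled], "^0\\.\\d{2}$")
  expect_equal(unique(fmt$exact_5_include[!filled]), "")
})

test_that("the default grid covers the full replicated design", {
  grid <- default_study_grid()
  expect_length(grid, 64)
  key <- vapply(grid, function(s)
    paste(s$distribution, s$shift, s$n1, s$n2, s$decimals), character(1))
  expect_equal(anyDuplicated(key), 0L)
  expect_setequal(vapply(grid, `[[`, character(1), "distribution"),
                  c("normal", "exponential", "cauchy", "laplace"))
})
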