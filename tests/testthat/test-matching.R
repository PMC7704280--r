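test_that("worked-example equivalence classes and match state are exact", {
  ex <- worked_example()
  cls <- equivalence_classes(ex$real, "origin")
  expect_setequal(names(cls), c("European", "Japanese", "Hispanic", "North African"))
  expect_equal(sort(cls[["Hispanic"]]), c(3L, 4L))
  expect_equal(lengths(cls)[["European"]], 1L)
  expect_equal(sum(lengths(cls)), n_records(ex$real))

  ms <- compute_match_state(ex$real, ex$synthetic, ex$population, "origin")
  expect_equal(ms$f, c(1L, 1L, 2L, 2L, 1L))
  expect_equal(ms$F, c(1, 3, 3, 3, 1))
  expect_equal(ms$I, rep(1L, 5))
  # the single Hispanic synthetic record is the partner of both Hispanic reals
  expect_equal(ms$partners[[3]], 5L)
  expect_equal(ms$partners[[4]], 5L)
  expect_equal(ms$N, 8L)
})

test_that("hash-join matching equals the nested-loop oracle on random fixtures", {
  for (seed in 1:10) {
    fx <- random_fixture(seed, N = 200, n = 50, m = 50, sensitive = FALSE)
    ms <- compute_match_state(fx$real, fx$synthetic, fx$population, fx$qi)
    or <- oracle_match_state(fx$real$records, fx$synthetic$records,
                             fx$population$records, fx$qi)
    expect_equal(ms$f, or$f)
    expect_equal(ms$F, or$F)
    expect_equal(ms$I, or$I)
    expect_equal(lapply(ms$partners, sort), lapply(or$partners, sort))
  }
})

test_that("class sizes over a 50-record fixture sum to n and match brute force", {
  fx <- random_fixture(99, N = 120, n = 50, m = 10, n_qi = 3, sensitive = FALSE)
  cls <- equivalence_classes(fx$real, fx$qi)
  expect_equal(sum(lengths(cls)), 50)
  sizes <- integer(50)
  for (cl in cls) sizes[cl] <- length(cl)
  or <- oracle_match_state(fx$real$records, fx$real$records,
                           fx$population$records, fx$qi)
  expect_equal(sizes, or$f)
})

test_that("generalizing a quasi-identifier never shrinks classes or drops matches", {
  set.seed(11)
  meta <- list(
    variable_spec("age", "quasi_identifier", "continuous",
                  hierarchy = default_hierarchy("age")),
    variable_spec("sex", "quasi_identifier", "nominal",
                  hierarchy = default_hierarchy("suppress")))
  pop_df <- data.frame(age = sample(0:99, 300, replace = TRUE),
                       sex = sample(c("F", "M"), 300, replace = TRUE))
  pop <- sdc_dataset(pop_df, meta, "population")
  real <- sdc_dataset(pop_df[sample(300, 80), ], meta, "real_sample")
  syn <- sdc_dataset(pop_df[sample(300, 80, replace = TRUE), ], meta, "synthetic_sample")

  base <- compute_match_state(real, syn, pop, attack_config(c("age", "sex"), c(1, 0)))
  coarser <- list(attack_config(c("age", "sex"), c(2, 0)),
                  attack_config(c("age", "sex"), c(3, 0)),
                  attack_config(c("age", "sex"), c(1, 1)),
                  attack_config(c("age", "sex"), c(3, 1)))
  for (cfg in coarser) {
    ms <- compute_match_state(real, syn, pop, cfg)
    expect_true(all(ms$f >= base$f))
    expect_true(all(ms$F >= base$F))
    expect_true(all(ms$I >= base$I))  # coarser values can only gain matches
  }
})

test_that("degenerate and invalid matching inputs behave as specified", {
  ex <- worked_example()
  # real against itself: every record matches itself
  self <- ex$real
  self$label <- "synthetic_sample"
  ms <- compute_match_state(ex$real, self, ex$population, "origin")
  expect_equal(ms$I, rep(1L, 5))

  # synthetic sharing no QI values: all I = 0
  alien <- sdc_dataset(data.frame(origin = rep("Martian", 3), income = c(1, 2, 3)),
                       unname(ex$synthetic$meta), "synthetic_sample")
  ms0 <- compute_match_state(ex$real, alien, ex$population, "origin")
  expect_equal(ms0$I, rep(0L, 5))
  expect_equal(lengths(ms0$partners), rep(0L, 5))

  # matching on a sensitive variable is a usage error
  expect_error(equivalence_classes(ex$real, "income"), "not quasi-identifier")
  # raw continuous QI equality is refused
  meta <- list(variable_spec("age", "quasi_identifier", "continuous"))
  ds <- sdc_dataset(data.frame(age = c(30.1, 30.1)), meta, "real_sample")
  expect_error(equivalence_classes(ds, "age"), "bin it via a hierarchy")

  # a real tuple absent from the population is an error
  stranger <- ex$real
  stranger$records$origin[1] <- "Martian"
  expect_error(compute_match_state(stranger, ex$synthetic, ex$population, "origin"),
               "not a subset of population")
})

test_that("missing quasi-identifier values never match anything", {
  ex <- worked_example()
  real <- ex$real
  real$records$origin[2] <- NA
  syn <- ex$synthetic
  syn$records$origin[1] <- NA
  ms <- compute_match_state(real, syn, ex$population, "origin")
  expect_equal(ms$f[2], 1L)
  expect_equal(ms$F[2], 1)
  expect_equal(ms$I[2], 0L)
  # remaining records unaffected apart from the lost Japanese partner
  expect_equal(ms$I[-2], rep(1L, 4))
})

test_that("coarsest generalization collapses everything into one class", {
  ex <- worked_example()
  meta <- list(variable_spec("origin", "quasi_identifier", "nominal",
                             hierarchy = default_hierarchy("suppress")),
               variable_spec("income", "sensitive", "continuous"))
  real <- sdc_dataset(ex$real$records, meta, "real_sample")
  cls <- equivalence_classes(real, attack_config("origin", 1))
  expect_length(cls, 1)
  expect_equal(sort(cls[[1]]), 1:5)
})
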