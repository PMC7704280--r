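test_that("generalization recodes values per hierarchy level", {
  meta <- list(
    variable_spec("age", "quasi_identifier", "continuous",
                  hierarchy = list(hierarchy_level("bin", breaks = seq(0, 120, 10)),
                                   hierarchy_level("suppress"))),
    variable_spec("zip", "quasi_identifier", "nominal",
                  hierarchy = default_hierarchy("zip")))
  ds <- sdc_dataset(data.frame(age = c(37, 61), zip = c("98101", "20500"),
                               stringsAsFactors = FALSE),
                    meta, "population")
  g1 <- apply_generalization(ds, attack_config(c("age", "zip"), c(1, 1)))
  expect_equal(g1$records$age, c("[30,40)", "[60,70)"))
  expect_equal(g1$records$zip, c("981**", "205**"))
  g2 <- apply_generalization(ds, attack_config("zip", 2))
  expect_equal(g2$records$zip, c("9****", "2****"))
  # level 0 everywhere is the identity
  g0 <- apply_generalization(ds, attack_config("zip", 0))
  expect_equal(g0$records, ds$records)
  # level beyond the hierarchy depth is a usage error
  expect_error(apply_generalization(ds, attack_config("zip", 9)),
               "no generalization level 9")
})

test_that("enumeration counts follow the subset-times-levels lattice", {
  nom <- function(nm, hier = NULL) variable_spec(nm, "quasi_identifier", "nominal",
                                                 hierarchy = hier)
  expect_length(enumerate_configs(list(nom("a"), nom("b"))), 3)
  two_lv <- list(hierarchy_level("suppress"))
  expect_length(enumerate_configs(list(nom("a", two_lv), nom("b", two_lv))), 8)
  expect_length(enumerate_configs(lapply(letters[1:9], nom)), 511)
  # deterministic lexicographic order, repeatable
  cfgs <- enumerate_configs(list(nom("b"), nom("a")))
  expect_equal(vapply(cfgs, function(c) paste(c$qi, collapse = "+"), character(1)),
               c("a", "b", "a+b"))
  # cap exceeded is an error naming the remedy
  deep <- list(hierarchy_level("suppress"))
  expect_error(enumerate_configs(lapply(letters[1:9], nom, hier = two_lv),
                                 max_configs = 100),
               "max_configs")
})

test_that("continuous QIs enter the search only through hierarchy levels", {
  meta <- list(
    variable_spec("age", "quasi_identifier", "continuous",
                  hierarchy = list(hierarchy_level("bin", breaks = seq(0, 120, 10)))),
    variable_spec("sex", "quasi_identifier", "nominal"))
  cfgs <- enumerate_configs(meta)
  # age alone (level 1), sex alone (level 0), both: 3 configs
  expect_length(cfgs, 3)
  age_levels <- unlist(lapply(cfgs, function(c) c$levels[names(c$levels) == "age"]))
  expect_true(all(age_levels >= 1))
  # a continuous QI without any hierarchy is dropped with a warning
  meta2 <- list(variable_spec("wt", "quasi_identifier", "continuous"),
                variable_spec("sex", "quasi_identifier", "nominal"))
  expect_warning(cfgs2 <- enumerate_configs(meta2), "dropped from search")
  expect_length(cfgs2, 1)
})

test_that("the searched maximum dominates every individually queried config", {
  set.seed(8)
  meta <- list(
    variable_spec("region", "quasi_identifier", "nominal",
                  hierarchy = default_hierarchy("suppress")),
    variable_spec("band", "quasi_identifier", "nominal"),
    variable_spec("flag", "quasi_identifier", "nominal"),
    variable_spec("score", "sensitive", "continuous"))
  pop_df <- data.frame(
    region = sample(paste0("r", 1:6), 250, replace = TRUE),
    band = sample(paste0("b", 1:4), 250, replace = TRUE),
    flag = sample(c("y", "n"), 250, replace = TRUE),
    score = round(stats::rnorm(250, 50, 10), 1),
    stringsAsFactors = FALSE)
  pop <- sdc_dataset(pop_df, meta, "population")
  rows <- sample(250, 60)
  real <- sdc_dataset(pop_df[rows, ], meta, "real_sample")
  syn <- sdc_dataset(pop_df[sample(250, 60, replace = TRUE), ], meta,
                     "synthetic_sample")
  params <- risk_parameters(seed = 4)

  rep <- max_risk_search(real, syn, pop, params = params)
  # independent exhaustive evaluation outside the search harness
  cfgs <- enumerate_configs(meta)
  per_config <- vapply(cfgs, function(cf) {
    assess_risk(real, syn, pop, params = params, config = cf)$overall
  }, numeric(1))
  expect_equal(rep$overall, max(per_config), tolerance = 1e-12)
  expect_true(all(rep$overall >= per_config - 1e-12))
  expect_equal(rep$n_configs_evaluated, length(cfgs))

  # all-raw config is dominated by the max
  raw <- assess_risk(real, syn, pop, params = params,
                     config = attack_config(c("band", "flag", "region")))
  expect_gte(rep$overall, raw$overall - 1e-12)

  # determinism: same seed, same argmax and value
  rep2 <- max_risk_search(real, syn, pop, params = params)
  expect_identical(rep2$winning_config, rep$winning_config)
  expect_identical(rep2$overall, rep$overall)
})

test_that("a single-QI search equals the direct single-config assessment", {
  ex <- worked_example()
  params <- risk_parameters(seed = 2)
  searched <- assess_risk(ex$real, ex$synthetic, ex$population, params = params,
                          search = TRUE)
  direct <- assess_risk(ex$real, ex$synthetic, ex$population, params = params,
                        config = attack_config("origin"))
  expect_equal(searched$overall, direct$overall)
  expect_equal(searched$winning_config$qi, "origin")
})
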