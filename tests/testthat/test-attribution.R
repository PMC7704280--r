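test_that("nominal rule: exact match learns something new iff the value is a minority", {
  expect_equal(nominal_learn_new("a", "b", 0.1), "not_learned")
  expect_equal(nominal_learn_new("Hispanic", "Hispanic", 0.4), "learned")  # 0.6 > sqrt(0.24)
  expect_equal(nominal_learn_new(NA, "a", 0.4), "skipped_missing")
  expect_error(nominal_learn_new("a", "a", 0), "must occur in the real sample")
  # (1 - p) > sqrt(p (1 - p))  <=>  p < 1/2, checked over a grid
  for (p in seq(0.01, 0.99, by = 0.01)) {
    expect_equal(nominal_learn_new("a", "a", p) == "learned", p < 0.5)
  }
})

test_that("unscaled MAD matches hand computation", {
  expect_equal(mad_unscaled(c(70, 100, 130, 65, 95)), 25)
  expect_equal(mad_unscaled(rep(3, 10)), 0)
  expect_equal(mad_unscaled(c(1, NA, 3)), 1)
})

test_that("1-d k-means discretization partitions correctly", {
  d <- discretize_continuous(c(0, 0, 0, 100, 100))
  expect_equal(d$k, 2)
  expect_equal(d$p, c(0.6, 0.6, 0.6, 0.4, 0.4))
  expect_length(unique(d$cluster[1:3]), 1)
  expect_length(unique(d$cluster[4:5]), 1)

  # cluster proportions weighted by size sum to 1
  set.seed(3)
  x <- stats::rnorm(200)
  d2 <- discretize_continuous(x)
  sizes <- table(d2$cluster)
  expect_equal(sum(sizes) , 200)
  expect_equal(unname(sapply(split(d2$p, d2$cluster), unique)),
               unname(as.numeric(sizes) / 200))

  # constant input: single cluster, p = 1
  d3 <- discretize_continuous(rep(5, 10))
  expect_equal(d3$k, 1)
  expect_equal(d3$p, rep(1, 10))

  # missing values keep their slots as NA
  d4 <- discretize_continuous(c(1, NA, 2, 200))
  expect_true(is.na(d4$p[2]))
})

test_that("majority rule recovers a well-separated 3-component mixture", {
  set.seed(17)
  x <- c(stats::rnorm(100, -10, 0.5), stats::rnorm(100, 0, 0.5),
         stats::rnorm(100, 10, 0.5))
  d <- discretize_continuous(x)
  expect_equal(d$k, 3)
})

test_that("continuous rule compares the weighted difference to the scaled MAD", {
  # North African worked-example pair: 95 vs 100, threshold 1.48 * 25 = 37
  expect_equal(continuous_learn_new(95, 100, p_s = 1, mad_x = 25), "learned")
  # European pair: 70 vs 110 -> 40 is outside the threshold
  expect_equal(continuous_learn_new(70, 110, p_s = 1, mad_x = 25), "not_learned")
  expect_equal(continuous_learn_new(5, 5, p_s = 0.2, mad_x = 1), "learned")
  expect_equal(continuous_learn_new(NA, 5, p_s = 1, mad_x = 1), "skipped_missing")
  # widening the multiplier can only flip not_learned -> learned
  for (mult in c(0.5, 1, 1.48, 3)) {
    v1 <- continuous_learn_new(70, 110, 1, 25, multiplier = mult)
    v2 <- continuous_learn_new(70, 110, 1, 25, multiplier = mult * 2)
    expect_false(v1 == "learned" && v2 == "not_learned")
  }
})

# 10 real records, `n_sens` nominal sensitive variables; sv1 has a rare
# value for record 1 (p = 0.1), all other variables are constant (p = 1,
# never learned even on an exact match)
learned_fraction_fixture <- function(n_sens = 20) {
  rec <- data.frame(qid = paste0("u", 1:10), stringsAsFactors = FALSE)
  rec$sv1 <- c("rare", rep("common", 9))
  for (i in 2:n_sens) rec[[paste0("sv", i)]] <- "same"
  meta <- c(list(variable_spec("qid", "quasi_identifier", "nominal")),
            lapply(paste0("sv", 1:n_sens), variable_spec,
                   role = "sensitive", kind = "nominal"))
  real <- sdc_dataset(rec, meta, "real_sample")
  pop <- sdc_dataset(rec, meta, "population")
  syn <- sdc_dataset(rec, meta, "synthetic_sample")
  list(real = real, synthetic = syn, population = pop)
}

test_that("the L% rule counts learned fractions over partners", {
  fx <- learned_fraction_fixture(20)
  ms <- compute_match_state(fx$real, fx$synthetic, fx$population, "qid")
  # record 1: exactly 1 of 20 sensitive variables learned -> 5% >= L = 5%
  attr5 <- attribution_results(fx$real, fx$synthetic, ms,
                               risk_parameters(L = 5, seed = 1))
  expect_equal(attr5$R[1], 1L)
  # all other records: nothing learned anywhere -> R = 0
  expect_equal(attr5$R[-1], rep(0L, 9))
  # raising L above the attainable fraction flips record 1 off
  attr10 <- attribution_results(fx$real, fx$synthetic, ms,
                                risk_parameters(L = 10, seed = 1))
  expect_equal(attr10$R[1], 0L)
  # lowering L never turns an R_s from 1 to 0
  attr0 <- attribution_results(fx$real, fx$synthetic, ms,
                               risk_parameters(L = 0, seed = 1))
  expect_true(all(attr0$R >= attr5$R, na.rm = TRUE))
})

test_that("any matched partner reaching L% sets R_s = 1", {
  fractions_fixture <- synthrisk:::record_learns_new(
    data.frame(sv = "rare", stringsAsFactors = FALSE),
    data.frame(sv = c("other", "rare"), stringsAsFactors = FALSE),
    profiles = list(sv = list(kind = "nominal", prop = c(rare = 0.1, other = 0.9))),
    p_s_record = list(), L = 5)
  expect_equal(fractions_fixture$fractions, c(0, 1))
  expect_equal(fractions_fixture$R, 1L)
})

test_that("R_s is computed only for matched records and NA elsewhere", {
  fx <- learned_fraction_fixture(5)
  syn <- fx$synthetic
  syn$records$qid[2:10] <- paste0("v", 2:10)  # only record 1 still matches
  pop <- fx$population
  pop$records <- rbind(pop$records, syn$records[2:10, ])
  ms <- compute_match_state(fx$real, syn, pop, "qid")
  expect_equal(ms$I, c(1L, rep(0L, 9)))
  res <- attribution_results(fx$real, syn, ms, risk_parameters(L = 5))
  expect_false(is.na(res$R[1]))
  expect_true(all(is.na(res$R[-1])))
})

test_that("no sensitive variables degrades to pure identity disclosure with a warning", {
  rec <- data.frame(qid = c("a", "b"), stringsAsFactors = FALSE)
  meta <- list(variable_spec("qid", "quasi_identifier", "nominal"))
  real <- sdc_dataset(rec, meta, "real_sample")
  syn <- sdc_dataset(rec, meta, "synthetic_sample")
  pop <- sdc_dataset(rec, meta, "population")
  ms <- compute_match_state(real, syn, pop, "qid")
  expect_warning(res <- attribution_results(real, syn, ms, risk_parameters()),
                 "pure identity disclosure")
  expect_equal(res$R, c(1L, 1L))
})
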