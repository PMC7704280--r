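# Independent oracles: deliberately naive straight-line / nested-loop
# implementations used to cross-check the vectorized engine.

# O(n*m) nested-loop matcher on raw nominal QI columns. NA never
# matches anything (not even NA).
oracle_match_state <- function(real_df, syn_df, pop_df, qi) {
  n <- nrow(real_df)
  tuple_eq <- function(df, i, df2, j) {
    all(vapply(qi, function(q) {
      a <- df[[q]][i]; b <- df2[[q]][j]
      !is.na(a) && !is.na(b) && a == b
    }, logical(1)))
  }
  f <- integer(n); F_ <- numeric(n); I <- integer(n)
  partners <- vector("list", n)
  for (i in seq_len(n)) {
    f[i] <- sum(vapply(seq_len(n), function(j) tuple_eq(real_df, i, real_df, j),
                       logical(1)))
    if (any(vapply(qi, function(q) is.na(real_df[[q]][i]), logical(1)))) {
      f[i] <- 1L; F_[i] <- 1; I[i] <- 0L; partners[[i]] <- integer(0)
      next
    }
    F_[i] <- sum(vapply(seq_len(nrow(pop_df)), function(j)
      tuple_eq(real_df, i, pop_df, j), logical(1)))
    hits <- which(vapply(seq_len(nrow(syn_df)), function(j)
      tuple_eq(real_df, i, syn_df, j), logical(1)))
    partners[[i]] <- hits
    I[i] <- as.integer(length(hits) > 0)
  }
  list(f = f, F = F_, I = I, partners = partners)
}

# literal per-record transcription of the risk sums
oracle_pop_to_sample <- function(f, I, R, lambda_c, N) {
  total <- 0
  for (s in seq_along(f)) {
    r <- if (is.na(R[s])) 0 else R[s]
    total <- total + lambda_c[s] * (1 / f[s]) * I[s] * r
  }
  total / N
}

oracle_sample_to_pop <- function(F_, I, R, lambda_c, n) {
  total <- 0
  for (s in seq_along(F_)) {
    r <- if (is.na(R[s])) 0 else R[s]
    total <- total + lambda_c[s] * (1 / F_[s]) * I[s] * r
  }
  total / n
}

# closed-form triangular CDF for (min, mode, max)
oracle_ptri <- function(q, a, c_, b) {
  ifelse(q <= a, 0,
  ifelse(q < c_, (q - a)^2 / ((b - a) * (c_ - a)),
  ifelse(q < b, 1 - (b - q)^2 / ((b - a) * (b - c_)), 1)))
}

# random population / real / synthetic triple on nominal QIs; real and
# synthetic rows are drawn from the population so the subset property
# holds by construction
random_fixture <- function(seed, N = 400, n = 80, m = 80, n_qi = 3,
                           n_cat = 4, sensitive = TRUE) {
  set.seed(seed)
  pop <- as.data.frame(
    stats::setNames(lapply(seq_len(n_qi), function(i)
      sample(paste0("c", seq_len(n_cat)), N, replace = TRUE,
             prob = stats::runif(n_cat))),
      paste0("q", seq_len(n_qi))),
    stringsAsFactors = FALSE)
  meta <- lapply(paste0("q", seq_len(n_qi)), function(nm)
    variable_spec(nm, "quasi_identifier", "nominal"))
  if (sensitive) {
    pop$sv_num <- round(stats::rnorm(N, 100, 20), 1)
    pop$sv_cat <- sample(c("a", "b", "c"), N, replace = TRUE, prob = c(.6, .3, .1))
    meta <- c(meta, list(variable_spec("sv_num", "sensitive", "continuous"),
                         variable_spec("sv_cat", "sensitive", "nominal")))
  }
  real_rows <- sample.int(N, n)
  syn_rows <- sample.int(N, m, replace = TRUE)
  list(
    population = sdc_dataset(pop, meta, "population"),
    real = sdc_dataset(pop[real_rows, , drop = FALSE], meta, "real_sample"),
    synthetic = sdc_dataset(pop[syn_rows, , drop = FALSE], meta, "synthetic_sample"),
    qi = paste0("q", seq_len(n_qi))
  )
}

# parameters that force lambda_c = 1 exactly (no error, certain
# verification, zero-width triangular ranges)
params_lambda_one <- function(...) {
  risk_parameters(error_rate = c(0, 0, 0), verification_rate = c(1, 1, 1), ...)
}
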