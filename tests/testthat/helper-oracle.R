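# Independent oracles and small fixture builders used across test files.

# Weighted check (pinball) loss of an arbitrary line.
pinball_loss <- function(x, y, w, tau, a, b) {
  u <- y - a - b * x
  sum(w * u * (tau - (u < 0)))
}

# Exhaustive vertex-enumeration LP oracle for weighted simple quantile
# regression: an optimal line interpolates two observations, so on small
# instances the optimum is found by scoring every line through a pair of
# points.  Ties resolve to the smallest slope.
oracle_quantreg <- function(x, y, w, tau) {
  n <- length(x)
  best <- Inf; b_best <- NA_real_; a_best <- NA_real_
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      if (x[i] == x[j]) next
      b <- (y[i] - y[j]) / (x[i] - x[j])
      a <- y[i] - b * x[i]
      L <- pinball_loss(x, y, w, tau, a, b)
      if (is.na(b_best) || L < best - 1e-12 * (1 + abs(best)) ||
          (L < best + 1e-12 * (1 + abs(best)) && b < b_best - 1e-12)) {
        best <- L; b_best <- b; a_best <- a
      }
    }
  }
  list(slope = b_best, intercept = a_best, loss = best)
}

# Wrap raw vectors as a pair_set so solver-level tests can drive
# fit_quantile_slope/bootstrap_slopes directly.
fake_pairs <- function(x, y, w = rep(1, length(x)),
                       cluster = as.character(seq_along(x)), kind = "OP") {
  structure(data.frame(dependent_id = paste0("d", seq_along(x)),
                       independent_id = paste0("i", seq_along(x)),
                       y = y, x = x, weight = w, cluster_id = cluster,
                       stringsAsFactors = FALSE),
            kind = kind, class = c("pair_set", "data.frame"))
}

# Long-format pedigree data.frame builder (one exam per row).
ped_df <- function(individual_id, cohort_id = "C", sex = "M", age = 40,
                   exam = 1, phenotype = 300, father_id = NA_character_,
                   mother_id = NA_character_, sibship_id = NA_character_) {
  data.frame(individual_id = individual_id, cohort_id = cohort_id,
             sex = sex, age = age, exam = exam, phenotype = phenotype,
             father_id = father_id, mother_id = mother_id,
             sibship_id = sibship_id, stringsAsFactors = FALSE)
}

# An adjustment model with known coefficients, for tests that need exact
# residuals.
constant_model <- function(cohort_id, intercept) {
  structure(list(cohort_id = cohort_id,
                 coefficients = c(intercept = intercept, sex = 0, age = 0,
                                  age2 = 0, sex_age = 0, sex_age2 = 0),
                 n_rows = NA_integer_, sigma = NA_real_),
            class = "adjustment_model")
}

# Memoised large gamma = 0 run shared by the recovery tests, so the
# 20000-family table is generated and adjusted only once per session.
.big_run_cache <- new.env(parent = emptyenv())
big_null_run <- function() {
  if (is.null(.big_run_cache$run)) {
    params <- sim_params(n_families = 20000, gamma = 0, seed = 424242)
    tab <- generate_pedigree(params)
    adj <- compute_adjusted(tab)
    .big_run_cache$run <- list(params = params, table = tab, adjusted = adj)
  }
  .big_run_cache$run
}
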