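test_that("points on an exact line are fitted with zero loss at any quantile", {
  x <- as.numeric(1:12)
  pr <- fake_pairs(x, 2 * x)
  for (q in c(10, 25, 50, 75, 90)) {
    f <- fit_quantile_slope(pr, q)
    expect_equal(f$slope, 2, tolerance = 1e-12)
    expect_equal(f$intercept, 0, tolerance = 1e-12)
    expect_equal(f$loss, 0, tolerance = 1e-12)
  }
  ols <- fit_ols_slope(pr)
  expect_equal(ols$slope, 2, tolerance = 1e-12)
  expect_equal(ols$se, 0, tolerance = 1e-12)
})

test_that("median regression on a 12-point instance matches the
           vertex-enumeration oracle", {
  set.seed(7)
  x <- rnorm(12); y <- 0.4 * x + rnorm(12)
  pr <- fake_pairs(x, y)
  f <- fit_quantile_slope(pr, 50)
  o <- oracle_quantreg(x, y, rep(1, 12), 0.5)
  expect_equal(f$slope, o$slope, tolerance = 1e-10)
  expect_equal(f$loss, o$loss, tolerance = 1e-10)
})

test_that("the solver agrees with the LP oracle across weights, quantiles,
           and small instances", {
  set.seed(101)
  for (rep in 1:60) {
    n <- sample(5:15, 1)
    x <- rnorm(n)
    y <- runif(1, -1, 1) * x + rnorm(n)
    w <- if (rep %% 2 == 0) rexp(n) + 0.2 else rep(1, n)
    tau <- sample(c(0.1, 0.25, 0.5, 0.75, 0.9), 1)
    got <- .qr_fit_cpp(x, y, w, tau, 0)
    want <- oracle_quantreg(x, y, w, tau)
    expect_true(got$converged)
    expect_equal(got$loss, want$loss, tolerance = 1e-9)
    expect_equal(got$slope, want$slope, tolerance = 1e-8)
  }
})

test_that("with symmetric errors the median slope approaches the OLS slope", {
  set.seed(11)
  n <- 20000
  x <- rnorm(n); y <- 1.3 + 0.7 * x + rnorm(n)
  pr <- fake_pairs(x, y)
  expect_equal(fit_quantile_slope(pr, 50)$slope, fit_ols_slope(pr)$slope,
               tolerance = 0.05)
})

test_that("every fitted quantile beats the OLS line on its own check loss
           and fitted values are monotone in q at the mean of x", {
  set.seed(12)
  n <- 2000
  x <- rnorm(n)
  y <- 0.3 * x + rnorm(n) * (1 + 0.3 * pmax(x, 0))
  pr <- fake_pairs(x, y)
  ols <- fit_ols_slope(pr)
  grid <- quantile_grid(seq(5, 95, 5))
  fits <- lapply(grid, function(q) fit_quantile_slope(pr, q))
  for (k in seq_along(grid)) {
    loss_q <- fits[[k]]$loss
    loss_ols <- pinball_loss(x, y, rep(1, n), grid[k] / 100,
                             ols$intercept, ols$slope)
    expect_lte(loss_q, loss_ols + 1e-9)
  }
  at_mean <- vapply(fits, function(f) f$intercept + f$slope * mean(x),
                    numeric(1))
  expect_true(all(diff(at_mean) >= -1e-9))
})

test_that("weighted fits respect weights exactly and are invariant to
           duplicating the data", {
  set.seed(13)
  n <- 30
  x <- rnorm(n); y <- 0.5 * x + rnorm(n)
  w <- rep(c(1, 2), length.out = n)
  # integer weight w equals replicating the row w times
  xr <- rep(x, w); yr <- rep(y, w)
  f_w <- .qr_fit_cpp(x, y, as.numeric(w), 0.3, 0)
  f_r <- .qr_fit_cpp(xr, yr, rep(1, length(xr)), 0.3, 0)
  expect_equal(f_w$slope, f_r$slope, tolerance = 1e-10)
  expect_equal(f_w$loss, f_r$loss, tolerance = 1e-10)
  # uniform weight scaling leaves OLS slope and se unchanged
  pr1 <- fake_pairs(x, y, w = rep(1, n))
  pr2 <- fake_pairs(x, y, w = rep(7, n))
  expect_equal(fit_ols_slope(pr1)$slope, fit_ols_slope(pr2)$slope)
  expect_equal(fit_ols_slope(pr1)$se, fit_ols_slope(pr2)$se)
})

test_that("bootstrap is reproducible, PSD, and honest about degeneracy", {
  set.seed(14)
  n <- 400
  x <- rnorm(n); y <- 0.4 * x + rnorm(n)
  pr <- fake_pairs(x, y, cluster = as.character(rep(1:100, each = 4)))
  grid <- quantile_grid(c(25, 50, 75))
  a <- bootstrap_slopes(pr, grid, n_boot = 60, seed = 5)
  b <- bootstrap_slopes(pr, grid, n_boot = 60, seed = 5)
  expect_identical(a$beta, b$beta)
  expect_identical(a$cov, b$cov)
  expect_identical(a$boot_beta, b$boot_beta)
  c2 <- bootstrap_slopes(pr, grid, n_boot = 60, seed = 6)
  expect_false(identical(a$boot_beta, c2$boot_beta))

  expect_equal(a$cov, t(a$cov))
  expect_true(all(eigen(a$cov, symmetric = TRUE,
                        only.values = TRUE)$values > -1e-12))
  expect_equal(a$se, sqrt(diag(a$cov)))

  expect_error(bootstrap_slopes(pr, grid, n_boot = 10, seed = 1), "n_boot")
  expect_error(bootstrap_slopes(pr, grid, n_boot = 60), "seed")

  # 30 identical clusters: every resample reproduces the same data set,
  # so all replicate slopes coincide and se = 0
  x0 <- c(-2, -1, 0, 1, 2); y0 <- c(-1.9, -1.2, 0.1, 0.8, 2.2)
  prd <- fake_pairs(rep(x0, 30), rep(y0, 30),
                    cluster = as.character(rep(1:30, each = 5)))
  d <- bootstrap_slopes(prd, quantile_grid(c(50)), n_boot = 60, seed = 2)
  expect_equal(unname(d$se), 0, tolerance = 1e-12)
})

test_that("bootstrap standard errors track the asymptotic quantile-regression
           variance", {
  set.seed(15)
  n <- 5000
  x <- rnorm(n); y <- 0.5 * x + rnorm(n)
  pr <- fake_pairs(x, y)
  sf <- bootstrap_slopes(pr, quantile_grid(c(50)), n_boot = 200,
                         unit = "observation", seed = 8)
  # avar(b_hat) = tau (1 - tau) / f(F^-1(tau))^2 / (n var(x)) with
  # f the N(0,1) error density: at the median, 0.25 * 2 * pi / (n var(x))
  se_asym <- sqrt(0.25 * 2 * pi / (n * stats::var(x)))
  expect_equal(unname(sf$se), se_asym, tolerance = 0.2)
})

test_that("slope functions and pair sets serialize to readable TSV/JSON", {
  set.seed(21)
  n <- 200
  pr <- fake_pairs(rnorm(n), rnorm(n),
                   cluster = as.character(rep(1:50, each = 4)))
  sf <- bootstrap_slopes(pr, quantile_grid(c(25, 50, 75)), n_boot = 50,
                         seed = 4)
  fj <- withr::local_tempfile(fileext = ".json")
  ft <- withr::local_tempfile(fileext = ".tsv")
  slope_function_json(sf, fj)
  back <- jsonlite::read_json(fj, simplifyVector = TRUE)
  expect_equal(back$beta, sf$beta)
  expect_equal(back$percentiles, sf$percentiles)
  expect_equal(back$seed, 4)
  slope_function_tsv(sf, ft)
  tsv <- read.delim(ft)
  expect_equal(tsv$percentile, sf$percentiles)
  expect_equal(tsv$se, sf$se, tolerance = 1e-12)

  fp <- withr::local_tempfile(fileext = ".tsv")
  write_pairs(pr, fp)
  pt <- read.delim(fp)
  expect_equal(nrow(pt), n)
  expect_equal(unique(pt$kind), "OP")

  tab <- generate_pedigree(sim_params(n_families = 40, seed = 9))
  adj <- compute_adjusted(tab)
  fa <- withr::local_tempfile(fileext = ".tsv")
  write_adjusted(adj, fa)
  at <- read.delim(fa)
  expect_equal(nrow(at), nrow(adj))
  expect_equal(at$adjusted_value, adj$adjusted_value, tolerance = 1e-9)
})
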