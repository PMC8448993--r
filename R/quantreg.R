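#' Percentile grid
#'
#' Strictly increasing percentiles in (0, 100) at which quantile slopes
#' are fitted.  The default 5, 6, ..., 95 covers the distribution between
#' its 5th and 95th percentiles at one-percent resolution.
#'
#' @param percentiles numeric vector.
#' @return Validated numeric vector of class `quantile_grid`.
#' @export
quantile_grid <- function(percentiles = 5:95) {
  p <- as.numeric(percentiles)
  if (length(p) == 0 || any(!is.finite(p)) || any(p <= 0) || any(p >= 100) ||
      any(diff(p) <= 0)) {
    stop("percentiles must be strictly increasing and inside (0, 100)",
         call. = FALSE)
  }
  structure(p, class = "quantile_grid")
}

pairs_xyw <- function(pairs) {
  stopifnot(inherits(pairs, "pair_set"))
  if (nrow(pairs) < 10) stop("need at least 10 pairs", call. = FALSE)
  if (stats::var(pairs$x) == 0) {
    stop("degenerate pair set: independent values have zero variance",
         call. = FALSE)
  }
  if (any(pairs$weight <= 0)) stop("weights must be positive", call. = FALSE)
  list(x = pairs$x, y = pairs$y, w = pairs$weight)
}

wls_slope <- function(x, y, w) {
  xm <- sum(w * x) / sum(w)
  ym <- sum(w * y) / sum(w)
  sxx <- sum(w * (x - xm)^2)
  b <- sum(w * (x - xm) * (y - ym)) / sxx
  a <- ym - b * xm
  res <- y - a - b * x
  df <- length(x) - 2
  sigma2 <- sum(w * res^2) / df
  list(intercept = a, slope = b, se = sqrt(sigma2 / sxx))
}

#' Weighted simple quantile regression at one percentile
#'
#' Minimises the weighted check (pinball) loss
#' `sum_i w_i * rho_q(y_i - a - b x_i)` with
#' `rho_q(u) = u (q/100 - 1\{u < 0\})` over intercept and slope, by an
#' exact pivoting solver that terminates at an optimal vertex of the
#' underlying linear program (the fitted line interpolates two
#' observations; ties resolve to the smallest-slope optimal vertex).
#'
#' @param pairs a `pair_set` from [build_op_pairs()] or [build_fs_pairs()].
#' @param q percentile in (0, 100).
#' @return List with `intercept`, `slope`, `loss` (the attained check
#'   loss), `converged`, `iterations`.
#' @export
fit_quantile_slope <- function(pairs, q) {
  stopifnot(length(q) == 1, q > 0, q < 100)
  d <- pairs_xyw(pairs)
  b0 <- wls_slope(d$x, d$y, d$w)$slope
  fit <- .qr_fit_cpp(d$x, d$y, d$w, q / 100, b0)
  if (!fit$converged) {
    stop("quantile regression did not converge at q = ", q,
         " (", fit$iterations, " pivots; n = ", length(d$x), ")",
         call. = FALSE)
  }
  fit
}

#' Weighted least-squares slope with analytic standard error
#'
#' The traditional (whole-distribution) regression slope: weighted least
#' squares of `y` on `x`, with the SE computed from the weighted residual
#' variance.  Invariant to uniform rescaling of the weights.
#'
#' @inheritParams fit_quantile_slope
#' @return List with `intercept`, `slope`, `se`.
#' @export
fit_ols_slope <- function(pairs) {
  d <- pairs_xyw(pairs)
  wls_slope(d$x, d$y, d$w)
}

#' Quantile slope function with joint bootstrap covariance
#'
#' Fits the weighted quantile regression at every percentile of `grid` on
#' the full pair set, then resamples `n_boot` times, refitting the whole
#' grid per replicate so that the replicate slope matrix yields both
#' per-percentile standard errors and the full covariance across
#' percentiles (the simultaneous-fit covariance needed by trend tests).
#'
#' @inheritParams fit_quantile_slope
#' @param grid a [quantile_grid()].
#' @param n_boot number of bootstrap replicates (>= 50); 1000 gives
#'   publication-quality bands, smaller values are fine for simulation
#'   studies.
#' @param unit resampling unit: `"cluster"` (default) resamples whole
#'   families/sibships with their weights intact and respects the
#'   dependence among pairs sharing an individual; `"observation"`
#'   resamples individual pairs, reproducing the behaviour of classical
#'   simultaneous quantile-regression software.
#' @param seed integer seed; required, so runs are reproducible.
#' @return A `quantile_slope_function`: list with `percentiles`, `beta`,
#'   `intercept`, `se`, `cov` (bootstrap covariance of the slopes across
#'   percentiles), `boot_beta` (replicate matrix), `n_boot`, `n_dropped`
#'   (degenerate replicates, at most 5% tolerated), `unit`, `seed`, `kind`.
#' @export
bootstrap_slopes <- function(pairs, grid = quantile_grid(), n_boot = 1000,
                             unit = c("cluster", "observation"),
                             seed) {
  unit <- match.arg(unit)
  if (missing(seed)) stop("seed is required for bootstrap_slopes",
                          call. = FALSE)
  stopifnot(inherits(grid, "quantile_grid"))
  if (n_boot < 50) stop("n_boot must be at least 50", call. = FALSE)
  d <- pairs_xyw(pairs)
  taus <- as.numeric(grid) / 100
  b0 <- wls_slope(d$x, d$y, d$w)$slope

  point <- .qr_fit_grid_cpp(d$x, d$y, d$w, taus, b0)
  if (any(point[, "converged"] != 1)) {
    stop("quantile regression did not converge at q = ",
         paste(grid[point[, "converged"] != 1], collapse = ", "),
         call. = FALSE)
  }

  cl <- as.character(pairs$cluster_id)
  cluster_rows <- split(seq_along(cl), cl)
  n_cl <- length(cluster_rows)
  n <- length(d$x)

  boot <- matrix(NA_real_, n_boot, length(taus))
  dropped <- 0L
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      idx <- if (unit == "cluster") {
        unlist(cluster_rows[sample.int(n_cl, n_cl, replace = TRUE)],
               use.names = FALSE)
      } else {
        sample.int(n, n, replace = TRUE)
      }
      xb <- d$x[idx]
      if (stats::var(xb) == 0) {
        dropped <- dropped + 1L
        next
      }
      m <- .qr_fit_grid_cpp(xb, d$y[idx], d$w[idx], taus, b0)
      if (any(m[, "converged"] != 1)) {
        dropped <- dropped + 1L
        next
      }
      boot[b, ] <- m[, "slope"]
    }
  })
  if (dropped > 0.05 * n_boot) {
    stop("bootstrap failure: ", dropped, " of ", n_boot,
         " replicates degenerate", call. = FALSE)
  }
  boot <- boot[stats::complete.cases(boot), , drop = FALSE]
  covb <- stats::cov(boot)
  covb <- (covb + t(covb)) / 2

  structure(list(percentiles = as.numeric(grid),
                 beta = unname(point[, "slope"]),
                 intercept = unname(point[, "intercept"]),
                 loss = unname(point[, "loss"]),
                 se = sqrt(diag(covb)),
                 cov = covb,
                 boot_beta = boot,
                 n_boot = as.integer(n_boot),
                 n_dropped = dropped,
                 unit = unit,
                 seed = as.integer(seed),
                 kind = attr(pairs, "kind")),
            class = "quantile_slope_function")
}

#' @export
print.quantile_slope_function <- function(x, ...) {
  cat("<quantile_slope_function> kind=", x$kind %||% "?", ", ",
      length(x$percentiles), " percentiles (",
      min(x$percentiles), "-", max(x$percentiles), "), ",
      nrow(x$boot_beta), " bootstrap replicates (unit=", x$unit,
      ", seed=", x$seed, ")\n", sep = "")
  show <- x$percentiles %in% c(10, 25, 50, 75, 90)
  if (!any(show)) show <- seq_along(x$percentiles) <= 5
  print(data.frame(percentile = x$percentiles[show],
                   beta = round(x$beta[show], 4),
                   se = round(x$se[show], 4)), row.names = FALSE)
  invisible(x)
}

#' Serialize a quantile slope function
#'
#' `slope_function_json()` writes grid, slopes, intercepts, bootstrap SEs,
#' `n_boot`, `unit`, and `seed` as JSON; `slope_function_tsv()` writes one
#' row per percentile.
#'
#' @param qsf a `quantile_slope_function`.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
slope_function_json <- function(qsf, path) {
  stopifnot(inherits(qsf, "quantile_slope_function"))
  jsonlite::write_json(
    list(kind = qsf$kind, percentiles = qsf$percentiles, beta = qsf$beta,
         intercept = qsf$intercept, se = qsf$se, n_boot = qsf$n_boot,
         unit = qsf$unit, seed = qsf$seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname slope_function_json
#' @export
slope_function_tsv <- function(qsf, path) {
  stopifnot(inherits(qsf, "quantile_slope_function"))
  utils::write.table(
    data.frame(percentile = qsf$percentiles, beta = qsf$beta,
               intercept = qsf$intercept, se = qsf$se),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# check-loss of an arbitrary line; used for optimality certificates
check_loss_line <- function(pairs, q, intercept, slope) {
  u <- pairs$y - intercept - slope * pairs$x
  sum(pairs$weight * u * (q / 100 - (u < 0)))
}
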