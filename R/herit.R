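#' Heritability from the offspring-parent regression slope
#'
#' Under phenotypic assortative mating with spouse correlation `r_spouse`,
#' the narrow-sense heritability is `h2 = 2 * beta_op / (1 + r_spouse)`.
#'
#' @param beta_op offspring-parent regression slope(s).
#' @param r_spouse phenotypic spouse correlation, `> -1`.
#' @return Heritability estimate(s).
#' @examples
#' h2_from_op(0.2235, 0.1062)  # 0.4041
#' @export
h2_from_op <- function(beta_op, r_spouse) {
  if (any(r_spouse == -1)) stop("r_spouse = -1: division by zero",
                                call. = FALSE)
  2 * beta_op / (1 + r_spouse)
}

#' Standard error of the offspring-parent heritability (delta method)
#'
#' Fixed-`r` delta method: `se_h2 = 2 * se_beta / (1 + r_spouse)`.  The
#' spouse correlation is treated as a known constant; its sampling
#' uncertainty is not propagated.
#'
#' @param se_beta standard error of the slope.
#' @inheritParams h2_from_op
#' @return SE of the heritability.
#' @export
h2_se_op <- function(se_beta, r_spouse) {
  stopifnot(all(se_beta >= 0))
  2 * se_beta / (1 + r_spouse)
}

#' Heritability from the full-sib regression slope (Falconer inversion)
#'
#' Inverts the full-sib resemblance under assortative mating:
#' `h2 = (sqrt(1 + 8 r beta_fs) - 1) / (2 r)`, with the continuous limit
#' `2 * beta_fs` applied when `|r| < 1e-8`.
#'
#' @param beta_fs full-sib regression slope(s).
#' @inheritParams h2_from_op
#' @return Heritability estimate(s).
#' @export
h2_from_fs <- function(beta_fs, r_spouse) {
  disc <- 1 + 8 * r_spouse * beta_fs
  if (any(disc < 0)) {
    stop("domain error: 1 + 8 * r_spouse * beta_fs < 0", call. = FALSE)
  }
  ifelse(rep(abs(r_spouse) < 1e-8, length.out = length(disc)),
         2 * beta_fs,
         (sqrt(disc) - 1) / (2 * r_spouse))
}

#' Full-sib slope implied by a heritability (exact inverse)
#'
#' Algebraic inverse of [h2_from_fs()]:
#' `beta_fs = h2 / 2 + r_spouse * h2^2 / 2`.  Round-trips with
#' [h2_from_fs()] to machine precision.
#'
#' @param h2 heritability value(s).
#' @inheritParams h2_from_op
#' @return Implied full-sib regression slope(s).
#' @export
fs_slope_from_h2 <- function(h2, r_spouse) {
  h2 / 2 + r_spouse * h2^2 / 2
}

#' Standard error of the full-sib heritability (delta method)
#'
#' Fixed-`r` delta method with gradient `dh2/dbeta = 2 / sqrt(1 + 8 r
#' beta)`: `se_h2 = 2 * se_beta / sqrt(1 + 8 * r_spouse * beta_fs)`.
#'
#' @inheritParams h2_se_op
#' @param beta_fs full-sib slope at which the gradient is evaluated.
#' @return SE of the heritability.
#' @export
h2_se_fs <- function(se_beta, beta_fs, r_spouse) {
  stopifnot(all(se_beta >= 0))
  disc <- 1 + 8 * r_spouse * beta_fs
  if (any(disc <= 0)) {
    stop("domain error: 1 + 8 * r_spouse * beta_fs <= 0", call. = FALSE)
  }
  2 * se_beta / sqrt(disc)
}

#' Quantile-specific heritability function
#'
#' Transforms a fitted [bootstrap_slopes()] object to heritability per
#' percentile, with delta-method standard errors on the bootstrap slope
#' SEs, normal-approximation 95% confidence intervals, and the
#' delta-transformed bootstrap covariance across percentiles (needed by
#' [trend_test()]).  The transformed bootstrap replicate matrix is kept in
#' the `"boot_h2"` attribute so percentile intervals can be formed as
#' well.  A full-sib percentile whose slope violates the domain of the
#' inversion is flagged (`flag = "domain"`, `h2 = NA`) rather than
#' failing the whole function; estimates above 1 are flagged `"gt1"` but
#' not clamped.
#'
#' @param slopes a `quantile_slope_function`.
#' @param r_spouse phenotypic spouse correlation.
#' @param method `"OP"` or `"FS"`; defaults to the pair kind recorded in
#'   `slopes`.
#' @return A data.frame (class `heritability_function`) with columns
#'   `percentile`, `beta`, `se_beta`, `h2`, `se_h2`, `ci_lo`, `ci_hi`,
#'   `flag`; attributes `cov_beta`, `cov_h2`, `boot_h2`, `method`,
#'   `r_spouse`.
#' @export
heritability_function <- function(slopes, r_spouse, method = NULL) {
  stopifnot(inherits(slopes, "quantile_slope_function"))
  method <- match.arg(method %||% slopes$kind, c("OP", "FS"))
  beta <- slopes$beta
  if (method == "OP") {
    h2 <- h2_from_op(beta, r_spouse)
    grad <- rep(2 / (1 + r_spouse), length(beta))
    boot_h2 <- h2_from_op(slopes$boot_beta, r_spouse)
    flag <- rep("ok", length(beta))
  } else {
    disc <- 1 + 8 * r_spouse * beta
    flag <- ifelse(disc < 0, "domain", "ok")
    h2 <- rep(NA_real_, length(beta))
    grad <- rep(NA_real_, length(beta))
    okp <- disc >= 0
    h2[okp] <- h2_from_fs(beta[okp], r_spouse)
    grad[okp] <- if (abs(r_spouse) < 1e-8) 2 else 2 / sqrt(disc[okp])
    bd <- 1 + 8 * r_spouse * slopes$boot_beta
    boot_h2 <- matrix(NA_real_, nrow(slopes$boot_beta),
                      ncol(slopes$boot_beta))
    okb <- bd >= 0
    if (abs(r_spouse) < 1e-8) {
      boot_h2[okb] <- 2 * slopes$boot_beta[okb]
    } else {
      boot_h2[okb] <- (sqrt(bd[okb]) - 1) / (2 * r_spouse)
    }
  }
  flag[!is.na(h2) & h2 > 1] <- "gt1"
  se_h2 <- abs(grad) * slopes$se
  cov_h2 <- slopes$cov * outer(grad, grad)
  dimnames(cov_h2) <- NULL

  out <- data.frame(percentile = slopes$percentiles,
                    beta = beta,
                    se_beta = slopes$se,
                    h2 = h2,
                    se_h2 = se_h2,
                    ci_lo = h2 - qnorm(0.975) * se_h2,
                    ci_hi = h2 + qnorm(0.975) * se_h2,
                    flag = flag,
                    stringsAsFactors = FALSE)
  structure(out, cov_beta = slopes$cov, cov_h2 = cov_h2, boot_h2 = boot_h2,
            method = method, r_spouse = r_spouse,
            class = c("heritability_function", "data.frame"))
}

#' Orthogonal polynomial trend contrast on a percentile grid
#'
#' Discrete orthogonal polynomial contrast vectors: mutually orthogonal
#' across degrees and orthogonal to the constant vector.  The degree-1
#' contrast is scaled so that `sum(c * values)` equals the ordinary
#' least-squares slope of the values on the percentiles, i.e. the change
#' per one-percent increment; higher degrees are unit-norm.
#'
#' @param percentiles numeric grid (>= degree + 2 points).
#' @param degree 1 (linear), 2 (quadratic), or 3 (cubic).
#' @return Contrast vector of the same length as `percentiles`.
#' @export
trend_contrast <- function(percentiles, degree) {
  stopifnot(degree %in% 1:3)
  p <- as.numeric(percentiles)
  if (length(p) < degree + 2) {
    stop("need at least degree + 2 percentiles", call. = FALSE)
  }
  if (degree == 1) {
    d <- p - mean(p)
    return(d / sum(d^2))
  }
  pm <- stats::poly(p, degree = degree)
  v <- pm[, degree]
  v - mean(v)  # poly columns are already centred; keep exact
}

#' Polynomial trend test across percentiles
#'
#' Tests for a linear, quadratic, or cubic trend of a quantile-indexed
#' estimate (slope or heritability) using an orthogonal polynomial
#' contrast and the joint bootstrap covariance across percentiles:
#' `estimate = c' v`, `var = c' Cov c`, two-sided normal p-value.  For
#' degree 1 the estimate is the change per one-percent increment of the
#' distribution.
#'
#' @param values estimates per percentile (e.g. `h2` column of a
#'   [heritability_function()], or a slope vector).  `NA` entries (flagged
#'   percentiles) are dropped together with the matching rows of `cov`.
#' @param cov covariance matrix of `values` across percentiles.
#' @param percentiles the percentile grid.
#' @param degree 1, 2, or 3.
#' @return A `trend_test_result` data.frame row: `degree`, `estimate`,
#'   `se`, `z`, `p`.
#' @export
trend_test <- function(values, cov, percentiles, degree = 1) {
  stopifnot(length(values) == length(percentiles),
            all(dim(cov) == length(values)))
  ok <- !is.na(values)
  values <- values[ok]
  cov <- cov[ok, ok, drop = FALSE]
  percentiles <- percentiles[ok]
  cv <- trend_contrast(percentiles, degree)
  est <- sum(cv * values)
  v <- drop(t(cv) %*% cov %*% cv)
  if (!is.finite(v) || v <= 0) {
    warning("singular bootstrap covariance: using pseudo-variance from ",
            "clipped eigenvalues", call. = FALSE)
    e <- eigen(cov, symmetric = TRUE)
    lam <- pmax(e$values, max(e$values, 0) * 1e-12 + 1e-300)
    v <- drop(t(cv) %*% e$vectors %*% (lam * t(e$vectors)) %*% cv)
  }
  se <- sqrt(v)
  z <- est / se
  structure(data.frame(degree = degree, estimate = est, se = se, z = z,
                       p = 2 * stats::pnorm(-abs(z))),
            class = c("trend_test_result", "data.frame"))
}

#' Trend tests of a heritability function on both scales
#'
#' Convenience wrapper running [trend_test()] for degrees 1-3 on the
#' heritability scale and on the regression-slope scale of a
#' [heritability_function()].
#'
#' @param hf a `heritability_function`.
#' @param degrees degrees to test.
#' @return Data.frame with columns `scale`, `degree`, `estimate`, `se`,
#'   `z`, `p`.
#' @export
trend_tests <- function(hf, degrees = 1:3) {
  stopifnot(inherits(hf, "heritability_function"))
  one <- function(scale, values, covm) {
    do.call(rbind, lapply(degrees, function(d) {
      cbind(scale = scale,
            as.data.frame(trend_test(values, covm, hf$percentile, d)))
    }))
  }
  rbind(one("h2", hf$h2, attr(hf, "cov_h2")),
        one("beta", hf$beta, attr(hf, "cov_beta")))
}
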