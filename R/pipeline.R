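#' Pipeline run configuration
#'
#' @param input path to a pedigree file (see [read_pedigree()]); exactly
#'   one of `input`/`sim` must be given.
#' @param sim a [sim_params()] object to generate the input instead.
#' @param grid [quantile_grid()] of fitted percentiles.
#' @param display_percentiles percentiles highlighted in the printed
#'   report (default the 10th, 25th, 50th, 75th, 90th).
#' @param n_boot bootstrap replicates.
#' @param boot_unit `"cluster"` or `"observation"` (see
#'   [bootstrap_slopes()]).
#' @param seed integer seed (required: the bootstrap depends on it).
#' @param offspring_sex optional `"M"` or `"F"`: restricts pairs to
#'   offspring/sibs of that sex (the pooled-sex adjustment is reused).
#' @param parent_cohort,offspring_cohort optional cohort filters defining
#'   a per-generation analysis; the spouse correlation is then computed
#'   within `parent_cohort`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, sim = NULL,
                            grid = quantile_grid(),
                            display_percentiles = c(10, 25, 50, 75, 90),
                            n_boot = 1000,
                            boot_unit = c("cluster", "observation"),
                            seed,
                            offspring_sex = NULL,
                            parent_cohort = NULL,
                            offspring_cohort = NULL) {
  if (is.null(input) == is.null(sim)) {
    stop("give exactly one of `input` (file path) or `sim` (sim_params)",
         call. = FALSE)
  }
  if (missing(seed)) stop("seed is required", call. = FALSE)
  structure(list(input = input, sim = sim, grid = grid,
                 display_percentiles = display_percentiles,
                 n_boot = n_boot, boot_unit = match.arg(boot_unit),
                 seed = as.integer(seed), offspring_sex = offspring_sex,
                 parent_cohort = parent_cohort,
                 offspring_cohort = offspring_cohort),
            class = "pipeline_config")
}

subset_pairs <- function(pairs, keep) {
  out <- as.data.frame(pairs)[keep, , drop = FALSE]
  rownames(out) <- NULL
  attributes(out) <- c(attributes(out),
                       attributes(pairs)[c("kind", "n_sibs", "n_sibships")])
  class(out) <- c("pair_set", "data.frame")
  out
}

#' Run the full quantile-heritability pipeline
#'
#' Executes adjust -> pairs -> quantile regression -> heritability/trend
#' for both the offspring-parent (OP) and full-sib (FS) analyses, and
#' optionally writes a report bundle (per-percentile TSV, trend JSON, and
#' a run manifest with seed and counts) to `out_dir`.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory (created if needed).
#' @return A list (class `quantherit_report`) with elements `table`
#'   counts, `r_spouse`, and per-analysis (`op`, `fs`) OLS slopes, slope
#'   functions, heritability functions, and trend tests.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- "input"
  result <- tryCatch({
    table <- if (!is.null(config$input)) read_pedigree(config$input)
             else generate_pedigree(config$sim)

    stage <- "adjust"
    adjusted <- compute_adjusted(table)

    stage <- "pairs"
    r_sp <- spouse_correlation(adjusted, table,
                               cohort = config$parent_cohort)
    op <- build_op_pairs(adjusted, table,
                         parent_cohort = config$parent_cohort,
                         offspring_cohort = config$offspring_cohort)
    fs <- build_fs_pairs(adjusted, table, cohort = config$offspring_cohort)
    if (!is.null(config$offspring_sex)) {
      sex_of <- setNames(adjusted$sex, adjusted$individual_id)
      op <- subset_pairs(op, sex_of[op$dependent_id] ==
                           config$offspring_sex)
      fs <- subset_pairs(fs, sex_of[fs$dependent_id] ==
                           config$offspring_sex)
    }

    stage <- "quantreg"
    analyses <- list(op = op, fs = fs)
    fitted <- lapply(seq_along(analyses), function(i) {
      pr <- analyses[[i]]
      sf <- bootstrap_slopes(pr, grid = config$grid,
                             n_boot = config$n_boot,
                             unit = config$boot_unit,
                             seed = config$seed + (i - 1L))
      list(pairs = pr, ols = fit_ols_slope(pr), slopes = sf)
    })
    names(fitted) <- names(analyses)

    stage <- "herit_trend"
    for (nm in names(fitted)) {
      hf <- heritability_function(fitted[[nm]]$slopes, r_sp$r)
      fitted[[nm]]$herit <- hf
      fitted[[nm]]$trend <- trend_tests(hf)
      fitted[[nm]]$h2_overall <- if (nm == "op") {
        list(h2 = h2_from_op(fitted[[nm]]$ols$slope, r_sp$r),
             se = h2_se_op(fitted[[nm]]$ols$se, r_sp$r))
      } else {
        list(h2 = h2_from_fs(fitted[[nm]]$ols$slope, r_sp$r),
             se = h2_se_fs(fitted[[nm]]$ols$se, fitted[[nm]]$ols$slope,
                           r_sp$r))
      }
    }

    manifest <- list(
      seed = config$seed,
      n_boot = config$n_boot,
      boot_unit = config$boot_unit,
      n_individuals = length(unique(table$individual_id)),
      n_exam_rows = nrow(table),
      n_adjusted = nrow(adjusted),
      n_couples = r_sp$n_couples,
      r_spouse = r_sp$r,
      n_op_pairs = nrow(fitted$op$pairs),
      n_fs_pairs = nrow(fitted$fs$pairs),
      n_sibs = attr(fitted$fs$pairs, "n_sibs"),
      n_sibships = attr(fitted$fs$pairs, "n_sibships"),
      filters = list(offspring_sex = config$offspring_sex,
                     parent_cohort = config$parent_cohort,
                     offspring_cohort = config$offspring_cohort))

    structure(list(manifest = manifest, r_spouse = r_sp,
                   op = fitted$op, fs = fitted$fs,
                   display_percentiles = config$display_percentiles),
              class = "quantherit_report")
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  if (!is.null(out_dir)) write_report(result, out_dir)
  result
}

#' Write a pipeline report bundle
#'
#' Writes `report_op.tsv` / `report_fs.tsv` (percentile, beta, se_beta,
#' h2, se_h2, ci_lo, ci_hi), `trend.json` (trend tests per analysis and
#' scale), and `manifest.json` (seed, counts, spouse correlation).
#'
#' @param report a `quantherit_report` from [run_pipeline()].
#' @param out_dir output directory.
#' @return Invisibly, `out_dir`.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "quantherit_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("op", "fs")) {
    hf <- report[[nm]]$herit
    utils::write.table(
      data.frame(percentile = hf$percentile,
                 beta = sprintf("%.10g", hf$beta),
                 se_beta = sprintf("%.10g", hf$se_beta),
                 h2 = sprintf("%.10g", hf$h2),
                 se_h2 = sprintf("%.10g", hf$se_h2),
                 ci_lo = sprintf("%.10g", hf$ci_lo),
                 ci_hi = sprintf("%.10g", hf$ci_hi),
                 flag = hf$flag),
      file.path(out_dir, paste0("report_", nm, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(
    list(op = report$op$trend, fs = report$fs$trend),
    file.path(out_dir, "trend.json"), dataframe = "rows", digits = 10)
  jsonlite::write_json(report$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = 10, null = "null")
  invisible(out_dir)
}

#' @export
print.quantherit_report <- function(x, ...) {
  m <- x$manifest
  cat("<quantherit_report> seed=", m$seed, ", ", m$n_individuals,
      " individuals, ", m$n_couples, " couples (r_spouse=",
      sprintf("%.4f", m$r_spouse), ")\n", sep = "")
  for (nm in c("op", "fs")) {
    a <- x[[nm]]
    cat("\n", toupper(nm), " analysis: ", nrow(a$pairs), " pairs; overall ",
        "beta=", sprintf("%.4f +/- %.4f", a$ols$slope, a$ols$se),
        ", h2=", sprintf("%.4f +/- %.4f", a$h2_overall$h2, a$h2_overall$se),
        "\n", sep = "")
    hf <- a$herit
    show <- hf$percentile %in% x$display_percentiles
    print(data.frame(percentile = hf$percentile[show],
                     beta = round(hf$beta[show], 4),
                     h2 = round(hf$h2[show], 4),
                     se_h2 = round(hf$se_h2[show], 4)), row.names = FALSE)
    lin <- a$trend[a$trend$scale == "h2" & a$trend$degree == 1, ]
    cat("linear trend (h2 per percent): ",
        sprintf("%.4f +/- %.4f, p = %.3g", lin$estimate, lin$se, lin$p),
        "\n", sep = "")
  }
  invisible(x)
}
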