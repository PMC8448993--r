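#' Fit the sex/age adjustment model for one cohort
#'
#' Ordinary least squares at the exam-row level (each exam is one
#' observation) with predictors sex, age, age^2, sex x age, and
#' sex x age^2.  Fitting within cohort absorbs cohort-specific assay and
#' fasting-status offsets, so residuals are comparable across cohorts.
#'
#' @param table a [pedigree_table()].
#' @param cohort_id cohort to fit.
#' @return An `adjustment_model`: list with `cohort_id`, `coefficients`
#'   (intercept, sex, age, age2, sex_age, sex_age2; micromol/L units),
#'   `n_rows`, and the residual SD.
#' @export
fit_adjustment <- function(table, cohort_id) {
  stopifnot(inherits(table, "pedigree_table"))
  rows <- table[table$cohort_id == cohort_id & !is.na(table$phenotype), ,
                drop = FALSE]
  if (nrow(rows) < 10) {
    stop("degenerate design in cohort ", cohort_id,
         ": fewer than 10 exam rows with phenotype", call. = FALSE)
  }
  male <- as.numeric(rows$sex == "M")
  if (length(unique(male)) < 2) {
    stop("degenerate design in cohort ", cohort_id,
         ": only one sex represented", call. = FALSE)
  }
  X <- cbind(intercept = 1, sex = male, age = rows$age, age2 = rows$age^2,
             sex_age = male * rows$age, sex_age2 = male * rows$age^2)
  fit <- stats::lm.fit(X, rows$phenotype)
  if (fit$rank < ncol(X)) {
    stop("degenerate design in cohort ", cohort_id,
         ": rank-deficient adjustment design matrix", call. = FALSE)
  }
  structure(list(cohort_id = cohort_id,
                 coefficients = fit$coefficients,
                 n_rows = nrow(rows),
                 sigma = sqrt(sum(fit$residuals^2) /
                                (nrow(rows) - ncol(X)))),
            class = "adjustment_model")
}

#' @export
print.adjustment_model <- function(x, ...) {
  cat("<adjustment_model> cohort ", x$cohort_id, " (", x$n_rows,
      " exam rows)\n", sep = "")
  print(round(x$coefficients, 4))
  invisible(x)
}

predict_adjustment <- function(model, sex, age) {
  male <- as.numeric(sex == "M")
  b <- model$coefficients
  b[["intercept"]] + b[["sex"]] * male + b[["age"]] * age +
    b[["age2"]] * age^2 + b[["sex_age"]] * male * age +
    b[["sex_age2"]] * male * age^2
}

#' Sex/age-adjusted phenotypes averaged over exams
#'
#' Computes per-exam residuals (observed minus fitted from the cohort's
#' [fit_adjustment()] model) and averages them over each individual's
#' available exams.  Exams with missing phenotype are skipped; individuals
#' with no valid exam are excluded and reported via the `"excluded"`
#' attribute.  Residuals are left centred at zero (downstream regressions
#' are location invariant); percentile labels downstream refer to this
#' residual distribution.
#'
#' @param table a [pedigree_table()].
#' @param models list of `adjustment_model`s; by default one is fitted per
#'   cohort present in `table`.
#' @return A data.frame (class `adjusted_phenotypes`) with one row per
#'   individual: `individual_id`, `cohort_id`, `sex`, `adjusted_value`
#'   (micromol/L), `n_exams_used`, plus the parental/sibship link columns
#'   carried over for pair construction.
#' @export
compute_adjusted <- function(table, models = NULL) {
  stopifnot(inherits(table, "pedigree_table"))
  cohorts <- unique(table$cohort_id)
  if (is.null(models)) {
    models <- lapply(cohorts, function(ch) fit_adjustment(table, ch))
  }
  names(models) <- vapply(models, function(m) m$cohort_id, character(1))
  missing_models <- setdiff(cohorts, names(models))
  if (length(missing_models) > 0) {
    stop("no adjustment model for cohort(s): ",
         paste(missing_models, collapse = ", "), call. = FALSE)
  }

  tab <- as.data.frame(table)
  tab$residual <- NA_real_
  for (ch in cohorts) {
    sel <- tab$cohort_id == ch & !is.na(tab$phenotype)
    tab$residual[sel] <- tab$phenotype[sel] -
      predict_adjustment(models[[ch]], tab$sex[sel], tab$age[sel])
  }

  ok <- !is.na(tab$residual)
  sums <- rowsum(tab$residual[ok], tab$individual_id[ok])
  counts <- rowsum(rep(1L, sum(ok)), tab$individual_id[ok])
  ind <- ped_individuals(table)
  m <- match(ind$individual_id, rownames(sums))
  out <- data.frame(individual_id = ind$individual_id,
                    cohort_id = ind$cohort_id,
                    sex = ind$sex,
                    adjusted_value = as.vector(sums)[m] /
                      as.vector(counts)[m],
                    n_exams_used = as.integer(as.vector(counts)[m]),
                    father_id = ind$father_id,
                    mother_id = ind$mother_id,
                    sibship_id = ind$sibship_id,
                    stringsAsFactors = FALSE)
  excluded <- out$individual_id[is.na(out$adjusted_value)]
  if (length(excluded) > 0) {
    message(length(excluded),
            " individual(s) excluded: no exam with a phenotype value")
  }
  out <- out[!is.na(out$adjusted_value), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, excluded = excluded, models = models,
            class = c("adjusted_phenotypes", "data.frame"))
}

#' Write adjusted phenotypes as TSV
#'
#' @param adjusted result of [compute_adjusted()].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_adjusted <- function(adjusted, path) {
  stopifnot(inherits(adjusted, "adjusted_phenotypes"))
  utils::write.table(
    adjusted[c("individual_id", "cohort_id", "adjusted_value",
               "n_exams_used")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
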