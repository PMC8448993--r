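#' Pedigree phenotype tables
#'
#' A `pedigree_table` holds longitudinal family phenotype data in long
#' format: one row per individual-exam, with parental and sibship links.
#' It is a `data.frame` with columns
#' \describe{
#'   \item{individual_id}{character, unique per person}
#'   \item{cohort_id}{character, the cohort/generation the person belongs to}
#'   \item{sex}{`"M"` or `"F"`}
#'   \item{age}{years at the exam, finite and positive}
#'   \item{exam}{positive integer exam number, unique within individual}
#'   \item{phenotype}{trait concentration in micromol/L; `NA` marks a
#'     missed measurement (the exam row is then ignored in averaging)}
#'   \item{father_id, mother_id}{character or `NA`; must resolve to a male
#'     (resp. female) individual when present in the table}
#'   \item{sibship_id}{character or `NA`; groups full siblings}
#' }
#'
#' @param data data.frame with the columns above (`sex` may also be coded
#'   1/2 with 1 = male, or lower case letters).
#' @param provenance free-text origin note stored as an attribute.
#' @return A validated `pedigree_table`.
#' @seealso [read_pedigree()], [write_pedigree()], [generate_pedigree()]
#' @export
pedigree_table <- function(data, provenance = "") {
  stopifnot(is.data.frame(data))
  missing_cols <- setdiff(ped_columns(), names(data))
  if (length(missing_cols) > 0) {
    stop("pedigree format error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  data <- as.data.frame(data)[ped_columns()]
  for (col in c("individual_id", "cohort_id", "father_id", "mother_id",
                "sibship_id")) {
    data[[col]] <- as.character(data[[col]])
    data[[col]][!is.na(data[[col]]) & data[[col]] == ""] <- NA_character_
  }
  data$sex <- normalize_sex(data$sex)
  data$age <- as.numeric(data$age)
  data$exam <- as.integer(data$exam)
  data$phenotype <- as.numeric(data$phenotype)
  rownames(data) <- NULL

  problems <- validate_pedigree(data)
  if (length(problems) > 0) {
    shown <- utils::head(problems, 20)
    stop("pedigree validation error:\n  ",
         paste(shown, collapse = "\n  "),
         if (length(problems) > 20)
           paste0("\n  ... and ", length(problems) - 20, " more"),
         call. = FALSE)
  }
  structure(data, provenance = provenance,
            class = c("pedigree_table", "data.frame"))
}

ped_columns <- function() {
  c("individual_id", "cohort_id", "sex", "age", "exam", "phenotype",
    "father_id", "mother_id", "sibship_id")
}

# Accepts "M"/"F" (any case) and 1/2 (1 = male); returns "M"/"F" or NA.
normalize_sex <- function(sex) {
  s <- toupper(trimws(as.character(sex)))
  out <- rep(NA_character_, length(s))
  out[s %in% c("M", "1")] <- "M"
  out[s %in% c("F", "2")] <- "F"
  out
}

#' Validate a pedigree data.frame
#'
#' Checks every row and returns one diagnostic string per violation (with
#' 1-based data row numbers); an empty character vector means the table is
#' valid.  Validation is total: no malformed row is silently dropped.
#'
#' @param data data.frame in `pedigree_table` column layout, already
#'   type-converted.
#' @return Character vector of diagnostics.
#' @export
validate_pedigree <- function(data) {
  n <- nrow(data)
  if (n == 0) return(character(0))
  row <- seq_len(n)
  problems <- character(0)
  note <- function(rows, msg) {
    if (length(rows) > 0) c(problems, paste0("row ", rows, ": ", msg))
    else problems
  }

  problems <- note(row[is.na(data$individual_id)], "missing individual_id")
  problems <- note(row[is.na(data$cohort_id)], "missing cohort_id")
  problems <- note(row[is.na(data$sex)], "sex not one of M/F/1/2")
  problems <- note(row[!is.finite(data$age) | data$age <= 0],
                   "age must be finite and > 0")
  problems <- note(row[is.na(data$exam) | data$exam <= 0],
                   "exam must be a positive integer")
  bad_phen <- !is.na(data$phenotype) &
    (!is.finite(data$phenotype) | data$phenotype <= 0)
  problems <- note(row[bad_phen], "phenotype must be finite and > 0 (or NA)")

  dup <- duplicated(data[c("individual_id", "exam")]) &
    !is.na(data$individual_id) & !is.na(data$exam)
  problems <- note(row[dup], "duplicate (individual_id, exam)")

  self_f <- !is.na(data$father_id) & data$father_id == data$individual_id
  self_m <- !is.na(data$mother_id) & data$mother_id == data$individual_id
  problems <- note(row[self_f | self_m], "individual is its own parent")

  # per-individual consistency of static fields
  for (col in c("cohort_id", "sex", "father_id", "mother_id", "sibship_id")) {
    v <- data[[col]]
    key <- data$individual_id
    filled <- ifelse(is.na(v), "\r<NA>", v)
    first <- filled[!duplicated(key)][match(key, key[!duplicated(key)])]
    problems <- note(row[filled != first],
                     paste0(col, " inconsistent across rows of the same individual"))
  }

  # parent links resolvable within the table must point to the right sex
  sex_of <- data$sex[!duplicated(data$individual_id)]
  names(sex_of) <- data$individual_id[!duplicated(data$individual_id)]
  fa <- data$father_id
  resolvable_f <- !is.na(fa) & fa %in% names(sex_of)
  problems <- note(row[resolvable_f & sex_of[fa] != "M"],
                   "father_id refers to a non-male individual")
  mo <- data$mother_id
  resolvable_m <- !is.na(mo) & mo %in% names(sex_of)
  problems <- note(row[resolvable_m & sex_of[mo] != "F"],
                   "mother_id refers to a non-female individual")

  problems
}

#' Read a pedigree phenotype file
#'
#' Reads a delimited text file (UTF-8, tab-separated by default, one row
#' per individual-exam) into a validated [pedigree_table()].  Absent
#' parent/sibship links are encoded as empty fields.
#'
#' @param path file path.
#' @param sep field delimiter, default tab.
#' @return A `pedigree_table`.
#' @examples
#' f <- system.file("extdata", "synthetic_pedigree_small.tsv",
#'                  package = "quantherit")
#' read_pedigree(f)
#' @export
read_pedigree <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, sep = sep, header = TRUE,
                           colClasses = "character", na.strings = NULL,
                           check.names = FALSE, fileEncoding = "UTF-8")
  missing_cols <- setdiff(ped_columns(), names(raw))
  if (length(missing_cols) > 0) {
    stop("pedigree format error in ", path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  raw$phenotype[raw$phenotype == ""] <- NA
  pedigree_table(raw, provenance = paste0("read from ", path))
}

#' Write a pedigree phenotype file
#'
#' Writes a [pedigree_table()] as UTF-8 tab-separated text, one row per
#' individual-exam.  Numeric values are written with 17 significant digits
#' so that [read_pedigree()] recovers the table exactly.
#'
#' @param table a `pedigree_table`.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_pedigree <- function(table, path) {
  stopifnot(inherits(table, "pedigree_table"))
  out <- as.data.frame(table)
  out$age <- sprintf("%.17g", out$age)
  out$phenotype <- ifelse(is.na(out$phenotype), "",
                          sprintf("%.17g", out$phenotype))
  out$exam <- as.character(out$exam)
  for (col in c("father_id", "mother_id", "sibship_id")) {
    out[[col]][is.na(out[[col]])] <- ""
  }
  con <- tryCatch(file(path, open = "w", encoding = "UTF-8"),
                  error = function(e) stop("cannot write ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.pedigree_table <- function(x, ...) {
  ids <- unique(x$individual_id)
  cat("<pedigree_table> ", length(ids), " individuals, ", nrow(x),
      " exam rows, ", length(unique(x$cohort_id)), " cohort(s)\n", sep = "")
  if (nzchar(attr(x, "provenance") %||% ""))
    cat("provenance: ", attr(x, "provenance"), "\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One row per individual with the static fields; used by pair builders.
ped_individuals <- function(table) {
  first <- !duplicated(table$individual_id)
  out <- as.data.frame(table)[first, c("individual_id", "cohort_id", "sex",
                                       "father_id", "mother_id", "sibship_id")]
  rownames(out) <- NULL
  out
}
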