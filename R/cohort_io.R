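# Cohort CSV schema: one row per child, fixed column set, booleans as 0/1,
# missing word comprehension as an empty field, "." decimal separator, UTF-8.

cohort_columns <- c("child_id", "age_months", "sex", "parental_education",
                    "vocab_count", "no_two_word", "parental_concerns",
                    "word_comprehension", "sld_age3",
                    "ref_vocab_z", "ref_grammar_z")

education_levels <- c("compulsory", "vocational", "university_entrance",
                      "university")

#' Write a cohort to CSV
#'
#' @param cohort A cohort `data.frame` as produced by [generate_cohort()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  validate_cohort(cohort)
  out <- cohort[cohort_columns]
  for (col in c("no_two_word", "parental_concerns", "sld_age3")) {
    out[[col]] <- as.integer(out[[col]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a cohort from CSV
#'
#' Validates the header and every row; range or encoding violations are
#' reported with the offending row number and field.
#'
#' @param path Path to a cohort CSV written in the package schema.
#' @return A validated cohort `data.frame`.
#' @export
read_cohort_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                         fileEncoding = "UTF-8")
  if (nrow(raw) == 0L) stop("no records in '", path, "'", call. = FALSE)
  unknown <- setdiff(names(raw), cohort_columns)
  if (length(unknown) > 0L) {
    stop("unknown columns: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  missing_cols <- setdiff(cohort_columns, names(raw))
  if (length(missing_cols) > 0L) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("no_two_word", "parental_concerns", "sld_age3")) {
    v <- raw[[col]]
    bad <- which(!is.na(v) & !v %in% c(0L, 1L))
    if (length(bad) > 0L) {
      stop("row ", bad[1L], ": field '", col, "' must be 0 or 1",
           call. = FALSE)
    }
    raw[[col]] <- v == 1L
  }
  validate_cohort(raw[cohort_columns])
}

validate_cohort <- function(cohort) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0L) {
    stop("no records", call. = FALSE)
  }
  missing_cols <- setdiff(cohort_columns, names(cohort))
  if (length(missing_cols) > 0L) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  check_range <- function(col, lo, hi, allow_na = FALSE) {
    v <- cohort[[col]]
    bad <- which((!allow_na & is.na(v)) |
                   (!is.na(v) & (v < lo | v > hi | v != round(v))))
    if (length(bad) > 0L) {
      stop("row ", bad[1L], ": field '", col, "' out of range [", lo, ", ",
           hi, "]", call. = FALSE)
    }
  }
  check_range("vocab_count", 0, 37)
  check_range("word_comprehension", 0, 9, allow_na = TRUE)
  check_range("age_months", 23, 25)
  bad_sex <- which(!cohort$sex %in% c("male", "female"))
  if (length(bad_sex) > 0L) {
    stop("row ", bad_sex[1L], ": field 'sex' must be 'male' or 'female'",
         call. = FALSE)
  }
  bad_edu <- which(!cohort$parental_education %in% education_levels)
  if (length(bad_edu) > 0L) {
    stop("row ", bad_edu[1L],
         ": field 'parental_education' has an unknown level", call. = FALSE)
  }
  if (anyNA(cohort$sld_age3)) {
    stop("row ", which(is.na(cohort$sld_age3))[1L],
         ": field 'sld_age3' is required for every record", call. = FALSE)
  }
  cohort
}
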