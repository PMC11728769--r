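#' @title Patient-table input/output
#' @description Comma-separated patient tables with a fixed, documented
#'   header, UTF-8, "." decimal separator, and one leading provenance
#'   comment line (prefixed `#`) recording the spec hash, coefficient hash
#'   and seed. Numeric values are serialized with 17 significant digits so
#'   that read-after-write reproduces them exactly.
#' @name cohort-io
NULL

#' Write a cohort table
#'
#' @param table A cohort data frame (columns of [cohort_columns()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(table, path) {
  miss <- setdiff(cohort_columns(), names(table))
  if (length(miss)) {
    stop_config("cohort table missing column '%s'", miss[1L])
  }
  tab <- table[cohort_columns()]
  prov <- sprintf("# oncopop cohort | spec_hash=%s coef_hash=%s seed=%s",
                  attr(table, "spec_hash") %||% "NA",
                  attr(table, "coef_hash") %||% "NA",
                  as.character(attr(table, "seed") %||% "NA"))
  fmt <- vapply(tab, function(col) {
    if (is.numeric(col) && !is.integer(col)) {
      sprintf("%.17g", col)
    } else as.character(col)
  }, FUN.VALUE = character(nrow(tab)))
  if (nrow(tab) == 1L) fmt <- matrix(fmt, nrow = 1L)
  lines <- c(prov,
             paste(cohort_columns(), collapse = ","),
             apply(fmt, 1L, paste, collapse = ","))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a cohort table
#'
#' @param path CSV file as written by [write_cohort()]; comment lines
#'   (prefix `#`) are skipped.
#' @return A `cohort` data frame.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop_config("file not found: %s", path)
  tab <- utils::read.csv(path, comment.char = "#",
                         stringsAsFactors = FALSE,
                         colClasses = c(patient_id = "integer",
                                        tumor = "character",
                                        sex = "character",
                                        origin = "character",
                                        ecog = "integer")[
                           intersect(c("patient_id", "tumor", "sex",
                                       "origin", "ecog"),
                                     scan_header(path))])
  miss <- setdiff(cohort_columns(), names(tab))
  if (length(miss)) {
    stop_config("cohort file missing required column '%s'", miss[1L])
  }
  if (nrow(tab) == 0L) stop_config("cohort file contains a header but no rows")
  structure(tab[cohort_columns()], class = c("cohort", "data.frame"))
}

scan_header <- function(path) {
  con <- file(path, "r")
  on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line)) return(character(0))
    if (!startsWith(line, "#")) return(strsplit(line, ",")[[1L]])
  }
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Virtual cohort: %d patients\n", nrow(x)))
  cat(sprintf("  provenance: spec %s, coefficients %s, seed %s\n",
              attr(x, "spec_hash") %||% "-", attr(x, "coef_hash") %||% "-",
              as.character(attr(x, "seed") %||% "-")))
  print(utils::head(as.data.frame(x), 5L))
  if (nrow(x) > 5L) cat(sprintf("  ... %d more rows\n", nrow(x) - 5L))
  invisible(x)
}

#' Summary statistics of a cohort
#'
#' Mean and SD per numeric column plus category counts for the primaries.
#'
#' @param object A cohort.
#' @param ... Unused.
#' @return Data frame of per-variable summaries, invisibly (printed).
#' @export
summary.cohort <- function(object, ...) {
  num <- names(object)[vapply(object, is.numeric, logical(1))]
  num <- setdiff(num, c("patient_id", "ecog"))
  out <- data.frame(
    variable = num,
    mean = vapply(num, function(v) mean(object[[v]]), numeric(1)),
    sd = vapply(num, function(v) stats::sd(object[[v]]), numeric(1)),
    row.names = NULL)
  cat(sprintf("Cohort of %d patients; %.1f%% female\n", nrow(object),
              100 * mean(object$sex == "female")))
  print(out, digits = 4)
  invisible(out)
}
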