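#' Cohort table schema
#'
#' Column names of the delimited cohort table. Visit components
#' (`tjc28_*`, `sjc28_*`, `esr_*`, `vas_*`) and/or precomputed DAS28
#' columns must be present; when both are supplied the raw components
#' win and discrepancies above 0.01 are logged.
#'
#' @return A list with `required`, `visit`, `das28`, and `methylation`
#'   column names.
#' @export
cohort_schema <- function() {
  meth <- paste0("cg17330251_", 1:12)
  visit <- c("tjc28_baseline", "sjc28_baseline", "esr_baseline", "vas_baseline",
             "tjc28_month6", "sjc28_month6", "esr_month6", "vas_month6")
  list(
    required = c("id", "age", "sex", "genotype", meth,
                 "neut", "lymph", "mono", "plt", "pct"),
    visit = visit,
    das28 = c("das28_baseline", "das28_month6"),
    methylation = meth
  )
}

#' Write a cohort table to a CSV file
#'
#' @param cohort Cohort data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and validate a cohort table
#'
#' Reads a comma-delimited cohort file with header matching the
#' [cohort_schema()] (order-free, case-insensitive). Genotypes are
#' normalised to upper case; every field is range-checked with
#' row/column-named errors.
#'
#' @param path CSV file path.
#' @return A validated data frame of class `lef_cohort`.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  schema <- cohort_schema()
  names(raw) <- tolower(names(raw))
  want <- tolower(c(schema$required, schema$visit, schema$das28))
  missing_req <- setdiff(tolower(schema$required), names(raw))
  if (length(missing_req))
    stop("missing required column(s): ", paste(missing_req, collapse = ", "))
  have_visit <- all(tolower(schema$visit) %in% names(raw))
  have_das <- all(tolower(schema$das28) %in% names(raw))
  if (!have_visit && !have_das)
    stop("need either the visit component columns (",
         paste(schema$visit, collapse = ", "),
         ") or precomputed das28_baseline/das28_month6")
  extra <- setdiff(names(raw), want)
  cohort <- raw[, intersect(want, names(raw)), drop = FALSE]

  fail <- function(row, col, msg)
    stop(sprintf("row %d, column %s: %s", row, col, msg))
  check_range <- function(col, lo, hi, strict_lo = FALSE) {
    if (!col %in% names(cohort)) return(invisible())
    v <- cohort[[col]]
    bad <- which(!is.na(v) &
                   (!is.finite(v) | v < lo | v > hi |
                      (strict_lo & v <= lo)))
    if (length(bad)) fail(bad[1], col, sprintf(
      "value %s out of range [%s, %s]", format(v[bad[1]]), lo, hi))
  }

  cohort$genotype <- toupper(trimws(cohort$genotype))
  badg <- which(!cohort$genotype %in% c("CC", "CT", "TT"))
  if (length(badg)) fail(badg[1], "genotype",
                         paste("invalid genotype", cohort$genotype[badg[1]]))
  cohort$genotype <- factor(cohort$genotype, levels = c("CC", "CT", "TT"))
  cohort$sex <- tolower(trimws(cohort$sex))
  bads <- which(!cohort$sex %in% c("female", "male"))
  if (length(bads)) fail(bads[1], "sex", paste("invalid sex", cohort$sex[bads[1]]))
  cohort$sex <- factor(cohort$sex, levels = c("female", "male"))

  check_range("age", 0, 120)
  for (m in tolower(schema$methylation)) check_range(m, 0, 1)
  for (v in c("tjc28_baseline", "sjc28_baseline", "tjc28_month6", "sjc28_month6"))
    check_range(v, 0, 28)
  for (v in c("esr_baseline", "esr_month6")) check_range(v, 0, 200, strict_lo = TRUE)
  for (v in c("vas_baseline", "vas_month6")) check_range(v, 0, 100)
  for (v in c("neut", "lymph", "mono", "plt", "pct"))
    check_range(v, 0, Inf, strict_lo = TRUE)

  names(cohort) <- c(schema$required, schema$visit, schema$das28)[
    match(names(cohort), tolower(c(schema$required, schema$visit, schema$das28)))]
  attr(cohort, "extra_columns") <- extra
  class(cohort) <- c("lef_cohort", "data.frame")
  cohort
}
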