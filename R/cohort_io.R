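# Data model and delimited-text I/O for the two core tables.

#' Construct a genus abundance table
#'
#' A participants x genera matrix of relative abundances (fractions). Rows
#' need not sum exactly to 1 (some pipelines drop unclassified reads) but may
#' not exceed 1 beyond numerical tolerance.
#'
#' @param values numeric matrix, participants in rows, genera in columns.
#' @param participant_ids character vector of unique participant identifiers.
#' @param genus_names character vector of unique genus labels.
#'
#' @return A numeric matrix of class `"genus_table"` with participant IDs as
#'   rownames and genus names as colnames.
#' @export
genus_table <- function(values, participant_ids = rownames(values),
                        genus_names = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(participant_ids) || is.null(genus_names))
    stop("participant_ids and genus_names are required")
  participant_ids <- as.character(participant_ids)
  genus_names <- as.character(genus_names)
  if (anyDuplicated(participant_ids))
    stop("duplicate participant IDs: ",
         paste(unique(participant_ids[duplicated(participant_ids)]), collapse = ", "))
  if (anyDuplicated(genus_names))
    stop("duplicate genus names: ",
         paste(unique(genus_names[duplicated(genus_names)]), collapse = ", "))
  if (!is.numeric(values)) stop("abundance values must be numeric")
  if (anyNA(values)) stop("abundance values may not be missing")
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    stop(sprintf("negative abundance at participant '%s', genus '%s'",
                 participant_ids[neg[1, 1]], genus_names[neg[1, 2]]))
  }
  rs <- rowSums(values)
  if (any(rs > 1 + 1e-6)) {
    bad <- which.max(rs)
    stop(sprintf("row sum %.6f > 1 for participant '%s'", rs[bad],
                 participant_ids[bad]))
  }
  dimnames(values) <- list(participant_ids, genus_names)
  class(values) <- c("genus_table", class(values))
  values
}

#' @export
print.genus_table <- function(x, ...) {
  cat(sprintf("genus_table: %d participants x %d genera\n", nrow(x), ncol(x)))
  cat(sprintf("  mean row sum %.4f; overall prevalence (abundance > 0) %.1f%%\n",
              mean(rowSums(x)), 100 * mean(x > 0)))
  invisible(x)
}

#' Read a genus abundance table from delimited text
#'
#' First column is the participant ID; remaining columns are genus
#' abundances. Integer count tables are accepted and converted to relative
#' fractions row-wise; fractional tables are validated as-is unless
#' `renormalize` is set.
#'
#' @param path path to a TSV or CSV file (delimiter inferred from extension,
#'   `.csv` = comma, otherwise tab).
#' @param renormalize divide each row by its sum (default `FALSE`: validate
#'   only).
#'
#' @return A [genus_table()].
#' @export
read_abundance_table <- function(path, renormalize = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2) stop("abundance table needs an ID column plus >= 1 genus")
  ids <- df[[1]]
  num <- df[-1]
  for (j in seq_along(num)) {
    v <- suppressWarnings(as.numeric(num[[j]]))
    bad <- which(is.na(v) & !is.na(num[[j]]) & nzchar(num[[j]]))
    if (length(bad))
      stop(sprintf("non-numeric abundance '%s' at row %d (participant '%s'), column '%s'",
                   num[[j]][bad[1]], bad[1], ids[bad[1]], names(num)[j]))
    if (anyNA(v))
      stop(sprintf("missing abundance at column '%s'", names(num)[j]))
    num[[j]] <- v
  }
  m <- as.matrix(num)
  # count tables (all values integral, sums >> 1) become fractions
  if (all(abs(m - round(m)) < 1e-9) && any(rowSums(m) > 1 + 1e-6)) {
    rs <- rowSums(m)
    if (any(rs == 0)) stop("count table contains an all-zero row")
    m <- m / rs
  }
  if (renormalize) {
    rs <- rowSums(m)
    if (any(rs == 0)) stop("cannot renormalize an all-zero row")
    m <- m / rs
  }
  genus_table(m, participant_ids = ids, genus_names = colnames(m))
}

#' Write a genus abundance table as delimited text
#'
#' @param table a [genus_table()].
#' @param path output path (`.csv` writes comma-separated, otherwise tab).
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(table, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(participant_id = rownames(table),
                   as.data.frame(unclass(table), check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = TRUE, row.names = FALSE)
  invisible(path)
}

# columns every cohort table must carry (README documents the schema)
cohort_required_cols <- function() {
  c("participant_id", "province", "region", "age", "sex", "bmi", "income",
    "marital", "education", "residence", "urbanisation_index", "energy",
    "smoking", "alcohol", "physical_activity",
    "rice", "wheat", "fruit", "vegetable", "nuts", "pork", "poultry",
    "milk", "egg", "fish", "vegetable_oil", "animal_oil", "fibre",
    "fasting_glucose_0", "fasting_insulin_0", "hba1c_0",
    "fasting_glucose_1", "fasting_insulin_1", "hba1c_1",
    "diabetes_medication_1", "followup_years")
}

cohort_categorical_cols <- function() {
  c("province", "region", "sex", "marital", "education", "residence")
}

#' Read a participant metadata (cohort) table
#'
#' Requires the full documented column set: identifiers, province and region,
#' demographics, anthropometrics, lifestyle, the 12 food-group intakes plus
#' fibre, and baseline (`_0`) / follow-up (`_1`) glycaemic panels. Missing
#' values (empty cells or `NA`) are preserved; imputation is a separate,
#' explicit step ([impute_missing()]).
#'
#' @param path path to a TSV or CSV file.
#' @return A `data.frame` of class `"cohort_table"`.
#' @export
read_cohort_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  as_cohort_table(df)
}

#' Validate a data frame as a cohort table
#'
#' @param df a data frame holding the documented cohort columns.
#' @return `df` with categorical columns as character, numeric columns as
#'   numeric, classed `"cohort_table"`.
#' @export
as_cohort_table <- function(df) {
  req <- cohort_required_cols()
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(df$participant_id))
    stop("duplicate participant IDs in cohort table")
  cats <- cohort_categorical_cols()
  for (nm in setdiff(req, c("participant_id", cats))) {
    df[[nm]] <- as.numeric(df[[nm]])
    if (any(df[[nm]] < 0, na.rm = TRUE))
      stop("negative value in physical-quantity column '", nm, "'")
  }
  for (nm in cats) df[[nm]] <- as.character(df[[nm]])
  if (!all(stats::na.omit(df$region) %in% c("North", "South")))
    stop("region must be 'North' or 'South'")
  # region must be a deterministic function of province
  map <- unique(df[!is.na(df$region), c("province", "region")])
  if (anyDuplicated(map$province))
    stop("province maps to more than one region")
  df$participant_id <- as.character(df$participant_id)
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Write a cohort table as delimited text
#'
#' @param cohort a cohort table.
#' @param path output path (`.csv` = comma, otherwise tab).
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(cohort, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(as.data.frame(cohort), path, sep = sep, quote = TRUE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
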