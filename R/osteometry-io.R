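## Specimen data model and tabular interchange.
##
## A dataset is a data.frame of one row per specimen with identifier columns
## (specimen_id, taxon, group, source, focal), the measurement columns of
## MEASUREMENT_VARS (cm; NA = not preserved / not measured), and an
## `estimated` column holding a semicolon-separated list of measurement names
## whose values were inferred rather than measured (e.g. a humeral length
## reconstructed from a conspecific ulna/humerus ratio).

ID_COLS <- c("specimen_id", "taxon", "group", "source", "focal", "estimated")

#' Construct a specimen dataset
#'
#' Assembles and validates a specimen-by-measurement table for downstream
#' analysis. All linear measurements are in centimeters.
#'
#' @param df data.frame with at least `specimen_id`, `taxon` and `group`
#'   columns plus any of the measurement columns
#'   `r paste(MEASUREMENT_VARS, collapse = ", ")`. Optional columns: `source`
#'   (one of `"direct"`, `"photogrammetry"`, `"literature"`), `focal`
#'   (logical; the single focal fossil specimen), `estimated`
#'   (semicolon-separated names of inferred measurements).
#' @param metadata named list of free-form metadata (units, provenance,
#'   generator seed); stored as an attribute and preserved on round-trip.
#' @return A `mfs_data` object (a validated data.frame).
#' @details Validation enforces: unique non-empty specimen ids; `group` drawn
#'   from the five extant locomotor habits plus `mesotheriid_fossil`; strictly
#'   positive finite measurements; `OL < UL`; consistency of the functional
#'   ulna length `|FUL - (UL - OL)| <= 0.01 * UL`; and `WFA < MTCIII_L`.
#'   Any violation raises a classed `mfs_validation_error` naming the
#'   specimen and rule, so a malformed table never yields a partial dataset.
#' @examples
#' d <- mfs_data(data.frame(specimen_id = "s1", taxon = "t", group = "digger",
#'                          UL = 10, OL = 2))
#' @export
mfs_data <- function(df, metadata = list()) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (col in c("specimen_id", "taxon", "group"))
    if (!col %in% names(df))
      mfs_schema_error(sprintf("missing mandatory column '%s'", col))
  n <- nrow(df)
  if (!"source" %in% names(df)) df$source <- rep("direct", n)
  if (!"focal" %in% names(df)) df$focal <- rep(FALSE, n)
  if (!"estimated" %in% names(df)) df$estimated <- rep("", n)
  df$focal <- as.logical(df$focal)
  df$estimated[is.na(df$estimated)] <- ""
  df$estimated <- as.character(df$estimated)
  for (v in MEASUREMENT_VARS) if (!v %in% names(df)) df[[v]] <- rep(NA_real_, n)
  df <- df[, c(setdiff(ID_COLS, "estimated"), MEASUREMENT_VARS, "estimated")]
  validate_mfs_data(df)
  structure(df, metadata = metadata, class = c("mfs_data", "data.frame"))
}

validate_mfs_data <- function(df) {
  if (nrow(df) == 0) return(invisible(df))
  ids <- as.character(df$specimen_id)
  if (any(is.na(ids) | !nzchar(ids)))
    mfs_validation_error("specimen_id must be non-empty for every record")
  if (anyDuplicated(ids))
    mfs_validation_error(sprintf("duplicated specimen_id: %s",
                                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  bad <- !df$group %in% GROUPS
  if (any(bad))
    mfs_validation_error(sprintf(
      "specimen %s: group '%s' not one of {%s}",
      ids[bad][1], df$group[bad][1], paste(GROUPS, collapse = ", ")))
  for (v in MEASUREMENT_VARS) {
    x <- df[[v]]
    bad <- !is.na(x) & (!is.finite(x) | x <= 0)
    if (any(bad))
      mfs_validation_error(sprintf(
        "specimen %s: %s must be strictly positive and finite", ids[bad][1], v))
  }
  both <- !is.na(df$OL) & !is.na(df$UL)
  bad <- both & df$OL >= df$UL
  if (any(bad))
    mfs_validation_error(sprintf("specimen %s: rule OL < UL violated", ids[bad][1]))
  ful <- !is.na(df$FUL) & both
  bad <- ful & abs(df$FUL - (df$UL - df$OL)) > 0.01 * df$UL
  if (any(bad))
    mfs_validation_error(sprintf(
      "specimen %s: FUL inconsistent with UL - OL (tolerance 1%% of UL)", ids[bad][1]))
  w <- !is.na(df$WFA) & !is.na(df$MTCIII_L)
  bad <- w & df$WFA >= df$MTCIII_L
  if (any(bad))
    mfs_validation_error(sprintf("specimen %s: rule WFA < MTCIII_L violated", ids[bad][1]))
  invisible(df)
}

#' Metadata of a specimen dataset
#' @param d a `mfs_data` object
#' @return Named list of metadata stored at construction or read time.
#' @export
mfs_metadata <- function(d) attr(d, "metadata") %||% list()

#' Names of estimated measurements for each specimen
#' @param d a `mfs_data` object
#' @return List (one element per specimen) of character vectors of
#'   measurement names flagged as inferred rather than measured.
#' @export
estimated_fields <- function(d) {
  out <- strsplit(ifelse(is.na(d$estimated), "", d$estimated), ";", fixed = TRUE)
  out <- lapply(out, function(x) x[nzchar(x)])
  names(out) <- d$specimen_id
  out
}

#' Read a specimen measurement table
#'
#' Reads a delimited text table (comma by default, tab accepted) with one row
#' per specimen. Blank measurement cells become missing values; a trailing
#' asterisk on a numeric cell, or names listed in an `estimated` /
#' `estimated_fields` column, mark measurements as inferred.
#'
#' @param path path to a UTF-8 delimited text file.
#' @param sep field separator; `NULL` (default) picks `"\t"` for `.tsv`/`.tab`
#'   files and `","` otherwise.
#' @param col_map optional named character vector mapping file column names to
#'   canonical names (e.g. `c("MTCIII-L" = "MTCIII_L")`), for importing tables
#'   whose headers differ from the canonical schema.
#' @return A validated [mfs_data] object.
#' @export
read_measurements <- function(path, sep = NULL, col_map = NULL) {
  if (!file.exists(path)) mfs_error(sprintf("file not found: %s", path), "mfs_io_error")
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, encoding = "UTF-8",
                           na.strings = character())
  if (!is.null(col_map)) {
    hit <- names(raw) %in% names(col_map)
    names(raw)[hit] <- unname(col_map[names(raw)[hit]])
  }
  names(raw)[names(raw) == "estimated_fields"] <- "estimated"
  for (col in c("specimen_id", "taxon", "group"))
    if (!col %in% names(raw))
      mfs_schema_error(sprintf("missing mandatory column '%s'", col))
  if (!any(MEASUREMENT_VARS %in% names(raw)))
    mfs_schema_error("no measurement column found (expected at least one of the canonical abbreviations)")

  est <- if ("estimated" %in% names(raw)) raw$estimated else rep("", nrow(raw))
  est[is.na(est)] <- ""
  for (v in intersect(MEASUREMENT_VARS, names(raw))) {
    cells <- trimws(raw[[v]])
    starred <- grepl("\\*$", cells)
    cells <- sub("\\*$", "", cells)
    blank <- !nzchar(cells) | toupper(cells) %in% c("NA", "N/A")
    num <- suppressWarnings(as.numeric(cells))
    bad <- !blank & is.na(num)
    if (any(bad))
      mfs_parse_error(sprintf("non-numeric value '%s' in column %s, row %d",
                              raw[[v]][bad][1], v, which(bad)[1]))
    num[blank] <- NA_real_
    raw[[v]] <- num
    if (any(starred))
      est[starred] <- ifelse(nzchar(est[starred]),
                             paste(est[starred], v, sep = ";"), v)
  }
  raw$estimated <- est
  if ("focal" %in% names(raw))
    raw$focal <- toupper(trimws(raw$focal)) %in% c("TRUE", "T", "1", "YES")
  mfs_data(raw, metadata = list(path = path, units = "cm"))
}

#' Write a specimen measurement table
#'
#' Inverse of [read_measurements()]: writes the dataset so that reading it
#' back reproduces every field (numeric values at full precision).
#'
#' @param d a `mfs_data` object
#' @param path output file path
#' @param sep field separator (default comma)
#' @return `path`, invisibly.
#' @export
write_measurements <- function(d, path, sep = ",") {
  df <- as.data.frame(d)
  num <- vapply(df, is.numeric, logical(1))
  for (v in names(df)[num])
    df[[v]] <- ifelse(is.na(df[[v]]), "", sprintf("%.12g", df[[v]]))
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

## ---- structured results serialization -----------------------------------

#' Write an analysis result to structured text
#'
#' Serializes any of the package's result objects (index or lever tables,
#' morphospace fits, habit comparisons, radial spaces, plain lists) as JSON
#' with full numeric precision, so that [read_results()] round-trips values
#' to at least 10 significant digits.
#'
#' @param obj result object
#' @param path output file path
#' @return `path`, invisibly.
#' @export
write_results <- function(obj, path) {
  payload <- list(class = class(obj), value = strip_for_json(obj))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", force = TRUE)
  invisible(path)
}

strip_for_json <- function(x) {
  if (is.data.frame(x)) {
    attr(x, "metadata") <- NULL
    return(as.data.frame(x))
  }
  if (is.matrix(x)) return(list(.matrix = TRUE, dim = dim(x),
                                dimnames = dimnames(x), data = as.vector(x)))
  if (is.list(x)) return(lapply(unclass(x), strip_for_json))
  x
}

restore_from_json <- function(x) {
  if (is.list(x) && isTRUE(x$.matrix)) {
    m <- matrix(unlist(x$data), nrow = x$dim[[1]], ncol = x$dim[[2]])
    if (!is.null(x$dimnames)) dimnames(m) <- lapply(x$dimnames, unlist)
    return(m)
  }
  if (is.list(x)) return(lapply(x, restore_from_json))
  x
}

#' Read a result written by [write_results()]
#' @param path file path
#' @return The deserialized object with its class restored.
#' @export
read_results <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = TRUE, simplifyMatrix = FALSE)
  obj <- restore_from_json(payload$value)
  cls <- unlist(payload$class)
  if (identical(cls, c("mfs_data", "data.frame"))) {
    if (NROW(obj) == 0)  # JSON drops columns of an empty table
      obj <- data.frame(specimen_id = character(), taxon = character(),
                        group = character(), stringsAsFactors = FALSE)
    return(mfs_data(obj))
  }
  if (is.data.frame(obj) || !"data.frame" %in% cls) class(obj) <- cls
  obj
}
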