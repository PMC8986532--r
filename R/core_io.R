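# Readers/writers for sample tables and beta matrices, and the study
# day-of-year convention (day 1 = 1 May, day 365 = 30 April; no leap days).

# cumulative days before each month in a non-leap year
.MONTH_OFFSET <- c(0L, 31L, 59L, 90L, 120L, 151L, 181L, 212L, 243L, 273L, 304L, 334L)
.MONTH_LEN <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
.MAY1_CAL_DOY <- 121L  # calendar day-of-year of 1 May, non-leap

#' Convert a calendar date to the study day-of-year
#'
#' The study year runs from 1 May (day 1) to 30 April (day 365) so that a
#' single hibernation period falls inside one cycle. Leap days are rejected:
#' the circannual analyses use a fixed 365-day period.
#'
#' @param month Integer month, 1-12.
#' @param day_of_month Integer day within the month (non-leap calendar).
#' @return Integer study day in 1..365.
#' @examples
#' calendar_to_study_doy(5, 1)   # 1
#' calendar_to_study_doy(4, 18)  # 353
#' calendar_to_study_doy(9, 16)  # 139
#' @export
calendar_to_study_doy <- function(month, day_of_month) {
  if (length(month) != length(day_of_month))
    stop("month and day_of_month must have equal length")
  month <- as.integer(month); day_of_month <- as.integer(day_of_month)
  bad <- is.na(month) | is.na(day_of_month) | month < 1L | month > 12L |
    day_of_month < 1L | day_of_month > .MONTH_LEN[pmax(pmin(month, 12L), 1L)]
  if (any(bad))
    stop("invalid calendar date(s) at position(s): ", paste(which(bad), collapse = ", "),
         " (29 February is rejected; 365-day year)")
  cal <- .MONTH_OFFSET[month] + day_of_month
  ((cal - .MAY1_CAL_DOY) %% 365L) + 1L
}

#' Convert a study day-of-year back to a calendar date
#'
#' Inverse of [calendar_to_study_doy()].
#'
#' @param doy Integer study day in 1..365.
#' @return A list with integer vectors `month` and `day_of_month`.
#' @export
study_doy_to_calendar <- function(doy) {
  doy <- as.integer(doy)
  if (any(is.na(doy) | doy < 1L | doy > 365L))
    stop("study doy must be in 1..365")
  cal <- ((doy - 1L + .MAY1_CAL_DOY - 1L) %% 365L) + 1L
  month <- findInterval(cal - 1L, .MONTH_OFFSET)
  list(month = month, day_of_month = cal - .MONTH_OFFSET[month])
}

#' Convert a 1-January-origin Julian day to the study day-of-year
#'
#' @param jday Integer calendar day-of-year (1 = 1 Jan), 1..365.
#' @return Integer study day (1 = 1 May).
#' @export
julian_to_study_doy <- function(jday) {
  jday <- as.integer(jday)
  if (any(is.na(jday) | jday < 1L | jday > 365L))
    stop("Julian day must be in 1..365 (365-day year)")
  ((jday - .MAY1_CAL_DOY) %% 365L) + 1L
}

.SUPP_COLS <- c(sample_id = "Basename", animal_id = "AnimalID", age = "Age",
                doy = "Trap_jday", epigenetic_state = "Epigenetic_state",
                clock_age = "EC_predicted")
.GENERIC_COLS <- c(sample_id = "sample_id", animal_id = "animal_id", age = "age",
                   doy = "doy", epigenetic_state = "epigenetic_state",
                   clock_age = "clock_age")

#' Read a per-sample metadata table
#'
#' Two dialects are supported: `"supplementary_data_1"` with the study's
#' column names (`Basename`, `AnimalID`, `Age`, `Trap_jday`,
#' `Epigenetic_state`, `EC_predicted`) and `"generic"` with lowercase
#' canonical names (`sample_id`, `animal_id`, `age`, `doy`, ...). The day of
#' sample collection is converted to the study day-of-year at ingest; the
#' `doy_origin` switch states whether the file's day column counts from
#' 1 January (`"jan1"`, the usual Julian-date reading) or already uses the
#' 1 May study origin (`"may1"`).
#'
#' @param path Path to a CSV file.
#' @param dialect `"supplementary_data_1"` or `"generic"`.
#' @param doy_origin `"jan1"` or `"may1"`.
#' @return A `data.frame` with columns `sample_id`, `animal_id`, `age`,
#'   `doy`, and (when present in the file) `epigenetic_state`, `clock_age`,
#'   plus any extra columns carried through unchanged.
#' @export
read_sample_table <- function(path,
                              dialect = c("supplementary_data_1", "generic"),
                              doy_origin = c("jan1", "may1")) {
  dialect <- match.arg(dialect)
  doy_origin <- match.arg(doy_origin)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  map <- if (dialect == "supplementary_data_1") .SUPP_COLS else .GENERIC_COLS
  required <- map[c("sample_id", "animal_id", "age", "doy")]
  missing <- setdiff(required, names(raw))
  if (length(missing))
    stop("missing required column(s) for dialect '", dialect, "': ",
         paste(missing, collapse = ", "))
  out <- data.frame(sample_id = as.character(raw[[map[["sample_id"]]]]),
                    animal_id = as.character(raw[[map[["animal_id"]]]]),
                    age = suppressWarnings(as.numeric(raw[[map[["age"]]]])),
                    doy = suppressWarnings(as.integer(raw[[map[["doy"]]]])),
                    stringsAsFactors = FALSE)
  for (f in c("epigenetic_state", "clock_age"))
    if (map[[f]] %in% names(raw)) out[[f]] <- as.numeric(raw[[map[[f]]]])
  extra <- setdiff(names(raw), map)
  for (nm in extra) out[[nm]] <- raw[[nm]]
  if (nrow(out) == 0L) return(validate_sample_table(out))
  bad <- which(is.na(out$age) | out$age < 0 | is.na(out$doy) |
                 out$doy < 1L | out$doy > 365L)
  if (length(bad))
    stop("invalid age/doy in row(s): ", paste(bad, collapse = ", "))
  if (doy_origin == "jan1") out$doy <- julian_to_study_doy(out$doy)
  validate_sample_table(out)
}

#' Validate a sample table
#'
#' Checks the SampleTable invariants: unique sample ids, non-negative ages,
#' study days within 1..365.
#'
#' @param table A data.frame with at least `sample_id`, `animal_id`, `age`,
#'   `doy`.
#' @return The table, invisibly unchanged, for use in pipelines.
#' @export
validate_sample_table <- function(table) {
  need <- c("sample_id", "animal_id", "age", "doy")
  missing <- setdiff(need, names(table))
  if (length(missing))
    stop("sample table lacks column(s): ", paste(missing, collapse = ", "))
  if (nrow(table)) {
    if (anyDuplicated(table$sample_id))
      stop("duplicate sample_id(s): ",
           paste(unique(table$sample_id[duplicated(table$sample_id)]), collapse = ", "))
    if (any(table$age < 0)) stop("negative age(s) in row(s): ",
                                 paste(which(table$age < 0), collapse = ", "))
    if (any(table$doy < 1 | table$doy > 365))
      stop("doy outside 1..365 in row(s): ",
           paste(which(table$doy < 1 | table$doy > 365), collapse = ", "))
  }
  table
}

#' Write a sample table to CSV (generic dialect)
#'
#' @param table A sample table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(table, path) {
  validate_sample_table(table)
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a methylation beta matrix
#'
#' A light container: a numeric matrix of beta values in [0,1] with CpG
#' sites in rows and samples in columns, carrying site and sample ids as
#' dimnames.
#'
#' @param beta Numeric matrix (sites x samples), values in [0,1].
#' @param site_ids,sample_ids Character vectors; default to existing dimnames.
#' @return A validated matrix of class `beta_matrix`.
#' @export
beta_matrix <- function(beta, site_ids = rownames(beta), sample_ids = colnames(beta)) {
  beta <- as.matrix(beta)
  if (is.null(site_ids) || is.null(sample_ids))
    stop("site_ids and sample_ids are required")
  if (length(site_ids) != nrow(beta) || length(sample_ids) != ncol(beta))
    stop("id lengths inconsistent with matrix dimensions")
  if (anyDuplicated(site_ids)) stop("duplicate site ids")
  dimnames(beta) <- list(as.character(site_ids), as.character(sample_ids))
  bad <- which(is.na(beta) | beta < 0 | beta > 1, arr.ind = TRUE)
  if (nrow(bad))
    stop("beta value outside [0,1] at site ", rownames(beta)[bad[1, 1]],
         ", sample ", colnames(beta)[bad[1, 2]])
  class(beta) <- c("beta_matrix", class(beta))
  beta
}

#' Read a beta matrix from delimited text
#'
#' Expects a header row of sample ids and a first column of CpG site ids;
#' comma- or tab-separated (detected from the extension, override with
#' `sep`).
#'
#' @param path Path to a CSV/TSV file.
#' @param sep Field separator; default inferred (`"\\t"` for `.tsv`).
#' @return A `beta_matrix`.
#' @export
read_beta_matrix <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           stringsAsFactors = FALSE)
  m <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric beta values in ", path)
  beta_matrix(m, site_ids = raw[[1]], sample_ids = colnames(raw)[-1])
}

#' Write a beta matrix to delimited text
#'
#' @param beta A `beta_matrix`.
#' @param path Output path; `.tsv` extension selects tab separation.
#' @param digits Significant digits kept on write (default 10).
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(beta, path, digits = 10) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- data.frame(site_id = rownames(beta),
                   signif(unclass(beta), digits),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
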