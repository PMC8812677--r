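#' Validate a contact table against the registry schema
#'
#' Row-level validation: parseable ISO dates, documented enum values for
#' setting / mode / provider class / profession / source, and the
#' structural rule that telemedicine providers only make remote contacts.
#' Malformed rows are rejected (with row numbers and reasons), not fixed.
#'
#' @param dt data.frame/data.table with the columns of
#'   `person_id, date, setting, mode, provider_class, profession,
#'   diag1..diag8, source`.
#' @return List: `contacts` (valid rows, `date` typed as `IDate`, blank
#'   diagnoses as `""`) and `rejected` (data.table `row`, `reason`).
#' @export
validate_contacts <- function(dt) {
  dt <- as.data.table(dt)
  miss <- setdiff(CONTACT_SCHEMA_COLS, names(dt))
  if (length(miss)) {
    stop("contact table lacks required columns: ", paste(miss, collapse = ", "))
  }
  n <- nrow(dt)
  reasons <- rep("", n)
  add_reason <- function(bad, why) {
    reasons[bad] <<- fifelse(reasons[bad] == "", why,
                             paste(reasons[bad], why, sep = "; "))
  }
  d <- suppressWarnings(as.IDate(as.character(dt$date)))
  add_reason(is.na(d), "unparseable date")
  add_reason(!dt$setting %in% CONTACT_SETTINGS, "unknown setting")
  add_reason(!dt$mode %in% CONTACT_MODES, "unknown mode")
  add_reason(!dt$provider_class %in% PROVIDER_CLASSES, "unknown provider_class")
  add_reason(!dt$profession %in% PROFESSIONS, "unknown profession")
  add_reason(!dt$source %in% CONTACT_SOURCES, "unknown source")
  add_reason(dt$provider_class == "telemedicine" & dt$mode == "in_person",
             "telemedicine provider with in-person mode")
  bad <- reasons != ""
  out <- dt[!bad]
  out[, date := as.IDate(as.character(date))]
  for (cl in DIAG_COLS) {
    v <- out[[cl]]
    v[is.na(v)] <- ""
    set(out, NULL, cl, as.character(v))
  }
  list(contacts = out[],
       rejected = data.table(row = which(bad), reason = reasons[bad]))
}

#' Read a contact registry CSV
#'
#' Comma-delimited UTF-8 with the exact schema header; rows failing
#' validation are rejected, counted and reported (attribute `"rejected"`
#' on the returned table; a message summarises the counts).
#'
#' @param path CSV file path.
#' @return data.table of valid contacts with attribute `"rejected"`.
#' @export
read_contacts <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  hdr <- names(fread(path, nrows = 0L))
  miss <- setdiff(CONTACT_SCHEMA_COLS, hdr)
  if (length(miss)) {
    stop("contact table lacks required columns: ", paste(miss, collapse = ", "))
  }
  extra <- setdiff(hdr, c("contact_id", CONTACT_SCHEMA_COLS))
  if (length(extra)) {
    stop("unexpected columns in ", path, ": ", paste(extra, collapse = ", "))
  }
  dt <- fread(path, colClasses = list(character = c("date", DIAG_COLS)),
              na.strings = NULL)
  v <- validate_contacts(dt)
  if (nrow(v$rejected)) {
    message(nrow(v$rejected), " of ", nrow(dt),
            " rows rejected during validation of ", basename(path))
  }
  setattr(v$contacts, "rejected", v$rejected)
  v$contacts
}

#' Write a contact table as CSV (dates as ISO 8601 days)
#' @param contacts contact table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_contacts <- function(contacts, path) {
  dt <- as.data.table(contacts)
  dt <- copy(dt)
  dt[, date := format(as.Date(date))]
  fwrite(dt, path)
  invisible(path)
}

#' Read a population-denominator table
#'
#' @param path CSV with columns `year` and `population` (registered
#'   population at December 31 of the preceding year).
#' @return data.table.
#' @export
read_population <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- fread(path)
  if (!all(c("year", "population") %in% names(dt))) {
    stop("population table must have columns 'year' and 'population'")
  }
  if (any(dt$population <= 0)) stop("population must be positive")
  dt[]
}
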