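#' Study configuration
#'
#' Windows and periods that define episode construction: a contact is an
#' index contact only if the person had no RTI-relevant physician contact in
#' the preceding `washout_days`; any physician outpatient contact 1 to
#' `followup_days` days after an index is a follow-up of that index.
#' An RTI contact exactly `washout_days` earlier still blocks index status
#' ("at least 181 days" is read inclusively; `washout_days` is the
#' off-by-one knob).
#'
#' @param washout_days clean-period length in days (default 181).
#' @param followup_days follow-up attribution window in days (default 30).
#' @param index_periods named list of length-2 Date vectors; index contacts
#'   are turned into episodes only when dated inside one of these intervals.
#'   Defaults to January 1 - June 30 of 2018, 2019 and 2020.
#' @param code_set character vector of code-or-range entries (see
#'   [compile_code_set()]).
#' @return Object of class `study_config`.
#' @export
study_config <- function(washout_days = 181L,
                         followup_days = 30L,
                         index_periods = default_index_periods(),
                         code_set = rti_code_set()) {
  washout_days <- as.integer(washout_days)
  followup_days <- as.integer(followup_days)
  if (washout_days <= followup_days) {
    stop("washout_days must exceed followup_days")
  }
  if (is.null(names(index_periods)) || any(names(index_periods) == "")) {
    stop("index_periods must be a named list")
  }
  index_periods <- lapply(index_periods, function(p) {
    p <- as.Date(p)
    if (length(p) != 2L || any(is.na(p)) || p[1] > p[2]) {
      stop("each index period must be c(start, end) with start <= end")
    }
    p
  })
  ## periods must not overlap
  if (length(index_periods) > 1L) {
    ord <- order(vapply(index_periods, function(p) as.numeric(p[1]), 0))
    sorted <- index_periods[ord]
    for (i in seq_len(length(sorted) - 1L)) {
      if (sorted[[i]][2] >= sorted[[i + 1L]][1]) stop("index periods overlap")
    }
  }
  structure(list(washout_days = washout_days, followup_days = followup_days,
                 index_periods = index_periods, code_set = code_set),
            class = "study_config")
}

#' Default index periods: the first half-years of 2018, 2019 and 2020
#' @return Named list of Date pairs.
#' @export
default_index_periods <- function() {
  list(
    "2018H1" = as.Date(c("2018-01-01", "2018-06-30")),
    "2019H1" = as.Date(c("2019-01-01", "2019-06-30")),
    "2020H1" = as.Date(c("2020-01-01", "2020-06-30"))
  )
}

#' @export
print.study_config <- function(x, ...) {
  cat("<study_config> washout", x$washout_days, "d, follow-up window",
      x$followup_days, "d,", length(x$index_periods), "index periods\n")
  invisible(x)
}

#' Contact typology from modality and provider class
#'
#' Collapses modality and provider class into the three-way typology used
#' throughout: `telemedicine` for private on-demand providers (always
#' remote), `remote_traditional` for remote contacts with a primary-care
#' centre or emergency room, and `in_person` otherwise.  Primary-care and
#' emergency-room in-person visits deliberately share one label.
#'
#' @param mode character vector, `"in_person"` or `"remote"`.
#' @param provider_class character vector, `"traditional"` or `"telemedicine"`.
#' @return Character vector of typologies.
#' @export
contact_typology <- function(mode, provider_class) {
  fifelse(provider_class == "telemedicine", "telemedicine",
          fifelse(mode == "remote", "remote_traditional", "in_person"))
}

#' Deterministically sort a contact table
#'
#' Orders by person, date and, within a day, by setting, provider class,
#' source (in the documented enum orders) and original row order, so that
#' same-day ties are broken reproducibly.
#'
#' @param contacts contact table.
#' @return A sorted copy as data.table, with a `contact_id` column added
#'   (original row number) when absent.
#' @export
sort_contacts <- function(contacts) {
  dt <- as.data.table(contacts)
  if (!"contact_id" %in% names(dt)) dt[, contact_id := .I]
  dt[, `:=`(
    .set_rk = match(setting, CONTACT_SETTINGS),
    .pc_rk = match(provider_class, PROVIDER_CLASSES),
    .src_rk = match(source, CONTACT_SOURCES),
    .row0 = seq_len(.N)
  )]
  setorder(dt, person_id, date, .set_rk, .pc_rk, .src_rk, .row0)
  dt[, c(".set_rk", ".pc_rk", ".src_rk", ".row0") := NULL]
  dt[]
}

## running maximum that ignores NA (NA until the first non-missing value)
cummax_na <- function(x) {
  y <- cummax(fifelse(is.na(x), -Inf, as.numeric(x)))
  fifelse(is.infinite(y), NA_real_, y)
}

## last-observation-carried-forward (NA until the first non-missing value)
shift_locf <- function(x) {
  if (!length(x)) return(x)
  filled <- !is.na(x)
  idx <- cummax(fifelse(filled, seq_along(x), 0L))
  out <- x[pmax(idx, 1L)]
  out[idx == 0L] <- x[1][NA]
  out
}

#' Classify contacts as index, follow-up, limbo or other
#'
#' Implements the episode definitions on a whole contact table (any number
#' of persons).  Scanning each person's physician contacts in date order:
#'
#' * **index** - an outpatient (primary-care or emergency-room, including
#'   telemedicine) physician contact carrying an RTI-relevant diagnosis,
#'   with no RTI-relevant physician contact of the same person in the
#'   preceding `washout_days` days.  An earlier same-day RTI contact also
#'   blocks index status (an index is the *first* such contact).
#' * **follow_up** - a physician outpatient contact, regardless of
#'   diagnosis, dated 1 to `followup_days` days after an index of the same
#'   person.  Inpatient stays are never follow-ups.
#' * **limbo** - an RTI-relevant physician contact that is neither index
#'   nor follow-up (typically 31-181 days after the person's most recent
#'   RTI contact; also RTI-coded inpatient stays).  Limbo contacts appear
#'   in no tally but still reset the washout clock.
#' * **other** - everything else, including all non-physician contacts,
#'   which are ignored by the episode rules entirely.
#'
#' Every RTI-relevant physician contact - index, follow-up or limbo, in any
#' setting - resets the washout clock.
#'
#' @param contacts contact table, sorted by date within person (error
#'   otherwise; use [sort_contacts()] first).
#' @param config a [study_config()].
#' @param codeset optional pre-compiled code set; compiled from
#'   `config$code_set` when `NULL`.
#' @return data.table: the input plus columns `contact_id`, `typology`,
#'   `rti` (RTI-relevant physician contact), `label`
#'   (`index`/`follow_up`/`limbo`/`other`), `parent_index_id` (contact_id
#'   of the attributed index, follow-ups only) and `offset` (days after
#'   that index).
#' @export
classify_contacts <- function(contacts, config = study_config(),
                              codeset = NULL) {
  stopifnot(inherits(config, "study_config"))
  if (is.null(codeset)) codeset <- compile_code_set(config$code_set)
  dt <- as.data.table(contacts)
  req <- c("person_id", "date", "setting", "mode", "provider_class",
           "profession", "source")
  miss <- setdiff(req, names(dt))
  if (length(miss)) stop("contact table lacks columns: ",
                         paste(miss, collapse = ", "))
  dt <- copy(dt)
  dt[, date := as.IDate(date)]
  if (anyNA(dt$date)) stop("contact table contains unparseable dates")
  ## precondition: already date-sorted within person
  if (nrow(dt) > 1L) {
    bad <- dt[, if (.N > 1L) any(diff(as.integer(date)) < 0L) else FALSE,
              by = person_id][V1 == TRUE]
    if (nrow(bad)) {
      stop("contacts must be sorted ascending by date within person ",
           "(see sort_contacts()); violated for person_id ",
           bad$person_id[1])
    }
  }
  dt <- sort_contacts(dt)
  if (anyDuplicated(dt$contact_id)) stop("contact_id values must be unique")

  dt[, `:=`(
    physician = profession == "physician",
    day = as.integer(date)
  )]
  dt[, rti := rti_flags(dt, codeset) & physician]
  dt[, outpatient := physician & setting != "inpatient"]
  dt[, typology := fifelse(outpatient,
                           contact_typology(mode, provider_class),
                           NA_character_)]

  ## washout clock: day of most recent strictly-earlier-sorted RTI contact
  dt[, prev_rti_day := shift(cummax_na(fifelse(rti, as.numeric(day), NA_real_))),
     by = person_id]
  dt[, blocked := !is.na(prev_rti_day) &
       (day - prev_rti_day) <= config$washout_days]
  dt[, label := "other"]
  dt[rti & outpatient & !blocked, label := "index"]

  ## follow-up: 1..followup_days after the person's most recent index
  dt[, `:=`(prev_idx_day = NA_integer_, prev_idx_id = NA_integer_)]
  dt[, prev_idx_day := {
    v <- fifelse(label == "index", day, NA_integer_)
    as.integer(shift_locf(shift(v)))
  }, by = person_id]
  dt[, prev_idx_id := {
    v <- fifelse(label == "index", as.integer(contact_id), NA_integer_)
    as.integer(shift_locf(shift(v)))
  }, by = person_id]
  dt[, off := day - prev_idx_day]
  dt[, `:=`(parent_index_id = NA_integer_, offset = NA_integer_)]
  dt[outpatient & label != "index" & !is.na(off) & off >= 1L &
       off <= config$followup_days,
     `:=`(label = "follow_up", parent_index_id = prev_idx_id,
          offset = as.integer(off))]
  dt[rti & label == "other", label := "limbo"]

  ## indexes of one person must be further apart than the follow-up window,
  ## so follow-up attribution is unique by construction
  gaps <- dt[label == "index", diff(day), by = person_id]
  if (nrow(gaps) && any(gaps$V1 <= config$followup_days)) {
    stop("internal error: two indexes of one person within the follow-up window")
  }

  dt[, c("physician", "day", "prev_rti_day", "blocked", "prev_idx_day",
         "prev_idx_id", "off") := NULL]
  dt[]
}

#' Assemble episodes from labeled contacts
#'
#' One episode per index contact dated inside a configured index period;
#' its follow-ups are attached even when dated after the period end (the
#' data window extends past the last period).  Indexes outside all periods
#' produce no episode but have already influenced the washout in
#' [classify_contacts()].
#'
#' @param labeled output of [classify_contacts()].
#' @param config a [study_config()].
#' @return Object of class `rti_episodes`: list with data.tables
#'   `episodes` (`episode_id`, `person_id`, `contact_id`, `date`, `year`,
#'   `month`, `index_type`, `period`) and `followups` (`episode_id`,
#'   `contact_id`, `date`, `offset`, `fu_type`), plus the `config`.
#' @export
build_episodes <- function(labeled, config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  dt <- as.data.table(labeled)
  if (!all(c("label", "typology", "contact_id") %in% names(dt))) {
    stop("build_episodes() expects the output of classify_contacts()")
  }
  idx <- dt[label == "index",
            .(contact_id, person_id, date = as.IDate(date),
              index_type = typology)]
  idx[, period := NA_character_]
  for (nm in names(config$index_periods)) {
    p <- config$index_periods[[nm]]
    idx[date >= p[1] & date <= p[2], period := nm]
  }
  idx <- idx[!is.na(period)]
  setorder(idx, person_id, date)
  idx[, episode_id := .I]
  idx[, `:=`(year = as.integer(format(date, "%Y")),
             month = as.integer(format(date, "%m")))]
  setcolorder(idx, c("episode_id", "person_id", "contact_id", "date",
                     "year", "month", "index_type", "period"))

  fu <- dt[label == "follow_up",
           .(contact_id, parent_index_id, date = as.IDate(date),
             offset, fu_type = typology)]
  fu <- idx[, .(episode_id, parent_index_id = contact_id)][
    fu, on = "parent_index_id", nomatch = NULL]
  fu[, parent_index_id := NULL]
  setorder(fu, episode_id, date, contact_id)
  setcolorder(fu, c("episode_id", "contact_id", "date", "offset", "fu_type"))

  structure(list(episodes = idx[], followups = fu[], config = config),
            class = "rti_episodes")
}

#' @export
print.rti_episodes <- function(x, ...) {
  cat("<rti_episodes>", nrow(x$episodes), "episodes,",
      nrow(x$followups), "follow-up contacts across",
      length(unique(x$episodes$period)), "period(s)\n")
  invisible(x)
}

#' Unique patients hospitalized with an RTI-relevant diagnosis
#'
#' Counts distinct persons having at least one inpatient record with an
#' RTI-relevant diagnosis dated inside the period; each patient counts once
#' per period however many stays they have.  This is the numerator of the
#' hospitalizations-per-1000 rate.
#'
#' @param contacts contact table.
#' @param codeset compiled code set.
#' @param period length-2 Date vector `c(start, end)`.
#' @return Integer count of unique patients.
#' @export
count_hospitalized_patients <- function(contacts, codeset, period) {
  dt <- as.data.table(contacts)
  period <- as.Date(period)
  stopifnot(length(period) == 2L, !anyNA(period))
  if (nrow(dt) == 0L) return(0L)
  dt <- dt[setting == "inpatient"]
  if (nrow(dt) == 0L) return(0L)
  dt[, date := as.IDate(date)]
  dt <- dt[date >= period[1] & date <= period[2]]
  if (nrow(dt) == 0L) return(0L)
  uniqueN(dt[rti_flags(dt, codeset), person_id])
}
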