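#' Events per 1000 inhabitants
#'
#' `1000 * count / population`, displayed with half-up rounding to two
#' decimals (the registry-table convention).
#'
#' @param count event count (vectorized).
#' @param population registered population at December 31 of the preceding
#'   year; must be positive.
#' @param digits decimals for display rounding (`NULL` for the raw rate).
#' @return Numeric rate per 1000.
#' @examples
#' per_1000(107330, 1344685)  # 79.82
#' @export
per_1000 <- function(count, population, digits = 2) {
  if (any(population <= 0)) stop("population must be positive")
  if (any(count < 0)) stop("count must be non-negative")
  r <- 1000 * count / population
  if (is.null(digits)) r else round_half_up(r, digits)
}

#' Follow-up contacts per index contact
#'
#' @param followup_total number of follow-up contacts.
#' @param index_total number of index contacts; must be positive (the ratio
#'   is undefined at zero indexes and an error is raised rather than
#'   returning 0).
#' @param digits decimals for display rounding (`NULL` for the raw ratio).
#' @return Numeric ratio.
#' @examples
#' followups_per_index(57253, 87125)  # 0.66
#' @export
followups_per_index <- function(followup_total, index_total, digits = 2) {
  if (any(index_total <= 0)) {
    stop("followups_per_index is undefined with zero index contacts")
  }
  r <- followup_total / index_total
  if (is.null(digits)) r else round_half_up(r, digits)
}

share_of <- function(n, total) if (total > 0) n / total else NA_real_

#' Summarize one index period
#'
#' Produces the period-level aggregate: index and follow-up totals, rates
#' per 1000 inhabitants, modality shares for both contact roles, the
#' follow-ups-per-index ratio and (when supplied) unique hospitalized
#' patients per 1000.  Rounded display values are accompanied by `_raw`
#' columns carrying the unrounded quantities.  The combined remote share
#' is the sum of the two rounded remote shares, matching how such tables
#' are read.
#'
#' @param es an [rti_episodes][build_episodes()] object.
#' @param period period name (must exist in `es$config$index_periods`).
#' @param population denominator for the period's study year.
#' @param hospitalized unique hospitalized patient count (optional).
#' @return One-row data.table.
#' @export
summarize_period <- function(es, period, population, hospitalized = NA_integer_) {
  stopifnot(inherits(es, "rti_episodes"))
  if (!period %in% names(es$config$index_periods)) {
    stop("unknown period '", period, "'")
  }
  ep <- es$episodes[es$episodes$period == period]
  fu <- es$followups[ep[, .(episode_id)], on = "episode_id", nomatch = NULL]
  n_idx <- nrow(ep)
  n_fu <- nrow(fu)
  if (n_idx == 0L) {
    warning("period '", period, "' contains no episodes; shares undefined")
  }
  types <- contact_types()
  idx_by <- vapply(types, function(t) sum(ep$index_type == t), 0L)
  fu_by <- vapply(types, function(t) sum(fu$fu_type == t), 0L)
  s_idx <- vapply(idx_by, share_of, 0, total = n_idx)
  s_fu <- vapply(fu_by, share_of, 0, total = n_fu)
  out <- data.table(
    period = period,
    population = population,
    index_total = n_idx,
    index_per_1000 = per_1000(n_idx, population),
    index_per_1000_raw = per_1000(n_idx, population, digits = NULL),
    share_in_person = round_half_up(s_idx[["in_person"]]),
    share_remote_traditional = round_half_up(s_idx[["remote_traditional"]]),
    share_telemedicine = round_half_up(s_idx[["telemedicine"]]),
    share_in_person_raw = s_idx[["in_person"]],
    share_remote_traditional_raw = s_idx[["remote_traditional"]],
    share_telemedicine_raw = s_idx[["telemedicine"]],
    followup_total = n_fu,
    followup_per_1000 = per_1000(n_fu, population),
    followup_per_1000_raw = per_1000(n_fu, population, digits = NULL),
    fu_share_in_person = round_half_up(s_fu[["in_person"]]),
    fu_share_remote_traditional = round_half_up(s_fu[["remote_traditional"]]),
    fu_share_telemedicine = round_half_up(s_fu[["telemedicine"]]),
    followups_per_index =
      if (n_idx > 0) followups_per_index(n_fu, n_idx) else NA_real_,
    followups_per_index_raw =
      if (n_idx > 0) followups_per_index(n_fu, n_idx, digits = NULL) else NA_real_,
    hospitalized_patients = as.integer(hospitalized),
    hospitalized_per_1000 =
      if (is.na(hospitalized)) NA_real_ else per_1000(hospitalized, population)
  )
  out[, share_remote_combined :=
        round_half_up(share_remote_traditional + share_telemedicine)]
  out[]
}

#' Period summary table across all configured periods
#'
#' Convenience wrapper over [summarize_period()]: one row per configured
#' period that has episodes or population data, with hospitalized-patient
#' counts computed from the raw contact table when it is supplied.
#'
#' @param es an [rti_episodes][build_episodes()] object.
#' @param populations data.frame with columns `year` and `population`; the
#'   year of a period is the year of its start date.
#' @param contacts optional raw contact table for hospitalization counts.
#' @param codeset optional compiled code set (compiled from the config
#'   when `NULL`).
#' @return data.table, one row per period.
#' @export
period_summary_table <- function(es, populations, contacts = NULL,
                                 codeset = NULL) {
  stopifnot(inherits(es, "rti_episodes"))
  popdt <- as.data.table(populations)
  stopifnot(all(c("year", "population") %in% names(popdt)))
  if (is.null(codeset)) codeset <- compile_code_set(es$config$code_set)
  rows <- list()
  for (nm in names(es$config$index_periods)) {
    p <- es$config$index_periods[[nm]]
    yr <- as.integer(format(p[1], "%Y"))
    popn <- popdt[year == yr, population]
    if (!length(popn)) next
    hosp <- if (!is.null(contacts)) {
      count_hospitalized_patients(contacts, codeset, p)
    } else NA_integer_
    has_ep <- nrow(es$episodes[period == nm]) > 0L
    if (!has_ep && nrow(es$episodes) > 0L &&
        !any(es$episodes$year == yr)) next
    rows[[nm]] <- suppressWarnings(
      summarize_period(es, nm, popn[1], hosp))
  }
  rbindlist(rows)
}

#' Follow-ups per index decomposed by contact typology
#'
#' Cell (i, j) is the number of follow-up contacts of typology j attached
#' to index contacts of typology i, divided by the number of indexes of
#' typology i.  The `all` index row pools all indexes; the `all` follow-up
#' column sums the three typology cells.  Typologies with zero indexes
#' yield `NA` cells with a warning rather than being dropped.
#'
#' @param es an [rti_episodes][build_episodes()] object.
#' @param period optional period name to restrict to (default: all
#'   episodes pooled).
#' @return data.table in long format: `index_type` (incl. `"all"`),
#'   `followup_type` (incl. `"all"`), `n_index`, `n_followups`,
#'   `per_index_raw`, `per_index` (half-up, 2 decimals).
#' @export
followup_matrix <- function(es, period = NULL) {
  stopifnot(inherits(es, "rti_episodes"))
  ep <- es$episodes
  if (!is.null(period)) ep <- ep[ep$period == period]
  fu <- es$followups[ep[, .(episode_id, index_type)], on = "episode_id",
                     nomatch = NULL]
  types <- contact_types()
  grid <- CJ(index_type = c("all", types), followup_type = c("all", types))
  idx_counts <- c(
    all = nrow(ep),
    vapply(types, function(t) sum(ep$index_type == t), 0L)
  )
  count_fu <- function(it, jt) {
    sel <- if (it == "all") rep(TRUE, nrow(fu)) else fu$index_type == it
    if (jt != "all") sel <- sel & fu$fu_type == jt
    sum(sel)
  }
  grid[, n_index := idx_counts[index_type]]
  grid[, n_followups := mapply(count_fu, index_type, followup_type)]
  grid[, per_index_raw := fifelse(n_index > 0, n_followups / n_index, NA_real_)]
  grid[, per_index := round_half_up(per_index_raw)]
  if (any(grid$n_index == 0L)) {
    warning("typologies with zero index contacts: ",
            paste(unique(grid[n_index == 0L, index_type]), collapse = ", "),
            " (cells undefined)")
  }
  setorder(grid, index_type, followup_type)
  grid[]
}

#' Monthly trend series
#'
#' Per calendar month of the index periods: index contacts per 1000, the
#' remote share of index contacts, per-1000 index rates split by typology,
#' follow-up contacts (attributed to their index's month) per 1000 and per
#' index, and follow-up modality shares.  These are the plottable series
#' behind the usual trend figures.
#'
#' @param es an [rti_episodes][build_episodes()] object.
#' @param populations data.frame with `year`, `population`.
#' @return data.table keyed by (`year`, `month`).
#' @export
monthly_series <- function(es, populations) {
  stopifnot(inherits(es, "rti_episodes"))
  popdt <- as.data.table(populations)
  ep <- copy(es$episodes)
  if (nrow(ep) == 0L) {
    return(data.table(year = integer(), month = integer()))
  }
  fu <- es$followups[ep[, .(episode_id, year, month)], on = "episode_id",
                     nomatch = NULL]
  em <- ep[, .(
    n_index = .N,
    n_in_person = sum(index_type == "in_person"),
    n_remote_traditional = sum(index_type == "remote_traditional"),
    n_telemedicine = sum(index_type == "telemedicine")
  ), by = .(year, month)]
  fm <- fu[, .(
    n_followups = .N,
    n_fu_in_person = sum(fu_type == "in_person"),
    n_fu_remote_traditional = sum(fu_type == "remote_traditional"),
    n_fu_telemedicine = sum(fu_type == "telemedicine")
  ), by = .(year, month)]
  out <- fm[em, on = c("year", "month")]
  for (cl in names(out)) set(out, which(is.na(out[[cl]])), cl, 0L)
  out <- popdt[, .(year = as.integer(year), population)][out, on = "year"]
  if (anyNA(out$population)) {
    stop("population table lacks year(s): ",
         paste(unique(out[is.na(population), year]), collapse = ", "))
  }
  out[, `:=`(
    index_per_1000 = per_1000(n_index, population),
    share_remote = fifelse(
      n_index > 0,
      round_half_up((n_remote_traditional + n_telemedicine) / n_index),
      NA_real_),
    in_person_per_1000 = per_1000(n_in_person, population),
    remote_traditional_per_1000 = per_1000(n_remote_traditional, population),
    telemedicine_per_1000 = per_1000(n_telemedicine, population),
    followup_per_1000 = per_1000(n_followups, population),
    followups_per_index = fifelse(n_index > 0,
                                  round_half_up(n_followups / n_index),
                                  NA_real_),
    fu_share_in_person = fifelse(n_followups > 0,
                                 round_half_up(n_fu_in_person / n_followups),
                                 NA_real_),
    fu_share_remote_traditional =
      fifelse(n_followups > 0,
              round_half_up(n_fu_remote_traditional / n_followups), NA_real_),
    fu_share_telemedicine =
      fifelse(n_followups > 0,
              round_half_up(n_fu_telemedicine / n_followups), NA_real_)
  )]
  setorder(out, year, month)
  out[]
}
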