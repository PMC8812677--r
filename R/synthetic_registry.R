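## Diagnosis pools used by the generator.  RTI pools contain only codes
## inside the default code set (see rti_code_set()); the background pool
## contains deliberate near-misses (B34.9, R06.1, J30.9) so specificity of
## the matcher is exercised by every simulated registry.
RTI_DX_POOL <- c("J00", "J019", "J029", "J039", "J069", "J060", "J101",
                 "J111", "J129", "J159", "J189", "J209", "J22", "R05",
                 "R060", "R509", "B342", "B99", "H650", "H660", "H662")
COVID_DX_POOL <- c("U071", "U072", "ZV100", "B342")
BACKGROUND_DX_POOL <- c("Z000", "Z029", "I109", "E119", "M545", "K590",
                        "F419", "N390", "L309", "B349", "R061", "J309")

## structural window constants shared with study_config() defaults: the
## generator schedules consecutive true indexes of a person at least
## washout + follow-up window + 1 days apart, so every RTI-coded contact of
## an episode lies strictly outside the next index's clean period.
GEN_WASHOUT_DAYS <- 181L
GEN_FOLLOWUP_DAYS <- 30L
GEN_MIN_INDEX_GAP <- GEN_WASHOUT_DAYS + GEN_FOLLOWUP_DAYS + 1L

#' Build a monthly incidence schedule
#'
#' @param year,month integer vectors (recycled to common length).
#' @param incidence expected new RTI episodes per 1000 persons per month.
#' @return data.table with columns `year`, `month`, `incidence`.
#' @export
monthly_incidence <- function(year, month, incidence) {
  dt <- data.table(year = as.integer(year), month = as.integer(month),
                   incidence = as.numeric(incidence))
  if (anyNA(dt)) stop("incidence schedule contains missing values")
  if (anyDuplicated(dt[, .(year, month)])) {
    stop("duplicate (year, month) in incidence schedule")
  }
  dt[]
}

#' Simulation parameters for the synthetic contact registry
#'
#' Full parameterization of the generator.  Episode arrivals are
#' per-person Bernoulli draws per calendar month with probability
#' `incidence/1000`, thinned so that consecutive true indexes of one person
#' are at least 212 days apart (181-day clean period plus the 30-day
#' follow-up window); follow-up counts per (index type, follow-up type)
#' cell are Poisson with the configured mean and dates uniform on days
#' 1-30 after the index; background (non-RTI) physician contacts arrive as
#' a Poisson stream and are rejection-sampled out of follow-up windows so
#' the configured intensities are exactly what an ideal pipeline recovers.
#'
#' @param population_size number of persons at risk.
#' @param calendar_window length-2 Dates, first/last contact date
#'   (default 2017-08-01 to 2020-07-31).
#' @param monthly_rti_incidence [monthly_incidence()] table; months of the
#'   window absent from the table have rate 0.
#' @param index_mode_mix named list of probability vectors over
#'   [contact_types()], one per regime (`prepandemic`, and optionally
#'   `pandemic`); each must sum to 1.
#' @param pandemic_start Date from which the `pandemic` regime applies
#'   (by calendar month; default 2020-03-01).
#' @param followup_intensity 3x3 numeric matrix of expected follow-up
#'   contacts per index within 30 days, rows = index type, columns =
#'   follow-up type (both in [contact_types()] order).
#' @param background_contact_rate expected non-RTI physician contacts per
#'   person-month (default 0.15).
#' @param missing_diagnosis_prob 2x2 matrix, rows = provider class
#'   (`traditional`, `telemedicine`), columns = mode (`in_person`,
#'   `remote`): probability that a truly RTI-relevant contact has all its
#'   registered diagnoses removed.  Default all zero.
#' @param hospitalization_prob probability that an episode includes an
#'   RTI-coded inpatient stay (default 0.06).
#' @param followup_rti_dx_prob probability that a follow-up contact carries
#'   an RTI-relevant diagnosis (default 0.5; follow-ups are attributed
#'   regardless of diagnosis, and physicians frequently leave the diagnosis
#'   unregistered at a return visit).
#' @param seed integer RNG seed (mandatory; generation is bit-reproducible
#'   given the seed).
#' @return Object of class `sim_params`.
#' @export
sim_params <- function(population_size,
                       calendar_window = as.Date(c("2017-08-01", "2020-07-31")),
                       monthly_rti_incidence,
                       index_mode_mix,
                       pandemic_start = as.Date("2020-03-01"),
                       followup_intensity,
                       background_contact_rate = 0.15,
                       missing_diagnosis_prob = NULL,
                       hospitalization_prob = 0.06,
                       followup_rti_dx_prob = 0.5,
                       seed) {
  if (missing(seed)) stop("seed is mandatory")
  population_size <- as.integer(population_size)
  stopifnot(population_size > 0L)
  calendar_window <- as.Date(calendar_window)
  stopifnot(length(calendar_window) == 2L, !anyNA(calendar_window),
            calendar_window[1] <= calendar_window[2])
  stopifnot(is.data.frame(monthly_rti_incidence))
  inc <- as.data.table(monthly_rti_incidence)
  if (any(inc$incidence < 0)) stop("incidence rates must be non-negative")
  if (any(inc$incidence > 1000)) {
    stop("infeasible schedule: monthly incidence above 1000/1000 persons")
  }
  types <- contact_types()
  if (!is.list(index_mode_mix) || is.null(names(index_mode_mix))) {
    stop("index_mode_mix must be a named list of probability vectors")
  }
  for (nm in names(index_mode_mix)) {
    v <- index_mode_mix[[nm]]
    if (!all(types %in% names(v))) {
      stop("mode mix '", nm, "' must name all of: ", paste(types, collapse = ", "))
    }
    v <- v[types]
    if (any(v < 0) || abs(sum(v) - 1) > 1e-9) {
      stop("mode mix '", nm, "' must be non-negative and sum to 1")
    }
    index_mode_mix[[nm]] <- v
  }
  if (!"prepandemic" %in% names(index_mode_mix)) {
    stop("index_mode_mix must contain at least a 'prepandemic' entry")
  }
  fi <- as.matrix(followup_intensity)
  if (!all(dim(fi) == c(3L, 3L)) ||
      !identical(rownames(fi), types) || !identical(colnames(fi), types)) {
    stop("followup_intensity must be a 3x3 matrix with contact_types() dimnames")
  }
  if (any(fi < 0)) stop("follow-up intensities must be non-negative")
  if (is.null(missing_diagnosis_prob)) {
    missing_diagnosis_prob <- matrix(0, 2, 2,
                                     dimnames = list(PROVIDER_CLASSES, CONTACT_MODES))
  }
  mp <- as.matrix(missing_diagnosis_prob)
  if (!all(dim(mp) == c(2L, 2L)) ||
      !identical(rownames(mp), PROVIDER_CLASSES) ||
      !identical(colnames(mp), CONTACT_MODES)) {
    stop("missing_diagnosis_prob must be a 2x2 matrix (provider class x mode)")
  }
  probs <- c(mp, hospitalization_prob, followup_rti_dx_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  stopifnot(background_contact_rate >= 0)
  structure(list(
    population_size = population_size,
    calendar_window = calendar_window,
    monthly_rti_incidence = inc,
    index_mode_mix = index_mode_mix,
    pandemic_start = as.Date(pandemic_start),
    followup_intensity = fi,
    background_contact_rate = background_contact_rate,
    missing_diagnosis_prob = mp,
    hospitalization_prob = hospitalization_prob,
    followup_rti_dx_prob = followup_rti_dx_prob,
    seed = as.integer(seed)
  ), class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params>", x$population_size, "persons,",
      format(x$calendar_window[1]), "to", format(x$calendar_window[2]),
      "| seed", x$seed, "\n")
  invisible(x)
}

#' Presets emulating the published study conditions
#'
#' Documented parameter presets for the two study regimes.  Both scale to
#' any population size; rates and mixes are fixed:
#'
#' * `prepandemic` (calendar window Aug 2017 - Jul 2018): seasonal RTI
#'   incidence peaking in February with a January-June total of about
#'   80 episodes per 1000, mode mix 0.92/0.04/0.04
#'   (in-person / remote-traditional / telemedicine), follow-up
#'   intensities with row totals 0.48 / 0.73 / 0.49 per index.
#' * `pandemic` (Aug 2019 - Jul 2020): incidence peaking in March 2020 and
#'   then dropping below seasonal norms (January-June total about 63 per
#'   1000), mode mix shifting from 0.92/0.04/0.04 to 0.605/0.25/0.145 from
#'   March 2020 (so the half-year averages are 0.74/0.16/0.10), follow-up
#'   intensity row totals 0.60 / 0.90 / 0.69, and COVID-19 codes in the
#'   diagnosis pool.
#'
#' Both presets leave diagnosis missingness at zero: their target rates
#' describe the *registered* contact process, so no additional masking is
#' applied (missingness is a sensitivity knob, not part of the presets).
#'
#' @param scenario `"prepandemic"` or `"pandemic"`.
#' @param population_size persons at risk (default 100000).
#' @param seed RNG seed (default 1).
#' @return A [sim_params()] object.
#' @export
paper_like_params <- function(scenario = c("prepandemic", "pandemic"),
                              population_size = 100000, seed = 1L) {
  scenario <- match.arg(scenario)
  types <- contact_types()
  autumn <- c(5, 7, 9, 10, 12) # Aug..Dec, both lead-in years
  if (scenario == "prepandemic") {
    inc <- monthly_incidence(
      year = c(rep(2017L, 5), rep(2018L, 7)),
      month = c(8:12, 1:7),
      incidence = c(autumn, 15, 19, 16, 12, 10, 8, 4)
    )
    mix <- list(prepandemic = c(in_person = 0.92, remote_traditional = 0.04,
                                telemedicine = 0.04))
    fi <- rbind(
      in_person = c(0.30, 0.16, 0.01) * (0.48 / 0.47),
      remote_traditional = c(0.37, 0.35, 0.01),
      telemedicine = c(0.30, 0.05, 0.13) * (0.49 / 0.48)
    )
    window <- as.Date(c("2017-08-01", "2018-07-31"))
    hosp <- 0.06
  } else {
    inc <- monthly_incidence(
      year = c(rep(2019L, 5), rep(2020L, 7)),
      month = c(8:12, 1:7),
      incidence = c(autumn, 13, 14, 16, 9, 6.3, 5, 3)
    )
    mix <- list(
      prepandemic = c(in_person = 0.92, remote_traditional = 0.04,
                      telemedicine = 0.04),
      pandemic = c(in_person = 0.605, remote_traditional = 0.25,
                   telemedicine = 0.145)
    )
    fi <- rbind(
      in_person = c(0.30, 0.27, 0.02) * (0.60 / 0.59),
      remote_traditional = c(0.29, 0.58, 0.02) * (0.90 / 0.89),
      telemedicine = c(0.28, 0.14, 0.26) * (0.69 / 0.68)
    )
    window <- as.Date(c("2019-08-01", "2020-07-31"))
    hosp <- 0.08
  }
  colnames(fi) <- types
  rownames(fi) <- types
  sim_params(
    population_size = population_size,
    calendar_window = window,
    monthly_rti_incidence = inc,
    index_mode_mix = mix,
    pandemic_start = as.Date("2020-03-01"),
    followup_intensity = fi,
    background_contact_rate = 0.15,
    hospitalization_prob = hosp,
    followup_rti_dx_prob = 0.5,
    seed = seed
  )
}

## regime of a contact date under the params
regime_of <- function(date, params) {
  if ("pandemic" %in% names(params$index_mode_mix)) {
    fifelse(as.Date(format(as.Date(date), "%Y-%m-01")) >= params$pandemic_start,
            "pandemic", "prepandemic")
  } else {
    rep("prepandemic", length(date))
  }
}

## draw one typology per row given regime labels
draw_types <- function(regime, params) {
  types <- contact_types()
  out <- character(length(regime))
  for (rg in unique(regime)) {
    i <- which(regime == rg)
    out[i] <- sample(types, length(i), replace = TRUE,
                     prob = params$index_mode_mix[[rg]])
  }
  out
}

## diagnosis pool draw; pandemic regime mixes in COVID codes
draw_rti_dx <- function(regime) {
  n <- length(regime)
  dx <- sample(RTI_DX_POOL, n, replace = TRUE)
  pand <- regime == "pandemic"
  if (any(pand)) {
    swap <- pand & runif(n) < 0.35
    dx[swap] <- sample(COVID_DX_POOL, sum(swap), replace = TRUE)
  }
  dx
}

## typology -> schema fields (setting drawn for in-person contacts)
typology_fields <- function(type) {
  n <- length(type)
  setting <- rep("primary_care", n)
  ip <- type == "in_person"
  if (any(ip)) {
    setting[ip] <- sample(c("primary_care", "emergency_room"), sum(ip),
                          replace = TRUE, prob = c(0.85, 0.15))
  }
  list(
    setting = setting,
    mode = fifelse(type == "in_person", "in_person", "remote"),
    provider_class = fifelse(type == "telemedicine", "telemedicine",
                             "traditional"),
    source = fifelse(type == "telemedicine", "telemedicine_register",
                     "regional")
  )
}

empty_contact_block <- function() {
  dt <- data.table(person_id = integer(), date = as.IDate(character()),
                   setting = character(), mode = character(),
                   provider_class = character(), profession = character(),
                   source = character(),
                   true_role = character(), episode_id = integer(),
                   dx1 = character(), dx2 = character())
  dt
}

#' Simulate a synthetic contact registry
#'
#' Generates a contact table (the same schema the pipeline consumes), a
#' population-denominator table, and a ground-truth table keyed by contact
#' id.  See [sim_params()] for the generating model.  Ground truth is
#' assigned before diagnosis masking, so misclassification caused by
#' unregistered diagnoses can be quantified against it.
#'
#' @param params a [sim_params()] object.
#' @return List with class `rti_simulation`: `contacts` (data.table in the
#'   contact schema plus `contact_id`), `population` (`year`,
#'   `population`), `truth` (`contact_id`, `person_id`, `true_role` in
#'   index / follow_up / hospitalization / background, `parent_index_id`,
#'   `episode_id`), and `params`.
#' @export
simulate_registry <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  pop <- params$population_size
  win <- params$calendar_window
  months <- month_seq(win[1], win[2])
  inc <- params$monthly_rti_incidence

  ## --- candidate index events: Bernoulli per person-month -----------------
  cand_list <- vector("list", length(months))
  for (k in seq_along(months)) {
    m0 <- months[k]
    yr <- as.integer(format(m0, "%Y"))
    mo <- as.integer(format(m0, "%m"))
    rate <- inc[year == yr & month == mo, incidence]
    p <- if (length(rate)) rate[1] / 1000 else 0
    if (p <= 0) next
    hit <- which(runif(pop) < p)
    if (!length(hit)) next
    lo <- max(as.integer(m0), as.integer(win[1]))
    hi <- min(as.integer(m0) + days_in_month(m0) - 1L, as.integer(win[2]))
    cand_list[[k]] <- data.table(
      person_id = hit,
      date = as.IDate(lo + sample(0:(hi - lo), length(hit), replace = TRUE))
    )
  }
  cand <- rbindlist(cand_list)

  ## --- thin candidates to respect the clean period ------------------------
  if (nrow(cand)) {
    setorder(cand, person_id, date)
    cand[, keep := TRUE]
    multi <- cand[, .N, by = person_id][N > 1L, person_id]
    if (length(multi)) {
      greedy <- function(d) {
        keep <- logical(length(d))
        last <- -Inf
        for (i in seq_along(d)) {
          if (d[i] - last >= GEN_MIN_INDEX_GAP) {
            keep[i] <- TRUE
            last <- d[i]
          }
        }
        keep
      }
      cand[person_id %in% multi, keep := greedy(as.integer(date)),
           by = person_id]
    }
    idx <- cand[keep == TRUE][, keep := NULL]
  } else {
    idx <- data.table(person_id = integer(), date = as.IDate(character()))
  }

  ## --- index attributes ----------------------------------------------------
  n_idx <- nrow(idx)
  if (n_idx) {
    idx[, episode_id := seq_len(.N)]
    idx[, regime := regime_of(date, params)]
    idx[, type := draw_types(regime, params)]
    tf <- typology_fields(idx$type)
    idx[, `:=`(setting = tf$setting, mode = tf$mode,
               provider_class = tf$provider_class, source = tf$source,
               profession = "physician", true_role = "index")]
    idx[, dx1 := draw_rti_dx(regime)]
    idx[, dx2 := fifelse(runif(.N) < 0.3, draw_rti_dx(regime), "")]
  } else {
    idx[, `:=`(episode_id = integer(), regime = character(),
               type = character(), setting = character(), mode = character(),
               provider_class = character(), source = character(),
               profession = character(), true_role = character(),
               dx1 = character(), dx2 = character())]
  }

  ## --- follow-up contacts: Poisson counts per (index type, fu type) -------
  fu_blocks <- list()
  if (n_idx) {
    types <- contact_types()
    for (j in types) {
      lambda <- params$followup_intensity[idx$type, j]
      nfu <- rpois(n_idx, lambda)
      tot <- sum(nfu)
      if (!tot) next
      src <- rep(seq_len(n_idx), nfu)
      off <- sample(seq_len(GEN_FOLLOWUP_DAYS), tot, replace = TRUE)
      blk <- data.table(
        person_id = idx$person_id[src],
        episode_id = idx$episode_id[src],
        date = idx$date[src] + off,
        type = j
      )
      blk <- blk[date <= win[2]]
      if (!nrow(blk)) next
      tfb <- typology_fields(blk$type)
      blk[, `:=`(setting = tfb$setting, mode = tfb$mode,
                 provider_class = tfb$provider_class, source = tfb$source,
                 profession = "physician", true_role = "follow_up")]
      blk[, regime := regime_of(date, params)]
      u <- runif(nrow(blk))
      p <- params$followup_rti_dx_prob
      blk[, dx1 := ""]
      rti_rows <- which(u < p)
      blk[rti_rows, dx1 := draw_rti_dx(regime)]
      non <- which(u >= p & u < p + (1 - p) * 0.5)
      blk[non, dx1 := sample(BACKGROUND_DX_POOL, length(non), replace = TRUE)]
      blk[, dx2 := ""]
      blk[, c("regime", "type") := NULL]
      fu_blocks[[j]] <- blk
    }
  }
  fu <- if (length(fu_blocks)) rbindlist(fu_blocks, use.names = TRUE) else
    empty_contact_block()

  ## --- hospitalizations -----------------------------------------------------
  if (n_idx) {
    hosp_i <- which(runif(n_idx) < params$hospitalization_prob)
  } else {
    hosp_i <- integer()
  }
  if (length(hosp_i)) {
    hosp <- data.table(
      person_id = idx$person_id[hosp_i],
      episode_id = idx$episode_id[hosp_i],
      date = idx$date[hosp_i] + sample(0:14, length(hosp_i), replace = TRUE)
    )
    hosp <- hosp[date <= win[2]]
    hosp[, `:=`(setting = "inpatient", mode = "in_person",
                provider_class = "traditional", profession = "physician",
                source = "regional", true_role = "hospitalization")]
    hosp[, dx1 := draw_rti_dx(regime_of(date, params))]
    hosp[, dx2 := ""]
  } else {
    hosp <- empty_contact_block()
  }

  ## --- background (non-RTI) contacts --------------------------------------
  bg_list <- vector("list", length(months))
  for (k in seq_along(months)) {
    m0 <- months[k]
    n_bg <- rpois(1L, pop * params$background_contact_rate)
    if (!n_bg) next
    lo <- max(as.integer(m0), as.integer(win[1]))
    hi <- min(as.integer(m0) + days_in_month(m0) - 1L, as.integer(win[2]))
    bg_list[[k]] <- data.table(
      person_id = sample.int(pop, n_bg, replace = TRUE),
      date = as.IDate(lo + sample(0:(hi - lo), n_bg, replace = TRUE))
    )
  }
  bg <- rbindlist(bg_list)
  if (nrow(bg)) {
    bg[, profession := fifelse(runif(.N) < 0.85, "physician", "other")]
    bg[, mode := fifelse(profession == "physician" & runif(.N) < 0.15,
                         "remote", "in_person")]
    bg[, setting := fifelse(runif(.N) < 0.9, "primary_care", "emergency_room")]
    bg[mode == "remote", setting := "primary_care"]
    bg[, `:=`(provider_class = "traditional", source = "regional",
              true_role = "background", episode_id = NA_integer_)]
    bg[, dx1 := sample(BACKGROUND_DX_POOL, .N, replace = TRUE)]
    bg[runif(.N) < 0.1, dx1 := ""]
    bg[, dx2 := ""]
    ## keep physician background out of follow-up windows so that the
    ## configured follow-up intensities are exactly recoverable
    if (n_idx) {
      wins <- idx[, .(person_id, lo = date + 1L, hi = date + GEN_FOLLOWUP_DAYS)]
      bg[, rid := .I]
      hitrows <- bg[wins, on = .(person_id, date >= lo, date <= hi),
                    nomatch = NULL, x.rid]
      drop <- intersect(unique(hitrows), bg[profession == "physician", rid])
      if (length(drop)) bg <- bg[!rid %in% drop]
      bg[, rid := NULL]
    }
  } else {
    bg <- empty_contact_block()
  }

  ## --- assemble -------------------------------------------------------------
  keep_cols <- c("person_id", "date", "setting", "mode", "provider_class",
                 "profession", "source", "true_role", "episode_id",
                 "dx1", "dx2")
  idx_out <- if (n_idx) idx[, keep_cols, with = FALSE] else
    empty_contact_block()[, keep_cols, with = FALSE]
  if (!"episode_id" %in% names(fu)) fu[, episode_id := NA_integer_]
  if (!"episode_id" %in% names(hosp)) hosp[, episode_id := NA_integer_]
  all_ct <- rbindlist(list(idx_out, fu[, keep_cols, with = FALSE],
                           hosp[, keep_cols, with = FALSE],
                           bg[, keep_cols, with = FALSE]), use.names = TRUE)
  for (cl in DIAG_COLS) all_ct[, (cl) := ""]
  all_ct[, diag1 := dx1]
  all_ct[, diag2 := dx2]
  all_ct[, c("dx1", "dx2") := NULL]

  ## --- mask diagnoses on truly-RTI contacts --------------------------------
  cs <- compile_code_set()
  truly_rti <- all_ct$true_role %in% c("index", "hospitalization") |
    (all_ct$true_role == "follow_up" & matches_code_set(all_ct$diag1, cs))
  mp <- params$missing_diagnosis_prob
  if (any(mp > 0) && any(truly_rti)) {
    pmask <- mp[cbind(all_ct$provider_class, all_ct$mode)]
    masked <- truly_rti & runif(nrow(all_ct)) < pmask
    if (any(masked)) {
      for (cl in DIAG_COLS) set(all_ct, which(masked), cl, "")
    }
  }

  ## deterministic contact ids: sort exactly as the pipeline does
  all_ct <- sort_contacts(all_ct)
  all_ct[, contact_id := .I]

  truth <- all_ct[, .(contact_id, person_id, true_role, episode_id)]
  parent <- truth[true_role == "index",
                  .(episode_id, parent_index_id = contact_id)]
  truth <- parent[truth, on = "episode_id"]
  truth[true_role == "index", parent_index_id := NA_integer_]
  setcolorder(truth, c("contact_id", "person_id", "true_role",
                       "parent_index_id", "episode_id"))
  setorder(truth, contact_id)

  contacts <- all_ct[, c("contact_id", CONTACT_SCHEMA_COLS), with = FALSE]

  years <- sort(unique(as.integer(format(months, "%Y"))))
  population <- data.table(year = years, population = pop)

  structure(list(contacts = contacts[], population = population[],
                 truth = truth[], params = params),
            class = "rti_simulation")
}

#' @export
print.rti_simulation <- function(x, ...) {
  tab <- table(x$truth$true_role)
  cat("<rti_simulation>", nrow(x$contacts), "contacts |",
      paste(names(tab), as.integer(tab), collapse = ", "), "\n")
  invisible(x)
}
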