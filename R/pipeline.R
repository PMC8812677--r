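#' Pipeline configuration
#'
#' Bundles everything one analysis run needs: either paths to contact and
#' population CSVs or a simulation scenario, the study windows and code
#' set, the robust-SE variant, and the output directory.  Validated before
#' any stage runs.
#'
#' @param out_dir output directory (created if absent).
#' @param contacts path to a contact CSV (ignored when `scenario` is set).
#' @param population path to a population CSV (ignored when `scenario` is
#'   set).
#' @param scenario `"prepandemic"` or `"pandemic"` to simulate input with
#'   [paper_like_params()] instead of reading files.
#' @param population_size persons simulated when `scenario` is set.
#' @param seed RNG seed (mandatory when simulating).
#' @param washout_days,followup_days,index_periods,code_set see
#'   [study_config()].
#' @param hc_type robust covariance variant (default `"HC1"`).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            contacts = NULL,
                            population = NULL,
                            scenario = NULL,
                            population_size = 100000,
                            seed = NULL,
                            washout_days = 181L,
                            followup_days = 30L,
                            index_periods = default_index_periods(),
                            code_set = rti_code_set(),
                            hc_type = "HC1") {
  cfg <- study_config(washout_days, followup_days, index_periods, code_set)
  if (is.null(scenario)) {
    if (is.null(contacts) || is.null(population)) {
      stop("either a scenario or both contact and population paths are required")
    }
  } else {
    scenario <- match.arg(scenario, c("prepandemic", "pandemic"))
    if (is.null(seed)) stop("seed is mandatory when simulating")
  }
  structure(list(out_dir = out_dir, contacts = contacts,
                 population = population, scenario = scenario,
                 population_size = as.integer(population_size),
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 study = cfg, hc_type = hc_type),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognised keys mirror the arguments of [pipeline_config()];
#' `index_periods` is a mapping from period name to `[start, end]` dates
#' and `code_set` a list of code-or-range strings.
#'
#' @param path YAML file.
#' @return A [pipeline_config()] object.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  periods <- if (!is.null(y$index_periods)) {
    lapply(y$index_periods, function(p) as.Date(unlist(p)))
  } else default_index_periods()
  pipeline_config(
    out_dir = y$out_dir %||% ".",
    contacts = y$contacts,
    population = y$population,
    scenario = y$scenario,
    population_size = y$population_size %||% 100000,
    seed = y$seed,
    washout_days = y$washout_days %||% 181L,
    followup_days = y$followup_days %||% 30L,
    index_periods = periods,
    code_set = if (!is.null(y$code_set)) unlist(y$code_set) else rti_code_set(),
    hc_type = y$hc_type %||% "HC1"
  )
}

write_resolved_config <- function(config, path) {
  y <- list(
    out_dir = config$out_dir, contacts = config$contacts,
    population = config$population, scenario = config$scenario,
    population_size = config$population_size, seed = config$seed,
    washout_days = config$study$washout_days,
    followup_days = config$study$followup_days,
    index_periods = lapply(config$study$index_periods, format),
    code_set = as.list(config$study$code_set),
    hc_type = config$hc_type
  )
  yaml::write_yaml(y[!vapply(y, is.null, TRUE)], path)
}

#' Run the full analysis pipeline
#'
#' Executes (simulate or read) -> classify -> episodes -> period summary /
#' follow-up matrix / monthly series -> contrasts, writing every stage's
#' output as CSV under `config$out_dir` together with a run log of
#' per-stage record counts and the resolved configuration.  Contrast
#' testing is skipped (with a log note) when the data do not span both the
#' pandemic and the reference period.  Any stage error aborts the run with
#' the stage name and cause.
#'
#' Files written: `labeled_contacts.csv`, `episodes.csv`, `followups.csv`,
#' `period_summary.csv`, `followup_matrix.csv`, `monthly_series.csv`,
#' `contrasts.csv`, `run_log.txt`, `resolved_config.yaml`, and - when
#' simulating - `contacts.csv`, `population.csv`, `ground_truth.csv`.
#'
#' @param config a [pipeline_config()].
#' @return Invisible list with all in-memory results (`contacts`,
#'   `labeled`, `episodes`, `summary`, `followup_matrix`,
#'   `monthly_series`, `contrasts`, `log`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  note <- function(...) {
    line <- paste0(...)
    log_lines <<- c(log_lines, line)
    message(line)
  }

  ## --- input ---------------------------------------------------------------
  if (!is.null(config$scenario)) {
    sim <- tryCatch({
      params <- paper_like_params(config$scenario,
                                  population_size = config$population_size,
                                  seed = config$seed)
      simulate_registry(params)
    }, error = function(e) stage_stop("simulate", e))
    contacts <- sim$contacts
    populations <- sim$population
    write_contacts(contacts, file.path(config$out_dir, "contacts.csv"))
    fwrite(populations, file.path(config$out_dir, "population.csv"))
    fwrite(sim$truth, file.path(config$out_dir, "ground_truth.csv"))
    note("simulate: ", nrow(contacts), " contacts, scenario ",
         config$scenario, ", seed ", config$seed)
    n_rejected <- 0L
  } else {
    contacts <- tryCatch(read_contacts(config$contacts),
                         error = function(e) stage_stop("read", e))
    populations <- tryCatch(read_population(config$population),
                            error = function(e) stage_stop("read", e))
    n_rejected <- nrow(attr(contacts, "rejected") %||% data.table())
    note("read: ", nrow(contacts), " valid contacts (", n_rejected,
         " rejected)")
    contacts <- sort_contacts(contacts)
  }

  codeset <- compile_code_set(config$study$code_set)

  ## --- classification ------------------------------------------------------
  labeled <- tryCatch(classify_contacts(contacts, config$study, codeset),
                      error = function(e) stage_stop("classify", e))
  note("classify: ", sum(labeled$label == "index"), " index, ",
       sum(labeled$label == "follow_up"), " follow-up, ",
       sum(labeled$label == "limbo"), " limbo, ",
       sum(labeled$label == "other"), " other")
  stopifnot(nrow(labeled) == nrow(contacts)) # every valid row gets a label

  ## --- episodes ------------------------------------------------------------
  es <- tryCatch(build_episodes(labeled, config$study),
                 error = function(e) stage_stop("episodes", e))
  note("episodes: ", nrow(es$episodes), " episodes with ",
       nrow(es$followups), " attributed follow-ups")

  ## --- aggregation ---------------------------------------------------------
  agg <- tryCatch({
    list(
      summary = period_summary_table(es, populations, contacts, codeset),
      fmat = if (nrow(es$episodes)) {
        rbindlist(lapply(unique(es$episodes$period), function(p) {
          m <- suppressWarnings(followup_matrix(es, period = p))
          m[, period := p]
          m
        }))
      } else {
        data.table(index_type = character(), followup_type = character(),
                   n_index = integer(), n_followups = integer(),
                   per_index_raw = numeric(), per_index = numeric(),
                   period = character())
      },
      monthly = monthly_series(es, populations)
    )
  }, error = function(e) stage_stop("summarize", e))
  note("summarize: ", nrow(agg$summary), " period rows, ",
       nrow(agg$monthly), " monthly rows")

  ## --- contrasts -----------------------------------------------------------
  records <- index_level_records(es)
  contrasts <- if (nrow(records) &&
                   all(c("pandemic", "reference") %in% records$group)) {
    tryCatch(table5_contrasts(records, hc_type = config$hc_type),
             error = function(e) stage_stop("compare", e))
  } else {
    note("compare: skipped (data do not span both period groups)")
    data.table(stratum = character(), test = character(),
               outcome = character(), estimate = numeric(), se = numeric(),
               statistic = numeric(), df = integer(), p_value = numeric(),
               n_pandemic = integer(), n_reference = integer(),
               note = character())
  }
  if (nrow(contrasts)) note("compare: ", nrow(contrasts), " contrast rows")

  ## --- outputs -------------------------------------------------------------
  out <- function(x, f) fwrite(x, file.path(config$out_dir, f))
  lab_out <- copy(labeled)[, date := format(as.Date(date))]
  out(lab_out, "labeled_contacts.csv")
  ep_out <- copy(es$episodes)[, date := format(as.Date(date))]
  out(ep_out, "episodes.csv")
  fu_out <- copy(es$followups)[, date := format(as.Date(date))]
  out(fu_out, "followups.csv")
  out(agg$summary, "period_summary.csv")
  out(agg$fmat, "followup_matrix.csv")
  out(agg$monthly, "monthly_series.csv")
  out(contrasts, "contrasts.csv")
  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
  write_resolved_config(config, file.path(config$out_dir,
                                          "resolved_config.yaml"))

  invisible(list(contacts = contacts, labeled = labeled, episodes = es,
                 summary = agg$summary, followup_matrix = agg$fmat,
                 monthly_series = agg$monthly, contrasts = contrasts,
                 log = log_lines))
}
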