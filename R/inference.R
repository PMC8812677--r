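#' Index-visit-level records for period contrasts
#'
#' One row per index contact dated March-June of a study year, with its
#' follow-up counts split by follow-up typology.  The grouping contrasts
#' the pandemic spring (March-June 2020) against the pooled corresponding
#' periods of 2018 and 2019.
#'
#' @param es an [rti_episodes][build_episodes()] object.
#' @param pandemic_year year forming the pandemic group (default 2020).
#' @param reference_years years pooled as the comparison group
#'   (default 2018 and 2019).
#' @param months calendar months defining the contrast window (default
#'   March-June).
#' @return data.table: `episode_id`, `group` (`reference`/`pandemic`),
#'   `index_type`, `fu_all`, `fu_in_person`, `fu_remote_traditional`,
#'   `fu_telemedicine`.
#' @export
index_level_records <- function(es, pandemic_year = 2020L,
                                reference_years = c(2018L, 2019L),
                                months = 3:6) {
  stopifnot(inherits(es, "rti_episodes"))
  ep <- es$episodes[month %in% months &
                      year %in% c(pandemic_year, reference_years)]
  if (nrow(ep) == 0L) {
    return(data.table(episode_id = integer(), group = character(),
                      index_type = character(), fu_all = integer(),
                      fu_in_person = integer(),
                      fu_remote_traditional = integer(),
                      fu_telemedicine = integer()))
  }
  fu <- es$followups[ep[, .(episode_id)], on = "episode_id", nomatch = NULL]
  cnt <- fu[, .(
    fu_all = .N,
    fu_in_person = sum(fu_type == "in_person"),
    fu_remote_traditional = sum(fu_type == "remote_traditional"),
    fu_telemedicine = sum(fu_type == "telemedicine")
  ), by = episode_id]
  out <- cnt[ep[, .(episode_id, year, index_type)], on = "episode_id"]
  for (cl in c("fu_all", "fu_in_person", "fu_remote_traditional",
               "fu_telemedicine")) {
    set(out, which(is.na(out[[cl]])), cl, 0L)
  }
  out[, group := fifelse(year == pandemic_year, "pandemic", "reference")]
  out[, year := NULL]
  setcolorder(out, c("episode_id", "group", "index_type", "fu_all",
                     "fu_in_person", "fu_remote_traditional",
                     "fu_telemedicine"))
  out[]
}

FU_OUTCOMES <- c(all = "fu_all", in_person = "fu_in_person",
                 remote_traditional = "fu_remote_traditional",
                 telemedicine = "fu_telemedicine")

#' Regression-based unpaired t-test with robust standard errors
#'
#' Regresses an index-level follow-up count on the period-group indicator.
#' The coefficient equals the difference in group means (pandemic minus
#' reference); its standard error is heteroskedasticity-consistent
#' (HC1 sandwich with finite-sample scaling, by default) and the two-sided
#' p-value uses a t reference with n - 2 degrees of freedom
#' (indistinguishable from normal at registry sample sizes).
#'
#' @param records output of [index_level_records()].
#' @param outcome one of `"all"`, `"in_person"`, `"remote_traditional"`,
#'   `"telemedicine"`.
#' @param hc_type robust covariance variant passed to
#'   [sandwich::vcovHC()] (default `"HC1"`).
#' @return One-row data.table: `outcome`, `estimate`, `se`, `statistic`,
#'   `df`, `p_value`, `mean_pandemic`, `mean_reference`, `n_pandemic`,
#'   `n_reference`, `note` (degenerate inputs are flagged here, with
#'   `p_value` left `NA`).
#' @export
robust_diff_test <- function(records, outcome = "all", hc_type = "HC1") {
  dt <- as.data.table(records)
  outcome <- match.arg(outcome, names(FU_OUTCOMES))
  col <- FU_OUTCOMES[[outcome]]
  groups <- unique(dt$group)
  if (!all(c("pandemic", "reference") %in% groups)) {
    stop("both period groups must be present (found: ",
         paste(groups, collapse = ", "), ")")
  }
  y <- dt[[col]]
  g <- factor(dt$group, levels = c("reference", "pandemic"))
  fit <- lm(y ~ g)
  est <- unname(coef(fit)[2])
  n <- length(y)
  note <- ""
  degenerate <- stats::var(y[g == "pandemic"]) == 0 &&
    stats::var(y[g == "reference"]) == 0
  se <- if (degenerate) 0 else sqrt(sandwich::vcovHC(fit, type = hc_type)[2, 2])
  if (degenerate || se <= 0 || !is.finite(se)) {
    note <- "degenerate: zero residual variance; p undefined"
    stat <- NA_real_
    p <- NA_real_
    se <- if (is.finite(se)) se else NA_real_
  } else {
    stat <- est / se
    p <- 2 * pt(-abs(stat), df = n - 2L)
  }
  data.table(
    outcome = outcome, estimate = est, se = se, statistic = stat,
    df = n - 2L, p_value = p,
    mean_pandemic = mean(y[g == "pandemic"]),
    mean_reference = mean(y[g == "reference"]),
    n_pandemic = sum(g == "pandemic"),
    n_reference = sum(g == "reference"),
    note = note
  )
}

#' Pearson chi-squared statistic for a contingency table
#'
#' Classic Pearson statistic: expected cell counts are products of the
#' margins over the grand total and the statistic is the sum of
#' (observed - expected)^2 / expected, with (rows - 1)(columns - 1)
#' degrees of freedom and no continuity correction.
#'
#' @param tab numeric matrix of counts with all-positive row and column
#'   margins (a zero margin makes the test degenerate and raises an error
#'   naming the margin).
#' @return List: `statistic`, `df`, `p_value`, `expected`.
#' @export
pearson_chisq <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("cell counts must be non-negative")
  rs <- rowSums(tab)
  cs <- colSums(tab)
  if (any(rs == 0)) {
    stop("degenerate margin: row '",
         paste(rownames(tab)[rs == 0] %||% which(rs == 0), collapse = ", "),
         "' has zero total")
  }
  if (any(cs == 0)) {
    stop("degenerate margin: column '",
         paste(colnames(tab)[cs == 0] %||% which(cs == 0), collapse = ", "),
         "' has zero total")
  }
  expected <- outer(rs, cs) / sum(tab)
  stat <- sum((tab - expected)^2 / expected)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(statistic = stat, df = df,
       p_value = pchisq(stat, df, lower.tail = FALSE), expected = expected)
}

#' Chi-squared test of follow-up-contact composition
#'
#' Tests whether the distribution of follow-up contact types (in-person,
#' remote traditional, telemedicine) in the pandemic period differs from
#' the pooled reference periods.  Units are follow-up *contacts*: the
#' 2 x 3 table holds total follow-up contact counts per group and type.
#'
#' @param records output of [index_level_records()].
#' @return One-row data.table: `statistic`, `df`, `p_value`, plus the
#'   underlying table as attribute `"table"`.
#' @export
composition_chisq <- function(records) {
  dt <- as.data.table(records)
  if (!all(c("pandemic", "reference") %in% unique(dt$group))) {
    stop("both period groups must be present")
  }
  tab <- rbind(
    reference = c(
      in_person = sum(dt[group == "reference", fu_in_person]),
      remote_traditional = sum(dt[group == "reference", fu_remote_traditional]),
      telemedicine = sum(dt[group == "reference", fu_telemedicine])
    ),
    pandemic = c(
      in_person = sum(dt[group == "pandemic", fu_in_person]),
      remote_traditional = sum(dt[group == "pandemic", fu_remote_traditional]),
      telemedicine = sum(dt[group == "pandemic", fu_telemedicine])
    )
  )
  res <- pearson_chisq(tab)
  out <- data.table(statistic = res$statistic, df = res$df,
                    p_value = res$p_value)
  setattr(out, "table", tab)
  out[]
}

#' Full contrast table by index typology
#'
#' One stratum per index typology plus `"all"`; each stratum carries four
#' robust difference tests (total and per-follow-up-type counts, pandemic
#' minus pooled reference) and one composition chi-squared test.  Strata
#' that lack one of the groups are emitted with `NA` results and a note,
#' never silently dropped.
#'
#' @param records output of [index_level_records()].
#' @param hc_type robust covariance variant (default `"HC1"`).
#' @return Tidy data.table: `stratum`, `test` (`robust_t` or
#'   `composition_chisq`), `outcome`, `estimate`, `se`, `statistic`, `df`,
#'   `p_value`, `n_pandemic`, `n_reference`, `note`.
#' @export
table5_contrasts <- function(records, hc_type = "HC1") {
  dt <- as.data.table(records)
  if (nrow(dt) == 0L) stop("no index-level records supplied")
  strata <- c("all", contact_types())
  rows <- list()
  for (st in strata) {
    sub <- if (st == "all") dt else dt[index_type == st]
    n_p <- sum(sub$group == "pandemic")
    n_r <- sum(sub$group == "reference")
    if (n_p == 0L || n_r == 0L) {
      rows[[length(rows) + 1L]] <- data.table(
        stratum = st, test = "robust_t", outcome = names(FU_OUTCOMES),
        estimate = NA_real_, se = NA_real_, statistic = NA_real_,
        df = NA_integer_, p_value = NA_real_,
        n_pandemic = n_p, n_reference = n_r,
        note = "stratum lacks one period group")
      next
    }
    for (oc in names(FU_OUTCOMES)) {
      r <- robust_diff_test(sub, oc, hc_type = hc_type)
      rows[[length(rows) + 1L]] <- data.table(
        stratum = st, test = "robust_t", outcome = oc,
        estimate = r$estimate, se = r$se, statistic = r$statistic,
        df = r$df, p_value = r$p_value,
        n_pandemic = r$n_pandemic, n_reference = r$n_reference,
        note = r$note)
    }
    chi <- tryCatch(composition_chisq(sub), error = function(e) e)
    if (inherits(chi, "error")) {
      rows[[length(rows) + 1L]] <- data.table(
        stratum = st, test = "composition_chisq", outcome = "composition",
        estimate = NA_real_, se = NA_real_, statistic = NA_real_,
        df = NA_integer_, p_value = NA_real_,
        n_pandemic = n_p, n_reference = n_r,
        note = conditionMessage(chi))
    } else {
      rows[[length(rows) + 1L]] <- data.table(
        stratum = st, test = "composition_chisq", outcome = "composition",
        estimate = NA_real_, se = NA_real_, statistic = chi$statistic,
        df = as.integer(chi$df), p_value = chi$p_value,
        n_pandemic = n_p, n_reference = n_r, note = "")
    }
  }
  rbindlist(rows)
}
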