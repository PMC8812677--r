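library(data.table)

## build a schema-complete contact table from parallel vectors
make_contacts <- function(person_id, date, diag1 = "", diag2 = "",
                          setting = "primary_care", mode = "in_person",
                          provider_class = "traditional",
                          profession = "physician", source = "regional") {
  n <- length(person_id)
  dt <- data.table(
    person_id = person_id,
    date = as.IDate(date),
    setting = rep_len(setting, n),
    mode = rep_len(mode, n),
    provider_class = rep_len(provider_class, n),
    profession = rep_len(profession, n)
  )
  for (cl in paste0("diag", 1:8)) set(dt, NULL, cl, "")
  set(dt, NULL, "diag1", rep_len(diag1, n))
  set(dt, NULL, "diag2", rep_len(diag2, n))
  set(dt, NULL, "source", rep_len(source, n))
  dt[]
}

## follow-up intensity matrix in contact_types() order
fi_matrix <- function(in_person, remote_traditional, telemedicine) {
  m <- rbind(in_person, remote_traditional, telemedicine)
  dimnames(m) <- list(contact_types(), contact_types())
  m
}

## minimal rti_episodes object for aggregation tests
make_es <- function(episodes, followups = NULL, config = study_config()) {
  ep <- as.data.table(episodes)
  if (!"episode_id" %in% names(ep)) ep[, episode_id := .I]
  if (!"person_id" %in% names(ep)) ep[, person_id := .I]
  if (!"contact_id" %in% names(ep)) ep[, contact_id := .I]
  if (!"date" %in% names(ep)) ep[, date := as.IDate("2020-03-15")]
  ep[, date := as.IDate(date)]
  if (!"year" %in% names(ep)) ep[, year := as.integer(format(date, "%Y"))]
  if (!"month" %in% names(ep)) ep[, month := as.integer(format(date, "%m"))]
  if (!"period" %in% names(ep)) ep[, period := paste0(year, "H1")]
  fu <- if (is.null(followups)) {
    data.table(episode_id = integer(), contact_id = integer(),
               date = as.IDate(character()), offset = integer(),
               fu_type = character())
  } else {
    f <- as.data.table(followups)
    if (!"contact_id" %in% names(f)) f[, contact_id := .I + 10000L]
    if (!"offset" %in% names(f)) f[, offset := 5L]
    if (!"date" %in% names(f)) {
      f[, date := ep$date[match(episode_id, ep$episode_id)] + offset]
    }
    f[, date := as.IDate(date)]
    f
  }
  structure(list(episodes = ep[], followups = fu[], config = config),
            class = "rti_episodes")
}

## O(n^2) reference classifier: for each contact, scan every other contact
## of the same person.  Independent of the single-pass implementation.
brute_classify <- function(contacts, config = study_config(),
                           codeset = compile_code_set()) {
  dt <- sort_contacts(as.data.table(contacts))
  n <- nrow(dt)
  phys <- dt$profession == "physician"
  rti <- rti_flags(dt, codeset) & phys
  outp <- phys & dt$setting != "inpatient"
  day <- as.integer(as.IDate(dt$date))
  pid <- dt$person_id
  label <- rep("other", n)
  for (i in seq_len(n)) {
    if (!(rti[i] && outp[i])) next
    blocked <- FALSE
    for (j in seq_len(n)) {
      if (j == i || pid[j] != pid[i] || !rti[j]) next
      gap <- day[i] - day[j]
      if ((gap >= 1L && gap <= config$washout_days) ||
          (gap == 0L && j < i)) {
        blocked <- TRUE
        break
      }
    }
    if (!blocked) label[i] <- "index"
  }
  parent <- rep(NA_integer_, n)
  offset <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    if (label[i] == "index" || !outp[i]) next
    for (j in seq_len(n)) {
      if (label[j] != "index" || pid[j] != pid[i]) next
      gap <- day[i] - day[j]
      if (gap >= 1L && gap <= config$followup_days) {
        label[i] <- "follow_up"
        parent[i] <- dt$contact_id[j]
        offset[i] <- gap
      }
    }
  }
  label[rti & label == "other"] <- "limbo"
  data.table(contact_id = dt$contact_id, label = label,
             parent_index_id = parent, offset = offset)
}

## random small registry exercising every enum combination
random_registry <- function(seed, n_persons = 5, max_contacts = 12,
                            span_days = 420) {
  set.seed(seed)
  rows <- list()
  pool <- c("J069", "J20", "R060", "R061", "H660", "U071", "ZV100",
            "Z000", "B349", "J309", "")
  for (p in seq_len(n_persons)) {
    k <- sample.int(max_contacts, 1)
    kind <- sample(c("ip", "rt", "tm", "inpat", "nurse"), k, replace = TRUE,
                   prob = c(0.4, 0.2, 0.15, 0.1, 0.15))
    rows[[p]] <- data.table(
      person_id = p,
      date = as.IDate("2018-01-01") + sample.int(span_days, k, replace = TRUE),
      setting = c(ip = "primary_care", rt = "primary_care",
                  tm = "primary_care", inpat = "inpatient",
                  nurse = "primary_care")[kind],
      mode = c(ip = "in_person", rt = "remote", tm = "remote",
               inpat = "in_person", nurse = "in_person")[kind],
      provider_class = c(ip = "traditional", rt = "traditional",
                         tm = "telemedicine", inpat = "traditional",
                         nurse = "traditional")[kind],
      profession = c(ip = "physician", rt = "physician", tm = "physician",
                     inpat = "physician", nurse = "other")[kind],
      diag1 = sample(pool, k, replace = TRUE),
      diag2 = sample(c(pool, rep("", 10)), k, replace = TRUE),
      source = c(ip = "regional", rt = "regional",
                 tm = "telemedicine_register", inpat = "regional",
                 nurse = "regional")[kind]
    )
  }
  dt <- rbindlist(rows)
  for (cl in paste0("diag", 3:8)) dt[, (cl) := ""]
  setcolorder(dt, c("person_id", "date", "setting", "mode", "provider_class",
                    "profession", paste0("diag", 1:8), "source"))
  sort_contacts(dt)
}
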