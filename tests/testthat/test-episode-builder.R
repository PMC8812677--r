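cfg <- study_config()
cs <- compile_code_set()

test_that("a first-ever RTI contact is an index", {
  ct <- make_contacts(1L, "2018-02-01", diag1 = "J069")
  lab <- classify_contacts(ct, cfg, cs)
  expect_identical(lab$label, "index")
})

test_that("any-diagnosis physician contact within 30 days is a follow-up", {
  ct <- make_contacts(c(1L, 1L), c("2018-02-01", "2018-02-11"),
                      diag1 = c("J069", "Z000"))
  lab <- classify_contacts(ct, cfg, cs)
  expect_identical(lab$label, c("index", "follow_up"))
  expect_identical(lab$offset, c(NA_integer_, 10L))
  expect_identical(lab$parent_index_id[2], lab$contact_id[1])
})

test_that("every RTI contact resets the washout clock", {
  ## day 0 index; day 100 RTI is limbo (31-181 after the last RTI contact);
  ## day 250 is only 150 days after day 100, so still limbo, not index
  d0 <- as.Date("2018-01-01")
  ct <- make_contacts(rep(1L, 3), d0 + c(0, 100, 250), diag1 = "J20")
  lab <- classify_contacts(ct, cfg, cs)
  expect_identical(lab$label, c("index", "limbo", "limbo"))
})

test_that("an RTI follow-up stays a follow-up but resets the clock", {
  d0 <- as.Date("2018-01-01")
  ct <- make_contacts(rep(1L, 2), d0 + c(0, 20), diag1 = "J069")
  lab <- classify_contacts(ct, cfg, cs)
  expect_identical(lab$label, c("index", "follow_up"))
  ## a day-40 RTI contact is 20 days after the follow-up's diagnosis:
  ## blocked from index status by the reset clock
  ct3 <- make_contacts(rep(1L, 3), d0 + c(0, 20, 40), diag1 = "J069")
  lab3 <- classify_contacts(ct3, cfg, cs)
  expect_identical(lab3$label, c("index", "follow_up", "limbo"))
})

test_that("washout boundary: an RTI contact exactly 181 days earlier blocks", {
  d0 <- as.Date("2018-01-01")
  ct <- make_contacts(rep(1L, 2), d0 + c(0, 181), diag1 = "J069")
  expect_identical(classify_contacts(ct, cfg, cs)$label, c("index", "limbo"))
  ct2 <- make_contacts(rep(1L, 2), d0 + c(0, 182), diag1 = "J069")
  expect_identical(classify_contacts(ct2, cfg, cs)$label, c("index", "index"))
})

test_that("same-day contacts: never follow-ups, only the first can be index", {
  d0 <- as.Date("2018-03-01")
  ct <- make_contacts(rep(1L, 2), c(d0, d0), diag1 = c("J069", "J20"))
  lab <- classify_contacts(ct, cfg, cs)
  expect_identical(sort(lab$label), c("index", "limbo"))
  ## non-RTI same-day contact is neither follow-up nor limbo
  ct2 <- make_contacts(rep(1L, 2), c(d0, d0), diag1 = c("J069", "Z000"))
  expect_setequal(classify_contacts(ct2, cfg, cs)$label, c("index", "other"))
})

test_that("non-physician and inpatient contacts follow the stated rules", {
  d0 <- as.Date("2018-01-01")
  ## nurse contacts are ignored entirely, even with RTI codes
  ct <- make_contacts(rep(1L, 2), d0 + c(0, 10), diag1 = "J069",
                      profession = c("other", "physician"))
  lab <- classify_contacts(ct, cfg, cs)
  expect_identical(lab$label, c("other", "index"))
  ## inpatient RTI stays are never indexes or follow-ups but reset the clock
  ct2 <- make_contacts(rep(1L, 2), d0 + c(0, 100), diag1 = "J069",
                       setting = c("inpatient", "primary_care"))
  lab2 <- classify_contacts(ct2, cfg, cs)
  expect_identical(lab2$label, c("limbo", "limbo"))
})

test_that("unsorted input is a contract violation", {
  ct <- make_contacts(c(1L, 1L), as.Date(c("2018-02-10", "2018-02-01")),
                      diag1 = "J069")
  expect_error(classify_contacts(ct, cfg, cs), "sorted")
})

test_that("single-pass classifier matches the brute-force reference", {
  for (seed in 1:200) {
    reg <- random_registry(seed)
    got <- classify_contacts(reg, cfg, cs)
    ref <- brute_classify(reg, cfg, cs)
    got <- got[order(contact_id)]
    ref <- ref[order(contact_id)]
    expect_identical(got$label, ref$label,
                     label = paste("labels, registry seed", seed))
    expect_identical(got$parent_index_id, ref$parent_index_id,
                     label = paste("parents, registry seed", seed))
    expect_identical(got$offset, ref$offset,
                     label = paste("offsets, registry seed", seed))
  }
})

test_that("no two indexes of one person fall within the washout window", {
  for (seed in c(7, 42, 99)) {
    reg <- random_registry(seed, n_persons = 8, span_days = 900)
    lab <- classify_contacts(reg, cfg, cs)
    idx <- lab[label == "index"]
    gaps <- idx[, diff(as.integer(date)), by = person_id]$V1
    if (length(gaps)) expect_true(all(gaps > cfg$washout_days))
    fu <- lab[label == "follow_up"]
    if (nrow(fu)) {
      expect_true(all(fu$offset >= 1L & fu$offset <= cfg$followup_days))
      ## every follow-up's parent is an index of the same person
      par <- merge(fu[, .(person_id, parent_index_id)],
                   idx[, .(parent_index_id = contact_id,
                           idx_person = person_id)],
                   by = "parent_index_id")
      expect_identical(nrow(par), nrow(fu))
      expect_identical(par$person_id, par$idx_person)
    }
  }
})

test_that("window monotonicity: wider follow-up, fewer-or-equal indexes", {
  wide_fu <- study_config(followup_days = 45L)
  long_wash <- study_config(washout_days = 300L)
  short_wash <- study_config(washout_days = 120L)
  for (seed in 1:25) {
    reg <- random_registry(seed, span_days = 700)
    base <- classify_contacts(reg, cfg, cs)
    expect_gte(sum(classify_contacts(reg, wide_fu, cs)$label == "follow_up"),
               sum(base$label == "follow_up"))
    expect_lte(sum(classify_contacts(reg, long_wash, cs)$label == "index"),
               sum(classify_contacts(reg, short_wash, cs)$label == "index"))
  }
})

test_that("episodes keep period assignment and late follow-ups", {
  ct <- make_contacts(c(1L, 1L, 2L, 3L),
                      as.Date(c("2020-06-25", "2020-07-10",
                                "2017-12-15", "2020-03-05")),
                      diag1 = c("J069", "", "J20", "U071"))
  lab <- classify_contacts(ct, cfg, cs)
  es <- build_episodes(lab, cfg)
  ## person 2's index predates all periods: washout only, no episode
  expect_identical(nrow(es$episodes), 2L)
  e1 <- es$episodes[person_id == 1L]
  expect_identical(e1$period, "2020H1")
  ## the July follow-up is attached despite falling after the period end
  expect_identical(es$followups[episode_id == e1$episode_id, offset], 15L)
})

test_that("a labeled stream with zero indexes yields no episodes", {
  ct <- make_contacts(1L, "2018-02-01", diag1 = "Z000")
  es <- build_episodes(classify_contacts(ct, cfg, cs), cfg)
  expect_identical(nrow(es$episodes), 0L)
  expect_identical(nrow(es$followups), 0L)
})

test_that("hospitalized patients are counted uniquely per period", {
  period <- as.Date(c("2020-01-01", "2020-06-30"))
  ## one patient, three RTI stays
  ct <- make_contacts(rep(1L, 3), as.Date("2020-02-01") + c(0, 10, 20),
                      diag1 = "J189", setting = "inpatient")
  expect_identical(count_hospitalized_patients(ct, cs, period), 1L)
  ## no inpatient rows
  ct2 <- make_contacts(1L, "2020-02-01", diag1 = "J189")
  expect_identical(count_hospitalized_patients(ct2, cs, period), 0L)
  ## 5 patients / 7 stays; RTI-coded in-period stays for persons 1, 2, 3;
  ## person 4 has a non-RTI stay, person 5 an out-of-period RTI stay
  ct3 <- make_contacts(
    c(1L, 1L, 2L, 3L, 3L, 4L, 5L),
    as.Date(c("2020-02-01", "2020-02-20", "2020-03-01", "2020-04-01",
              "2020-04-10", "2020-05-01", "2019-12-01")),
    diag1 = c("J189", "J129", "U071", "J159", "J189", "Z000", "J189"),
    setting = "inpatient")
  expect_identical(count_hospitalized_patients(ct3, cs, period), 3L)
})
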