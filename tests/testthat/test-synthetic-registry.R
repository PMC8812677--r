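flat_params <- function(pop = 2000, seed = 1L, incidence = 12,
                        missing = NULL, bg = 0.15) {
  sim_params(
    population_size = pop,
    calendar_window = as.Date(c("2018-01-01", "2018-07-31")),
    monthly_rti_incidence = monthly_incidence(2018L, 1:6, incidence),
    index_mode_mix = list(prepandemic = c(in_person = 0.34,
                                          remote_traditional = 0.33,
                                          telemedicine = 0.33)),
    followup_intensity = fi_matrix(c(0.3, 0.1, 0.05),
                                   c(0.2, 0.3, 0.05),
                                   c(0.2, 0.1, 0.3)),
    background_contact_rate = bg,
    missing_diagnosis_prob = missing,
    seed = seed
  )
}

test_that("parameter validation rejects inconsistent inputs", {
  expect_error(paper_like_params("elizabethan"), "arg")
  p <- flat_params()
  expect_error(sim_params(population_size = 100,
                          monthly_rti_incidence = monthly_incidence(2018, 1, 1200),
                          index_mode_mix = p$index_mode_mix,
                          followup_intensity = p$followup_intensity,
                          seed = 1),
               "infeasible")
  bad_mix <- list(prepandemic = c(in_person = 0.5, remote_traditional = 0.4,
                                  telemedicine = 0.4))
  expect_error(sim_params(population_size = 100,
                          monthly_rti_incidence = p$monthly_rti_incidence,
                          index_mode_mix = bad_mix,
                          followup_intensity = p$followup_intensity,
                          seed = 1),
               "sum to 1")
  expect_error(sim_params(population_size = 100,
                          monthly_rti_incidence = p$monthly_rti_incidence,
                          index_mode_mix = p$index_mode_mix,
                          followup_intensity = p$followup_intensity),
               "seed")
})

test_that("zero incidence produces a background-only registry", {
  sim <- simulate_registry(flat_params(pop = 500, incidence = 0))
  expect_identical(sum(sim$truth$true_role == "index"), 0L)
  expect_true(all(sim$truth$true_role == "background"))
  cs <- compile_code_set()
  expect_identical(sum(rti_flags(sim$contacts, cs)), 0L)
})

test_that("identical params and seed reproduce byte-identical output", {
  s1 <- simulate_registry(flat_params(seed = 99L))
  s2 <- simulate_registry(flat_params(seed = 99L))
  expect_identical(s1$contacts, s2$contacts)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$population, s2$population)
  s3 <- simulate_registry(flat_params(seed = 100L))
  expect_false(identical(s1$contacts, s3$contacts))
})

test_that("ground truth respects its structural invariants", {
  sim <- simulate_registry(flat_params(pop = 5000, seed = 3L))
  tr <- sim$truth
  ct <- sim$contacts
  idx <- tr[true_role == "index"]
  ## inter-index gaps per person exceed the washout
  d <- merge(idx, ct[, .(contact_id, date)], by = "contact_id")
  gaps <- d[order(person_id, date), diff(as.integer(date)), by = person_id]$V1
  if (length(gaps)) expect_true(all(gaps > 181L))
  ## every follow-up has a parent index dated 1-30 days earlier
  fu <- merge(tr[true_role == "follow_up"],
              ct[, .(contact_id, date)], by = "contact_id")
  fu <- merge(fu, d[, .(parent_index_id = contact_id, idx_date = date,
                        idx_person = person_id)],
              by = "parent_index_id")
  expect_identical(nrow(fu), sum(tr$true_role == "follow_up"))
  off <- as.integer(fu$date) - as.integer(fu$idx_date)
  expect_true(all(off >= 1L & off <= 30L))
  expect_identical(fu$person_id, fu$idx_person)
  ## population table carries the configured size for each study year
  expect_true(all(sim$population$population == 5000L))
})

test_that("empirical follow-up intensity converges to the configured means", {
  p <- paper_like_params("pandemic", population_size = 60000, seed = 8L)
  sim <- simulate_registry(p)
  tr <- sim$truth
  ## indexes with an untruncated 30-day window
  idx <- merge(tr[true_role == "index", .(contact_id)],
               sim$contacts[, .(contact_id, date, mode, provider_class)],
               by = "contact_id")
  idx <- idx[date <= p$calendar_window[2] - 30L]
  idx[, type := contact_typology(mode, provider_class)]
  fu_per_idx <- tr[true_role == "follow_up", .N, by = parent_index_id]
  idx <- fu_per_idx[idx, on = c(parent_index_id = "contact_id")]
  idx[is.na(N), N := 0L]
  expect_gt(nrow(idx), 5000)
  lambda <- rowSums(p$followup_intensity)
  for (t in contact_types()) {
    obs <- idx[type == t, N]
    se <- sqrt(lambda[[t]] / length(obs))
    expect_lt(abs(mean(obs) - lambda[[t]]), 4 * se,
              label = paste("mean follow-ups per", t, "index"))
  }
})

test_that("raising diagnosis missingness lowers recovered index counts", {
  miss <- matrix(0, 2, 2, dimnames = list(c("traditional", "telemedicine"),
                                          c("in_person", "remote")))
  miss["traditional", "remote"] <- 0.2
  p0 <- paper_like_params("pandemic", population_size = 20000, seed = 21L)
  sim0 <- simulate_registry(p0)
  p1 <- p0
  p1$missing_diagnosis_prob <- miss
  sim1 <- simulate_registry(p1)
  cfg <- study_config()
  cs <- compile_code_set()
  n0 <- sum(classify_contacts(sim0$contacts, cfg, cs)$label == "index")
  n1 <- sum(classify_contacts(sim1$contacts, cfg, cs)$label == "index")
  truth_n <- sum(sim1$truth$true_role == "index")
  expect_lt(n1, n0)
  expect_lt(n1, truth_n)
  expect_identical(n0, sum(sim0$truth$true_role == "index"))
})

test_that("recovered index rate sits in the binomial interval of the model", {
  ## flat 12/1000/month over one 6-month period: under the per-person
  ## per-month Bernoulli arrival model a person has an index with
  ## probability 1 - (1 - p)^6, and the washout cannot reject within a
  ## 181-day window, so the count is Binomial(pop, q)
  pop <- 50000
  sim <- simulate_registry(flat_params(pop = pop, seed = 17L))
  cfg <- study_config()
  lab <- classify_contacts(sim$contacts, cfg)
  ## zero missingness: every ground-truth index label is recovered
  m <- merge(lab[, .(contact_id, label)],
             sim$truth[, .(contact_id, true_role)], by = "contact_id")
  idx_truth <- m[true_role == "index"]
  expect_gte(mean(idx_truth$label == "index"), 0.99)
  q <- 1 - (1 - 0.012)^6
  n_idx <- sum(lab$label == "index" &
                 lab$date >= as.Date("2018-01-01") &
                 lab$date <= as.Date("2018-06-30"))
  ci <- pop * (q + c(-1, 1) * 1.96 * sqrt(q * (1 - q) / pop))
  expect_gt(n_idx, ci[1])
  expect_lt(n_idx, ci[2])
})

test_that("presets reproduce the documented follow-up intensity totals", {
  pre <- paper_like_params("prepandemic", seed = 1L)
  pan <- paper_like_params("pandemic", seed = 1L)
  expect_equal(unname(rowSums(pre$followup_intensity)),
               c(0.48, 0.73, 0.49), tolerance = 1e-12)
  expect_equal(unname(rowSums(pan$followup_intensity)),
               c(0.60, 0.90, 0.69), tolerance = 1e-12)
  ## both presets satisfy the full parameter invariants by construction
  expect_s3_class(pre, "sim_params")
  expect_s3_class(pan, "sim_params")
  ## the pandemic mode mix averages to the reported half-year shares:
  ## weights = monthly incidence, Jan-Feb prepandemic, Mar-Jun pandemic
  inc <- pan$monthly_rti_incidence[year == 2020 & month %in% 1:6]
  w <- inc$incidence / sum(inc$incidence)
  avg <- colSums(rbind(
    w[1] * pan$index_mode_mix$prepandemic,
    w[2] * pan$index_mode_mix$prepandemic,
    w[3] * pan$index_mode_mix$pandemic,
    w[4] * pan$index_mode_mix$pandemic,
    w[5] * pan$index_mode_mix$pandemic,
    w[6] * pan$index_mode_mix$pandemic
  ))
  expect_equal(unname(round_half_up(avg)), c(0.74, 0.16, 0.10),
               tolerance = 1e-12)
})
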