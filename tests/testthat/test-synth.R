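quiet_cfg <- function(...) {
  pac_config(linkage_missed_rate = 0, linkage_false_rate = 0, ...)
}

test_that("generation is reproducible under a fixed seed and varies across seeds", {
  cfg <- quiet_cfg()
  a <- simulate_cohort(400, cfg, seed = 5)
  b <- simulate_cohort(400, cfg, seed = 5)
  expect_identical(a$maternities, b$maternities)
  expect_identical(a$hospital, b$hospital)
  expect_identical(a$registry, b$registry)
  # byte-identical files
  fa <- withr::local_tempfile(); fb <- withr::local_tempfile()
  write_hospital(a$hospital, fa); write_hospital(b$hospital, fb)
  expect_identical(readLines(fa), readLines(fb))
  c3 <- simulate_cohort(400, cfg, seed = 6)
  expect_false(identical(a$maternities$delivery_date,
                         c3$maternities$delivery_date))
})

test_that("planted registry diagnoses all fall inside their exposure window", {
  s <- simulate_cohort(8000, quiet_cfg(), seed = 12)
  w <- make_window(s$maternities)
  ev <- s$ledger$registry_events
  inc <- ev[ev$mechanism != "prevalent_history", ]
  i <- match(inc$maternity_id, w$maternity_id)
  expect_true(all(inc$diagnosis_date >= w$start_date[i] &
                    inc$diagnosis_date <= w$end_date[i]))
  # prevalent history predates every window of the woman
  prev <- ev[ev$mechanism == "prevalent_history", ]
  if (nrow(prev) > 0) {
    starts <- tapply(w$start_date, w$woman_id, min)
    expect_true(all(prev$diagnosis_date <
                      as.Date(starts[prev$woman_id], origin = "1970-01-01")))
  }
})

test_that("perfect capture with no error mechanisms yields perfect validity", {
  # single maternities: windows of one woman never overlap, so capture is
  # the only determinant of ascertainment
  cfg <- quiet_cfg(
    capture_prob = setNames(rep(1, 13), clinical_groups()),
    extra_admissions_mean = setNames(rep(0, 13), clinical_groups()),
    timing_mixture = c(same_month = 1, prior_1_2 = 0, prior_3_5 = 0,
                       prior_6_plus = 0),
    fp_prevalent_rate = 0, fp_miscode_rate = 0, fp_noise_rate = 0,
    group_incidence = setNames(rep(200, 13), clinical_groups()),
    maternities_per_woman = c(`1` = 1))
  s <- simulate_cohort(6000, cfg, seed = 8)
  fit <- pac_validation(s$maternities, s$hospital, s$registry)
  any_e <- fit$estimates[fit$estimates$group == "any", ]
  expect_gt(fit$counts$tp[fit$counts$group == "any"], 50)
  expect_equal(any_e$sensitivity, 1)
  expect_equal(any_e$ppv, 1)
  r <- fit$rates[fit$rates$group == "any", ]
  expect_equal(r$irr_index, 1)
  expect_equal(r$irr_all, 1)  # mean multiplicity is 1 with no extras
  expect_equal(as.integer(fit$timing$counts[["same_month"]]),
               sum(fit$timing$counts))
})

test_that("the pipeline recovers the truth ledger exactly when linkage noise is off", {
  for (sd in c(3, 14)) {
    s <- simulate_cohort(12000, quiet_cfg(), seed = sd)
    fit <- pac_validation(s$maternities, s$hospital, s$registry)
    ts <- truth_summary(s$ledger)
    expect_equal(fit$counts[, c("group", "tp", "fp", "fn")], ts$expected,
                 ignore_attr = TRUE)
    expect_equal(fit$fp$counts[["prevalent"]],
                 unname(ts$mechanism_counts["prevalent_fp"]))
  }
})

test_that("recovered timing bins equal the ledger tally without FP interference", {
  inc <- setNames(rep(1500, 13), clinical_groups())
  cfg <- quiet_cfg(fp_prevalent_rate = 0, fp_miscode_rate = 0,
                   fp_noise_rate = 0, group_incidence = inc,
                   maternities_per_woman = c(`1` = 1))
  s <- simulate_cohort(8000, cfg, seed = 17)
  fit <- pac_validation(s$maternities, s$hospital, s$registry)
  tally <- truth_summary(s$ledger)$timing_tally
  expect_equal(fit$timing$counts[names(tally)], tally)
  expect_equal(fit$timing$counts[["after_registration"]], 0L)
  # and the proportions sit near the configured mixture (Monte-Carlo bound)
  n <- sum(tally)
  expect_gt(n, 500)
  p <- fit$timing$proportions[names(cfg$timing_mixture)]
  expect_true(all(abs(p - cfg$timing_mixture) <
                    4 * sqrt(cfg$timing_mixture *
                               (1 - cfg$timing_mixture) / n) + 0.01))
})

test_that("registry group shares track the configured incidence profile", {
  # about 1,000 expected incident cancers under the default incidence profile
  cfg <- quiet_cfg(fp_miscode_rate = 0, background_admissions = FALSE,
                   capture_prob = setNames(rep(0, 13), clinical_groups()))
  s <- simulate_cohort(475000, cfg, seed = 23)
  ev <- s$ledger$registry_events
  inc <- ev[ev$mechanism == "incident", ]
  share <- mean(inc$group == "melanoma")
  expect_gt(nrow(inc), 700)
  # default melanoma share of registry incidence is 322/988 = 32.6%
  expect_lt(abs(share - 322 / 988), 0.05)
})

test_that("misconfigured generators are rejected", {
  expect_error(pac_config(nonsense = 1), "unknown")
  expect_error(pac_config(fp_noise_rate = 1.4), "\\[0, 1\\]")
  expect_error(pac_config(study_end = as.Date("2000-01-01")), "study_end")
  cfg <- pac_config(timing_mixture = c(same_month = 2, prior_1_2 = 1,
                                       prior_3_5 = 1, prior_6_plus = 0))
  expect_equal(sum(cfg$timing_mixture), 1)  # renormalized
})

test_that("a generator configuration survives a YAML round trip", {
  cfg <- quiet_cfg(fp_noise_rate = 0.25)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_generator_config(cfg, path)
  cfg2 <- read_generator_config(path)
  expect_equal(cfg2$fp_noise_rate, 0.25)
  expect_equal(cfg2$group_incidence, cfg$group_incidence)
  expect_equal(cfg2$study_start, cfg$study_start)
  s1 <- simulate_cohort(200, cfg, seed = 2)
  s2 <- simulate_cohort(200, cfg2, seed = 2)
  expect_identical(s1$hospital, s2$hospital)
  # the shipped default configuration file parses to the in-code defaults
  shipped <- system.file("extdata", "generator_defaults.yaml",
                         package = "pacvalid")
  cfg3 <- read_generator_config(shipped)
  expect_equal(cfg3$capture_prob, pac_config()$capture_prob)
})

test_that("missed-link noise removes registry cases and inflates apparent sensitivity bias", {
  cfg <- pac_config(linkage_missed_rate = 0.2, linkage_false_rate = 0,
                    group_incidence = setNames(rep(1000, 13),
                                               clinical_groups()))
  s <- simulate_cohort(12000, cfg, seed = 9)
  fit <- pac_validation(s$maternities, s$hospital, s$registry)
  ts <- truth_summary(s$ledger)
  # detached registry records mean fewer registry cases than planted ...
  reg_n <- fit$counts$tp[fit$counts$group == "any"] +
    fit$counts$fn[fit$counts$group == "any"]
  planted <- ts$expected$tp[ts$expected$group == "any"] +
    ts$expected$fn[ts$expected$group == "any"]
  expect_lt(reg_n, planted)
  # ... and their captured admissions now surface as false positives
  expect_gt(fit$counts$fp[fit$counts$group == "any"],
            ts$expected$fp[ts$expected$group == "any"])
})
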