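mk_windows <- function() {
  make_window(data.frame(
    woman_id = c("w1", "w1", "w2"),
    maternity_id = c("m1", "m2", "m3"),
    delivery_date = as.Date(c("2003-06-01", "2006-06-01", "2004-01-10")),
    gestation_weeks = 40))
}

test_that("registry cases keep incident cancers, collapse duplicates, split groups", {
  w <- mk_windows()
  reg <- data.frame(
    woman_id = c("w1", "w1", "w1", "w2", "w2"),
    registry_id = c("R1", "R2", "R3", "R4", "R5"),
    diagnosis_date = as.Date(c("2003-03-01", "2003-04-01", "2003-05-01",
                               "2004-02-01", "2003-09-01")),
    group = c("melanoma", "melanoma", "breast", "colorectal", "colorectal"),
    first_notification_date = as.Date(c("2003-03-01", "2003-04-01",
                                        "2003-05-01", "2004-02-01",
                                        "2000-01-01")),
    stringsAsFactors = FALSE)
  cases <- registry_cases(reg, w)
  # duplicate melanoma collapses to the earliest; breast is a second primary;
  # w2's colorectal with pre-window first notification is prevalent, excluded
  expect_equal(nrow(cases), 3L)
  mel <- cases[cases$group == "melanoma", ]
  expect_equal(mel$source_record_id, "R1")
  expect_setequal(cases$group[cases$maternity_id == "m1"],
                  c("melanoma", "breast"))
  expect_equal(cases$maternity_id[cases$group == "colorectal"], "m3")
})

test_that("all-hospitalisation cases count records; index keeps the earliest", {
  w <- mk_windows()
  hosp <- data.frame(
    woman_id = c("w1", "w1", "w1", "w1", "w2"),
    record_id = c(7, 3, 10, 11, 12),
    admission_date = as.Date(c("2003-03-10", "2003-03-10", "2003-04-20",
                               "2009-01-01", "2004-02-05")),
    diag1 = c("C43.1", "C43.9", "C43.2", "C43.2", "O80"),
    diag2 = c("", "", "", "", "Z37.0"),
    stringsAsFactors = FALSE)
  all_c <- hospital_all_cases(hosp, w)
  expect_equal(nrow(all_c), 3L)  # record is the unit; 2009 outside, w2 no code
  idx <- hospital_index_cases(hosp, w)
  expect_equal(nrow(idx), 1L)
  # equal earliest dates: smallest record_id wins
  expect_equal(idx$source_record_id, "3")
  expect_true(nrow(idx) <= nrow(all_c))
})

test_that("records with only out-of-scope codes never affect the case sets", {
  set.seed(41)
  coh <- random_small_cohort(25)
  w <- make_window(coh$maternities)
  junk <- coh$hospital
  eligible <- vapply(seq_len(nrow(junk)), function(i) {
    any(!classify_code(c(junk$diag1[i], junk$diag2[i])[
      nzchar(c(junk$diag1[i], junk$diag2[i]))]) %in%
        c("secondary", "out_of_scope"))
  }, logical(1))
  pruned <- junk[eligible, ]
  for (f in list(hospital_all_cases, hospital_index_cases)) {
    a <- f(junk, w); b <- f(pruned, w)
    rownames(a) <- rownames(b) <- NULL
    expect_equal(a[order(a$source_record_id), ],
                 b[order(b$source_record_id), ], ignore_attr = TRUE)
  }
})

test_that("ascertainment matches brute-force set construction on random cohorts", {
  set.seed(42)
  for (rep in 1:8) {
    coh <- random_small_cohort(sample(10:50, 1))
    w <- make_window(coh$maternities)
    reg <- registry_cases(coh$registry, w)
    want_reg <- oracle_registry_cases(coh$registry, w)
    expect_setequal(paste(reg$maternity_id, reg$group),
                    paste(want_reg$maternity_id, want_reg$group))
    all_c <- hospital_all_cases(coh$hospital, w)
    want_all <- oracle_hospital_all(coh$hospital, w)
    expect_equal(sort(paste(all_c$maternity_id, all_c$group,
                            all_c$source_record_id)),
                 sort(paste(want_all$maternity_id, want_all$group,
                            want_all$record_id)))
    idx <- hospital_index_cases(coh$hospital, w)
    want_idx <- oracle_hospital_index(coh$hospital, w)
    expect_setequal(paste(idx$maternity_id, idx$group, idx$source_record_id),
                    paste(want_idx$maternity_id, want_idx$group,
                          want_idx$record_id))
    # per-group counts sum to the any total within each source
    for (cases in list(reg, all_c, idx)) {
      per_group <- table(factor(cases$group, levels = clinical_groups()))
      expect_equal(sum(per_group), nrow(cases))
    }
  }
})

test_that("all/index ratio recovers the planted admission multiplicity", {
  inc <- setNames(rep(0, 13), clinical_groups())
  inc["breast"] <- 2000  # per 100,000
  # one maternity per woman: no overlapping sibling windows, so every
  # non-index admission is exactly one planted extra
  cfg <- pac_config(group_incidence = inc,
                    capture_prob = setNames(rep(1, 13), clinical_groups()),
                    extra_admissions_mean = setNames(rep(1.23, 13),
                                                     clinical_groups()),
                    fp_prevalent_rate = 0, fp_miscode_rate = 0,
                    fp_noise_rate = 0, linkage_missed_rate = 0,
                    linkage_false_rate = 0,
                    maternities_per_woman = c(`1` = 1))
  s <- simulate_cohort(20000, cfg, seed = 99)
  w <- make_window(s$maternities)
  all_c <- hospital_all_cases(s$hospital, w)
  idx <- hospital_index_cases(s$hospital, w)
  # exact: every non-index admission is a planted extra
  mech <- s$ledger$admission_events$mechanism
  expect_equal(nrow(all_c), sum(mech %in% c("index", "extra")))
  expect_equal(nrow(all_c) - nrow(idx), sum(mech == "extra"))
  # stochastic: mean multiplicity near 1 + 1.23 (Poisson extras)
  expect_gt(nrow(idx), 200)
  expect_lt(abs(nrow(all_c) / nrow(idx) - 2.23), 0.25)
})
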