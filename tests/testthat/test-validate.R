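cases_df <- function(pairs) {
  data.frame(maternity_id = vapply(pairs, `[[`, "", 1),
             group = vapply(pairs, `[[`, "", 2), stringsAsFactors = FALSE)
}

test_that("cross-classification on hand-worked sets", {
  idx <- cases_df(list(c("m1", "breast")))
  reg <- cases_df(list(c("m1", "breast"), c("m2", "melanoma")))
  tt <- cross_classify(idx, reg, 10)
  br <- tt[tt$group == "breast", ]
  expect_equal(unlist(br[, c("tp", "fp", "fn", "tn")]),
               c(tp = 1, fp = 0, fn = 0, tn = 9))
  mel <- tt[tt$group == "melanoma", ]
  expect_equal(unlist(mel[, c("tp", "fp", "fn", "tn")]),
               c(tp = 0, fp = 0, fn = 1, tn = 9))
  # disjoint singletons of one group
  tt2 <- cross_classify(cases_df(list(c("m1", "breast"))),
                        cases_df(list(c("m2", "breast"))), 10)
  expect_equal(unlist(tt2[tt2$group == "breast", c("tp", "fp", "fn")]),
               c(tp = 0, fp = 1, fn = 1))
  # the any row is the element-wise column sum of the 13 groups
  g <- tt[tt$group != "any", ]
  expect_equal(unlist(tt[tt$group == "any", c("tp", "fp", "fn", "tn")]),
               c(tp = sum(g$tp), fp = sum(g$fp), fn = sum(g$fn), tn = sum(g$tn)))
  expect_error(cross_classify(idx, reg, 1), "smaller")
})

test_that("cross-classification equals brute-force set algebra on random sets", {
  set.seed(51)
  for (rep in 1:10) {
    mats <- sprintf("m%02d", 1:15)
    idx <- unique(cases_df(lapply(1:12, function(i)
      c(sample(mats, 1), sample(clinical_groups(), 1)))))
    reg <- unique(cases_df(lapply(1:12, function(i)
      c(sample(mats, 1), sample(clinical_groups(), 1)))))
    tt <- cross_classify(idx, reg, 15)
    for (g in clinical_groups()) {
      expect_equal(unlist(tt[tt$group == g, c("tp", "fp", "fn", "tn")]),
                   oracle_cross_classify(idx, reg, 15, g))
    }
  }
})

test_that("Clopper-Pearson interval closed forms and dual-route equality", {
  # boundary closed forms hold to 1e-12
  n <- c(6, 8, 20)
  lo_xn <- proportion_ci(n, n)[, "low"]
  expect_equal(lo_xn, 0.025^(1 / n), tolerance = 1e-12)
  expect_equal(proportion_ci(n, n)[, "high"], rep(1, 3))
  ci0 <- proportion_ci(0, 20)
  expect_equal(ci0[, "low"], c(low = 0))
  expect_equal(ci0[, "high"], c(high = 1 - 0.025^(1 / 20)), tolerance = 1e-12)
  # equality with stats::binom.test on a grid (independent implementation)
  set.seed(61)
  for (i in 1:25) {
    nn <- sample(1:500, 1); xx <- sample(0:nn, 1)
    expect_equal(as.numeric(proportion_ci(xx, nn)),
                 as.numeric(stats::binom.test(xx, nn)$conf.int),
                 tolerance = 1e-10)
  }
  # interval contains the point estimate
  x <- c(0, 1, 5, 115, 319); n <- c(10, 10, 10, 319, 319)
  ci <- proportion_ci(x, n)
  expect_true(all(ci[, "low"] <= x / n & x / n <= ci[, "high"]))
  # width shrinks with n at a fixed proportion
  ns <- c(10, 20, 50, 100, 200, 500)
  w <- apply(proportion_ci(0.3 * ns, ns), 1, diff)
  expect_true(all(diff(w) < 0))
  expect_error(proportion_ci(5, 4), "invalid")
  expect_error(proportion_ci(1, 10, level = 1.2), "level")
})

test_that("reporting characteristics reproduce overall published-scale values", {
  tt <- data.frame(group = "any", tp = 580, fp = 166, fn = 380,
                   tn = 679736 - 580 - 166 - 380)
  rc <- reporting_characteristics(tt)
  expect_equal(rc$sensitivity, 580 / 960, tolerance = 1e-12)
  expect_equal(round_half_up(100 * rc$sensitivity), 60.4)
  expect_equal(round_half_up(100 * rc$ppv), 77.7)
  # rare disease: specificity and NPV round to at least 99.9%
  expect_gte(round_half_up(100 * rc$specificity), 99.9)
  expect_gte(round_half_up(100 * rc$npv), 99.9)
})

test_that("zero denominators are flagged undefined, not reported as zero", {
  tt <- data.frame(group = "melanoma", tp = 0, fp = 0, fn = 5, tn = 95)
  rc <- reporting_characteristics(tt)
  expect_equal(rc$sensitivity, 0)
  expect_true(is.na(rc$ppv))
  expect_equal(rc$specificity, 1)
  expect_match(rc$undefined, "ppv")
})

test_that("rates and IRRs are computed on unrounded values", {
  cts <- data.frame(group = c("melanoma", "any"),
                    registry_n = c(322, 988),
                    hospital_all_n = c(168, 1718),
                    hospital_index_n = c(142, 770))
  r <- rates_and_irr(cts, 679736)
  expect_equal(r$registry_rate[2], 1e5 * 988 / 679736, tolerance = 1e-12)
  expect_equal(round_half_up(r$registry_rate[1]), 47.4)
  expect_equal(round_half_up(r$irr_all[2]), 1.7)
  expect_equal(round_half_up(r$irr_index[2]), 0.8)
  # equal counts give IRR exactly 1; zero registry count is undefined
  r2 <- rates_and_irr(data.frame(group = "any", registry_n = c(5),
                                 hospital_all_n = 5, hospital_index_n = 5), 100)
  expect_equal(r2$irr_all, 1)
  r3 <- rates_and_irr(data.frame(group = "any", registry_n = 0,
                                 hospital_all_n = 3, hospital_index_n = 1), 100)
  expect_true(is.na(r3$irr_all))
})

test_that("false positives adjudicate as prevalent, misclassified or unexplained", {
  w <- make_window(data.frame(
    woman_id = c("w1", "w2", "w3"), maternity_id = c("m1", "m2", "m3"),
    delivery_date = as.Date("2004-06-01"), gestation_weeks = 40))
  registry <- data.frame(
    woman_id = c("w1", "w2"), registry_id = c("R1", "R2"),
    diagnosis_date = as.Date(c("2001-05-01", "2004-02-01")),
    group = c("breast", "colorectal"),
    first_notification_date = as.Date(c("2001-05-01", "2004-02-01")),
    stringsAsFactors = FALSE)
  reg_set <- registry_cases(registry, w)
  fp <- data.frame(
    maternity_id = c("m1", "m2", "m3"), woman_id = c("w1", "w2", "w3"),
    group = c("breast", "upper_gi", "respiratory"), stringsAsFactors = FALSE)
  adj <- adjudicate_fp(fp, registry, reg_set, w)
  expect_equal(adj$cases$category,
               c("prevalent", "misclassified_type", "unexplained"))
  expect_equal(sum(adj$counts), nrow(fp))
  # precedence: a prevalent same-group history wins over a different-group match
  registry2 <- rbind(registry, data.frame(
    woman_id = "w2", registry_id = "R3",
    diagnosis_date = as.Date("2000-01-01"), group = "upper_gi",
    first_notification_date = as.Date("2000-01-01")))
  adj2 <- adjudicate_fp(fp, registry2, registry_cases(registry2, w), w)
  expect_equal(adj2$cases$category[2], "prevalent")
})

test_that("timing bins follow calendar months, not 30-day blocks", {
  adm <- as.Date(c("2005-03-28", "2005-01-15", "2004-10-02", "2004-08-15",
                   "2005-04-02"))
  reg <- as.Date(rep("2005-03-02", 5))
  td <- timing_distribution(adm, reg)
  expect_equal(as.integer(td$counts),
               c(1L, 1L, 1L, 1L, 1L))  # same, 1-2, 3-5, 6+, after
  expect_equal(sum(td$proportions), 1)
  empty <- timing_distribution(as.Date(character(0)), as.Date(character(0)))
  expect_equal(sum(empty$counts), 0L)
  expect_equal(sum(empty$proportions), 0)
})
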