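mk_assign <- function(ids, groups) {
  data.frame(patient_id = ids, cluster = groups, stringsAsFactors = FALSE)
}

test_that("chi-square on a perfectly separated 2x2 table equals 20", {
  ids <- paste0("p", 1:20)
  cov <- data.frame(patient_id = ids,
                    flag = rep(c("yes", "no"), each = 10),
                    stringsAsFactors = FALSE)
  assign <- mk_assign(ids, rep(c("A", "B"), each = 10))
  res <- summarize_groups(cov, assign)
  row <- res$tests[res$tests$variable == "flag", ]
  expect_equal(row$test, "chi-square")
  expect_equal(row$statistic, 20.0)
})

test_that("identical group distributions give statistic 0 and p = 1", {
  ids <- paste0("p", 1:40)
  cov <- data.frame(patient_id = ids, flag = rep(c("x", "y"), 20),
                    stringsAsFactors = FALSE)
  assign <- mk_assign(ids, rep(c("A", "B"), each = 20))
  row <- summarize_groups(cov, assign)$tests
  expect_equal(row$statistic, 0)
  expect_equal(row$p_value, 1)
})

test_that("Mann-Whitney exact p on {1,2,3} vs {4,5,6} is 0.1", {
  ids <- paste0("p", 1:6)
  cov <- data.frame(patient_id = ids, marker = c(1, 2, 3, 4, 5, 6))
  assign <- mk_assign(ids, rep(c("A", "B"), each = 3))
  row <- summarize_groups(cov, assign)$tests
  expect_equal(row$test, "mann-whitney")
  expect_equal(row$statistic, 0) # U statistic
  expect_equal(row$p_value, 0.1, tolerance = 1e-12)
})

test_that("small 2x2 tables switch to Fisher's exact test", {
  ids <- paste0("p", 1:12)
  cov <- data.frame(patient_id = ids,
                    rare = c(rep("yes", 2), rep("no", 4),
                             rep("yes", 1), rep("no", 5)))
  assign <- mk_assign(ids, rep(c("A", "B"), each = 6))
  row <- summarize_groups(cov, assign)$tests
  expect_equal(row$test, "fisher")
  expect_true(row$p_value >= 0 && row$p_value <= 1)
})

test_that("more than two groups route to ANOVA or Kruskal-Wallis", {
  set.seed(19)
  ids <- paste0("p", 1:120)
  assign <- mk_assign(ids, rep(c("A", "B", "C", "D"), each = 30))
  cov <- data.frame(patient_id = ids,
                    gaussian = rnorm(120, rep(c(0, 0, 0, 2), each = 30)),
                    skewed = rexp(120, rep(c(1, 1, 1, 0.3), each = 30)))
  tests <- summarize_groups(cov, assign)$tests
  expect_equal(tests$test[tests$variable == "gaussian"], "anova")
  expect_equal(tests$test[tests$variable == "skewed"], "kruskal-wallis")
  expect_lt(tests$p_value[tests$variable == "gaussian"], 0.01)
})

test_that("categorical percentages sum to 100 within each group", {
  ch <- small_cohort(n = 80, seed = 23)
  assign <- mk_assign(sort(ch$covariates$patient_id),
                      rep(c("A", "B"), 40))
  res <- summarize_groups(ch$covariates, assign)
  summ <- res$summaries
  cat_rows <- summ[!is.na(summ$category), ]
  pct <- as.numeric(sub(".*\\(([0-9.]+)\\)", "\\1", cat_rows$summary))
  agg <- tapply(pct, paste(cat_rows$variable, cat_rows$group), sum)
  expect_true(all(abs(agg - 100) <= 0.1))
})

test_that("single-valued variables are reported degenerate, not tested", {
  ids <- paste0("p", 1:10)
  cov <- data.frame(patient_id = ids, constant = rep(5, 10))
  assign <- mk_assign(ids, rep(c("A", "B"), 5))
  row <- summarize_groups(cov, assign)$tests
  expect_equal(row$note, "degenerate")
  expect_true(is.na(row$p_value))
})

test_that("Kaplan-Meier estimate matches the hand product-limit", {
  rec <- data.frame(time = c(5, 10, 15), event = c(TRUE, TRUE, FALSE),
                    group = "all")
  km <- km_estimate(rec)
  expect_equal(km$survival[km$time == 5], 2 / 3)
  expect_equal(km$survival[km$time == 10], 1 / 3)
  # censored record never drops the curve
  expect_equal(min(km$survival), 1 / 3)

  # no events: survival stays at 1
  rec0 <- data.frame(time = c(3, 9, 28), event = FALSE, group = "all")
  expect_true(all(km_estimate(rec0)$survival == 1))

  # all events, no censoring: empirical survival function
  set.seed(20)
  tms <- sort(sample(1:100, 8))
  recf <- data.frame(time = tms, event = TRUE, group = "all")
  kmf <- km_estimate(recf)
  expect_equal(kmf$survival, 1 - seq_len(8) / 8)

  # independent hand oracle on a mixed pattern
  set.seed(21)
  tmix <- sample(1:20, 30, TRUE)
  emix <- runif(30) < 0.6
  kmm <- km_estimate(data.frame(time = tmix, event = emix, group = "all"))
  hand <- km_hand(tmix, emix)
  got <- kmm$survival[match(hand$time, kmm$time)]
  expect_equal(got, hand$surv, tolerance = 1e-12)
})

test_that("KM is non-increasing and starts at 1", {
  ch <- small_cohort(n = 100, seed = 24)
  surv <- survival_records(ch, truth_for(ch, sort(ch$truth$patient_id)))
  km <- km_estimate(surv)
  for (g in unique(km$group)) {
    s <- km$survival[km$group == g]
    expect_true(all(diff(s) <= 1e-12))
    expect_true(all(s <= 1))
  }
})

test_that("log-rank statistic is 0 for identical groups and matches the
           hand risk-table oracle", {
  base <- data.frame(time = c(2, 5, 9, 14), event = c(TRUE, TRUE, FALSE, TRUE))
  same <- rbind(cbind(base, group = "A"), cbind(base, group = "B"))
  res <- logrank_test(same)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$df, 1)

  # two-group toy: early events in A, late events in B
  toy <- data.frame(time = c(1, 2, 20, 25), event = TRUE,
                    group = c("A", "A", "B", "B"))
  res2 <- logrank_test(toy)
  expect_equal(res2$statistic,
               logrank_hand_2g(toy$time, toy$event, toy$group),
               tolerance = 1e-9)

  # label permutation invariance
  toy2 <- toy
  toy2$group <- c("B", "B", "A", "A")
  expect_equal(logrank_test(toy2)$statistic, res2$statistic)
})

test_that("log-rank input contracts are enforced", {
  one <- data.frame(time = 1:4, event = TRUE, group = "A")
  expect_error(logrank_test(one), "two groups")
  bad <- data.frame(time = c(0, 1), event = TRUE, group = c("A", "B"))
  expect_error(logrank_test(bad), "positive")
  expect_error(km_estimate(bad), "positive")
})

test_that("survival curves order the archetypes by mortality at 28 days", {
  ch <- generate_cohort(cohort_config(n_patients = 1000, seed = 26))
  surv <- survival_records(ch, truth_for(ch, sort(ch$truth$patient_id)))
  km <- km_estimate(surv)
  final <- vapply(c("RW", "DW", "RI", "DI"), function(g) {
    s <- km$survival[km$group == g]
    s[length(s)]
  }, 0)
  expect_true(final["RW"] < final[["DW"]] &&
                final["RW"] < final[["DI"]] &&
                final["RI"] > final[["DW"]] &&
                final["RI"] > final[["DI"]])
  expect_lt(logrank_test(surv)$p_value, 0.001)
})
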