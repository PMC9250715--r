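test_that("the 6-hour snapshot uses exactly window-1 information", {
  ch <- small_cohort(n = 25, seed = 27)
  snap <- build_feature_snapshot(ch, 6)
  traj <- build_trajectories(ch)
  organs <- sofa_rubric()$organs
  # with one visible window, latest == worst == window-1 subscores
  for (o in organs) {
    expect_equal(unname(snap$features[, paste0("sofa_", o, "_latest")]),
                 unname(traj$subscores[o, 1, ]))
    expect_equal(unname(snap$features[, paste0("sofa_", o, "_worst")]),
                 unname(traj$subscores[o, 1, ]))
  }
  expect_error(build_feature_snapshot(ch, 12), "cutoff")
})

test_that("snapshots are leakage-free: corrupting later data changes nothing", {
  ch <- small_cohort(n = 20, seed = 28, missing_rate = 0.2)
  for (t in c(6, 24, 48)) {
    snap1 <- build_feature_snapshot(ch, t)
    ch2 <- ch
    late <- ch2$measurements$hour >= t
    ch2$measurements$value[late] <- ch2$measurements$value[late] * 0 + 7
    snap2 <- build_feature_snapshot(ch2, t)
    expect_identical(snap1$features, snap2$features)
  }
  # a measurement at exactly hour t is excluded
  ch3 <- ch
  ch3$measurements <- rbind(
    ch3$measurements,
    data.frame(patient_id = ch$covariates$patient_id[1], hour = 24,
               variable = "bilirubin", value = 15, unit = "mg/dL"))
  expect_identical(build_feature_snapshot(ch3, 24)$features,
                   build_feature_snapshot(ch, 24)$features)
})

test_that("worst-so-far features are monotone in the cutoff", {
  ch <- small_cohort(n = 15, seed = 29)
  s6 <- build_feature_snapshot(ch, 6)$features
  s60 <- build_feature_snapshot(ch, 60)$features
  worst_cols <- grep("^sofa_.*_worst$", colnames(s6), value = TRUE)
  for (cl in worst_cols)
    expect_true(all(s60[, cl] >= s6[, cl]))
})

test_that("a perfectly separable label is learned almost exactly", {
  set.seed(30)
  n <- 400
  ids <- sprintf("q%03d", 1:n)
  driver <- runif(n)
  labels <- cut(driver, breaks = c(-Inf, 0.25, 0.5, 0.75, Inf),
                labels = c("RW", "DW", "RI", "DI"))
  feats <- cbind(driver = driver,
                 noise1 = rnorm(n), noise2 = rnorm(n))
  rownames(feats) <- ids
  snap <- structure(list(features = feats, patient_id = ids,
                         cutoff_hour = 6), class = "feature_snapshot")
  fit <- train_classifier(snap, labels, seed = 1)
  rep_ <- evaluate_classifier(fit, n_boot = 200, seed = 1)
  expect_gte(rep_$accuracy, 0.95)
  expect_true(rep_$ci["low"] <= rep_$accuracy &&
                rep_$accuracy <= rep_$ci["high"])
})

test_that("randomly permuted labels predict at chance level", {
  set.seed(31)
  n <- 400
  feats <- matrix(rnorm(n * 6), n,
                  dimnames = list(sprintf("q%03d", 1:n), paste0("f", 1:6)))
  labels <- sample(rep(c("RW", "DW", "RI", "DI"), each = n / 4))
  snap <- structure(list(features = feats, patient_id = rownames(feats),
                         cutoff_hour = 6), class = "feature_snapshot")
  fit <- train_classifier(snap, labels, seed = 2)
  rep_ <- evaluate_classifier(fit, n_boot = 200, seed = 2)
  n_test <- length(fit$test)
  se <- sqrt(0.25 * 0.75 / n_test)
  expect_lt(abs(rep_$accuracy - 0.25), 3 * se)
})

test_that("training and evaluation are deterministic given the seed", {
  ch <- small_cohort(n = 60, seed = 32)
  labels <- truth_for(ch, sort(ch$covariates$patient_id))
  snap <- build_feature_snapshot(ch, 24)
  f1 <- train_classifier(snap, labels, seed = 9)
  f2 <- train_classifier(snap, labels, seed = 9)
  expect_identical(predict(f1$model, f1$features[f1$test, ]),
                   predict(f2$model, f2$features[f2$test, ]))
  r1 <- evaluate_classifier(f1, n_boot = 150, seed = 4)
  r2 <- evaluate_classifier(f2, n_boot = 150, seed = 4)
  expect_identical(r1$accuracy, r2$accuracy)
  expect_identical(r1$ci, r2$ci)
})

test_that("confusion matrix rows sum to the test class counts", {
  ch <- small_cohort(n = 80, seed = 33)
  labels <- truth_for(ch, sort(ch$covariates$patient_id))
  snap <- build_feature_snapshot(ch, 24)
  fit <- train_classifier(snap, labels, seed = 5)
  rep_ <- evaluate_classifier(fit, n_boot = 120, seed = 5)
  truth_counts <- table(droplevels(fit$labels[fit$test]))
  expect_equal(as.vector(rowSums(rep_$confusion)),
               as.vector(truth_counts))
  expect_error(evaluate_classifier(fit, n_boot = 10), "at least 100")
})

test_that("the same patients are held out at every cutoff hour", {
  ch <- small_cohort(n = 50, seed = 34)
  labels <- truth_for(ch, sort(ch$covariates$patient_id))
  y <- factor(labels)
  split <- stratified_split(y, seed = 3)
  fits <- lapply(c(6, 24), function(t) {
    train_classifier(build_feature_snapshot(ch, t), labels, seed = 3,
                     split = split, ntree = 100)
  })
  expect_identical(fits[[1]]$test, fits[[2]]$test)
})

test_that("Shapley attribution is exact for additive models", {
  f <- function(M) rowSums(as.matrix(M))
  r <- shapley_attribution(f, data.frame(a = 2, b = 4),
                           data.frame(a = 0, b = 0),
                           n_permutations = 200, seed = 1)
  expect_equal(as.vector(r$values), c(2, 4), tolerance = 0.05)
  expect_equal(r$baseline[1] + sum(r$values), r$prediction[1],
               tolerance = 1e-9)
})

test_that("duplicated features share credit symmetrically", {
  f <- function(M) { M <- as.matrix(M); 1 * (M[, 1] > 0.5 & M[, 2] > 0.5) }
  r <- shapley_attribution(f, data.frame(x1 = 1, x2 = 1),
                           data.frame(x1 = 0, x2 = 0),
                           n_permutations = 600, seed = 2)
  expect_equal(r$values[1, "x1"], r$values[1, "x2"], tolerance = 0.05)
})

test_that("Monte-Carlo Shapley matches exhaustive enumeration at 3 features", {
  set.seed(35)
  w <- c(1.5, -2, 0.5)
  f <- function(M) {
    M <- as.matrix(M)
    M %*% w + 0.8 * M[, 1] * M[, 2]
  }
  bg <- data.frame(a = 0.2, b = -0.1, c = 0.4)
  x <- c(a = 1, b = 2, c = -1)
  exact <- shapley_exact(function(m) f(m), x, unlist(bg))
  mc <- shapley_attribution(f, as.data.frame(t(x)), bg,
                            n_permutations = 5000, seed = 3)
  expect_equal(as.vector(mc$values), exact, tolerance = 0.05)
})

test_that("attribution inputs are validated", {
  f <- function(M) rowSums(as.matrix(M))
  expect_error(shapley_attribution(f, data.frame(a = 1), data.frame(),
                                   n_permutations = 100), "non-empty")
  expect_error(shapley_attribution(f, data.frame(a = 1), data.frame(a = 0),
                                   n_permutations = 10), "at least 50")
})
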