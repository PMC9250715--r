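.snapshot_hours <- c(6, 24, 36, 48, 60)
.snapshot_labs <- c("lactate", "wbc", "temperature", "platelets",
                    "bilirubin", "creatinine", "map", "gcs",
                    "pao2_fio2_ratio")

#' Build a leakage-free feature snapshot
#'
#' Assembles the per-patient feature matrix available strictly before a
#' cutoff hour: demographics (age, sex), comorbidity index, ventilation
#' flag, the six organ SOFA subscores recomputed from measurements in
#' `[0, t)` only (both the latest window's value and the worst so far,
#' imputed within the visible windows), and the worst laboratory/vital
#' values in `[0, t)`. A measurement at exactly hour `t` is excluded.
#' Missing lab features are imputed by the cohort median with a paired
#' missingness-indicator column.
#'
#' @param cohort A `sepsis_cohort`.
#' @param t Cutoff hour, one of 6, 24, 36, 48, 60.
#' @return Object of class `feature_snapshot`: list with `features`
#'   (numeric matrix, one row per patient, sorted id), `patient_id`,
#'   `cutoff_hour`.
#' @export
build_feature_snapshot <- function(cohort, t) {
  if (!t %in% .snapshot_hours)
    stop("cutoff hour must be one of ", paste(.snapshot_hours, collapse = ", "))
  cov <- cohort$covariates[order(cohort$covariates$patient_id), ]
  ids <- cov$patient_id
  rec <- cohort$measurements[cohort$measurements$hour < t, , drop = FALSE]
  grid_t <- window_grid(horizon_hours = t, width_hours = 6)
  traj_t <- build_trajectories(rec, covariates = cov, grid = grid_t)
  stopifnot(identical(traj_t$patient_id, as.character(ids)))
  kt <- grid_t$n_windows
  organs <- sofa_rubric()$organs
  latest <- t(traj_t$subscores[, kt, , drop = TRUE]) # n x 6
  if (length(ids) == 1) latest <- matrix(latest, 1, 6)
  worst <- t(apply(traj_t$subscores, c(1, 3), max)) # n x 6
  colnames(latest) <- paste0("sofa_", organs, "_latest")
  colnames(worst) <- paste0("sofa_", organs, "_worst")

  # worst raw values over a single [0, t) window
  agg <- aggregate_windows(rec, window_grid(horizon_hours = t,
                                            width_hours = t))
  labm <- matrix(NA_real_, length(ids), length(.snapshot_labs),
                 dimnames = list(ids, paste0(.snapshot_labs, "_worst")))
  for (v in .snapshot_labs) {
    sel <- agg[agg$variable == v, ]
    labm[match(as.character(sel$patient_id), as.character(ids)), # nolint
         paste0(v, "_worst")] <- sel$value
  }
  miss <- 1 * is.na(labm)
  colnames(miss) <- sub("_worst$", "_missing", colnames(labm))
  for (j in seq_len(ncol(labm))) {
    med <- median(labm[, j], na.rm = TRUE)
    if (is.na(med)) med <- 0
    labm[is.na(labm[, j]), j] <- med
  }
  feat <- cbind(
    age = cov$age,
    sex_male = 1 * (cov$sex == "male"),
    comorbidity_index = cov$comorbidity_index,
    ventilated = 1 * cov$ventilated,
    septic_shock = if ("septic_shock" %in% names(cov))
      1 * cov$septic_shock else NULL,
    latest, worst, labm, miss
  )
  rownames(feat) <- ids
  structure(list(features = feat, patient_id = as.character(ids),
                 cutoff_hour = t),
            class = "feature_snapshot")
}

#' Train a subphenotype classifier
#'
#' Random forest (500 trees, square-root feature subsampling) on a
#' stratified 70/30 train/test split. The split and the forest are seeded,
#' so repeated calls are identical.
#'
#' @param snapshot A `feature_snapshot`.
#' @param labels Archetype (or cluster) label per patient, aligned with
#'   `snapshot$patient_id`.
#' @param seed Integer seed.
#' @param train_frac Training fraction (default 0.7).
#' @param ntree Number of trees (default 500).
#' @param split Optional precomputed list with `train` and `test` index
#'   vectors, to reuse one split across cutoff hours.
#' @return Object of class `subphenotype_model`: list with `model`,
#'   `train`, `test` (row indices), `labels`, `snapshot` metadata.
#' @export
train_classifier <- function(snapshot, labels, seed = 1, train_frac = 0.7,
                             ntree = 500, split = NULL) {
  y <- factor(labels)
  X <- as.data.frame(snapshot$features)
  stopifnot(nrow(X) == length(y))
  if (is.null(split)) {
    split <- stratified_split(y, train_frac = train_frac, seed = seed)
  }
  if (any(table(y[split$train]) == 0))
    stop("stratification error: a class is absent from the training split")
  set.seed(as.integer(seed))
  rf <- randomForest::randomForest(
    x = X[split$train, , drop = FALSE], y = droplevels(y[split$train]),
    ntree = ntree, mtry = max(1, floor(sqrt(ncol(X)))))
  structure(list(model = rf, train = split$train, test = split$test,
                 labels = y, features = X,
                 cutoff_hour = snapshot$cutoff_hour, seed = seed),
            class = "subphenotype_model")
}

#' Stratified train/test split
#'
#' @param y Factor of class labels.
#' @param train_frac Training fraction.
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(y, train_frac = 0.7, seed = 1) {
  set.seed(as.integer(seed))
  y <- factor(y)
  train <- integer(0)
  for (lv in levels(y)) {
    idx <- which(y == lv)
    n_tr <- max(1, round(train_frac * length(idx)))
    train <- c(train, sort(idx[sample.int(length(idx), n_tr)]))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(y), train))
}

#' Evaluate a fitted subphenotype classifier
#'
#' Held-out accuracy with a percentile bootstrap confidence interval
#' (resampling the test set with replacement), per-class precision and
#' recall, and the confusion matrix.
#'
#' @param fit A `subphenotype_model`.
#' @param n_boot Number of bootstrap resamples (>= 100, default 1000).
#' @param seed Integer seed for the bootstrap.
#' @param conf Confidence level (default 0.95).
#' @return Object of class `prediction_report`: list with `cutoff_hour`,
#'   `accuracy`, `ci` (low, high), `per_class` (precision/recall),
#'   `confusion` (rows = truth, columns = prediction).
#' @export
evaluate_classifier <- function(fit, n_boot = 1000, seed = 1, conf = 0.95) {
  if (n_boot < 100) stop("n_boot must be at least 100")
  if (!length(fit$test)) stop("empty test set")
  truth <- droplevels(fit$labels[fit$test])
  pred <- predict(fit$model, fit$features[fit$test, , drop = FALSE])
  pred <- factor(as.character(pred), levels = levels(truth))
  acc <- mean(pred == truth)
  set.seed(as.integer(seed))
  hits <- pred == truth
  boots <- vapply(seq_len(n_boot), function(b) {
    mean(hits[sample.int(length(hits), replace = TRUE)])
  }, 0)
  alpha <- (1 - conf) / 2
  ci <- unname(quantile(boots, c(alpha, 1 - alpha)))
  conf_mat <- table(truth = truth, prediction = pred)
  prec <- diag(conf_mat) / pmax(colSums(conf_mat), 1)
  rec <- diag(conf_mat) / pmax(rowSums(conf_mat), 1)
  structure(list(cutoff_hour = fit$cutoff_hour, accuracy = acc,
                 ci = c(low = min(ci[1], acc), high = max(ci[2], acc)),
                 per_class = data.frame(class = levels(truth),
                                        precision = as.numeric(prec),
                                        recall = as.numeric(rec)),
                 confusion = conf_mat, n_boot = n_boot),
            class = "prediction_report")
}

#' @export
print.prediction_report <- function(x, ...) {
  cat(sprintf("Prediction at %d h: accuracy %.3f (95%% CI %.3f-%.3f)\n",
              x$cutoff_hour, x$accuracy, x$ci["low"], x$ci["high"]))
  invisible(x)
}

#' Prediction accuracy at successive cutoff hours
#'
#' Runs one train/evaluate cycle per cutoff hour on an identical patient
#' split (the same patients are held out at every cutoff), reporting how
#' early the subphenotypes become predictable.
#'
#' @param cohort A `sepsis_cohort`.
#' @param labels Subphenotype label per patient (sorted patient id).
#' @param times Cutoff hours (default 6, 24, 36, 48, 60).
#' @param seed Integer seed.
#' @param n_boot Bootstrap resamples per report.
#' @param ntree Trees per forest.
#' @return List of `prediction_report`s ordered by cutoff hour.
#' @export
accuracy_over_time <- function(cohort, labels, times = .snapshot_hours,
                               seed = 1, n_boot = 1000, ntree = 500) {
  times <- sort(times)
  y <- factor(labels)
  split <- stratified_split(y, seed = seed)
  lapply(times, function(t) {
    snap <- build_feature_snapshot(cohort, t)
    fit <- train_classifier(snap, labels, seed = seed, ntree = ntree,
                            split = split)
    evaluate_classifier(fit, n_boot = n_boot, seed = seed)
  })
}

#' Monte-Carlo permutation Shapley attribution
#'
#' Model-agnostic Shapley values estimated by sampling random feature
#' orderings: for each ordering, features are switched one at a time
#' from a background draw to the explained instance and the marginal change
#' in the model output is credited to the switched feature (the
#' Strumbelj-Kononenko sampling scheme). Within each sampled ordering the
#' marginal contributions telescope, so per instance the attributions sum
#' exactly to `f(x)` minus the average background prediction used
#' (local accuracy).
#'
#' @param f Prediction function: takes a data frame / matrix of rows,
#'   returns one number per row (e.g. a class probability).
#' @param X Instances to explain (data frame or matrix).
#' @param background Background data (data frame or matrix) supplying
#'   reference draws for absent features; must be non-empty.
#' @param n_permutations Sampled orderings per instance (>= 50, default
#'   200).
#' @param seed Integer seed.
#' @return Object of class `attribution_report`: list with `values`
#'   (instances x features signed Shapley values), `baseline` (per-instance
#'   average background prediction), `prediction` (f at each instance),
#'   `mean_abs` (per-feature mean absolute value), `n_permutations`,
#'   `seed`.
#' @export
shapley_attribution <- function(f, X, background, n_permutations = 200,
                                seed = 1) {
  X <- as.data.frame(X)
  background <- as.data.frame(background)
  if (!nrow(background)) stop("background sample must be non-empty")
  if (n_permutations < 50) stop("n_permutations must be at least 50")
  p <- ncol(X)
  set.seed(as.integer(seed))
  vals <- matrix(0, nrow(X), p, dimnames = list(rownames(X), colnames(X)))
  baseline <- numeric(nrow(X))
  fx <- as.numeric(f(X))
  for (i in seq_len(nrow(X))) {
    xi <- X[i, , drop = FALSE]
    # build all evaluation rows for all orderings, one f call
    bg_idx <- sample.int(nrow(background), n_permutations, replace = TRUE)
    orders <- replicate(n_permutations, sample.int(p), simplify = FALSE)
    block <- vector("list", n_permutations)
    for (s in seq_len(n_permutations)) {
      z <- background[rep(bg_idx[s], p + 1), , drop = FALSE]
      ord <- orders[[s]]
      for (j in seq_len(p)) {
        cols <- ord[seq_len(j)]
        z[j + 1, cols] <- xi[1, cols]
      }
      block[[s]] <- z
    }
    evals <- as.numeric(f(do.call(rbind, block)))
    phi <- numeric(p)
    base_i <- 0
    for (s in seq_len(n_permutations)) {
      off <- (s - 1) * (p + 1)
      seqv <- evals[off + seq_len(p + 1)]
      contrib <- diff(seqv)
      phi[orders[[s]]] <- phi[orders[[s]]] + contrib
      base_i <- base_i + seqv[1]
    }
    vals[i, ] <- phi / n_permutations
    baseline[i] <- base_i / n_permutations
  }
  structure(list(values = vals, baseline = baseline, prediction = fx,
                 mean_abs = colMeans(abs(vals)),
                 n_permutations = n_permutations, seed = seed),
            class = "attribution_report")
}

#' Shapley attribution of a subphenotype model
#'
#' Explains the predicted-class probability of a fitted subphenotype
#' classifier for a set of held-out patients, with training rows as the
#' background.
#'
#' @param fit A `subphenotype_model`.
#' @param instances Row indices (into the snapshot) to explain; defaults to
#'   up to 50 test rows.
#' @param n_permutations,seed Passed to [shapley_attribution()].
#' @return An `attribution_report` with an extra `class` element giving the
#'   explained (predicted) class per instance, and `mean_abs_by_class`.
#' @export
explain_model <- function(fit, instances = NULL, n_permutations = 200,
                          seed = 1) {
  if (is.null(instances)) instances <- head(fit$test, 50)
  X <- fit$features[instances, , drop = FALSE]
  pred_class <- as.character(predict(fit$model, X))
  bg <- fit$features[fit$train, , drop = FALSE]
  set.seed(as.integer(seed))
  if (nrow(bg) > 100) bg <- bg[sort(sample.int(nrow(bg), 100)), , drop = FALSE]
  reports <- vector("list", length(instances))
  for (i in seq_along(instances)) {
    cls <- pred_class[i]
    f <- function(M) predict(fit$model, M, type = "prob")[, cls]
    reports[[i]] <- shapley_attribution(f, X[i, , drop = FALSE], bg,
                                        n_permutations = n_permutations,
                                        seed = seed + i)
  }
  vals <- do.call(rbind, lapply(reports, function(r) r$values))
  rownames(vals) <- rownames(X)
  by_class <- do.call(rbind, lapply(split(seq_along(instances), pred_class),
                                    function(ix)
                                      colMeans(abs(vals[ix, , drop = FALSE]))))
  structure(list(values = vals,
                 baseline = vapply(reports, function(r) r$baseline[1], 0),
                 prediction = vapply(reports, function(r) r$prediction[1], 0),
                 class = pred_class,
                 mean_abs = colMeans(abs(vals)),
                 mean_abs_by_class = by_class,
                 n_permutations = n_permutations, seed = seed),
            class = "attribution_report")
}
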