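#' Table-1-style comparison of subphenotypes
#'
#' Compares every covariate across the assigned groups. Categorical
#' variables get an R x C chi-square test without continuity correction,
#' switching to Fisher's exact test for 2 x 2 tables with any expected cell
#' below 5. Continuous variables are screened for normality per group
#' (Shapiro-Wilk at alpha = 0.05); if every group passes, two groups are
#' compared with Student's t-test and more with one-way ANOVA, otherwise
#' with the Mann-Whitney or Kruskal-Wallis test. Summaries are mean (SD)
#' for variables passing the screen and median [IQR] otherwise; categorical
#' summaries are count (percent within group). Variables with a single
#' observed value are reported as degenerate and not tested. All tests are
#' two-tailed.
#'
#' @param covariates Data frame with `patient_id` and the variables to
#'   compare; logical/character/factor columns are treated as categorical.
#' @param assignment `cluster_assignment` or data frame with `patient_id`
#'   and a group column (`label` preferred, else `cluster`).
#' @return Object of class `group_comparison`: list with `tests` (one row
#'   per variable: `variable`, `type`, `test`, `statistic`, `p_value`,
#'   `note`) and `summaries` (long data frame: `variable`, `group`,
#'   `category`, `summary`).
#' @export
summarize_groups <- function(covariates, assignment) {
  gcol <- if ("label" %in% names(assignment)) "label" else "cluster"
  idx <- match(covariates$patient_id, assignment$patient_id)
  if (anyNA(idx)) stop("covariates must cover only assigned patients")
  grp <- factor(assignment[[gcol]][idx])
  vars <- setdiff(names(covariates), "patient_id")
  tests <- list(); summaries <- list()
  for (v in vars) {
    x <- covariates[[v]]
    categorical <- is.character(x) || is.factor(x) || is.logical(x)
    if (categorical) {
      res <- .compare_categorical(x, grp, v)
    } else {
      res <- .compare_continuous(x, grp, v)
    }
    tests[[v]] <- res$test
    summaries[[v]] <- res$summary
  }
  structure(list(tests = do.call(rbind, tests),
                 summaries = do.call(rbind, summaries)),
            class = "group_comparison")
}

.compare_categorical <- function(x, grp, v) {
  x <- factor(x)
  tab <- table(x, grp)
  summ <- do.call(rbind, lapply(levels(grp), function(g) {
    cnt <- tab[, g]
    pct <- if (sum(cnt) > 0) 100 * cnt / sum(cnt) else rep(0, length(cnt))
    data.frame(variable = v, group = g, category = rownames(tab),
               summary = sprintf("%d (%.1f)", cnt, pct),
               stringsAsFactors = FALSE)
  }))
  if (nlevels(x) < 2 || nlevels(grp) < 2) {
    tst <- data.frame(variable = v, type = "categorical", test = NA,
                      statistic = NA_real_, p_value = NA_real_,
                      note = "degenerate", stringsAsFactors = FALSE)
    return(list(test = tst, summary = summ))
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (all(dim(tab) == c(2, 2)) && any(expected < 5)) {
    ft <- fisher.test(tab)
    tst <- data.frame(variable = v, type = "categorical", test = "fisher",
                      statistic = NA_real_, p_value = ft$p.value, note = "",
                      stringsAsFactors = FALSE)
  } else {
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    tst <- data.frame(variable = v, type = "categorical",
                      test = "chi-square",
                      statistic = unname(ct$statistic),
                      p_value = ct$p.value, note = "",
                      stringsAsFactors = FALSE)
  }
  list(test = tst, summary = summ)
}

.shapiro_ok <- function(x) {
  x <- x[!is.na(x)]
  # the screen is powerless below a handful of observations; such groups
  # are routed to the rank-based tests
  if (length(x) < 4 || length(unique(x)) < 3) return(FALSE)
  if (length(x) > 5000) x <- x[seq(1, length(x), length.out = 5000)]
  shapiro.test(x)$p.value >= 0.05
}

.compare_continuous <- function(x, grp, v) {
  splits <- split(x, grp)
  normal <- all(vapply(splits, .shapiro_ok, TRUE))
  summ <- do.call(rbind, lapply(names(splits), function(g) {
    xi <- splits[[g]][!is.na(splits[[g]])]
    s <- if (normal) {
      sprintf("%.1f (%.1f)", mean(xi), sd(xi))
    } else {
      q <- quantile(xi, c(0.25, 0.5, 0.75), names = FALSE)
      sprintf("%.1f [%.1f-%.1f]", q[2], q[1], q[3])
    }
    data.frame(variable = v, group = g, category = NA_character_,
               summary = s, stringsAsFactors = FALSE)
  }))
  if (length(unique(x[!is.na(x)])) < 2 || nlevels(grp) < 2) {
    tst <- data.frame(variable = v, type = "continuous", test = NA,
                      statistic = NA_real_, p_value = NA_real_,
                      note = "degenerate", stringsAsFactors = FALSE)
    return(list(test = tst, summary = summ))
  }
  if (nlevels(grp) == 2) {
    if (normal) {
      tt <- t.test(x ~ grp, var.equal = TRUE)
      tst <- c("t-test", unname(tt$statistic), tt$p.value)
    } else {
      wt <- suppressWarnings(wilcox.test(x ~ grp))
      tst <- c("mann-whitney", unname(wt$statistic), wt$p.value)
    }
  } else {
    if (normal) {
      av <- summary(aov(x ~ grp))[[1]]
      tst <- c("anova", av[["F value"]][1], av[["Pr(>F)"]][1])
    } else {
      kw <- kruskal.test(x ~ grp)
      tst <- c("kruskal-wallis", unname(kw$statistic), kw$p.value)
    }
  }
  list(test = data.frame(variable = v, type = "continuous", test = tst[1],
                         statistic = as.numeric(tst[2]),
                         p_value = as.numeric(tst[3]), note = "",
                         stringsAsFactors = FALSE),
       summary = summ)
}

#' Kaplan-Meier survival estimate per group
#'
#' Product-limit estimator `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` over the
#' distinct event times of each group; censored records reduce the risk set
#' only. All deaths at a tied time are processed against the risk set at
#' that time.
#'
#' @param records Data frame with `time` (days, > 0), `event` (logical or
#'   0/1 death indicator) and `group`.
#' @return Data frame, one row per distinct time per group: `group`, `time`,
#'   `n_risk`, `n_event`, `survival`.
#' @export
km_estimate <- function(records) {
  .validate_survival(records)
  fit <- survival::survfit(survival::Surv(time, event) ~ group,
                           data = records)
  strata <- if (is.null(fit$strata)) {
    rep(as.character(records$group[1]), length(fit$time))
  } else {
    rep(sub("^group=", "", names(fit$strata)), fit$strata)
  }
  data.frame(group = strata, time = fit$time, n_risk = fit$n.risk,
             n_event = fit$n.event, survival = fit$surv,
             stringsAsFactors = FALSE)
}

#' Log-rank test across groups
#'
#' Observed-minus-expected event counts over the pooled event times with
#' hypergeometric variance; the statistic is chi-squared with one degree of
#' freedom fewer than the number of groups.
#'
#' @inheritParams km_estimate
#' @return List with `statistic`, `df`, `p_value`.
#' @export
logrank_test <- function(records) {
  .validate_survival(records)
  if (length(unique(records$group)) < 2)
    stop("log-rank test needs at least two groups")
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group,
                            data = records)
  df <- length(sd_$n) - 1
  list(statistic = unname(sd_$chisq), df = df,
       p_value = pchisq(sd_$chisq, df, lower.tail = FALSE))
}

.validate_survival <- function(records) {
  stopifnot(all(c("time", "event", "group") %in% names(records)))
  if (any(records$time <= 0)) stop("survival times must be positive")
  grp_n <- table(records$group)
  if (any(grp_n == 0) || !nrow(records))
    stop("every group needs at least one record")
  invisible(TRUE)
}

#' Survival records from a cohort and an assignment
#'
#' @param cohort A `sepsis_cohort` with outcomes attached.
#' @param groups Vector of group labels aligned with the cohort's patients
#'   (sorted patient id), or a `cluster_assignment`.
#' @return Data frame with `patient_id`, `time`, `event`, `group`.
#' @export
survival_records <- function(cohort, groups) {
  out <- cohort$outcomes
  if (is.null(out)) stop("cohort has no outcomes")
  out <- out[order(out$patient_id), ]
  if (inherits(groups, "data.frame")) {
    gcol <- if ("label" %in% names(groups)) "label" else "cluster"
    groups <- groups[[gcol]][match(out$patient_id, groups$patient_id)]
  }
  data.frame(patient_id = out$patient_id, time = out$survival_time,
             event = out$death, group = groups, stringsAsFactors = FALSE)
}
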