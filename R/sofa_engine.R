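#' Windowing grid for SOFA trajectories
#'
#' Half-open, left-closed 6-hour windows partitioning the observation
#' horizon: window k covers hours `[width * (k - 1), width * k)`. The default
#' 72-hour horizon gives the 12 windows of a standard SOFA trajectory; a
#' measurement at exactly hour 6 belongs to window 2.
#'
#' @param horizon_hours Observation horizon in hours (default 72).
#' @param width_hours Window width in hours (default 6).
#' @return Object of class `window_grid` with `n_windows` and the window
#'   boundaries.
#' @export
window_grid <- function(horizon_hours = 72, width_hours = 6) {
  stopifnot(horizon_hours > 0, width_hours > 0,
            horizon_hours %% width_hours == 0)
  n <- as.integer(horizon_hours / width_hours)
  structure(list(horizon_hours = horizon_hours, width_hours = width_hours,
                 n_windows = n,
                 starts = width_hours * (seq_len(n) - 1),
                 ends = width_hours * seq_len(n)),
            class = "window_grid")
}

#' Aggregate raw measurements to per-window worst values
#'
#' Assigns each measurement to its 6-hour window and keeps, per patient,
#' window and variable, the value that maximizes the resulting SOFA subscore:
#' the minimum for PaO2/FiO2, platelets, MAP, GCS and urine output, the
#' maximum for bilirubin, creatinine and vasopressor doses. Daily urine
#' output (`urine_24h`, mL/day) is divided by 4 and recorded as `urine_6h`
#' before comparison. Measurements at or beyond the horizon are dropped;
#' windows with no observation are simply absent from the result.
#'
#' @param records Data frame with columns `patient_id`, `hour`, `variable`,
#'   `value` (a `unit` column is allowed and ignored).
#' @param grid A [window_grid()].
#' @return `data.table` with columns `patient_id`, `window`, `variable`,
#'   `value` (the worst value).
#' @export
aggregate_windows <- function(records, grid = window_grid()) {
  stopifnot(all(c("patient_id", "hour", "variable", "value") %in%
                names(records)))
  dt <- data.table::as.data.table(records)[
    , c("patient_id", "hour", "variable", "value"), with = FALSE]
  unknown <- setdiff(unique(dt$variable), .known_variables())
  if (length(unknown))
    stop("unknown measurement variable(s): ", paste(unknown, collapse = ", "))
  if (any(dt$hour < 0)) stop("hour must be >= 0")
  .check_measurement_ranges(dt)
  dt <- dt[hour < grid$horizon_hours]
  dt[, window := as.integer(hour %/% grid$width_hours) + 1L]
  # daily urine to the 6-h scale
  dt[variable == "urine_24h", `:=`(value = value / 4, variable = "urine_6h")]
  dt[, dir := .worst_direction(variable)]
  out <- dt[, .(value = if (dir[1] == "min") min(value) else max(value)),
            by = .(patient_id, window, variable)]
  data.table::setkey(out, patient_id, window, variable)
  out[]
}

.check_measurement_ranges <- function(dt) {
  nonneg <- c("platelets", "urine_6h", "urine_24h", "dopamine", "dobutamine",
              "epinephrine", "norepinephrine", "bilirubin", "creatinine",
              "pao2_fio2_ratio")
  variable <- value <- NULL
  bad <- dt[variable %in% nonneg & value < 0]
  if (nrow(bad))
    stop("negative values for variable(s): ",
         paste(unique(bad$variable), collapse = ", "))
  badg <- dt[variable == "gcs" & (value < 3 | value > 15)]
  if (nrow(badg)) stop("gcs values outside [3, 15]")
  invisible(TRUE)
}

#' Impute a subscore trajectory
#'
#' Completes a 6 x K organ-subscore matrix with missing entries: per organ
#' row, last observation carried forward (LOCF) first, then next observation
#' carried backward (NOCB) for leading gaps; rows with no observation at all
#' are set to 0 throughout. The operation is total and idempotent.
#'
#' @param subscores Integer matrix (organs x windows) with `NA` for missing.
#' @return Completed integer matrix of the same shape.
#' @export
impute_trajectory <- function(subscores) {
  m <- as.matrix(subscores)
  out <- do.call(rbind, lapply(seq_len(nrow(m)),
                               function(i) .locf_nocb_zero(m[i, ])))
  dimnames(out) <- dimnames(m)
  storage.mode(out) <- "integer"
  out
}

.locf_nocb_zero <- function(x) {
  if (all(is.na(x))) return(rep(0L, length(x)))
  x <- zoo::na.locf(x, na.rm = FALSE)
  x <- zoo::na.locf(x, fromLast = TRUE, na.rm = FALSE)
  x
}

#' Build SOFA trajectories for a cohort
#'
#' Composes worst-value window aggregation, rubric scoring and LOCF/NOCB/zero
#' imputation into per-patient SOFA trajectories: a 6 x K integer subscore
#' matrix, its column-sum totals and the pre-imputation observability mask.
#' Row order is sorted patient id and the result is invariant to the order of
#' the input records.
#'
#' @param x A `sepsis_cohort` (see [generate_cohort()]) or a data frame of
#'   measurement records.
#' @param covariates Optional covariate table supplying the patient roster
#'   and the `ventilated` flag; taken from `x` when `x` is a cohort. Patients
#'   on the roster without measurements get all-zero trajectories.
#' @param grid A [window_grid()].
#' @param rubric A [sofa_rubric()].
#' @return Object of class `sofa_trajectories`: list with `patient_id`,
#'   `totals` (n x K integer matrix), `subscores` (6 x K x n array),
#'   `observed` (logical 6 x K x n array) and `grid`.
#' @export
build_trajectories <- function(x, covariates = NULL, grid = window_grid(),
                               rubric = sofa_rubric()) {
  if (inherits(x, "sepsis_cohort")) {
    records <- x$measurements
    if (is.null(covariates)) covariates <- x$covariates
  } else {
    records <- x
  }
  if (NROW(records) == 0 && is.null(covariates))
    stop("empty cohort: no measurements and no covariates")
  agg <- aggregate_windows(records, grid)
  ids <- if (!is.null(covariates)) {
    sort(unique(as.character(covariates$patient_id)))
  } else {
    sort(unique(as.character(agg$patient_id)))
  }
  if (!length(ids)) stop("empty cohort")
  K <- grid$n_windows
  organs <- sofa_rubric()$organs
  vent <- rep(FALSE, length(ids))
  names(vent) <- ids
  if (!is.null(covariates) && "ventilated" %in% names(covariates))
    vent[as.character(covariates$patient_id)] <- covariates$ventilated

  # wide worst-value table over the full (patient, window) lattice
  agg[, patient_id := as.character(patient_id)]
  agg <- agg[patient_id %in% ids]
  lattice <- data.table::CJ(patient_id = ids, window = seq_len(K))
  if (nrow(agg)) {
    wide <- data.table::dcast(agg, patient_id + window ~ variable,
                              value.var = "value")
    wide <- wide[lattice, on = c("patient_id", "window")]
  } else {
    wide <- lattice
  }
  data.table::setkey(wide, patient_id, window)
  gv <- function(nm) {
    if (nm %in% names(wide)) wide[[nm]] else rep(NA_real_, nrow(wide))
  }
  vvent <- vent[wide$patient_id]
  raw <- rbind(
    respiration    = .score_respiration(gv("pao2_fio2_ratio"), vvent),
    coagulation    = .score_coagulation(gv("platelets")),
    liver          = .score_liver(gv("bilirubin")),
    cardiovascular = .score_cardiovascular(gv("map"), gv("dopamine"),
                                           gv("dobutamine"),
                                           gv("epinephrine"),
                                           gv("norepinephrine")),
    cns            = .score_cns(gv("gcs")),
    renal          = .score_renal(gv("creatinine"), gv("urine_6h"))
  )
  n <- length(ids)
  sub <- array(as.integer(raw), dim = c(6, K, n),
               dimnames = list(organs, NULL, ids))
  # rows of `wide` are ordered patient-major then window; raw columns follow
  observed <- !is.na(sub)
  totals <- matrix(0L, n, K, dimnames = list(ids, NULL))
  for (i in seq_len(n)) {
    si <- impute_trajectory(matrix(sub[, , i], 6, K,
                                   dimnames = list(organs, NULL)))
    sub[, , i] <- si
    totals[i, ] <- colSums(si)
  }
  structure(list(patient_id = ids, totals = totals, subscores = sub,
                 observed = observed, grid = grid),
            class = "sofa_trajectories")
}

#' @export
print.sofa_trajectories <- function(x, ...) {
  cat(sprintf("SOFA trajectories: %d patients x %d windows (%d-h horizon)\n",
              nrow(x$totals), x$grid$n_windows, x$grid$horizon_hours))
  cat(sprintf("mean baseline SOFA (window 1): %.2f\n", mean(x$totals[, 1])))
  invisible(x)
}

#' Extract the trajectory matrix
#'
#' @param traj A `sofa_trajectories` object or a bare numeric matrix.
#' @return Numeric matrix, patients in rows (sorted id), windows in columns.
#' @export
trajectory_matrix <- function(traj) {
  if (inherits(traj, "sofa_trajectories")) return(traj$totals)
  as.matrix(traj)
}
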