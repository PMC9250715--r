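#' Default archetype specifications
#'
#' The four latent trajectory archetypes the generator draws from, shaped
#' like the subphenotypes recovered from real ICU cohorts: Rapidly Worsening
#' (RW, total SOFA rising 4.5 to 7.2), Delayed Worsening (DW, 5.2 falling to
#' 3.7 at 48 h then rising to 4.8), Rapidly Improving (RI, 5.5 falling to
#' 2.8) and Delayed Improving (DI, 4.0 rising to 5.2 at 36 h then falling to
#' 3.5); interior windows are linear interpolations between those anchors.
#' Default prevalences (13.1/20.5/41.3/25.1%) and in-hospital mortality
#' (28.3/10.6/5.5/10.7%) mirror the development-cohort subphenotypes.
#'
#' @param noise_sd Per-window Gaussian noise (SOFA points) on the latent
#'   total before subscore decomposition; recycled over archetypes.
#' @return Named list of `archetype_spec` lists with fields `name`,
#'   `mean_curve` (12 values), `noise_sd`, `prevalence`, `mortality_rate`.
#' @export
archetype_specs <- function(noise_sd = 1.0) {
  interp <- function(anchors_w, anchors_v) {
    stats::approx(anchors_w, anchors_v, xout = 1:12)$y
  }
  curves <- list(
    RW = interp(c(1, 12), c(4.5, 7.2)),
    DW = interp(c(1, 8, 12), c(5.2, 3.7, 4.8)),
    RI = interp(c(1, 12), c(5.5, 2.8)),
    DI = interp(c(1, 6, 12), c(4.0, 5.2, 3.5))
  )
  prev <- c(RW = 0.131, DW = 0.205, RI = 0.413, DI = 0.251)
  mort <- c(RW = 0.283, DW = 0.106, RI = 0.055, DI = 0.107)
  noise_sd <- rep_len(noise_sd, 4)
  out <- lapply(seq_along(curves), function(i) {
    nm <- names(curves)[i]
    structure(list(name = nm, mean_curve = curves[[i]],
                   noise_sd = noise_sd[i], prevalence = unname(prev[nm]),
                   mortality_rate = unname(mort[nm])),
              class = "archetype_spec")
  })
  names(out) <- names(curves)
  out
}

# fixed archetype-specific organ weights used to split a total score into
# six subscores; worsening weighted to liver/coagulation/respiration,
# improving to cardiovascular/CNS, mirroring the organ-pattern differences
# reported for the subphenotypes
.archetype_weights <- function() {
  organs <- c("respiration", "coagulation", "liver",
              "cardiovascular", "cns", "renal")
  w <- rbind(
    RW = c(0.22, 0.22, 0.22, 0.14, 0.08, 0.12),
    DW = c(0.22, 0.20, 0.08, 0.12, 0.18, 0.20),
    RI = c(0.12, 0.08, 0.06, 0.30, 0.24, 0.20),
    DI = c(0.22, 0.20, 0.10, 0.26, 0.12, 0.10)
  )
  colnames(w) <- organs
  w
}

#' Cohort generator configuration
#'
#' @param n_patients Number of patients (>= 8 so each archetype can appear
#'   at least twice).
#' @param archetypes List of archetype specifications, see
#'   [archetype_specs()].
#' @param missing_rate Probability, per (patient, variable, window), that a
#'   variable has no measurement in that window (missing completely at
#'   random).
#' @param full_missing_rate Probability, per (patient, variable), that the
#'   variable is absent for the whole 72 h.
#' @param seed Integer seed; identical configurations generate identical
#'   cohorts.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 2000, archetypes = archetype_specs(),
                          missing_rate = 0.2, full_missing_rate = 0.02,
                          seed = 1) {
  cfg <- structure(list(n_patients = as.integer(n_patients),
                        archetypes = archetypes,
                        missing_rate = missing_rate,
                        full_missing_rate = full_missing_rate,
                        seed = as.integer(seed)),
                   class = "cohort_config")
  validate_cohort_config(cfg)
  cfg
}

#' @rdname cohort_config
#' @param config Object to validate.
#' @export
validate_cohort_config <- function(config) {
  if (!is.list(config$archetypes) || !length(config$archetypes))
    stop("configuration error: archetypes must be a non-empty list")
  prev <- vapply(config$archetypes, function(a) a$prevalence, 0)
  if (abs(sum(prev) - 1) > 1e-9)
    stop("configuration error: archetype prevalences must sum to 1")
  for (a in config$archetypes) {
    if (length(a$mean_curve) != 12 || any(a$mean_curve < 0) ||
        any(a$mean_curve > 24))
      stop("configuration error: mean_curve must be 12 values in [0, 24]")
    if (a$noise_sd < 0) stop("configuration error: noise_sd must be >= 0")
    if (a$mortality_rate < 0 || a$mortality_rate > 1)
      stop("configuration error: mortality_rate must be in [0, 1]")
  }
  if (!is.null(config$archetypes$RW)) {
    cv <- config$archetypes$RW$mean_curve
    if (cv[12] <= cv[1]) stop("configuration error: RW curve must rise")
  }
  if (!is.null(config$archetypes$RI)) {
    cv <- config$archetypes$RI$mean_curve
    if (cv[12] >= cv[1]) stop("configuration error: RI curve must fall")
  }
  if (config$n_patients < 8)
    stop("configuration error: n_patients must be >= 8")
  for (r in c("missing_rate", "full_missing_rate")) {
    if (config[[r]] < 0 || config[[r]] >= 1)
      stop("configuration error: ", r, " must be in [0, 1)")
  }
  invisible(config)
}

# split integer totals (length N) into six integer subscores in 0..4 summing
# to the total, by largest-remainder rounding of archetype organ weights
.decompose_totals <- function(totals, weights) {
  target <- pmin(pmax(round(totals), 0), 24)
  M <- target %o% weights
  base <- pmin(floor(M), 4)
  pri <- ifelse(base < 4, M - floor(M), -Inf)
  need <- target - rowSums(base)
  while (any(need > 0)) {
    rows <- which(need > 0)
    j <- max.col(pri[rows, , drop = FALSE], ties.method = "first")
    idx <- cbind(rows, j)
    base[idx] <- base[idx] + 1
    pri[idx] <- ifelse(base[idx] < 4, pri[idx] - 1, -Inf)
    need[rows] <- need[rows] - 1
  }
  storage.mode(base) <- "integer"
  colnames(base) <- names(weights)
  base
}

# band-midpoint measurement values indexed by subscore 0..4; chosen so the
# scoring rubric maps each value back to exactly the generating subscore
.backgen_tables <- function() {
  list(
    pao2_fio2_ratio = c(450, 350, 250, 150, 50),
    platelets       = c(200, 125, 75, 35, 10),
    bilirubin       = c(0.6, 1.55, 3.95, 8.95, 15),
    gcs             = c(15, 13, 11, 7, 4),
    creatinine      = c(0.8, 1.55, 2.7, 4.2, 6.0),
    urine_6h        = c(400, 350, 300, 100, 30),
    map             = c(80, 65, 65, 65, 65)
  )
}

#' Generate a synthetic ICU sepsis cohort
#'
#' Draws each patient's latent archetype by prevalence, builds a noisy copy
#' of the archetype mean total-SOFA curve, decomposes it into six integer
#' organ subscores with fixed archetype-specific organ weights, and
#' back-generates raw measurement records by picking, for every subscore,
#' a value in the interior of the corresponding rubric band (so the scoring
#' engine recovers the generated subscores exactly). Auxiliary predictor
#' streams (lactate, white-cell count, temperature) and covariates (age,
#' sex, comorbidity index, ventilation, ICU unit, septic shock) are drawn
#' with archetype-linked distributions; measurement-level missingness and
#' 28-day outcomes are then attached. Identical configurations give
#' identical cohorts.
#'
#' @param config A [cohort_config()].
#' @return Object of class `sepsis_cohort`: list with `measurements`,
#'   `covariates`, `outcomes`, `truth` (patient_id, archetype) and `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  set.seed(config$seed)
  n <- config$n_patients
  ids <- sprintf("P%05d", seq_len(n))
  specs <- config$archetypes
  prev <- vapply(specs, function(a) a$prevalence, 0)
  arch <- sample(names(specs), n, replace = TRUE, prob = prev)

  curves <- do.call(rbind, lapply(specs, function(a) a$mean_curve))
  noise <- vapply(specs, function(a) a$noise_sd, 0)
  latent <- curves[arch, , drop = FALSE] +
    matrix(rnorm(n * 12, 0, rep(noise[arch], 12)), n, 12)
  latent <- pmin(pmax(latent, 0), 24)

  W <- .archetype_weights()
  organs <- colnames(W)
  sub <- array(0L, dim = c(n, 12, 6), dimnames = list(ids, NULL, organs))
  for (a in names(specs)) {
    rows <- which(arch == a)
    if (!length(rows)) next
    wa <- if (a %in% rownames(W)) W[a, ] else colMeans(W)
    dec <- .decompose_totals(as.vector(latent[rows, ]), wa) # (len*12) x 6
    sub[rows, , ] <- array(dec, dim = c(length(rows), 12, 6))
  }

  # ventilation: forced whenever a respiration subscore of 3-4 was drawn,
  # plus archetype-linked extra probability toward realistic overall rates
  vent_target <- c(RW = 0.464, DW = 0.393, RI = 0.379, DI = 0.425)
  forced <- apply(sub[, , "respiration", drop = FALSE] >= 3, 1, any)
  vt <- vent_target[arch]
  vt[is.na(vt)] <- 0.4
  p_forced <- tapply(forced, arch, mean)[arch]
  p_extra <- pmax(0, (vt - p_forced) / pmax(1 - p_forced, 1e-9))
  ventilated <- forced | (runif(n) < p_extra)
  # a non-ventilated patient cannot carry a respiration subscore above 2
  resp <- sub[, , "respiration"]
  resp[!ventilated & resp > 2] <- 2L
  sub[, , "respiration"] <- resp

  measurements <- .backgen_measurements(ids, sub, arch)
  covariates <- .draw_covariates(ids, arch, ventilated)
  truth <- data.frame(patient_id = ids, archetype = arch,
                      stringsAsFactors = FALSE)
  cohort <- structure(list(measurements = measurements,
                           covariates = covariates,
                           outcomes = NULL, truth = truth, config = config),
                      class = "sepsis_cohort")
  cohort <- inject_missingness(cohort, config)
  attach_outcomes(cohort, seed = config$seed + 101L)
}

.backgen_measurements <- function(ids, sub, arch) {
  n <- length(ids)
  tbl <- .backgen_tables()
  hour <- rep(6 * (0:11) + 3, each = n) # mid-window sampling times
  pw <- function(values) data.table::data.table(
    patient_id = rep(ids, 12), hour = hour, value = values)
  mk <- function(variable, scorevec, unit) {
    d <- pw(tbl[[variable]][scorevec + 1L])
    d[, `:=`(variable = variable, unit = unit)]
    d
  }
  resp <- as.vector(sub[, , "respiration"])
  coag <- as.vector(sub[, , "coagulation"])
  livr <- as.vector(sub[, , "liver"])
  card <- as.vector(sub[, , "cardiovascular"])
  cns  <- as.vector(sub[, , "cns"])
  renl <- as.vector(sub[, , "renal"])
  out <- list(
    mk("pao2_fio2_ratio", resp, "mmHg"),
    mk("platelets", coag, "10^3/uL"),
    mk("bilirubin", livr, "mg/dL"),
    mk("gcs", cns, "score"),
    mk("creatinine", renl, "mg/dL"),
    mk("urine_6h", renl, "mL/6h"),
    mk("map", card, "mmHg")
  )
  # vasopressor records only where the cardiovascular subscore needs them
  dop <- which(card == 2L)
  nor3 <- which(card == 3L)
  nor4 <- which(card == 4L)
  press <- data.table::rbindlist(list(
    data.table::data.table(patient_id = rep(ids, 12)[dop], hour = hour[dop],
                           value = 2.5, variable = "dopamine",
                           unit = "ug/kg/min"),
    data.table::data.table(patient_id = rep(ids, 12)[nor3], hour = hour[nor3],
                           value = 0.05, variable = "norepinephrine",
                           unit = "ug/kg/min"),
    data.table::data.table(patient_id = rep(ids, 12)[nor4], hour = hour[nor4],
                           value = 0.3, variable = "norepinephrine",
                           unit = "ug/kg/min")
  ))
  # auxiliary predictor streams with archetype-linked levels
  aux_mean <- list(
    lactate     = c(RW = 3.2, DW = 1.9, RI = 1.6, DI = 1.9),
    wbc         = c(RW = 13, DW = 12, RI = 16, DI = 12),
    temperature = c(RW = 37.4, DW = 37.5, RI = 38.2, DI = 37.5)
  )
  aux_sd <- c(lactate = 0.8, wbc = 4, temperature = 0.6)
  aux_floor <- c(lactate = 0.3, wbc = 0.5, temperature = 34)
  aux_unit <- c(lactate = "mmol/L", wbc = "10^3/uL", temperature = "C")
  aux <- lapply(names(aux_mean), function(v) {
    base <- aux_mean[[v]][arch]
    base[is.na(base)] <- mean(aux_mean[[v]])
    level <- rnorm(n, base, aux_sd[[v]] / 2) # patient level
    vals <- rep(level, 12) + rnorm(n * 12, 0, aux_sd[[v]] / 2)
    d <- pw(pmax(vals, aux_floor[[v]]))
    d[, `:=`(variable = v, unit = aux_unit[[v]])]
    d
  })
  res <- data.table::rbindlist(c(out, list(press), aux), use.names = TRUE)
  data.table::setcolorder(res, c("patient_id", "hour", "variable", "value",
                                 "unit"))
  data.table::setkey(res, patient_id, hour, variable)
  as.data.frame(res)
}

.draw_covariates <- function(ids, arch, ventilated) {
  n <- length(ids)
  male_p <- c(RW = 0.626, DW = 0.571, RI = 0.569, DI = 0.506)
  shock_p <- c(RW = 0.142, DW = 0.105, RI = 0.155, DI = 0.126)
  como_mu <- c(RW = 5.5, DW = 4.3, RI = 4.3, DI = 4.3)
  mp <- male_p[arch]; mp[is.na(mp)] <- 0.56
  sp <- shock_p[arch]; sp[is.na(sp)] <- 0.136
  cm <- como_mu[arch]; cm[is.na(cm)] <- 4.5
  data.frame(
    patient_id = ids,
    age = round(pmin(pmax(rnorm(n, 65, 15), 18), 99), 1),
    sex = ifelse(runif(n) < mp, "male", "female"),
    comorbidity_index = rnbinom(n, size = 2, mu = cm),
    ventilated = ventilated,
    icu_unit = sample(c("MICU", "SICU", "TSICU", "CCU", "CSRU"), n,
                      replace = TRUE,
                      prob = c(0.558, 0.165, 0.127, 0.095, 0.056)),
    septic_shock = runif(n) < sp,
    stringsAsFactors = FALSE
  )
}

#' Delete measurements at random
#'
#' Applies the configured missing-completely-at-random mechanism: each
#' (patient, variable, window) cell is deleted independently with probability
#' `missing_rate`, and each (patient, variable) pair loses all 72 h with
#' probability `full_missing_rate`. Truth labels, covariates and outcomes are
#' unchanged.
#'
#' @param cohort A `sepsis_cohort`.
#' @param config A [cohort_config()] supplying the rates.
#' @return The cohort with thinned `measurements`.
#' @export
inject_missingness <- function(cohort, config = cohort$config) {
  for (r in c("missing_rate", "full_missing_rate")) {
    if (config[[r]] < 0 || config[[r]] >= 1)
      stop("configuration error: ", r, " must be in [0, 1)")
  }
  if (config$missing_rate == 0 && config$full_missing_rate == 0)
    return(cohort)
  m <- data.table::as.data.table(cohort$measurements)
  m[, window := as.integer(hour %/% 6) + 1L]
  cells <- unique(m[, .(patient_id, variable, window)])
  cells[, drop_cell := runif(.N) < config$missing_rate]
  pairs <- unique(cells[, .(patient_id, variable)])
  pairs[, drop_all := runif(.N) < config$full_missing_rate]
  m <- cells[m, on = c("patient_id", "variable", "window")]
  m <- pairs[m, on = c("patient_id", "variable")]
  m <- m[!(drop_cell | drop_all)]
  m[, c("drop_cell", "drop_all", "window") := NULL]
  data.table::setcolorder(m, c("patient_id", "hour", "variable", "value",
                               "unit"))
  data.table::setkey(m, patient_id, hour, variable)
  cohort$measurements <- as.data.frame(m)
  cohort
}

#' Attach 28-day outcomes
#'
#' Draws per-patient in-hospital death as Bernoulli with the archetype's
#' mortality rate, event times uniform on (0, 28] days for deaths, and
#' administrative censoring at 28 days for survivors; ICU length of stay is
#' drawn log-normal with archetype-specific medians. The generated ordering
#' of mortality risk (RW > DW, DI > RI under the defaults) follows the
#' subphenotype outcome pattern.
#'
#' @param cohort A `sepsis_cohort` with truth labels.
#' @param seed Integer seed for the outcome draws.
#' @return The cohort with an `outcomes` data frame (`patient_id`, `death`,
#'   `survival_time` in days, `censored`, `los`).
#' @export
attach_outcomes <- function(cohort, seed = 1L) {
  if (is.null(cohort$truth) || !nrow(cohort$truth))
    stop("state error: cohort has no truth labels")
  set.seed(as.integer(seed))
  arch <- cohort$truth$archetype
  n <- length(arch)
  mort <- vapply(cohort$config$archetypes, function(a) a$mortality_rate, 0)
  rate <- mort[arch]
  rate[is.na(rate)] <- mean(mort)
  death <- runif(n) < rate
  stime <- rep(28, n)
  stime[death] <- runif(sum(death)) * 28
  stime[death & stime == 0] <- 1e-3
  los_med <- c(RW = 2.9, DW = 2.9, RI = 2.4, DI = 2.9)
  lm <- los_med[arch]; lm[is.na(lm)] <- 2.8
  los <- round(rlnorm(n, log(lm), 0.8), 1)
  cohort$outcomes <- data.frame(
    patient_id = cohort$truth$patient_id,
    death = death,
    survival_time = stime,
    censored = !death,
    los = pmax(los, 0.1),
    stringsAsFactors = FALSE
  )
  cohort
}

#' @export
print.sepsis_cohort <- function(x, ...) {
  cat(sprintf("Synthetic sepsis cohort: %d patients, %d measurement records\n",
              nrow(x$covariates), nrow(x$measurements)))
  print(table(x$truth$archetype))
  invisible(x)
}
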