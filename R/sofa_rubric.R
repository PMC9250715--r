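#' SOFA scoring rubric
#'
#' Threshold bands mapping window-level worst values (plus support flags) to
#' the six organ subscores of the Sequential Organ Failure Assessment (SOFA)
#' score. Bands follow the standard SOFA definition: respiration scores 3-4
#' additionally require respiratory support (the patient-level `ventilated`
#' flag), the cardiovascular subscore combines mean arterial pressure with
#' vasopressor doses, and the renal subscore is the worse of the creatinine
#' band and the urine-output band. Urine thresholds are expressed per 6 hours
#' (daily thresholds divided by 4, i.e. < 125 and < 50 mL/6 h).
#'
#' @return An object of class `sofa_rubric` describing the bands. The object
#'   is mainly informational; scoring itself is done by [score_window()].
#' @export
sofa_rubric <- function() {
  structure(list(
    organs = c("respiration", "coagulation", "liver",
               "cardiovascular", "cns", "renal"),
    respiration = "PaO2/FiO2: >=400 -> 0; <400 -> 1; <300 -> 2; <200 with ventilation -> 3; <100 with ventilation -> 4",
    coagulation = "platelets (10^3/uL): >=150 -> 0; <150 -> 1; <100 -> 2; <50 -> 3; <20 -> 4",
    liver = "bilirubin (mg/dL): <1.2 -> 0; 1.2-1.9 -> 1; 2.0-5.9 -> 2; 6.0-11.9 -> 3; >=12 -> 4",
    cardiovascular = "MAP >= 70 and no vasopressors -> 0; MAP < 70 -> 1; dopamine <= 5 or any dobutamine -> 2; dopamine > 5 or epi/norepi <= 0.1 -> 3; dopamine > 15 or epi/norepi > 0.1 -> 4 (doses ug/kg/min)",
    cns = "GCS: 15 -> 0; 13-14 -> 1; 10-12 -> 2; 6-9 -> 3; <6 -> 4",
    renal = "creatinine (mg/dL): <1.2 -> 0; 1.2-1.9 -> 1; 2.0-3.4 -> 2; 3.5-4.9 -> 3; >=5.0 -> 4; urine < 125 mL/6 h -> 3; < 50 mL/6 h -> 4; subscore = max(creatinine band, urine band)"
  ), class = "sofa_rubric")
}

#' @export
print.sofa_rubric <- function(x, ...) {
  cat("SOFA scoring rubric (six organ subscores, each 0-4):\n")
  for (o in x$organs) cat(sprintf("  %-14s %s\n", o, x[[o]]))
  invisible(x)
}

# vectorized band lookups; each takes numeric vectors (NA allowed) and
# returns integer subscores with NA where the organ input is missing

.score_respiration <- function(pf, ventilated) {
  s <- ifelse(pf < 100 & ventilated, 4L,
       ifelse(pf < 200 & ventilated, 3L,
       ifelse(pf < 300, 2L,
       ifelse(pf < 400, 1L, 0L))))
  s
}

.score_coagulation <- function(platelets) {
  ifelse(platelets < 20, 4L,
  ifelse(platelets < 50, 3L,
  ifelse(platelets < 100, 2L,
  ifelse(platelets < 150, 1L, 0L))))
}

.score_liver <- function(bilirubin) {
  ifelse(bilirubin >= 12, 4L,
  ifelse(bilirubin >= 6, 3L,
  ifelse(bilirubin >= 2, 2L,
  ifelse(bilirubin >= 1.2, 1L, 0L))))
}

.score_cardiovascular <- function(map, dopamine, dobutamine,
                                  epinephrine, norepinephrine) {
  dop <- ifelse(is.na(dopamine), 0, dopamine)
  dob <- ifelse(is.na(dobutamine), 0, dobutamine)
  epi <- ifelse(is.na(epinephrine), 0, epinephrine)
  nor <- ifelse(is.na(norepinephrine), 0, norepinephrine)
  any_dose <- dop > 0 | dob > 0 | epi > 0 | nor > 0
  s <- rep(NA_integer_, length(map))
  have <- !is.na(map) | any_dose
  s4 <- dop > 15 | epi > 0.1 | nor > 0.1
  s3 <- dop > 5 | (epi > 0 & epi <= 0.1) | (nor > 0 & nor <= 0.1)
  s2 <- (dop > 0 & dop <= 5) | dob > 0
  s1 <- !is.na(map) & map < 70
  s[have] <- ifelse(s4[have], 4L,
             ifelse(s3[have], 3L,
             ifelse(s2[have], 2L,
             ifelse(s1[have], 1L, 0L))))
  s
}

.score_cns <- function(gcs) {
  ifelse(gcs < 6, 4L,
  ifelse(gcs <= 9, 3L,
  ifelse(gcs <= 12, 2L,
  ifelse(gcs <= 14, 1L, 0L))))
}

.score_renal <- function(creatinine, urine_6h) {
  cr <- ifelse(creatinine >= 5, 4L,
        ifelse(creatinine >= 3.5, 3L,
        ifelse(creatinine >= 2, 2L,
        ifelse(creatinine >= 1.2, 1L, 0L))))
  ur <- ifelse(urine_6h < 50, 4L,
        ifelse(urine_6h < 125, 3L, 0L))
  pmax(cr, ur, na.rm = TRUE)
}

#' Score a single 6-hour window
#'
#' Maps the worst values of one 6-hour window to the six SOFA organ subscores
#' and their total. Missing organ inputs yield a missing (`NA`) subscore, to
#' be resolved later by trajectory-level imputation; the total is defined
#' only when all six subscores are resolved.
#'
#' @param values Named list or vector of window-level worst values. Recognised
#'   names: `pao2_fio2_ratio`, `platelets` (10^3/uL), `bilirubin` (mg/dL),
#'   `map` (mmHg), `dopamine`, `dobutamine`, `epinephrine`, `norepinephrine`
#'   (ug/kg/min), `gcs` (3-15), `creatinine` (mg/dL), `urine_6h` (mL/6 h).
#' @param ventilated Logical; whether the patient is on respiratory support
#'   (required for respiration subscores 3-4).
#' @param rubric A [sofa_rubric()]; present for interface completeness.
#' @return List with integer `subscores` (named length-6 vector, possibly NA)
#'   and `total` (NA unless all six subscores are resolved).
#' @examples
#' score_window(list(pao2_fio2_ratio = 450, platelets = 250, bilirubin = 0.5,
#'                   map = 80, gcs = 15, creatinine = 0.8, urine_6h = 400))
#' @export
score_window <- function(values, ventilated = FALSE, rubric = sofa_rubric()) {
  values <- as.list(values)
  g <- function(nm) {
    v <- values[[nm]]
    if (is.null(v)) NA_real_ else as.numeric(v)
  }
  .validate_values(values)
  cand <- c(g("urine_6h"), g("urine_24h") / 4)
  cand <- cand[!is.na(cand)]
  urine <- if (length(cand)) min(cand) else NA_real_
  sub <- c(
    respiration    = .score_respiration(g("pao2_fio2_ratio"), isTRUE(ventilated)),
    coagulation    = .score_coagulation(g("platelets")),
    liver          = .score_liver(g("bilirubin")),
    cardiovascular = .score_cardiovascular(g("map"), g("dopamine"),
                                           g("dobutamine"), g("epinephrine"),
                                           g("norepinephrine")),
    cns            = .score_cns(g("gcs")),
    renal          = .score_renal(g("creatinine"), urine)
  )
  total <- if (anyNA(sub)) NA_integer_ else sum(sub)
  list(subscores = sub, total = total)
}

.validate_values <- function(values) {
  nonneg <- c("platelets", "urine_6h", "urine_24h", "dopamine", "dobutamine",
              "epinephrine", "norepinephrine", "bilirubin", "creatinine",
              "pao2_fio2_ratio")
  for (nm in intersect(names(values), nonneg)) {
    v <- values[[nm]]
    if (length(v) && any(!is.na(v) & v < 0))
      stop("negative value for '", nm, "' is outside the representable range")
  }
  if (!is.null(values$gcs)) {
    v <- values$gcs
    if (any(!is.na(v) & (v < 3 | v > 15)))
      stop("gcs outside [3, 15] is outside the representable range")
  }
  invisible(TRUE)
}
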