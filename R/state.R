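#' @name state
#' @title Individual state representation
#'
#' @description
#' A simulated individual is represented as a flat named numeric vector so
#' that equation evaluation reduces to indexed sums. The slots cover the
#' baseline demographics, the seven continuous risk factors, the binary
#' statuses, the event-history flags (monotone: once set, never cleared),
#' per-event `t_since_*` counters (years since the event occurred), and the
#' derived predictors recomputed every cycle (`intercept` = 1, `bmi_sq` =
#' BMI squared, `diabetes_duration` = current age minus age at onset,
#' `hba1c_ngsp` = HbA1c on the NGSP percent scale).
#'
#' Sex is encoded as `male` (1 = male, 0 = female). HbA1c is stored in
#' IFCC mmol/mol; eGFR in ml/min per 1.73 m^2; SBP in mmHg; lipids in
#' mmol/l; BMI in kg/m^2; all times and ages in years.
NULL

.state_slots <- function() {
  c("baseline_age", "current_age", "male", "age_at_onset",
    "hba1c", "bmi", "sbp", "tg", "hdl", "ldl", "egfr",
    "current_smoker", "former_smoker", "microalbuminuria", "macroalbuminuria",
    .t1d_events,
    paste0("t_since_", .t1d_events),
    "intercept", "bmi_sq", "diabetes_duration", "hba1c_ngsp",
    "alive", "survival_time")
}

#' Construct an individual state vector
#'
#' Builds the full state vector for one simulated person from baseline
#' values, filling derived slots and auxiliary counters. Unspecified binary
#' statuses and history flags default to 0.
#'
#' @param age baseline age in years.
#' @param sex `"male"` or `"female"`.
#' @param hba1c HbA1c in mmol/mol (IFCC).
#' @param bmi BMI in kg/m^2.
#' @param sbp systolic blood pressure, mmHg.
#' @param tg triacylglycerols, mmol/l.
#' @param hdl,ldl HDL- and LDL-cholesterol, mmol/l.
#' @param egfr estimated glomerular filtration rate, ml/min per 1.73 m^2.
#' @param age_at_onset age at diabetes onset, years.
#' @param current_smoker,former_smoker,microalbuminuria,macroalbuminuria
#'   binary statuses (0/1); current and former smoker are mutually
#'   exclusive.
#' @param history named 0/1 vector over event flags (`"mi"`, `"stroke"`,
#'   `"chf"`, `"pci"`, `"cabg"`, `"angina"`, `"pvd"`, `"amputation"`,
#'   `"hypoglycaemia"`, `"hyperglycaemia"`, `"esrd"`).
#' @param time_since_event named numeric vector, years since each positive
#'   history event (defaults to 0, i.e. event at baseline).
#' @return Named numeric vector of class `"individual_state"`.
#' @export
#' @examples
#' s <- individual_state(age = 40, sex = "male", hba1c = 65, bmi = 25,
#'                       egfr = 96, history = c(mi = 1))
#' s[["diabetes_duration"]]
individual_state <- function(age, sex = c("male", "female"),
                             hba1c = 65, bmi = 24.9, sbp = 127.3,
                             tg = 1.16, hdl = 1.59, ldl = 2.72, egfr = 96.05,
                             age_at_onset = 15.01,
                             current_smoker = 0, former_smoker = 0,
                             microalbuminuria = 0, macroalbuminuria = 0,
                             history = NULL, time_since_event = NULL) {
  sex <- match.arg(sex)
  s <- stats::setNames(numeric(length(.state_slots())), .state_slots())
  s["baseline_age"] <- age
  s["current_age"] <- age
  s["male"] <- as.numeric(sex == "male")
  s["age_at_onset"] <- age_at_onset
  s["hba1c"] <- hba1c; s["bmi"] <- bmi; s["sbp"] <- sbp
  s["tg"] <- tg; s["hdl"] <- hdl; s["ldl"] <- ldl; s["egfr"] <- egfr
  s["current_smoker"] <- current_smoker
  s["former_smoker"] <- former_smoker
  s["microalbuminuria"] <- microalbuminuria
  s["macroalbuminuria"] <- macroalbuminuria
  if (!is.null(history)) {
    bad <- setdiff(names(history), .t1d_events)
    if (length(bad)) stop("unknown history flag(s): ", paste(bad, collapse = ", "))
    s[names(history)] <- as.numeric(history)
  }
  if (!is.null(time_since_event)) {
    bad <- setdiff(names(time_since_event), .t1d_events)
    if (length(bad)) stop("unknown event(s) in time_since_event: ",
                          paste(bad, collapse = ", "))
    s[paste0("t_since_", names(time_since_event))] <- as.numeric(time_since_event)
  }
  s["alive"] <- 1
  s["survival_time"] <- 0
  s <- .refresh_derived(s)
  class(s) <- "individual_state"
  validate_state(s)
  s
}

# recompute the derived predictor slots from the primary slots
.refresh_derived <- function(s) {
  s["intercept"] <- 1
  s["bmi_sq"] <- s[["bmi"]]^2
  s["diabetes_duration"] <- s[["current_age"]] - s[["age_at_onset"]]
  s["hba1c_ngsp"] <- ifcc_to_ngsp(s[["hba1c"]])
  s
}

#' Validate an individual state vector
#'
#' Checks the state invariants: the age ordering current age first, then
#' baseline age, onset age and zero (non-increasing), non-negative
#' continuous factors and survival time, 0/1 coding of
#' binary slots, and mutual exclusivity of current and former smoking.
#'
#' @param s state vector from [individual_state()].
#' @return `s`, invisibly; errors describe the violated invariant.
#' @export
validate_state <- function(s) {
  missing <- setdiff(.state_slots(), names(s))
  if (length(missing)) stop("state is missing slot(s): ",
                            paste(missing, collapse = ", "))
  if (!(s[["current_age"]] >= s[["baseline_age"]] &&
        s[["baseline_age"]] >= s[["age_at_onset"]] &&
        s[["age_at_onset"]] >= 0))
    stop("state violates current_age >= baseline_age >= age_at_onset >= 0")
  cont <- c("hba1c", "bmi", "sbp", "tg", "hdl", "ldl", "egfr")
  if (any(s[cont] < 0)) stop("continuous risk factors must be >= 0")
  if (s[["survival_time"]] < 0) stop("survival_time must be >= 0")
  bin <- c("male", "current_smoker", "former_smoker", "microalbuminuria",
           "macroalbuminuria", "alive", .t1d_events)
  if (any(!s[bin] %in% c(0, 1))) stop("binary slots must be 0 or 1")
  if (s[["current_smoker"]] == 1 && s[["former_smoker"]] == 1)
    stop("current_smoker and former_smoker are mutually exclusive")
  invisible(s)
}

#' @export
print.individual_state <- function(x, ...) {
  cat(sprintf("<individual_state> %s, age %.1f (baseline %.1f), %s\n",
              if (x[["male"]] == 1) "male" else "female",
              x[["current_age"]], x[["baseline_age"]],
              if (x[["alive"]] == 1) "alive" else "dead"))
  cat(sprintf("  HbA1c %.1f mmol/mol (%.2f%%), BMI %.1f, eGFR %.1f, SBP %.1f\n",
              x[["hba1c"]], x[["hba1c_ngsp"]], x[["bmi"]], x[["egfr"]],
              x[["sbp"]]))
  flags <- .t1d_events[x[.t1d_events] == 1]
  cat("  history:", if (length(flags)) paste(flags, collapse = ", ") else "none",
      "\n")
  invisible(x)
}
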