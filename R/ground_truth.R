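# Death baseline: Gompertz with shape 0.1 and rate solved so that the
# discrete annual-cycle life expectancy of the reference individual
# (linear predictor 0) from age 20 is 50.0 years with half-cycle credit.
.gt_death_rate <- 5.24e-5
.gt_death_shape <- 0.1

# reference annual rates for the non-fatal/complication equations
# (exponential baselines, linear predictor centred at the reference state)
.gt_event_rates <- c(
  nonfatal_mi = 0.004, fatal_mi = 0.001, nonfatal_stroke = 0.003,
  fatal_stroke = 0.001, chf = 0.003, angina = 0.004, pvd = 0.005,
  amputation = 0.004, hypoglycaemia = 0.030, hyperglycaemia = 0.030,
  esrd = 0.002, pci = 0.004, cabg = 0.003)

#' Default effect configuration for the ground-truth model generator
#'
#' Sign-and-magnitude ranges (each a `c(lo, hi)` pair on the log-hazard-
#' ratio scale, per unit of the predictor) from which
#' [generate_ground_truth_model()] draws coefficients. `death` applies to
#' the all-cause-death equation, `complications` to every other event
#' equation, `history_on_death` to each accumulated history flag in the
#' death equation (`esrd` has its own wider range). `bmi_sq` encodes a
#' U-shaped BMI effect: the linear BMI coefficient is set to
#' `-50 * bmi_sq` so the hazard is minimised at BMI 25 kg/m^2.
#'
#' @return Nested list of coefficient ranges.
#' @export
default_effect_config <- function() {
  list(
    death = list(hba1c = c(0.008, 0.015),     # per mmol/mol, harmful
                 egfr = c(-0.010, -0.004),    # per ml/min/1.73m^2, protective
                 current_smoker = c(0.3, 0.6),
                 male = c(0.1, 0.3),
                 bmi_sq = c(0.0010, 0.0020)),
    complications = list(hba1c = c(0.005, 0.020),
                         egfr = c(-0.010, -0.002),
                         current_smoker = c(0.1, 0.4)),
    history_on_death = list(default = c(0.2, 0.5), esrd = c(0.6, 1.0))
  )
}

.draw_range <- function(range, label) {
  if (!is.numeric(range) || length(range) != 2L)
    stop("effect config '", label, "': range must be c(lo, hi)")
  if (range[1] > range[2])
    stop("effect config '", label, "': contradictory range (lo > hi)")
  if (range[1] == range[2]) return(range[1])
  stats::runif(1L, range[1], range[2])
}

# reference state used to centre every event equation's linear predictor
.gt_reference_state <- function()
  individual_state(age = 20, sex = "male")

#' Generate a ground-truth simulation model
#'
#' Builds a complete, valid model (14 event equations + 10 progression
#' equations) with coefficients drawn reproducibly from the sign-and-
#' magnitude ranges of an effect configuration. Each event equation's
#' linear predictor is centred (via its `intercept` coefficient) to be 0
#' at a reference 20-year-old male at registry-mean risk-factor values, so
#' the baseline rates are interpretable as the reference individual's
#' hazards; the death baseline is calibrated so that the reference
#' individual's life expectancy lands in a plausible band for type 1
#' diabetes (roughly 45-50 years from age 20 before complication burden).
#'
#' Progression defaults are mild mean-reverting drifts towards the
#' registry means for the continuous factors, an annual eGFR decline of
#' 0.8 ml/min per 1.73 m^2, high smoking persistence, and small
#' HbA1c-dependent albuminuria incidence.
#'
#' The generator exists so that every downstream stage (cohorts, engine,
#' life table) is exercisable and testable although the fitted registry
#' coefficients of the source model are not published: all numerical
#' equation content here is declared configuration, not an estimate.
#'
#' @param seed integer seed; the same seed yields an identical model.
#' @param effect_config nested range list as [default_effect_config()];
#'   ranges set to `c(0, 0)` yield zero coefficients (a baseline-only
#'   model when all are zero).
#' @return A complete [t1d_model()].
#' @export
#' @examples
#' m <- generate_ground_truth_model(seed = 1)
#' m$event_equations$death$coefficients[["hba1c"]] > 0
generate_ground_truth_model <- function(seed = 1,
                                        effect_config = default_effect_config()) {
  if (!is.list(effect_config) ||
      !all(c("death", "complications", "history_on_death") %in%
           names(effect_config)))
    stop("effect_config must have elements death, complications, ",
         "history_on_death (see default_effect_config())")
  .with_seed(seed, {
    ref <- .gt_reference_state()

    death_cf <- vapply(names(effect_config$death), function(p)
      .draw_range(effect_config$death[[p]], paste0("death$", p)), numeric(1))
    if ("bmi_sq" %in% names(death_cf))
      death_cf["bmi"] <- -50 * death_cf[["bmi_sq"]]  # hazard minimum at BMI 25
    hod <- effect_config$history_on_death
    hist_cf <- vapply(.t1d_events, function(ev)
      .draw_range(if (!is.null(hod[[ev]])) hod[[ev]] else hod$default,
                  paste0("history_on_death$", ev)), numeric(1))
    death_cf <- c(death_cf, hist_cf)

    centre <- function(cf, lab) {
      eq0 <- list(event = lab, coefficients = cf,
                  age_interactions = numeric(0))
      class(eq0) <- "event_equation"
      c(cf, intercept = -linear_predictor(eq0, ref))
    }
    death_eq <- event_equation("death", "gompertz",
                               rate = .gt_death_rate, shape = .gt_death_shape,
                               coefficients = centre(death_cf, "death"))

    comp_eqs <- lapply(names(.gt_event_rates), function(ev) {
      cf <- vapply(names(effect_config$complications), function(p)
        .draw_range(effect_config$complications[[p]],
                    paste0("complications$", p)), numeric(1))
      event_equation(ev, "exponential", rate = .gt_event_rates[[ev]],
                     coefficients = centre(cf, ev))
    })

    revert <- function(target, mean, keep, noise)
      progression_equation(target,
                           stats::setNames(c((1 - keep) * mean, keep),
                                           c("intercept", target)),
                           noise_sd = noise)
    prog <- list(
      revert("hba1c", 65, 0.97, 1.0),
      revert("bmi", 24.90, 0.99, 0.2),
      revert("sbp", 127.30, 0.95, 2.0),
      revert("tg", 1.16, 0.95, 0.05),
      revert("hdl", 1.59, 0.95, 0.03),
      revert("ldl", 2.72, 0.95, 0.08),
      progression_equation("egfr", c(intercept = -0.8, egfr = 1.0),
                           noise_sd = 1.0),
      # smokers persist (p ~ 0.95), non-smokers rarely start (p ~ 0.02)
      progression_equation("current_smoker",
                           c(intercept = -4, current_smoker = 7)),
      # albuminuria incidence rises with HbA1c; ~1%/yr at the mean
      progression_equation("microalbuminuria",
                           c(intercept = stats::qlogis(0.01) - 0.02 * 65,
                             hba1c = 0.02)),
      progression_equation("macroalbuminuria",
                           c(intercept = stats::qlogis(0.004) - 0.02 * 65,
                             hba1c = 0.02, microalbuminuria = 1.5)))

    t1d_model(c(list(death_eq), comp_eqs), prog, complete = TRUE)
  })
}
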