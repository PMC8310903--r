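#' Define a proportional-hazards event equation
#'
#' One annual-cycle event risk is governed by a parametric proportional
#' hazards equation: a baseline hazard `h0(t)` on the age time scale,
#' scaled by `exp(lp)` where `lp` is a linear predictor over the
#' individual's state (see [linear_predictor()]). Three baseline families
#' are supported, parameterised through their cumulative hazard `H0(t)`:
#'
#' * `exponential`: `H0(t) = rate * t`
#' * `weibull`: `H0(t) = rate * t^shape`, `shape > 0`
#' * `gompertz`: `H0(t) = rate/shape * (exp(shape * t) - 1)` (`shape = 0`
#'   degenerates to the exponential)
#'
#' @param event event name; one of the 13 endpoints or `"death"` (see
#'   `t1d_event_names()`), or any label for ad-hoc models.
#' @param family baseline hazard family.
#' @param rate baseline rate parameter, `>= 0`.
#' @param shape shape parameter (Weibull `> 0`; Gompertz any real;
#'   ignored for exponential).
#' @param coefficients named numeric vector of log-hazard-ratio
#'   coefficients; names must resolve against state slots (including the
#'   derived predictors `intercept`, `bmi_sq`, `diabetes_duration`,
#'   `hba1c_ngsp`, and the `t_since_*` counters).
#' @param age_interactions named numeric vector of coefficients on
#'   predictor-by-current-age interaction terms.
#' @param fatal whether drawing the event terminates the individual;
#'   defaults to `TRUE` for `death`, `fatal_mi` and `fatal_stroke`.
#' @return An object of class `"event_equation"`.
#' @export
#' @examples
#' eq <- event_equation("death", "gompertz", rate = 5e-5, shape = 0.1,
#'                      coefficients = c(hba1c = 0.01))
event_equation <- function(event,
                           family = c("exponential", "weibull", "gompertz"),
                           rate, shape = NULL,
                           coefficients = numeric(0),
                           age_interactions = numeric(0),
                           fatal = event %in% .t1d_fatal_default) {
  family <- match.arg(family)
  if (!is.character(event) || length(event) != 1L)
    stop("event must be a single name")
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate < 0)
    stop("equation '", event, "': baseline rate must be a finite number >= 0")
  if (family == "weibull") {
    if (is.null(shape) || !is.finite(shape) || shape <= 0)
      stop("equation '", event, "': Weibull shape must be > 0")
  } else if (family == "gompertz") {
    if (is.null(shape) || !is.finite(shape))
      stop("equation '", event, "': Gompertz shape must be finite")
  } else {
    shape <- NULL
  }
  .check_coef_vec(coefficients, event, "coefficients")
  .check_coef_vec(age_interactions, event, "age_interactions")
  structure(list(event = event, family = family, rate = rate, shape = shape,
                 coefficients = coefficients,
                 age_interactions = age_interactions,
                 fatal = isTRUE(fatal)),
            class = "event_equation")
}

.check_coef_vec <- function(x, event, what) {
  if (length(x) == 0L) return(invisible(NULL))
  if (!is.numeric(x) || is.null(names(x)) || any(names(x) == "") ||
      anyDuplicated(names(x)))
    stop("equation '", event, "': ", what,
         " must be a named numeric vector with unique names")
  if (any(!is.finite(x)))
    stop("equation '", event, "': ", what, " must be finite")
  invisible(NULL)
}

#' Define a risk-factor progression equation
#'
#' Annual update rule for one risk factor. Continuous targets (HbA1c, BMI,
#' SBP, triacylglycerols, HDL, LDL, eGFR) use a linear rule: the next
#' value equals the linear predictor plus optional Gaussian noise, clamped
#' at zero. Binary targets (current smoking status, microalbuminuria,
#' macroalbuminuria) use a logistic rule: the next status is Bernoulli
#' with probability `plogis(lp)`; albuminuria states are absorbing (never
#' revert once set) while smoking status may transition in both
#' directions, a quitter becoming a former smoker.
#'
#' @param target risk-factor name (see `Details`); determines the kind.
#' @param coefficients named numeric vector on state predictors (include
#'   an `intercept` term for a constant).
#' @param noise_sd standard deviation of additive Gaussian noise for
#'   continuous targets; 0 gives a deterministic mean update.
#' @return An object of class `"progression_equation"`.
#' @export
#' @examples
#' # mean-reverting HbA1c: next = 0.98 * current + 1.3
#' progression_equation("hba1c", c(intercept = 1.3, hba1c = 0.98))
progression_equation <- function(target, coefficients, noise_sd = 0) {
  if (!target %in% .t1d_progression_targets)
    stop("unknown progression target '", target, "'; must be one of: ",
         paste(.t1d_progression_targets, collapse = ", "))
  kind <- if (target %in% .t1d_continuous_targets) "continuous-linear"
          else "binary-logistic"
  .check_coef_vec(coefficients, target, "coefficients")
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0)
    stop("equation '", target, "': noise_sd must be a single number >= 0")
  if (kind == "binary-logistic" && noise_sd != 0)
    stop("equation '", target, "': binary-logistic targets take no noise_sd")
  structure(list(target = target, kind = kind, coefficients = coefficients,
                 noise_sd = noise_sd),
            class = "progression_equation")
}

#' Evaluate an equation's linear predictor on a state
#'
#' Computes `sum(beta_i * x_i) + sum(gamma_j * x_j * current_age)` where
#' the `x` values are read from the state vector by predictor name. The
#' result is deterministic and finite; an unresolvable predictor name is a
#' configuration error naming both the predictor and the equation.
#'
#' @param eq an [event_equation()] or [progression_equation()].
#' @param state a state vector from [individual_state()].
#' @return The linear predictor, a single finite number.
#' @export
#' @examples
#' s <- individual_state(age = 40, sex = "male", bmi = 25)
#' eq <- event_equation("death", "exponential", rate = 0.01,
#'                      coefficients = c(bmi = 0.1),
#'                      age_interactions = c(bmi = -0.001))
#' linear_predictor(eq, s)  # 2.5 - 1.0 = 1.5
linear_predictor <- function(eq, state) {
  lab <- if (inherits(eq, "event_equation")) eq$event else eq$target
  lp <- 0
  if (length(eq$coefficients)) {
    idx <- match(names(eq$coefficients), names(state))
    if (anyNA(idx))
      stop("equation '", lab, "': predictor(s) not found in state: ",
           paste(names(eq$coefficients)[is.na(idx)], collapse = ", "))
    lp <- lp + sum(eq$coefficients * unclass(state)[idx])
  }
  if (length(eq$age_interactions)) {
    idx <- match(names(eq$age_interactions), names(state))
    if (anyNA(idx))
      stop("equation '", lab, "': interaction predictor(s) not found in state: ",
           paste(names(eq$age_interactions)[is.na(idx)], collapse = ", "))
    lp <- lp + state[["current_age"]] * sum(eq$age_interactions * unclass(state)[idx])
  }
  if (!is.finite(lp)) stop("equation '", lab, "': non-finite linear predictor")
  lp
}

# baseline cumulative-hazard increment over [age, age + 1]
.baseline_cumhaz_increment <- function(family, rate, shape, age) {
  switch(family,
    exponential = rate,
    weibull = rate * ((age + 1)^shape - age^shape),
    gompertz = if (shape == 0) rate
               else rate * exp(shape * age) * expm1(shape) / shape,
    stop("unknown baseline family '", family, "'"))
}

#' Annual event probability under a proportional-hazards equation
#'
#' Converts the equation's hazard into the probability that the event
#' occurs during the coming one-year cycle, using the exact cumulative-
#' hazard increment of the baseline family over `[age, age + 1]`:
#' `p = 1 - exp(-(H0(age + 1) - H0(age)) * exp(lp))`. This is exact for
#' proportional-hazards models with predictors held at their
#' start-of-cycle values (no `h * 1` approximation), so it remains a valid
#' probability for arbitrarily large hazards.
#'
#' @inheritParams linear_predictor
#' @param eq an [event_equation()].
#' @return Probability in `[0, 1]`, nondecreasing in any predictor with a
#'   positive coefficient.
#' @export
#' @examples
#' s <- individual_state(age = 40, sex = "female")
#' eq <- event_equation("death", "exponential", rate = 0.02)
#' annual_event_probability(eq, s)  # 1 - exp(-0.02)
annual_event_probability <- function(eq, state) {
  if (state[["alive"]] != 1)
    stop("annual_event_probability(): state is not alive")
  dH0 <- .baseline_cumhaz_increment(eq$family, eq$rate, eq$shape,
                                    state[["current_age"]])
  p <- -expm1(-dH0 * exp(linear_predictor(eq, state)))
  if (!is.finite(p)) stop("equation '", eq$event, "': non-finite probability")
  min(max(p, 0), 1)
}

#' Apply one annual cycle of risk-factor progression
#'
#' Updates the state's risk factors by one cycle using a list of
#' progression equations. All linear predictors are evaluated on the
#' incoming state (a simultaneous update: no equation sees another's new
#' value), then applied: continuous factors are set to `lp` plus optional
#' Gaussian noise and clamped at 0; binary factors transition via
#' `Bernoulli(plogis(lp))`. Albuminuria flags never revert; smoking
#' transitions maintain current/former exclusivity. Derived predictor
#' slots are refreshed afterwards. With all `noise_sd = 0` and no binary
#' targets the update is deterministic.
#'
#' Random draws come from the current R random number generator; seed the
#' session (or use the simulation engine's per-stream seeding) for
#' reproducibility.
#'
#' @param eqs list of [progression_equation()] objects.
#' @param state a state vector from [individual_state()].
#' @return The updated state vector.
#' @export
apply_progression <- function(eqs, state) {
  if (state[["alive"]] != 1) stop("apply_progression(): state is not alive")
  lps <- vapply(eqs, linear_predictor, numeric(1), state = state)
  for (i in seq_along(eqs)) {
    eq <- eqs[[i]]
    if (eq$kind == "continuous-linear") {
      v <- lps[[i]]
      if (eq$noise_sd > 0) v <- v + stats::rnorm(1L, 0, eq$noise_sd)
      state[eq$target] <- max(v, 0)
    } else {
      p <- stats::plogis(lps[[i]])
      if (eq$target == "current_smoker") {
        smokes <- stats::runif(1L) < p
        if (smokes && state[["current_smoker"]] == 0) {
          state["current_smoker"] <- 1
          state["former_smoker"] <- 0
        } else if (!smokes && state[["current_smoker"]] == 1) {
          state["current_smoker"] <- 0
          state["former_smoker"] <- 1
        }
      } else if (state[[eq$target]] == 0) {   # absorbing: never reverts
        if (stats::runif(1L) < p) state[eq$target] <- 1
      }
    }
  }
  .refresh_derived(state)
}

#' @export
print.event_equation <- function(x, ...) {
  shp <- if (is.null(x$shape)) "" else sprintf(", shape %.4g", x$shape)
  cat(sprintf("<event_equation> %s%s: %s(rate %.4g%s), %d coefficient(s), %d age interaction(s)\n",
              x$event, if (x$fatal) " [fatal]" else "", x$family, x$rate, shp,
              length(x$coefficients), length(x$age_interactions)))
  invisible(x)
}

#' @export
print.progression_equation <- function(x, ...) {
  cat(sprintf("<progression_equation> %s (%s), %d coefficient(s), noise_sd %.4g\n",
              x$target, x$kind, length(x$coefficients), x$noise_sd))
  invisible(x)
}
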