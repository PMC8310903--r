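#' Names of the event equations and progression targets
#'
#' The full simulation model comprises 14 proportional-hazards event
#' equations — fatal and non-fatal myocardial infarction, fatal and
#' non-fatal stroke, heart failure, angina, peripheral vascular disease,
#' amputation, hypoglycaemia, hyperglycaemia, end-stage renal disease,
#' percutaneous coronary intervention, coronary artery bypass graft, and
#' all-cause death — and 10 progression equations for HbA1c, BMI, systolic
#' BP, triacylglycerols, HDL- and LDL-cholesterol, eGFR, smoking status,
#' microalbuminuria and macroalbuminuria.
#'
#' @return Character vector of canonical names.
#' @export
t1d_event_names <- function() .t1d_event_equations

#' @rdname t1d_event_names
#' @export
t1d_progression_targets <- function() .t1d_progression_targets

#' Assemble a microsimulation model
#'
#' Bundles event equations and progression equations, the annual cycle
#' convention, and the termination cap into a single model object consumed
#' by the simulation engine. With `complete = TRUE` the model is required
#' to carry exactly one event equation per canonical event (see
#' [t1d_event_names()]) and one progression equation per risk factor;
#' partial models (for example a death-only model used as an analytic test
#' bed) are allowed with the default `complete = FALSE`.
#'
#' @param event_equations list of [event_equation()] objects with unique
#'   event names.
#' @param progression_equations list of [progression_equation()] objects
#'   with unique targets (may be empty).
#' @param max_age age at which death is forced, guaranteeing termination
#'   of the run-until-death loop. Default 120 years.
#' @param event_evaluation_order order in which event equations are
#'   evaluated and drawn each cycle; a permutation of the event names.
#'   Defaults to the order given.
#' @param half_cycle_correction credit half a year of survival for the
#'   cycle in which death occurs (standard discrete-time correction).
#' @param complete require the full 14 + 10 equation set.
#' @return An object of class `"t1d_model"`.
#' @export
#' @examples
#' m <- t1d_model(list(event_equation("death", "exponential", rate = 0.05)))
#' m
t1d_model <- function(event_equations, progression_equations = list(),
                      max_age = 120, event_evaluation_order = NULL,
                      half_cycle_correction = TRUE, complete = FALSE) {
  if (!length(event_equations)) stop("at least one event equation is required")
  stopifnot(all(vapply(event_equations, inherits, logical(1), "event_equation")),
            all(vapply(progression_equations, inherits, logical(1),
                       "progression_equation")))
  ev_names <- vapply(event_equations, `[[`, character(1), "event")
  if (anyDuplicated(ev_names))
    stop("duplicate event equation(s): ",
         paste(unique(ev_names[duplicated(ev_names)]), collapse = ", "))
  names(event_equations) <- ev_names
  pr_names <- vapply(progression_equations, `[[`, character(1), "target")
  if (anyDuplicated(pr_names))
    stop("duplicate progression equation(s): ",
         paste(unique(pr_names[duplicated(pr_names)]), collapse = ", "))
  names(progression_equations) <- pr_names
  if (complete) {
    miss_e <- setdiff(.t1d_event_equations, ev_names)
    extra_e <- setdiff(ev_names, .t1d_event_equations)
    if (length(miss_e) || length(extra_e))
      stop("complete model requires exactly one equation per event; missing: ",
           paste(miss_e, collapse = ", "), "; unexpected: ",
           paste(extra_e, collapse = ", "))
    miss_p <- setdiff(.t1d_progression_targets, pr_names)
    if (length(miss_p))
      stop("complete model missing progression equation(s): ",
           paste(miss_p, collapse = ", "))
  }
  if (is.null(event_evaluation_order)) event_evaluation_order <- ev_names
  if (!setequal(event_evaluation_order, ev_names) ||
      length(event_evaluation_order) != length(ev_names))
    stop("event_evaluation_order must be a permutation of the event names")
  if (!is.numeric(max_age) || length(max_age) != 1L || max_age <= 0)
    stop("max_age must be a single positive number")
  structure(list(event_equations = event_equations,
                 progression_equations = progression_equations,
                 cycle_length = 1,
                 max_age = max_age,
                 event_evaluation_order = event_evaluation_order,
                 half_cycle_correction = isTRUE(half_cycle_correction)),
            class = "t1d_model")
}

#' @export
print.t1d_model <- function(x, ...) {
  cat(sprintf("<t1d_model> %d event equation(s), %d progression equation(s)\n",
              length(x$event_equations), length(x$progression_equations)))
  cat(sprintf("  annual cycles, max_age %g, half-cycle correction %s\n",
              x$max_age, if (x$half_cycle_correction) "on" else "off"))
  cat("  events:", paste(x$event_evaluation_order, collapse = ", "), "\n")
  if (length(x$progression_equations))
    cat("  progression:", paste(names(x$progression_equations),
                                collapse = ", "), "\n")
  invisible(x)
}

# short digest of a model's numerical content, for run manifests
.model_digest <- function(model) {
  parts <- vapply(model$event_equations, function(e)
    paste(e$event, e$family, e$rate, paste(e$shape, collapse = ""),
          paste(names(e$coefficients), e$coefficients, collapse = ","),
          paste(names(e$age_interactions), e$age_interactions, collapse = ","),
          e$fatal), character(1))
  parts2 <- vapply(model$progression_equations, function(e)
    paste(e$target, e$kind,
          paste(names(e$coefficients), e$coefficients, collapse = ","),
          e$noise_sd), character(1))
  .digest_string(c(parts, parts2, model$max_age,
                   model$event_evaluation_order,
                   model$half_cycle_correction))
}

.as_named_numeric <- function(x, where, what) {
  if (is.null(x) || !length(x)) return(numeric(0))
  if (is.null(names(x)) || any(names(x) == ""))
    stop("model config, ", where, ": ", what, " entries must be named")
  out <- .cfg_num(unlist(x), where, what)
  out
}

# numbers are stored as %.17g strings in the config so that doubles
# round-trip exactly (plain YAML scalars lose precision)
.cfg_num <- function(x, where, what) {
  out <- suppressWarnings(as.numeric(x))
  if (anyNA(out))
    stop("model config, ", where, ": ", what, " values must be numeric")
  names(out) <- names(x)
  out
}

.num_out <- function(x) sprintf("%.17g", x)

#' Read or write a model configuration file
#'
#' Models are serialised as YAML: top-level keys `max_age`,
#' `half_cycle_correction`, `event_evaluation_order`, `events` and
#' `progression`. Each entry under `events` declares `family`, `rate`,
#' optional `shape`, optional `fatal`, and maps `coefficients` /
#' `age_interactions`; each entry under `progression` declares
#' `coefficients` and optional `noise_sd`. `read_model_spec()` validates
#' the schema and reports the offending equation and field on error.
#'
#' @param path file path.
#' @param model a [t1d_model()].
#' @param complete passed to [t1d_model()] when reading.
#' @return `read_model_spec()` returns a `t1d_model`; `write_model_spec()`
#'   returns `path` invisibly.
#' @export
read_model_spec <- function(path, complete = FALSE) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg) || is.null(cfg$events))
    stop("model config '", path, "': missing top-level 'events' map")
  evs <- lapply(names(cfg$events), function(nm) {
    e <- cfg$events[[nm]]
    if (is.null(e$family)) stop("model config, event '", nm, "': missing family")
    if (is.null(e$rate)) stop("model config, event '", nm, "': missing rate")
    event_equation(nm, family = e$family,
                   rate = .cfg_num(e$rate, nm, "rate"),
                   shape = if (is.null(e$shape)) NULL
                           else .cfg_num(e$shape, nm, "shape"),
                   coefficients = .as_named_numeric(e$coefficients, nm,
                                                    "coefficients"),
                   age_interactions = .as_named_numeric(e$age_interactions, nm,
                                                        "age_interactions"),
                   fatal = if (is.null(e$fatal)) nm %in% .t1d_fatal_default
                           else isTRUE(e$fatal))
  })
  prs <- lapply(names(cfg$progression), function(nm) {
    e <- cfg$progression[[nm]]
    progression_equation(nm,
                         coefficients = .as_named_numeric(e$coefficients, nm,
                                                          "coefficients"),
                         noise_sd = if (is.null(e$noise_sd)) 0
                                    else .cfg_num(e$noise_sd, nm, "noise_sd"))
  })
  t1d_model(evs, prs,
            max_age = if (is.null(cfg$max_age)) 120 else cfg$max_age,
            event_evaluation_order = cfg$event_evaluation_order,
            half_cycle_correction = if (is.null(cfg$half_cycle_correction))
              TRUE else isTRUE(cfg$half_cycle_correction),
            complete = complete)
}

#' @rdname read_model_spec
#' @export
write_model_spec <- function(model, path) {
  stopifnot(inherits(model, "t1d_model"))
  num_list <- function(x) as.list(stats::setNames(.num_out(x), names(x)))
  events <- lapply(model$event_equations, function(e) {
    out <- list(family = e$family, rate = .num_out(e$rate))
    if (!is.null(e$shape)) out$shape <- .num_out(e$shape)
    out$fatal <- e$fatal
    if (length(e$coefficients)) out$coefficients <- num_list(e$coefficients)
    if (length(e$age_interactions))
      out$age_interactions <- num_list(e$age_interactions)
    out
  })
  progression <- lapply(model$progression_equations, function(e) {
    out <- list(coefficients = num_list(e$coefficients))
    if (e$noise_sd > 0) out$noise_sd <- .num_out(e$noise_sd)
    out
  })
  yaml::write_yaml(list(max_age = model$max_age,
                        half_cycle_correction = model$half_cycle_correction,
                        event_evaluation_order = model$event_evaluation_order,
                        events = events,
                        progression = progression),
                   path)
  invisible(path)
}
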