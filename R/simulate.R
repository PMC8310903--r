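# Pre-resolve an equation system against the state layout: predictor
# names become integer indices so the cycle loop is indexed sums only.
.compile_model <- function(model) {
  slots <- .state_slots()
  resolve <- function(nms, lab, what) {
    idx <- match(nms, slots)
    if (anyNA(idx))
      stop("equation '", lab, "': ", what, " not found in state: ",
           paste(nms[is.na(idx)], collapse = ", "))
    idx
  }
  events <- lapply(model$event_evaluation_order, function(nm) {
    e <- model$event_equations[[nm]]
    flag <- .t1d_event_flag[[nm]]
    if (is.null(flag)) flag <- NA_character_   # ad-hoc event names
    list(event = nm,
         idx = resolve(names(e$coefficients), nm, "predictor(s)"),
         beta = unname(e$coefficients),
         iidx = resolve(names(e$age_interactions), nm,
                        "interaction predictor(s)"),
         gamma = unname(e$age_interactions),
         fam = match(e$family, c("exponential", "weibull", "gompertz")),
         rate = e$rate,
         shape = if (is.null(e$shape)) 0 else e$shape,
         fatal = e$fatal,
         flag_i = if (is.na(flag)) 0L else match(flag, slots),
         tsince_i = if (is.na(flag)) 0L
                    else match(paste0("t_since_", flag), slots))
  })
  prog <- lapply(model$progression_equations, function(e)
    list(target = e$target,
         kind = if (e$kind == "continuous-linear") 1L else 2L,
         idx = resolve(names(e$coefficients), e$target, "predictor(s)"),
         beta = unname(e$coefficients),
         noise = e$noise_sd,
         target_i = match(e$target, slots)))
  flags_i <- match(.t1d_events, slots)
  list(max_age = model$max_age,
       half = model$half_cycle_correction,
       events = events, prog = prog,
       flags_i = flags_i,
       tsince_i = match(paste0("t_since_", .t1d_events), slots),
       i_base = match("baseline_age", slots),
       i_age = match("current_age", slots),
       i_alive = match("alive", slots),
       i_surv = match("survival_time", slots),
       i_bmi = match("bmi", slots),
       i_bmi_sq = match("bmi_sq", slots),
       i_onset = match("age_at_onset", slots),
       i_dur = match("diabetes_duration", slots),
       i_hba1c = match("hba1c", slots),
       i_ngsp = match("hba1c_ngsp", slots),
       i_cur = match("current_smoker", slots),
       i_for = match("former_smoker", slots))
}

# run one individual to death; sv is the raw numeric state vector
.simulate_compiled <- function(sv, cm) {
  base <- sv[[cm$i_base]]
  nev <- length(cm$events)
  cycle <- 0L
  repeat {
    age <- sv[[cm$i_age]]
    if (age >= cm$max_age) return(cm$max_age - base)   # forced death at cap
    cycle <- cycle + 1L
    u <- stats::runif(nev)
    fatal <- FALSE
    drawn <- integer(0)
    for (k in seq_len(nev)) {
      e <- cm$events[[k]]
      dH0 <- if (e$fam == 1L) e$rate
        else if (e$fam == 2L) e$rate * ((age + 1)^e$shape - age^e$shape)
        else if (e$shape == 0) e$rate
        else e$rate * exp(e$shape * age) * expm1(e$shape) / e$shape
      lp <- sum(e$beta * sv[e$idx])
      if (length(e$gamma)) lp <- lp + age * sum(e$gamma * sv[e$iidx])
      p <- -expm1(-dH0 * exp(lp))
      if (!is.finite(p))
        stop("non-finite probability for equation '", e$event,
             "' at cycle ", cycle)
      if (u[k] < p) {
        if (e$fatal) fatal <- TRUE else drawn <- c(drawn, k)
      }
    }
    if (fatal) {
      sv[cm$i_alive] <- 0
      return((age - base) + if (cm$half) 0.5 else 0)
    }
    # auxiliary counters age one year for pre-existing histories,
    # reset to 0 for events drawn this cycle
    pre <- sv[cm$flags_i] == 1
    sv[cm$tsince_i[pre]] <- sv[cm$tsince_i[pre]] + 1
    for (k in drawn) {
      e <- cm$events[[k]]
      if (e$flag_i > 0L) {
        sv[e$flag_i] <- 1
        sv[e$tsince_i] <- 0
      }
    }
    # simultaneous progression update from the start-of-cycle snapshot
    np <- length(cm$prog)
    if (np) {
      lps <- numeric(np)
      for (k in seq_len(np)) lps[k] <- sum(cm$prog[[k]]$beta *
                                           sv[cm$prog[[k]]$idx])
      for (k in seq_len(np)) {
        pe <- cm$prog[[k]]
        if (pe$kind == 1L) {
          v <- lps[k]
          if (pe$noise > 0) v <- v + stats::rnorm(1L, 0, pe$noise)
          sv[pe$target_i] <- max(v, 0)
        } else {
          pp <- stats::plogis(lps[k])
          if (pe$target_i == cm$i_cur) {
            smokes <- stats::runif(1L) < pp
            if (smokes && sv[cm$i_cur] == 0) {
              sv[cm$i_cur] <- 1; sv[cm$i_for] <- 0
            } else if (!smokes && sv[cm$i_cur] == 1) {
              sv[cm$i_cur] <- 0; sv[cm$i_for] <- 1
            }
          } else if (sv[pe$target_i] == 0) {
            if (stats::runif(1L) < pp) sv[pe$target_i] <- 1
          }
        }
      }
      sv[cm$i_bmi_sq] <- sv[cm$i_bmi]^2
      sv[cm$i_ngsp] <- .NGSP_SLOPE * sv[cm$i_hba1c] + .NGSP_INTERCEPT
    }
    sv[cm$i_age] <- age + 1
    sv[cm$i_dur] <- sv[cm$i_age] - sv[cm$i_onset]
    sv[cm$i_surv] <- sv[cm$i_surv] + 1
  }
}

#' Simulate one individual until death
#'
#' Runs the annual-cycle loop for a single individual: each cycle the
#' annual probability of every event equation is computed from the
#' start-of-cycle state (in `event_evaluation_order`) and drawn as an
#' independent Bernoulli; a drawn fatal event (all-cause death, fatal MI,
#' fatal stroke) ends the run with half-a-cycle of credit when the
#' half-cycle correction is on; drawn non-fatal events set their history
#' flags (monotone) and reset the matching `t_since_*` counter; risk
#' factors then progress by one cycle (effective next cycle) and age
#' advances one year. Death is forced when `max_age` is reached, which
#' guarantees termination.
#'
#' Randomness comes from the current R RNG; see [simulate_cohort()] for
#' the hierarchical per-stream seeding used across a cohort.
#'
#' @param state an [individual_state()] (must be alive).
#' @param model a [t1d_model()].
#' @return Survival time in years from the baseline age, in
#'   `[0, max_age - baseline_age]`.
#' @export
#' @examples
#' m <- t1d_model(list(event_equation("death", "exponential", rate = 0.1)))
#' set.seed(1)
#' simulate_individual(individual_state(age = 40, sex = "male"), m)
simulate_individual <- function(state, model) {
  stopifnot(inherits(model, "t1d_model"))
  if (state[["alive"]] != 1) stop("simulate_individual(): state is not alive")
  cm <- .compile_model(model)
  .simulate_compiled(unclass(state), cm)
}

#' @rdname simulate_individual
#' @param object a [t1d_model()] (for the [stats::simulate()] generic).
#' @param nsim number of independent survival draws.
#' @param seed optional seed (caller RNG restored).
#' @param ... ignored.
#' @export
simulate.t1d_model <- function(object, nsim = 1,  seed = NULL,
                               state = .gt_reference_state(), ...) {
  cm <- .compile_model(object)
  sv <- unclass(state)
  .with_seed(seed, vapply(seq_len(nsim),
                          function(i) .simulate_compiled(sv, cm), numeric(1)))
}

# numeric sub-key identifying a cell within the seeding hierarchy
.cell_key <- function(cell) {
  strtoi(substr(.digest_string(unlist(cell, use.names = FALSE)), 1, 7), 16L)
}

#' Construct a simulation result from a survival matrix
#'
#' Container for per-individual, per-replication survival times of one
#' cohort. Normally produced by [simulate_cohort()]; the constructor is
#' exported so that results can also be assembled from externally stored
#' survival times.
#'
#' @param cell the cell definition (list or grid row).
#' @param survival_matrix numeric matrix, individuals in rows,
#'   replications in columns.
#' @param seed_record optional list describing the seed hierarchy.
#' @return Object of class `"simulation_result"` with
#'   `per_individual_mean` equal to the exact row means.
#' @export
simulation_result <- function(cell, survival_matrix, seed_record = NULL) {
  survival_matrix <- as.matrix(survival_matrix)
  if (!is.numeric(survival_matrix) || any(!is.finite(survival_matrix)) ||
      any(survival_matrix < 0))
    stop("survival_matrix must be finite, non-negative and numeric")
  structure(list(cell = as.list(cell),
                 survival_matrix = survival_matrix,
                 per_individual_mean = rowMeans(survival_matrix),
                 replications = ncol(survival_matrix),
                 seed_record = seed_record),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("<simulation_result> %d individual(s) x %d replication(s); mean survival %.2f years\n",
              nrow(x$survival_matrix), x$replications,
              mean(x$per_individual_mean)))
  invisible(x)
}

#' Simulate a synthetic cohort with replications
#'
#' Runs [simulate_individual()] for every cohort member and replication.
#' The stream for each (individual, replication) pair is seeded as
#' `mix_seed(master_seed, cell_key, individual, replication)`, so every
#' stream is independent, reconstructible without stored state, and
#' bit-identical across reruns with the same master seed. Because streams
#' are keyed rather than sequential, two models simulated with the same
#' master seed share all random draws until their trajectories diverge —
#' the common-random-numbers coupling used for monotonicity comparisons.
#'
#' @param cohort a [build_synthetic_cohort()] result.
#' @param model a [t1d_model()].
#' @param replications number of replications per individual (default
#'   100; the per-individual life expectancy is the mean across them).
#' @param master_seed integer master seed.
#' @return A [simulation_result()].
#' @export
simulate_cohort <- function(cohort, model, replications = 100,
                            master_seed = 1) {
  stopifnot(inherits(cohort, "synthetic_cohort"), inherits(model, "t1d_model"))
  if (replications < 1) stop("replications must be >= 1")
  cm <- .compile_model(model)
  n <- nrow(cohort$members)
  key <- .cell_key(cohort$cell)
  states <- lapply(seq_len(n),
                   function(i) unclass(.member_state(cohort$members[i, ])))
  surv <- matrix(NA_real_, nrow = n, ncol = replications)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  for (i in seq_len(n)) {
    sv <- states[[i]]
    for (r in seq_len(replications)) {
      set.seed(mix_seed(master_seed, key, i, r))
      surv[i, r] <- tryCatch(.simulate_compiled(sv, cm), error = function(e)
        stop("cell ", paste(unlist(cohort$cell), collapse = "/"),
             ", individual ", i, ", replication ", r, ": ",
             conditionMessage(e), call. = FALSE))
    }
  }
  simulation_result(cohort$cell, surv,
                    seed_record = list(master_seed = master_seed,
                                       cell_key = key,
                                       scheme = "mix_seed(master, cell, individual, replication)"))
}

#' Persist or load simulation results as a long-format table
#'
#' One CSV row per (individual, replication) pair with the cell id and
#' the survival time, mirroring the in-memory survival matrix exactly.
#'
#' @param result a [simulation_result()].
#' @param cell_id integer id of the cell in its grid.
#' @param path file path.
#' @return `write_simulation_result()` returns `path` invisibly.
#' @export
write_simulation_result <- function(result, cell_id, path) {
  m <- result$survival_matrix
  long <- data.frame(cell_id = cell_id,
                     individual = rep(seq_len(nrow(m)), times = ncol(m)),
                     replication = rep(seq_len(ncol(m)), each = nrow(m)),
                     survival_time = sprintf("%.17g", as.vector(m)))
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
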