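# binary variables carried by the copula (former smoker is handled by the
# three-category smoking draw, current smoker and sex independently)
.copula_vars <- c("microalbuminuria", "macroalbuminuria", .t1d_events)

# macrovascular complication block: moderate positive co-occurrence
.macrovascular <- c("mi", "stroke", "chf", "pci", "cabg", "angina", "pvd")

.default_proportions <- c(
  male = 0.556, current_smoker = 0.136, former_smoker = 0.043,
  microalbuminuria = 0.210, macroalbuminuria = 0.083,
  mi = 0.029, stroke = 0.018, chf = 0.013, pci = 0.014, cabg = 0.025,
  angina = 0.010, pvd = 0.037, amputation = 0.042,
  hypoglycaemia = 0.140, hyperglycaemia = 0.142, esrd = 0.006)

.default_moments <- list(
  age = c(mean = 36.98, sd = 14.94),
  bmi = c(mean = 24.90, sd = 3.71),
  egfr = c(mean = 96.05, sd = 26.52),
  hba1c = c(mean = 65, sd = 13),
  age_at_onset = c(mean = 15.01, sd = 7.60),
  sbp = c(mean = 127.30, sd = 16.91),
  tg = c(mean = 1.16, sd = 0.85),
  hdl = c(mean = 1.59, sd = 0.46),
  ldl = c(mean = 2.72, sd = 0.82))

.default_dependence <- function() {
  k <- length(.copula_vars)
  m <- matrix(0, k, k, dimnames = list(.copula_vars, .copula_vars))
  for (a in .macrovascular) for (b in .macrovascular)
    if (a != b) m[a, b] <- 1.0
  m["microalbuminuria", "macroalbuminuria"] <- 1.0
  m["macroalbuminuria", "microalbuminuria"] <- 1.0
  m
}

#' Summary description of a registry population
#'
#' Marginal description of an individual-level diabetes-registry
#' population: proportions of the binary characteristics, mean and SD of
#' the continuous risk factors, and a pairwise log-odds-ratio matrix
#' encoding the co-occurrence of the binary complication histories. The
#' defaults reproduce the baseline characteristics of a Swedish national
#' type 1 diabetes registry cross-section of 27,841 adults (55.6% male,
#' 13.6% current smokers, BMI 24.90 +/- 3.71 kg/m^2, HbA1c 65 +/- 13
#' mmol/mol, and so on), with moderate positive dependence (log odds ratio
#' 1.0) among the macrovascular complication histories and between micro-
#' and macroalbuminuria.
#'
#' @param proportions named vector of binary-variable fractions in (0, 1).
#' @param continuous_moments named list of `c(mean =, sd =)` pairs for the
#'   continuous factors (ages in years; units as in [individual_state()]).
#' @param dependence symmetric zero-diagonal log-odds-ratio matrix over
#'   the jointly sampled binary variables (albuminuria and the eleven
#'   complication histories).
#' @return An object of class `"population_summary"`.
#' @export
#' @examples
#' ps <- population_summary()
#' ps$proportions[["male"]]
population_summary <- function(proportions = .default_proportions,
                               continuous_moments = .default_moments,
                               dependence = .default_dependence()) {
  stopifnot(is.numeric(proportions), !is.null(names(proportions)))
  if (any(proportions <= 0 | proportions >= 1))
    stop("all proportions must lie strictly in (0, 1)")
  miss <- setdiff(names(.default_proportions), names(proportions))
  if (length(miss)) stop("proportions missing: ", paste(miss, collapse = ", "))
  for (nm in names(continuous_moments)) {
    m <- continuous_moments[[nm]]
    if (!is.numeric(m) || !all(c("mean", "sd") %in% names(m)) || m[["sd"]] <= 0)
      stop("continuous_moments[['", nm, "']] must have mean and sd > 0")
  }
  miss <- setdiff(names(.default_moments), names(continuous_moments))
  if (length(miss))
    stop("continuous_moments missing: ", paste(miss, collapse = ", "))
  if (!is.matrix(dependence) || !isTRUE(all.equal(dependence, t(dependence))) ||
      any(diag(dependence) != 0))
    stop("dependence must be a symmetric matrix with zero diagonal")
  if (!setequal(rownames(dependence), .copula_vars))
    stop("dependence must be indexed by: ", paste(.copula_vars, collapse = ", "))
  structure(list(proportions = proportions,
                 continuous_moments = continuous_moments,
                 dependence = dependence[.copula_vars, .copula_vars]),
            class = "population_summary")
}

#' @export
print.population_summary <- function(x, ...) {
  cat("<population_summary>\n")
  cat(sprintf("  %d binary proportions (male %.1f%%, current smoker %.1f%%)\n",
              length(x$proportions), 100 * x$proportions[["male"]],
              100 * x$proportions[["current_smoker"]]))
  cat(sprintf("  %d continuous factors (BMI %.2f +/- %.2f, HbA1c %g +/- %g)\n",
              length(x$continuous_moments),
              x$continuous_moments$bmi[["mean"]], x$continuous_moments$bmi[["sd"]],
              x$continuous_moments$hba1c[["mean"]],
              x$continuous_moments$hba1c[["sd"]]))
  cat(sprintf("  %d nonzero pairwise log-odds ratios\n",
              sum(x$dependence[upper.tri(x$dependence)] != 0)))
  invisible(x)
}

# P(Z1 > a, Z2 > b) under a bivariate standard normal with correlation rho
.bvn_tail <- function(a, b, rho) {
  if (abs(rho) < 1e-12) return(stats::pnorm(a, lower.tail = FALSE) *
                               stats::pnorm(b, lower.tail = FALSE))
  s <- sqrt(1 - rho^2)
  f <- function(z) stats::dnorm(z) * stats::pnorm((rho * z - b) / s)
  stats::integrate(f, a, Inf, rel.tol = 1e-11, abs.tol = 1e-13)$value
}

# log odds ratio of the 2x2 table induced by thresholding at (a, b);
# cell probabilities are clamped away from 0 so the log stays finite
.threshold_logor <- function(a, b, rho) {
  p1 <- stats::pnorm(a, lower.tail = FALSE)
  p2 <- stats::pnorm(b, lower.tail = FALSE)
  p11 <- min(max(.bvn_tail(a, b, rho), 1e-12), min(p1, p2) - 1e-12)
  p10 <- max(p1 - p11, 1e-12)
  p01 <- max(p2 - p11, 1e-12)
  p00 <- max(1 - p1 - p2 + p11, 1e-12)
  log(p11 * p00 / (p10 * p01))
}

# tetrachoric-style inversion: copula correlation realising a target
# pairwise log odds ratio at the two marginal thresholds; the log OR is
# increasing in rho and vanishes at rho = 0, so the root is bracketed in
# the half-interval matching the target's sign
.solve_copula_rho <- function(a, b, target_logor, pair) {
  if (target_logor == 0) return(0)
  f <- function(r) .threshold_logor(a, b, r) - target_logor
  lo <- if (target_logor > 0) 0 else -0.999
  hi <- if (target_logor > 0) 0.999 else 0
  sol <- tryCatch(stats::uniroot(f, c(lo, hi), tol = 1e-9),
                  error = function(e)
                    stop("infeasible dependence for pair ", pair[1], " ~ ",
                         pair[2], " (log OR ", target_logor,
                         " not attainable at these marginals)"))
  sol$root
}

# latent correlation matrix for the copula variables; errors name the
# offending pair when the requested dependence is infeasible
.copula_correlation <- function(summary) {
  vars <- .copula_vars
  k <- length(vars)
  thr <- stats::qnorm(summary$proportions[vars], lower.tail = FALSE)
  R <- diag(k)
  dimnames(R) <- list(vars, vars)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    lor <- summary$dependence[vars[i], vars[j]]
    if (lor != 0)
      R[i, j] <- R[j, i] <- .solve_copula_rho(thr[i], thr[j], lor,
                                              c(vars[i], vars[j]))
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) {
    off <- which(abs(R) == max(abs(R[upper.tri(R)])), arr.ind = TRUE)[1, ]
    stop("infeasible dependence matrix: latent correlation not positive ",
         "definite (strongest pair ", vars[off[1]], " ~ ", vars[off[2]], ")")
  }
  list(R = R, thresholds = thr)
}

# lower-truncated (at 0) normal draws via the inverse-CDF map
.rtruncnorm0 <- function(n, mean, sd, upper = Inf) {
  lo <- stats::pnorm(0, mean, sd)
  hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, lo, hi), mean, sd)
}

# analytic mean of a normal truncated below at 0 (used by moment tests)
.truncnorm0_mean <- function(mean, sd) {
  a <- -mean / sd
  mean + sd * stats::dnorm(a) / stats::pnorm(a, lower.tail = FALSE)
}

#' Generate a synthetic registry-style population
#'
#' Draws an individual-level table of `n` people whose marginal structure
#' matches a [population_summary()]: continuous risk factors from normals
#' truncated below at 0 with the stated moments (age at onset additionally
#' truncated above at the individual's age), sex and current/former/never
#' smoking from their exact marginal probabilities (the three smoking
#' categories are mutually exclusive by construction), and the albuminuria
#' and complication-history flags from a Gaussian copula whose latent
#' correlations are solved to reproduce the summary's pairwise log odds
#' ratios at the stated marginals.
#'
#' @param summary a [population_summary()].
#' @param n number of individuals, `>= 1`.
#' @param seed integer seed; the draw is fully reproducible from it and
#'   the caller's RNG state is restored afterwards.
#' @return A `data.frame` with one row per individual and one column per
#'   baseline state field (see [individual_state()]), plus `person_id`
#'   and character `sex`.
#' @export
#' @examples
#' pop <- generate_registry_population(population_summary(), n = 500, seed = 1)
#' mean(pop$sex == "male")
generate_registry_population <- function(summary = population_summary(),
                                         n, seed = NULL) {
  stopifnot(inherits(summary, "population_summary"))
  if (!is.numeric(n) || length(n) != 1L || n < 1) stop("n must be >= 1")
  n <- as.integer(n)
  .with_seed(seed, {
    mom <- summary$continuous_moments
    age <- .rtruncnorm0(n, mom$age[["mean"]], mom$age[["sd"]])
    onset <- .rtruncnorm0(n, mom$age_at_onset[["mean"]], mom$age_at_onset[["sd"]],
                          upper = age)
    cont <- lapply(c("hba1c", "bmi", "sbp", "tg", "hdl", "ldl", "egfr"),
                   function(v) .rtruncnorm0(n, mom[[v]][["mean"]],
                                            mom[[v]][["sd"]]))
    names(cont) <- c("hba1c", "bmi", "sbp", "tg", "hdl", "ldl", "egfr")

    sex <- ifelse(stats::runif(n) < summary$proportions[["male"]],
                  "male", "female")
    u <- stats::runif(n)
    p_cur <- summary$proportions[["current_smoker"]]
    p_for <- summary$proportions[["former_smoker"]]
    current_smoker <- as.numeric(u < p_cur)
    former_smoker <- as.numeric(u >= p_cur & u < p_cur + p_for)

    cop <- .copula_correlation(summary)
    Z <- matrix(stats::rnorm(n * length(.copula_vars)), nrow = n) %*%
      chol(cop$R)
    X <- sweep(Z, 2, cop$thresholds, `>`) * 1
    colnames(X) <- .copula_vars

    out <- data.frame(person_id = seq_len(n), sex = sex, age = age,
                      age_at_onset = onset, cont,
                      current_smoker = current_smoker,
                      former_smoker = former_smoker,
                      X, check.names = FALSE,
                      stringsAsFactors = FALSE)
    out
  })
}

.population_columns <- function()
  c("person_id", "sex", "age", "age_at_onset", "hba1c", "bmi", "sbp",
    "tg", "hdl", "ldl", "egfr", "current_smoker", "former_smoker",
    .copula_vars)

#' Write or read an individual-level population table
#'
#' The population (or cohort member) table is persisted as plain CSV with
#' one column per baseline state field. `read_population()` validates the
#' schema: all documented columns present, binaries strictly 0/1, sex
#' either `"male"` or `"female"`, and continuous fields numeric and
#' non-negative.
#'
#' @param population data.frame as from [generate_registry_population()].
#' @param path file path.
#' @return `read_population()` returns the validated data.frame;
#'   `write_population()` returns `path` invisibly.
#' @export
write_population <- function(population, path) {
  cols <- .population_columns()
  miss <- setdiff(cols, names(population))
  if (length(miss)) stop("population is missing column(s): ",
                         paste(miss, collapse = ", "))
  utils::write.csv(population[cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_population
#' @export
read_population <- function(path) {
  pop <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.population_columns(), names(pop))
  if (length(miss)) stop("population file '", path, "' missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!all(pop$sex %in% c("male", "female")))
    stop("population file '", path, "': sex must be 'male' or 'female'")
  for (v in c("current_smoker", "former_smoker", .copula_vars)) {
    if (!all(pop[[v]] %in% c(0, 1)))
      stop("population file '", path, "': column '", v, "' must be 0/1")
    pop[[v]] <- as.numeric(pop[[v]])
  }
  for (v in c("age", "age_at_onset", "hba1c", "bmi", "sbp", "tg", "hdl",
              "ldl", "egfr"))
    if (!is.numeric(pop[[v]]) || any(pop[[v]] < 0))
      stop("population file '", path, "': column '", v,
           "' must be numeric and >= 0")
  pop
}
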