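#' Default risk-factor level grid for the life expectancy table
#'
#' Six table risk factors with two levels for the binary factors and four
#' for the continuous ones: sex (male/female); current age 20, 30, 40, 50
#' years; smoking status (smoker/non-smoker); BMI 20, 25, 30, 35 kg/m^2;
#' eGFR 30, 60, 90, 120 ml/min per 1.73 m^2; HbA1c 42, 64, 86, 108
#' mmol/mol (6, 8, 10, 12% NGSP). The full Cartesian product has
#' 2 x 4 x 2 x 4 x 4 x 4 = 1024 cells.
#'
#' @return Named list of level vectors in canonical factor order.
#' @export
default_grid_levels <- function() {
  list(sex = c("male", "female"),
       age = c(20, 30, 40, 50),
       smoking = c("smoker", "non-smoker"),
       bmi = c(20, 25, 30, 35),
       egfr = c(30, 60, 90, 120),
       hba1c = c(42, 64, 86, 108))
}

#' Build the cell grid of table risk-factor combinations
#'
#' Forms the Cartesian product of the declared levels in the canonical
#' factor order (sex, age, smoking, bmi, egfr, hba1c), the last factor
#' varying fastest. Each row of the result defines one table cell.
#'
#' @param levels named list of level vectors; every factor needs at least
#'   one level. Defaults to [default_grid_levels()].
#' @return A `data.frame` with one row per cell, columns `cell_id` plus
#'   the six factors; `nrow` equals the product of the level counts.
#' @export
#' @examples
#' nrow(build_cell_grid())  # 1024
build_cell_grid <- function(levels = default_grid_levels()) {
  wanted <- names(default_grid_levels())
  miss <- setdiff(wanted, names(levels))
  if (length(miss)) stop("grid levels missing factor(s): ",
                         paste(miss, collapse = ", "))
  if (any(lengths(levels[wanted]) == 0))
    stop("every factor needs at least one level; empty: ",
         paste(wanted[lengths(levels[wanted]) == 0], collapse = ", "))
  g <- expand.grid(rev(levels[wanted]), KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE)
  g <- g[, rev(names(g))]               # canonical column order, last fastest
  rownames(g) <- NULL
  cbind(cell_id = seq_len(nrow(g)), g)
}

#' Empirical joint distribution of binary covariate combinations
#'
#' Scans an individual-level population for every unique combination of
#' the named binary variables, labels each combination with a stable
#' identifier (combinations ordered lexicographically on the 0/1 vector,
#' so identifiers are invariant to row permutations of the input), and
#' records the empirical probability mass function and its cumulative
#' distribution. Only combinations observed in the population are in the
#' support.
#'
#' @param population data.frame containing the variables.
#' @param variables character vector of column names; each column must be
#'   strictly 0/1.
#' @return An object of class `"combination_distribution"` with elements
#'   `variables`, `combinations` (matrix, one row per combination),
#'   `identifiers`, `pmf`, `cdf` and `digest`.
#' @export
#' @examples
#' pop <- data.frame(a = c(0,0,0,0,0,0,0,1,1,1), b = c(0,0,0,0,0,0,0,0,0,1))
#' d <- build_combination_distribution(pop, c("a", "b"))
#' d$pmf  # 0.7, 0.2, 0.1
build_combination_distribution <- function(population, variables) {
  if (!nrow(population)) stop("population must be nonempty")
  miss <- setdiff(variables, names(population))
  if (length(miss)) stop("population is missing column(s): ",
                         paste(miss, collapse = ", "))
  for (v in variables)
    if (!all(population[[v]] %in% c(0, 1)))
      stop("column '", v, "' is not strictly 0/1")
  keys <- do.call(paste0, population[variables])
  tab <- table(keys)
  keys_sorted <- sort(names(tab))       # lexicographic on the binary vector
  pmf <- as.numeric(tab[keys_sorted]) / length(keys)
  combos <- do.call(rbind, lapply(strsplit(keys_sorted, ""), as.numeric))
  colnames(combos) <- variables
  structure(list(variables = variables,
                 combinations = combos,
                 identifiers = seq_along(keys_sorted),
                 pmf = pmf,
                 cdf = cumsum(pmf),
                 digest = .digest_string(c(variables, keys_sorted,
                                           sprintf("%.15g", pmf)))),
            class = "combination_distribution")
}

#' @export
print.combination_distribution <- function(x, ...) {
  cat(sprintf("<combination_distribution> %d variable(s), %d combination(s), digest %s\n",
              length(x$variables), length(x$identifiers), x$digest))
  invisible(x)
}

#' Sample binary-covariate combinations by the inverse transform method
#'
#' Each draw generates a uniform variate `u` and selects the first
#' identifier whose cumulative probability reaches `u`; the corresponding
#' 0/1 combination is emitted. Uniforms may be injected through `u` for
#' deterministic verification; otherwise they come from the current RNG.
#'
#' @param dist a [build_combination_distribution()] result.
#' @param n number of draws (ignored when `u` is supplied).
#' @param u optional numeric vector of uniforms in `[0, 1]`.
#' @return Matrix of sampled combinations, one row per draw, with the
#'   selected identifiers in attribute `"identifier"`.
#' @export
#' @examples
#' pop <- data.frame(a = rep(c(0, 1), c(7, 3)))
#' d <- build_combination_distribution(pop, "a")
#' sample_combinations(d, u = c(0.05, 0.75, 0.95))
sample_combinations <- function(dist, n = length(u), u = NULL) {
  stopifnot(inherits(dist, "combination_distribution"))
  if (is.null(u)) {
    if (n < 0) stop("n must be >= 0")
    u <- stats::runif(n)
  }
  idx <- findInterval(u, dist$cdf, left.open = TRUE) + 1L
  out <- dist$combinations[idx, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "identifier") <- dist$identifiers[idx]
  out
}

#' Build a synthetic cohort for one table cell
#'
#' Constructs `n` individuals who all carry the cell's six table
#' risk-factor levels exactly, with the remaining ("hidden") covariates
#' filled by category:
#'
#' 1. table factors — fixed at the cell's levels;
#' 2. hidden binaries — complication histories sampled jointly from
#'    `history_dist`, micro/macroalbuminuria jointly from
#'    `albuminuria_dist` (a separate joint distribution), former-smoker
#'    as an independent Bernoulli forced to 0 in smoker cells;
#' 3. hidden continuous factors (age at onset, SBP, triacylglycerols,
#'    HDL, LDL) — set to the population means for every member;
#' 4. age-interaction terms — derived from categories 1-3 (recomputed by
#'    the engine each cycle).
#'
#' The cohort is reproducible from `seed`; because the table factors
#' consume no randomness, cohorts for different cells built with the same
#' seed share identical hidden-covariate streams, which supports
#' common-random-numbers comparisons across cells.
#'
#' @param cell one row of [build_cell_grid()] (or an equivalent list with
#'   the six factors).
#' @param summary a [population_summary()] supplying means and the
#'   former-smoker proportion.
#' @param history_dist joint distribution of the eleven complication
#'   histories.
#' @param albuminuria_dist joint distribution of micro/macroalbuminuria.
#' @param n cohort size (default 1000).
#' @param seed integer seed (caller RNG restored).
#' @param grid optional grid for strict level checking: when supplied,
#'   cell levels outside it raise a configuration error.
#' @return Object of class `"synthetic_cohort"`: `cell`, `members`
#'   (data.frame in the population schema), and `provenance`.
#' @export
build_synthetic_cohort <- function(cell, summary = population_summary(),
                                   history_dist, albuminuria_dist,
                                   n = 1000, seed = NULL, grid = NULL) {
  stopifnot(inherits(summary, "population_summary"),
            inherits(history_dist, "combination_distribution"),
            inherits(albuminuria_dist, "combination_distribution"))
  cell <- as.list(cell)
  need <- names(default_grid_levels())
  miss <- setdiff(need, names(cell))
  if (length(miss)) stop("cell is missing factor(s): ",
                         paste(miss, collapse = ", "))
  if (!is.null(grid)) {
    lv <- default_grid_levels()
    for (f in need) {
      ok <- cell[[f]] %in% unique(grid[[f]])
      if (!ok) stop("cell level ", f, " = ", cell[[f]],
                    " is outside the declared grid")
    }
  }
  if (!setequal(history_dist$variables, .t1d_events))
    stop("history_dist must cover the complication histories: ",
         paste(.t1d_events, collapse = ", "))
  if (!setequal(albuminuria_dist$variables,
                c("microalbuminuria", "macroalbuminuria")))
    stop("albuminuria_dist must cover microalbuminuria and macroalbuminuria")
  if (n < 1) stop("n must be >= 1")
  n <- as.integer(n)

  .with_seed(seed, {
    hist <- sample_combinations(history_dist, n)
    alb <- sample_combinations(albuminuria_dist, n)
    smoker_cell <- identical(cell$smoking, "smoker")
    former <- if (smoker_cell) numeric(n)
              else as.numeric(stats::runif(n) <
                              summary$proportions[["former_smoker"]])
    mom <- summary$continuous_moments
    members <- data.frame(
      person_id = seq_len(n),
      sex = rep(cell$sex, n),
      age = rep(as.numeric(cell$age), n),
      age_at_onset = rep(mom$age_at_onset[["mean"]], n),
      hba1c = rep(as.numeric(cell$hba1c), n),
      bmi = rep(as.numeric(cell$bmi), n),
      sbp = rep(mom$sbp[["mean"]], n),
      tg = rep(mom$tg[["mean"]], n),
      hdl = rep(mom$hdl[["mean"]], n),
      ldl = rep(mom$ldl[["mean"]], n),
      egfr = rep(as.numeric(cell$egfr), n),
      current_smoker = rep(as.numeric(smoker_cell), n),
      former_smoker = former,
      microalbuminuria = alb[, "microalbuminuria"],
      macroalbuminuria = alb[, "macroalbuminuria"],
      stringsAsFactors = FALSE)
    members <- cbind(members, as.data.frame(hist[, .t1d_events, drop = FALSE]))
    structure(list(cell = cell,
                   members = members,
                   provenance = list(seed = seed,
                                     history_digest = history_dist$digest,
                                     albuminuria_digest = albuminuria_dist$digest)),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d member(s): %s, age %s, %s, BMI %s, eGFR %s, HbA1c %s\n",
              nrow(x$members), x$cell$sex, x$cell$age, x$cell$smoking,
              x$cell$bmi, x$cell$egfr, x$cell$hba1c))
  invisible(x)
}

# one cohort member row -> full simulation state vector
.member_state <- function(row) {
  individual_state(age = row$age,
                   sex = row$sex,
                   hba1c = row$hba1c, bmi = row$bmi, sbp = row$sbp,
                   tg = row$tg, hdl = row$hdl, ldl = row$ldl,
                   egfr = row$egfr,
                   age_at_onset = row$age_at_onset,
                   current_smoker = row$current_smoker,
                   former_smoker = row$former_smoker,
                   microalbuminuria = row$microalbuminuria,
                   macroalbuminuria = row$macroalbuminuria,
                   history = stats::setNames(as.numeric(row[.t1d_events]),
                                             .t1d_events))
}
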