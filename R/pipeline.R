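#' Configure an end-to-end life-table run
#'
#' Two scale presets are provided. `"full"` is the full study scale:
#' the 1024-cell default grid, synthetic registry population of 27,841,
#' cohorts of 1000 members, 100 replications. `"demo"` preserves every
#' code path at desk scale: a 16-cell grid (both sexes, ages 20/50, both
#' smoking statuses, BMI 25, eGFR 90, HbA1c 42/108), a registry
#' population of 20,000, cohorts of 200 members, 10 replications. Any
#' field can be overridden.
#'
#' @param preset `"demo"` or `"full"`.
#' @param master_seed integer master seed driving every random stage.
#' @param grid_levels named list of factor levels (see
#'   [default_grid_levels()]).
#' @param cohort_size members per synthetic cohort.
#' @param replications replications per individual.
#' @param population_n size of the generated registry population.
#' @param model a [t1d_model()], or `NULL` to generate a ground-truth
#'   model from the master seed, or a path to a YAML model file.
#' @param summary a [population_summary()].
#' @param output_dir directory for the output bundle.
#' @param colour_metric,colour_scope passed to [colourise()].
#' @param write_results also write the long-format per-replication
#'   survival table (can be large at full scale).
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(preset = c("demo", "full"), master_seed = 1,
                       grid_levels = NULL, cohort_size = NULL,
                       replications = NULL, population_n = NULL,
                       model = NULL, summary = population_summary(),
                       output_dir = tempfile("let1d_run_"),
                       colour_metric = "life_expectancy",
                       colour_scope = "stratum",
                       write_results = FALSE) {
  preset <- match.arg(preset)
  demo_grid <- list(sex = c("male", "female"), age = c(20, 50),
                    smoking = c("smoker", "non-smoker"), bmi = 25,
                    egfr = 90, hba1c = c(42, 108))
  cfg <- list(preset = preset,
              master_seed = as.integer(master_seed),
              grid_levels = if (!is.null(grid_levels)) grid_levels
                            else if (preset == "full") default_grid_levels()
                            else demo_grid,
              cohort_size = if (!is.null(cohort_size)) cohort_size
                            else if (preset == "full") 1000 else 200,
              replications = if (!is.null(replications)) replications
                             else if (preset == "full") 100 else 10,
              population_n = if (!is.null(population_n)) population_n
                             else if (preset == "full") 27841 else 20000,
              model = model, summary = summary, output_dir = output_dir,
              colour_metric = colour_metric, colour_scope = colour_scope,
              write_results = isTRUE(write_results))
  if (cfg$cohort_size < 1 || cfg$replications < 1 || cfg$population_n < 1)
    stop("cohort_size, replications and population_n must all be >= 1")
  class(cfg) <- "run_config"
  cfg
}

.stage_msg <- function(...) message(format(Sys.time(), "[%H:%M:%S] "), ...)

#' Run the full pipeline: generate, build, simulate, tabulate
#'
#' Executes every stage in order: (1) generate the synthetic registry
#' population; (2) count its joint binary-combination distributions;
#' (3) build the cell grid and one synthetic cohort per cell; (4) run the
#' replicated annual-cycle simulation for every cohort; (5) aggregate,
#' assemble and colour-grade the life table; (6) write the bundle:
#' `population.csv`, `life_table.csv`, `life_table.html`,
#' `life_table_grey.html`, optional `results.csv`, and `manifest.json`
#' echoing the configuration, seeds, digests and stage timings. The same
#' configuration and master seed reproduce the bundle byte-for-byte
#' (manifest timings aside).
#'
#' @param config a [run_config()].
#' @return The colourised [assemble_table()] result, invisibly, with the
#'   manifest in attribute `"manifest"`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  timings <- list()
  clock <- function(stage, expr) {
    s <- Sys.time()
    out <- force(expr)
    timings[[stage]] <<- round(as.numeric(difftime(Sys.time(), s,
                                                   units = "secs")), 3)
    out
  }

  .stage_msg("stage 1/6: registry population (n = ", config$population_n, ")")
  pop <- clock("population",
               generate_registry_population(config$summary,
                                            n = config$population_n,
                                            seed = mix_seed(config$master_seed, 1)))
  write_population(pop, file.path(config$output_dir, "population.csv"))

  .stage_msg("stage 2/6: joint combination distributions")
  hist_dist <- clock("distributions", build_combination_distribution(pop, .t1d_events))
  alb_dist <- build_combination_distribution(
    pop, c("microalbuminuria", "macroalbuminuria"))

  model <- config$model
  if (is.null(model)) {
    model <- generate_ground_truth_model(seed = mix_seed(config$master_seed, 2))
  } else if (is.character(model)) {
    model <- read_model_spec(model, complete = TRUE)
  }
  stopifnot(inherits(model, "t1d_model"))

  .stage_msg("stage 3/6: cell grid and synthetic cohorts")
  grid <- build_cell_grid(config$grid_levels)
  cohorts <- clock("cohorts", lapply(seq_len(nrow(grid)), function(i)
    build_synthetic_cohort(grid[i, ], config$summary, hist_dist, alb_dist,
                           n = config$cohort_size,
                           seed = mix_seed(config$master_seed, 3, i))))

  .stage_msg("stage 4/6: simulation (", nrow(grid), " cells x ",
             config$cohort_size, " members x ", config$replications,
             " replications)")
  results <- clock("simulation", {
    res <- vector("list", nrow(grid))
    strata <- paste(grid$sex, grid$age)
    done <- character(0)
    for (i in seq_len(nrow(grid))) {
      if (!strata[i] %in% done) {
        .stage_msg("  stratum ", strata[i])
        done <- c(done, strata[i])
      }
      res[[i]] <- simulate_cohort(cohorts[[i]], model,
                                  replications = config$replications,
                                  master_seed = config$master_seed)
    }
    res
  })
  if (config$write_results) {
    paths <- file.path(config$output_dir,
                       sprintf("results_cell%04d.csv", seq_along(results)))
    for (i in seq_along(results))
      write_simulation_result(results[[i]], grid$cell_id[i], paths[i])
  }

  .stage_msg("stage 5/6: life-table assembly and colour grading")
  table <- clock("life_table", {
    cells <- do.call(rbind, lapply(results, aggregate_cell))
    colourise(assemble_table(cells), metric = config$colour_metric,
              scope = config$colour_scope)
  })

  .stage_msg("stage 6/6: outputs")
  files <- write_life_table(table,
                            csv = file.path(config$output_dir, "life_table.csv"),
                            html = file.path(config$output_dir, "life_table.html"),
                            grey_html = file.path(config$output_dir,
                                                  "life_table_grey.html"))
  manifest <- list(
    preset = config$preset,
    master_seed = config$master_seed,
    grid_levels = config$grid_levels,
    cohort_size = config$cohort_size,
    replications = config$replications,
    population_n = config$population_n,
    n_cells = nrow(grid),
    model_digest = .model_digest(model),
    history_digest = hist_dist$digest,
    albuminuria_digest = alb_dist$digest,
    seed_scheme = list(population = "mix_seed(master, 1)",
                       model = "mix_seed(master, 2)",
                       cohort_i = "mix_seed(master, 3, i)",
                       stream = "mix_seed(master, cell_key, individual, replication)"),
    colour = list(metric = config$colour_metric, scope = config$colour_scope),
    files = basename(c("population.csv", files)),
    timings_sec = timings,
    total_sec = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 3))
  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  .stage_msg("done in ", manifest$total_sec, " s: ", config$output_dir)
  attr(table, "manifest") <- manifest
  invisible(table)
}
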