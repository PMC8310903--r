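# all-cell aggregate helper: one aggregated row per grid cell from
# constant survival matrices (value per cell supplied by `f`)
toy_table <- function(levels, f, n_members = 4) {
  grid <- build_cell_grid(levels)
  cells <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    v <- f(grid[i, ])
    aggregate_cell(simulation_result(grid[i, -1],
                                     matrix(v, nrow = n_members, ncol = 1)))
  }))
  assemble_table(cells)
}

two_level_grid <- list(sex = c("male", "female"), age = c(20, 50),
                       smoking = "non-smoker", bmi = 25, egfr = c(30, 120),
                       hba1c = c(42, 108))

test_that("cell aggregation computes mean, SD (n-1) and SE identities", {
  cell <- list(sex = "male", age = 20, smoking = "smoker", bmi = 25,
               egfr = 90, hba1c = 64)
  res <- simulation_result(cell, matrix(c(10, 20, 30, 40), nrow = 4))
  agg <- aggregate_cell(res)
  expect_equal(agg$life_expectancy, 25.0)
  expect_equal(agg$sd, 12.9099, tolerance = 1e-4)
  expect_equal(agg$se, 6.4550, tolerance = 1e-4)
  expect_identical(agg$se, agg$sd / sqrt(4))
  expect_identical(agg$age_at_death, 20 + agg$life_expectancy)

  flat <- aggregate_cell(simulation_result(cell, matrix(30, nrow = 5)))
  expect_identical(c(flat$life_expectancy, flat$sd, flat$se), c(30, 0, 0))
})

test_that("assembly validates completeness and supports order-free lookup", {
  tab <- toy_table(two_level_grid, function(cell) cell$egfr / 3)
  expect_identical(nrow(tab$cells), 16L)
  expect_identical(length(unique(tab$cells$stratum)), 4L)

  hit <- life_table_lookup(tab, "female", 50, "non-smoker", 25, 120, 42)
  expect_equal(hit$life_expectancy, 40)

  # permutation invariance: shuffled input rows yield the same table
  grid <- build_cell_grid(two_level_grid)
  cells <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i)
    aggregate_cell(simulation_result(grid[i, -1],
                                     matrix(grid$egfr[i] / 3, nrow = 4)))))
  set.seed(1)
  tab2 <- assemble_table(cells[sample(nrow(cells)), ])
  expect_equal(tab2$cells[names(tab$cells)], tab$cells)

  expect_error(assemble_table(cells[-3, ]), "missing cell")
  expect_error(assemble_table(rbind(cells, cells[3, ])), "duplicate")
})

test_that("default grid assembles into 8 age-sex strata of 128 cells", {
  lv <- default_grid_levels()
  grid <- build_cell_grid(lv)
  cells <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i)
    aggregate_cell(simulation_result(grid[i, -1], matrix(50 - i / 100,
                                                         nrow = 1)))))
  tab <- assemble_table(cells)
  expect_identical(nrow(tab$cells), 1024L)
  expect_identical(as.integer(table(tab$cells$stratum)),
                   rep(128L, 8))
})

test_that("colour grading anchors extremes and maps ties identically", {
  vals <- c(29.3, 40.0, 50.6)
  lv <- list(sex = "male", age = 20, smoking = "non-smoker", bmi = 25,
             egfr = c(30, 60, 90), hba1c = 42)
  tab <- toy_table(lv, function(cell) vals[match(cell$egfr, c(30, 60, 90))])
  tab <- colourise(tab)
  d <- tab$cells
  green <- grDevices::rgb(let1d:::.lt_ramp(1), maxColorValue = 255)
  red <- grDevices::rgb(let1d:::.lt_ramp(0), maxColorValue = 255)
  expect_identical(d$colour[which.max(d$life_expectancy)], green)
  expect_identical(d$colour[which.min(d$life_expectancy)], red)
  # interior point sits at the normalised position (40 - 29.3) / 21.3
  mid <- grDevices::rgb(let1d:::.lt_ramp((40 - 29.3) / (50.6 - 29.3)),
                        maxColorValue = 255)
  expect_identical(d$colour[d$life_expectancy == 40], mid)

  # constant stratum: uniform midpoint colour, not an error
  flat <- colourise(toy_table(lv, function(cell) 33))
  expect_identical(unique(flat$cells$colour),
                   grDevices::rgb(let1d:::.lt_ramp(0.5), maxColorValue = 255))

  # colour is monotone in the metric: greyscale lightness increases with LE
  tab16 <- colourise(toy_table(two_level_grid, function(cell) cell$egfr / 3 +
                                 (cell$hba1c == 42) * 2))
  for (g in unique(tab16$cells$stratum)) {
    d <- tab16$cells[tab16$cells$stratum == g, ]
    o <- order(d$life_expectancy)
    lightness <- grDevices::col2rgb(d$grey)[1, ] / 255
    expect_true(all(diff(lightness[o]) >= 0))
  }
})

test_that("whole-table scope normalises across the entire population", {
  tab <- toy_table(two_level_grid, function(cell) cell$age +
                     cell$egfr / 10 + (cell$sex == "male") * 0.1 +
                     (cell$hba1c == 42) * 0.01)
  tab <- colourise(tab, metric = "age_at_death", scope = "table")
  d <- tab$cells
  green <- grDevices::rgb(let1d:::.lt_ramp(1), maxColorValue = 255)
  expect_identical(sum(d$colour == green), 1L)
  expect_identical(d$colour[which.max(d$age_at_death)], green)
})

test_that("stratum gaps compute max minus min per age-sex group", {
  tab <- toy_table(two_level_grid, function(cell)
    ifelse(cell$sex == "male", 30, 36) + (cell$egfr == 120) * 20)
  g <- stratum_gaps(tab)
  expect_identical(nrow(g), 4L)
  expect_true(all(g$gap == 20))
  expect_equal(g$max[g$stratum == "male:20"], 50)
})

test_that("age at death equals baseline age plus life expectancy, exactly", {
  tab <- toy_table(two_level_grid, function(cell) 25 + cell$egfr / 7)
  expect_identical(tab$cells$age_at_death,
                   tab$cells$age + tab$cells$life_expectancy)
})

test_that("CSV and HTML outputs agree and the CSV round-trips losslessly", {
  tab <- colourise(toy_table(two_level_grid,
                             function(cell) 20 + cell$egfr / 7 +
                               (cell$hba1c == 42) * 3.21))
  csv <- withr::local_tempfile(fileext = ".csv")
  html <- withr::local_tempfile(fileext = ".html")
  ghtml <- withr::local_tempfile(fileext = ".html")
  write_life_table(tab, csv, html, ghtml)

  d <- utils::read.csv(csv)
  expect_identical(nrow(d), 16L)
  back <- read_life_table(csv)
  for (v in c("life_expectancy", "sd", "se", "age_at_death", "n_members"))
    expect_identical(back$cells[[v]], tab$cells[[v]])
  expect_identical(back$cells$colour, tab$cells$colour)

  # HTML shows each cell's one-decimal value on its colour
  page <- paste(readLines(html), collapse = "\n")
  for (i in seq_len(nrow(tab$cells))) {
    shown <- sprintf("%.1f", let1d:::.round_half_up(tab$cells$life_expectancy[i]))
    expect_match(page, paste0(">", shown, "<"), fixed = TRUE)
    expect_match(page, tab$cells$colour[i], fixed = TRUE)
  }
  grey_page <- paste(readLines(ghtml), collapse = "\n")
  expect_match(grey_page, tab$cells$grey[1], fixed = TRUE)
})

test_that("display rounding is half away from zero at one decimal", {
  expect_identical(let1d:::.round_half_up(c(29.25, 29.34, -1.25)),
                   c(29.3, 29.3, -1.3))
})
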