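.lt_factors <- function() names(default_grid_levels())

#' Aggregate a cohort's simulation result into one life-table cell
#'
#' The cell's life expectancy is the mean of the per-individual life
#' expectancies (each itself a mean over replications); its SD is the
#' sample standard deviation (n - 1 denominator) across the cohort
#' members, the SE is `sd / sqrt(n_members)`, and the age at death is the
#' baseline age plus the life expectancy (exact identities, asserted by
#' the table invariants).
#'
#' @param result a [simulation_result()].
#' @return One-row `data.frame`: the six factor levels plus
#'   `life_expectancy`, `sd`, `se`, `age_at_death`, `n_members`.
#' @export
aggregate_cell <- function(result) {
  stopifnot(inherits(result, "simulation_result"))
  le <- result$per_individual_mean
  if (!length(le)) stop("empty simulation result")
  n <- length(le)
  m <- mean(le)
  s <- if (n > 1) stats::sd(le) else 0
  cell <- result$cell
  data.frame(sex = cell$sex, age = as.numeric(cell$age),
             smoking = cell$smoking, bmi = as.numeric(cell$bmi),
             egfr = as.numeric(cell$egfr), hba1c = as.numeric(cell$hba1c),
             life_expectancy = m, sd = s, se = s / sqrt(n),
             age_at_death = as.numeric(cell$age) + m, n_members = n,
             stringsAsFactors = FALSE)
}

#' Assemble aggregated cells into a life expectancy table
#'
#' Checks that the aggregated cells form exactly one entry per
#' combination of the observed factor levels (a full Cartesian grid, no
#' duplicates — violations are reported with the offending combination),
#' orders them canonically, and attaches the age-sex stratum of each
#' cell.
#'
#' @param cells `data.frame` of rows from [aggregate_cell()].
#' @param layout list with `rows` and `cols`: which factors span the HTML
#'   table rows and columns. Default rows `(egfr, hba1c)`, columns
#'   `(age, sex, smoking, bmi)` — presentation only, any lossless
#'   arrangement is equivalent.
#' @return Object of class `"life_table"`.
#' @export
assemble_table <- function(cells,
                           layout = list(rows = c("egfr", "hba1c"),
                                         cols = c("age", "sex", "smoking", "bmi"))) {
  fac <- .lt_factors()
  miss <- setdiff(c(fac, "life_expectancy", "sd", "se", "age_at_death",
                    "n_members"), names(cells))
  if (length(miss)) stop("cells missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!setequal(unlist(layout), fac))
    stop("layout must assign each of ", paste(fac, collapse = ", "),
         " to rows or cols")
  levels <- lapply(cells[fac], function(x) sort(unique(x)))
  names(levels) <- fac
  levels$sex <- intersect(c("male", "female"), levels$sex)
  levels$smoking <- intersect(c("smoker", "non-smoker"), levels$smoking)
  grid <- build_cell_grid(levels)
  key <- function(d) do.call(paste, c(d[fac], sep = "|"))
  ck <- key(cells)
  dup <- ck[duplicated(ck)]
  if (length(dup)) stop("duplicate cell(s): ", paste(unique(dup), collapse = "; "))
  gk <- key(grid)
  missing_cells <- setdiff(gk, ck)
  if (length(missing_cells))
    stop("missing cell(s): ", paste(missing_cells, collapse = "; "))
  cells <- cells[match(gk, ck), , drop = FALSE]
  rownames(cells) <- NULL
  cells <- cbind(cell_id = grid$cell_id, cells)
  cells$stratum <- paste(cells$sex, cells$age, sep = ":")
  structure(list(cells = cells, levels = levels, layout = layout),
            class = "life_table")
}

#' Look up one cell by its six factor levels
#'
#' @param table a [assemble_table()] result.
#' @param sex,age,smoking,bmi,egfr,hba1c the factor levels.
#' @return The matching one-row `data.frame`; an error if absent.
#' @export
life_table_lookup <- function(table, sex, age, smoking, bmi, egfr, hba1c) {
  stopifnot(inherits(table, "life_table"))
  d <- table$cells
  hit <- d$sex == sex & d$age == age & d$smoking == smoking &
    d$bmi == bmi & d$egfr == egfr & d$hba1c == hba1c
  if (sum(hit) != 1)
    stop("no cell for combination ",
         paste(sex, age, smoking, bmi, egfr, hba1c, sep = "/"))
  d[hit, , drop = FALSE]
}

# colour anchors: dark red (worst) to green (best), interpolated in Lab
.lt_ramp <- grDevices::colorRamp(c("#A50026", "#006837"), space = "Lab")

.value_to_colour <- function(v) {
  rgb <- .lt_ramp(v)
  grDevices::rgb(rgb[, 1], rgb[, 2], rgb[, 3], maxColorValue = 255)
}

.value_to_grey <- function(v) grDevices::grey(0.2 + 0.7 * v)

#' Colour-grade a life table
#'
#' Maps the chosen metric to a colour gradient: within each scope group
#' (the age-sex strata by default, or the whole table) the group minimum
#' maps to dark red, the maximum to green, with linear interpolation on
#' the normalised value in Lab colour space. A greyscale variant maps the
#' same normalised value to lightness (dark = worst). Ties receive
#' identical colours; a constant group gets the midpoint colour.
#'
#' @param table a [assemble_table()] result.
#' @param metric `"life_expectancy"` or `"age_at_death"`.
#' @param scope `"stratum"` (normalise within each age-sex stratum) or
#'   `"table"` (across the whole table).
#' @return The table with `colour` and `grey` hex columns added.
#' @export
colourise <- function(table, metric = c("life_expectancy", "age_at_death"),
                      scope = c("stratum", "table")) {
  stopifnot(inherits(table, "life_table"))
  metric <- match.arg(metric)
  scope <- match.arg(scope)
  d <- table$cells
  grp <- if (scope == "stratum") d$stratum else rep("all", nrow(d))
  v <- numeric(nrow(d))
  for (g in unique(grp)) {
    i <- grp == g
    x <- d[[metric]][i]
    rng <- range(x)
    v[i] <- if (rng[1] == rng[2]) 0.5 else (x - rng[1]) / (rng[2] - rng[1])
  }
  d$colour <- .value_to_colour(v)
  d$grey <- .value_to_grey(v)
  table$cells <- d
  table$colour_metric <- metric
  table$colour_scope <- scope
  table
}

#' Life-expectancy gaps within age-sex strata
#'
#' For each stratum, the spread between the best and worst cells:
#' `gap = max(metric) - min(metric)`. This is the summary used to state,
#' for example, the gap between worst and best risk-factor combinations
#' among 20-year-old men.
#'
#' @param table a [assemble_table()] result.
#' @param metric column to summarise.
#' @return `data.frame` with `stratum`, `min`, `max`, `gap`.
#' @export
stratum_gaps <- function(table, metric = "life_expectancy") {
  stopifnot(inherits(table, "life_table"))
  d <- table$cells
  out <- do.call(rbind, lapply(split(d[[metric]], d$stratum), function(x)
    data.frame(min = min(x), max = max(x), gap = max(x) - min(x))))
  data.frame(stratum = rownames(out), out, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' @export
print.life_table <- function(x, ...) {
  cat(sprintf("<life_table> %d cell(s), %d age-sex stratum(a)\n",
              nrow(x$cells), length(unique(x$cells$stratum))))
  cat(sprintf("  life expectancy %.1f-%.1f years%s\n",
              min(x$cells$life_expectancy), max(x$cells$life_expectancy),
              if (!is.null(x$colour_metric))
                sprintf("; coloured by %s (%s scope)", x$colour_metric,
                        x$colour_scope) else ""))
  invisible(x)
}

#' @export
summary.life_table <- function(object, ...) {
  g <- stratum_gaps(object)
  cat(sprintf("Life expectancy table: %d cells, %d strata\n",
              nrow(object$cells), nrow(g)))
  print(g, digits = 3)
  invisible(g)
}

#' @export
plot.life_table <- function(x, metric = NULL, ...) {
  d <- x$cells
  if (is.null(metric)) metric <- if (is.null(x$colour_metric))
    "life_expectancy" else x$colour_metric
  if (is.null(d$colour)) x <- colourise(x, metric)
  d <- x$cells
  rk <- interaction(lapply(x$layout$rows, function(f) d[[f]]), drop = FALSE)
  ck <- interaction(lapply(x$layout$cols, function(f) d[[f]]), drop = FALSE)
  ri <- as.integer(rk); ci <- as.integer(ck)
  graphics::plot(NA, xlim = c(0.5, max(ci) + 0.5),
                 ylim = c(max(ri) + 0.5, 0.5), xlab = "", ylab = "",
                 axes = FALSE, main = metric, ...)
  graphics::rect(ci - 0.5, ri - 0.5, ci + 0.5, ri + 0.5, col = d$colour,
                 border = "white")
  graphics::text(ci, ri, sprintf("%.1f", .round_half_up(d[[metric]])),
                 cex = 0.5)
  invisible(x)
}

#' Write a life table to CSV and HTML
#'
#' Writes (a) a tidy CSV with one row per cell (six factor levels, life
#' expectancy, SD, SE, age at death, member count, colour and greyscale
#' hex codes) that round-trips losslessly through [read_life_table()];
#' (b) optionally a self-contained HTML grid in the configured layout
#' with coloured cells and one-decimal values (rounded half away from
#' zero); (c) optionally the greyscale HTML variant.
#'
#' @param table a colourised [assemble_table()] result.
#' @param csv path for the CSV (required).
#' @param html,grey_html optional paths for the HTML renderings.
#' @return Invisible character vector of the files written.
#' @export
write_life_table <- function(table, csv, html = NULL, grey_html = NULL) {
  stopifnot(inherits(table, "life_table"))
  d <- table$cells
  if (is.null(d$colour)) stop("colourise() the table before writing")
  out <- d[c(.lt_factors(), "life_expectancy", "sd", "se", "age_at_death",
             "n_members", "colour", "grey")]
  num <- c("life_expectancy", "sd", "se", "age_at_death")
  for (v in num) out[[v]] <- sprintf("%.17g", out[[v]])
  utils::write.csv(out, csv, row.names = FALSE, quote = FALSE)
  written <- csv
  if (!is.null(html)) {
    writeLines(.render_html(table, grey = FALSE), html)
    written <- c(written, html)
  }
  if (!is.null(grey_html)) {
    writeLines(.render_html(table, grey = TRUE), grey_html)
    written <- c(written, grey_html)
  }
  invisible(written)
}

#' @rdname write_life_table
#' @export
read_life_table <- function(csv) {
  d <- utils::read.csv(csv, stringsAsFactors = FALSE)
  for (v in c("life_expectancy", "sd", "se", "age_at_death"))
    d[[v]] <- as.numeric(d[[v]])
  d$n_members <- as.integer(d$n_members)
  tab <- assemble_table(d[setdiff(names(d), c("colour", "grey"))])
  # reattach the stored colours in canonical order
  key <- do.call(paste, c(d[.lt_factors()], sep = "|"))
  key2 <- do.call(paste, c(tab$cells[.lt_factors()], sep = "|"))
  tab$cells$colour <- d$colour[match(key2, key)]
  tab$cells$grey <- d$grey[match(key2, key)]
  tab
}

# contrast-aware text colour for a cell background
.text_colour <- function(hex) {
  rgb <- grDevices::col2rgb(hex)
  lum <- (0.299 * rgb[1, ] + 0.587 * rgb[2, ] + 0.114 * rgb[3, ]) / 255
  ifelse(lum > 0.5, "#000000", "#ffffff")
}

.render_html <- function(table, grey = FALSE) {
  d <- table$cells
  metric <- if (is.null(table$colour_metric)) "life_expectancy"
            else table$colour_metric
  rows_f <- table$layout$rows
  cols_f <- table$layout$cols
  rlev <- expand.grid(rev(table$levels[rows_f]), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)[, rev(seq_along(rows_f)),
                                                drop = FALSE]
  names(rlev) <- rows_f
  clev <- expand.grid(rev(table$levels[cols_f]), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)[, rev(seq_along(cols_f)),
                                                drop = FALSE]
  names(clev) <- cols_f
  key <- function(x) do.call(paste, c(x, sep = "|"))
  dk <- key(d[c(rows_f, cols_f)])
  esc <- function(x) gsub("&", "&amp;", x, fixed = TRUE)
  head_rows <- vapply(cols_f, function(f)
    paste0("<tr><th>", f, "</th>",
           paste0("<th>", esc(as.character(clev[[f]])), "</th>",
                  collapse = ""), "</tr>"), character(1))
  body <- vapply(seq_len(nrow(rlev)), function(ri) {
    lab <- paste(vapply(rows_f, function(f) as.character(rlev[ri, f]),
                        character(1)), collapse = " / ")
    cells <- vapply(seq_len(nrow(clev)), function(ci) {
      k <- paste(c(unlist(rlev[ri, , drop = TRUE]),
                   unlist(clev[ci, , drop = TRUE])), collapse = "|")
      i <- match(k, dk)
      bg <- if (grey) d$grey[i] else d$colour[i]
      sprintf('<td style="background:%s;color:%s">%.1f</td>', bg,
              .text_colour(bg), .round_half_up(d[[metric]][i]))
    }, character(1))
    paste0("<tr><th>", lab, "</th>", paste(cells, collapse = ""), "</tr>")
  }, character(1))
  c("<!DOCTYPE html>",
    "<html><head><meta charset=\"utf-8\"><title>Life expectancy table</title>",
    "<style>table{border-collapse:collapse;font:11px sans-serif}",
    "td,th{border:1px solid #ddd;padding:2px 5px;text-align:center}</style>",
    "</head><body>",
    sprintf("<p>%s by %s (rows: %s; columns: %s)</p>", metric,
            paste(c(rows_f, cols_f), collapse = ", "),
            paste(rows_f, collapse = " x "), paste(cols_f, collapse = " x ")),
    "<table>", head_rows, body, "</table></body></html>")
}
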