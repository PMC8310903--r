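test_that("linear predictor evaluates coefficient and interaction terms", {
  s <- individual_state(age = 40, sex = "male", hba1c = 65, bmi = 25)

  eq0 <- event_equation("death", "exponential", rate = 0.01)
  expect_identical(linear_predictor(eq0, s), 0)

  eq1 <- event_equation("death", "exponential", rate = 0.01,
                        coefficients = c(hba1c = 0.02))
  expect_equal(linear_predictor(eq1, s), 1.30)

  eq2 <- event_equation("death", "exponential", rate = 0.01,
                        coefficients = c(bmi = 0.1),
                        age_interactions = c(bmi = -0.001))
  expect_equal(linear_predictor(eq2, s), 2.5 - 1.0)

  bad <- event_equation("death", "exponential", rate = 0.01,
                        coefficients = c(not_a_predictor = 1))
  expect_error(linear_predictor(bad, s), "not_a_predictor")
  expect_error(linear_predictor(bad, s), "death")
})

test_that("linear predictor is linear in the coefficient vector", {
  s <- individual_state(age = 35, sex = "female", hba1c = 80, bmi = 28,
                        egfr = 70, current_smoker = 1)
  set.seed(99)
  for (i in 1:20) {
    beta <- runif(3, -0.5, 0.5)
    split <- runif(1, -1, 2)
    eq_whole <- event_equation("x", "exponential", rate = 0.01, fatal = TRUE,
                               coefficients = c(hba1c = beta[1], egfr = beta[2],
                                                current_smoker = beta[3]))
    eq_a <- event_equation("x", "exponential", rate = 0.01, fatal = TRUE,
                           coefficients = c(hba1c = beta[1] * split,
                                            egfr = beta[2], current_smoker = beta[3]))
    eq_b <- event_equation("x", "exponential", rate = 0.01, fatal = TRUE,
                           coefficients = c(hba1c = beta[1] * (1 - split)))
    expect_equal(linear_predictor(eq_a, s) + linear_predictor(eq_b, s),
                 linear_predictor(eq_whole, s))
    # the probability depends on the coefficients only through the lp sum:
    # loading the same total onto the constant term gives the same p
    eq_c <- event_equation("x", "exponential", rate = 0.01, fatal = TRUE,
                           coefficients = c(intercept = linear_predictor(eq_whole, s)))
    expect_equal(annual_event_probability(eq_c, s),
                 annual_event_probability(eq_whole, s))
  }
})

test_that("annual event probability matches closed forms and quadrature oracle", {
  s40 <- individual_state(age = 40, sex = "male")

  expect_identical(annual_event_probability(
    event_equation("death", "exponential", rate = 0), s40), 0)
  expect_equal(annual_event_probability(
    event_equation("death", "exponential", rate = 0.02), s40),
    1 - exp(-0.02))

  cases <- expand.grid(age = c(0, 20, 40.5, 80), lp = c(-1, 0, 0.5, 2),
                       family = c("exponential", "weibull", "gompertz"),
                       stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    shape <- switch(cs$family, exponential = NULL, weibull = 1.7,
                    gompertz = 0.09)
    rate <- switch(cs$family, exponential = 0.015, weibull = 2e-4,
                   gompertz = 8e-5)
    eq <- event_equation("death", cs$family, rate = rate, shape = shape,
                         coefficients = c(intercept = cs$lp))
    s <- individual_state(age = cs$age, sex = "male", age_at_onset = 0)
    expect_equal(annual_event_probability(eq, s),
                 oracle_annual_probability(cs$family, rate, shape,
                                           cs$age, cs$lp),
                 tolerance = 1e-8)
  }
})

test_that("annual event probability is monotone in positive-coefficient predictors", {
  eq <- event_equation("death", "gompertz", rate = 1e-4, shape = 0.08,
                       coefficients = c(hba1c = 0.01))
  p <- vapply(seq(40, 120, by = 10), function(h)
    annual_event_probability(eq, individual_state(age = 30, sex = "male",
                                                  hba1c = h)), numeric(1))
  expect_true(all(diff(p) >= 0))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("probability preconditions and parameter validation are enforced", {
  s <- individual_state(age = 40, sex = "male")
  expect_error(event_equation("death", "weibull", rate = 0.01, shape = -1),
               "shape")
  expect_error(event_equation("death", "exponential", rate = -0.1), "rate")
  dead <- s
  dead["alive"] <- 0
  expect_error(annual_event_probability(
    event_equation("death", "exponential", rate = 0.1), dead), "not alive")
})

test_that("progression applies simultaneous linear updates with clamping", {
  s <- individual_state(age = 30, sex = "female", hba1c = 65, bmi = 25)

  # identity updates leave the state unchanged
  ident <- lapply(c("hba1c", "bmi", "sbp", "tg", "hdl", "ldl", "egfr"),
                  function(v) progression_equation(v, setNames(1, v)))
  s2 <- apply_progression(ident, s)
  expect_equal(unclass(s2), unclass(s))

  # hand-evaluated single update: 0.98 * 65 + 1 = 64.7
  eq <- progression_equation("hba1c", c(intercept = 1.0, hba1c = 0.98))
  expect_equal(apply_progression(list(eq), s)[["hba1c"]], 64.7)

  # zero-noise progression is deterministic
  expect_identical(apply_progression(list(eq), s), apply_progression(list(eq), s))

  # negative linear prediction clamps at zero
  down <- progression_equation("tg", c(intercept = -5))
  expect_identical(apply_progression(list(down), s)[["tg"]], 0)

  # updates are simultaneous: bmi_sq seen by another equation is the
  # start-of-cycle value even though bmi itself changes
  eqs <- list(progression_equation("bmi", c(intercept = 30)),
              progression_equation("sbp", c(bmi_sq = 1)))
  s3 <- apply_progression(eqs, s)
  expect_equal(s3[["sbp"]], 625)   # 25^2, not 30^2
  expect_equal(s3[["bmi_sq"]], 900)  # derived slot refreshed afterwards
})

test_that("binary progression respects logistic limits and absorbing states", {
  s <- individual_state(age = 30, sex = "male")
  never <- progression_equation("microalbuminuria", c(intercept = -50))
  always <- progression_equation("microalbuminuria", c(intercept = 50))
  set.seed(1)
  expect_identical(apply_progression(list(never), s)[["microalbuminuria"]], 0)
  s4 <- apply_progression(list(always), s)
  expect_identical(s4[["microalbuminuria"]], 1)
  # absorbing: a certain-zero transition does not clear the flag
  expect_identical(apply_progression(list(never), s4)[["microalbuminuria"]], 1)

  # smoking transitions preserve current/former exclusivity
  smoker <- individual_state(age = 30, sex = "male", current_smoker = 1)
  quit <- progression_equation("current_smoker", c(intercept = -50))
  s5 <- apply_progression(list(quit), smoker)
  expect_identical(unname(s5[c("current_smoker", "former_smoker")]), c(0, 1))
})

test_that("HbA1c standardisation reproduces the published level pairs", {
  expect_equal(round(ifcc_to_ngsp(c(42, 64, 86, 108))), c(6, 8, 10, 12))
  expect_equal(round(ifcc_to_ngsp(65), 2), 8.10)
  expect_equal(ifcc_to_ngsp(0), 2.152)
  expect_equal(round(ngsp_to_ifcc(c(6, 12))), c(42, 108))
  x <- seq(0, 150, by = 0.37)
  expect_equal(ngsp_to_ifcc(ifcc_to_ngsp(x)), x, tolerance = 1e-9)
  expect_error(ifcc_to_ngsp(-1), ">= 0")
  expect_error(ngsp_to_ifcc(2.0), ">=")
})

test_that("model constructor validates completeness and evaluation order", {
  d <- event_equation("death", "exponential", rate = 0.01)
  expect_s3_class(t1d_model(list(d)), "t1d_model")
  expect_error(t1d_model(list(d), complete = TRUE), "missing")
  expect_error(t1d_model(list(d, d)), "duplicate")
  expect_error(t1d_model(list(d), event_evaluation_order = c("death", "mi")),
               "permutation")
  full <- generate_ground_truth_model(seed = 2)
  expect_setequal(names(full$event_equations), t1d_event_names())
  expect_setequal(names(full$progression_equations), t1d_progression_targets())
})

test_that("model specs round-trip through the YAML configuration format", {
  m <- generate_ground_truth_model(seed = 7)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_model_spec(m, path)
  m2 <- read_model_spec(path, complete = TRUE)
  expect_equal(m2, m, tolerance = 1e-12)

  # schema violations are reported with the offending equation
  cfg <- yaml::read_yaml(path)
  cfg$events$death$family <- NULL
  bad <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, bad)
  expect_error(read_model_spec(bad), "death.*missing family")
})
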