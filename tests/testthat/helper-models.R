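# shared fixtures, built in code

# death-only model with constant annual probability p each cycle
death_only_model <- function(p, half_cycle = TRUE, max_age = 220) {
  t1d_model(list(event_equation("death", "exponential", rate = -log(1 - p))),
            half_cycle_correction = half_cycle, max_age = max_age)
}

# one registry-scale population, generated once and reused across tests
.pop_cache <- new.env(parent = emptyenv())
shared_registry_population <- function() {
  if (is.null(.pop_cache$pop))
    .pop_cache$pop <- generate_registry_population(population_summary(),
                                                   n = 27841, seed = 424242)
  .pop_cache$pop
}

# small toy population with a known 3-combination joint distribution
toy_population <- function() {
  data.frame(a = c(rep(0, 7), 1, 1, 1),
             b = c(rep(0, 7), 0, 0, 1))
}

# quadrature oracle for the annual event probability: integrates the
# hazard h0(t) * exp(lp) over [age, age + 1] independently of the
# closed-form cumulative-hazard increments used by the implementation
oracle_annual_probability <- function(family, rate, shape, age, lp) {
  h0 <- switch(family,
               exponential = function(t) rep(rate, length(t)),
               weibull = function(t) rate * shape * t^(shape - 1),
               gompertz = function(t) rate * exp(shape * t))
  H <- stats::integrate(h0, age, age + 1, rel.tol = 1e-12,
                        abs.tol = 1e-15)$value
  1 - exp(-H * exp(lp))
}
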