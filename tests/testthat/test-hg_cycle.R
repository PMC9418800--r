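test_that("parameter validation rejects over-unity outgoing fractions", {
  expect_error(box_model_params(k_ev = 0.8, k_dw = 0.4), "exceed 1")
  expect_error(box_model_params(atm_dep = -0.1), "non-negative")
  expect_error(box_model_params(nonsense = 1), "unknown parameter")
})

test_that("a zero system stays at zero and a pulse deposits as configured", {
  p <- box_model_params()
  z <- step_annual(rep(0, 6), 0, p)
  expect_equal(unname(z$state), rep(0, 6))
  expect_equal(unname(z$fields), c(0, 0, 0))

  # 100 t pulse into an empty atmosphere, deposition fraction 0.8:
  # 80 t deposited in year one, 40% of it to land, split 0.6/0.3/0.1
  s <- step_annual(rep(0, 6), 100, p)
  expect_equal(s$deposition_t, 80)
  expect_equal(s$state[["soil_fast"]], 80 * 0.4 * 0.6)
  expect_equal(s$state[["ocean_surface"]], 80 * 0.6)
  expect_equal(s$state[["atm"]], 20)
})

test_that("mercury mass balance closes to 1e-9 relative at every step", {
  p <- box_model_params()
  set.seed(3)
  emis <- runif(60, 0, 1000)
  run <- run_scenario(emis, p, years = 1961:2020)
  stored <- rowSums(run[, hg_compartments])
  expect_equal(stored + cumsum(run$burial_t), cumsum(run$emission_t),
               tolerance = 1e-9)
})

test_that("the steady state is a fixed point of the annual update", {
  p <- box_model_params()
  m <- steady_state(p, 2500)
  nxt <- step_annual(m, 2500, p)$state
  expect_equal(nxt, m, tolerance = 1e-9)
})

test_that("scenario responses are linear in emissions from a zero state", {
  p <- box_model_params()
  e1 <- small_world$emissions
  r1 <- run_scenario(e1, p)
  e2 <- dplyr::mutate(e1, mass_t = 2 * mass_t)
  r2 <- run_scenario(e2, p)
  expect_equal(r2$D, 2 * r1$D, tolerance = 1e-12)
  expect_equal(r2$P, 2 * r1$P, tolerance = 1e-12)
  expect_equal(r2$S, 2 * r1$S, tolerance = 1e-12)

  # superposition of two different series
  set.seed(5)
  yrs <- 1990:2010
  ea <- runif(21, 0, 500); eb <- runif(21, 0, 500)
  ra <- run_scenario(ea, p, years = yrs)
  rb <- run_scenario(eb, p, years = yrs)
  rab <- run_scenario(ea + eb, p, years = yrs)
  expect_equal(rab$D, ra$D + rb$D, tolerance = 1e-12)
})

test_that("deposition lags its equilibrium level under growing emissions", {
  p <- box_model_params()
  yrs <- 1970:2012
  emis <- 100 * 1.05^(seq_along(yrs) - 1)
  run <- run_scenario(emis, p, years = yrs)
  # equilibrium deposition for the current emission rate, from steady state
  d_eq <- vapply(emis, function(e) {
    m <- steady_state(p, e)
    p$atm_dep * (m[["atm"]] + e) * 1e12 / p$earth_area_m2
  }, numeric(1))
  expect_true(all(run$D <= d_eq + 1e-12))
})

test_that("legacy reservoirs damp deposition growth from a spun-up state", {
  p <- box_model_params()
  yrs <- 1970:2012
  emis <- 100 * 1.05^(seq_along(yrs) - 1)
  init <- steady_state(p, p$all_sources_emission_t)
  run <- run_scenario(emis, p, years = yrs, init = init)
  d_growth <- run$D[length(yrs)] / run$D[1]
  e_growth <- emis[length(yrs)] / emis[1]
  expect_lt(d_growth, e_growth)
})

test_that("attribution ratios behave at the identity and zero limits", {
  p <- box_model_params()
  base <- run_baseline(p, 2000:2012)
  expect_equal(unname(attribution_ratios(base, base, 2012)), c(1, 1, 1))

  zero <- run_scenario(rep(0, 13), p, years = 2000:2012)
  expect_equal(unname(attribution_ratios(zero, base, 2012)), c(0, 0, 0))
  expect_error(attribution_ratios(base, zero, 2012), "strictly positive")

  # a scenario exceeding its baseline is clipped with a warning
  big <- run_scenario(rep(2 * p$all_sources_emission_t, 13), p,
                      years = 2000:2012,
                      init = 2 * steady_state(p, p$all_sources_emission_t))
  expect_warning(r <- attribution_ratios(big, base, 2012), "clipping")
  expect_true(all(r <= 1))
})
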