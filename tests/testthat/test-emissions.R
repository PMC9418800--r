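test_that("cumulative emissions sum annual masses and are window-additive", {
  e <- emission_series(2001:2005, rep(10, 5))
  expect_equal(cumulative_emissions(e, c(2001, 2005)), 50)
  expect_equal(cumulative_emissions(e, c(2003, 2003)), 10)

  set.seed(11)
  e2 <- emission_series(1970:2012, runif(43, 0, 900))
  whole <- cumulative_emissions(e2, c(1970, 2012))
  split <- cumulative_emissions(e2, c(1970, 1989)) +
    cumulative_emissions(e2, c(1990, 2012))
  expect_equal(split, whole)

  expect_error(cumulative_emissions(e, c(1999, 2000)), "outside")
  expect_error(cumulative_emissions(e, c(2005, 2001)), "first <= last")
  expect_error(emission_series(2001:2003, c(1, -2, 3)), "non-negative")
  expect_error(emission_series(c(2001, 2001, 2002), rep(1, 3)),
               "strictly increasing")
})

test_that("regional shares form a partition of the total", {
  e <- dplyr::bind_rows(
    emission_series(2000:2002, rep(10, 3), "Sub-Saharan Africa"),
    emission_series(2000:2002, rep(30, 3), "South America"))
  sh <- regional_share(e)
  expect_equal(sum(sh$share), 1, tolerance = 1e-12)
  expect_equal(sh$share[sh$region == "South America"], 0.75)

  one <- regional_share(emission_series(2000:2002, rep(5, 3),
                                        "tropical Asia"))
  expect_equal(one$share, 1)

  zero <- emission_series(2000:2002, rep(0, 3), "rest-of-world")
  expect_error(regional_share(zero), "zero total")
})

test_that("proxy extrapolation is ratio-to-base-year index scaling", {
  base <- emission_series(2008:2012, c(700, 720, 750, 780, 800))
  flat <- proxy_series(2012:2021, rep(100, 10), "gold_supply")
  ex <- extrapolate_by_proxy(base, flat, 2013:2021)
  expect_equal(ex$mass_t[ex$proxy == "gold_supply"], rep(800, 9))

  doubled <- proxy_series(2012:2013, c(100, 200), "gold_price")
  ex2 <- extrapolate_by_proxy(base, doubled, 2013)
  expect_equal(ex2$mass_t[ex2$proxy == "gold_price"], 1600)

  # the unweighted mean lies inside the per-proxy envelope every year
  pr <- dplyr::bind_rows(
    proxy_series(2012:2016, c(100, 90, 80, 95, 70), "gold_price"),
    proxy_series(2012:2016, c(100, 110, 120, 118, 125), "mine_production"),
    proxy_series(2012:2016, c(100, 101, 97, 99, 103), "gold_demand"))
  ex3 <- extrapolate_by_proxy(base, pr, 2013:2016)
  by_year <- split(ex3, ex3$year)
  for (b in by_year) {
    m <- b$mass_t[b$proxy == "multi_proxy_mean"]
    others <- b$mass_t[b$proxy != "multi_proxy_mean"]
    expect_gte(m, min(others))
    expect_lte(m, max(others))
    expect_equal(m, mean(others))
  }

  no_base <- proxy_series(2013:2021, 1:9, "gold_demand")
  expect_error(extrapolate_by_proxy(base, no_base, 2013:2021),
               "no value in base year")
})

test_that("re-basing on a multi-year proxy mean is supported", {
  base <- emission_series(2010:2012, c(750, 780, 800))
  p <- proxy_series(2010:2013, c(80, 100, 120, 120), "gold_price")
  ex_final <- extrapolate_by_proxy(base, p, 2013)
  ex_mean <- extrapolate_by_proxy(base, p, 2013, rebase = "mean")
  expect_equal(ex_final$mass_t[ex_final$proxy == "gold_price"],
               800 * 120 / 120)
  expect_equal(ex_mean$mass_t[ex_mean$proxy == "gold_price"],
               800 * 120 / 100)
})

test_that("emission and proxy CSV round-trips preserve the tables", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_emissions_csv(small_world$emissions, tmp)
  back <- read_emissions_csv(tmp)
  expect_equal(as.data.frame(back), as.data.frame(small_world$emissions),
               tolerance = 1e-12)
})
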