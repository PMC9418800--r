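test_that("benefit transfer is the income power law", {
  expect_equal(benefit_transfer(1000, 5e4, 5e4), 1000)
  expect_equal(benefit_transfer(1000, 5e4, 2.5e4, elasticity = 1), 500)
  expect_equal(benefit_transfer(1000, 5e4, 100, elasticity = 0), 1000)
  # elasticity 1 preserves income ratios across countries
  v <- benefit_transfer(1000, 5e4, c(1e4, 3e4), elasticity = 1)
  expect_equal(v[2] / v[1], 3)
  expect_error(benefit_transfer(1000, 5e4, -1), "positive")
})

test_that("monetization combines the endpoints linearly", {
  h <- monetize(10, 1, el = 2e4, vsl = 6.3e6)
  expect_equal(h$H_total, 6.5e6)
  expect_equal(h$H_IQ, 2e5)
  z <- monetize(0, 0, 2e4, 6.3e6)
  expect_equal(z$H_total, 0)
  expect_equal(monetize(20, 2, 2e4, 6.3e6)$H_total, 2 * h$H_total)
})

test_that("value attribution by differencing matches monetized impacts", {
  hb <- monetize(10, 1, 2e4, 6.3e6)
  expect_equal(attribute_value(hb, hb)$H_total, 0)
  expect_equal(attribute_value(hb, monetize(0, 0, 2e4, 6.3e6))$H_total,
               hb$H_total)
  expect_error(attribute_value(monetize(1, 0, 1, 1), monetize(2, 0, 1, 1)),
               "negative attribution")

  # consistency with endpoint-level differencing for random valid inputs
  p <- dose_response_params()
  set.seed(41)
  for (k in 1:15) {
    eb <- runif(1, 0.01, 0.4); ea <- runif(1, 0, eb)
    el <- runif(1, 1e3, 3e4); vsl <- runif(1, 1e5, 8e6)
    nb <- 1e5
    h_base <- monetize(iq_decrement(eb, 65, p, nb)$total,
                       fha_deaths(eb, 65, p, toy_demog), el, vsl)
    h_cf <- monetize(iq_decrement(eb - ea, 65, p, nb)$total,
                     fha_deaths(eb - ea, 65, p, toy_demog), el, vsl)
    att <- attribute_value(h_base, h_cf)
    imp <- attributable_impact(eb, ea, 65, p, toy_demog, nb)
    direct <- monetize(imp$dIQ_total, imp$dCF, el, vsl)
    expect_equal(att$H_total, direct$H_total, tolerance = 1e-9)
  }
})

test_that("discounting compounds toward the base year and is linear", {
  d <- discount_series(100, 2018, rate = 0.03, base_year = 2020)
  expect_equal(d$total, 100 * 1.03^2)
  expect_equal(discount_series(c(5, 7), 2000:2001, rate = 0)$discounted,
               c(5, 7))

  # constant series: closed-form geometric sum
  yrs <- 2000:2010
  d2 <- discount_series(rep(100, 11), yrs, 0.03, base_year = 2010)
  closed <- 100 * sum(1.03^(2010 - yrs))
  expect_equal(d2$total, closed)

  # sum-then-discount equals discount-then-sum
  set.seed(51)
  a <- runif(11); b <- runif(11)
  expect_equal(discount_series(a + b, yrs, 0.03, 2020)$total,
               discount_series(a, yrs, 0.03, 2020)$total +
                 discount_series(b, yrs, 0.03, 2020)$total,
               tolerance = 1e-12)
})

test_that("currency adjustment chains consistently", {
  expect_equal(currency_adjust(100, 2012, 2012), 100)
  ab <- currency_adjust(100, 2005, 2012)
  bc <- currency_adjust(ab, 2012, 2020)
  expect_equal(bc, currency_adjust(100, 2005, 2020), tolerance = 1e-12)
  expect_error(currency_adjust(100, 1971, 2020), "missing")
})
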