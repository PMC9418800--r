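intake_of <- function(...) food_profile(..., value_name = "intake_kg_day")
conc_of <- function(...) food_profile(..., value_name = "mehg_ug_kg")

test_that("baseline intake is the body-weight-normalized sum of I x C", {
  i <- intake_of(seafood = 0.05)
  c <- conc_of(seafood = 100)
  expect_equal(baseline_exposure(i, c, 70)$E_baseline, 5 / 70)

  expect_equal(baseline_exposure(intake_of(), conc_of(), 60)$E_baseline, 0)

  i3 <- intake_of(seafood = 0.02, freshwater_fish = 0.01, rice = 0.1)
  c3 <- conc_of(seafood = 80, freshwater_fish = 60, rice = 5)
  e1 <- baseline_exposure(i3, c3, 65)$E_baseline
  c6 <- conc_of(seafood = 160, freshwater_fish = 120, rice = 10)
  expect_equal(baseline_exposure(i3, c6, 65)$E_baseline, 2 * e1)

  expect_error(baseline_exposure(i3, c3, 0), "positive")
})

test_that("strata are summed within categories", {
  i <- intake_of(seafood = c(0.02, 0.01), rice = 0.1)
  c <- conc_of(seafood = c(120, 300), rice = 4)
  e <- baseline_exposure(i, c, 60)
  expect_equal(e$by_category[["seafood"]], 0.02 * 120 + 0.01 * 300)
  expect_equal(e$E_baseline, (2.4 + 3 + 0.4) / 60)
})

test_that("ASGM exposure scales each pathway by its compartment ratio", {
  i <- intake_of(seafood = 0.02, freshwater_fish = 0.01, rice = 0.1)
  c <- conc_of(seafood = 80, freshwater_fish = 60, rice = 5)
  full <- asgm_exposure(i, c, 65, c(rD = 1, rP = 1, rS = 1))
  expect_equal(full$E_asgm, full$E_baseline)
  none <- asgm_exposure(i, c, 65, c(rD = 0, rP = 0, rS = 0))
  expect_equal(none$E_asgm, 0)

  # equal per-category exposures: the ASGM share is the mean of the ratios
  ie <- intake_of(seafood = 0.01, freshwater_fish = 0.01, rice = 0.01)
  ce <- conc_of(seafood = 50, freshwater_fish = 50, rice = 50)
  r <- c(rD = 0.122, rP = 0.104, rS = 0.0063)
  eq <- asgm_exposure(ie, ce, 65, r)
  expect_equal(eq$E_asgm / eq$E_baseline, mean(r), tolerance = 1e-12)

  # category mapping: seafood responds to rP only
  sea <- asgm_exposure(intake_of(seafood = 0.05), conc_of(seafood = 100),
                       70, c(rD = 0.9, rP = 0.2, rS = 0.9))
  expect_equal(sea$E_asgm, 0.2 * sea$E_baseline)

  expect_error(asgm_exposure(i, c, 65, c(rD = 1.2, rP = 0.5, rS = 0.5)),
               "\\[0, 1\\]")
})

test_that("ASGM exposure is bounded by baseline and monotone in each ratio", {
  i <- intake_of(seafood = 0.03, freshwater_fish = 0.008, rice = 0.12)
  c <- conc_of(seafood = 70, freshwater_fish = 50, rice = 6)
  set.seed(9)
  for (k in 1:25) {
    r <- c(rD = runif(1), rP = runif(1), rS = runif(1))
    e <- asgm_exposure(i, c, 62, r)
    expect_lte(e$E_asgm, e$E_baseline + 1e-15)
    r2 <- pmin(r + c(rD = 0.1, rP = 0, rS = 0), 1)
    expect_gte(asgm_exposure(i, c, 62, r2)$E_asgm, e$E_asgm)
  }
})

test_that("the vectorized country table agrees with the scalar operations", {
  ratios <- tibble::tibble(year = 2012, rD = 0.122, rP = 0.104, rS = 0.0063)
  diet <- small_world$diet[small_world$diet$year == 2012, ]
  tbl <- country_exposure(diet, ratios)
  one <- diet[diet$country == diet$country[1], ]
  i <- dplyr::transmute(one, category, stratum, intake_kg_day)
  c <- dplyr::transmute(one, category, stratum, mehg_ug_kg)
  direct <- asgm_exposure(i, c, one$bw_kg[1],
                          c(rD = 0.122, rP = 0.104, rS = 0.0063))
  row <- tbl[tbl$country == one$country[1], ]
  expect_equal(row$E_baseline, direct$E_baseline)
  expect_equal(row$E_asgm, direct$E_asgm)
})
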