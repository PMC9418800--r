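#' Consumer price index used for currency-year conversion
#'
#' US CPI-U annual averages (1982-84 = 100) for the years the valuation
#' needs; used to restate the reference earning-loss (2008 USD) and
#' value-of-statistical-life (2005 USD) coefficients in the reporting
#' currency year.
#'
#' @return Named numeric vector, names are years.
#' @export
default_cpi <- function() {
  c(`1970` = 38.8, `1975` = 53.8, `1980` = 82.4, `1985` = 107.6,
    `1990` = 130.7, `1995` = 152.4, `2000` = 172.2, `2005` = 195.3,
    `2008` = 215.303, `2010` = 218.056, `2012` = 229.594,
    `2015` = 237.017, `2020` = 258.811, `2021` = 270.970)
}

#' Economic valuation parameters
#'
#' @param el_ref Lifelong earning loss per IQ point in the reference
#'   economy (USD per point); default $18,832 in 2008 USD.
#' @param el_ref_year Currency year of `el_ref`.
#' @param vsl_ref Value of statistical life (USD); default $6.3 million in
#'   2005 USD.
#' @param vsl_ref_year Currency year of `vsl_ref`.
#' @param ref_income PPP-adjusted GDP per capita of the reference economy
#'   (USD person-1 yr-1) against which country values are transferred.
#' @param elasticity Income elasticity of the benefit transfer; 1 is pure
#'   proportional scaling.
#' @param discount_rate Annual discount rate (default 3%).
#' @param discount_base_year Year values are discounted to (2020 by
#'   default; 2012 is the supported alternative).
#' @param cpi Named CPI vector, see [default_cpi()].
#' @return An `econ_params` list.
#' @export
econ_params <- function(el_ref = 18832, el_ref_year = 2008,
                        vsl_ref = 6.3e6, vsl_ref_year = 2005,
                        ref_income = 48000, elasticity = 1,
                        discount_rate = 0.03, discount_base_year = 2020,
                        cpi = default_cpi()) {
  if (el_ref <= 0 || vsl_ref <= 0 || ref_income <= 0)
    stop("monetary reference values must be positive")
  if (discount_rate < 0 || discount_rate >= 1)
    stop("discount rate must lie in [0, 1)")
  structure(list(el_ref = el_ref, el_ref_year = el_ref_year,
                 vsl_ref = vsl_ref, vsl_ref_year = vsl_ref_year,
                 ref_income = ref_income, elasticity = elasticity,
                 discount_rate = discount_rate,
                 discount_base_year = discount_base_year, cpi = cpi),
            class = "econ_params")
}

#' Transfer a monetary value to another economy by income
#'
#' `value = ref_value * (target_income / ref_income)^elasticity`, the
#' standard benefit-transfer power law on PPP-adjusted GDP per capita.
#'
#' @param ref_value Reference monetary value (USD).
#' @param ref_income,target_income Positive PPP GDP per capita.
#' @param elasticity Income elasticity (1 = proportional).
#' @return Transferred value (USD), vectorized over `target_income`.
#' @export
benefit_transfer <- function(ref_value, ref_income, target_income,
                             elasticity = 1) {
  if (any(ref_income <= 0) || any(target_income <= 0))
    stop("incomes must be positive")
  ref_value * (target_income / ref_income)^elasticity
}

#' Restate a value in another currency year
#'
#' Multiplicative price-index adjustment; the chain
#' `adjust(a -> b) * adjust(b -> c)` equals `adjust(a -> c)` exactly.
#'
#' @param value Monetary value (USD of `from_year`).
#' @param from_year,to_year Currency years; both must be present in `cpi`.
#' @param cpi Named CPI vector, see [default_cpi()].
#' @return Value in `to_year` USD.
#' @export
currency_adjust <- function(value, from_year, to_year, cpi = default_cpi()) {
  f <- cpi[as.character(from_year)]
  t <- cpi[as.character(to_year)]
  if (anyNA(f) || anyNA(t))
    stop("CPI factor missing for year ", from_year, " or ", to_year)
  value * unname(t / f)
}

#' Monetize a health impact
#'
#' `H = EL * dIQ + VSL * dCF`; the two components are retained so the
#' endpoint composition of the loss can be reported.
#'
#' @param d_iq IQ points lost (points yr-1).
#' @param d_cf Fatal heart attacks (deaths yr-1).
#' @param el Earning loss per IQ point (USD, already transferred and in
#'   the reporting currency year).
#' @param vsl Value of statistical life (USD, ditto).
#' @return List with `H_IQ`, `H_FHA`, `H_total` (USD yr-1).
#' @export
monetize <- function(d_iq, d_cf, el, vsl) {
  if (any(c(d_iq, d_cf, el, vsl) < 0)) stop("inputs must be non-negative")
  h_iq <- el * d_iq
  h_fha <- vsl * d_cf
  list(H_IQ = h_iq, H_FHA = h_fha, H_total = h_iq + h_fha)
}

#' Attribute monetized losses to a source by differencing
#'
#' Componentwise `H(baseline) - H(counterfactual without the source)`;
#' exact for the linear IQ component and consistent with
#' [attributable_impact()] for the concave endpoint.
#'
#' @param H_baseline,H_counterfactual Lists as returned by [monetize()].
#' @return List with attributed `H_IQ`, `H_FHA`, `H_total`.
#' @export
attribute_value <- function(H_baseline, H_counterfactual) {
  out <- Map(function(b, c) b - c,
             H_baseline[c("H_IQ", "H_FHA", "H_total")],
             H_counterfactual[c("H_IQ", "H_FHA", "H_total")])
  if (any(unlist(out) < -1e-9))
    stop("negative attribution: counterfactual exceeds baseline")
  lapply(out, function(x) pmax(x, 0))
}

#' Discount an annual value series to a base year
#'
#' `value(y) * (1 + rate)^(base_year - y)`: years before the base are
#' compounded up, years after are discounted down.
#'
#' @param values Annual values (USD).
#' @param years Years aligned with `values`.
#' @param rate Annual discount rate.
#' @param base_year Year to discount to.
#' @return List with `discounted` (per-year) and `total`.
#' @export
discount_series <- function(values, years, rate = 0.03, base_year = 2020) {
  stopifnot(length(values) == length(years))
  d <- values * (1 + rate)^(base_year - years)
  list(discounted = d, total = sum(d))
}
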