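#' Troy ounces per metric ton
#' @export
TROY_OZ_PER_TON <- 32150.7

#' Gross revenue of gold production
#'
#' Revenue is the gross value of the metal at the annual-average price:
#' `production (t) * 32,150.7 oz t-1 * price (USD oz-1)`.
#'
#' @param production_t Gold produced (metric tons), vectorized.
#' @param price_usd_oz Gold price (USD per troy ounce), vectorized.
#' @return Revenue in USD.
#' @examples
#' gold_revenue(86, 35) # ~ $97 million (1970)
#' @export
gold_revenue <- function(production_t, price_usd_oz) {
  if (any(production_t < 0) || any(price_usd_oz < 0))
    stop("production and price must be non-negative")
  production_t * TROY_OZ_PER_TON * price_usd_oz
}

#' Loss-to-earning ratio of health losses against gold revenue
#'
#' @param loss Annual monetized health losses (USD), aligned with
#'   `revenue`.
#' @param revenue Annual gold revenue (USD).
#' @return List with `annual` (elementwise ratio; `NA` with a warning where
#'   revenue is zero) and `cumulative` (sum of losses over sum of
#'   revenues).
#' @export
loss_earning_ratio <- function(loss, revenue) {
  stopifnot(length(loss) == length(revenue))
  if (sum(revenue) <= 0) stop("total revenue must be positive")
  annual <- ifelse(revenue > 0, loss / revenue, NA_real_)
  if (anyNA(annual)) warning("zero-revenue year(s); annual ratio undefined there")
  list(annual = annual, cumulative = sum(loss) / sum(revenue))
}

#' Average annual geometric growth rate between two endpoints
#'
#' `(v_end / v_start)^(1 / n_years) - 1`.
#'
#' @param v_start,v_end Positive endpoint values.
#' @param n_years Number of years between them (>= 1).
#' @return Annual rate (fraction).
#' @examples
#' geometric_growth_rate(0.59, 7.1, 42) # ~0.061
#' @export
geometric_growth_rate <- function(v_start, v_end, n_years) {
  if (v_start <= 0 || v_end <= 0) stop("endpoint values must be positive")
  if (n_years < 1) stop("n_years must be >= 1")
  (v_end / v_start)^(1 / n_years) - 1
}

#' Cost of a mercury-capture intervention
#'
#' Retorts capture mercury vapor during amalgam burning; the program cost
#' is simply miners times unit cost.
#'
#' @param n_miners Number of miners equipped.
#' @param unit_cost Cost per retort (USD).
#' @return USD.
#' @export
intervention_cost <- function(n_miners, unit_cost = 20) {
  if (n_miners < 0 || unit_cost < 0) stop("inputs must be non-negative")
  n_miners * unit_cost
}

#' Ratio of the global general-population risk to the miners' own risk
#'
#' The mining population's burden is approximated as a fixed fraction of
#' the all-source global methylmercury risk; the ratio compares the
#' ASGM-attributable loss borne by the general population against that
#' local burden.
#'
#' @param global_annual_loss ASGM-attributable loss to the general
#'   population (USD yr-1).
#' @param total_mehg_loss All-source global methylmercury loss (USD yr-1).
#' @param miner_fraction Fraction of `total_mehg_loss` borne by miners and
#'   their communities.
#' @return Dimensionless ratio.
#' @export
miner_vs_global_ratio <- function(global_annual_loss, total_mehg_loss,
                                  miner_fraction) {
  if (total_mehg_loss <= 0 || miner_fraction <= 0)
    stop("denominator must be positive")
  global_annual_loss / (miner_fraction * total_mehg_loss)
}
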