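#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Reporting continents for loss aggregation
#' @export
report_regions <- c("Europe", "Asia", "North America", "Africa",
                    "South America", "Oceania")

#' Configuration of the synthetic world generator
#'
#' The generator emulates the statistical structure of the inventories the
#' analysis consumes: a regional ASGM emission inventory, country tables of
#' food intake and food methylmercury (right-skewed, hence log-normal
#' across countries), demography, baseline fatal-heart-attack incidence and
#' PPP income, a gold market, and market proxy series. All draws are fixed
#' by `seed`.
#'
#' @param n_countries Number of synthetic countries.
#' @param seed Integer seed fixing every draw.
#' @param years Years covered by the emission inventory and country tables.
#' @param regional_totals_t Named vector of 1970-2012 ASGM emission totals
#'   by source region (t).
#' @param emission_growth_factor Ratio of final-year to first-year annual
#'   emission.
#' @param emission_jitter_sd Log-scale year-to-year jitter of the emission
#'   path (totals are preserved exactly); 0 gives a clean geometric path.
#' @param intake_meanlog,intake_sdlog Named (seafood, freshwater_fish,
#'   rice) log-normal location/scale of per-capita intake (kg day-1).
#' @param conc_meanlog,conc_sdlog Ditto for food MeHg (ug kg-1).
#' @param pop_2012_total Global population in 2012.
#' @param pop_sdlog Dispersion of country population sizes.
#' @param birth_rate_range Crude birth rate range (births person-1 yr-1).
#' @param adult_fraction Fraction of population treated as adults for the
#'   cardiovascular endpoint.
#' @param fha_incidence_male,fha_incidence_female Baseline fatal-heart-attack
#'   incidence medians (deaths person-1 yr-1).
#' @param fha_incidence_sdlog Country dispersion of incidence.
#' @param gdp_pc_median,gdp_pc_sdlog PPP GDP per capita distribution (2012
#'   USD person-1).
#' @param bw_range Mean adult body weight range (kg).
#' @param pop_growth,newborn_growth,gdp_growth Annual growth rates used to
#'   roll the 2012 tables back through the run window.
#' @return A `synthetic_world_config` list.
#' @export
synthetic_world_config <- function(
    n_countries = 20, seed = 1, years = 1970:2012,
    regional_totals_t = c("Sub-Saharan Africa" = 4970,
                          "South America" = 4470,
                          "tropical Asia" = 2610,
                          "rest-of-world" = 3350),
    emission_growth_factor = 6.8, emission_jitter_sd = 0.03,
    intake_meanlog = c(seafood = log(0.030), freshwater_fish = log(0.008),
                       rice = log(0.12)),
    intake_sdlog = c(seafood = 0.8, freshwater_fish = 0.9, rice = 1.0),
    conc_meanlog = c(seafood = log(60), freshwater_fish = log(50),
                     rice = log(4)),
    conc_sdlog = c(seafood = 0.4, freshwater_fish = 0.4, rice = 0.5),
    pop_2012_total = 7.05e9, pop_sdlog = 1.2,
    birth_rate_range = c(0.010, 0.028), adult_fraction = 0.65,
    fha_incidence_male = 1.3e-3, fha_incidence_female = 0.9e-3,
    fha_incidence_sdlog = 0.5,
    gdp_pc_median = 13000, gdp_pc_sdlog = 1.0, bw_range = c(55, 75),
    pop_growth = 0.015, newborn_growth = 0.003, gdp_growth = 0.033) {
  cfg <- as.list(environment())
  if (any(regional_totals_t < 0)) stop("regional totals must be non-negative")
  if (!setequal(names(regional_totals_t), asgm_regions))
    stop("regional totals must cover exactly the declared source regions")
  if (emission_growth_factor <= 0 || n_countries < 1)
    stop("infeasible configuration")
  stopifnot(all(intake_sdlog > 0), all(conc_sdlog > 0), pop_sdlog > 0,
            gdp_pc_sdlog > 0, fha_incidence_sdlog > 0,
            adult_fraction > 0, adult_fraction <= 1)
  structure(cfg, class = "synthetic_world_config")
}

#' @keywords internal
synthetic_emissions <- function(cfg) {
  yrs <- cfg$years
  n <- length(yrs)
  g <- cfg$emission_growth_factor^(1 / (n - 1))
  shape <- g^(seq_len(n) - 1)
  if (cfg$emission_jitter_sd > 0) {
    jit <- stats::rlnorm(n, 0, cfg$emission_jitter_sd)
    jit[c(1, n)] <- 1   # keep the endpoint growth factor exact
    shape <- shape * jit
  }
  dplyr::bind_rows(lapply(names(cfg$regional_totals_t), function(reg) {
    tibble::tibble(year = yrs, region = reg, scenario = "asgm_only",
                   mass_t = shape / sum(shape) * cfg$regional_totals_t[[reg]])
  }))
}

#' @keywords internal
stylized_gold_market <- function(years = 1970:2012) {
  # production: geometric between the 86 t (1970) and 590 t (2012) anchors;
  # price: piecewise geometric through ~$35 (1970), ~$420 (2005), ~$1776
  # (2012) per troy oz
  production <- 86 * (590 / 86)^((years - 1970) / 42)
  price <- ifelse(years <= 2005,
                  35 * (420 / 35)^((years - 1970) / 35),
                  420 * (1776 / 420)^((years - 2005) / 7))
  tibble::tibble(year = years, production_t = production,
                 price_usd_oz = price,
                 revenue_usd = gold_revenue(production, price))
}

#' @keywords internal
stylized_proxies <- function() {
  yrs <- 2012:2021
  dplyr::bind_rows(
    proxy_series(yrs, c(100, 84.5, 75.9, 69.5, 75.0, 75.3, 76.0, 83.5,
                        106.1, 107.8), "gold_price"),
    proxy_series(yrs, c(100, 104.1, 111.2, 115.2, 115.6, 120.1, 122.7,
                        122.7, 119.0, 119.0), "mine_production"),
    proxy_series(yrs, c(100, 107.5, 95.9, 95.2, 97.8, 93.2, 99.8, 98.9,
                        82.9, 91.7), "gold_demand"),
    proxy_series(yrs, c(100, 95.6, 98.0, 96.7, 99.9, 98.9, 104.5, 108.2,
                        106.1, 104.8), "gold_supply"))
}

#' Generate a complete synthetic input bundle
#'
#' Emits every table the pipeline consumes. Country-level quantities are
#' drawn once for 2012 and rolled back through the window with the
#' configured growth rates (population 1.5% yr-1, newborns 0.3% yr-1,
#' income 3.3% yr-1 by default); intake and food concentrations are held
#' constant in time, since the baseline environment is taken as stationary.
#'
#' @param cfg A [synthetic_world_config()].
#' @return A list of tibbles: `emissions`, `diet`, `demog`, `econ`,
#'   `gold`, `proxies`, `regions`, plus the `config`.
#' @export
generate_world <- function(cfg = synthetic_world_config()) {
  stopifnot(inherits(cfg, "synthetic_world_config"))
  with_seed(cfg$seed, {
    yrs <- cfg$years
    final <- max(yrs)
    countries <- sprintf("C%02d", seq_len(cfg$n_countries))
    emissions <- synthetic_emissions(cfg)

    region <- sample(report_regions, cfg$n_countries, replace = TRUE,
                     prob = c(0.2, 0.3, 0.1, 0.2, 0.12, 0.08))
    regions <- tibble::tibble(country = countries, region = region)

    pop <- stats::rlnorm(cfg$n_countries, 0, cfg$pop_sdlog)
    pop <- pop / sum(pop) * cfg$pop_2012_total
    birth_rate <- stats::runif(cfg$n_countries, cfg$birth_rate_range[1],
                               cfg$birth_rate_range[2])
    bw <- stats::runif(cfg$n_countries, cfg$bw_range[1], cfg$bw_range[2])
    inc_m <- stats::rlnorm(cfg$n_countries, log(cfg$fha_incidence_male),
                           cfg$fha_incidence_sdlog)
    inc_f <- stats::rlnorm(cfg$n_countries, log(cfg$fha_incidence_female),
                           cfg$fha_incidence_sdlog)
    gdp <- stats::rlnorm(cfg$n_countries, log(cfg$gdp_pc_median),
                         cfg$gdp_pc_sdlog)

    diet0 <- dplyr::bind_rows(lapply(food_categories, function(cat) {
      tibble::tibble(
        country = countries, category = cat, stratum = 1L,
        intake_kg_day = stats::rlnorm(cfg$n_countries,
                                      cfg$intake_meanlog[[cat]],
                                      cfg$intake_sdlog[[cat]]),
        mehg_ug_kg = stats::rlnorm(cfg$n_countries,
                                   cfg$conc_meanlog[[cat]],
                                   cfg$conc_sdlog[[cat]]),
        bw_kg = bw)
    }))
    diet <- tidyr::crossing(year = yrs, diet0) |>
      dplyr::arrange(.data$country, .data$year, .data$category)

    base <- tibble::tibble(country = countries, pop_2012 = pop,
                           birth_rate = birth_rate, bw_kg = bw,
                           inc_m = inc_m, inc_f = inc_f, gdp_2012 = gdp)
    demog <- tidyr::crossing(year = yrs, base) |>
      dplyr::mutate(
        pop_y = .data$pop_2012 * (1 + cfg$pop_growth)^(.data$year - final),
        newborns = .data$pop_2012 * .data$birth_rate *
          (1 + cfg$newborn_growth)^(.data$year - final)) |>
      tidyr::crossing(gender = c("male", "female")) |>
      dplyr::mutate(
        pop = .data$pop_y * cfg$adult_fraction / 2,
        fha_incidence = ifelse(.data$gender == "male", .data$inc_m,
                               .data$inc_f)) |>
      dplyr::select("country", "year", "gender", "pop", "fha_incidence",
                    "newborns", "bw_kg")

    econ <- tidyr::crossing(year = yrs, base[, c("country", "gdp_2012")]) |>
      dplyr::mutate(ppp_gdp_pc = .data$gdp_2012 *
                      (1 + cfg$gdp_growth)^(.data$year - final)) |>
      dplyr::select("country", "year", "ppp_gdp_pc")

    list(emissions = emissions, diet = diet, demog = demog, econ = econ,
         gold = stylized_gold_market(yrs), proxies = stylized_proxies(),
         regions = regions, config = cfg)
  })
}

#' Published headline anchors of the ASGM mercury assessment
#'
#' Printed global aggregates from the assessment this package emulates,
#' used as inputs when recomputing its arithmetic identities (shares,
#' growth rates, loss-to-earning ratios) and as calibration anchors for
#' [reference_world()].
#'
#' @return Tibble with `quantity`, `value`, `unit`.
#' @export
published_anchors <- function() {
  tibble::tribble(
    ~quantity, ~value, ~unit,
    "cumulative_asgm_emissions_1970_2012", 15400, "t",
    "emissions_subsaharan_africa", 4970, "t",
    "emissions_south_america", 4470, "t",
    "emissions_tropical_asia", 2610, "t",
    "iq_decrement_2012", 5.8e5, "points/yr",
    "fha_deaths_2012", 1430, "deaths/yr",
    "loss_1970", 0.59e9, "USD2020/yr",
    "loss_2012", 7.1e9, "USD2020/yr",
    "h_iq_2012", 3.8e9, "USD2020/yr",
    "h_fha_2012", 3.4e9, "USD2020/yr",
    "cumulative_loss_1970_2012", 154e9, "USD2020",
    "cumulative_revenue_1970_2012", 319e9, "USD2020",
    "gold_production_1970", 86, "t",
    "gold_production_2012", 590, "t",
    "gold_price_1970", 35, "USD/oz",
    "gold_price_2005", 420, "USD/oz",
    "gold_price_2012", 1776, "USD/oz",
    "revenue_2012", 34.3e9, "USD/yr",
    "total_mehg_loss_all_sources", 117e9, "USD2020/yr",
    "miner_risk_fraction", 0.04, "1",
    "n_miners", 15e6, "persons",
    "retort_unit_cost", 20, "USD")
}

#' Synthetic input bundle calibrated to the published global aggregates
#'
#' A deterministic synthetic world whose emission totals and gold market
#' reproduce the printed inventory and market anchors, and whose food
#' concentration, incidence and income scales are solved at generation
#' time so the 2012 global ASGM-attributable impacts match the published
#' 5.8e5 IQ points, 1,430 fatal heart attacks and $3.8B IQ-component loss.
#' Country-level detail remains synthetic: only global aggregates are
#' anchored.
#'
#' @param seed Seed for the underlying country draws.
#' @return A world bundle as from [generate_world()], with an extra
#'   `published` table of the printed anchors.
#' @export
reference_world <- function(seed = 20120801) {
  cfg <- synthetic_world_config(seed = seed, emission_jitter_sd = 0)
  world <- generate_world(cfg)
  anchors <- published_anchors()
  a <- function(q) anchors$value[anchors$quantity == q]

  bp <- box_model_params()
  dr <- dose_response_params()
  ec <- econ_params()
  asgm <- run_scenario(world$emissions, bp)
  base <- run_baseline(bp, cfg$years)
  ratios <- attribution_ratio_series(asgm, base)

  sub12 <- function(w) {
    w$diet <- w$diet[w$diet$year == 2012, ]
    w$demog <- w$demog[w$demog$year == 2012, ]
    w$econ <- w$econ[w$econ$year == 2012, ]
    w
  }
  imp <- function(w) {
    country_impacts(sub12(w), ratios[ratios$year == 2012, ], dr, ec) |>
      dplyr::summarise(dIQ = sum(.data$dIQ), dCF = sum(.data$dCF),
                       H_IQ = sum(.data$H_IQ), H_FHA = sum(.data$H_FHA))
  }
  g0 <- imp(world)
  # IQ decrement is exactly linear in food concentration
  conc_scale <- a("iq_decrement_2012") / g0$dIQ
  world$diet$mehg_ug_kg <- world$diet$mehg_ug_kg * conc_scale
  # monetized IQ loss is linear in the income level through the transfer
  g1 <- imp(world)
  world$econ$ppp_gdp_pc <- world$econ$ppp_gdp_pc * a("h_iq_2012") / g1$H_IQ
  # FHA incidence: solve a level and an income gradient jointly so both
  # the death count and its valuation anchor hold (cardiovascular
  # mortality falls with income, so a negative gradient is the realistic
  # shape of the country field)
  gdp12 <- world$econ[world$econ$year == 2012, ]
  rel_income <- stats::setNames(gdp12$ppp_gdp_pc / mean(gdp12$ppp_gdp_pc),
                                gdp12$country)
  with_incidence <- function(level, gradient) {
    w <- world
    k_c <- level * rel_income[w$demog$country]^(-gradient)
    w$demog$fha_incidence <- pmin(w$demog$fha_incidence * unname(k_c), 1)
    w
  }
  solve_level <- function(gradient) {
    f <- function(level) imp(with_incidence(level, gradient))$dCF -
      a("fha_deaths_2012")
    guess <- a("fha_deaths_2012") / imp(with_incidence(1, gradient))$dCF
    stats::uniroot(f, guess * c(1e-2, 1e2), extendInt = "upX",
                   tol = 1e-10)$root
  }
  h_fha_at <- function(gradient)
    imp(with_incidence(solve_level(gradient), gradient))$H_FHA
  gradient <- tryCatch(
    stats::uniroot(function(t) h_fha_at(t) - a("h_fha_2012"),
                   c(-2, 4), extendInt = "downX", tol = 1e-8)$root,
    error = function(e) 0)
  level <- solve_level(gradient)
  k_c <- level * rel_income[world$demog$country]^(-gradient)
  world$demog$fha_incidence <- pmin(world$demog$fha_incidence * unname(k_c), 1)

  world$published <- anchors
  world
}

#' Write a world bundle as CSV tables
#'
#' @param world Bundle from [generate_world()] or [reference_world()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_world_csv <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in setdiff(names(world), "config"))
    utils::write.csv(world[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  invisible(dir)
}
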