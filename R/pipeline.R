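#' Country-year attributable impacts and monetized losses
#'
#' Joins the exposure, demography and income tables, applies the
#' dose-response differencing and monetizes with country-specific
#' earning-loss and value-of-statistical-life coefficients (reference
#' values restated in the reporting currency year, then transferred by PPP
#' income).
#'
#' @param world Input bundle, see [generate_world()].
#' @param ratios Tibble `year`, `rD`, `rP`, `rS`.
#' @param dr_params [dose_response_params()].
#' @param ec_params [econ_params()].
#' @return Tibble with one row per country-year: exposures, `dIQ`, `dCF`,
#'   `H_IQ`, `H_FHA`, `H_total`, `currency_year`.
#' @export
country_impacts <- function(world, ratios,
                            dr_params = dose_response_params(),
                            ec_params = econ_params()) {
  expo <- country_exposure(world$diet, ratios)
  cy <- ec_params$discount_base_year
  el_ref_now <- currency_adjust(ec_params$el_ref, ec_params$el_ref_year,
                                cy, ec_params$cpi)
  vsl_ref_now <- currency_adjust(ec_params$vsl_ref, ec_params$vsl_ref_year,
                                 cy, ec_params$cpi)
  p <- dr_params
  demog <- world$demog |>
    dplyr::group_by(.data$country, .data$year) |>
    dplyr::summarise(expected_fha = sum(.data$pop * .data$fha_incidence),
                     newborns = .data$newborns[1], .groups = "drop")
  expo |>
    dplyr::inner_join(demog, by = c("country", "year")) |>
    dplyr::inner_join(world$econ, by = c("country", "year")) |>
    dplyr::mutate(
      dIQ = p$gamma * p$lambda * p$beta * .data$E_asgm * .data$bw_kg *
        .data$newborns,
      hair_b = p$phi * p$lambda * p$beta * .data$E_baseline * .data$bw_kg,
      hair_c = p$phi * p$lambda * p$beta *
        (.data$E_baseline - .data$E_asgm) * .data$bw_kg,
      dCF = p$omega * .data$expected_fha *
        (exp(-.data$hair_c) - exp(-.data$hair_b)),
      el = benefit_transfer(el_ref_now, ec_params$ref_income,
                            .data$ppp_gdp_pc, ec_params$elasticity),
      vsl = benefit_transfer(vsl_ref_now, ec_params$ref_income,
                             .data$ppp_gdp_pc, ec_params$elasticity),
      H_IQ = .data$el * .data$dIQ,
      H_FHA = .data$vsl * .data$dCF,
      H_total = .data$H_IQ + .data$H_FHA,
      currency_year = cy) |>
    dplyr::select("country", "year", "E_baseline", "E_asgm", "dIQ", "dCF",
                  "H_IQ", "H_FHA", "H_total", "currency_year")
}

#' Run the full emission-to-valuation pipeline
#'
#' Orchestrates every stage: ASGM-only and all-sources scenario runs of the
#' mercury cycle, yearly attribution ratios, country exposure, health
#' impacts, monetization, and the gold-revenue comparison.
#'
#' @param world Input bundle from [generate_world()] or
#'   [reference_world()].
#' @param box_params [box_model_params()].
#' @param dr_params [dose_response_params()].
#' @param ec_params [econ_params()].
#' @return List with `scenario_asgm`, `scenario_baseline`, `ratios`,
#'   `country_year`, `global_year` (global sums per year, with gold
#'   revenue, annual and discounted losses), `economics` (cumulative
#'   discounted loss, revenue and their ratio) and the parameter objects.
#' @export
run_pipeline <- function(world, box_params = box_model_params(),
                         dr_params = dose_response_params(),
                         ec_params = econ_params()) {
  years <- sort(unique(world$emissions$year))
  asgm <- run_scenario(world$emissions, box_params)
  baseline <- run_baseline(box_params, years)
  ratios <- attribution_ratio_series(asgm, baseline)
  cy_tbl <- country_impacts(world, ratios, dr_params, ec_params)

  global <- cy_tbl |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(dIQ = sum(.data$dIQ), dCF = sum(.data$dCF),
                     H_IQ = sum(.data$H_IQ), H_FHA = sum(.data$H_FHA),
                     H_total = sum(.data$H_total), .groups = "drop") |>
    dplyr::left_join(world$gold[, c("year", "revenue_usd")], by = "year")
  disc <- function(v) discount_series(v, global$year, ec_params$discount_rate,
                                      ec_params$discount_base_year)
  global$H_total_disc <- disc(global$H_total)$discounted
  global$revenue_disc <- disc(global$revenue_usd)$discounted
  econ <- list(
    cumulative_loss = sum(global$H_total_disc),
    cumulative_revenue = sum(global$revenue_disc),
    loss_earning = loss_earning_ratio(global$H_total_disc,
                                      global$revenue_disc))
  list(scenario_asgm = asgm, scenario_baseline = baseline, ratios = ratios,
       country_year = cy_tbl, global_year = global, economics = econ,
       params = list(box = box_params, dose_response = dr_params,
                     econ = ec_params))
}

#' Aggregate pipeline results by country, region or globally
#'
#' @param results Output of [run_pipeline()].
#' @param world The input bundle (for the country-to-region lookup).
#' @param level `"country"`, `"region"` or `"global"`.
#' @param years Years to include (default all).
#' @return Tibble of summed impacts and losses with a `share` column
#'   (shares of `H_total`, summing to one over the partition).
#' @export
aggregate_impacts <- function(results, world,
                              level = c("country", "region", "global"),
                              years = NULL) {
  level <- match.arg(level)
  cy <- results$country_year
  if (!is.null(years)) cy <- cy[cy$year %in% years, ]
  cy <- dplyr::left_join(cy, world$regions, by = "country")
  key <- switch(level, country = "country", region = "region",
                global = NULL)
  grouped <- if (is.null(key)) dplyr::mutate(cy, scope = "global") |>
    dplyr::group_by(.data$scope) else dplyr::group_by(cy, .data[[key]])
  out <- grouped |>
    dplyr::summarise(dIQ = sum(.data$dIQ), dCF = sum(.data$dCF),
                     H_IQ = sum(.data$H_IQ), H_FHA = sum(.data$H_FHA),
                     H_total = sum(.data$H_total), .groups = "drop")
  dplyr::mutate(out, share = .data$H_total / sum(.data$H_total))
}

#' Write pipeline result tables and a JSON run summary
#'
#' @param results Output of [run_pipeline()].
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_results <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(results$ratios, file.path(dir, "attribution_ratios.csv"),
                   row.names = FALSE)
  utils::write.csv(results$country_year, file.path(dir, "country_year.csv"),
                   row.names = FALSE)
  utils::write.csv(results$global_year, file.path(dir, "global_year.csv"),
                   row.names = FALSE)
  summary <- list(
    years = range(results$global_year$year),
    cumulative_loss = results$economics$cumulative_loss,
    cumulative_revenue = results$economics$cumulative_revenue,
    cumulative_loss_earning_ratio = results$economics$loss_earning$cumulative,
    discount_rate = results$params$econ$discount_rate,
    discount_base_year = results$params$econ$discount_base_year)
  jsonlite::write_json(summary, file.path(dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
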