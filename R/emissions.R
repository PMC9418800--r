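#' Regions used for ASGM emission accounting
#'
#' The emission inventory is carried at the resolution of four aggregate
#' source regions; all downstream stages only consume global or regional
#' annual totals.
#'
#' @export
asgm_regions <- c("Sub-Saharan Africa", "South America", "tropical Asia",
                  "rest-of-world")

#' Construct an annual emission series
#'
#' An emission series is a tidy table with one row per region-year holding
#' the mercury mass emitted to the atmosphere that year.
#'
#' @param year Integer years (strictly increasing within each region).
#' @param mass_t Emitted mercury, metric tons per year (non-negative).
#' @param region Region label; either one of [asgm_regions] or `"Global"`.
#' @param scenario `"asgm_only"` or `"all_sources"`.
#' @return A tibble with columns `year`, `region`, `scenario`, `mass_t`.
#' @export
emission_series <- function(year, mass_t, region = "Global",
                            scenario = c("asgm_only", "all_sources")) {
  scenario <- match.arg(scenario)
  out <- tibble::tibble(year = as.integer(year), region = region,
                        scenario = scenario, mass_t = as.numeric(mass_t))
  validate_emissions(out)
  out
}

#' @keywords internal
validate_emissions <- function(emis) {
  stopifnot(all(c("year", "region", "scenario", "mass_t") %in% names(emis)))
  if (any(emis$mass_t < 0)) stop("emission mass must be non-negative")
  if (!all(emis$scenario %in% c("asgm_only", "all_sources")))
    stop("unknown scenario label")
  bad <- emis |>
    dplyr::group_by(.data$region, .data$scenario) |>
    dplyr::summarise(ok = !is.unsorted(.data$year, strictly = TRUE),
                     .groups = "drop")
  if (!all(bad$ok)) stop("years must be strictly increasing within a region")
  ok_region <- emis$region %in% c(asgm_regions, "Global")
  if (!all(ok_region))
    stop("unknown region label(s): ",
         paste(unique(emis$region[!ok_region]), collapse = ", "))
  invisible(emis)
}

#' Total emitted mass over a window of years
#'
#' @param emis Emission series (all regions are summed).
#' @param window Length-2 integer vector `c(first, last)`, inclusive.
#' @return Total mass in metric tons.
#' @examples
#' e <- emission_series(2001:2005, rep(10, 5))
#' cumulative_emissions(e, c(2001, 2005)) # 50
#' @export
cumulative_emissions <- function(emis, window = range(emis$year)) {
  validate_emissions(emis)
  window <- as.integer(window)
  if (length(window) != 2L || window[1] > window[2])
    stop("window must be c(first, last) with first <= last")
  yrs <- unique(emis$year)
  if (window[1] < min(yrs) || window[2] > max(yrs))
    stop("window outside the years covered by the series")
  keep <- emis$year >= window[1] & emis$year <= window[2]
  if (!any(keep)) stop("empty window")
  sum(emis$mass_t[keep])
}

#' Regional shares of total emissions
#'
#' Shares are computed against the all-region total over the window and sum
#' to one over an exhaustive region partition.
#'
#' @inheritParams cumulative_emissions
#' @return Tibble with `region`, `mass_t`, `share`.
#' @export
regional_share <- function(emis, window = range(emis$year)) {
  validate_emissions(emis)
  keep <- emis$year >= window[1] & emis$year <= window[2]
  by_region <- emis[keep, ] |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(mass_t = sum(.data$mass_t), .groups = "drop")
  total <- sum(by_region$mass_t)
  if (total <= 0) stop("zero total emission over the window")
  dplyr::mutate(by_region, share = .data$mass_t / total)
}

#' Construct a proxy index series for emission extrapolation
#'
#' @param year Integer years.
#' @param value Positive index values.
#' @param name One of `"gold_price"`, `"gold_demand"`, `"mine_production"`,
#'   `"gold_supply"`.
#' @return Tibble with `year`, `proxy`, `value`.
#' @export
proxy_series <- function(year, value,
                         name = c("gold_price", "gold_demand",
                                  "mine_production", "gold_supply")) {
  name <- match.arg(name)
  if (any(value <= 0)) stop("proxy values must be positive")
  tibble::tibble(year = as.integer(year), proxy = name,
                 value = as.numeric(value))
}

#' Extrapolate emissions beyond the inventory by market proxies
#'
#' Each proxy scales the final-year emission of the base series by the
#' proxy's index relative to its base value,
#' `E(t) = E(base) * proxy(t) / proxy(base)`. The multi-proxy mean is the
#' unweighted average of the per-proxy series.
#'
#' @param base Emission series covering the base year (regions are summed).
#' @param proxies Tibble of proxy series (rows `year`, `proxy`, `value`),
#'   e.g. several [proxy_series()] row-bound together.
#' @param window Years to extrapolate to, e.g. `2013:2021`.
#' @param rebase `"final_year"` rebases each proxy on its value in the base
#'   series' last year; `"mean"` rebases on the proxy mean over
#'   `rebase_window`.
#' @param rebase_window Years for `rebase = "mean"`; defaults to the last
#'   three base-series years.
#' @return Tibble with `year`, `proxy`, `mass_t`; the unweighted average
#'   appears as `proxy == "multi_proxy_mean"`.
#' @export
extrapolate_by_proxy <- function(base, proxies, window,
                                 rebase = c("final_year", "mean"),
                                 rebase_window = NULL) {
  rebase <- match.arg(rebase)
  validate_emissions(base)
  base_year <- max(base$year)
  e_base <- sum(base$mass_t[base$year == base_year])
  out <- lapply(split(proxies, proxies$proxy), function(p) {
    ref <- if (rebase == "final_year") {
      v <- p$value[p$year == base_year]
      if (length(v) != 1L)
        stop("proxy '", p$proxy[1], "' has no value in base year ", base_year)
      v
    } else {
      rw <- if (is.null(rebase_window)) (base_year - 2L):base_year else rebase_window
      v <- p$value[p$year %in% rw]
      if (length(v) == 0L)
        stop("proxy '", p$proxy[1], "' has no values in the rebase window")
      mean(v)
    }
    keep <- p$year %in% window
    if (!any(keep)) stop("proxy '", p$proxy[1], "' does not cover the window")
    tibble::tibble(year = p$year[keep], proxy = p$proxy[1],
                   mass_t = e_base * p$value[keep] / ref)
  })
  out <- dplyr::bind_rows(out)
  mean_series <- out |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(proxy = "multi_proxy_mean", mass_t = mean(.data$mass_t),
                     .groups = "drop")
  dplyr::bind_rows(out, mean_series) |>
    dplyr::arrange(.data$proxy, .data$year)
}

#' Read / write emission and proxy CSV tables
#'
#' Emission CSVs have columns `year, region, scenario, mass_t`; proxy CSVs
#' have `year, proxy, value`.
#'
#' @param path File path.
#' @name emissions_io
#' @export
read_emissions_csv <- function(path) {
  emis <- tibble::as_tibble(utils::read.csv(path))
  validate_emissions(emis)
  emis
}

#' @rdname emissions_io
#' @param emis Emission table to write.
#' @export
write_emissions_csv <- function(emis, path) {
  validate_emissions(emis)
  utils::write.csv(emis, path, row.names = FALSE)
  invisible(path)
}

#' @rdname emissions_io
#' @export
read_proxies_csv <- function(path) {
  p <- tibble::as_tibble(utils::read.csv(path))
  stopifnot(all(c("year", "proxy", "value") %in% names(p)))
  if (any(p$value <= 0)) stop("proxy values must be positive")
  p
}
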