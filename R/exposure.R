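#' Food categories of the dietary methylmercury pathway
#'
#' Seafood methylmercury tracks plankton MeHg, freshwater fish tracks
#' atmospheric deposition, and rice tracks soil mercury; the mapping is
#' fixed throughout the package.
#' @keywords internal
food_categories <- c("seafood", "freshwater_fish", "rice")

#' Build an intake or concentration profile
#'
#' Profiles are tidy tables with one row per food category and stratum
#' (e.g. fish trophic level, rice production region). The default is a
#' single stratum per category.
#'
#' @param seafood,freshwater_fish,rice Per-stratum values: intake in
#'   kg person-1 day-1 or MeHg concentration in ug kg-1.
#' @param value_name Column name for the values.
#' @return Tibble `category`, `stratum`, `<value_name>`.
#' @export
food_profile <- function(seafood = 0, freshwater_fish = 0, rice = 0,
                         value_name = "value") {
  vals <- list(seafood = seafood, freshwater_fish = freshwater_fish,
               rice = rice)
  out <- dplyr::bind_rows(lapply(names(vals), function(cat) {
    v <- vals[[cat]]
    tibble::tibble(category = cat, stratum = seq_along(v), value = as.numeric(v))
  }))
  if (any(out$value < 0)) stop("intakes and concentrations must be non-negative")
  names(out)[names(out) == "value"] <- value_name
  out
}

#' @keywords internal
match_strata <- function(intake, conc) {
  stopifnot(all(c("category", "stratum") %in% names(intake)),
            all(c("category", "stratum") %in% names(conc)))
  m <- dplyr::inner_join(intake, conc, by = c("category", "stratum"))
  if (nrow(m) != nrow(intake) || nrow(m) != nrow(conc))
    stop("intake and concentration strata do not match")
  m
}

#' Baseline per-capita methylmercury intake
#'
#' Sums intake times concentration over food categories and strata, then
#' normalizes by body weight:
#' `E = (I_seafood C_seafood + I_fwfish C_fwfish + I_rice C_rice) / BW`.
#'
#' @param intake Intake profile (`intake_kg_day` column), see
#'   [food_profile()].
#' @param conc Concentration profile (`mehg_ug_kg` column).
#' @param bw_kg Body weight used for normalization (kg, > 0).
#' @return List with `E_baseline` (ug per kg body weight per day),
#'   `by_category` (ug person-1 day-1 per category) and `bw_kg`.
#' @examples
#' i <- food_profile(seafood = 0.05, value_name = "intake_kg_day")
#' c <- food_profile(seafood = 100, value_name = "mehg_ug_kg")
#' baseline_exposure(i, c, bw_kg = 70)$E_baseline # 5/70
#' @export
baseline_exposure <- function(intake, conc, bw_kg) {
  if (bw_kg <= 0) stop("body weight must be positive")
  m <- match_strata(intake, conc)
  by_cat <- m |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(ug_day = sum(.data$intake_kg_day * .data$mehg_ug_kg),
                     .groups = "drop")
  full <- stats::setNames(rep(0, 3), food_categories)
  full[by_cat$category] <- by_cat$ug_day
  list(E_baseline = sum(full) / bw_kg, by_category = full, bw_kg = bw_kg)
}

#' ASGM-attributable per-capita methylmercury intake
#'
#' Scales each food-category term of the baseline intake by the attribution
#' ratio of the environmental compartment that feeds it: plankton MeHg for
#' seafood, atmospheric deposition for freshwater fish, soil mercury for
#' rice. Linear scaling of food concentration with environmental level is a
#' conservative upper bound on the ASGM share.
#'
#' @inheritParams baseline_exposure
#' @param ratios Named vector `c(rD, rP, rS)` from [attribution_ratios()],
#'   each in `[0, 1]`.
#' @return List with `E_asgm`, `E_baseline`, `by_category` (ASGM-share
#'   ug person-1 day-1) and `bw_kg`.
#' @export
asgm_exposure <- function(intake, conc, bw_kg, ratios) {
  stopifnot(all(c("rD", "rP", "rS") %in% names(ratios)))
  if (any(ratios < 0 | ratios > 1))
    stop("attribution ratios must lie in [0, 1]")
  base <- baseline_exposure(intake, conc, bw_kg)
  scale <- c(seafood = unname(ratios[["rP"]]),
             freshwater_fish = unname(ratios[["rD"]]),
             rice = unname(ratios[["rS"]]))
  asgm_cat <- base$by_category * scale[names(base$by_category)]
  list(E_asgm = sum(asgm_cat) / bw_kg, E_baseline = base$E_baseline,
       by_category = asgm_cat, bw_kg = bw_kg)
}

#' Country-year exposure table
#'
#' Vectorized exposure computation over a long country table (the CSV
#' dialect written by the synthetic world generator): one row per country,
#' year, category and stratum.
#'
#' @param diet Tibble with columns `country`, `year`, `category`,
#'   `stratum`, `intake_kg_day`, `mehg_ug_kg`, `bw_kg`.
#' @param ratios Tibble `year`, `rD`, `rP`, `rS` (see
#'   [attribution_ratio_series()]).
#' @return Tibble `country`, `year`, `bw_kg`, `E_baseline`, `E_asgm`
#'   (both ug per kg body weight per day).
#' @export
country_exposure <- function(diet, ratios) {
  stopifnot(all(c("country", "year", "category", "stratum", "intake_kg_day",
                  "mehg_ug_kg", "bw_kg") %in% names(diet)))
  if (!all(diet$category %in% food_categories))
    stop("unknown food category")
  d <- dplyr::inner_join(diet, ratios, by = "year")
  if (nrow(d) < nrow(diet)) stop("ratios do not cover all diet years")
  d |>
    dplyr::mutate(
      ug_day = .data$intake_kg_day * .data$mehg_ug_kg,
      r = dplyr::case_when(.data$category == "seafood" ~ .data$rP,
                           .data$category == "freshwater_fish" ~ .data$rD,
                           .data$category == "rice" ~ .data$rS)) |>
    dplyr::group_by(.data$country, .data$year, .data$bw_kg) |>
    dplyr::summarise(E_baseline = sum(.data$ug_day) / .data$bw_kg[1],
                     E_asgm = sum(.data$ug_day * .data$r) / .data$bw_kg[1],
                     .groups = "drop")
}
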