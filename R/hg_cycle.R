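#' Compartments of the reduced-complexity global mercury cycle
#'
#' Order of the state vector and of the rows/columns of
#' [transfer_matrix()].
#' @export
hg_compartments <- c("atm", "soil_fast", "soil_slow", "soil_armored",
                     "ocean_surface", "ocean_deep")

#' Parameters of the six-compartment annual mercury cycle
#'
#' The global cycle is represented by six well-mixed reservoirs (atmosphere;
#' fast, slow and armored soil; surface and subsurface ocean) exchanging
#' mass through first-order annual transfer fractions. Emission enters the
#' atmosphere; deposition is split between land and ocean; soils and the
#' surface ocean re-emit legacy mercury back to the atmosphere; the only
#' permanent sink is burial from the subsurface ocean. All processes are
#' linear, so scenario runs superpose.
#'
#' @param ... Named overrides of the packaged calibrated defaults (see
#'   `inst/extdata/box_model_params.yaml` for the full key list and units).
#' @return A `box_model_params` list, validated so every compartment's
#'   outgoing annual fractions sum to at most one.
#' @export
box_model_params <- function(...) {
  p <- yaml::read_yaml(system.file("extdata", "box_model_params.yaml",
                                   package = "asgmrisk"))
  over <- list(...)
  unknown <- setdiff(names(over), names(p))
  if (length(unknown) > 0)
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  p[names(over)] <- over
  p$land_split <- as.numeric(p$land_split)
  validate_box_params(p)
  structure(p, class = "box_model_params")
}

#' @keywords internal
validate_box_params <- function(p) {
  num <- unlist(p[setdiff(names(p), "land_split")])
  if (any(num < 0) || any(p$land_split < 0))
    stop("all box-model coefficients must be non-negative")
  if (abs(sum(p$land_split) - 1) > 1e-12)
    stop("land_split must sum to 1")
  if (p$atm_dep > 1 || p$f_land > 1)
    stop("deposition fractions must be <= 1")
  out <- c(atm = p$atm_dep,
           soil_fast = p$r_fast + p$a_fs,
           soil_slow = p$r_slow + p$a_sa,
           soil_armored = p$r_arm,
           ocean_surface = p$k_ev + p$k_dw,
           ocean_deep = p$k_up + p$k_bur)
  if (any(out > 1))
    stop("outgoing annual fractions exceed 1 for: ",
         paste(names(out)[out > 1], collapse = ", "))
  invisible(p)
}

#' Annual transfer matrix of the cycle
#'
#' Column j gives the destination fractions of compartment j's start-of-year
#' mass; burial leaves the system, so the ocean-deep column sums to less
#' than one.
#'
#' @param params A [box_model_params()] object.
#' @return 6 x 6 matrix, rows/columns ordered atmosphere, fast/slow/armored
#'   soil, surface/deep ocean.
#' @export
transfer_matrix <- function(params) {
  p <- params
  M <- matrix(0, 6, 6, dimnames = list(hg_compartments, hg_compartments))
  dep <- p$atm_dep
  M["atm", "atm"] <- 1 - dep
  M["soil_fast", "atm"] <- dep * p$f_land * p$land_split[1]
  M["soil_slow", "atm"] <- dep * p$f_land * p$land_split[2]
  M["soil_armored", "atm"] <- dep * p$f_land * p$land_split[3]
  M["ocean_surface", "atm"] <- dep * (1 - p$f_land)
  M["atm", "soil_fast"] <- p$r_fast
  M["soil_slow", "soil_fast"] <- p$a_fs
  M["soil_fast", "soil_fast"] <- 1 - p$r_fast - p$a_fs
  M["atm", "soil_slow"] <- p$r_slow
  M["soil_armored", "soil_slow"] <- p$a_sa
  M["soil_slow", "soil_slow"] <- 1 - p$r_slow - p$a_sa
  M["atm", "soil_armored"] <- p$r_arm
  M["soil_armored", "soil_armored"] <- 1 - p$r_arm
  M["atm", "ocean_surface"] <- p$k_ev
  M["ocean_deep", "ocean_surface"] <- p$k_dw
  M["ocean_surface", "ocean_surface"] <- 1 - p$k_ev - p$k_dw
  M["ocean_surface", "ocean_deep"] <- p$k_up
  M["ocean_deep", "ocean_deep"] <- 1 - p$k_up - p$k_bur
  M
}

#' @keywords internal
diagnose_fields <- function(state, deposition_t, params) {
  c(D = deposition_t * 1e12 / params$earth_area_m2,
    P = params$p_yield * state[["ocean_surface"]],
    S = params$s_yield * (state[["soil_fast"]] + state[["soil_slow"]] +
                            state[["soil_armored"]]))
}

#' Advance the mercury cycle by one year
#'
#' The year's emission is added to the atmosphere, then all annual transfer
#' fractions are applied simultaneously. Mass balance closes exactly:
#' the change in total stored mass equals emission minus burial.
#'
#' @param state Named numeric vector of compartment masses (metric tons),
#'   in the order of `transfer_matrix()`; non-negative.
#' @param emission_t Mercury emitted this year (t).
#' @param params A [box_model_params()] object.
#' @return List with `state` (next-year masses), `deposition_t`,
#'   `burial_t`, and `fields` (named vector `D` in ug m-2 yr-1, `P` in
#'   fmol L-1, `S` in ng g-1, diagnosed on the end-of-year state).
#' @export
step_annual <- function(state, emission_t, params) {
  if (any(state < 0)) stop("compartment masses must be non-negative")
  if (emission_t < 0) stop("emission must be non-negative")
  M <- transfer_matrix(params)
  avail <- state
  avail[1] <- avail[1] + emission_t
  deposition_t <- params$atm_dep * avail[[1]]
  burial_t <- params$k_bur * avail[[6]]
  nxt <- as.vector(M %*% avail)
  names(nxt) <- hg_compartments
  list(state = nxt, deposition_t = deposition_t, burial_t = burial_t,
       fields = diagnose_fields(nxt, deposition_t, params))
}

#' Steady state under constant emission
#'
#' Solves the linear fixed point of the annual update for a constant
#' emission rate; used to initialize the all-sources baseline scenario.
#'
#' @inheritParams step_annual
#' @return Named vector of compartment masses (t).
#' @export
steady_state <- function(params, emission_t) {
  M <- transfer_matrix(params)
  m <- solve(diag(6) - M, M[, 1] * emission_t)
  names(m) <- hg_compartments
  m
}

#' Run a multi-year emission scenario through the mercury cycle
#'
#' The ASGM-only scenario starts from zero mass (the inventory begins in
#' 1970 and no ASGM legacy precedes it); the all-sources baseline starts
#' from the steady state of its constant emission.
#'
#' @param emissions Either an emission table (regions are summed per year)
#'   or a numeric vector of annual masses aligned with `years`.
#' @param params A [box_model_params()] object.
#' @param years Integer years of the run; defaults to the table's years.
#' @param init Initial compartment masses; defaults to zero.
#' @return A `scenario_fields` tibble: `year`, diagnostics `D`, `P`, `S`,
#'   the six compartment masses, `emission_t`, `deposition_t`, `burial_t`.
#' @export
run_scenario <- function(emissions, params = box_model_params(),
                         years = NULL, init = NULL) {
  if (is.data.frame(emissions)) {
    validate_emissions(emissions)
    by_year <- emissions |>
      dplyr::group_by(.data$year) |>
      dplyr::summarise(mass_t = sum(.data$mass_t), .groups = "drop") |>
      dplyr::arrange(.data$year)
    if (is.null(years)) years <- by_year$year
    e <- by_year$mass_t[match(years, by_year$year)]
    if (anyNA(e)) stop("emissions do not cover the run window")
  } else {
    if (is.null(years)) stop("years must be given with a numeric emission vector")
    e <- as.numeric(emissions)
    if (length(e) == 1L) e <- rep(e, length(years))
    if (length(e) != length(years)) stop("emissions and years length mismatch")
  }
  state <- if (is.null(init)) stats::setNames(rep(0, 6), hg_compartments)
           else { stopifnot(length(init) == 6); stats::setNames(as.numeric(init), hg_compartments) }
  n <- length(years)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    st <- step_annual(state, e[i], params)
    state <- st$state
    rows[[i]] <- tibble::tibble(year = years[i],
                                D = st$fields[["D"]], P = st$fields[["P"]],
                                S = st$fields[["S"]],
                                !!!stats::setNames(as.list(state), hg_compartments),
                                emission_t = e[i],
                                deposition_t = st$deposition_t,
                                burial_t = st$burial_t)
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("scenario_fields", class(out))
  out
}

#' Run the baseline (all-sources) scenario at steady state
#'
#' @param params A [box_model_params()] object; its
#'   `all_sources_emission_t` drives the run.
#' @param years Years to report.
#' @return A `scenario_fields` tibble (constant in time by construction).
#' @export
run_baseline <- function(params = box_model_params(), years = 1970:2012) {
  e <- params$all_sources_emission_t
  init <- steady_state(params, e)
  run_scenario(rep(e, length(years)), params, years = years, init = init)
}

#' ASGM attribution ratios of the environmental fields
#'
#' Diagnoses the ASGM contribution to each environmental compartment as the
#' ratio of the ASGM-only to the baseline scenario field in a given year:
#' `rD` for atmospheric deposition, `rP` for plankton methylmercury, `rS`
#' for soil mercury. Because all processes are linear, these ratios bound
#' the ASGM share of food methylmercury from each pathway.
#'
#' @param asgm,baseline `scenario_fields` tibbles covering `year`.
#' @param year Diagnosis year.
#' @return Named vector `c(rD, rP, rS)`, clipped to `[0, 1]` with a warning
#'   if a ratio exceeds one.
#' @export
attribution_ratios <- function(asgm, baseline, year) {
  a <- asgm[asgm$year == year, ]
  b <- baseline[baseline$year == year, ]
  if (nrow(a) != 1L || nrow(b) != 1L) stop("year not covered by both scenarios")
  denom <- c(b$D, b$P, b$S)
  if (any(denom <= 0)) stop("baseline fields must be strictly positive")
  r <- c(rD = a$D / b$D, rP = a$P / b$P, rS = a$S / b$S)
  if (any(r > 1)) {
    warning("attribution ratio exceeded 1; clipping")
    r <- pmin(r, 1)
  }
  pmax(r, 0)
}

#' Attribution ratios for every year of a run
#'
#' @inheritParams attribution_ratios
#' @return Tibble `year`, `rD`, `rP`, `rS`.
#' @export
attribution_ratio_series <- function(asgm, baseline) {
  yrs <- intersect(asgm$year, baseline$year)
  out <- lapply(yrs, function(y) {
    r <- attribution_ratios(asgm, baseline, y)
    tibble::tibble(year = y, rD = r[["rD"]], rP = r[["rP"]], rS = r[["rS"]])
  })
  dplyr::bind_rows(out)
}
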