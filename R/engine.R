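#' Run one grazing simulation
#'
#' Executes the per-tick behavioral schedule on a pasture until the
#' animal-unit-month target is met. Each tick is one patch interaction per
#' cow and is exactly one of: a whole-herd watering trip (a leader's
#' hydration reached zero), a whole-herd site change (a leader's patience for
#' the overgrazed neighborhood ran out), or ordinary movement-and-grazing in
#' which every cow relocates by the herding rule or the environmental rule
#' and then eats its destination cell. A grazing-day passes when herd-mean
#' consumption reaches `daily_intake_g`; at day end toxicosis is assessed
#' (body burden above the individual tolerance is recorded as a death and the
#' burden reset) and every burden is halved (one-grazing-day half-life).
#'
#' @param pasture a [pasture()].
#' @param config a [sim_config()].
#' @param herd optional pre-built [create_herd()] data.frame (extra columns
#'   `msal_level` and `hydration` may be set for controlled experiments); by
#'   default the herd is created from the config seed.
#' @param params optional [derive_behavior_params()] override.
#' @param record_daily keep the per-cow per-day intake records (TRUE).
#' @param audit_every if > 0, recompute the forage and MSAL mass balance
#'   every that many ticks and report the worst relative error.
#' @param max_ticks if > 0, stop unconditionally after this many ticks
#'   (diagnostics and fixture tests).
#' @param lattice_spacing_m spacing of the candidate-site evaluation lattice.
#' @return an object of class `graztox_run`: `summary` (one-row data.frame),
#'   `daily` (per-cow per-day records), `death_events`, `cows` (final cow
#'   state), `pasture` (final grids), `day_travel_mean_m`,
#'   `day_site_changes`.
#' @export
run_simulation <- function(pasture, config, herd = NULL, params = NULL,
                           record_daily = TRUE, audit_every = 0,
                           max_ticks = 0, lattice_spacing_m = 25L) {
  stopifnot(inherits(pasture, "pasture"), inherits(config, "sim_config"))
  accessible_ha <- sum(pasture$accessible) / 1e4
  if (is.null(params))
    params <- derive_behavior_params(config, accessible_ha,
                                     n_cows = if (!is.null(herd)) nrow(herd))
  if (is.null(herd)) herd <- create_herd(config, params, pasture)
  if (!all(c("x", "y", "heading", "role_code", "msal_tolerance",
             "larkspur_attraction") %in% names(herd)))
    stop("herd is missing required columns", call. = FALSE)
  if (is.null(herd$msal_level)) herd$msal_level <- 0
  if (is.null(herd$hydration)) herd$hydration <- params$hydration_capacity_g

  par <- list(
    herd_distance_m = params$herd_distance_m,
    space_per_cow_m2 = params$space_per_cow_m2,
    site_tolerance = params$site_tolerance,
    hydration_capacity_g = params$hydration_capacity_g,
    daily_intake_g = config$daily_intake_g,
    target_aums = config$target_aums,
    au_per_cow = config$au_per_cow,
    days_per_month = config$days_per_month,
    water_threshold_frac = config$water_threshold_frac,
    satiation_g = config$satiation_frac * config$daily_intake_g,
    herdmate_count = params$herdmate_count,
    lattice_spacing_m = as.integer(lattice_spacing_m),
    audit_every = as.integer(audit_every),
    max_ticks = as.double(max_ticks),
    record_daily = TRUE  # summary intake statistics always need the records
  )
  set.seed(seed_offset(config$seed, 4L))
  res <- .run_sim_cpp(pasture$forage_g, pasture$msal_mg, pasture$n_forage_g,
                      pasture$times_grazed, pasture$accessible, pasture$water,
                      herd, par)

  n <- nrow(herd)
  days <- res$grazing_days
  daily <- res$daily
  daily$role <- role_levels[daily$role_code + 1L]
  ev <- res$death_events
  ev$role <- if (nrow(ev)) role_levels[ev$role_code + 1L] else character(0)

  ist <- if (nrow(daily) > 0) {
    intake_statistics(daily)
  } else {
    list(mean_daily = NA_real_, sd_daily = NA_real_, mean_max = NA_real_,
         sd_max = NA_real_, cv_total = NA_real_)
  }
  fin <- pasture
  fin$forage_g <- res$forage_g
  fin$msal_mg <- res$msal_mg
  fin$times_grazed <- res$times_grazed
  moves <- res$herd_moves + res$env_moves
  summary <- data.frame(
    hcf = config$hcf, sd = config$sd, seed = config$seed,
    n_cows = n, deaths = res$deaths, grazing_days = days,
    ticks = res$ticks,
    aums_consumed = days * n * config$au_per_cow / config$days_per_month,
    status = res$status,
    mean_daily_msal_mg = ist$mean_daily, sd_daily_msal_mg = ist$sd_daily,
    mean_max_daily_msal_mg = ist$mean_max,
    sd_max_daily_msal_mg = ist$sd_max,
    cv_total_msal = ist$cv_total,
    site_changes_per_day = if (days > 0) res$site_changes / days else NA_real_,
    mean_travel_m_per_day = if (days > 0) mean(res$day_travel_mean_m)
                            else NA_real_,
    sd_times_grazed = grazing_heterogeneity(fin),
    herd_move_fraction = if (moves > 0) res$herd_moves / moves else NA_real_,
    deaths_leader = res$deaths_by_role[["leader"]],
    deaths_follower = res$deaths_by_role[["follower"]],
    deaths_independent = res$deaths_by_role[["independent"]],
    water_visits = res$water_visits,
    site_changes = res$site_changes,
    consumed_forage_g = res$consumed_forage_g,
    consumed_msal_mg = res$consumed_msal_mg,
    initial_forage_g = res$initial_forage_g,
    initial_msal_mg = res$initial_msal_mg,
    stringsAsFactors = FALSE
  )
  structure(list(
    summary = summary,
    daily = if (record_daily) daily else daily[0, ],
    death_events = ev,
    cows = res$cow,
    pasture = fin,
    day_travel_mean_m = res$day_travel_mean_m,
    day_site_changes = res$day_site_changes,
    audit_max_relerr = res$audit_max_relerr,
    config = config, params = params
  ), class = "graztox_run")
}

#' @export
print.graztox_run <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "Grazing simulation (HCF %.3g, SD %.3g AU/ha): %d cows, %d grazing-days, %s\n",
    s$hcf, s$sd, s$n_cows, s$grazing_days, s$status))
  cat(sprintf("  lethal acute toxicosis cases: %d (L/F/I %d/%d/%d)\n",
              s$deaths, s$deaths_leader, s$deaths_follower,
              s$deaths_independent))
  cat(sprintf("  AUMs consumed %.2f; forage removed %.1f%%\n",
              s$aums_consumed, 100 * s$consumed_forage_g / s$initial_forage_g))
  invisible(x)
}

#' @export
summary.graztox_run <- function(object, ...) object$summary

#' Single-visit grazing intake
#'
#' The eat rule applied to one cell visit: a cow removes 40% of available
#' forage on the cell's first grazing, 50% of what remains on the second and
#' 60% on later visits; alkaloid is removed at the same fraction scaled by the
#' cow's larkspur attraction, capped at the cell content.
#'
#' @param forage_g forage in the cell (g).
#' @param msal_mg MSAL content of the cell (mg).
#' @param times_grazed previous grazings of the cell.
#' @param attraction the cow's larkspur-attraction factor.
#' @return list with `forage_intake_g` and `msal_intake_mg`.
#' @export
eat_intake <- function(forage_g, msal_mg, times_grazed, attraction = 1.0) {
  .eat_kernel_cpp(forage_g, msal_mg, as.integer(times_grazed), attraction)
}
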