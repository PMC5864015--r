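#' Simulation configuration
#'
#' User-facing inputs of a single model run: the two experimental factors
#' (herd-cohesion factor and stocking density), forage and larkspur inputs,
#' the animal-unit-month stopping target, and unit constants.
#'
#' @param hcf herd-cohesion factor in \[1, 10\]; larger is more cohesive.
#' @param sd stocking density (animal-units per hectare, > 0).
#' @param target_aums run length target in animal-unit-months (> 0).
#' @param seed integer RNG seed.
#' @param kgs_per_hectare mean usable forage (kg/ha), carried for provenance.
#' @param median_plant_mass_g median larkspur mass (g), provenance.
#' @param msal_concentration_mg_per_g MSAL concentration (mg/g), provenance.
#' @param au_per_cow animal-units per 500 kg cow.
#' @param days_per_month days in one animal-unit-month.
#' @param daily_intake_g mean daily forage consumption of a 500 kg cow (g);
#'   herd-mean consumption of this amount defines one grazing-day.
#' @param site_tolerance optional override of the herd-size-dependent leader
#'   patience threshold (see [derive_behavior_params()]).
#' @param water_threshold_frac hydration fraction below which a leader due for
#'   a site change goes to water instead.
#' @param satiation_frac voluntary daily intake bound as a fraction of
#'   `daily_intake_g`; a cow at or past the bound keeps moving with the herd
#'   but stops grazing until the next grazing-day (0 disables).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(hcf, sd, target_aums, seed = 1L,
                       kgs_per_hectare = 500, median_plant_mass_g = 3.5,
                       msal_concentration_mg_per_g = 3.0,
                       au_per_cow = 1.1, days_per_month = 30.44,
                       daily_intake_g = 12500, site_tolerance = NULL,
                       water_threshold_frac = 0.2, satiation_frac = 1.025) {
  if (hcf < 1 || hcf > 10) stop("hcf must lie in [1, 10]", call. = FALSE)
  if (sd <= 0) stop("stocking density must be positive", call. = FALSE)
  if (target_aums <= 0) stop("target_aums must be positive", call. = FALSE)
  structure(list(
    hcf = hcf, sd = sd, target_aums = target_aums, seed = as.integer(seed),
    kgs_per_hectare = kgs_per_hectare,
    median_plant_mass_g = median_plant_mass_g,
    msal_concentration_mg_per_g = msal_concentration_mg_per_g,
    au_per_cow = au_per_cow, days_per_month = days_per_month,
    daily_intake_g = daily_intake_g, site_tolerance = site_tolerance,
    water_threshold_frac = water_threshold_frac,
    satiation_frac = satiation_frac
  ), class = "sim_config")
}

#' Derive behavioral constants from the experimental factors
#'
#' Maps the herd-cohesion factor (HCF) geometrically onto its two stated
#' ranges: desired mean herdmate distance 100 m (HCF 1) down to 10 m (HCF 10),
#' and per-cow space at a fresh feeding site 1000 m^2 down to 10 m^2. Herd
#' size is stocking density times accessible area divided by 1.1 AU per cow.
#' The leader patience threshold (site tolerance) grows with herd size,
#' `max(2, ceiling(n_cows / 25))`, unless overridden in the config. Hydration
#' capacity is half the daily intake, so it depletes to zero twice per
#' grazing-day.
#'
#' @param config a [sim_config()].
#' @param accessible_ha accessible pasture area (ha).
#' @param n_cows optional explicit herd size (bypasses the stocking-density
#'   computation, e.g. for a pre-built herd).
#' @return an object of class `behavior_params`.
#' @export
derive_behavior_params <- function(config, accessible_ha, n_cows = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (accessible_ha <= 0) stop("accessible_ha must be positive", call. = FALSE)
  if (is.null(n_cows))
    n_cows <- round(config$sd * accessible_ha / config$au_per_cow)
  if (n_cows < 1)
    stop("stocking density too low: herd of zero cows", call. = FALSE)
  u <- (config$hcf - 1) / 9
  st <- if (is.null(config$site_tolerance)) max(2, ceiling(n_cows / 25))
        else config$site_tolerance
  structure(list(
    n_cows = as.integer(n_cows),
    herd_distance_m = 100 * 10^(-u),
    space_per_cow_m2 = 1000 * 100^(-u),
    site_tolerance = as.integer(st),
    hydration_capacity_g = config$daily_intake_g / 2,
    herdmate_count = 20L
  ), class = "behavior_params")
}

#' Feeding-site radius
#'
#' Radius (m) of the disc allocated at a site change: the herd's total space
#' allowance `n_cows * space_per_cow_m2` as a disc area.
#'
#' @param n_cows herd size.
#' @param space_per_cow_m2 per-cow space allocation (m^2).
#' @return radius in metres.
#' @export
site_radius <- function(n_cows, space_per_cow_m2) {
  sqrt(n_cows * space_per_cow_m2 / pi)
}

# rejection-sampled truncated normal
rtruncnorm <- function(n, mean, sd, lo, hi) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need) > 0) {
    x <- stats::rnorm(length(need), mean, sd)
    ok <- x >= lo & x <= hi
    out[need[ok]] <- x[ok]
    need <- need[!ok]
  }
  out
}

role_levels <- c("leader", "follower", "independent")

# largest-remainder apportionment of 5/85/10% with at least one leader
role_counts <- function(n_cows) {
  q <- n_cows * c(0.05, 0.85, 0.10)
  fl <- floor(q)
  rem <- q - fl
  left <- n_cows - sum(fl)
  if (left > 0) {
    ord <- order(-rem, seq_along(rem))  # tie-break leader > follower > indep
    fl[ord[seq_len(left)]] <- fl[ord[seq_len(left)]] + 1
  }
  if (fl[1] == 0) {  # the herd always has a leader
    donor <- which.max(fl[2:3]) + 1L
    fl[donor] <- fl[donor] - 1
    fl[1] <- 1
  }
  stats::setNames(as.integer(fl), role_levels)
}

#' Create the cow population
#'
#' Roles are apportioned 5% leader / 85% follower / 10% independent by
#' largest remainder (guaranteeing at least one leader) and shuffled over cow
#' ids. Each cow draws a lethal MSAL tolerance from Normal(4000, 333.33) mg
#' truncated to \[3000, 5000\] and a larkspur attraction factor from
#' Normal(1, 0.083) truncated to \[0.75, 1.25\]. All cows start at one
#' uniformly chosen accessible cell with full hydration and independent
#' uniform headings. Reproducible from `config$seed`.
#'
#' @param config a [sim_config()].
#' @param params a [derive_behavior_params()] result.
#' @param pasture a [pasture()] (for the accessible mask).
#' @return a data.frame of class `herd`, one row per cow.
#' @export
create_herd <- function(config, params, pasture) {
  stopifnot(inherits(config, "sim_config"),
            inherits(params, "behavior_params"))
  acc <- pasture$accessible
  if (!any(acc)) stop("no accessible cells", call. = FALSE)
  set.seed(seed_offset(config$seed, 3L))
  n <- params$n_cows
  cnt <- role_counts(n)
  roles <- rep(role_levels, cnt)
  roles <- roles[sample.int(n)]
  tol <- rtruncnorm(n, 4000, 333.33, 3000, 5000)
  attr_ <- rtruncnorm(n, 1.0, 0.083, 0.75, 1.25)
  H <- nrow(acc)
  cell <- which(acc)[sample.int(sum(acc), 1L)]
  cy <- (cell - 1L) %% H + 1L
  cx <- (cell - 1L) %/% H + 1L
  heading <- stats::runif(n, 0, 2 * pi)
  structure(data.frame(
    id = seq_len(n),
    role = roles,
    role_code = match(roles, role_levels) - 1L,
    x = rep(cx - 0.5, n), y = rep(cy - 0.5, n),
    heading = heading,
    msal_tolerance = tol,
    larkspur_attraction = attr_,
    msal_level = 0,
    hydration = params$hydration_capacity_g,
    stringsAsFactors = FALSE
  ), class = c("herd", "data.frame"))
}
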