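pop_sd <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

#' Alkaloid-intake statistics for one run
#'
#' From the per-cow per-day intake records of a single run: the mean and
#' standard deviation of individual daily alkaloid intake, the mean and
#' standard deviation of each cow's maximum daily intake (its worst day), and
#' the coefficient of variation of per-cow total intake. All standard
#' deviations are population (divisor n) standard deviations.
#'
#' @param daily data.frame with columns `cow` and `daily_msal_mg` (one row
#'   per cow per grazing-day).
#' @return list with `mean_daily`, `sd_daily`, `mean_max`, `sd_max`,
#'   `cv_total`.
#' @export
intake_statistics <- function(daily) {
  if (!all(c("cow", "daily_msal_mg") %in% names(daily)))
    stop("daily records need columns 'cow' and 'daily_msal_mg'", call. = FALSE)
  if (nrow(daily) == 0) stop("no daily records", call. = FALSE)
  x <- daily$daily_msal_mg
  per_max <- tapply(x, daily$cow, max)
  per_tot <- tapply(x, daily$cow, sum)
  mt <- mean(per_tot)
  list(
    mean_daily = mean(x),
    sd_daily = pop_sd(x),
    mean_max = mean(per_max),
    sd_max = pop_sd(per_max),
    cv_total = if (mt > 0) pop_sd(per_tot) / mt else 0
  )
}

#' Grazing heterogeneity
#'
#' Population standard deviation of the times-grazed count over accessible
#' cells at the end of a run — a measure of how unevenly grazing impact was
#' distributed.
#'
#' @param pasture a [pasture()] (typically the final state of a run).
#' @return numeric scalar.
#' @export
grazing_heterogeneity <- function(pasture) {
  stopifnot(inherits(pasture, "pasture"))
  pop_sd(as.numeric(pasture$times_grazed[pasture$accessible]))
}

#' Fraction of herd-driven moves
#'
#' Proportion of grazing-patch choices made by the herding rule rather than
#' the environmental-movement rule — a measure of herd-based versus
#' individual optimization.
#'
#' @param herd_moves count of herding moves.
#' @param env_moves count of environmental moves.
#' @return fraction in \[0, 1\].
#' @export
herd_move_fraction <- function(herd_moves, env_moves) {
  total <- herd_moves + env_moves
  if (total <= 0) stop("no moves recorded", call. = FALSE)
  herd_moves / total
}

#' Detect distinct subherds by single-linkage clustering
#'
#' Groups cows into subherds as the connected components obtained by chaining
#' pairs closer than the linkage distance (single-linkage clustering cut at
#' that height).
#'
#' @param x,y cow coordinates (m).
#' @param linkage_distance_m chaining distance (default 50 m).
#' @return list with `count` and `sizes` (decreasing).
#' @export
detect_subherds <- function(x, y, linkage_distance_m = 50) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 1)
  if (n == 1) return(list(count = 1L, sizes = 1L))
  hc <- stats::hclust(stats::dist(cbind(x, y)), method = "single")
  cl <- stats::cutree(hc, h = linkage_distance_m)
  sizes <- sort(as.integer(table(cl)), decreasing = TRUE)
  list(count = length(sizes), sizes = sizes)
}
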