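test_that("the single-visit eat rule removes 40/50/60% and caps alkaloid at
           the cell content", {
  # first visit: 40% of 50 g
  v1 <- eat_intake(50, 21, 0, 1.0)
  expect_equal(v1$forage_intake_g, 20)
  expect_equal(v1$msal_intake_mg, 8.4)
  # second visit eats 50% of what remains, third 60%
  v2 <- eat_intake(50 - 20, 0, 1, 1.0)
  expect_equal(v2$forage_intake_g, 15)
  expect_equal(eat_intake(10, 0, 2, 1)$forage_intake_g, 6)
  expect_equal(eat_intake(10, 0, 7, 1)$forage_intake_g, 6)
  # attraction scales alkaloid intake, not forage
  expect_equal(eat_intake(50, 21, 0, 1.25)$msal_intake_mg, 10.5)
  expect_equal(eat_intake(50, 21, 0, 1.25)$forage_intake_g, 20)
  # the cap: attraction cannot extract more alkaloid than the cell holds
  expect_equal(eat_intake(50, 10, 2, 2.0)$msal_intake_mg, 10)
})

test_that("ten engine ticks on a tie-free 5x5 pasture with one cow match an
           independent hand simulation exactly", {
  p <- fixture_5x5()
  cow <- fixture_cow()
  cfg <- sim_config(hcf = 4, sd = 0.5, target_aums = 100, seed = 1)
  r <- run_simulation(p, cow, config = cfg, max_ticks = 10)
  o <- oracle_single_cow(p, cow, 10)
  expect_equal(r$pasture$forage_g, o$forage, tolerance = 0)
  expect_equal(r$pasture$msal_mg, o$msal, tolerance = 0)
  expect_identical(r$pasture$times_grazed, matrix(as.integer(o$times), 5, 5))
  expect_equal(r$cows$x, o$x, tolerance = 0)
  expect_equal(r$cows$y, o$y, tolerance = 0)
  expect_equal(r$cows$cumulative_consumption_g, o$cum, tolerance = 0)
  expect_equal(r$cows$total_msal_mg, o$total_msal, tolerance = 0)
  # one patch interaction per cow per tick
  expect_identical(sum(r$pasture$times_grazed), 10L)
})

test_that("body burden decays with a one-grazing-day half-life under zero
           intake", {
  # toxin-free pasture, one cow with a preloaded burden, exactly 3 days
  forage <- matrix(50, 60, 60)
  water <- matrix(FALSE, 60, 60); water[30, 30] <- TRUE
  p <- pasture(forage, water = water)
  cow <- fixture_cow(tolerance = 1e9)
  cow$x <- 30.5; cow$y <- 30.5
  cow$msal_level <- 2000
  cfg <- sim_config(hcf = 4, sd = 0.5, target_aums = 2.5 * 1.1 / 30.44,
                    seed = 3)
  r <- run_simulation(p, cow, config = cfg)
  expect_identical(r$summary$grazing_days, 3L)
  expect_identical(r$summary$deaths, 0L)
  expect_equal(r$cows$msal_level_mg, 2000 * 0.5^3, tolerance = 0)
})

test_that("toxicosis is assessed at day end: burden above tolerance is a
           death and resets to zero", {
  forage <- matrix(50, 60, 60)
  msal <- matrix(30, 60, 60)  # 7500 mg over a 12.5 kg day >> 4000 tolerance
  water <- matrix(FALSE, 60, 60); water[30, 30] <- TRUE
  p <- pasture(forage, msal, water = water)
  cow <- fixture_cow(tolerance = 4000, attraction = 1.0)
  cow$x <- 30.5; cow$y <- 30.5
  cfg <- sim_config(hcf = 4, sd = 0.5, target_aums = 0.5 * 1.1 / 30.44,
                    seed = 3)
  r <- run_simulation(p, cow, config = cfg)
  expect_identical(r$summary$grazing_days, 1L)
  expect_identical(r$summary$deaths, 1L)
  ev <- r$death_events
  expect_identical(nrow(ev), 1L)
  expect_gt(ev$msal_level_mg, ev$msal_tolerance_mg)
  expect_equal(r$cows$msal_level_mg, 0)  # reset, then halved
  expect_identical(r$cows$deaths, 1L)
})

test_that("only leaders trigger watering, and watering relocates and refills
           the whole herd in one tick", {
  forage <- matrix(50, 40, 40)
  water <- matrix(FALSE, 40, 40); water[5, 5] <- TRUE
  p <- pasture(forage, water = water)
  herd <- rbind(fixture_cow(role = "leader", x = 20.5, y = 20.5),
                fixture_cow(role = "follower", x = 22.5, y = 22.5))
  herd$id <- 1:2
  herd$hydration <- c(6250, 0)  # thirsty follower must not trigger
  cfg <- sim_config(hcf = 4, sd = 0.5, target_aums = 1, seed = 5)
  r <- run_simulation(p, herd, config = cfg, max_ticks = 1)
  expect_identical(r$summary$water_visits, 0)
  expect_identical(sum(r$pasture$times_grazed), 2L)

  herd$hydration <- c(0, 6250)  # leader at zero triggers for everyone
  r2 <- run_simulation(p, herd, config = cfg, max_ticks = 1)
  expect_identical(r2$summary$water_visits, 1)
  # both cows stand on the single water cell; nothing was grazed
  expect_equal(r2$cows$x, c(4.5, 4.5))
  expect_equal(r2$cows$y, c(4.5, 4.5))
  expect_identical(sum(r2$pasture$times_grazed), 0L)
})

test_that("hydration depletes to zero twice per grazing-day", {
  forage <- matrix(50, 60, 60)
  water <- matrix(FALSE, 60, 60); water[30, 30] <- TRUE
  p <- pasture(forage, water = water)
  cow <- fixture_cow()
  cow$x <- 30.5; cow$y <- 30.5
  days <- 3
  cfg <- sim_config(hcf = 4, sd = 0.5,
                    target_aums = (days - 0.5) * 1.1 / 30.44, seed = 3)
  r <- run_simulation(p, cow, config = cfg)
  expect_identical(r$summary$grazing_days, as.integer(days))
  expect_gte(r$summary$water_visits, 2 * days - 1)
  expect_lte(r$summary$water_visits, 2 * days + 1)
})

test_that("forage and alkaloid mass balance holds at every tick and a
           toxin-free pasture records no deaths", {
  land <- small_pasture()
  land$msal_mg[] <- 0
  land$initial_msal_mg[] <- 0
  cfg <- sim_config(hcf = 7, sd = 2, target_aums = 0.6, seed = 13)
  r <- run_simulation(land, cfg, audit_every = 1)
  expect_identical(r$summary$deaths, 0L)
  expect_lt(r$audit_max_relerr, 1e-6)
  expect_identical(r$summary$status, "completed")
  # grazing never touches inaccessible cells
  expect_true(all(r$pasture$times_grazed[!land$accessible] == 0L))
})

test_that("runs are reproducible from the seed and diverge across seeds", {
  land <- small_pasture()
  cfg <- sim_config(hcf = 4, sd = 1, target_aums = 0.4, seed = 31)
  r1 <- run_simulation(land, cfg)
  r2 <- run_simulation(land, cfg)
  expect_identical(r1$summary, r2$summary)
  expect_identical(r1$daily, r2$daily)
  expect_identical(r1$pasture$times_grazed, r2$pasture$times_grazed)
  r3 <- run_simulation(land, sim_config(hcf = 4, sd = 1, target_aums = 0.4,
                                        seed = 32))
  expect_false(identical(r1$pasture$times_grazed, r3$pasture$times_grazed))
})

test_that("a pasture too poor to feed the herd terminates as forage
           exhausted", {
  p <- pasture(matrix(5, 20, 20))
  cow <- fixture_cow()
  cow$x <- 10.5; cow$y <- 10.5
  cfg <- sim_config(hcf = 4, sd = 0.5, target_aums = 100, seed = 2)
  r <- run_simulation(p, cow, config = cfg)
  expect_identical(r$summary$status, "forage_exhausted")
  expect_identical(r$summary$grazing_days, 0L)
})

test_that("site placement honors role order and the four-neighbor spacing
           rule", {
  forage <- matrix(1, 30, 30)
  forage[15, 15] <- 9  # unique best cell
  acc <- matrix(TRUE, 30, 30)
  # follower listed first: placement must still give the leader first choice
  pl <- graztox:::.site_placement_cpp(forage, acc, 14L, 14L, 8,
                                      c(1L, 0L))
  leader_pos <- c(pl$x[2], pl$y[2])
  follower_pos <- c(pl$x[1], pl$y[1])
  expect_equal(leader_pos, c(14, 14))  # 0-based cell of the forage maximum
  # follower keeps off the leader's cell and its von Neumann neighbors
  expect_gt(sum(abs(follower_pos - leader_pos)), 1)
  # with equal forage everywhere the first cow takes the site centre
  pl2 <- graztox:::.site_placement_cpp(matrix(1, 30, 30), acc, 10L, 10L, 6,
                                       c(0L, 1L, 1L))
  expect_equal(c(pl2$x[1], pl2$y[1]), c(10, 10))
})

test_that("candidate-site scoring matches a brute-force rank oracle and
           prefers pristine high-forage ground", {
  set.seed(8)
  H <- 120; W <- 120
  forage <- matrix(runif(H * W, 20, 40), H, W)
  forage[40:80, 40:80] <- 95  # pristine rich block
  times <- matrix(3L, H, W)
  times[40:80, 40:80] <- 0L
  acc <- matrix(TRUE, H, W)
  nf <- neighborhood_mean(forage, 3)
  radius <- 12
  sc <- graztox:::.rank_sites_cpp(forage, nf, times, acc, radius, 25L)

  # brute-force square-window means + rank scoring
  oracle_score <- numeric(nrow(sc))
  win_mean <- function(m, x, y, h) {
    xs <- max(1, x + 1 - h):min(W, x + 1 + h)
    ys <- max(1, y + 1 - h):min(H, y + 1 + h)
    mean(m[ys, xs])
  }
  h <- round(radius)
  mt <- mapply(function(x, y) win_mean(times, x, y, h), sc$x, sc$y)
  mf <- mapply(function(x, y) win_mean(forage, x, y, h), sc$x, sc$y)
  mn <- mapply(function(x, y) win_mean(nf, x, y, h), sc$x, sc$y)
  expect_equal(sc$mean_times, mt, tolerance = 1e-9)
  expect_equal(sc$mean_forage, mf, tolerance = 1e-9)
  expect_equal(sc$mean_n_forage, mn, tolerance = 1e-9)
  oracle <- rank(-mt, ties.method = "first") +
    rank(mf, ties.method = "first") + rank(mn, ties.method = "first")
  expect_equal(sc$score, as.numeric(oracle))
  best <- sc[which.max(sc$score), ]
  expect_true(best$x >= 39 && best$x <= 79 && best$y >= 39 && best$y <= 79)
})
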