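test_that("index field generation is deterministic, normalized and loses
           autocorrelation as the correlation length shrinks", {
  cfg <- landscape_config(120, 80, seed = 5)
  g1 <- generate_index_field(cfg)
  g2 <- generate_index_field(cfg)
  expect_identical(g1, g2)
  expect_equal(dim(g1), c(80, 120))
  expect_equal(min(g1), 0)
  expect_equal(max(g1), 1)
  g3 <- generate_index_field(landscape_config(120, 80, seed = 6))
  expect_false(identical(g1, g3))

  # near-zero correlation length: white noise, lag-1 autocorrelation ~ 0
  w <- generate_index_field(landscape_config(200, 200, seed = 5,
                                             correlation_length_m = 1e-6))
  r <- stats::cor(as.vector(w[, -1]), as.vector(w[, -200]))
  expect_lt(abs(r), 0.05)

  # the default length produces visible spatial structure
  s <- generate_index_field(landscape_config(200, 200, seed = 5))
  rs <- stats::cor(as.vector(s[, -1]), as.vector(s[, -200]))
  expect_gt(rs, 0.5)
})

test_that("forage distribution hits the one-third / three-times endpoints and
           the exact accessible-cell mean", {
  # index attaining 0 and 1 with mean(3^(2u-1)) = 1: 75% zeros, 25% ones,
  # so the endpoint cells carry exactly mean/3 and 3*mean
  idx <- matrix(rep(c(0, 0, 0, 1), 25), 10, 10)
  f <- forage_from_index(idx, 500)
  expect_equal(min(f), 50 / 3, tolerance = 1e-12)
  expect_equal(max(f), 150, tolerance = 1e-12)
  expect_equal(max(f) / min(f), 9, tolerance = 1e-9)
  expect_equal(mean(f), 50, tolerance = 1e-12)

  # uniform midpoint index: every accessible cell exactly the mean
  u <- matrix(0.5, 6, 6)
  expect_equal(forage_from_index(u, 500), matrix(50, 6, 6))

  # arbitrary index attaining 0 and 1: ratio 9, mean exact over accessible
  set.seed(1)
  idx2 <- matrix(runif(400), 20, 20)
  idx2[5, 5] <- 0; idx2[7, 7] <- 1
  acc <- matrix(TRUE, 20, 20); acc[, 1] <- FALSE
  f2 <- forage_from_index(idx2, 730, acc)
  expect_equal(mean(f2[acc]), 73, tolerance = 1e-9)
  expect_equal(max(f2[acc]) / min(f2[acc]), 9, tolerance = 1e-6)
  expect_true(all(f2[!acc] == 0))

  expect_error(forage_from_index(matrix(2, 2, 2), 500), "\\[0, 1\\]")
  expect_error(forage_from_index(u, 500, accessible = matrix(FALSE, 6, 6)),
               "accessible")
})

test_that("larkspur layer: MSAL content is count x index-scaled mass x
           concentration and the point process is clustered", {
  cfg <- landscape_config(100, 100, seed = 3)
  # uniform high index: every plant 50% larger than the median
  idx1 <- matrix(1, 100, 100)
  lk <- generate_larkspur_field(idx1, cfg)
  expect_true(all(lk$plant_count >= 0))
  expect_equal(lk$msal_mg, lk$plant_count * (3.5 * 1.5) * 3.0)
  # uniform low index: 50% smaller
  lk0 <- generate_larkspur_field(matrix(0, 100, 100), cfg)
  expect_equal(lk0$msal_mg, lk0$plant_count * (3.5 * 0.5) * 3.0)
  # a cell with 2 plants at the midpoint index carries 2 * 3.5 * 3 = 21 mg
  lkm <- generate_larkspur_field(matrix(0.5, 100, 100), cfg)
  two <- which(lkm$plant_count == 2)
  expect_gt(length(two), 0)
  expect_equal(lkm$msal_mg[two], rep(21, length(two)))

  # no patches and no background: a toxin-free pasture
  cfg0 <- landscape_config(100, 100, seed = 3, patch_intensity_per_ha = 0,
                           background_density = 0)
  lkz <- generate_larkspur_field(matrix(0.5, 100, 100), cfg0)
  expect_true(all(lkz$msal_mg == 0))

  # clustering: variance-to-mean ratio of counts on 100 ha well above 1
  cfgbig <- landscape_config(1000, 1000, seed = 11, within_patch_density = 4,
                             background_density = 0.02)
  idx <- generate_index_field(cfgbig)
  big <- generate_larkspur_field(idx, cfgbig)
  counts <- as.numeric(big$plant_count)
  expect_gt(var(counts) / mean(counts), 1)
})

test_that("water feature is a contained, reproducible, never-empty stream", {
  cfg <- landscape_config(150, 90, seed = 21)
  acc <- accessible_mask(cfg)
  w1 <- generate_water_feature(cfg)
  expect_true(any(w1))
  expect_true(all(acc[w1]))
  expect_identical(w1, generate_water_feature(cfg))
  # fully broken stream still keeps at least one water cell
  cfgb <- landscape_config(150, 90, seed = 21, stream_break_fraction = 1)
  expect_gte(sum(generate_water_feature(cfgb)), 1)
})

test_that("neighborhood disc mean matches enumeration and a brute-force
           oracle", {
  # constant grid: mean is the constant at any radius
  cg <- matrix(3.7, 12, 12)
  for (r in c(1, 3, 10)) expect_equal(neighborhood_mean(cg, r), cg)

  # radius 1: the 5-cell von Neumann disc
  g <- matrix(0, 11, 11); g[6, 6] <- 1
  expect_equal(neighborhood_mean(g, 1)[6, 6], 1 / 5)
  # radius 3 disc has 29 cells
  g2 <- matrix(0, 21, 21); g2[11, 11] <- 1
  nm3 <- neighborhood_mean(g2, 3)
  expect_equal(nm3[11, 11], 1 / 29)

  # brute-force oracle on random grids, including truncated edge discs
  set.seed(42)
  gr <- matrix(rnorm(400), 20, 20)
  for (r in c(1, 3, 10)) {
    oracle <- matrix(0, 20, 20)
    for (y in 1:20) for (x in 1:20) {
      vals <- c()
      for (yy in 1:20) for (xx in 1:20) {
        if ((xx - x)^2 + (yy - y)^2 <= r^2) vals <- c(vals, gr[yy, xx])
      }
      oracle[y, x] <- mean(vals)
    }
    expect_equal(neighborhood_mean(gr, r), oracle, tolerance = 1e-12)
  }
  expect_error(neighborhood_mean(gr, 0.5), ">= 1")
})

test_that("ESRI ASCII grid round-trips, maps NODATA to the mask, and rejects
           malformed input", {
  d <- withr::local_tempdir()
  g <- matrix(c(1.5, 2, -3, 0, 4.25, 6, 7, 8, 9), 3, 3)
  p <- file.path(d, "g.asc")
  write_ascii_grid(g, p)
  expect_equal(read_ascii_grid(p), g)

  # masked cells become NODATA on write and NA on read
  mask <- matrix(FALSE, 3, 3); mask[2, 2] <- TRUE
  write_ascii_grid(g, p, mask = mask)
  back <- read_ascii_grid(p)
  expect_true(is.na(back[2, 2]))
  expect_equal(back[!mask], g[!mask])

  # foreign cellsize: warn and carry on as 1 m cells
  writeLines(c("ncols 2", "nrows 2", "xllcorner 0", "yllcorner 0",
               "cellsize 30", "NODATA_value -9999", "1 2", "3 4"),
             file.path(d, "c.asc"))
  expect_warning(gc30 <- read_ascii_grid(file.path(d, "c.asc")), "cellsize")
  expect_equal(gc30, matrix(c(1, 3, 2, 4), 2, 2))

  # ragged row: error naming the line
  writeLines(c("ncols 3", "nrows 2", "xllcorner 0", "yllcorner 0",
               "cellsize 1", "NODATA_value -9999", "1 2 3", "4 5"),
             file.path(d, "r.asc"))
  expect_error(read_ascii_grid(file.path(d, "r.asc")), "line 8")
  # malformed header
  writeLines(c("ncols x", "nrows 2"), file.path(d, "h.asc"))
  expect_error(read_ascii_grid(file.path(d, "h.asc")), "malformed|line")
})

test_that("a generated landscape satisfies the pasture invariants and
           round-trips through the ASCII serialization", {
  land <- small_pasture()
  expect_s3_class(land, "pasture")
  acc <- land$accessible
  expect_equal(mean(land$initial_forage_g[acc]),
               land$config$kgs_per_hectare / 10, tolerance = 1e-9)
  expect_true(all(land$forage_g <= land$initial_forage_g))
  expect_true(all(land$msal_mg >= 0))
  expect_true(all(acc[land$water]))
  expect_equal(land$n_forage_g, neighborhood_mean(land$initial_forage_g, 3))

  d <- withr::local_tempdir()
  write_landscape(land, d)
  back <- read_landscape(d)
  expect_equal(back$accessible, land$accessible)
  expect_equal(back$initial_forage_g, land$initial_forage_g,
               tolerance = 1e-12)
  expect_equal(back$initial_msal_mg, land$initial_msal_mg, tolerance = 1e-12)
  expect_equal(back$water, land$water)

  # full determinism under a fixed seed
  again <- generate_landscape(landscape_config(100, 100, seed = 9))
  expect_identical(again$initial_forage_g, land$initial_forage_g)
  expect_identical(again$initial_msal_mg, land$initial_msal_mg)
})

test_that("configuration validation rejects impossible landscapes", {
  expect_error(landscape_config(0, 10), ">= 1")
  expect_error(landscape_config(10, 10, correlation_length_m = 0), "positive")
  expect_error(landscape_config(10, 10, kgs_per_hectare = -1), "positive")
  expect_error(landscape_config(10, 10, within_patch_density = 0.5),
               "exceed 1")
  expect_error(landscape_config(10, 10, background_density = -0.1),
               "nonnegative")
  expect_error(accessible_mask(landscape_config(6, 6,
                                                fence_margin_cells = 3)),
               "no accessible")
})
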