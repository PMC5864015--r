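#' Synthetic pasture landscape configuration
#'
#' Parameters of the synthetic landscape generator. The generator statistically
#' emulates a foothills pasture with a dangerous amount of Geyer's larkspur:
#' a spatially correlated productivity index drives both forage mass (1/3x to
#' 3x the pasture mean) and larkspur plant mass (+-50% of the median), larkspur
#' plants follow a clustered (Poisson-cluster) point process with dense patches
#' (>1 plant per m^2) on a sparse background, and water is a single stream-like
#' polyline that may be intermittently dry.
#'
#' @param width_cells,height_cells grid dimensions; one cell is 1 m^2.
#' @param seed integer RNG seed; all layers are reproducible from it.
#' @param correlation_length_m spatial correlation scale (m) of the
#'   productivity index field.
#' @param kgs_per_hectare mean usable forage over accessible cells (kg/ha).
#' @param patch_intensity_per_ha expected larkspur patch centres per hectare.
#' @param patch_radius_m patch radius (m).
#' @param within_patch_density mean plants per m^2 inside patches (> 1 by the
#'   field definition of a larkspur patch).
#' @param background_density mean plants per m^2 outside patches.
#' @param median_plant_mass_g median larkspur plant mass (g).
#' @param msal_concentration_mg_per_g MSAL alkaloid concentration (mg/g).
#' @param fence_margin_cells width of the inaccessible border strip (cells).
#' @param stream_break_fraction fraction of the stream path dropped to emulate
#'   an intermittently subsurface stream (at least one water cell is always
#'   retained).
#' @return an object of class `landscape_config`.
#' @export
landscape_config <- function(width_cells, height_cells, seed = 1L,
                             correlation_length_m = 16,
                             kgs_per_hectare = 500,
                             patch_intensity_per_ha = 0.5,
                             patch_radius_m = 18,
                             within_patch_density = 4,
                             background_density = 0.02,
                             median_plant_mass_g = 3.5,
                             msal_concentration_mg_per_g = 3.0,
                             fence_margin_cells = 2L,
                             stream_break_fraction = 0.3) {
  width_cells <- as.integer(width_cells)
  height_cells <- as.integer(height_cells)
  if (width_cells < 1L || height_cells < 1L)
    stop("landscape dimensions must be >= 1 cell", call. = FALSE)
  if (correlation_length_m <= 0)
    stop("correlation_length_m must be positive", call. = FALSE)
  if (kgs_per_hectare <= 0)
    stop("kgs_per_hectare must be positive", call. = FALSE)
  if (background_density < 0 || within_patch_density < 0)
    stop("plant densities must be nonnegative", call. = FALSE)
  if (within_patch_density <= 1)
    stop("within_patch_density must exceed 1 plant per m^2 (patch definition)",
         call. = FALSE)
  if (within_patch_density < background_density)
    stop("within_patch_density must be >= background_density", call. = FALSE)
  if (msal_concentration_mg_per_g < 0)
    stop("msal_concentration_mg_per_g must be nonnegative", call. = FALSE)
  if (stream_break_fraction < 0 || stream_break_fraction > 1)
    stop("stream_break_fraction must be in [0, 1]", call. = FALSE)
  structure(list(
    width_cells = width_cells, height_cells = height_cells,
    seed = as.integer(seed),
    correlation_length_m = correlation_length_m,
    kgs_per_hectare = kgs_per_hectare,
    patch_intensity_per_ha = patch_intensity_per_ha,
    patch_radius_m = patch_radius_m,
    within_patch_density = within_patch_density,
    background_density = background_density,
    median_plant_mass_g = median_plant_mass_g,
    msal_concentration_mg_per_g = msal_concentration_mg_per_g,
    fence_margin_cells = as.integer(fence_margin_cells),
    stream_break_fraction = stream_break_fraction
  ), class = "landscape_config")
}

# deterministic derived seeds, kept below 2^31
seed_offset <- function(seed, k) {
  as.integer((as.numeric(seed) %% 97651021) * 19 + k) %% 2147483647L
}

#' Accessibility mask for a landscape configuration
#'
#' Cells within `fence_margin_cells` of the grid edge are outside the fence
#' line and inaccessible.
#'
#' @param config a [landscape_config()].
#' @return logical matrix (rows = y, cols = x), `TRUE` where accessible.
#' @export
accessible_mask <- function(config) {
  H <- config$height_cells; W <- config$width_cells
  m <- matrix(TRUE, H, W)
  f <- config$fence_margin_cells
  if (f > 0L) {
    if (2L * f >= min(H, W))
      stop("fence margin leaves no accessible cells", call. = FALSE)
    m[seq_len(f), ] <- FALSE
    m[H - seq_len(f) + 1L, ] <- FALSE
    m[, seq_len(f)] <- FALSE
    m[, W - seq_len(f) + 1L] <- FALSE
  }
  m
}

#' Generate the spatially correlated productivity index field
#'
#' A stand-in for a remotely sensed vegetation index: Gaussian white noise
#' smoothed with a Gaussian kernel (circular convolution via FFT) whose
#' standard deviation is half the correlation length, then min-max normalized
#' to attain 0 and 1.
#'
#' @param config a [landscape_config()].
#' @return numeric matrix in \[0, 1\] with `height_cells` rows.
#' @export
generate_index_field <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  set.seed(seed_offset(config$seed, 0L))
  W <- config$width_cells; H <- config$height_cells
  z <- matrix(stats::rnorm(W * H), H, W)
  sigma <- config$correlation_length_m / 2
  if (sigma >= 0.5 && W > 1 && H > 1) {
    ky <- 0:(H - 1); ky <- pmin(ky, H - ky)
    kx <- 0:(W - 1); kx <- pmin(kx, W - kx)
    kern <- outer(exp(-0.5 * (ky / sigma)^2), exp(-0.5 * (kx / sigma)^2))
    kern <- kern / sum(kern)
    z <- Re(stats::fft(stats::fft(z) * stats::fft(kern), inverse = TRUE)) /
      (W * H)
  }
  r <- range(z)
  if (r[2] > r[1]) (z - r[1]) / (r[2] - r[1]) else matrix(0.5, H, W)
}

#' Distribute forage from the productivity index
#'
#' Initial forage per cell is `m * 3^(2u - 1)` for index `u`, with the single
#' global factor `m` chosen so the mean over accessible cells equals
#' `kgs_per_hectare / 10` grams per m^2. Where the index attains 0 and 1 the
#' least-productive cells hold one third of the mean and the most productive
#' three times the mean (max/min ratio 9).
#'
#' @param index numeric matrix in \[0, 1\].
#' @param kgs_per_hectare target mean usable forage (kg/ha).
#' @param accessible optional logical matrix; inaccessible cells get 0 forage
#'   and are excluded from the mean constraint.
#' @return numeric matrix of initial forage (g per cell).
#' @export
forage_from_index <- function(index, kgs_per_hectare, accessible = NULL) {
  if (any(index < -1e-12 | index > 1 + 1e-12, na.rm = TRUE))
    stop("index values must lie in [0, 1]", call. = FALSE)
  if (is.null(accessible)) accessible <- matrix(TRUE, nrow(index), ncol(index))
  if (!any(accessible)) stop("no accessible cells", call. = FALSE)
  raw <- 3^(2 * index - 1)
  target_mean <- kgs_per_hectare / 10  # kg/ha -> g/m^2
  out <- raw * (target_mean / mean(raw[accessible]))
  out[!accessible] <- 0
  out
}

#' Generate the clustered larkspur layer
#'
#' Plant counts follow a Poisson-cluster process: patch centres are a Poisson
#' number (`patch_intensity_per_ha` x area) of cells sampled with probability
#' proportional to the productivity index (Geyer's larkspur grows most densely
#' in productive areas); cells within `patch_radius_m` of a centre draw
#' Poisson(`within_patch_density`) plants, all others
#' Poisson(`background_density`). Per-plant mass scales linearly with the
#' index, `median_plant_mass_g * (0.5 + u)`, so plants in the most productive
#' cells are 50% larger than the median and those in the least productive 50%
#' smaller. Cell MSAL content (mg) is count x mass x concentration.
#'
#' @param index numeric matrix in \[0, 1\].
#' @param config a [landscape_config()].
#' @param accessible optional logical matrix; inaccessible cells carry no
#'   plants.
#' @return list with `plant_count` (integer matrix) and `msal_mg` (numeric
#'   matrix).
#' @export
generate_larkspur_field <- function(index, config, accessible = NULL) {
  stopifnot(inherits(config, "landscape_config"))
  H <- nrow(index); W <- ncol(index)
  if (is.null(accessible)) accessible <- matrix(TRUE, H, W)
  set.seed(seed_offset(config$seed, 1L))
  area_ha <- W * H / 1e4
  n_patch <- stats::rpois(1L, config$patch_intensity_per_ha * area_ha)
  in_patch <- matrix(FALSE, H, W)
  if (n_patch > 0L) {
    w <- as.vector(index) + 1e-9
    centers <- sample.int(W * H, n_patch, replace = TRUE, prob = w)
    r <- config$patch_radius_m
    ri <- ceiling(r)
    for (c0 in centers) {
      cy <- (c0 - 1L) %% H + 1L
      cx <- (c0 - 1L) %/% H + 1L
      ys <- max(1L, cy - ri):min(H, cy + ri)
      xs <- max(1L, cx - ri):min(W, cx + ri)
      dd <- outer((ys - cy)^2, (xs - cx)^2, "+")
      in_patch[ys, xs] <- in_patch[ys, xs] | (dd <= r^2)
    }
  }
  lambda <- ifelse(in_patch, config$within_patch_density,
                   config$background_density)
  counts <- matrix(stats::rpois(W * H, as.vector(lambda)), H, W)
  counts[!accessible] <- 0L
  mass <- config$median_plant_mass_g * (0.5 + index)
  msal <- counts * mass * config$msal_concentration_mg_per_g
  list(plant_count = counts, msal_mg = msal)
}

#' Generate the stream water feature
#'
#' A lateral random-walk polyline across the accessible area, split into
#' segments of which a fraction `stream_break_fraction` is dropped (the stream
#' is intermittently below ground). At least one water cell is always retained.
#'
#' @param config a [landscape_config()].
#' @param accessible optional logical matrix.
#' @return logical matrix, `TRUE` at water cells (all accessible).
#' @export
generate_water_feature <- function(config, accessible = NULL) {
  stopifnot(inherits(config, "landscape_config"))
  H <- config$height_cells; W <- config$width_cells
  if (is.null(accessible)) accessible <- accessible_mask(config)
  if (!any(accessible)) stop("no accessible cells", call. = FALSE)
  set.seed(seed_offset(config$seed, 2L))
  f <- config$fence_margin_cells
  x0 <- f + 1L; x1 <- W - f
  y_lo <- f + 1L; y_hi <- H - f
  y <- sample(y_lo:y_hi, 1L)
  path_x <- integer(0); path_y <- integer(0)
  for (x in x0:x1) {
    y <- y + sample(c(-1L, 0L, 0L, 1L), 1L)
    y <- min(max(y, y_lo), y_hi)
    path_x <- c(path_x, x); path_y <- c(path_y, y)
  }
  keep <- logical(length(path_x))
  seg_len <- 20L
  n_seg <- ceiling(length(path_x) / seg_len)
  seg_keep <- stats::runif(n_seg) >= config$stream_break_fraction
  for (s in seq_len(n_seg)) {
    idx <- ((s - 1L) * seg_len + 1L):min(s * seg_len, length(path_x))
    keep[idx] <- seg_keep[s]
  }
  ok <- accessible[cbind(path_y, path_x)]
  keep <- keep & ok
  if (!any(keep)) {  # floor rule: retain at least one water cell
    cand <- which(ok)
    keep[cand[ceiling(length(cand) / 2)]] <- TRUE
  }
  water <- matrix(FALSE, H, W)
  water[cbind(path_y[keep], path_x[keep])] <- TRUE
  water
}

#' Disc-neighborhood mean of a grid
#'
#' Each cell's value is the mean of the grid over cells whose centre lies
#' within `radius_m` metres of that cell's centre (cells are 1 m^2, centres on
#' the half-integer lattice). Edge cells use the truncated disc.
#'
#' @param grid numeric matrix.
#' @param radius_m radius in metres (>= 1).
#' @return numeric matrix of the same shape.
#' @export
neighborhood_mean <- function(grid, radius_m) {
  if (radius_m < 1) stop("radius_m must be >= 1", call. = FALSE)
  .neighborhood_mean_cpp(grid, radius_m)
}

#' Construct a pasture object
#'
#' The spatial state container of the simulation: per-cell forage (g), MSAL
#' alkaloid content (mg), grazing counts, accessibility and water cells, plus
#' the derived 3 m neighborhood mean of initial forage used by site selection.
#'
#' @param forage_g numeric matrix of initial forage (g per cell).
#' @param msal_mg numeric matrix of initial MSAL content (mg per cell);
#'   defaults to zero.
#' @param accessible logical matrix; defaults to all accessible.
#' @param water logical matrix of water cells; defaults to none. Water cells
#'   must be accessible.
#' @param config optional [landscape_config()] kept for provenance.
#' @return an object of class `pasture`.
#' @export
pasture <- function(forage_g, msal_mg = NULL, accessible = NULL, water = NULL,
                    config = NULL) {
  H <- nrow(forage_g); W <- ncol(forage_g)
  if (is.null(msal_mg)) msal_mg <- matrix(0, H, W)
  if (is.null(accessible)) accessible <- matrix(TRUE, H, W)
  if (is.null(water)) water <- matrix(FALSE, H, W)
  stopifnot(all(dim(msal_mg) == c(H, W)), all(dim(accessible) == c(H, W)),
            all(dim(water) == c(H, W)))
  if (any(water & !accessible))
    stop("every water cell must be accessible", call. = FALSE)
  if (any(forage_g < 0) || any(msal_mg < 0))
    stop("forage and MSAL content must be nonnegative", call. = FALSE)
  structure(list(
    accessible = accessible,
    forage_g = forage_g,
    initial_forage_g = forage_g,
    n_forage_g = neighborhood_mean(forage_g, 3),
    msal_mg = msal_mg,
    initial_msal_mg = msal_mg,
    times_grazed = matrix(0L, H, W),
    water = water,
    config = config
  ), class = "pasture")
}

#' Generate a full synthetic pasture
#'
#' Runs the index, forage, larkspur and water generators and assembles a
#' [pasture()] object. Fully reproducible from `config$seed`.
#'
#' @param config a [landscape_config()].
#' @return a `pasture` with an extra `index` element (the productivity field)
#'   and `plant_count` (larkspur plants per cell).
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  acc <- accessible_mask(config)
  index <- generate_index_field(config)
  forage <- forage_from_index(index, config$kgs_per_hectare, acc)
  lark <- generate_larkspur_field(index, config, acc)
  water <- generate_water_feature(config, acc)
  p <- pasture(forage, lark$msal_mg, acc, water, config)
  p$index <- index
  p$plant_count <- lark$plant_count
  p
}

#' @export
print.pasture <- function(x, ...) {
  acc_ha <- sum(x$accessible) / 1e4
  cat("Pasture:", ncol(x$forage_g), "x", nrow(x$forage_g), "m grid,",
      sprintf("%.2f accessible ha\n", acc_ha))
  cat(sprintf("  forage: %.1f kg total (%.1f kg/ha over accessible cells)\n",
              sum(x$forage_g) / 1e3,
              sum(x$forage_g[x$accessible]) / 1e3 / acc_ha))
  cat(sprintf("  MSAL alkaloid: %.2f g total; water cells: %d\n",
              sum(x$msal_mg) / 1e3, sum(x$water)))
  invisible(x)
}

#' Read and write ESRI ASCII grids
#'
#' Minimal ESRI ASCII raster dialect: a header with keys `ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize` and optionally `NODATA_value`,
#' followed by rows of values, row-major from the top (north) row. NODATA
#' cells become `NA` on read (the accessibility mask). A `cellsize` other
#' than 1 triggers a warning and is treated as 1 m model cells.
#'
#' @param path file path.
#' @param grid numeric matrix (row 1 is the top row).
#' @param mask optional logical matrix; `TRUE` cells are written as NODATA.
#' @param nodata NODATA sentinel value.
#' @return `read_ascii_grid` returns a numeric matrix with `NA` at NODATA
#'   cells; `write_ascii_grid` returns `path` invisibly.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 6L)
    stop("malformed ESRI ASCII grid (too short): ", path, call. = FALSE)
  hdr <- list()
  i <- 1L
  while (i <= length(lines)) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    key <- tolower(parts[1])
    if (!(key %in% c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
                     "nodata_value"))) break
    if (length(parts) != 2L || is.na(suppressWarnings(as.numeric(parts[2]))))
      stop("malformed header at line ", i, " of ", path, call. = FALSE)
    hdr[[key]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  for (k in c("ncols", "nrows", "cellsize"))
    if (is.null(hdr[[k]]))
      stop("missing header key '", k, "' in ", path, call. = FALSE)
  if (hdr$cellsize != 1)
    warning("cellsize ", hdr$cellsize, " in ", basename(path),
            "; treated as 1 m model cells", call. = FALSE)
  nodata <- if (is.null(hdr$nodata_value)) NA_real_ else hdr$nodata_value
  W <- as.integer(hdr$ncols); H <- as.integer(hdr$nrows)
  body <- lines[i:length(lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != H)
    stop("expected ", H, " data rows, found ", length(body), " in ", path,
         call. = FALSE)
  out <- matrix(NA_real_, H, W)
  for (r in seq_len(H)) {
    vals <- suppressWarnings(as.numeric(strsplit(trimws(body[r]), "\\s+")[[1]]))
    if (length(vals) != W || anyNA(vals))
      stop("ragged or non-numeric row at line ", i + r - 1L, " of ", path,
           call. = FALSE)
    out[r, ] <- vals
  }
  if (!is.na(nodata)) out[out == nodata] <- NA_real_
  out
}

#' @rdname read_ascii_grid
#' @export
write_ascii_grid <- function(grid, path, mask = NULL, nodata = -9999) {
  H <- nrow(grid); W <- ncol(grid)
  vals <- grid
  if (!is.null(mask)) vals[mask] <- nodata
  vals[is.na(vals)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", W), paste("nrows", H),
    "xllcorner 0", "yllcorner 0", "cellsize 1",
    paste("NODATA_value", nodata)
  ), con)
  for (r in seq_len(H))
    writeLines(paste(format(vals[r, ], trim = TRUE, scientific = FALSE,
                            digits = 15), collapse = " "), con)
  invisible(path)
}

#' Write or read a pasture's layers as ESRI ASCII grids
#'
#' Serializes `forage.asc`, `msal.asc` and `water.asc` (inaccessible cells as
#' NODATA). `read_landscape` reconstructs a fresh [pasture()]; the
#' accessibility mask comes from the NODATA cells of the forage layer.
#'
#' @param p a `pasture`.
#' @param dir directory to write to / read from.
#' @return `write_landscape` returns `dir` invisibly; `read_landscape` a
#'   `pasture`.
#' @export
write_landscape <- function(p, dir) {
  stopifnot(inherits(p, "pasture"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  inacc <- !p$accessible
  write_ascii_grid(p$initial_forage_g, file.path(dir, "forage.asc"), inacc)
  write_ascii_grid(p$initial_msal_mg, file.path(dir, "msal.asc"), inacc)
  write_ascii_grid(p$water * 1, file.path(dir, "water.asc"), inacc)
  invisible(dir)
}

#' @rdname write_landscape
#' @export
read_landscape <- function(dir) {
  forage <- read_ascii_grid(file.path(dir, "forage.asc"))
  msal <- read_ascii_grid(file.path(dir, "msal.asc"))
  water <- read_ascii_grid(file.path(dir, "water.asc"))
  acc <- !is.na(forage)
  forage[!acc] <- 0
  msal[is.na(msal)] <- 0
  w <- !is.na(water) & water > 0
  pasture(forage, msal, acc, w)
}
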