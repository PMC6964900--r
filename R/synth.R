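# Synthetic co-registered worlds: a stable fine-scale thermal anomaly
# (urban bumps + a coastal step) superimposed on coarse daily weather, a
# cloudy LST scene stack that observes the anomaly, and stations that
# observe the fine truth. Every stage of the pipeline, and every invariant
# it relies on, is testable against these worlds without any downloads.

#' Recipe for a synthetic downscaling world
#'
#' The recipe fixes the conditions the pipeline is designed for: a 1/8
#' degree coarse grid with 12:1 nesting (~1 km fine pixels), a warm-season
#' stack of 19 eight-day LST composites with blocky cloud dropouts, a
#' fine-scale anomaly whose imprint on air temperature is half its imprint
#' on LST (`r_true = 0.5`), and a June–August validation window over three
#' years. All randomness flows from the single `seed`; identical recipes
#' give identical worlds.
#'
#' @param coarse coarse [grid_spec()] (default 8 x 8 cells of 1/8 degree
#'   around a mid-latitude, mid-CONUS location)
#' @param nest integer fine pixels per coarse cell per axis (default 12)
#' @param urban_centers list of `c(row, col, amplitude, radius)` vectors in
#'   fine-pixel units: Gaussian warm bumps of the given amplitude (°C in
#'   LST) and e-folding radius
#' @param coast_col fine column at which a coastal step begins (`NA` for no
#'   coast); columns at or east of it get `water_offset`
#' @param water_offset °C LST offset of the "water" side (negative: water
#'   is cooler than land by day)
#' @param base_mean mean coarse daily maximum air temperature (°C)
#' @param ew_gradient total west-to-east gradient of the coarse daily
#'   maximum (°C across the domain)
#' @param day_sd standard deviation of the day-to-day swing of the coarse
#'   daily maximum (°C)
#' @param diurnal_amplitude peak-to-trough amplitude of the sinusoidal
#'   diurnal cycle (°C)
#' @param peak_hour local standard hour of the daily maximum (integer;
#'   default 14, just after the early-afternoon satellite overpass)
#' @param base_lst mean clear-sky afternoon LST (°C); LST runs well above
#'   the 2 m air temperature by day
#' @param scene_level_sd standard deviation of per-scene LST level shifts
#'   (°C), the sub-seasonal weather the composite averages away
#' @param r_true dimensionless coupling of the anomaly into air
#'   temperature: fine truth = coarse + `r_true` * anomaly (default 0.5)
#' @param noise_sd per-scene, per-pixel LST noise (°C)
#' @param cloud_fraction target fraction of each scene masked by clouds
#'   (blocky random rectangles, not i.i.d. pixels, to stress per-cell
#'   fallback logic)
#' @param cold_contam_frac fraction of surviving pixels per scene given a
#'   cold bias, imitating undetected partial cloud contamination
#' @param cold_bias °C bias applied to contaminated pixels (negative)
#' @param n_scenes number of composite scenes (default 19: the 8-day
#'   periods of May–September)
#' @param dates `Date` vector of simulated days (default June–August of
#'   2009–2011, 276 days)
#' @param seed integer master seed
#' @return an object of class `scene_recipe`
#' @export
scene_recipe <- function(coarse = grid_spec(west = -90.5, north = 39,
                                            dx = 0.125, nrows = 8, ncols = 8),
                         nest = 12L,
                         urban_centers = list(
                           c(row = 30, col = 34, amplitude = 4, radius = 6),
                           c(row = 62, col = 68, amplitude = 3, radius = 5)),
                         coast_col = 79L, water_offset = -6,
                         base_mean = 27, ew_gradient = 2, day_sd = 2.5,
                         diurnal_amplitude = 10, peak_hour = 14L,
                         base_lst = 36, scene_level_sd = 1.5,
                         r_true = 0.5, noise_sd = 0.5,
                         cloud_fraction = 0.3,
                         cold_contam_frac = 0.02, cold_bias = -10,
                         n_scenes = 19L,
                         dates = jja_dates(2009:2011),
                         seed = 1L) {
  stopifnot(inherits(coarse, "grid_spec"), nest >= 1L,
            is.finite(r_true), r_true > 0,
            cloud_fraction >= 0, cloud_fraction < 1,
            noise_sd >= 0, n_scenes >= 1L, length(dates) >= 1L)
  for (u in urban_centers)
    stopifnot(all(is.finite(u)), length(u) == 4L)
  fine <- refine_grid(coarse, nest)
  structure(list(coarse = coarse, fine = fine, nest = as.integer(nest),
                 urban_centers = urban_centers,
                 coast_col = coast_col, water_offset = water_offset,
                 base_mean = base_mean, ew_gradient = ew_gradient,
                 day_sd = day_sd, diurnal_amplitude = diurnal_amplitude,
                 peak_hour = as.integer(peak_hour), base_lst = base_lst,
                 scene_level_sd = scene_level_sd, r_true = r_true,
                 noise_sd = noise_sd, cloud_fraction = cloud_fraction,
                 cold_contam_frac = cold_contam_frac, cold_bias = cold_bias,
                 n_scenes = as.integer(n_scenes),
                 dates = as.Date(dates), seed = as.integer(seed)),
            class = "scene_recipe")
}

#' @rdname scene_recipe
#' @param years integer years
#' @export
jja_dates <- function(years) {
  do.call(c, lapply(years, function(y)
    seq(as.Date(paste0(y, "-06-01")), as.Date(paste0(y, "-08-31")),
        by = "day")))
}

#' @export
print.scene_recipe <- function(x, ...) {
  cat(sprintf("<scene_recipe> coarse %s, %d:1 nesting, %d scenes, %d days, seed %d\n",
              format(x$coarse), x$nest, x$n_scenes, length(x$dates), x$seed))
  invisible(x)
}

# run code under a given seed without disturbing the caller's RNG stream
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# nearest-cell upsampling and per-cell block means via the ownership map
upsample_to_fine <- function(cm, cmap) {
  matrix(cm[cmap$owner], cmap$fine$nrows, cmap$fine$ncols)
}

block_mean <- function(fm, cmap) {
  idx <- !is.na(cmap$owner)
  sums <- rowsum(as.numeric(fm[idx]), group = cmap$owner[idx])
  cnts <- rowsum(rep(1, sum(idx)), group = cmap$owner[idx])
  out <- matrix(NA_real_, cmap$coarse$nrows, cmap$coarse$ncols)
  out[as.integer(rownames(sums))] <- sums / cnts
  out
}

anomaly_field <- function(recipe) {
  fine <- recipe$fine
  a <- matrix(0, fine$nrows, fine$ncols)
  rows <- row(a); cols <- col(a)
  for (u in recipe$urban_centers)
    a <- a + u[["amplitude"]] *
      exp(-((rows - u[["row"]])^2 + (cols - u[["col"]])^2) /
            (2 * u[["radius"]]^2))
  if (!is.null(recipe$coast_col) && is.finite(recipe$coast_col))
    a[, cols[1, ] >= recipe$coast_col] <-
      a[, cols[1, ] >= recipe$coast_col] + recipe$water_offset
  a
}

#' Generate the synthetic truth
#'
#' Builds the world the downscaler assumes: a fixed fine-scale anomaly `a`
#' (Gaussian urban bumps plus a coastal step, re-centered to zero mean
#' within every coarse cell), coarse daily maxima (a west–east gradient
#' plus a seeded day-to-day swing), the fine daily-maximum truth
#' `upsample(coarse) + r_true * a`, and an hourly coarse air-temperature
#' cube whose sinusoidal diurnal cycle peaks at `peak_hour` local standard
#' time with exactly the coarse daily maximum. Because `a` has zero mean
#' per cell, the block mean of the fine truth over any coarse cell equals
#' the coarse value: the synthetic world satisfies the conservation premise
#' of the method exactly.
#'
#' @param recipe a [scene_recipe()]
#' @return an object of class `synth_world`: list with `recipe`, `cmap`,
#'   `a` (fine anomaly matrix), `dates`, `coarse_tmax` (array
#'   `[day, row, col]`), `truth_tmax` (array `[day, row, col]` on the fine
#'   grid) and `cube` (an [hourly_cube()] spanning all days)
#' @export
make_truth <- function(recipe) {
  stopifnot(inherits(recipe, "scene_recipe"))
  cmap <- build_cell_map(recipe$fine, recipe$coarse)
  a <- anomaly_field(recipe)
  a <- a - upsample_to_fine(block_mean(a, cmap), cmap)  # zero mean per cell

  coarse <- recipe$coarse; fine <- recipe$fine
  # coarse daily peaks over a contiguous span one day beyond the requested
  # dates on both sides, so every local day's 24 hours exist in the cube
  span <- seq(min(recipe$dates) - 1, max(recipe$dates) + 1, by = "day")
  ramp <- matrix(rep(seq(0, recipe$ew_gradient, length.out = coarse$ncols),
                     each = coarse$nrows), coarse$nrows, coarse$ncols)
  day_effect <- local_seed(recipe$seed, stats::rnorm(length(span), 0,
                                                     recipe$day_sd))
  peaks <- array(NA_real_, c(length(span), coarse$nrows, coarse$ncols))
  for (k in seq_along(span))
    peaks[k, , ] <- recipe$base_mean + ramp + day_effect[k]

  keep <- match(recipe$dates, span)
  coarse_tmax <- peaks[keep, , , drop = FALSE]
  truth <- array(NA_real_, c(length(recipe$dates), fine$nrows, fine$ncols))
  for (k in seq_along(recipe$dates))
    truth[k, , ] <- upsample_to_fine(coarse_tmax[k, , ], cmap) +
      recipe$r_true * a

  # hourly cube: sinusoid with max = daily peak at peak_hour local time
  offsets <- local_utc_offset(x_centers(coarse))
  t0 <- as.POSIXct(paste(span[1], "00:00:00"), tz = "UTC") -
    3600 * max(offsets)
  t1 <- as.POSIXct(paste(span[length(span)], "23:00:00"), tz = "UTC") -
    3600 * min(offsets)
  times <- seq(t0, t1, by = "hour")
  vals <- array(NA_real_, c(length(times), coarse$nrows, coarse$ncols))
  tnum <- as.numeric(times)
  day0 <- as.numeric(as.POSIXct(paste(span[1], "00:00:00"), tz = "UTC"))
  for (co in unique(offsets)) {
    colsel <- which(offsets == co)
    loc <- tnum + co * 3600
    kday <- floor((loc - day0) / 86400) + 1          # index into span
    hour <- (loc - day0) / 3600 - (kday - 1) * 24    # local hour 0..23
    shape <- (1 - cos(2 * pi * (hour - recipe$peak_hour) / 24)) / 2
    inside <- kday >= 1 & kday <= length(span)
    for (j in colsel) for (r in seq_len(coarse$nrows)) {
      vals[inside, r, j] <- peaks[cbind(kday[inside], r, j)] -
        recipe$diurnal_amplitude * shape[inside]
    }
  }
  cube <- hourly_cube(coarse, times, vals)
  structure(list(recipe = recipe, cmap = cmap, a = a, dates = recipe$dates,
                 coarse_tmax = coarse_tmax, truth_tmax = truth, cube = cube),
            class = "synth_world")
}

#' @export
print.synth_world <- function(x, ...) {
  cat(sprintf("<synth_world> %d days on fine %s (seed %d)\n",
              length(x$dates), format(x$recipe$fine), x$recipe$seed))
  invisible(x)
}

blocky_cloud_mask <- function(nr, nc, fraction) {
  mask <- matrix(FALSE, nr, nc)
  if (fraction <= 0) return(mask)
  lo <- max(2L, nr %/% 8L); hi <- max(lo + 1L, nr %/% 3L)
  guard <- 0L
  while (mean(mask) < fraction && guard < 10000L) {
    h <- sample(lo:hi, 1L); w <- sample(lo:hi, 1L)
    r0 <- sample(seq_len(max(nr - h + 1L, 1L)), 1L)
    c0 <- sample(seq_len(max(nc - w + 1L, 1L)), 1L)
    mask[r0:min(r0 + h - 1L, nr), c0:min(c0 + w - 1L, nc)] <- TRUE
    guard <- guard + 1L
  }
  mask
}

#' Generate the synthetic LST scene stack
#'
#' Each scene is `base_lst + scene level + a + noise`, with a seeded blocky
#' cloud mask removing about `cloud_fraction` of the pixels and a small
#' fraction of the survivors given a cold bias — the two failure modes the
#' upper-half compositing rule exists to absorb.
#'
#' @param recipe a [scene_recipe()]
#' @param a the fine anomaly matrix from [make_truth()]
#' @return a [scene_stack()]
#' @export
make_lst_stack <- function(recipe, a) {
  stopifnot(inherits(recipe, "scene_recipe"),
            all(dim(a) == c(recipe$fine$nrows, recipe$fine$ncols)))
  fine <- recipe$fine
  local_seed(recipe$seed + 1L, {
    levels <- stats::rnorm(recipe$n_scenes, 0, recipe$scene_level_sd)
    scenes <- lapply(seq_len(recipe$n_scenes), function(s) {
      vals <- recipe$base_lst + levels[s] + a
      if (recipe$noise_sd > 0)
        vals <- vals + matrix(stats::rnorm(length(vals), 0, recipe$noise_sd),
                              fine$nrows, fine$ncols)
      cloud <- blocky_cloud_mask(fine$nrows, fine$ncols,
                                 recipe$cloud_fraction)
      valid <- !cloud
      if (recipe$cold_contam_frac > 0) {
        cand <- which(valid)
        ncon <- floor(recipe$cold_contam_frac * length(cand))
        if (ncon > 0) {
          hit <- sample(cand, ncon)
          vals[hit] <- vals[hit] + recipe$cold_bias
        }
      }
      vals[!valid] <- NA_real_
      list(label = sprintf("scene_%02d", s), values = vals, valid = valid)
    })
    scene_stack(fine, scenes,
                season = sprintf("synthetic warm season, %d scenes",
                                 recipe$n_scenes))
  })
}

#' Generate synthetic stations
#'
#' Places `k` stations at seeded random fine pixels (jittered within the
#' pixel so extraction by containment is exercised, never pixel-center
#' special cases) and has each observe the fine truth at its containing
#' pixel, plus optional observation noise, on every recipe date.
#'
#' @param recipe a [scene_recipe()]
#' @param world a [make_truth()] result from the same recipe
#' @param k number of stations (default 5)
#' @param obs_noise_sd observation noise (°C, default 0)
#' @param seed seed (defaults to `recipe$seed + 2`)
#' @return a station table data frame (`station_id, lon, lat, date,
#'   obs_tmax_c`), plus a `pixel` attribute giving each station's fine
#'   pixel linear index
#' @export
make_stations <- function(recipe, world, k = 5L, obs_noise_sd = 0,
                          seed = recipe$seed + 2L) {
  stopifnot(inherits(recipe, "scene_recipe"), inherits(world, "synth_world"),
            k >= 1L)
  fine <- recipe$fine
  local_seed(seed, {
    pix <- sample(seq_len(fine$nrows * fine$ncols), k)
    pr <- ((pix - 1L) %% fine$nrows) + 1L
    pc <- ((pix - 1L) %/% fine$nrows) + 1L
    lon <- fine$west + (pc - 0.5 + stats::runif(k, -0.4, 0.4)) * fine$dx
    lat <- fine$north - (pr - 0.5 + stats::runif(k, -0.4, 0.4)) * fine$dy
    ndays <- length(world$dates)
    obs <- vapply(seq_len(k), function(i)
      world$truth_tmax[, pr[i], pc[i]], numeric(ndays))
    if (obs_noise_sd > 0)
      obs <- obs + matrix(stats::rnorm(length(obs), 0, obs_noise_sd),
                          ndays, k)
    df <- data.frame(
      station_id = rep(sprintf("SYN%02d", seq_len(k)), each = ndays),
      lon = rep(lon, each = ndays), lat = rep(lat, each = ndays),
      date = rep(world$dates, k),
      obs_tmax_c = as.numeric(obs),
      stringsAsFactors = FALSE)
    attr(df, "pixel") <- pix
    df
  })
}
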