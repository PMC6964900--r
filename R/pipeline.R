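# Stage-per-directory pipeline: each stage reads the artifacts of the
# previous one from a run directory and writes its own, so stages can be
# run separately (or from the command line) and re-running a stage with
# identical inputs reproduces identical outputs.

qc_to_code <- function(qc) {
  m <- matrix(match(qc, qc_levels) - 1L, nrow(qc), ncol(qc))
  storage.mode(m) <- "double"
  m
}

code_to_qc <- function(codes) {
  matrix(qc_levels[round(codes) + 1L], nrow(codes), ncol(codes))
}

stage_error <- function(stage, ...) {
  stop(sprintf("[%s] %s", stage, paste0(...)), call. = FALSE)
}

need_artifact <- function(stage, path, hint) {
  if (!file.exists(path))
    stage_error(stage, "missing artifact ", path, "; run `", hint, "` first")
  path
}

#' Write a synthetic world to a run directory
#'
#' Materializes a [scene_recipe()] as on-disk pipeline inputs: the hourly
#' coarse cube (`cube.txt`), the LST scene stack (`lst/scene_NN.asc`), the
#' station table (`stations.csv`) and, optionally, the fine truth rasters.
#'
#' @param dir run directory (created if needed)
#' @param recipe a [scene_recipe()]
#' @param k number of stations
#' @param obs_noise_sd station observation noise (°C)
#' @param write_truth also write `truth/truth_<date>.asc` rasters
#' @return the [make_truth()] world, invisibly
#' @export
stage_simulate <- function(dir, recipe = scene_recipe(), k = 5L,
                           obs_noise_sd = 0, write_truth = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  world <- make_truth(recipe)
  write_hourly_cube(world$cube, file.path(dir, "cube.txt"))
  stack <- make_lst_stack(recipe, world$a)
  dir.create(file.path(dir, "lst"), showWarnings = FALSE)
  for (i in seq_along(stack$scenes)) {
    sc <- stack$scenes[[i]]
    write_raster(field2d(recipe$fine, sc$values, sc$valid),
                 file.path(dir, "lst", sprintf("scene_%02d.asc", i)))
  }
  stations <- make_stations(recipe, world, k = k,
                            obs_noise_sd = obs_noise_sd)
  write_stations(stations, file.path(dir, "stations.csv"))
  if (write_truth) {
    dir.create(file.path(dir, "truth"), showWarnings = FALSE)
    for (kk in seq_along(world$dates))
      write_raster(field2d(recipe$fine, world$truth_tmax[kk, , ]),
                   file.path(dir, "truth",
                             sprintf("truth_%s.asc", world$dates[kk])))
  }
  invisible(world)
}

#' Pipeline stages over a run directory
#'
#' `stage_extrema` reduces the hourly cube to per-day coarse maxima;
#' `stage_composite` builds the robust LST composite and the departure
#' field; `stage_downscale` applies the departures to each day's coarse
#' maxima; `stage_validate` extracts coarse and downscaled estimates at the
#' stations and writes a per-city-style statistics table. Each stage
#' fails with a message naming the missing artifact if run out of order.
#'
#' @param dir run directory
#' @param dates `Date` vector of days to process
#' @param min_valid_pixels per-cell validity threshold, see
#'   [compute_departures()]
#' @param cfg a [downscale_config()]
#' @param window a [date_window()] for validation
#' @return each stage returns its main result invisibly
#' @name pipeline_stages
#' @export
stage_extrema <- function(dir, dates) {
  cube <- read_hourly_cube(need_artifact("extrema",
                                         file.path(dir, "cube.txt"),
                                         "simulate"))
  dir.create(file.path(dir, "extrema"), showWarnings = FALSE)
  out <- lapply(as.Date(dates), function(d) {
    ex <- daily_extrema(cube, d)
    write_raster(ex$tmax, file.path(dir, "extrema",
                                    sprintf("tmax_%s.asc", d)))
    ex
  })
  invisible(out)
}

#' @rdname pipeline_stages
#' @export
stage_composite <- function(dir, min_valid_pixels = 3L) {
  files <- sort(list.files(file.path(dir, "lst"), pattern = "\\.asc$",
                           full.names = TRUE))
  if (length(files) == 0L)
    stage_error("composite", "no LST scenes under ", file.path(dir, "lst"),
                "; run `simulate` first")
  fields <- lapply(files, read_raster)
  stack <- scene_stack(fields[[1]]$spec,
                       lapply(seq_along(fields), function(i)
                         list(label = basename(files[i]),
                              values = fields[[i]]$values,
                              valid = fields[[i]]$valid)))
  comp <- robust_composite(stack)
  cube <- read_hourly_cube(need_artifact("composite",
                                         file.path(dir, "cube.txt"),
                                         "simulate"))
  cmap <- build_cell_map(comp$spec, cube$spec)
  dep <- compute_departures(comp, cmap, min_valid_pixels = min_valid_pixels)
  dir.create(file.path(dir, "composite"), showWarnings = FALSE)
  write_raster(comp$t_h, file.path(dir, "composite", "t_h.asc"))
  write_raster(field2d(dep$spec, dep$d), file.path(dir, "composite", "d.asc"))
  write_raster(field2d(dep$spec, qc_to_code(dep$qc)),
               file.path(dir, "composite", "qc.asc"))
  invisible(dep)
}

#' @rdname pipeline_stages
#' @export
stage_downscale <- function(dir, dates, cfg = downscale_config()) {
  d_f <- read_raster(need_artifact("downscale",
                                   file.path(dir, "composite", "d.asc"),
                                   "composite"))
  qc_f <- read_raster(need_artifact("downscale",
                                    file.path(dir, "composite", "qc.asc"),
                                    "composite"))
  dir.create(file.path(dir, "downscaled"), showWarnings = FALSE)
  out <- lapply(as.Date(dates), function(d) {
    tl <- read_raster(need_artifact(
      "downscale", file.path(dir, "extrema", sprintf("tmax_%s.asc", d)),
      "extrema"))
    cmap <- build_cell_map(d_f$spec, tl$spec)
    dep <- structure(list(spec = d_f$spec, d = d_f$values,
                          qc = code_to_qc(qc_f$values),
                          cell_mean = NULL, cell_sigma = NULL, z = NULL),
                     class = "departure_field")
    ds <- if (cfg$mode == "constant_ratio") {
      downscale_constant_ratio(tl, dep, cfg, cmap)
    } else {
      downscale_sigma_ratio(neighborhood_stats(tl, cfg$neighborhood_cells),
                            dep, cmap)
    }
    write_raster(ds$t_dis, file.path(dir, "downscaled",
                                     sprintf("tdis_%s.asc", d)))
    ds
  })
  invisible(out)
}

#' @rdname pipeline_stages
#' @export
stage_validate <- function(dir, window) {
  stations <- read_stations(need_artifact("validate",
                                          file.path(dir, "stations.csv"),
                                          "simulate"))
  sites <- unique(stations[, c("station_id", "lon", "lat")])
  dates <- window_dates(window)
  dates <- dates[dates %in% stations$date]
  if (length(dates) == 0L)
    stage_error("validate", "no station dates fall inside the window")
  grab <- function(subdir, prefix) {
    do.call(rbind, lapply(dates, function(d) {
      f <- need_artifact("validate",
                         file.path(dir, subdir, sprintf("%s_%s.asc",
                                                        prefix, d)),
                         if (subdir == "extrema") "extrema" else "downscale")
      ex <- extract_at_points(read_raster(f), sites)
      data.frame(station_id = ex$station_id, date = d,
                 estimate = ex$value, stringsAsFactors = FALSE)
    }))
  }
  tabs <- list(coarse = grab("extrema", "tmax"),
               downscaled = grab("downscaled", "tdis"))
  stats <- do.call(rbind, lapply(names(tabs), function(prod) {
    st <- compute_stats(pair_series(tabs[[prod]], stations, window))
    st$product <- prod
    st
  }))
  stats <- stats[, c("station_id", "product", "n", "mean_diff", "rmsd")]
  utils::write.csv(stats, file.path(dir, "validation.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(stats)
}

#' Run the full downscaling pipeline
#'
#' Executes simulate (optional) → extrema → composite → downscale →
#' validate over a run directory, logging per-stage counts to `message()`.
#'
#' @param dir run directory
#' @param recipe a [scene_recipe()]; `NULL` to reuse existing inputs in
#'   `dir`
#' @param dates days to process (default: the recipe's dates)
#' @param cfg a [downscale_config()]
#' @param window a [date_window()] for validation; `NULL` skips validation
#' @param min_valid_pixels see [compute_departures()]
#' @return the validation statistics data frame (or `NULL` when validation
#'   is skipped), invisibly
#' @export
run_pipeline <- function(dir, recipe = scene_recipe(), dates = NULL,
                         cfg = downscale_config(), window = NULL,
                         min_valid_pixels = 3L) {
  if (!is.null(recipe)) {
    message("[simulate] writing synthetic inputs to ", dir)
    stage_simulate(dir, recipe)
    if (is.null(dates)) dates <- recipe$dates
  }
  if (is.null(dates))
    stage_error("run", "no dates given and no recipe to take them from")
  message("[extrema] ", length(dates), " day(s)")
  stage_extrema(dir, dates)
  dep <- stage_composite(dir, min_valid_pixels = min_valid_pixels)
  message("[composite] qc: ",
          paste(sprintf("%s=%d", qc_levels,
                        tabulate(match(dep$qc, qc_levels),
                                 length(qc_levels))),
                collapse = " "))
  message("[downscale] mode ", cfg$mode, ", ratio ", cfg$r_ratio)
  stage_downscale(dir, dates, cfg)
  stats <- NULL
  if (!is.null(window)) {
    stats <- stage_validate(dir, window)
    message("[validate] ", nrow(stats), " station/product rows written")
  }
  invisible(stats)
}
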