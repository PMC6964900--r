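# Shared fixture builders. Everything is generated in code under fixed
# seeds; geometry is scaled down where the full default world is not needed.

tiny_recipe <- function(...) {
  defaults <- list(
    coarse = grid_spec(west = -90.5, north = 39, dx = 0.125,
                       nrows = 4, ncols = 4),
    nest = 6L,
    urban_centers = list(c(row = 8, col = 9, amplitude = 4, radius = 3)),
    coast_col = 20L, water_offset = -5,
    n_scenes = 5L,
    dates = jja_dates(2009)[1:3],
    seed = 11L)
  args <- list(...)
  defaults[names(args)] <- args
  do.call(scene_recipe, defaults)
}

# a fully valid random field on a grid
random_field <- function(spec, mean = 25, sd = 3) {
  field2d(spec, matrix(rnorm(spec$nrows * spec$ncols, mean, sd),
                       spec$nrows, spec$ncols))
}

# departure field built directly from a composite-like fine matrix
departures_from_matrix <- function(m, cmap, min_valid_pixels = 3L) {
  spec <- cmap$fine
  stk <- scene_stack(spec, list(list(label = "only", values = m,
                                     valid = is.finite(m))))
  compute_departures(robust_composite(stk), cmap,
                     min_valid_pixels = min_valid_pixels)
}

# brute-force reference for the upper-half composite of one pixel history
oracle_upper_half <- function(values) {
  v <- values[is.finite(values)]
  if (length(v) == 0L) return(NA_real_)
  k <- ceiling(length(v) / 2)
  mean(rev(sort(v))[1:k])
}
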