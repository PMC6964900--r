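#' Downscaling configuration
#'
#' The disaggregation adds rescaled LST departures to the coarse daily
#' maximum: `t_dis = t_l + R * d` in `constant_ratio` mode, or
#' `t_dis = t_l + d * sigma_l / sigma_h` (equivalently `t_l + z * sigma_l`)
#' in `sigma_ratio` mode. The constant ratio `R` stands in for the ratio of
#' air-temperature to LST spatial variability; `R = 0.5` is the operational
#' choice for CONUS daily maxima, reflecting that 2 m air temperature varies
#' roughly half as much in space as surface skin temperature. `sigma_ratio`
#' mode instead derives the rescaling cell by cell from the data and is the
#' natural route to a spatially varying ratio; it is exposed but not the
#' default because neighborhood air-temperature variability can be dominated
#' by climatological gradients (coastlines in particular) and produce
#' unrealistic extremes.
#'
#' @param r_ratio positive dimensionless ratio applied to departures
#'   (default 0.5)
#' @param mode `"constant_ratio"` (default) or `"sigma_ratio"`
#' @param neighborhood_cells odd window size, in coarse cells, over which
#'   `sigma_l` is taken in `sigma_ratio` mode (default 1: the single owning
#'   cell, which preserves coarse-cell means)
#' @return an object of class `downscale_config`
#' @export
downscale_config <- function(r_ratio = 0.5,
                             mode = c("constant_ratio", "sigma_ratio"),
                             neighborhood_cells = 1L) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(r_ratio), length(r_ratio) == 1L, is.finite(r_ratio))
  if (mode == "constant_ratio" && r_ratio < 0)
    stop("r_ratio must be non-negative", call. = FALSE)
  neighborhood_cells <- as.integer(neighborhood_cells)
  if (neighborhood_cells < 1L || neighborhood_cells %% 2L == 0L)
    stop("neighborhood_cells must be an odd positive integer", call. = FALSE)
  structure(list(r_ratio = r_ratio, mode = mode,
                 neighborhood_cells = neighborhood_cells),
            class = "downscale_config")
}

#' Standardize departures
#'
#' Populates `z = d / cell_sigma` per pixel, using the owning cell's
#' population standard deviation. Cells with zero sigma (a perfectly uniform
#' composite) get `z = 0`, which reduces the downscaled value to the coarse
#' value there — the only defensible answer when the pattern carries no
#' information.
#'
#' @param dep a [compute_departures()] result
#' @param cmap the [build_cell_map()] the departures were computed with
#' @return `dep` with `z` populated (matrix on the fine grid)
#' @export
standardize <- function(dep, cmap) {
  stopifnot(inherits(dep, "departure_field"), inherits(cmap, "cell_map"))
  sigma <- dep$cell_sigma[cmap$owner]      # NA where unassigned
  sigma <- matrix(sigma, dep$spec$nrows, dep$spec$ncols)
  z <- matrix(0, dep$spec$nrows, dep$spec$ncols)
  ok <- dep$qc == "ok" & !is.na(sigma) & sigma > 0
  z[ok] <- dep$d[ok] / sigma[ok]
  dep$z <- z
  dep
}

cell_field <- function(x, name = "tmax") {
  if (inherits(x, "daily_extrema")) x[[name]] else x
}

#' Downscale with a constant departure ratio
#'
#' Applies `t_dis = t_l + R * d` per fine pixel, where `t_l` is the value of
#' the single owning coarse cell (no further neighborhood averaging — this
#' is what makes the scheme conserve coarse-cell means) and `d` is the fixed
#' seasonal departure. Pixels whose departure fell back to zero, or whose
#' cell sigma is degenerate, reproduce the coarse value exactly; pixels
#' owned by a cell with an invalid coarse temperature are invalid.
#'
#' @param tl coarse daily maxima: a [field2d()] on the coarse grid or a
#'   [daily_extrema()] (its `tmax` is used)
#' @param dep a [compute_departures()] result on the fine grid
#' @param cfg a [downscale_config()]
#' @param cmap the [build_cell_map()] tying the two grids together
#' @return an object of class `downscaled_field`: list with fine `spec`,
#'   `t_dis` ([field2d()]) and `qc` (character matrix propagated from `dep`)
#' @export
downscale_constant_ratio <- function(tl, dep, cfg = downscale_config(), cmap) {
  stopifnot(inherits(dep, "departure_field"), inherits(cmap, "cell_map"),
            inherits(cfg, "downscale_config"))
  tlf <- cell_field(tl)
  stopifnot(inherits(tlf, "field2d"))
  if (!same_grid(tlf$spec, cmap$coarse))
    stop("coarse temperature grid does not match the cell map", call. = FALSE)
  if (!same_grid(dep$spec, cmap$fine))
    stop("departure grid does not match the cell map", call. = FALSE)
  apply_departures(tlf, dep$d * cfg$r_ratio, dep$qc, cmap)
}

#' Downscale with per-cell sigma ratios
#'
#' Applies `t_dis = t_l + d * sigma_l / sigma_h`, the un-simplified form in
#' which the rescaling is the ratio of coarse air-temperature variability to
#' fine LST variability over a configurable neighborhood. Equivalent to
#' `t_l + z * sigma_l` with standardized departures. Cells with `sigma_h ==
#' 0` (or no sigma at all) fall back to the coarse value.
#'
#' @param tl_stats a [neighborhood_stats()] result
#' @param dep a [compute_departures()] result
#' @param cmap the shared [build_cell_map()]
#' @return a `downscaled_field`, as [downscale_constant_ratio()]
#' @export
downscale_sigma_ratio <- function(tl_stats, dep, cmap) {
  stopifnot(inherits(tl_stats, "neighborhood_stats"),
            inherits(dep, "departure_field"), inherits(cmap, "cell_map"))
  if (!same_grid(tl_stats$spec, cmap$coarse))
    stop("neighborhood stats grid does not match the cell map", call. = FALSE)
  ratio <- tl_stats$sigma_l / dep$cell_sigma
  ratio[!is.finite(ratio)] <- 0   # sigma_h == 0 or missing -> coarse value
  ratio_pix <- matrix(ratio[cmap$owner], dep$spec$nrows, dep$spec$ncols)
  ratio_pix[is.na(ratio_pix)] <- 0
  apply_departures(field2d(tl_stats$spec, tl_stats$t_l),
                   dep$d * ratio_pix, dep$qc, cmap)
}

apply_departures <- function(tlf, adj, qc, cmap) {
  fine <- cmap$fine
  tl_pix <- matrix(tlf$values[cmap$owner], fine$nrows, fine$ncols)
  ok_cell <- matrix(tlf$valid[cmap$owner], fine$nrows, fine$ncols)
  ok_cell[is.na(ok_cell)] <- FALSE
  t_dis <- tl_pix
  use <- qc == "ok" & ok_cell
  t_dis[use] <- tl_pix[use] + adj[use]
  t_dis[!ok_cell] <- NA_real_
  structure(list(spec = fine,
                 t_dis = field2d(fine, t_dis, ok_cell),
                 qc = qc),
            class = "downscaled_field")
}

#' @export
print.downscaled_field <- function(x, ...) {
  cat("<downscaled_field>\n  t_dis: "); print(x$t_dis)
  invisible(x)
}

#' Coarse-cell neighborhood mean and standard deviation
#'
#' For each coarse cell, `t_l` is the cell's own value and `sigma_l` the
#' population standard deviation of the valid coarse values in the centered
#' `window x window` block of cells around it (clipped at domain edges).
#' With `window = 1` the neighborhood is the single cell and `sigma_l` is 0.
#'
#' @param tl coarse [field2d()] or [daily_extrema()]
#' @param window odd positive window size in cells
#' @return an object of class `neighborhood_stats`: list with coarse `spec`,
#'   `t_l` and `sigma_l` matrices
#' @export
neighborhood_stats <- function(tl, window = 1L) {
  tlf <- cell_field(tl)
  stopifnot(inherits(tlf, "field2d"))
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L)
    stop("window must be an odd positive integer", call. = FALSE)
  s <- tlf$spec
  h <- (window - 1L) %/% 2L
  sigma <- matrix(NA_real_, s$nrows, s$ncols)
  for (r in seq_len(s$nrows)) {
    rr <- max(1L, r - h):min(s$nrows, r + h)
    for (c in seq_len(s$ncols)) {
      cc <- max(1L, c - h):min(s$ncols, c + h)
      v <- tlf$values[rr, cc]
      v <- v[is.finite(v)]
      if (length(v) >= 1L)
        sigma[r, c] <- sqrt(mean((v - mean(v))^2))
    }
  }
  structure(list(spec = s, t_l = tlf$values, sigma_l = sigma,
                 window = window),
            class = "neighborhood_stats")
}

#' Diagnose the air/LST variability ratio
#'
#' Estimates, per coarse cell and for the domain, the ratio
#' `sigma_l / sigma_h` that `constant_ratio` mode collapses into the single
#' constant `R`: `sigma_l` is the population standard deviation of the
#' coarse daily maxima over the `window x window` cell neighborhood
#' (averaged across the supplied days), and `sigma_h` the population
#' standard deviation of the composite LST over the fine pixels of the same
#' neighborhood. The domain summary is the median over cells with positive,
#' finite ratios; cells with degenerate `sigma_h` are omitted. Useful for
#' checking a chosen `R` against a region, or for mapping where a constant
#' ratio is least appropriate (coasts, mountains).
#'
#' @param tl_fields list of coarse [field2d()]/[daily_extrema()] objects
#'   (one per day)
#' @param comp a [robust_composite()] on the fine grid
#' @param cmap the shared [build_cell_map()]
#' @param window odd neighborhood size in coarse cells (default 3; a single
#'   cell gives `sigma_l = 0` everywhere and is not useful here)
#' @return an object of class `sigma_ratio_estimate`: list with `ratio_map`
#'   (coarse matrix), `global` (median ratio) and `n_cells` (cells entering
#'   the summary)
#' @export
estimate_sigma_ratio <- function(tl_fields, comp, cmap, window = 3L) {
  stopifnot(inherits(comp, "robust_composite"), inherits(cmap, "cell_map"),
            length(tl_fields) >= 1L)
  if (!same_grid(comp$spec, cmap$fine))
    stop("composite grid does not match the cell map", call. = FALSE)
  coarse <- cmap$coarse
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L)
    stop("window must be an odd positive integer", call. = FALSE)
  # mean over days of the neighborhood sigma of the coarse field
  sig_l_days <- vapply(tl_fields,
                       function(f) neighborhood_stats(f, window)$sigma_l,
                       numeric(coarse$nrows * coarse$ncols))
  sig_l <- matrix(rowMeans(matrix(sig_l_days, ncol = length(tl_fields))),
                  coarse$nrows, coarse$ncols)
  # neighborhood sigma of the fine composite, via the cell map
  h <- (window - 1L) %/% 2L
  th <- comp$t_h$values
  okpix <- comp$t_h$valid
  sig_h <- matrix(NA_real_, coarse$nrows, coarse$ncols)
  for (r in seq_len(coarse$nrows)) {
    rr <- max(1L, r - h):min(coarse$nrows, r + h)
    for (c in seq_len(coarse$ncols)) {
      cc <- max(1L, c - h):min(coarse$ncols, c + h)
      cells <- as.integer(outer(rr, (cc - 1L) * coarse$nrows, `+`))
      mem <- unlist(cmap$members[cells], use.names = FALSE)
      mem <- mem[okpix[mem]]
      if (length(mem) >= 2L)
        sig_h[r, c] <- sqrt(mean((th[mem] - mean(th[mem]))^2))
    }
  }
  ratio <- sig_l / sig_h
  usable <- is.finite(ratio) & sig_h > 0
  structure(list(ratio_map = ratio,
                 global = if (any(usable)) stats::median(ratio[usable]) else NA_real_,
                 n_cells = sum(usable), window = window),
            class = "sigma_ratio_estimate")
}

#' @export
print.sigma_ratio_estimate <- function(x, ...) {
  cat(sprintf(
    "<sigma_ratio_estimate> global median %.3f over %d cells (window %d)\n",
    x$global, x$n_cells, x$window))
  invisible(x)
}
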