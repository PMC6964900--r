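#' Decode a scaled-integer LST scene
#'
#' Satellite LST products are commonly distributed as scaled integers
#' (Kelvin times 50, i.e. a 0.02 K step) with 0 as the fill value — 0 K
#' being physically impossible, "non-zero" and "valid" coincide in raw
#' units. Valid pixels are converted to °C; fill pixels, and any pixel whose
#' scaled value would be a negative Kelvin temperature, are masked.
#'
#' @param raw numeric matrix of raw scaled values
#' @param scale multiplicative scale to Kelvin (default 0.02)
#' @param fill raw fill value (default 0)
#' @return list with `values` (°C matrix, `NA` where invalid) and `valid`
#'   (logical matrix)
#' @examples
#' ingest_scene(matrix(15000))  # 300 K = 26.85 degC
#' @export
ingest_scene <- function(raw, scale = 0.02, fill = 0) {
  stopifnot(is.numeric(scale), scale > 0)
  raw <- as.matrix(raw)
  valid <- is.finite(raw) & raw != fill
  kelvin <- raw * scale
  neg <- valid & kelvin < 0
  if (any(neg)) {
    warning(sum(neg), " pixel(s) decode to negative Kelvin; masked",
            call. = FALSE)
    valid <- valid & !neg
  }
  vals <- kelvin - 273.15
  vals[!valid] <- NA_real_
  list(values = vals, valid = valid)
}

#' A stack of co-registered LST scenes
#'
#' @param spec fine [grid_spec()] shared by all scenes
#' @param scenes list of scenes, each a list with `label` (e.g. the 8-day
#'   period start date), `values` (°C matrix) and `valid` (logical matrix)
#' @param season free-text season label (e.g. `"2009 May-Sep"`)
#' @return an object of class `scene_stack`
#' @export
scene_stack <- function(spec, scenes, season = "") {
  stopifnot(inherits(spec, "grid_spec"), is.list(scenes))
  for (sc in scenes) {
    if (!all(dim(sc$values) == c(spec$nrows, spec$ncols)))
      stop("scene '", sc$label, "' does not match the stack grid",
           call. = FALSE)
  }
  structure(list(spec = spec, scenes = scenes, season = season),
            class = "scene_stack")
}

#' @export
print.scene_stack <- function(x, ...) {
  cat(sprintf("<scene_stack> %d scene(s) on %s%s\n", length(x$scenes),
              format(x$spec),
              if (nzchar(x$season)) paste0(", season ", x$season) else ""))
  invisible(x)
}

upper_half_mean <- function(v) {
  v <- v[!is.na(v)]
  n <- length(v)
  if (n == 0L) return(NA_real_)
  mean(sort(v, decreasing = TRUE)[seq_len(ceiling(n / 2))])
}

#' Robust warm-season LST composite
#'
#' Per pixel, the mean of the upper half of the valid values across scenes:
#' with `n` valid samples the top `ceiling(n / 2)` are averaged. Keeping
#' only the upper half discards cloud fill and the occasional erroneously
#' low retrieval from partial cloud contamination, at the cost of a warm
#' bias that cancels when per-cell departures are taken. Any value below a
#' pixel's median therefore never influences the composite. A pixel with no
#' valid sample in any scene is invalid.
#'
#' @param stack a [scene_stack()] (at least one scene)
#' @return an object of class `robust_composite`: list with `spec`, `t_h`
#'   ([field2d()] of composite LST, °C) and `n_valid` (integer matrix of
#'   contributing scene counts)
#' @examples
#' sp <- grid_spec(0, 1, 1, nrows = 1, ncols = 1)
#' st <- scene_stack(sp, lapply(c(10, 20, 30, 40), function(v)
#'   list(label = "", values = matrix(v), valid = matrix(TRUE))))
#' robust_composite(st)$t_h$values  # mean of {30, 40} = 35
#' @export
robust_composite <- function(stack) {
  stopifnot(inherits(stack, "scene_stack"))
  if (length(stack$scenes) == 0L)
    stop("cannot composite an empty scene stack", call. = FALSE)
  spec <- stack$spec
  npix <- spec$nrows * spec$ncols
  V <- vapply(stack$scenes, function(sc) {
    v <- sc$values
    v[!sc$valid] <- NA_real_
    as.numeric(v)
  }, numeric(npix))
  V <- matrix(V, nrow = npix)
  t_h <- apply(V, 1L, upper_half_mean)
  n_valid <- rowSums(!is.na(V))
  structure(list(spec = spec,
                 t_h = field2d(spec, matrix(t_h, spec$nrows, spec$ncols)),
                 n_valid = matrix(as.integer(n_valid), spec$nrows, spec$ncols)),
            class = "robust_composite")
}

#' @export
print.robust_composite <- function(x, ...) {
  cat("<robust_composite>\n  t_h: "); print(x$t_h)
  cat(sprintf("  contributing scenes per pixel: %d .. %d\n",
              min(x$n_valid), max(x$n_valid)))
  invisible(x)
}

qc_levels <- c("ok", "fallback_zero", "unassigned")

#' Per-cell LST departures
#'
#' For each coarse cell owning at least `min_valid_pixels` valid composite
#' pixels, computes the cell mean and population standard deviation of the
#' composite over the valid members, and the per-pixel departure
#' `d = t_h - cell_mean`. These departures are the fixed geographic
#' temperature pattern — urban warmth, water bodies, land-cover contrasts —
#' later rescaled onto the coarse air temperatures. Centering uses only the
#' valid members, so the mean departure over `qc == "ok"` pixels is zero in
#' every cell by construction, which is what makes the downscaled field
#' conserve the coarse one.
#'
#' Cell standard deviations use the population (divide-by-n) denominator: a
#' cell's pixels are an enumeration, not a sample. Pixels in below-threshold
#' cells and pixels invalid in the composite get `d = 0` (the downscaled
#' value degrades to the coarse value) with `qc = "fallback_zero"`; pixels
#' outside the coarse domain get `qc = "unassigned"`.
#'
#' @param comp a [robust_composite()]
#' @param cmap a [build_cell_map()] whose fine grid matches `comp`
#' @param min_valid_pixels minimum valid members for a cell to contribute a
#'   pattern (default 3)
#' @return an object of class `departure_field`: list with fine `spec`, `d`
#'   (matrix, °C), `qc` (character matrix), `cell_mean` and `cell_sigma`
#'   (matrices on the coarse grid, `NA` for below-threshold cells), and `z`
#'   (standardized departures, `NULL` until [standardize()] is called)
#' @export
compute_departures <- function(comp, cmap, min_valid_pixels = 3L) {
  stopifnot(inherits(comp, "robust_composite"), inherits(cmap, "cell_map"))
  if (!same_grid(comp$spec, cmap$fine))
    stop("composite grid does not match the cell map's fine grid",
         call. = FALSE)
  fine <- cmap$fine; coarse <- cmap$coarse
  d <- matrix(0, fine$nrows, fine$ncols)
  qc <- matrix("unassigned", fine$nrows, fine$ncols)
  qc[!is.na(cmap$owner)] <- "fallback_zero"
  cell_mean <- matrix(NA_real_, coarse$nrows, coarse$ncols)
  cell_sigma <- matrix(NA_real_, coarse$nrows, coarse$ncols)
  th <- comp$t_h$values
  okpix <- comp$t_h$valid
  for (cell in seq_along(cmap$members)) {
    mem <- cmap$members[[cell]]
    if (length(mem) == 0L) next
    vmem <- mem[okpix[mem]]
    if (length(vmem) < min_valid_pixels) next
    mu <- mean(th[vmem])
    cell_mean[cell] <- mu
    cell_sigma[cell] <- sqrt(mean((th[vmem] - mu)^2))
    d[vmem] <- th[vmem] - mu
    qc[vmem] <- "ok"
  }
  structure(list(spec = fine, d = d, qc = qc,
                 cell_mean = cell_mean, cell_sigma = cell_sigma,
                 z = NULL),
            class = "departure_field")
}

#' @export
print.departure_field <- function(x, ...) {
  tab <- table(factor(x$qc, levels = qc_levels))
  cat(sprintf("<departure_field> %s\n", format(x$spec)))
  cat(sprintf("  qc: %s\n",
              paste(sprintf("%s=%d", names(tab), tab), collapse = " ")))
  if (any(x$qc == "ok"))
    cat(sprintf("  departures %.3f .. %.3f degC%s\n",
                min(x$d[x$qc == "ok"]), max(x$d[x$qc == "ok"]),
                if (is.null(x$z)) "" else " (standardized)"))
  invisible(x)
}
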