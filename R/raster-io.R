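#' Read and write single-band rasters
#'
#' Two on-disk formats are supported, both georeferenced regular lat/lon:
#'
#' * **ESRI ASCII grid** (`format = "asc"`): plain text, written at full
#'   double precision so a write/read cycle is bit-identical. Requires
#'   square pixels (`dx == dy`), as the format carries a single `cellsize`.
#' * **TIFF with world file** (`format = "tiff"`): a two-channel 32-bit
#'   float TIFF (data channel affinely rescaled to \[0, 1\], validity mask
#'   channel), a 6-line ESRI world file (`.tfw`) for the georeferencing and
#'   a small JSON sidecar recording the rescaling. Round-trips are exact to
#'   32-bit float precision.
#'
#' Invalid pixels are written as the nodata value (`asc`) or a zero mask
#' (`tiff`) and come back flagged invalid.
#'
#' @param path file path; `read_raster` infers the format from the
#'   extension when `format` is omitted
#' @param format `"asc"` or `"tiff"`
#' @param field a [field2d()] to write
#' @param nodata nodata value used in ASCII grids
#' @return `read_raster` returns a [field2d()]; `write_raster` returns
#'   `path` invisibly.
#' @export
read_raster <- function(path, format = c("auto", "asc", "tiff")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such raster file: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, asc = "asc", tif = , tiff = "tiff",
                     stop("cannot infer raster format from extension '",
                          ext, "'", call. = FALSE))
  }
  switch(format, asc = read_asc(path), tiff = read_tiff(path))
}

#' @rdname read_raster
#' @export
write_raster <- function(field, path, format = c("auto", "asc", "tiff"),
                         nodata = -9999) {
  stopifnot(inherits(field, "field2d"))
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, asc = "asc", tif = , tiff = "tiff",
                     stop("cannot infer raster format from extension '",
                          ext, "'", call. = FALSE))
  }
  switch(format,
         asc = write_asc(field, path, nodata = nodata),
         tiff = write_tiff(field, path))
  invisible(path)
}

write_asc <- function(field, path, nodata = -9999) {
  s <- field$spec
  if (abs(s$dx - s$dy) > 1e-12)
    stop("ASCII grids require square pixels (dx == dy); use format='tiff'",
         call. = FALSE)
  vals <- field$values
  vals[!field$valid] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", s$ncols),
    sprintf("nrows %d", s$nrows),
    sprintf("xllcorner %.17g", s$west),
    sprintf("yllcorner %.17g", s$north - s$nrows * s$dy),
    sprintf("cellsize %.17g", s$dx),
    sprintf("NODATA_value %.17g", nodata)), con)
  # rows from north to south, matching our matrix layout
  writeLines(apply(vals, 1L, function(r) paste(sprintf("%.17g", r),
                                               collapse = " ")), con)
  path
}

read_asc <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("malformed ASCII grid header in ", path,
         " (missing georeferencing keys)", call. = FALSE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  vals <- scan(text = lines[i:length(lines)], quiet = TRUE)
  if (length(vals) != nr * nc)
    stop("ASCII grid ", path, " has ", length(vals), " values, expected ",
         nr * nc, call. = FALSE)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  valid <- is.finite(m)
  if (!is.null(hdr$nodata_value)) valid <- valid & (m != hdr$nodata_value)
  spec <- grid_spec(west = hdr$xllcorner,
                    north = hdr$yllcorner + nr * hdr$cellsize,
                    dx = hdr$cellsize, dy = hdr$cellsize,
                    nrows = nr, ncols = nc)
  field2d(spec, m, valid)
}

write_tiff <- function(field, path) {
  s <- field$spec
  v <- field$values
  rng <- if (any(field$valid)) range(v[field$valid]) else c(0, 1)
  offset <- rng[1]
  scale <- max(rng[2] - rng[1], 1e-12)
  scaled <- (v - offset) / scale
  scaled[!field$valid] <- 0
  arr <- array(0, dim = c(s$nrows, s$ncols, 2L))
  arr[, , 1L] <- scaled
  arr[, , 2L] <- field$valid * 1
  tiff::writeTIFF(arr, path, bits.per.sample = 32L, compression = "none")
  # ESRI world file: pixel sizes then the center of the top-left pixel
  writeLines(sprintf("%.17g", c(s$dx, 0, 0, -s$dy,
                                s$west + 0.5 * s$dx,
                                s$north - 0.5 * s$dy)),
             world_path(path))
  writeLines(jsonlite::toJSON(list(scale = scale, offset = offset,
                                   crs = "EPSG:4326", units = "degC"),
                              auto_unbox = TRUE, digits = NA),
             sidecar_path(path))
  path
}

world_path <- function(path) paste0(tools::file_path_sans_ext(path), ".tfw")
sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

read_tiff <- function(path) {
  wf <- world_path(path)
  if (!file.exists(wf))
    stop("TIFF raster ", path, " has no world file (", wf,
         "): georeferencing missing", call. = FALSE)
  w <- as.numeric(readLines(wf))
  if (length(w) != 6L || !all(is.finite(w[c(1, 4:6)])) || w[1] <= 0 || w[4] >= 0)
    stop("malformed world file ", wf, call. = FALSE)
  # libtiff flags our mask channel as an unexpected extra sample; harmless
  arr <- withCallingHandlers(
    tiff::readTIFF(path),
    warning = function(w) {
      if (grepl("ExtraSamples", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  if (length(dim(arr)) != 3L || dim(arr)[3] < 2L)
    stop("expected a two-channel (data, mask) TIFF in ", path, call. = FALSE)
  meta <- jsonlite::fromJSON(sidecar_path(path))
  vals <- arr[, , 1L] * meta$scale + meta$offset
  valid <- arr[, , 2L] > 0.5
  dx <- w[1]; dy <- -w[4]
  spec <- grid_spec(west = w[5] - 0.5 * dx, north = w[6] + 0.5 * dy,
                    dx = dx, dy = dy,
                    nrows = dim(arr)[1], ncols = dim(arr)[2])
  field2d(spec, vals, valid)
}

#' Read and write station observation tables
#'
#' CSV with header `station_id,lon,lat,date,obs_tmax_c` and ISO-8601 dates.
#' `(station_id, date)` pairs must be unique and coordinates finite.
#'
#' @param path CSV path
#' @param stations data frame with the columns above
#' @return `read_stations` returns the validated data frame with `date`
#'   parsed to `Date`.
#' @export
read_stations <- function(path) {
  if (!file.exists(path)) stop("no such station file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("station_id", "lon", "lat", "date", "obs_tmax_c")
  if (!all(need %in% names(df)))
    stop("station table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  df$date <- as.Date(df$date)
  validate_stations(df)
  df
}

#' @rdname read_stations
#' @export
write_stations <- function(stations, path) {
  validate_stations(stations)
  utils::write.csv(
    stations[, c("station_id", "lon", "lat", "date", "obs_tmax_c")],
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_stations <- function(df) {
  if (!all(is.finite(df$lon)) || !all(is.finite(df$lat)))
    stop("station coordinates must be finite", call. = FALSE)
  if (anyDuplicated(df[, c("station_id", "date")]))
    stop("duplicate (station_id, date) pairs in station table", call. = FALSE)
  invisible(df)
}
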