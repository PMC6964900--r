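#' Read and write hourly cubes as plain text
#'
#' A simple self-describing text serialization for hourly temperature
#' cubes: a format line, the grid geometry, then one line per UTC hour
#' holding the timestamp and the pixel values in column-major order, at
#' full double precision. Missing samples are written as `NA`.
#'
#' @param cube an [hourly_cube()]
#' @param path file path
#' @return `read_hourly_cube` returns an [hourly_cube()];
#'   `write_hourly_cube` returns `path` invisibly.
#' @export
write_hourly_cube <- function(cube, path) {
  stopifnot(inherits(cube, "hourly_cube"))
  s <- cube$spec
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("lstdown_hourly_cube 1",
               sprintf("%.17g %.17g %.17g %.17g %d %d",
                       s$west, s$north, s$dx, s$dy, s$nrows, s$ncols),
               sprintf("%d", length(cube$times))), con)
  stamps <- format(cube$times, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  for (i in seq_along(cube$times)) {
    writeLines(paste(stamps[i],
                     paste(sprintf("%.17g", cube$values[i, , ]),
                           collapse = " ")), con)
  }
  invisible(path)
}

#' @rdname write_hourly_cube
#' @export
read_hourly_cube <- function(path) {
  if (!file.exists(path)) stop("no such cube file: ", path, call. = FALSE)
  con <- file(path, "r")
  on.exit(close(con))
  magic <- readLines(con, 1L)
  if (!identical(magic, "lstdown_hourly_cube 1"))
    stop(path, " is not an hourly-cube file", call. = FALSE)
  g <- scan(con, nlines = 1L, quiet = TRUE)
  spec <- grid_spec(west = g[1], north = g[2], dx = g[3], dy = g[4],
                    nrows = g[5], ncols = g[6])
  nt <- scan(con, nlines = 1L, quiet = TRUE)
  times <- rep(as.POSIXct(NA), nt)
  vals <- array(NA_real_, c(nt, spec$nrows, spec$ncols))
  for (i in seq_len(nt)) {
    parts <- strsplit(readLines(con, 1L), " ", fixed = TRUE)[[1]]
    times[i] <- as.POSIXct(parts[1], format = "%Y-%m-%dT%H:%M:%SZ",
                           tz = "UTC")
    vals[i, , ] <- suppressWarnings(as.numeric(parts[-1]))
  }
  hourly_cube(spec, times, vals)
}
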