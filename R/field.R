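#' A single-band raster field with a validity mask
#'
#' The common currency of every pipeline stage: a matrix of values (rows run
#' north to south, matching the [grid_spec()] convention) plus a logical
#' validity mask. Values at invalid pixels are stored as `NA` so downstream
#' arithmetic can never silently consume them.
#'
#' @param spec a [grid_spec()]
#' @param values numeric matrix, `spec$nrows` x `spec$ncols`
#' @param valid logical matrix of the same shape; defaults to
#'   `is.finite(values)`
#' @return an object of class `field2d`
#' @export
field2d <- function(spec, values, valid = NULL) {
  stopifnot(inherits(spec, "grid_spec"))
  values <- as.matrix(values)
  if (!all(dim(values) == c(spec$nrows, spec$ncols)))
    stop("values shape does not match the grid spec", call. = FALSE)
  if (is.null(valid)) valid <- is.finite(values)
  valid <- as.matrix(valid)
  if (!all(dim(valid) == dim(values)))
    stop("valid mask shape does not match values", call. = FALSE)
  valid <- valid & is.finite(values)
  storage.mode(values) <- "double"
  values[!valid] <- NA_real_
  structure(list(spec = spec, values = values, valid = valid),
            class = "field2d")
}

#' @export
print.field2d <- function(x, ...) {
  nv <- sum(x$valid)
  cat(sprintf("<field2d> %s, %d/%d valid pixels\n",
              format(x$spec), nv, length(x$valid)))
  if (nv > 0)
    cat(sprintf("  range %.3f .. %.3f\n",
                min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE)))
  invisible(x)
}

#' @export
as.matrix.field2d <- function(x, ...) x$values

#' @export
summary.field2d <- function(object, ...) {
  v <- object$values[object$valid]
  structure(list(spec = object$spec, n_valid = sum(object$valid),
                 n_total = length(object$valid),
                 stats = if (length(v)) summary(v) else NULL),
            class = "summary.field2d")
}

#' @export
print.summary.field2d <- function(x, ...) {
  cat(sprintf("field2d on %s: %d of %d pixels valid\n",
              format(x$spec), x$n_valid, x$n_total))
  if (!is.null(x$stats)) print(x$stats)
  invisible(x)
}

#' @export
#' @importFrom graphics image axis box
plot.field2d <- function(x, main = "", ...) {
  # image() wants x increasing and the matrix transposed relative to ours
  z <- t(x$values)[, rev(seq_len(x$spec$nrows)), drop = FALSE]
  image(x = x_centers(x$spec), y = rev(y_centers(x$spec)), z = z,
        xlab = "longitude", ylab = "latitude", main = main, useRaster = TRUE, ...)
  box()
  invisible(x)
}

#' Elementwise arithmetic keeps the mask
#' @export
Ops.field2d <- function(e1, e2) {
  f1 <- inherits(e1, "field2d"); f2 <- inherits(e2, "field2d")
  spec <- if (f1) e1$spec else e2$spec
  v1 <- if (f1) e1$values else e1
  v2 <- if (missing(e2)) NULL else if (f2) e2$values else e2
  vals <- if (missing(e2)) get(.Generic)(v1) else get(.Generic)(v1, v2)
  ok <- (if (f1) e1$valid else TRUE) & (if (f2) e2$valid else TRUE)
  if (is.logical(vals)) return(vals & ok)
  field2d(spec, vals, ok)
}
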