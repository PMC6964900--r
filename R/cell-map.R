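#' Fine-to-coarse pixel ownership
#'
#' Assigns every fine pixel whose center lies inside the coarse domain to the
#' coarse cell whose half-open box contains that center. The relation defines
#' the "neighborhood" over which LST departures are centered: each coarse
#' cell owns the fine pixels used to compute its mean and standard deviation.
#' Any relative alignment of the two grids is permitted; exact n:1 nesting is
#' just the common special case.
#'
#' @param fine,coarse [grid_spec()] objects
#' @return an object of class `cell_map` with elements `fine`, `coarse`,
#'   `owner` (integer matrix on the fine grid holding the column-major linear
#'   index of the owning coarse cell, `NA` where the center falls outside the
#'   coarse domain) and `members` (list over coarse cells of integer vectors
#'   of owned fine-pixel linear indices)
#' @export
build_cell_map <- function(fine, coarse) {
  stopifnot(inherits(fine, "grid_spec"), inherits(coarse, "grid_spec"))
  # row assignment depends only on latitude, column only on longitude
  rc <- floor((coarse$north - y_centers(fine)) / coarse$dy) + 1
  cc <- floor((x_centers(fine) - coarse$west) / coarse$dx) + 1
  rc[rc < 1 | rc > coarse$nrows] <- NA_integer_
  cc[cc < 1 | cc > coarse$ncols] <- NA_integer_
  owner <- outer(as.integer(rc), as.integer(cc),
                 function(r, c) (c - 1L) * coarse$nrows + r)
  ncell <- coarse$nrows * coarse$ncols
  members <- vector("list", ncell)
  assigned <- which(!is.na(owner))
  if (length(assigned) == 0L) {
    warning("fine and coarse domains do not overlap; cell map is empty",
            call. = FALSE)
  } else {
    grp <- split(assigned, owner[assigned])
    members[as.integer(names(grp))] <- grp
  }
  empty <- vapply(members, is.null, logical(1))
  members[empty] <- list(integer(0))
  structure(list(fine = fine, coarse = coarse, owner = owner,
                 members = members),
            class = "cell_map")
}

#' @export
print.cell_map <- function(x, ...) {
  n_assigned <- sum(!is.na(x$owner))
  sizes <- lengths(x$members)
  cat(sprintf("<cell_map> fine %s -> coarse %s\n",
              format(x$fine), format(x$coarse)))
  cat(sprintf("  %d of %d fine pixels assigned; cell occupancy %d .. %d\n",
              n_assigned, length(x$owner), min(sizes), max(sizes)))
  invisible(x)
}

#' Sample a gridded field at station locations
#'
#' Looks up, for each station, the value of the pixel whose box contains the
#' station coordinate (direct containment, no interpolation: gridded
#' estimates are compared to point observations as-is). Stations outside the
#' domain or over invalid pixels are flagged rather than erroring.
#'
#' @param field a [field2d()]
#' @param stations a data frame with numeric `lon` and `lat` columns (extra
#'   columns such as `station_id` are carried through)
#' @return the input data frame plus `value` (°C, `NA` when flagged) and
#'   `flag` (one of `"ok"`, `"invalid_pixel"`, `"outside_domain"`)
#' @export
extract_at_points <- function(field, stations) {
  stopifnot(inherits(field, "field2d"), is.data.frame(stations),
            all(c("lon", "lat") %in% names(stations)))
  loc <- locate_points(field$spec, stations$lon, stations$lat)
  idx <- (loc$col - 1L) * field$spec$nrows + loc$row
  value <- rep(NA_real_, nrow(stations))
  flag <- rep("outside_domain", nrow(stations))
  inb <- loc$inside
  ok <- inb & field$valid[ifelse(is.na(idx), 1L, idx)]
  flag[inb] <- "invalid_pixel"
  flag[ok] <- "ok"
  value[ok] <- field$values[idx[ok]]
  out <- stations
  out$value <- value
  out$flag <- flag
  out
}
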