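#' Define a hexagonal grid over geographic space
#'
#' Pointy-top hexagons addressed by axial coordinates `(q, r_ax)`.
#' `spacing` is the horizontal distance between adjacent column centers in
#' degrees (default 0.5°); for pointy-top hexagons this equals
#' `sqrt(3) * size` where `size` is the center-to-vertex radius. Longitude
#' and latitude are treated as planar — a display-scale approximation, not
#' an equal-area projection.
#'
#' @param spacing Horizontal center-to-center distance, degrees.
#' @param origin Length-2 lon/lat of the `(0, 0)` hexagon center.
#' @return A `hex_grid` object.
#' @export
hex_grid <- function(spacing = 0.5, origin = c(0, 0)) {
  stopifnot(spacing > 0, length(origin) == 2)
  structure(list(spacing = spacing, size = spacing / sqrt(3),
                 origin = as.numeric(origin)),
            class = "hex_grid")
}

#' @export
print.hex_grid <- function(x, ...) {
  cat(sprintf("<hex_grid> pointy-top, %g deg spacing, origin (%g, %g)\n",
              x$spacing, x$origin[1], x$origin[2]))
  invisible(x)
}

#' Assign points to hexagonal cells
#'
#' Maps each lon/lat point to the axial address of the containing hexagon
#' using fractional axial coordinates and cube rounding. Cube rounding
#' resolves edge-equidistant points deterministically (by which cube
#' coordinate accumulated the largest rounding error), so assignment is
#' stable across runs and record orderings.
#'
#' @param lon,lat Numeric vectors of coordinates (finite).
#' @param grid A [hex_grid()].
#' @return A tibble with `q`, `r_ax` (axial address) and the cell-center
#'   coordinates `center_lon`, `center_lat`.
#' @export
hex_assign <- function(lon, lat, grid = hex_grid()) {
  stopifnot(length(lon) == length(lat), all(is.finite(lon)),
            all(is.finite(lat)))
  x <- lon - grid$origin[1]
  y <- lat - grid$origin[2]
  s <- grid$size
  qf <- (sqrt(3) / 3 * x - 1 / 3 * y) / s
  rf <- (2 / 3 * y) / s
  ax <- cube_round(qf, rf)
  tibble::tibble(
    q = ax$q, r_ax = ax$r,
    center_lon = grid$origin[1] + s * sqrt(3) * (ax$q + ax$r / 2),
    center_lat = grid$origin[2] + s * 1.5 * ax$r
  )
}

cube_round <- function(qf, rf) {
  sf <- -qf - rf
  q <- round(qf); r <- round(rf); s_ <- round(sf)
  dq <- abs(q - qf); dr <- abs(r - rf); ds <- abs(s_ - sf)
  fix_q <- dq > dr & dq > ds
  fix_r <- !fix_q & dr > ds
  q[fix_q] <- -r[fix_q] - s_[fix_q]
  r[fix_r] <- -q[fix_r] - s_[fix_r]
  list(q = as.integer(q), r = as.integer(r))
}

#' Per-species percentages of records in hexagonal cells
#'
#' For each species, assigns its records to hexagons and reports the
#' percentage of the species' records in every non-empty cell — the
#' tabular form of a hexagon occurrence map. Percentages are exact (not
#' rounded), so they sum to 100 per species; species with zero records
#' are simply absent.
#'
#' @param records A record tibble with `species`, `lon`, `lat`.
#' @param grid A [hex_grid()].
#' @return A tibble with `species`, `q`, `r_ax`, `center_lon`,
#'   `center_lat`, `n`, `pct`.
#' @export
hex_percentages <- function(records, grid = hex_grid()) {
  check_columns(records, c("species", "lon", "lat"), "records")
  ok <- is.finite(records$lon) & is.finite(records$lat)
  records <- records[ok, , drop = FALSE]
  cells <- hex_assign(records$lon, records$lat, grid)
  dplyr::bind_cols(tibble::tibble(species = records$species), cells) |>
    dplyr::count(.data$species, .data$q, .data$r_ax, .data$center_lon,
                 .data$center_lat, name = "n") |>
    dplyr::group_by(.data$species) |>
    dplyr::mutate(pct = 100 * .data$n / sum(.data$n)) |>
    dplyr::ungroup()
}
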