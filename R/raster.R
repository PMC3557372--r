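#' Construct a stack of co-registered monthly raster layers
#'
#' A raster stack holds one value matrix per (variable, month) pair, all on
#' a common regular lon/lat grid. Values are point-registered at cell
#' centers; `origin` is the center of the lower-left (south-west) cell.
#' Matrices are stored with row 1 at the southern edge, so cell
#' `[i, j]` has center `(origin[1] + (j-1)*cell_size,
#' origin[2] + (i-1)*cell_size)`.
#'
#' @param layers Named list of numeric matrices, one per layer; all must
#'   share dimensions. Names follow `"<VAR>_<MM>"`, e.g. `"LST_03"`.
#' @param origin Length-2 numeric, lon/lat of the lower-left cell center.
#' @param cell_size Cell size in decimal degrees.
#' @param nodata Sentinel value marking missing cells (stored as `NA`
#'   internally; this value is used on write).
#' @return A `raster_stack` object.
#' @export
raster_stack <- function(layers, origin, cell_size, nodata = -9999) {
  stopifnot(is.list(layers), length(layers) >= 1,
            !is.null(names(layers)), length(origin) == 2, cell_size > 0)
  dims <- vapply(layers, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    rlang::abort("all layers must share the same grid shape")
  }
  info <- parse_layer_names(names(layers))
  if (anyDuplicated(paste(info$variable, info$month)) > 0) {
    dup <- info[duplicated(paste(info$variable, info$month)), ]
    rlang::abort(paste0("duplicate layer: ", dup$variable[1], " month ",
                        dup$month[1]))
  }
  layers <- lapply(layers, function(m) {
    m[!is.finite(m)] <- NA_real_
    m
  })
  structure(
    list(layers = layers, origin = as.numeric(origin),
         cell_size = cell_size, nodata = nodata,
         index = info),
    class = "raster_stack"
  )
}

parse_layer_names <- function(nm) {
  parts <- regmatches(nm, regexec("^([A-Za-z]+)_([0-9]{1,2})$", nm))
  bad <- vapply(parts, length, integer(1)) != 3
  if (any(bad)) {
    rlang::abort(paste0("layer name(s) not of the form VAR_MM: ",
                        paste(nm[bad], collapse = ", ")))
  }
  info <- tibble::tibble(
    layer = nm,
    variable = vapply(parts, `[`, character(1), 2),
    month = as.integer(vapply(parts, `[`, character(1), 3))
  )
  if (any(info$month < 1 | info$month > 12)) {
    rlang::abort("layer month must be in 1..12")
  }
  info
}

#' @export
print.raster_stack <- function(x, ...) {
  d <- dim(x$layers[[1]])
  cat(sprintf("<raster_stack> %d layer(s), %d x %d cells, %g deg cells\n",
              length(x$layers), d[1], d[2], x$cell_size))
  cat("  variables:", paste(unique(x$index$variable), collapse = ", "), "\n")
  cat(sprintf("  origin (lower-left cell center): %g, %g\n",
              x$origin[1], x$origin[2]))
  invisible(x)
}

#' @export
dim.raster_stack <- function(x) dim(x$layers[[1]])

#' Cell-center coordinates of a raster stack
#'
#' @param stack A [raster_stack()] (or an object sharing its geometry
#'   fields).
#' @return A list with numeric vectors `lon` (per column) and `lat`
#'   (per row, south to north).
#' @export
cell_centers <- function(stack) {
  d <- dim(stack$layers[[1]])
  list(lon = stack$origin[1] + (seq_len(d[2]) - 1) * stack$cell_size,
       lat = stack$origin[2] + (seq_len(d[1]) - 1) * stack$cell_size)
}

#' Write one raster layer as a plain-text grid
#'
#' The dialect is the ESRI ASCII-grid layout: a six-line header (`ncols`,
#' `nrows`, `xllcenter`, `yllcenter`, `cellsize`, `NODATA_value`) followed
#' by `nrows` whitespace-separated rows, northernmost row first.
#'
#' @param values Numeric matrix (row 1 = southern edge, as stored in a
#'   [raster_stack()]).
#' @param path Output file path.
#' @param origin,cell_size,nodata Grid geometry as in [raster_stack()].
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(values, path, origin, cell_size,
                             nodata = -9999) {
  d <- dim(values)
  values[is.na(values)] <- nodata
  header <- c(
    paste("ncols", d[2]), paste("nrows", d[1]),
    paste("xllcenter", format(origin[1], digits = 15)),
    paste("yllcenter", format(origin[2], digits = 15)),
    paste("cellsize", format(cell_size, digits = 15)),
    paste("NODATA_value", format(nodata, digits = 15))
  )
  # file rows run north -> south
  rows <- apply(values[rev(seq_len(d[1])), , drop = FALSE], 1,
                function(r) paste(format(r, digits = 15, trim = TRUE),
                                  collapse = " "))
  writeLines(c(header, rows), path)
  invisible(path)
}

read_ascii_grid <- function(path) {
  lines <- readLines(path)
  header <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    header[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  for (key in c("ncols", "nrows", "cellsize")) {
    if (is.null(header[[key]])) {
      rlang::abort(paste0(path, ": grid header missing ", key))
    }
  }
  cell <- header$cellsize
  if (!is.null(header$xllcenter)) {
    origin <- c(header$xllcenter, header$yllcenter)
  } else if (!is.null(header$xllcorner)) {
    origin <- c(header$xllcorner + cell / 2, header$yllcorner + cell / 2)
  } else {
    rlang::abort(paste0(path, ": grid header missing xllcenter/xllcorner"))
  }
  nodata <- if (is.null(header$nodata_value)) -9999 else header$nodata_value
  vals <- scan(text = lines[i:length(lines)], quiet = TRUE)
  if (length(vals) != header$ncols * header$nrows) {
    rlang::abort(paste0(path, ": expected ", header$ncols * header$nrows,
                        " values, found ", length(vals)))
  }
  m <- matrix(vals, nrow = header$nrows, ncol = header$ncols, byrow = TRUE)
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE]  # store south-up
  m[m == nodata] <- NA_real_
  list(values = m, origin = origin, cell_size = cell, nodata = nodata)
}

#' Read co-registered monthly grids into a raster stack
#'
#' Reads the plain-text grids named by a manifest and validates that every
#' layer shares the same shape, origin and cell size; any mismatch is a
#' hard error naming the offending layer. Duplicate (variable, month)
#' entries are rejected.
#'
#' @param manifest A tibble with columns `path`, `variable`, `month`
#'   declaring one grid file per layer.
#' @return A [raster_stack()].
#' @export
read_grid <- function(manifest) {
  check_columns(manifest, c("path", "variable", "month"), "manifest")
  key <- paste(manifest$variable, manifest$month)
  if (anyDuplicated(key) > 0) {
    rlang::abort(paste0("duplicate layer in manifest: ",
                        key[duplicated(key)][1]))
  }
  grids <- lapply(manifest$path, read_ascii_grid)
  ref <- grids[[1]]
  for (k in seq_along(grids)) {
    g <- grids[[k]]
    if (!identical(dim(g$values), dim(ref$values)) ||
        max(abs(g$origin - ref$origin)) > 1e-9 ||
        abs(g$cell_size - ref$cell_size) > 1e-9) {
      rlang::abort(paste0(
        "layer not co-registered with the first layer: ",
        manifest$variable[k], " month ", manifest$month[k],
        " (", manifest$path[k], ")"))
    }
  }
  layers <- lapply(grids, `[[`, "values")
  names(layers) <- sprintf("%s_%02d", manifest$variable, manifest$month)
  raster_stack(layers, ref$origin, ref$cell_size, ref$nodata)
}

#' Write every layer of a stack as plain-text grids
#'
#' @param stack A [raster_stack()].
#' @param dir Output directory (created if needed).
#' @return A manifest tibble (`path`, `variable`, `month`) suitable for
#'   [read_grid()].
#' @export
write_grid <- function(stack, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(names(stack$layers), ".asc"))
  for (k in seq_along(stack$layers)) {
    write_ascii_grid(stack$layers[[k]], paths[k], stack$origin,
                     stack$cell_size, stack$nodata)
  }
  tibble::tibble(path = paths, variable = stack$index$variable,
                 month = stack$index$month)
}

# nearest cell index along one axis: centers at origin + (i-1)*cell;
# ties (point exactly between two centers) go to the lower index
nearest_index <- function(coord, origin, cell, n) {
  u <- (coord - origin) / cell
  idx <- ceiling(u - 0.5) + 1
  idx[idx < 1 & u >= -0.5] <- 1          # on the outer half-cell edge
  out <- idx < 1 | idx > n | u > (n - 1) + 0.5
  idx[out] <- NA_integer_
  as.integer(idx)
}

#' Attach monthly environmental values to occurrence records
#'
#' Each record receives the value of the raster cell whose center is
#' nearest its point, computed in planar degrees — appropriate at the
#' ~5-km cell sizes of monthly satellite products. Ties between equidistant
#' centers are broken deterministically toward the lower (row, column)
#' index, i.e. southward and westward. Points outside the grid extent (the
#' outer cell edges) are flagged, never given fabricated values; points on
#' nodata cells yield incomplete vectors.
#'
#' @param records A record tibble with `lon`, `lat` columns.
#' @param stack A [raster_stack()].
#' @return `records` augmented with one numeric column per layer (named as
#'   the layer, e.g. `LST_07`) plus logical columns `env_complete` (no
#'   requested layer resolved to nodata) and `in_extent`.
#' @export
attach_environment <- function(records, stack) {
  check_columns(records, c("lon", "lat"), "records")
  d <- dim(stack$layers[[1]])
  col <- nearest_index(records$lon, stack$origin[1], stack$cell_size, d[2])
  row <- nearest_index(records$lat, stack$origin[2], stack$cell_size, d[1])
  in_extent <- !is.na(col) & !is.na(row)
  flat <- ifelse(in_extent, (col - 1L) * d[1] + row, NA_integer_)

  out <- records
  complete <- in_extent
  for (nm in names(stack$layers)) {
    v <- rep(NA_real_, nrow(records))
    v[in_extent] <- stack$layers[[nm]][flat[in_extent]]
    out[[nm]] <- v
    complete <- complete & !is.na(v)
  }
  out$env_complete <- complete
  out$in_extent <- in_extent
  out
}

#' Environmental matrix of all valid background cells
#'
#' Flattens a stack into one row per cell that is non-missing in every
#' layer, with the layer values as columns — the background sample over
#' which a climate space is fitted or a habitat classification run.
#'
#' @param stack A [raster_stack()].
#' @return A tibble with columns `cell_row`, `cell_col`, `lon`, `lat`, and
#'   one column per layer.
#' @export
background_env <- function(stack) {
  d <- dim(stack$layers[[1]])
  centers <- cell_centers(stack)
  vals <- vapply(stack$layers, as.numeric, numeric(prod(d)))
  ok <- rowSums(is.na(vals)) == 0
  rows <- rep(seq_len(d[1]), times = d[2])
  cols <- rep(seq_len(d[2]), each = d[1])
  out <- tibble::tibble(
    cell_row = rows[ok], cell_col = cols[ok],
    lon = centers$lon[cols[ok]], lat = centers$lat[rows[ok]]
  )
  dplyr::bind_cols(out, tibble::as_tibble(vals[ok, , drop = FALSE]))
}
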