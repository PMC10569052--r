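#' Gridded concentration field
#'
#' A concentration field on a regular metric grid, used both for the
#' a-priori (background) field and for the analysis produced by
#' [optimal_interpolation()]. Values are stored as a `ny x nx` matrix whose
#' first row is the *southernmost* row, so northing increases with the row
#' index; `NA` encodes missing cells.
#'
#' @param values Numeric matrix (`ny` rows, `nx` columns) of concentrations
#'   in ug/m3. Finite values must be non-negative; `NA` is allowed.
#' @param origin Length-2 numeric: easting/northing of the lower-left corner
#'   of the lower-left cell, in metres (projected CRS).
#' @param cell_size Cell edge length in metres (default 100).
#' @param check_nonneg Enforce non-negativity (default `TRUE`). Difference
#'   fields (e.g. analysis minus background) set this to `FALSE`.
#'
#' @return An object of class `aq_grid`.
#' @examples
#' g <- aq_grid(matrix(1:4, 2, 2), origin = c(0, 0), cell_size = 100)
#' grid_values(g)
#' @export
aq_grid <- function(values, origin = c(0, 0), cell_size = 100, check_nonneg = TRUE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.numeric(cell_size) || length(cell_size) != 1L || !is.finite(cell_size) ||
      cell_size <= 0) {
    stop("`cell_size` must be a single positive number", call. = FALSE)
  }
  if (length(origin) != 2L || !all(is.finite(origin))) {
    stop("`origin` must be two finite coordinates (easting, northing)", call. = FALSE)
  }
  if (check_nonneg) {
    finite <- is.finite(values)
    if (any(values[finite] < 0)) {
      stop("grid values must be >= 0 where present", call. = FALSE)
    }
  }
  structure(
    list(
      origin = as.numeric(origin),
      cell_size = as.numeric(cell_size),
      nx = ncol(values),
      ny = nrow(values),
      values = values
    ),
    class = "aq_grid"
  )
}

#' @export
print.aq_grid <- function(x, ...) {
  cat(sprintf(
    "<aq_grid> %d x %d cells of %g m, origin (%g, %g)\n",
    x$nx, x$ny, x$cell_size, x$origin[1], x$origin[2]
  ))
  v <- x$values[is.finite(x$values)]
  if (length(v)) {
    cat(sprintf(
      "  values: mean %.3f, range [%.3f, %.3f] ug/m3, %d missing cells\n",
      mean(v), min(v), max(v), sum(!is.finite(x$values))
    ))
  }
  invisible(x)
}

#' Extract or replace the value matrix of a grid
#' @param g An [aq_grid()].
#' @return `grid_values()` returns the `ny x nx` matrix (row 1 = south).
#' @export
grid_values <- function(g) {
  stopifnot(inherits(g, "aq_grid"))
  g$values
}

#' Cell centres of a grid as a tibble
#'
#' @param g An [aq_grid()].
#' @return A tibble with one row per cell: `col`, `row`, `easting`,
#'   `northing` (cell-centre coordinates, m) and `value` (ug/m3).
#' @export
grid_centers <- function(g) {
  stopifnot(inherits(g, "aq_grid"))
  col <- rep(seq_len(g$nx), each = g$ny)
  row <- rep(seq_len(g$ny), times = g$nx)
  tibble::tibble(
    col = col,
    row = row,
    easting = g$origin[1] + (col - 0.5) * g$cell_size,
    northing = g$origin[2] + (row - 0.5) * g$cell_size,
    value = as.vector(g$values[cbind(row, col)])
  )
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' @method as_tibble aq_grid
#' @export
as_tibble.aq_grid <- function(x, ...) grid_centers(x)

#' Map point coordinates to grid cells
#'
#' Nearest-cell lookup: each point is assigned the cell whose centre is
#' closest (i.e. the cell containing it; points up to one cell outside the
#' domain are clamped to the edge cell).
#'
#' @param g An [aq_grid()].
#' @param easting,northing Point coordinates in metres.
#' @return Integer matrix with columns `col`, `row`.
#' @export
grid_cell_of <- function(g, easting, northing) {
  stopifnot(inherits(g, "aq_grid"), length(easting) == length(northing))
  col <- floor((easting - g$origin[1]) / g$cell_size) + 1
  row <- floor((northing - g$origin[2]) / g$cell_size) + 1
  out_x <- col < 0 | col > g$nx + 1
  out_y <- row < 0 | row > g$ny + 1
  if (any(out_x | out_y, na.rm = TRUE)) {
    stop("point(s) more than one cell outside the grid domain", call. = FALSE)
  }
  cbind(
    col = pmin(pmax(as.integer(col), 1L), g$nx),
    row = pmin(pmax(as.integer(row), 1L), g$ny)
  )
}

#' Read and write gridded fields as ESRI ASCII rasters
#'
#' The on-disk format is the plain-text ESRI ASCII grid: a six-line header
#' (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`)
#' followed by `nrows` rows of values written north to south. Values are
#' written with 17 significant digits so a write/read round trip is lossless
#' to better than 1e-9 relative tolerance.
#'
#' @param path File path.
#' @return `read_grid()` returns an [aq_grid()]; `write_grid()` returns
#'   `path` invisibly.
#' @export
read_grid <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 7) stop("not an ESRI ASCII grid: file too short", call. = FALSE)
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) != 2) {
      stop(sprintf("malformed header line %d: %s", i, lines[i]), call. = FALSE)
    }
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize", "nodata_value")
  miss <- setdiff(need, names(hdr))
  if (length(miss)) {
    stop("grid header missing field(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  body <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  nx <- as.integer(hdr$ncols)
  ny <- as.integer(hdr$nrows)
  if (length(body) != nx * ny) {
    stop(sprintf(
      "grid metadata inconsistent with data: header promises %d x %d = %d values, found %d",
      nx, ny, nx * ny, length(body)
    ), call. = FALSE)
  }
  # file rows run north to south; flip to our south-first convention
  m <- matrix(body, nrow = ny, ncol = nx, byrow = TRUE)
  m <- m[rev(seq_len(ny)), , drop = FALSE]
  m[m == hdr$nodata_value] <- NA_real_
  aq_grid(m, origin = c(hdr$xllcorner, hdr$yllcorner), cell_size = hdr$cellsize)
}

#' @rdname read_grid
#' @param g An [aq_grid()] to write.
#' @export
write_grid <- function(g, path) {
  stopifnot(inherits(g, "aq_grid"))
  nodata <- -9999
  m <- g$values
  if (any(is.finite(m) & m == nodata)) {
    stop("grid contains the NODATA sentinel value ", nodata, call. = FALSE)
  }
  m[!is.finite(m)] <- nodata
  hdr <- c(
    sprintf("ncols %d", g$nx),
    sprintf("nrows %d", g$ny),
    sprintf("xllcorner %.17g", g$origin[1]),
    sprintf("yllcorner %.17g", g$origin[2]),
    sprintf("cellsize %.17g", g$cell_size),
    sprintf("NODATA_value %d", nodata)
  )
  rows <- apply(m[rev(seq_len(g$ny)), , drop = FALSE], 1, function(r) {
    paste(sprintf("%.17g", r), collapse = " ")
  })
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a gridded field
#'
#' @param object An [aq_grid()].
#' @param ... Unused.
#' @return A ggplot raster map of the field.
#' @export
autoplot.aq_grid <- function(object, ...) {
  df <- grid_centers(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$easting, .data$northing, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = expression(PM[2.5] ~ (mu * g ~ m^-3))) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Easting (m)", y = "Northing (m)")
}
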