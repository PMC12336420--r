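#' Lightweight single-band raster
#'
#' A minimal in-memory raster used throughout the package: a numeric matrix
#' plus grid metadata. Rows are stored in map order (row 1 is the northern
#' edge, as in an ESRI ASCII grid); coordinates refer to cell centers and the
#' grid origin is the lower-left corner of the lower-left cell.
#'
#' @param values Numeric matrix of cell values; `NA` marks nodata.
#' @param cellsize Cell edge length in meters (> 0).
#' @param xll,yll Coordinates of the lower-left corner of the grid, meters.
#' @return An object of class `scape_raster`.
#' @examples
#' r <- scape_raster(matrix(1:6, nrow = 2), cellsize = 100)
#' raster_dim(r)
#' @export
scape_raster <- function(values, cellsize, xll = 0, yll = 0) {
  values <- as.matrix(values)
  stopifnot(is.numeric(values) || is.logical(values))
  if (!is.numeric(cellsize) || length(cellsize) != 1 || cellsize <= 0) {
    stop("`cellsize` must be a single positive number", call. = FALSE)
  }
  storage.mode(values) <- "double"
  structure(
    list(values = values, cellsize = as.numeric(cellsize),
         xll = as.numeric(xll), yll = as.numeric(yll)),
    class = "scape_raster"
  )
}

#' @export
print.scape_raster <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<scape_raster> %d x %d cells, cellsize %g m, origin (%g, %g)\n",
              d[1], d[2], x$cellsize, x$xll, x$yll))
  rng <- range(x$values, na.rm = TRUE)
  cat(sprintf("  values in [%g, %g], %d nodata cells\n",
              rng[1], rng[2], sum(is.na(x$values))))
  invisible(x)
}

#' @rdname scape_raster
#' @param x A `scape_raster`.
#' @export
raster_dim <- function(x) dim(x$values)

#' Cell-center coordinates
#'
#' @param x A `scape_raster`.
#' @param row,col Cell indices (row 1 = northern edge).
#' @return Two-column matrix of x/y coordinates in meters.
#' @export
cell_center <- function(x, row, col) {
  nr <- nrow(x$values)
  cbind(x = x$xll + (col - 0.5) * x$cellsize,
        y = x$yll + (nr - row + 0.5) * x$cellsize)
}

#' Coordinates of every cell, as a tibble
#'
#' @param x A `scape_raster`.
#' @return Tibble with `row`, `col`, `x`, `y`, `value`.
#' @export
raster_tbl <- function(x) {
  d <- dim(x$values)
  idx <- expand.grid(row = seq_len(d[1]), col = seq_len(d[2]))
  cc <- cell_center(x, idx$row, idx$col)
  vals <- as.vector(x$values[cbind(idx$row, idx$col)])
  tibble::tibble(row = idx$row, col = idx$col,
                 x = cc[, 1], y = cc[, 2], value = vals)
}

#' Check that two rasters share a grid
#' @param a,b `scape_raster` objects.
#' @return `TRUE` invisibly, or an error.
#' @export
assert_aligned <- function(a, b) {
  ok <- identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$cellsize, b$cellsize)) &&
    isTRUE(all.equal(c(a$xll, a$yll), c(b$xll, b$yll)))
  if (!ok) stop("rasters are not aligned (dimensions, cellsize or origin differ)",
                call. = FALSE)
  invisible(TRUE)
}

#' Read an ESRI ASCII grid
#'
#' Parses the standard 6-line header (`ncols`, `nrows`, `xllcorner`,
#' `yllcorner`, `cellsize`, optional `NODATA_value`) followed by
#' whitespace-separated values, top row first.
#'
#' @param path Path to an `.asc` file.
#' @return A [scape_raster()].
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+[-0-9.eE+]+\\s*$", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop("not an ESRI ASCII grid: missing header field(s) ",
         paste(setdiff(need, names(hdr)), collapse = ", "), call. = FALSE)
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows) {
    stop("ESRI ASCII grid body has ", length(vals), " values, expected ",
         hdr$ncols * hdr$nrows, call. = FALSE)
  }
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA_real_
  scape_raster(m, cellsize = hdr$cellsize, xll = hdr$xllcorner,
               yll = hdr$yllcorner)
}

#' Write an ESRI ASCII grid
#'
#' @param x A [scape_raster()].
#' @param path Output path.
#' @param nodata Value written for `NA` cells.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(x, path, nodata = -9999) {
  stopifnot(inherits(x, "scape_raster"))
  m <- x$values
  m[is.na(m)] <- nodata
  hdr <- c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    sprintf("xllcorner %.10g", x$xll),
    sprintf("yllcorner %.10g", x$yll),
    sprintf("cellsize %.10g", x$cellsize),
    sprintf("NODATA_value %.10g", nodata)
  )
  body <- apply(m, 1, function(r) paste(format(r, trim = TRUE, scientific = FALSE,
                                               digits = 10), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Plot a raster with ggplot2
#'
#' @param x A [scape_raster()].
#' @param name Legend title.
#' @return A ggplot object.
#' @export
plot_raster <- function(x, name = "value") {
  df <- raster_tbl(x)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = name, na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "easting (m)", y = "northing (m)") +
    ggplot2::theme_minimal()
}
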