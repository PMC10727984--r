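#' Georeferenced grid layer
#'
#' A `grid_field` is the package's universal raster carrier: a numeric matrix
#' in north-up, row-major orientation (row 1 = northernmost row) together with
#' its geotransform. Missing cells are `NA`; all operations propagate `NA`.
#'
#' @param values numeric matrix (rows = latitude bands from north to south,
#'   columns = longitude from west to east).
#' @param xmin western edge of the grid, degrees longitude.
#' @param ymax northern edge of the grid, degrees latitude.
#' @param cell_size cell size in degrees (square cells).
#'
#' @return an object of class `grid_field`.
#' @export
grid_field <- function(values, xmin = 0, ymax = 65, cell_size = 0.5) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  stopifnot(is.finite(xmin), is.finite(ymax), cell_size > 0)
  structure(
    list(values = values, xmin = xmin, ymax = ymax, cell_size = cell_size),
    class = "grid_field"
  )
}

#' @export
print.grid_field <- function(x, ...) {
  v <- x$values
  cat(sprintf(
    "<grid_field> %d x %d cells, %.4g deg, origin (%.4g, %.4g)\n",
    nrow(v), ncol(v), x$cell_size, x$xmin, x$ymax
  ))
  fin <- v[is.finite(v)]
  if (length(fin)) {
    cat(sprintf("  values: [%.4g, %.4g], %d NA of %d\n",
                min(fin), max(fin), sum(is.na(v)), length(v)))
  } else {
    cat("  values: all NA\n")
  }
  invisible(x)
}

#' @export
dim.grid_field <- function(x) dim(x$values)

#' Latitude of each grid row (cell centres)
#'
#' @param field a `grid_field` (or anything with `ymax`/`cell_size`/`values`).
#' @return numeric vector of length `nrow(field$values)`.
#' @export
cell_latitudes <- function(field) {
  n <- nrow(field$values)
  field$ymax - field$cell_size * (seq_len(n) - 0.5)
}

# same grid shape and placement; tolerance absorbs float noise in the corners
same_grid <- function(a, b, tol = 1e-9) {
  identical(dim(a$values), dim(b$values)) &&
    abs(a$xmin - b$xmin) < tol &&
    abs(a$ymax - b$ymax) < tol &&
    abs(a$cell_size - b$cell_size) < tol
}

stop_if_misaligned <- function(a, b, what = "grids") {
  if (!same_grid(a, b)) {
    stop(sprintf("%s are not aligned: dims %s vs %s, origin (%g,%g)/%g vs (%g,%g)/%g",
                 what,
                 paste(dim(a$values), collapse = "x"),
                 paste(dim(b$values), collapse = "x"),
                 a$xmin, a$ymax, a$cell_size, b$xmin, b$ymax, b$cell_size),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Write a grid layer as an ESRI ASCII grid
#'
#' Plain-text raster interchange: the `.asc` header records the geotransform
#' (`xllcorner`, `yllcorner`, `cellsize`, `nodata_value`), then one text row
#' per grid row from north to south. Values are written with 17 significant
#' digits so a write/read round trip reproduces doubles exactly.
#'
#' @param field a `grid_field`.
#' @param path output file path.
#' @param nodata value used to encode `NA` cells (default -9999).
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(field, path, nodata = -9999) {
  v <- field$values
  n_rows <- nrow(v)
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", n_rows),
    sprintf("xllcorner %.17g", field$xmin),
    sprintf("yllcorner %.17g", field$ymax - n_rows * field$cell_size),
    sprintf("cellsize %.17g", field$cell_size),
    sprintf("nodata_value %.17g", nodata)
  )
  v[is.na(v)] <- nodata
  body <- apply(v, 1L, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid written by [write_ascii_grid()]
#'
#' @param path file path.
#' @return a `grid_field`; cells equal to the header's nodata value become `NA`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  key <- vapply(hdr, `[`, "", 1L)
  val <- as.numeric(vapply(hdr, `[`, "", 2L))
  names(val) <- tolower(key)
  n_rows <- as.integer(val[["nrows"]])
  n_cols <- as.integer(val[["ncols"]])
  body <- lines[-(1:6)]
  if (length(body) != n_rows) stop("corrupt ascii grid: row count mismatch")
  v <- matrix(
    scan(text = body, what = double(), quiet = TRUE),
    nrow = n_rows, ncol = n_cols, byrow = TRUE
  )
  v[v == val[["nodata_value"]]] <- NA_real_
  grid_field(v,
             xmin = val[["xllcorner"]],
             ymax = val[["yllcorner"]] + n_rows * val[["cellsize"]],
             cell_size = val[["cellsize"]])
}
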