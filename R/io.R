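#' Read a single-band raster from an ESRI ASCII grid file
#'
#' Reads the plain-text ESRI ASCII grid format (`.asc`): a six-line header
#' (`ncols`, `nrows`, `xllcorner`/`xllcenter`, `yllcorner`/`yllcenter`,
#' `cellsize`, optional `NODATA_value`) followed by row-major cell values with
#' row 1 at the northern edge. The format carries a single `cellsize`, so
#' pixels are square by construction. Cells equal to the declared nodata value
#' become invalid (`NA`).
#'
#' @param path path to an `.asc` file.
#' @param date optional ordinal day to attach to the grid.
#' @param range,clamp_tol passed to [ndvi_grid()]; values overshooting `range`
#'   by at most `clamp_tol` are clamped with a warning, larger excursions are
#'   an error.
#' @return an [ndvi_grid()].
#' @export
read_grid <- function(path, date = NA_real_, range = c(0, 1), clamp_tol = 0.01) {
  if (!file.exists(path)) stop("cannot read raster file: ", path)
  con <- file(path, "r"); on.exit(close(con))
  hdr <- character(0); vals_start <- character(0)
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line)) stop("truncated ESRI ASCII grid: ", path)
    if (grepl("^\\s*[A-Za-z]", line)) hdr <- c(hdr, line)
    else { vals_start <- line; break }
  }
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  keys <- tolower(kv[, 1]); vals <- as.numeric(kv[, 2])
  get <- function(k, default = NULL) {
    i <- match(k, keys)
    if (is.na(i)) default else vals[i]
  }
  nc <- get("ncols"); nr <- get("nrows")
  if (is.null(nc) || is.null(nr)) stop("missing ncols/nrows header: ", path)
  cs <- get("cellsize")
  if (is.null(cs)) stop("missing cellsize header: ", path)
  nodata <- get("nodata_value", -9999)
  xll <- get("xllcorner", get("xllcenter", 0) - cs / 2)
  yll <- get("yllcorner", get("yllcenter", 0) - cs / 2)
  body <- scan(con, what = numeric(), quiet = TRUE)
  body <- c(as.numeric(strsplit(trimws(vals_start), "\\s+")[[1]]), body)
  if (length(body) != nr * nc)
    stop(sprintf("expected %d cells, found %d in %s", nr * nc, length(body), path))
  m <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  ndvi_grid(m, pixel_size = cs, origin = c(xll, yll + nr * cs), date = date,
            range = range, clamp_tol = clamp_tol)
}

#' Write a grid to an ESRI ASCII grid file
#'
#' Invalid cells are written as the declared nodata value. Numbers are printed
#' with 17 significant digits so finite doubles round-trip exactly through
#' [read_grid()].
#'
#' @param grid an [ndvi_grid()].
#' @param path output path (conventionally `.asc`).
#' @param nodata nodata sentinel written for invalid cells; must not collide
#'   with a valid value.
#' @return `path`, invisibly.
#' @export
write_grid <- function(grid, path, nodata = -9999) {
  stopifnot(inherits(grid, "ndvi_grid"))
  v <- grid$values
  if (any(v == nodata, na.rm = TRUE))
    stop("a valid cell equals the nodata sentinel; choose another `nodata`")
  d <- dim(v); ps <- grid$pixel_size
  num <- function(x) sprintf("%.17g", x)
  hdr <- c(
    sprintf("ncols %d", d[2]),
    sprintf("nrows %d", d[1]),
    sprintf("xllcorner %s", num(grid$origin[1])),
    sprintf("yllcorner %s", num(grid$origin[2] - d[1] * ps)),
    sprintf("cellsize %s", num(ps)),
    sprintf("NODATA_value %s", num(nodata))
  )
  v[is.na(v)] <- nodata
  rows <- apply(v, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
  ok <- tryCatch({
    writeLines(c(hdr, rows), path); TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("cannot write raster file: ", path)
  invisible(path)
}
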