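# Grid geometry, raster stacks and ESRI ASCII grid I/O.
#
# Layers are stored as matrices indexed [row, col] with row 1 the
# *southernmost* row, so values[r, c] sits at
#   x = origin_x + (c - 0.5) * cell_size
#   y = origin_y + (r - 0.5) * cell_size
# ESRI ASCII files store rows north-to-south; readers/writers flip.

#' Define a raster grid
#'
#' @param n_rows,n_cols Grid dimensions (>= 1).
#' @param origin_x,origin_y Coordinates of the lower-left corner, in map
#'   units (decimal degrees for `crs = "lonlat"`, km for `crs = "planar"`).
#' @param cell_size Cell edge length in map units (> 0).
#' @param crs Either `"lonlat"` (WGS84 decimal degrees; great-circle
#'   distances) or `"planar"` (km units; Euclidean distances).
#' @return A `grid_spec` object.
#' @export
#' @examples
#' grid_spec(10, 20, cell_size = 0.5)
grid_spec <- function(n_rows, n_cols, origin_x = 0, origin_y = 0,
                      cell_size = 1, crs = c("planar", "lonlat")) {
  assert_count(n_rows, "n_rows")
  assert_count(n_cols, "n_cols")
  crs <- match.arg(crs)
  if (!is.numeric(cell_size) || cell_size <= 0)
    stop("`cell_size` must be > 0", call. = FALSE)
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 origin_x = origin_x, origin_y = origin_y,
                 cell_size = cell_size, crs = crs),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells, cell %g, origin (%g, %g), crs %s\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin_x, x$origin_y, x$crs))
  invisible(x)
}

grid_equal <- function(a, b, tol = 1e-9) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$origin_x - b$origin_x) < tol && abs(a$origin_y - b$origin_y) < tol &&
    abs(a$cell_size - b$cell_size) < tol
}

# Cell centers for every cell, in grid (row-major by column, i.e. R matrix
# element order: column-major).  Returns data.frame(x, y).
cell_centers <- function(grid) {
  cx <- grid$origin_x + (seq_len(grid$n_cols) - 0.5) * grid$cell_size
  cy <- grid$origin_y + (seq_len(grid$n_rows) - 0.5) * grid$cell_size
  data.frame(x = rep(cx, each = grid$n_rows), y = rep(cy, times = grid$n_cols))
}

# Row/col of points; the floor((coord - origin)/cell_size) convention assigns
# boundary points to the cell on their upper/right side deterministically.
point_cell <- function(grid, x, y) {
  col <- floor((x - grid$origin_x) / grid$cell_size) + 1L
  row <- floor((y - grid$origin_y) / grid$cell_size) + 1L
  inside <- col >= 1L & col <= grid$n_cols & row >= 1L & row <= grid$n_rows
  data.frame(row = row, col = col, inside = inside)
}

#' Bundle environmental layers into a raster stack
#'
#' @param grid A [grid_spec()].
#' @param layers Named list of numeric matrices (`n_rows x n_cols` each).
#' @param kind Character vector, one of `"continuous"`/`"categorical"` per
#'   layer (recycled if length 1).  Categorical layers must hold integer
#'   class codes.
#' @param mask Optional logical matrix; `TRUE` marks nodata cells, which are
#'   excluded from every downstream sum.
#' @return A `raster_stack` object.
#' @export
raster_stack <- function(grid, layers, kind = "continuous", mask = NULL) {
  stopifnot(inherits(grid, "grid_spec"), is.list(layers), length(layers) >= 1L)
  if (is.null(names(layers)) || anyDuplicated(names(layers)))
    stop("layers must be uniquely named", call. = FALSE)
  kind <- rep_len(kind, length(layers))
  names(kind) <- names(layers)
  for (nm in names(layers)) {
    m <- layers[[nm]]
    if (!is.matrix(m) || nrow(m) != grid$n_rows || ncol(m) != grid$n_cols)
      stop(sprintf("layer '%s' does not match the grid dimensions", nm),
           call. = FALSE)
    if (kind[[nm]] == "categorical" && any(m[is.finite(m)] != floor(m[is.finite(m)])))
      stop(sprintf("categorical layer '%s' must contain integer class codes", nm),
           call. = FALSE)
  }
  if (is.null(mask)) {
    mask <- matrix(FALSE, grid$n_rows, grid$n_cols)
  } else {
    stopifnot(is.logical(mask), nrow(mask) == grid$n_rows,
              ncol(mask) == grid$n_cols)
  }
  structure(list(grid = grid, layers = layers, kind = kind, mask = mask),
            class = "raster_stack")
}

#' @export
print.raster_stack <- function(x, ...) {
  cat(sprintf("<raster_stack> %d layer(s) on a %d x %d grid (%d nodata cells)\n",
              length(x$layers), x$grid$n_rows, x$grid$n_cols, sum(x$mask)))
  for (nm in names(x$layers))
    cat(sprintf("  %s [%s]\n", nm, x$kind[[nm]]))
  invisible(x)
}

# Layer values at all valid (unmasked) cells as a data.frame, plus the linear
# cell indices; used by prediction and overlap code.
stack_env_frame <- function(stack) {
  valid <- which(!stack$mask)
  env <- as.data.frame(lapply(stack$layers, function(m) m[valid]))
  attr(env, "kind") <- stack$kind
  attr(env, "cell_index") <- valid
  env
}

#' Gridded suitability surface
#'
#' @param grid A [grid_spec()].
#' @param values Numeric matrix of nonnegative suitabilities.
#' @param mask Logical nodata matrix (`TRUE` = nodata).
#' @return A `suitability_grid` object.
#' @export
suitability_grid <- function(grid, values, mask = NULL) {
  stopifnot(inherits(grid, "grid_spec"), is.matrix(values),
            nrow(values) == grid$n_rows, ncol(values) == grid$n_cols)
  if (is.null(mask)) mask <- matrix(FALSE, grid$n_rows, grid$n_cols)
  ok <- values[!mask]
  if (any(!is.finite(ok)) || any(ok < 0))
    stop("suitability values must be finite and >= 0 on unmasked cells",
         call. = FALSE)
  structure(list(grid = grid, values = values, mask = mask),
            class = "suitability_grid")
}

#' @export
print.suitability_grid <- function(x, ...) {
  v <- x$values[!x$mask]
  cat(sprintf("<suitability_grid> %d x %d, range [%g, %g]\n",
              x$grid$n_rows, x$grid$n_cols, min(v), max(v)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# ESRI ASCII grid I/O (plain-text raster interchange).

#' Write one layer as an ESRI ASCII grid
#'
#' @param values Numeric matrix (row 1 = southernmost row).
#' @param grid A [grid_spec()].
#' @param path Output file path.
#' @param mask Optional logical nodata matrix.
#' @param nodata Nodata sentinel written for masked cells.
#' @return `path`, invisibly.
#' @export
write_asc <- function(values, grid, path, mask = NULL, nodata = -9999) {
  stopifnot(is.matrix(values))
  hdr <- c(sprintf("ncols %d", grid$n_cols),
           sprintf("nrows %d", grid$n_rows),
           sprintf("xllcorner %.10g", grid$origin_x),
           sprintf("yllcorner %.10g", grid$origin_y),
           sprintf("cellsize %.10g", grid$cell_size),
           sprintf("NODATA_value %.10g", nodata))
  out <- values
  if (!is.null(mask)) out[mask] <- nodata
  out[!is.finite(out)] <- nodata
  # flip: file rows run north to south
  body <- apply(out[grid$n_rows:1, , drop = FALSE], 1,
                function(r) paste(format(r, trim = TRUE, digits = 10),
                                  collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path File path.
#' @param crs Coordinate system tag for the resulting grid.
#' @return A list with `grid` ([grid_spec()]), `values` matrix and logical
#'   `mask` (nodata cells).
#' @export
read_asc <- function(path, crs = "planar") {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  for (req in c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize"))
    if (is.null(hdr[[req]])) stop("malformed ESRI ASCII header: missing ", req,
                                  call. = FALSE)
  nodata <- hdr[["nodata_value"]] %||% -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc)
    stop("malformed ESRI ASCII body: expected ", nr * nc, " values, got ",
         length(vals), call. = FALSE)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)[nr:1, , drop = FALSE]
  mask <- m == nodata
  m[mask] <- NA_real_
  list(grid = grid_spec(nr, nc, hdr$xllcorner, hdr$yllcorner, hdr$cellsize,
                        crs = crs),
       values = m, mask = mask)
}

#' Write every layer of a stack as ESRI ASCII grids
#'
#' Writes `<dir>/<layer>.asc` per layer plus `<dir>/layers.yaml` recording
#' layer order and continuous/categorical kinds.
#'
#' @param stack A [raster_stack()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_rasters <- function(stack, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(stack$layers))
    write_asc(stack$layers[[nm]], stack$grid, file.path(dir, paste0(nm, ".asc")),
              mask = stack$mask)
  meta <- list(crs = stack$grid$crs,
               layers = lapply(names(stack$layers), function(nm)
                 list(name = nm, kind = unname(stack$kind[[nm]]))))
  yaml::write_yaml(meta, file.path(dir, "layers.yaml"))
  invisible(dir)
}

#' Read a raster stack written by [write_rasters()]
#'
#' All layers must share one grid; the nodata masks are unioned.
#'
#' @param dir Directory containing `layers.yaml` and the `.asc` files.
#' @return A [raster_stack()].
#' @export
read_rasters <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "layers.yaml"))
  layers <- list(); kinds <- character(); grid <- NULL; mask <- NULL
  for (ly in meta$layers) {
    r <- read_asc(file.path(dir, paste0(ly$name, ".asc")),
                  crs = meta$crs %||% "planar")
    if (is.null(grid)) {
      grid <- r$grid; mask <- r$mask
    } else if (!grid_equal(grid, r$grid)) {
      stop(sprintf("layer '%s' is not aligned with the reference grid", ly$name),
           call. = FALSE)
    } else {
      mask <- mask | r$mask
    }
    v <- r$values
    v[is.na(v)] <- if (ly$kind == "categorical") 0 else 0
    layers[[ly$name]] <- v
    kinds[ly$name] <- ly$kind
  }
  raster_stack(grid, layers, kind = kinds, mask = mask)
}
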