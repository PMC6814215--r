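#' @importFrom utils read.csv write.csv packageVersion
NULL

ASC_NODATA <- -9999

# --- single layers: ESRI ASCII grid (.asc) -------------------------------
# Plain-text raster interchange format: 6-line header (ncols, nrows,
# xllcorner, yllcorner, cellsize, NODATA_value) then rows top-to-bottom.
# The package is grid-agnostic, so xllcorner/yllcorner/cellsize are carried
# through but never interpreted; the nodata convention defines the mask.

#' Read a raster layer from an ESRI ASCII grid file
#'
#' Cells equal to the file's `NODATA_value` are excluded from the validity
#' mask. When a `reference` grid is supplied the file must match its shape
#' and mask exactly.
#'
#' @param path Path to a `.asc` file.
#' @param variable_name Name recorded on the returned layer.
#' @param units Units string recorded on the returned layer.
#' @param reference Optional [grid_spec()] the file must agree with.
#' @return A [raster_layer()].
#' @export
read_layer <- function(path, variable_name = "", units = "", reference = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, n = 6L)
  hdr <- list()
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1L]]
    hdr[[tolower(parts[1L])]] <- as.numeric(parts[2L])
  }
  need <- c("ncols", "nrows", "nodata_value")
  if (!all(need %in% names(hdr))) {
    stop("not an ASCII grid (missing header fields): ", path)
  }
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  vals <- scan(path, what = double(), skip = 6L, quiet = TRUE)
  if (length(vals) != nr * nc) {
    stop("expected ", nr * nc, " values, found ", length(vals), " in ", path)
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  mask <- m != hdr$nodata_value
  if (!any(mask)) stop("all cells are nodata in ", path)
  m[!mask] <- NA_real_
  grid <- grid_spec(nr, nc, valid_mask = mask)
  if (!is.null(reference)) {
    stop_if_grid_mismatch(reference, grid, c("reference grid and ", path))
    grid <- reference   # keep the reference's area weights
  }
  raster_layer(grid, m, variable_name = variable_name, units = units)
}

#' Write a raster layer as an ESRI ASCII grid file
#'
#' Values are written at full double precision, so a read/write round trip
#' reproduces values and mask exactly.
#'
#' @param layer A [raster_layer()].
#' @param path Destination path.
#' @param nodata Nodata sentinel written for out-of-area cells; must not
#'   collide with a valid value.
#' @return `path`, invisibly.
#' @export
write_layer <- function(layer, path, nodata = ASC_NODATA) {
  stopifnot(inherits(layer, "raster_layer"))
  if (any(valid_values(layer) == nodata)) {
    stop("layer contains the nodata sentinel ", nodata, " as a valid value")
  }
  g <- layer$grid
  hdr <- c(paste("ncols", g$n_cols), paste("nrows", g$n_rows),
           "xllcorner 0", "yllcorner 0", "cellsize 1",
           paste("NODATA_value", nodata))
  v <- layer$values
  v[!g$valid_mask] <- nodata
  body <- apply(v, 1L, function(row) paste(sprintf("%.17g", row), collapse = " "))
  ok <- tryCatch({
    writeLines(c(hdr, body), path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok || !file.exists(path)) stop("cannot write layer to ", path)
  invisible(path)
}

# --- ensemble stacks: one .asc per member plus a JSON manifest ------------

#' Write an ensemble stack (one ASCII grid per member plus a JSON manifest)
#'
#' @param stack An [ensemble_stack()].
#' @param dir Destination directory (created if absent).
#' @param name Base name for the files; defaults to the stack's variable name.
#' @return Path of the written manifest (`<name>.stack.json`), invisibly.
#' @export
write_stack <- function(stack, dir, name = NULL) {
  stopifnot(inherits(stack, "ensemble_stack"))
  if (is.null(name)) name <- stack$variable_name
  if (!nzchar(name)) stop("stack needs a name")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(stack$member_ids))
  for (m in seq_along(stack$member_ids)) {
    paths[m] <- paste0(name, "_", stack$member_ids[m], ".asc")
    write_layer(stack_member(stack, m), file.path(dir, paths[m]))
  }
  manifest <- file.path(dir, paste0(name, ".stack.json"))
  jsonlite::write_json(
    list(variable_name = stack$variable_name, units = stack$units,
         member_ids = as.list(stack$member_ids), paths = as.list(paths)),
    manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Read an ensemble stack from a stack manifest
#'
#' Members are read in manifest order; all must share one grid. A manifest
#' without member entries is rejected (the member dimension is absent).
#'
#' @param manifest Path to a `<name>.stack.json` manifest from [write_stack()].
#' @param reference Optional [grid_spec()] all members must agree with.
#' @return An [ensemble_stack()].
#' @export
read_stack <- function(manifest, reference = NULL) {
  if (!file.exists(manifest)) stop("manifest not found: ", manifest)
  meta <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  if (is.null(meta$member_ids) || is.null(meta$paths) || !length(meta$member_ids)) {
    stop("absent member dimension in ", manifest)
  }
  dir <- dirname(manifest)
  layers <- lapply(seq_along(meta$member_ids), function(m) {
    read_layer(file.path(dir, meta$paths[[m]]),
               variable_name = meta$variable_name %||% "",
               units = meta$units %||% "", reference = reference)
  })
  names(layers) <- meta$member_ids
  for (l in layers[-1L]) {
    stop_if_grid_mismatch(layers[[1L]]$grid, l$grid, "stack members")
  }
  layers_to_stack(layers, variable_name = meta$variable_name %||% "",
                  units = meta$units %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- vegetation type series ----------------------------------------------

#' Write a vegetation type series (one ASCII grid per year plus manifest)
#'
#' @param series A [veg_type_series()].
#' @param dir Destination directory.
#' @param name Base file name.
#' @return Manifest path (`<name>.series.json`), invisibly.
#' @export
write_veg_series <- function(series, dir, name) {
  stopifnot(inherits(series, "veg_type_series"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(series$years))
  for (y in seq_along(series$years)) {
    paths[y] <- paste0(name, "_y", series$years[y], ".asc")
    lay <- raster_layer(series$grid, series$values[y, , ],
                        variable_name = "vegetation_type", units = "code")
    write_layer(lay, file.path(dir, paths[y]))
  }
  manifest <- file.path(dir, paste0(name, ".series.json"))
  jsonlite::write_json(list(years = as.list(series$years), paths = as.list(paths)),
                       manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Read a vegetation type series from its manifest
#'
#' @param manifest Path from [write_veg_series()].
#' @param reference Optional [grid_spec()].
#' @return A [veg_type_series()].
#' @export
read_veg_series <- function(manifest, reference = NULL) {
  if (!file.exists(manifest)) stop("manifest not found: ", manifest)
  meta <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  if (is.null(meta$years) || !length(meta$years)) stop("absent year dimension")
  dir <- dirname(manifest)
  layers <- lapply(meta$paths, function(p) {
    read_layer(file.path(dir, p), reference = reference)
  })
  grid <- layers[[1L]]$grid
  vals <- array(NA_integer_, c(length(meta$years), grid$n_rows, grid$n_cols))
  for (y in seq_along(layers)) {
    stop_if_grid_mismatch(grid, layers[[y]]$grid, "series years")
    vals[y, , ] <- as.integer(round(layers[[y]]$values))
  }
  veg_type_series(grid, unlist(meta$years), vals)
}

# --- departure lookup table ----------------------------------------------

#' Construct a validated vegetation-departure lookup table
#'
#' The table maps every ordered pair of vegetation type codes to an expert
#' departure score in \[0, 3\]. It must be total on its declared type set,
#' score 0 on the diagonal, and is *not* assumed symmetric.
#'
#' @param df data.frame with columns `baseline_type`, `future_type`,
#'   `departure`.
#' @return Object of class `departure_table`: list with `types` (sorted code
#'   vector), `matrix` (baseline x future score matrix), `entries` (the
#'   data.frame).
#' @export
departure_table <- function(df) {
  need <- c("baseline_type", "future_type", "departure")
  if (!all(need %in% names(df))) {
    stop("departure table needs columns: ", paste(need, collapse = ", "))
  }
  if (any(!is.finite(df$departure)) || any(df$departure < 0 | df$departure > 3)) {
    stop("departure value outside [0, 3]")
  }
  types <- sort(unique(c(df$baseline_type, df$future_type)))
  key <- paste(df$baseline_type, df$future_type)
  if (anyDuplicated(key)) stop("duplicate (baseline, future) pair")
  all_pairs <- expand.grid(b = types, f = types)
  have <- paste(all_pairs$b, all_pairs$f) %in% key
  if (!all(have)) {
    miss <- all_pairs[!have, ][1L, ]
    stop("missing pair (", miss$b, ", ", miss$f, ") for declared type set")
  }
  diag_vals <- df$departure[df$baseline_type == df$future_type]
  if (any(diag_vals != 0)) stop("diagonal departure must be 0 for every type")
  mat <- matrix(NA_real_, length(types), length(types),
                dimnames = list(types, types))
  mat[cbind(match(df$baseline_type, types), match(df$future_type, types))] <-
    df$departure
  structure(list(types = types, matrix = mat, entries = df),
            class = "departure_table")
}

#' Load a vegetation-departure lookup table from CSV
#'
#' @param path CSV with columns `baseline_type,future_type,departure`.
#' @return A [departure_table()].
#' @export
load_departure_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  departure_table(read.csv(path))
}
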