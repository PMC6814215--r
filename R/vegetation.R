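#' Vegetation type series
#'
#' Yearly categorical vegetation-type codes on one grid, used to summarize a
#' period into its per-cell modal type.
#'
#' @param grid A [grid_spec()].
#' @param years Ordered vector of year labels.
#' @param values Integer array with dim `c(length(years), n_rows, n_cols)` of
#'   type codes.
#' @return An object of class `veg_type_series`.
#' @export
veg_type_series <- function(grid, years, values) {
  stopifnot(inherits(grid, "grid_spec"))
  if (length(years) < 1L) stop("series must contain at least one year")
  values <- as.array(values)
  want <- as.integer(c(length(years), grid$n_rows, grid$n_cols))
  if (!identical(dim(values), want)) {
    stop("values must have dim (", paste(want, collapse = ", "), ")")
  }
  storage.mode(values) <- "integer"
  for (y in seq_along(years)) {
    yr <- values[y, , ]
    if (anyNA(yr[grid$valid_mask])) {
      stop("year ", years[y], " has missing codes inside the study area")
    }
    yr[!grid$valid_mask] <- NA_integer_
    values[y, , ] <- yr
  }
  structure(list(grid = grid, years = years, values = values),
            class = "veg_type_series")
}

#' Modal vegetation type over a period
#'
#' Per cell, the most frequent type code across the years of the series.
#' Ties are broken deterministically to the lowest code, which makes the
#' result invariant to year order.
#'
#' @param series A [veg_type_series()].
#' @return A categorical [raster_layer()] (codes stored as numeric).
#' @export
modal_vegtype <- function(series) {
  stopifnot(inherits(series, "veg_type_series"))
  grid <- series$grid
  n_years <- length(series$years)
  # year x cell matrix over valid cells
  flat <- matrix(NA_integer_, n_years, sum(grid$valid_mask))
  for (y in seq_len(n_years)) flat[y, ] <- series$values[y, , ][grid$valid_mask]
  codes <- sort(unique(as.vector(flat)))
  counts <- vapply(codes, function(cd) colSums(flat == cd), numeric(ncol(flat)))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1L)  # single cell
  # max.col("first") on the code-sorted count matrix = lowest code wins ties
  mode_idx <- max.col(counts, ties.method = "first")
  out <- matrix(NA_real_, grid$n_rows, grid$n_cols)
  out[grid$valid_mask] <- codes[mode_idx]
  raster_layer(grid, out, variable_name = "modal_vegetation_type", units = "code")
}

#' Vegetation departure between baseline and future modal types
#'
#' Looks up, per cell, the expert departure score for the (baseline type,
#' future type) pair. Scores lie in \[0, 3\]; identical types score 0.
#'
#' @param baseline_mode,future_mode Categorical [raster_layer()]s of type
#'   codes on one grid (e.g. from [modal_vegtype()]).
#' @param table A `departure_table` (see [load_departure_table()]).
#' @return A [raster_layer()] of departure values in \[0, 3\].
#' @export
departure_layer <- function(baseline_mode, future_mode, table) {
  stopifnot(inherits(table, "departure_table"))
  stop_if_grid_mismatch(baseline_mode$grid, future_mode$grid, "departure inputs")
  grid <- baseline_mode$grid
  b <- baseline_mode$values[grid$valid_mask]
  f <- future_mode$values[grid$valid_mask]
  bad <- setdiff(unique(c(b, f)), table$types)
  if (length(bad)) {
    stop("vegetation code(s) absent from departure table: ",
         paste(bad, collapse = ", "))
  }
  dep <- table$matrix[cbind(match(b, table$types), match(f, table$types))]
  out <- matrix(NA_real_, grid$n_rows, grid$n_cols)
  out[grid$valid_mask] <- dep
  raster_layer(grid, out, variable_name = "vegetation_departure",
               units = "departure value")
}

#' Normalize departure values into the vegetation stress fuzzy layer
#'
#' Fixed linear conversion with fully-false threshold 0 and fully-true
#' threshold 3 — the full range of the expert departure score.
#'
#' @param departure A [raster_layer()] of departure values in \[0, 3\].
#' @return A [fuzzy_layer()].
#' @export
vegetation_stress <- function(departure) {
  convert_linear(departure, conversion_spec(0, 3),
                 statement = "mc2_vegetation_stress")
}
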