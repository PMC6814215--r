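#' Linear conversion specification
#'
#' The pair of raw-variable thresholds that maps raw values onto fuzzy truth:
#' `minthresh` is the fully-false threshold, `maxthresh` the fully-true
#' threshold. The usual orientation is increasing (`minthresh < maxthresh`);
#' a decreasing ramp (`minthresh > maxthresh`) is also accepted so that "is
#' Low"-style statements can be expressed without a separate operator.
#'
#' @param minthresh Raw value mapped to fuzzy 0 (fully false).
#' @param maxthresh Raw value mapped to fuzzy 1 (fully true).
#' @return An object of class `conversion_spec`.
#' @export
conversion_spec <- function(minthresh, maxthresh) {
  minthresh <- as.numeric(minthresh)
  maxthresh <- as.numeric(maxthresh)
  stopifnot(length(minthresh) == 1L, length(maxthresh) == 1L)
  if (!is.finite(minthresh) || !is.finite(maxthresh)) {
    stop("thresholds must be finite")
  }
  if (minthresh == maxthresh) {
    stop("degenerate conversion: minthresh equals maxthresh")
  }
  structure(list(minthresh = minthresh, maxthresh = maxthresh),
            class = "conversion_spec")
}

#' @export
print.conversion_spec <- function(x, ...) {
  cat(sprintf("<conversion_spec> false at %g, true at %g\n",
              x$minthresh, x$maxthresh))
  invisible(x)
}

#' Convert a raw layer to fuzzy truth by linear interpolation
#'
#' Implements the piecewise-linear membership rule: values at or below the
#' fully-false threshold map to 0, values at or above the fully-true threshold
#' map to 1, and values between interpolate linearly, i.e.
#' `(inputval - minthresh) / (maxthresh - minthresh)` clamped to \[0, 1\].
#' Both boundary values are assigned by the interpolation branch, so
#' `convert(minthresh) == 0` and `convert(maxthresh) == 1` exactly. With a
#' decreasing spec the ramp is reversed.
#'
#' @param layer A [raster_layer()] of raw values.
#' @param spec A [conversion_spec()].
#' @param statement Optional fuzzy statement recorded as the output's
#'   variable name; defaults to the input variable name.
#' @return A [fuzzy_layer()].
#' @export
convert_linear <- function(layer, spec, statement = NULL) {
  stopifnot(inherits(layer, "raster_layer"), inherits(spec, "conversion_spec"))
  f <- (layer$values - spec$minthresh) / (spec$maxthresh - spec$minthresh)
  f <- pmin(pmax(f, 0), 1)
  fuzzy_layer(layer$grid, f,
              variable_name = if (is.null(statement)) layer$variable_name else statement)
}

# Shared machinery for And/Or: per-cell extremum plus source attribution.
# `which_fun` is which.min or which.max applied to each cell's member column.
fuzzy_extremum <- function(inputs, op = c("and", "or")) {
  op <- match.arg(op)
  if (length(inputs) < 2L) stop("fuzzy ", op, " needs at least 2 inputs")
  grid <- inputs[[1L]]$grid
  k <- length(inputs)
  mat <- matrix(NA_real_, sum(grid$valid_mask), k)
  for (i in seq_len(k)) {
    stopifnot(inherits(inputs[[i]], "fuzzy_layer"))
    stop_if_grid_mismatch(grid, inputs[[i]]$grid, "fuzzy operator inputs")
    mat[, i] <- inputs[[i]]$values[grid$valid_mask]
  }
  ext <- mat[, 1L]
  for (i in seq_len(k)[-1L]) {
    ext <- if (op == "and") pmin(ext, mat[, i]) else pmax(ext, mat[, i])
  }
  hits <- mat == ext                       # which inputs attain the extremum
  idx <- max.col(hits, ties.method = "first")
  tie <- rowSums(hits) > 1L

  out_v <- idx_m <- matrix(NA_real_, grid$n_rows, grid$n_cols)
  tie_m <- matrix(NA, grid$n_rows, grid$n_cols)
  out_v[grid$valid_mask] <- ext
  idx_m[grid$valid_mask] <- idx
  tie_m[grid$valid_mask] <- tie
  storage.mode(idx_m) <- "integer"
  list(
    layer = fuzzy_layer(grid, out_v),
    attribution = attribution_layer(grid, idx_m, tie_m,
                                    input_names = vapply(inputs, function(l) l$variable_name, ""))
  )
}

#' Attribution layer
#'
#' Records, for every valid cell of an And/Or result, the index of the input
#' layer that supplied the result value. When several inputs attain the
#' extremum the lowest input index is recorded and the cell is flagged in
#' `tie` — a deterministic, auditable tie rule.
#'
#' @param grid A [grid_spec()].
#' @param index Integer matrix of 1-based input indices (`NA` off-mask).
#' @param tie Logical matrix flagging multi-source cells.
#' @param input_names Optional character vector naming the inputs.
#' @return An object of class `attribution_layer`.
#' @export
attribution_layer <- function(grid, index, tie, input_names = NULL) {
  stopifnot(inherits(grid, "grid_spec"))
  index <- as.matrix(index); tie <- as.matrix(tie)
  stopifnot(identical(dim(index), c(grid$n_rows, grid$n_cols)),
            identical(dim(tie), c(grid$n_rows, grid$n_cols)))
  idx <- index[grid$valid_mask]
  if (anyNA(idx)) stop("attribution must be defined on every valid cell")
  if (!is.null(input_names) && any(idx < 1L | idx > length(input_names))) {
    stop("attribution index outside input list")
  }
  structure(list(grid = grid, index = index, tie = tie,
                 input_names = input_names),
            class = "attribution_layer")
}

#' Fuzzy And: per-cell minimum with source attribution
#'
#' @param inputs List of two or more [fuzzy_layer()]s on one grid.
#' @return A list with elements `layer` (the [fuzzy_layer()] of per-cell
#'   minima) and `attribution` (an [attribution_layer()] naming, per cell,
#'   the minimizing input).
#' @export
fuzzy_and <- function(inputs) fuzzy_extremum(inputs, "and")

#' Fuzzy Or: per-cell maximum with source attribution
#'
#' @inheritParams fuzzy_and
#' @return As [fuzzy_and()], with per-cell maxima.
#' @export
fuzzy_or <- function(inputs) fuzzy_extremum(inputs, "or")

#' Fuzzy Union: per-cell mean
#'
#' The mean has no single source cell, so no attribution is produced.
#'
#' @inheritParams fuzzy_and
#' @return A [fuzzy_layer()] of per-cell means.
#' @export
fuzzy_union <- function(inputs) {
  if (length(inputs) < 2L) stop("fuzzy union needs at least 2 inputs")
  grid <- inputs[[1L]]$grid
  acc <- 0
  for (l in inputs) {
    stopifnot(inherits(l, "fuzzy_layer"))
    stop_if_grid_mismatch(grid, l$grid, "fuzzy operator inputs")
    acc <- acc + l$values
  }
  fuzzy_layer(grid, acc / length(inputs))
}
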