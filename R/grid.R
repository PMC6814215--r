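#' Grid specification
#'
#' A `grid_spec` describes the shared reporting-unit grid every layer in a
#' model run lives on: dimensions, a validity mask delimiting the study area,
#' and per-cell area weights used by all regional statistics. Every cross-layer
#' operation in the package requires its operands to share one `grid_spec`
#' (equal shape, mask, and weights); geospatial metadata (projection, cell
#' size) is deliberately out of scope — inputs must be co-registered upstream.
#'
#' @param n_rows,n_cols Grid dimensions (positive integers).
#' @param valid_mask Logical matrix (`n_rows` x `n_cols`); `TRUE` marks cells
#'   inside the study area. Default: all cells valid.
#' @param cell_area_weights Numeric matrix of nonnegative, finite per-cell
#'   weights (e.g. km2 or cosine-latitude). Default: uniform weight 1.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(n_rows, n_cols, valid_mask = NULL, cell_area_weights = NULL) {
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  stopifnot(length(n_rows) == 1L, length(n_cols) == 1L, n_rows >= 1L, n_cols >= 1L)
  if (is.null(valid_mask)) {
    valid_mask <- matrix(TRUE, n_rows, n_cols)
  }
  valid_mask <- as.matrix(valid_mask)
  if (!is.logical(valid_mask) || !identical(dim(valid_mask), c(n_rows, n_cols))) {
    stop("valid_mask must be a logical ", n_rows, " x ", n_cols, " matrix")
  }
  if (anyNA(valid_mask)) stop("valid_mask must not contain NA")
  if (!any(valid_mask)) stop("grid must contain at least one valid cell")
  if (is.null(cell_area_weights)) {
    cell_area_weights <- matrix(1, n_rows, n_cols)
  }
  cell_area_weights <- as.matrix(cell_area_weights)
  if (!identical(dim(cell_area_weights), c(n_rows, n_cols))) {
    stop("cell_area_weights must be a ", n_rows, " x ", n_cols, " matrix")
  }
  w <- cell_area_weights[valid_mask]
  if (any(!is.finite(w)) || any(w < 0)) {
    stop("cell_area_weights must be finite and >= 0 on all valid cells")
  }
  structure(
    list(n_rows = n_rows, n_cols = n_cols,
         valid_mask = valid_mask, cell_area_weights = cell_area_weights),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d, %d valid cells\n",
              x$n_rows, x$n_cols, sum(x$valid_mask)))
  invisible(x)
}

#' Test whether two grids are identical reporting-unit grids
#'
#' @param a,b `grid_spec` objects.
#' @return `TRUE` if shape, mask, and weights all agree.
#' @export
same_grid <- function(a, b) {
  inherits(a, "grid_spec") && inherits(b, "grid_spec") &&
    identical(dim(a$valid_mask), dim(b$valid_mask)) &&
    identical(a$valid_mask, b$valid_mask) &&
    isTRUE(all.equal(a$cell_area_weights, b$cell_area_weights))
}

stop_if_grid_mismatch <- function(a, b, what = "layers") {
  if (!same_grid(a, b)) stop("grid mismatch between ", what)
  invisible(TRUE)
}

#' Raster layer
#'
#' One co-registered 2-D grid of values plus the grid's validity mask: the
#' universal currency of the model. Values are defined (non-`NA`) exactly on
#' the valid cells of the grid; the constructor masks out-of-area cells and
#' rejects missing values inside the study area.
#'
#' @param grid A [grid_spec()].
#' @param values Numeric matrix matching the grid dimensions.
#' @param variable_name,units Optional metadata strings.
#' @return An object of class `raster_layer`.
#' @export
raster_layer <- function(grid, values, variable_name = "", units = "") {
  stopifnot(inherits(grid, "grid_spec"))
  values <- as.matrix(values)
  if (!identical(dim(values), c(grid$n_rows, grid$n_cols))) {
    stop("values must be a ", grid$n_rows, " x ", grid$n_cols, " matrix")
  }
  storage.mode(values) <- "double"
  values[!grid$valid_mask] <- NA_real_
  if (anyNA(values[grid$valid_mask])) {
    stop("values must be defined on every valid cell")
  }
  structure(
    list(grid = grid, values = values,
         variable_name = as.character(variable_name), units = as.character(units)),
    class = "raster_layer"
  )
}

#' @export
print.raster_layer <- function(x, ...) {
  v <- x$values[x$grid$valid_mask]
  cat(sprintf("<raster_layer> '%s' [%s] %d x %d, range [%.4g, %.4g]\n",
              x$variable_name, x$units, x$grid$n_rows, x$grid$n_cols,
              min(v), max(v)))
  invisible(x)
}

#' Fuzzy layer
#'
#' A [raster_layer()] whose values are fuzzy truths: 0 is fully false, 1 fully
#' true. The constructor enforces the \[0, 1\] range on valid cells (with a
#' tiny numerical tolerance, after which values are clamped).
#'
#' @inheritParams raster_layer
#' @return An object of class `fuzzy_layer` (inherits `raster_layer`).
#' @export
fuzzy_layer <- function(grid, values, variable_name = "", units = "fuzzy truth") {
  layer <- raster_layer(grid, values, variable_name, units)
  v <- layer$values[grid$valid_mask]
  tol <- 1e-9
  if (any(v < -tol) || any(v > 1 + tol)) {
    stop("fuzzy values must lie in [0, 1]")
  }
  layer$values[grid$valid_mask] <- pmin(pmax(v, 0), 1)
  class(layer) <- c("fuzzy_layer", "raster_layer")
  layer
}

as_fuzzy <- function(layer) {
  fuzzy_layer(layer$grid, layer$values, layer$variable_name, layer$units)
}

#' Ensemble stack
#'
#' A member x row x col array holding one variable (or one model node) across
#' the members of a climate-future ensemble. All members share one grid;
#' member identifiers are unique and ordered.
#'
#' @param grid A [grid_spec()].
#' @param member_ids Character vector of unique climate-future labels.
#' @param values Numeric array with dim `c(length(member_ids), n_rows, n_cols)`.
#' @param variable_name,units Optional metadata strings.
#' @return An object of class `ensemble_stack`.
#' @export
ensemble_stack <- function(grid, member_ids, values, variable_name = "", units = "") {
  stopifnot(inherits(grid, "grid_spec"))
  member_ids <- as.character(member_ids)
  if (length(member_ids) < 1L) stop("ensemble must have at least one member")
  if (anyDuplicated(member_ids)) stop("member_ids must be unique")
  values <- as.array(values)
  want <- c(length(member_ids), grid$n_rows, grid$n_cols)
  if (!identical(dim(values), as.integer(want))) {
    stop("values must have dim (", paste(want, collapse = ", "), ")")
  }
  storage.mode(values) <- "double"
  for (m in seq_along(member_ids)) {
    values[m, , ][!grid$valid_mask] <- NA_real_
    if (anyNA(values[m, , ][grid$valid_mask])) {
      stop("member ", member_ids[m], " has missing values inside the study area")
    }
  }
  structure(
    list(grid = grid, member_ids = member_ids, values = values,
         variable_name = as.character(variable_name), units = as.character(units)),
    class = "ensemble_stack"
  )
}

#' @export
print.ensemble_stack <- function(x, ...) {
  cat(sprintf("<ensemble_stack> '%s' %d members, %d x %d grid\n",
              x$variable_name, length(x$member_ids),
              x$grid$n_rows, x$grid$n_cols))
  invisible(x)
}

#' Extract one ensemble member as a raster layer
#'
#' @param stack An [ensemble_stack()].
#' @param member Member id (character) or index.
#' @return A [raster_layer()].
#' @export
stack_member <- function(stack, member) {
  stopifnot(inherits(stack, "ensemble_stack"))
  if (is.character(member)) {
    idx <- match(member, stack$member_ids)
    if (is.na(idx)) stop("unknown member id: ", member)
  } else {
    idx <- as.integer(member)
  }
  raster_layer(stack$grid, stack$values[idx, , ],
               stack$variable_name, stack$units)
}

#' Assemble raster layers into an ensemble stack
#'
#' @param layers Named list of [raster_layer()] objects (names = member ids),
#'   all on one grid.
#' @param variable_name,units Optional metadata strings.
#' @return An [ensemble_stack()].
#' @export
layers_to_stack <- function(layers, variable_name = "", units = "") {
  stopifnot(length(layers) >= 1L, !is.null(names(layers)))
  grid <- layers[[1L]]$grid
  vals <- array(NA_real_, c(length(layers), grid$n_rows, grid$n_cols))
  for (m in seq_along(layers)) {
    stop_if_grid_mismatch(grid, layers[[m]]$grid, "stack members")
    vals[m, , ] <- layers[[m]]$values
  }
  ensemble_stack(grid, names(layers), vals, variable_name, units)
}

# Valid-cell values of a layer as a plain vector (column-major cell order).
valid_values <- function(layer) layer$values[layer$grid$valid_mask]
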