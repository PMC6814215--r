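#' Reduce an ensemble stack across members
#'
#' Per-cell minimum, mean, or maximum across the members of a stack — the
#' three bracketing layers reported for every scenario.
#'
#' @param stack An [ensemble_stack()].
#' @param stat One of `"min"`, `"mean"`, `"max"`.
#' @return A [raster_layer()]; a [fuzzy_layer()] when all members are fuzzy
#'   (values within \[0, 1\]).
#' @export
reduce_stack <- function(stack, stat = c("min", "mean", "max")) {
  stat <- match.arg(stat)
  stopifnot(inherits(stack, "ensemble_stack"))
  vals <- switch(stat,
    mean = colMeans(stack$values, dims = 1),
    min = apply(stack$values, c(2, 3), min),
    max = apply(stack$values, c(2, 3), max))
  out <- raster_layer(stack$grid, vals,
                      variable_name = paste0(stack$variable_name, "_", stat),
                      units = stack$units)
  v <- valid_values(out)
  if (all(v >= 0 & v <= 1)) out <- as_fuzzy(out)
  out
}

# Per-cell population (divide-by-N) standard deviation across members.
stack_population_sd <- function(stack) {
  n <- length(stack$member_ids)
  mu <- colMeans(stack$values, dims = 1)
  ss <- colMeans(stack$values^2, dims = 1)
  sqrt(pmax(ss - mu^2, 0))
}

#' High Variability: ensemble dispersion as fuzzy truth
#'
#' Per cell, the standard deviation of the node value across ensemble
#' members, converted to fuzzy space with false threshold 0 (the minimum
#' possible standard deviation) and true threshold 0.5 (the maximum possible
#' standard deviation of values confined to \[0, 1\]). The default is the
#' population (divide-by-N) standard deviation, which is the only variant
#' that attains 0.5 exactly when half the members are at 0 and half at 1;
#' `sd = "sample"` is available for sensitivity checks.
#'
#' @param stack An [ensemble_stack()] of fuzzy values with >= 2 members.
#' @param sd `"population"` (default) or `"sample"`.
#' @return A [fuzzy_layer()].
#' @export
high_variability <- function(stack, sd = c("population", "sample")) {
  sd <- match.arg(sd)
  stopifnot(inherits(stack, "ensemble_stack"))
  n <- length(stack$member_ids)
  if (n < 2L) stop("high_variability needs at least 2 members")
  s <- stack_population_sd(stack)
  if (sd == "sample") s <- s * sqrt(n / (n - 1))
  grid <- stack$grid
  lay <- raster_layer(grid, s, variable_name = "ensemble_sd", units = "fuzzy truth")
  convert_linear(lay, conversion_spec(0, 0.5), statement = "high_variability")
}

#' Area-weighted mean of a layer
#'
#' `sum(w_i v_i) / sum(w_i)` over valid cells, with weights from the grid's
#' `cell_area_weights` (uniform by default, i.e. the plain mean).
#'
#' @param layer A [raster_layer()].
#' @return Scalar.
#' @export
area_weighted_mean <- function(layer) {
  stopifnot(inherits(layer, "raster_layer"))
  m <- layer$grid$valid_mask
  w <- layer$grid$cell_area_weights[m]
  if (sum(w) <= 0) stop("zero total weight over valid cells")
  sum(w * layer$values[m]) / sum(w)
}

#' Regional summary of one scenario's root-node ensemble
#'
#' Area-weighted means of the ensemble mean, minimum, maximum, and
#' [high_variability()] layers, plus each member's own area-weighted mean
#' (the per-member points of the box-and-whisker comparison).
#'
#' @param root_stack [ensemble_stack()] of the root node across members.
#' @param sd Passed to [high_variability()].
#' @return Object of class `scenario_summary`: list with scalars `mean`,
#'   `min`, `max`, `uncertainty` and named vector `member_means`.
#' @export
scenario_summary <- function(root_stack, sd = "population") {
  stopifnot(inherits(root_stack, "ensemble_stack"))
  n <- length(root_stack$member_ids)
  member_means <- vapply(seq_len(n), function(m) {
    area_weighted_mean(stack_member(root_stack, m))
  }, 0)
  names(member_means) <- root_stack$member_ids
  unc <- if (n >= 2L) area_weighted_mean(high_variability(root_stack, sd)) else 0
  structure(
    list(mean = area_weighted_mean(reduce_stack(root_stack, "mean")),
         min = area_weighted_mean(reduce_stack(root_stack, "min")),
         max = area_weighted_mean(reduce_stack(root_stack, "max")),
         uncertainty = unc,
         member_means = member_means),
    class = "scenario_summary"
  )
}

#' @export
print.scenario_summary <- function(x, ...) {
  cat(sprintf("<scenario_summary> mean %.3f (range %.3f-%.3f), uncertainty %.3f, %d members\n",
              x$mean, x$min, x$max, x$uncertainty, length(x$member_means)))
  invisible(x)
}

#' Between-scenario uncertainty for a matched ensemble pair
#'
#' Both scenarios are driven by the same climate futures, so members are
#' matched one-to-one by id. Per matched pair and cell the population
#' standard deviation of the two values (`|a - b| / 2`) is converted to
#' fuzzy space with thresholds (0, 0.5) — i.e. `|a - b|`, clipped to 1 —
#' then averaged over pairs and finally area-weighted over cells.
#' `method = "pooled"` instead pools the two ensembles into one 2N-member
#' stack and reports the area-weighted mean of its [high_variability()].
#'
#' @param stack_a,stack_b Root-node [ensemble_stack()]s with identical
#'   member ids (order-insensitive; matched by id).
#' @param method `"paired"` (default) or `"pooled"`.
#' @return Scalar in \[0, 1\].
#' @export
scenario_pair_uncertainty <- function(stack_a, stack_b,
                                      method = c("paired", "pooled")) {
  method <- match.arg(method)
  stopifnot(inherits(stack_a, "ensemble_stack"), inherits(stack_b, "ensemble_stack"))
  stop_if_grid_mismatch(stack_a$grid, stack_b$grid, "scenario stacks")
  if (!setequal(stack_a$member_ids, stack_b$member_ids)) {
    stop("unmatched member ids between scenarios")
  }
  ord <- match(stack_a$member_ids, stack_b$member_ids)
  grid <- stack_a$grid
  if (method == "paired") {
    diff_mean <- 0
    for (m in seq_along(stack_a$member_ids)) {
      d <- abs(stack_a$values[m, , ] - stack_b$values[ord[m], , ])
      diff_mean <- diff_mean + pmin(d, 1)
    }
    diff_mean <- diff_mean / length(stack_a$member_ids)
    area_weighted_mean(raster_layer(grid, diff_mean, "pair_uncertainty"))
  } else {
    n <- length(stack_a$member_ids)
    vals <- array(NA_real_, c(2L * n, grid$n_rows, grid$n_cols))
    vals[seq_len(n), , ] <- stack_a$values
    vals[n + seq_len(n), , ] <- stack_b$values
    pooled <- ensemble_stack(
      grid,
      c(paste0(stack_a$member_ids, "_a"), paste0(stack_b$member_ids, "_b")),
      vals, variable_name = stack_a$variable_name)
    area_weighted_mean(high_variability(pooled))
  }
}
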