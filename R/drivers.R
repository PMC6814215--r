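#' Fire-minus-mortality driver difference map
#'
#' Per-cell fire-loss risk minus mortality risk, in \[-1, 1\]; positive cells
#' are fire-driven, negative cells mortality-driven. Following the reporting
#' convention for ensembles, take the ensemble mean of each input *before*
#' differencing (see [reduce_stack()]).
#'
#' @param fire,mortality [fuzzy_layer()]s on one grid.
#' @return A [raster_layer()] in \[-1, 1\].
#' @export
driver_difference <- function(fire, mortality) {
  stop_if_grid_mismatch(fire$grid, mortality$grid, "driver layers")
  raster_layer(fire$grid, fire$values - mortality$values,
               variable_name = "fire_minus_mortality", units = "fuzzy truth")
}

#' Dominance summary: zero-risk, fire-driven, and mortality-driven fractions
#'
#' Splits the valid area into three exhaustive fractions: cells whose
#' combined risk is exactly 0; among the remaining cells, fire-dominated
#' (fire > mortality) and mortality-dominated (mortality > fire), with exact
#' ties split half-and-half so the three fractions always sum to 1. Fractions
#' are plain cell-count fractions by default; `weighted = TRUE` uses the
#' grid's area weights.
#'
#' @param fire,mortality [fuzzy_layer()]s of the two driver nodes.
#' @param risk [fuzzy_layer()] of the combined risk node used for the
#'   zero-risk test.
#' @param weighted Use `cell_area_weights` instead of plain counts.
#' @return Object of class `dominance_summary`: list with `zero_fraction`,
#'   `fire_fraction`, `mortality_fraction`.
#' @export
dominance_summary <- function(fire, mortality, risk, weighted = FALSE) {
  stop_if_grid_mismatch(fire$grid, mortality$grid, "driver layers")
  stop_if_grid_mismatch(fire$grid, risk$grid, "driver layers")
  grid <- fire$grid
  m <- grid$valid_mask
  w <- if (weighted) grid$cell_area_weights[m] else rep(1, sum(m))
  tot <- sum(w)
  r <- risk$values[m]; f <- fire$values[m]; mo <- mortality$values[m]
  zero <- r == 0
  fire_dom <- !zero & f > mo
  mort_dom <- !zero & mo > f
  tied <- !zero & f == mo
  structure(
    list(zero_fraction = sum(w[zero]) / tot,
         fire_fraction = (sum(w[fire_dom]) + 0.5 * sum(w[tied])) / tot,
         mortality_fraction = (sum(w[mort_dom]) + 0.5 * sum(w[tied])) / tot),
    class = "dominance_summary"
  )
}

#' @export
print.dominance_summary <- function(x, ...) {
  cat(sprintf("<dominance_summary> zero %.3f, fire %.3f, mortality %.3f\n",
              x$zero_fraction, x$fire_fraction, x$mortality_fraction))
  invisible(x)
}

#' Count fire- vs mortality-dominated ensemble members
#'
#' A member is fire-dominated when its fire-driven area fraction exceeds its
#' mortality-driven fraction, and conversely. The (measure-zero on
#' continuous data) member-level tie counts to the fire side with a warning.
#'
#' @param summaries List of [dominance_summary()] objects, one per member.
#' @return Named integer vector `c(fire_dominated =, mortality_dominated =)`.
#' @export
ensemble_dominance_counts <- function(summaries) {
  stopifnot(length(summaries) >= 1L)
  ff <- vapply(summaries, function(s) s$fire_fraction, 0)
  mf <- vapply(summaries, function(s) s$mortality_fraction, 0)
  if (any(ff == mf)) {
    warning(sum(ff == mf), " member(s) tied; counted as fire-dominated")
  }
  c(fire_dominated = sum(ff >= mf), mortality_dominated = sum(ff < mf))
}

#' Per-member fractions of area at the ensemble extremes
#'
#' For each member, the (optionally area-weighted) fraction of valid cells
#' where that member's value equals the cross-member maximum, and likewise
#' the minimum. Ties at an extremum credit every attaining member, so at
#' every cell at least one member is credited for each extremum.
#'
#' @param stack An [ensemble_stack()] with >= 2 members.
#' @param weighted Use `cell_area_weights` instead of plain counts.
#' @return data.frame with columns `member_id`, `frac_at_max`, `frac_at_min`.
#' @export
member_extremes <- function(stack, weighted = FALSE) {
  stopifnot(inherits(stack, "ensemble_stack"))
  n <- length(stack$member_ids)
  if (n < 2L) stop("member_extremes needs at least 2 members")
  grid <- stack$grid
  m <- grid$valid_mask
  w <- if (weighted) grid$cell_area_weights[m] else rep(1, sum(m))
  tot <- sum(w)
  mx <- apply(stack$values, c(2, 3), max)[m]
  mn <- apply(stack$values, c(2, 3), min)[m]
  frac_max <- frac_min <- numeric(n)
  for (i in seq_len(n)) {
    v <- stack$values[i, , ][m]
    frac_max[i] <- sum(w[v == mx]) / tot
    frac_min[i] <- sum(w[v == mn]) / tot
  }
  data.frame(member_id = stack$member_ids,
             frac_at_max = frac_max, frac_at_min = frac_min,
             stringsAsFactors = FALSE)
}

#' Per-member area-weighted climate deltas
#'
#' For each ensemble member, the area-weighted mean change (future minus
#' baseline) in temperature and in precipitation — the climate-summary axes
#' against which extreme-member behaviour is compared.
#'
#' @param tmax_future,precip_future [ensemble_stack()]s of the future-period
#'   per-member climatologies.
#' @param tmax_baseline,precip_baseline [raster_layer()]s of the shared
#'   baseline climatology.
#' @return data.frame with columns `member_id`, `delta_temperature`,
#'   `delta_precipitation`.
#' @export
climate_deltas <- function(tmax_future, tmax_baseline,
                           precip_future, precip_baseline) {
  stopifnot(inherits(tmax_future, "ensemble_stack"),
            inherits(precip_future, "ensemble_stack"))
  stop_if_grid_mismatch(tmax_future$grid, tmax_baseline$grid, "climate layers")
  stop_if_grid_mismatch(precip_future$grid, precip_baseline$grid, "climate layers")
  if (!identical(tmax_future$member_ids, precip_future$member_ids)) {
    stop("member-id mismatch between climate stacks")
  }
  grid <- tmax_future$grid
  dt <- vapply(seq_along(tmax_future$member_ids), function(i) {
    area_weighted_mean(raster_layer(
      grid, tmax_future$values[i, , ] - tmax_baseline$values))
  }, 0)
  dp <- vapply(seq_along(precip_future$member_ids), function(i) {
    area_weighted_mean(raster_layer(
      grid, precip_future$values[i, , ] - precip_baseline$values))
  }, 0)
  data.frame(member_id = tmax_future$member_ids,
             delta_temperature = dt, delta_precipitation = dp,
             stringsAsFactors = FALSE)
}
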