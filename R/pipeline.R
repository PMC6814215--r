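#' Derive conversion thresholds from a baseline distribution
#'
#' The fully-false threshold is the `p_false` percentile and the fully-true
#' threshold the `p_true` percentile of the layer's valid-cell values, under
#' the linear-interpolation percentile definition (R's default type-7
#' quantile: linear interpolation between order statistics).
#'
#' @param baseline_layer A [raster_layer()] of the variable over the
#'   baseline period.
#' @param p_false,p_true Percentiles in \[0, 100\], `p_false < p_true`
#'   (defaults 10 and 90).
#' @return A [conversion_spec()].
#' @export
derive_thresholds <- function(baseline_layer, p_false = 10, p_true = 90) {
  stopifnot(p_false >= 0, p_true <= 100, p_false < p_true)
  v <- valid_values(baseline_layer)
  if (length(unique(v)) < 2L) {
    stop("degenerate baseline: fewer than 2 distinct values")
  }
  q <- unname(quantile(v, c(p_false, p_true) / 100, type = 7))
  if (q[1L] == q[2L]) {
    stop("degenerate baseline: identical percentile thresholds")
  }
  conversion_spec(q[1L], q[2L])
}

#' The frozen published threshold profile
#'
#' The conversion thresholds printed for the original study (derived there
#' from the real baseline rasters, which are not deposited): biomass burned
#' (0, 110), fire frequency (0, 1), total biomass (31572, 73148), live
#' biomass (5839, 29387), observed biomass (4053, 21844), all g C m-2 except
#' fire frequency (fraction), and vegetation departure fixed at (0, 3).
#'
#' @return Named list `variable -> list(false =, true =)` suitable for the
#'   `thresholds` argument of [load_tree()].
#' @export
paper_thresholds <- function() {
  list(
    mc2_biomass_burned = list(false = 0, true = 110),
    mc2_fire_frequency = list(false = 0.0, true = 1.0),
    mc2_biomass = list(false = 31572, true = 73148),
    mc2_live_biomass = list(false = 5839, true = 29387),
    hudiburg_biomass = list(false = 4053, true = 21844),
    vegetation_departure = list(false = 0, true = 3)
  )
}

#' Derive the full threshold profile from a bundle's baseline
#'
#' Applies [derive_thresholds()] to each baseline MC2 variable and to the
#' observed-biomass layer; vegetation departure keeps its fixed (0, 3)
#' conversion (its scale is defined by the lookup table, not a
#' distribution).
#'
#' @param bundle A bundle from [generate_bundle()] or [read_bundle()].
#' @param p_false,p_true Percentiles (defaults 10 and 90).
#' @return Named list as [paper_thresholds()].
#' @export
derived_thresholds <- function(bundle, p_false = 10, p_true = 90) {
  vars <- c("mc2_biomass_burned", "mc2_fire_frequency",
            "mc2_biomass", "mc2_live_biomass")
  out <- lapply(vars, function(v) {
    s <- derive_thresholds(bundle$baseline[[v]], p_false, p_true)
    list(false = s$minthresh, true = s$maxthresh)
  })
  names(out) <- vars
  s <- derive_thresholds(bundle$observed_biomass, p_false, p_true)
  out$hudiburg_biomass <- list(false = s$minthresh, true = s$maxthresh)
  out$vegetation_departure <- list(false = 0, true = 3)
  out
}

#' Run configuration
#'
#' @param bundle In-memory bundle, or `NULL` to read from `manifest`.
#' @param manifest Path to a bundle `manifest.json`.
#' @param tree_config Path to the logic-tree JSON; default the shipped
#'   biomass-loss-risk tree.
#' @param threshold_profile `"derived"` (percentiles of the bundle baseline,
#'   the default), `"paper"` (the frozen published profile), or a named list.
#' @param p_false,p_true Percentile pair for derived thresholds.
#' @param sd `"population"` or `"sample"` standard deviation for the
#'   uncertainty layer.
#' @param pair_method `"paired"` or `"pooled"` between-scenario uncertainty.
#' @param weighted Area-weight the dominance/extremes fractions.
#' @param output_dir Directory for map and table products, or `NULL` to
#'   skip writing.
#' @return Object of class `run_config`.
#' @export
run_config <- function(bundle = NULL, manifest = NULL,
                       tree_config = system.file("extdata", "biomass_loss_risk_tree.json",
                                                 package = "fuzzyrisk"),
                       threshold_profile = "derived",
                       p_false = 10, p_true = 90,
                       sd = "population", pair_method = "paired",
                       weighted = FALSE, output_dir = NULL) {
  if (is.null(bundle)) {
    if (is.null(manifest)) stop("supply a bundle or a manifest path")
    bundle <- read_bundle(manifest)
  }
  stopifnot(p_false >= 0, p_true <= 100, p_false < p_true)
  structure(list(bundle = bundle, tree_config = tree_config,
                 threshold_profile = threshold_profile,
                 p_false = p_false, p_true = p_true, sd = sd,
                 pair_method = pair_method, weighted = weighted,
                 output_dir = output_dir),
            class = "run_config")
}

resolve_thresholds <- function(config) {
  tp <- config$threshold_profile
  if (is.list(tp)) return(tp)
  switch(tp,
         paper = paper_thresholds(),
         derived = derived_thresholds(config$bundle, config$p_false, config$p_true),
         stop("unknown threshold profile: ", tp))
}

# Per-member vegetation departure layers -> one raw-input stack.
departure_stack <- function(bundle, scenario, period) {
  base_mode <- modal_vegtype(bundle$baseline$veg_series)
  veg <- bundle$scenarios[[scenario]][[period]]$veg_series
  layers <- lapply(veg, function(series) {
    departure_layer(base_mode, modal_vegtype(series), bundle$departure_table)
  })
  layers_to_stack(layers, variable_name = "vegetation_departure",
                  units = "departure value")
}

#' Run the full analysis for one scenario and period
#'
#' Derives (or loads) the threshold profile, evaluates the logic tree
#' independently for every ensemble member, reduces the root and driver
#' nodes to min/mean/max layers, computes the uncertainty layer, the
#' regional summary, per-member driver dominance, member extremes, and
#' per-member climate deltas. When `config$output_dir` is set, writes the
#' 12 map products (min/mean/max/uncertainty for the root and the two driver
#' nodes), 3 CSV tables (summary, dominance, extremes), and a provenance
#' record.
#'
#' @param config A [run_config()].
#' @param scenario,period Names as in the bundle manifest.
#' @return Object of class `scenario_result`.
#' @export
run_scenario <- function(config, scenario, period) {
  stopifnot(inherits(config, "run_config"))
  bundle <- config$bundle
  if (!scenario %in% names(bundle$scenarios)) stop("unknown scenario: ", scenario)
  if (!period %in% names(bundle$scenarios[[scenario]])) {
    stop("unknown period '", period, "' for scenario ", scenario)
  }
  thresholds <- resolve_thresholds(config)
  tree <- load_tree(config$tree_config, thresholds = thresholds)
  sp <- bundle$scenarios[[scenario]][[period]]

  stacks <- sp$stacks[c("mc2_biomass_burned", "mc2_fire_frequency",
                        "mc2_biomass", "mc2_live_biomass")]
  stacks$vegetation_departure <- departure_stack(bundle, scenario, period)
  results <- evaluate_ensemble(tree, stacks,
                               shared_inputs = list(hudiburg_biomass = bundle$observed_biomass))

  root <- node_stack(results, "biomass_loss_risk")
  fire <- node_stack(results, "mc2_fire_loss_risk")
  mort <- node_stack(results, "mc2_mortality_risk")
  mc2_risk <- node_stack(results, "mc2_biomass_loss_risk")

  reductions <- lapply(list(biomass_loss_risk = root, mc2_fire_loss_risk = fire,
                            mc2_mortality_risk = mort),
                       function(s) list(min = reduce_stack(s, "min"),
                                        mean = reduce_stack(s, "mean"),
                                        max = reduce_stack(s, "max"),
                                        uncertainty = high_variability(s, config$sd)))

  summary <- scenario_summary(root, sd = config$sd)
  dominance <- lapply(seq_along(root$member_ids), function(m) {
    dominance_summary(results[[m]]$layers$mc2_fire_loss_risk,
                      results[[m]]$layers$mc2_mortality_risk,
                      results[[m]]$layers$mc2_biomass_loss_risk,
                      weighted = config$weighted)
  })
  names(dominance) <- root$member_ids
  counts <- ensemble_dominance_counts(dominance)
  extremes <- member_extremes(mc2_risk, weighted = config$weighted)
  deltas <- climate_deltas(sp$stacks$tmax, bundle$baseline$tmax,
                           sp$stacks$precip, bundle$baseline$precip)
  mean_diff <- driver_difference(reductions$mc2_fire_loss_risk$mean,
                                 reductions$mc2_mortality_risk$mean)

  res <- structure(
    list(scenario = scenario, period = period,
         member_results = results,
         root_stack = root, fire_stack = fire, mortality_stack = mort,
         mc2_risk_stack = mc2_risk,
         reductions = reductions, driver_difference = mean_diff,
         summary = summary, dominance = dominance,
         dominance_counts = counts, extremes = extremes,
         climate_deltas = deltas),
    class = "scenario_result")

  if (!is.null(config$output_dir)) write_scenario_products(res, config)
  res
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result> %s / %s: mean risk %.3f (range %.3f-%.3f), uncertainty %.3f\n",
              x$scenario, x$period, x$summary$mean, x$summary$min,
              x$summary$max, x$summary$uncertainty))
  invisible(x)
}

write_scenario_products <- function(res, config) {
  dir <- file.path(config$output_dir, paste0(res$scenario, "_", res$period))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (node in names(res$reductions)) {
    for (stat in names(res$reductions[[node]])) {
      write_layer(res$reductions[[node]][[stat]],
                  file.path(dir, paste0(node, "_", stat, ".asc")))
    }
  }
  s <- res$summary
  write.csv(data.frame(scenario = res$scenario, period = res$period,
                       member_id = c("(regional)", names(s$member_means)),
                       mean = c(s$mean, unname(s$member_means)),
                       min = c(s$min, rep(NA, length(s$member_means))),
                       max = c(s$max, rep(NA, length(s$member_means))),
                       uncertainty = c(s$uncertainty, rep(NA, length(s$member_means)))),
            file.path(dir, "summary.csv"), row.names = FALSE)
  write.csv(data.frame(member_id = names(res$dominance),
                       zero_fraction = vapply(res$dominance, `[[`, 0, "zero_fraction"),
                       fire_fraction = vapply(res$dominance, `[[`, 0, "fire_fraction"),
                       mortality_fraction = vapply(res$dominance, `[[`, 0, "mortality_fraction")),
            file.path(dir, "dominance.csv"), row.names = FALSE)
  write.csv(merge(res$climate_deltas, res$extremes, by = "member_id"),
            file.path(dir, "extremes.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(scenario = res$scenario, period = res$period,
         package_version = as.character(packageVersion("fuzzyrisk")),
         r_version = R.version.string,
         tree_config = config$tree_config,
         threshold_profile = if (is.list(config$threshold_profile)) "custom"
                             else config$threshold_profile,
         thresholds = resolve_thresholds(config),
         sd = config$sd, weighted = config$weighted,
         timestamp = format(Sys.time(), tz = "UTC")),
    file.path(dir, "provenance.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Run every scenario and period and assemble the comparison tables
#'
#' @param config A [run_config()].
#' @return Object of class `scenario_comparison`: list with `results`
#'   (scenario -> period -> [run_scenario()] result), `summary_table`
#'   (regional mean/min/max/uncertainty rows), `pair_uncertainty` (one row
#'   per scenario pair and period), `dominance_table` (min/max/mean of each
#'   dominance fraction across members, plus the fire/mortality member
#'   counts), `member_table` (per-member area-weighted means), and
#'   `extremes_table` (per-member climate deltas and extreme-area
#'   fractions).
#' @export
compare_scenarios <- function(config) {
  stopifnot(inherits(config, "run_config"))
  bundle <- config$bundle
  scens <- names(bundle$scenarios)
  periods <- names(bundle$scenarios[[1L]])
  results <- lapply(scens, function(sn) {
    r <- lapply(periods, function(pn) run_scenario(config, sn, pn))
    names(r) <- periods
    r
  })
  names(results) <- scens

  rows <- list(); mrows <- list(); drows <- list(); erows <- list()
  for (sn in scens) for (pn in periods) {
    res <- results[[sn]][[pn]]
    s <- res$summary
    rows[[length(rows) + 1L]] <- data.frame(
      scenario = sn, period = pn, mean = s$mean, min = s$min, max = s$max,
      uncertainty = s$uncertainty)
    mrows[[length(mrows) + 1L]] <- data.frame(
      scenario = sn, period = pn, member_id = names(s$member_means),
      member_mean = unname(s$member_means))
    zf <- vapply(res$dominance, `[[`, 0, "zero_fraction")
    ff <- vapply(res$dominance, `[[`, 0, "fire_fraction")
    mf <- vapply(res$dominance, `[[`, 0, "mortality_fraction")
    drows[[length(drows) + 1L]] <- data.frame(
      scenario = sn, period = pn,
      zero_min = min(zf), zero_max = max(zf), zero_mean = mean(zf),
      fire_min = min(ff), fire_max = max(ff), fire_mean = mean(ff),
      mortality_min = min(mf), mortality_max = max(mf), mortality_mean = mean(mf),
      fire_dominated = unname(res$dominance_counts["fire_dominated"]),
      mortality_dominated = unname(res$dominance_counts["mortality_dominated"]))
    erows[[length(erows) + 1L]] <- cbind(
      data.frame(scenario = sn, period = pn),
      merge(res$climate_deltas, res$extremes, by = "member_id"))
  }

  prows <- list()
  if (length(scens) >= 2L) {
    for (i in seq_len(length(scens) - 1L)) for (j in (i + 1L):length(scens)) {
      for (pn in periods) {
        u <- scenario_pair_uncertainty(results[[scens[i]]][[pn]]$root_stack,
                                       results[[scens[j]]][[pn]]$root_stack,
                                       method = config$pair_method)
        prows[[length(prows) + 1L]] <- data.frame(
          scenario_a = scens[i], scenario_b = scens[j], period = pn,
          uncertainty = u)
      }
    }
  }

  cmp <- structure(
    list(results = results,
         summary_table = do.call(rbind, rows),
         member_table = do.call(rbind, mrows),
         dominance_table = do.call(rbind, drows),
         extremes_table = do.call(rbind, erows),
         pair_uncertainty = do.call(rbind, prows)),
    class = "scenario_comparison")

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    for (tb in c("summary_table", "member_table", "dominance_table",
                 "extremes_table", "pair_uncertainty")) {
      write.csv(cmp[[tb]], file.path(config$output_dir, paste0(tb, ".csv")),
                row.names = FALSE)
    }
  }
  cmp
}
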