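#' @importFrom stats plogis quantile rnorm runif cor sd
NULL

# Smooth Gaussian random field: white noise convolved with a separable
# Gaussian kernel, then z-scored. Consumes the current RNG stream.
gaussian_random_field <- function(n_rows, n_cols, scale) {
  x <- matrix(rnorm(n_rows * n_cols), n_rows, n_cols)
  if (scale > 0) {
    k_half <- max(1L, ceiling(3 * scale))
    make_k <- function(n) {
      d <- abs(outer(seq_len(n), seq_len(n), "-"))
      k <- exp(-d^2 / (2 * scale^2))
      k / rowSums(k)
    }
    x <- make_k(n_rows) %*% x %*% t(make_k(n_cols))
  }
  (x - mean(x)) / sd(x)
}

z_field <- function(x) (x - mean(x)) / sd(x)

#' Configuration for the synthetic MC2-like data generator
#'
#' Defaults encode the conditions of the emulated study: 20 climate futures,
#' four scenarios (two CO2 pathways crossed with fire suppression on/off,
#' the no-suppression analog amplifying the fire variables), a baseline plus
#' three future periods with increasing forcing, and an observed-biomass
#' layer with an 11\% zero-biomass area fraction.
#'
#' @param n_rows,n_cols Grid dimensions (default 100 x 100).
#' @param n_members Ensemble size (default 20, must be >= 2).
#' @param seed Integer seed governing the whole bundle.
#' @param zero_biomass_fraction Fraction of valid cells with observed
#'   biomass 0 (default 0.11); applied as an exact count.
#' @param smoothing_scale Gaussian kernel scale of latent fields, in cells.
#' @param member_spread Multiplier on all between-member variation (climate
#'   delta spread and member-specific spatial noise); 1 is the default world,
#'   larger values inject more ensemble disagreement.
#' @param n_veg_years Years per vegetation-type series (default 7).
#' @param periods data.frame with columns `name`, `forcing`; forcing must be
#'   nondecreasing, first row is the baseline with forcing 0.
#' @param scenarios data.frame with columns `name`, `rcp_forcing`,
#'   `fire_mult`.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_rows = 100, n_cols = 100, n_members = 20,
                             seed = 1, zero_biomass_fraction = 0.11,
                             smoothing_scale = 5, member_spread = 1,
                             n_veg_years = 7,
                             periods = NULL, scenarios = NULL) {
  if (is.null(periods)) {
    periods <- data.frame(name = c("baseline", "early", "mid", "late"),
                          forcing = c(0, 0.35, 0.65, 1.0),
                          stringsAsFactors = FALSE)
  }
  if (is.null(scenarios)) {
    scenarios <- data.frame(name = c("rcp45_fs", "rcp45_nfs", "rcp85_fs", "rcp85_nfs"),
                            rcp_forcing = c(0.6, 0.6, 1.0, 1.0),
                            fire_mult = c(1.0, 1.25, 1.0, 1.25),
                            stringsAsFactors = FALSE)
  }
  stopifnot(n_members >= 2, n_rows >= 4, n_cols >= 4,
            zero_biomass_fraction >= 0, zero_biomass_fraction < 1,
            member_spread >= 0, n_veg_years >= 1)
  if (periods$forcing[1L] != 0) stop("first period must be the baseline (forcing 0)")
  if (is.unsorted(periods$forcing)) stop("period forcing must be nondecreasing")
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 n_members = as.integer(n_members), seed = as.integer(seed),
                 zero_biomass_fraction = zero_biomass_fraction,
                 smoothing_scale = smoothing_scale,
                 member_spread = member_spread,
                 n_veg_years = as.integer(n_veg_years),
                 periods = periods, scenarios = scenarios),
            class = "synthetic_config")
}

# Vegetation types are fixed-width bins of a climate suitability index.
VEG_BREAKS <- c(-Inf, 1, 2, 3, 4, Inf)
bin_vegtype <- function(index) {
  findInterval(index, VEG_BREAKS[-c(1L, length(VEG_BREAKS))]) + 1L
}

#' Default synthetic departure lookup table
#'
#' A stand-in for the expert table (which is not published): types are
#' ordered climate-suitability bins, so the departure score is the bin
#' distance capped at 3. Identical to the CSV shipped under
#' `inst/extdata/departure_table_synthetic.csv`.
#'
#' @param n_types Number of vegetation types (default 5).
#' @return A [departure_table()].
#' @export
synthetic_departure_table <- function(n_types = 5) {
  grid <- expand.grid(baseline_type = seq_len(n_types),
                      future_type = seq_len(n_types))
  grid$departure <- pmin(abs(grid$baseline_type - grid$future_type), 3)
  departure_table(grid)
}

#' Generate a synthetic MC2-like data bundle
#'
#' Deterministic given the config seed. Construction: smooth latent fields
#' (coastal proximity, elevation, productivity, dryness); baseline biomass an
#' increasing function of productivity with live biomass a noisy fraction of
#' it; per-member climate deltas drawn around each scenario/period forcing
#' (temperature up, precipitation mixed-sign); fire variables increasing with
#' member warming and dryness and decreasing with coastal proximity, with the
#' no-fire-suppression analog multiplying them up; vegetation types as bins
#' of a climate index that shift under warming; observed biomass as baseline
#' biomass under lognormal noise with an exact count of lowest-productivity
#' cells set to 0. Member-specific draws come from per-member substreams
#' (fixed seed offsets) and are reused across scenarios and periods, so the
#' "climate futures" are the same entities everywhere, as in a real ensemble.
#'
#' @param config A [synthetic_config()].
#' @return Object of class `synthetic_bundle`: list with `grid`, `baseline`
#'   (named raw layers + `veg_series` + `tmax`/`precip`), `observed_biomass`,
#'   `departure_table`, `scenarios` (scenario -> period -> list of `stacks`,
#'   `veg_series`, `deltas`), and `latents` (test-only ground truth).
#' @export
generate_bundle <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  nr <- config$n_rows; nc <- config$n_cols
  nm <- config$n_members; spread <- config$member_spread

  # --- study-area mask: carve an "ocean" corner so masks are exercised
  mask <- matrix(TRUE, nr, nc)
  mask[seq_len(max(1L, floor(nr * 0.08))), seq_len(max(1L, floor(nc * 0.12)))] <- FALSE
  grid <- grid_spec(nr, nc, valid_mask = mask)

  # --- latent fields (shared across scenarios/periods)
  set.seed(config$seed)
  sc <- config$smoothing_scale
  coast <- z_field(outer(rep(1, nr), (nc - seq_len(nc)) / (nc - 1)) +
                     0.25 * gaussian_random_field(nr, nc, sc))
  elevation <- z_field(outer(rep(1, nr), (seq_len(nc) - 1) / (nc - 1)) +
                         0.6 * gaussian_random_field(nr, nc, sc))
  productivity <- z_field(gaussian_random_field(nr, nc, sc) + 0.5 * coast -
                            0.3 * abs(elevation))
  dryness <- z_field(-0.7 * coast + 0.4 * elevation +
                       0.5 * gaussian_random_field(nr, nc, sc))
  obs_noise <- gaussian_random_field(nr, nc, max(1, sc / 2))
  live_noise <- gaussian_random_field(nr, nc, max(1, sc / 2))
  # annual noise of the baseline vegetation series
  eta_base <- rnorm(config$n_veg_years, 0, 0.35)

  # --- per-member substreams (seed offsets keep members stable)
  eps_T <- eps_P <- numeric(nm)
  f_fire <- f_bio <- f_tmax <- f_precip <- vector("list", nm)
  eta_member <- matrix(0, nm, config$n_veg_years)
  for (m in seq_len(nm)) {
    set.seed(config$seed + 1000L + m)
    eps_T[m] <- rnorm(1)
    eps_P[m] <- rnorm(1)
    f_fire[[m]] <- gaussian_random_field(nr, nc, sc)
    f_bio[[m]] <- gaussian_random_field(nr, nc, sc)
    f_tmax[[m]] <- gaussian_random_field(nr, nc, sc)
    f_precip[[m]] <- gaussian_random_field(nr, nc, sc)
    eta_member[m, ] <- rnorm(config$n_veg_years, 0, 0.35)
  }
  member_ids <- sprintf("cf%02d", seq_len(nm))

  # --- baseline (historical, single run; forcing 0)
  baseline_biomass <- 50000 * exp(0.35 * productivity)
  live_biomass <- baseline_biomass * 0.35 * exp(0.15 * live_noise)
  climate_index <- 2.5 + 1.2 * z_field(-0.8 * elevation - 0.5 * coast +
                                         0.4 * gaussian_random_field(nr, nc, sc))
  tmax_base <- 15 - 4 * elevation + 0.8 * gaussian_random_field(nr, nc, sc)
  precip_base <- pmax(1800 + 700 * coast +
                        150 * gaussian_random_field(nr, nc, sc), 300)

  fire_fields <- function(delta_T, member_field, fire_mult) {
    idx <- -1.1 + 0.9 * delta_T + 0.8 * dryness - 0.35 * coast +
      0.5 * spread * member_field
    freq <- pmin(plogis(idx) * fire_mult, 1)
    burned <- freq * 0.004 * live_biomass * exp(0.2 * spread * member_field) *
      fire_mult
    list(frequency = freq, burned = burned)
  }
  base_fire <- fire_fields(0, matrix(0, nr, nc), 1)

  lay <- function(v, name, units) raster_layer(grid, v, name, units)
  baseline <- list(
    mc2_biomass_burned = lay(base_fire$burned, "mc2_biomass_burned", "g C m-2"),
    mc2_fire_frequency = lay(base_fire$frequency, "mc2_fire_frequency", "fraction"),
    mc2_biomass = lay(baseline_biomass, "mc2_biomass", "g C m-2"),
    mc2_live_biomass = lay(live_biomass, "mc2_live_biomass", "g C m-2"),
    tmax = lay(tmax_base, "tmax", "degC"),
    precip = lay(precip_base, "precip", "mm")
  )
  base_veg_vals <- array(NA_integer_, c(config$n_veg_years, nr, nc))
  for (y in seq_len(config$n_veg_years)) {
    base_veg_vals[y, , ] <- bin_vegtype(climate_index + eta_base[y])
  }
  baseline$veg_series <- veg_type_series(grid, seq_len(config$n_veg_years),
                                         base_veg_vals)

  # --- observed biomass: lognormal noise, exact-count zeroing
  obs <- baseline_biomass * exp(0.3 * obs_noise)
  n_valid <- sum(mask)
  k_zero <- ceiling(config$zero_biomass_fraction * n_valid)
  if (k_zero > 0) {
    prod_valid <- productivity[mask]
    cut <- sort(prod_valid)[k_zero]
    zero_cells <- which(mask & productivity <= cut)[seq_len(k_zero)]
    obs[zero_cells] <- 0
  }
  observed_biomass <- lay(obs, "hudiburg_biomass", "g C m-2")

  # --- future stacks per scenario x period
  future_periods <- config$periods[-1L, , drop = FALSE]
  scen_list <- list()
  for (s in seq_len(nrow(config$scenarios))) {
    scen <- config$scenarios[s, ]
    per_list <- list()
    for (p in seq_len(nrow(future_periods))) {
      per <- future_periods[p, ]
      forcing <- scen$rcp_forcing * per$forcing
      delta_T <- forcing * 3.5 * pmax(0.25, 1 + 0.35 * spread * eps_T)
      delta_P <- forcing * (-40 + 120 * spread * eps_P)

      arr <- function() array(NA_real_, c(nm, nr, nc))
      a_burn <- arr(); a_freq <- arr(); a_bio <- arr(); a_live <- arr()
      a_tmax <- arr(); a_prec <- arr()
      veg_series <- vector("list", nm)
      for (m in seq_len(nm)) {
        fm <- fire_fields(delta_T[m], f_fire[[m]], scen$fire_mult)
        a_burn[m, , ] <- fm$burned
        a_freq[m, , ] <- fm$frequency
        a_bio[m, , ] <- baseline_biomass * exp(0.08 * spread * f_bio[[m]])
        a_live[m, , ] <- live_biomass * exp(0.08 * spread * f_bio[[m]])
        a_tmax[m, , ] <- tmax_base + delta_T[m] + 0.3 * spread * f_tmax[[m]]
        a_prec[m, , ] <- pmax(precip_base + delta_P[m] +
                                30 * spread * f_precip[[m]], 0)
        shift <- 0.45 * delta_T[m]
        vv <- array(NA_integer_, c(config$n_veg_years, nr, nc))
        for (y in seq_len(config$n_veg_years)) {
          vv[y, , ] <- bin_vegtype(climate_index + shift + eta_member[m, y])
        }
        veg_series[[m]] <- veg_type_series(grid, seq_len(config$n_veg_years), vv)
      }
      names(veg_series) <- member_ids
      stk <- function(a, name, units) ensemble_stack(grid, member_ids, a, name, units)
      per_list[[per$name]] <- list(
        stacks = list(
          mc2_biomass_burned = stk(a_burn, "mc2_biomass_burned", "g C m-2"),
          mc2_fire_frequency = stk(a_freq, "mc2_fire_frequency", "fraction"),
          mc2_biomass = stk(a_bio, "mc2_biomass", "g C m-2"),
          mc2_live_biomass = stk(a_live, "mc2_live_biomass", "g C m-2"),
          tmax = stk(a_tmax, "tmax", "degC"),
          precip = stk(a_prec, "precip", "mm")
        ),
        veg_series = veg_series,
        deltas = data.frame(member_id = member_ids,
                            delta_temperature = delta_T,
                            delta_precipitation = delta_P,
                            stringsAsFactors = FALSE)
      )
    }
    scen_list[[scen$name]] <- per_list
  }

  structure(
    list(config = config, grid = grid, member_ids = member_ids,
         baseline = baseline, observed_biomass = observed_biomass,
         departure_table = synthetic_departure_table(),
         scenarios = scen_list,
         latents = list(productivity = productivity, coast = coast,
                        elevation = elevation, dryness = dryness,
                        climate_index = climate_index,
                        eps_T = eps_T, eps_P = eps_P)),
    class = "synthetic_bundle"
  )
}

#' Write a synthetic bundle to disk
#'
#' Emits files consumable by the grid_io readers without modification:
#' ASCII-grid layers and stack manifests, vegetation-series manifests, the
#' departure-table CSV, per-scenario climate-delta CSVs, and a top-level
#' `manifest.json` listing every product.
#'
#' @param bundle A `synthetic_bundle` from [generate_bundle()].
#' @param dir Destination directory (must exist or be creatable).
#' @return Path of the written `manifest.json`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "synthetic_bundle"))
  ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create bundle directory: ", dir)
  man <- list(baseline = list(), scenarios = list())

  for (v in setdiff(names(bundle$baseline), "veg_series")) {
    p <- paste0("baseline_", v, ".asc")
    write_layer(bundle$baseline[[v]], file.path(dir, p))
    man$baseline[[v]] <- p
  }
  man$baseline$veg_series <- basename(
    write_veg_series(bundle$baseline$veg_series, dir, "baseline_veg"))
  write_layer(bundle$observed_biomass, file.path(dir, "hudiburg_biomass.asc"))
  man$observed_biomass <- "hudiburg_biomass.asc"
  write.csv(bundle$departure_table$entries,
            file.path(dir, "departure_table.csv"), row.names = FALSE)
  man$departure_table <- "departure_table.csv"

  for (sn in names(bundle$scenarios)) {
    for (pn in names(bundle$scenarios[[sn]])) {
      sp <- bundle$scenarios[[sn]][[pn]]
      sub <- paste0(sn, "_", pn)
      subdir <- file.path(dir, sub)
      entry <- list(stacks = list(), veg_series = list())
      for (v in names(sp$stacks)) {
        entry$stacks[[v]] <- file.path(sub, basename(
          write_stack(sp$stacks[[v]], subdir, name = v)))
      }
      for (mid in names(sp$veg_series)) {
        entry$veg_series[[mid]] <- file.path(sub, basename(
          write_veg_series(sp$veg_series[[mid]], subdir, paste0("veg_", mid))))
      }
      write.csv(sp$deltas, file.path(subdir, "climate_deltas.csv"),
                row.names = FALSE)
      entry$deltas <- file.path(sub, "climate_deltas.csv")
      man$scenarios[[sn]][[pn]] <- entry
    }
  }
  man$member_ids <- as.list(bundle$member_ids)
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(man, manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Read a bundle back from its manifest
#'
#' @param manifest Path to a `manifest.json` from [write_bundle()].
#' @return A list with the same layout as a `synthetic_bundle` (without
#'   `config` and `latents`, which are generator-side only).
#' @export
read_bundle <- function(manifest) {
  if (!file.exists(manifest)) stop("manifest not found: ", manifest)
  man <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  dir <- dirname(manifest)
  baseline <- list()
  for (v in setdiff(names(man$baseline), "veg_series")) {
    baseline[[v]] <- read_layer(file.path(dir, man$baseline[[v]]),
                                variable_name = v)
  }
  grid <- baseline[[1L]]$grid
  baseline$veg_series <- read_veg_series(
    file.path(dir, man$baseline$veg_series), reference = grid)
  observed <- read_layer(file.path(dir, man$observed_biomass),
                         variable_name = "hudiburg_biomass", reference = grid)
  # observed biomass legitimately contains zeros inside the study area but
  # shares the bundle grid; re-read against the full-grid reference
  dep <- load_departure_table(file.path(dir, man$departure_table))
  scen_list <- list()
  for (sn in names(man$scenarios)) {
    per_list <- list()
    for (pn in names(man$scenarios[[sn]])) {
      e <- man$scenarios[[sn]][[pn]]
      stacks <- lapply(e$stacks, function(p) {
        read_stack(file.path(dir, p), reference = grid)
      })
      veg <- lapply(e$veg_series, function(p) {
        read_veg_series(file.path(dir, p), reference = grid)
      })
      per_list[[pn]] <- list(stacks = stacks, veg_series = veg,
                             deltas = read.csv(file.path(dir, e$deltas)))
    }
    scen_list[[sn]] <- per_list
  }
  structure(list(grid = grid, member_ids = unlist(man$member_ids),
                 baseline = baseline, observed_biomass = observed,
                 departure_table = dep, scenarios = scen_list),
            class = "synthetic_bundle")
}
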