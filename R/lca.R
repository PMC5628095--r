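#' Configuration of the carbon life-cycle simulation
#'
#' Cradle-to-grave accounting of above-ground carbon in an urban tree
#' population: annual growth on the species curves, optional pruning,
#' stratified mortality, and interval reporting of the alive pool and the
#' accumulated dead pool. Defaults follow the reference case: start year
#' 2008, 60-year horizon, 10-year reports, 700 km2 (70,000 ha) of land
#' cover, carbon fraction 0.5, uncertainty flagged when a class's average
#' age exceeds 80 years. Pruning (10 percent of above-ground carbon every
#' 10 years, moved to the dead/residual pool) is available but off by
#' default.
#'
#' @param start_year First calendar year (the inventory's acquisition year).
#' @param horizon Years simulated.
#' @param report_interval Years between reports; a trailing partial interval
#'   is still reported.
#' @param land_cover_area_ha Land-cover area used for carbon densities, ha.
#' @param carbon_fraction Carbon fraction of dry biomass, in (0, 1].
#' @param avg_age_flag_threshold Average age (years) above which a report
#'   entry is flagged as highly uncertain.
#' @param pruning_enabled,pruning_fraction,pruning_interval Pruning stage
#'   settings.
#' @param seed Seed for stochastic mortality.
#' @return An `lca_config` list.
#' @export
lca_config <- function(start_year = 2008, horizon = 60, report_interval = 10,
                       land_cover_area_ha = 70000, carbon_fraction = 0.5,
                       avg_age_flag_threshold = 80,
                       pruning_enabled = FALSE, pruning_fraction = 0.10,
                       pruning_interval = 10, seed = NULL) {
  if (horizon < 1) stop("horizon must be >= 1")
  if (report_interval < 1) stop("report_interval must be >= 1")
  if (land_cover_area_ha <= 0) stop("land_cover_area_ha must be > 0")
  if (carbon_fraction <= 0 || carbon_fraction > 1) {
    stop("carbon_fraction must be in (0, 1]")
  }
  if (pruning_fraction < 0 || pruning_fraction >= 1) {
    stop("pruning_fraction must be in [0, 1)")
  }
  out <- list(start_year = start_year, horizon = horizon,
              report_interval = report_interval,
              land_cover_area_ha = land_cover_area_ha,
              carbon_fraction = carbon_fraction,
              avg_age_flag_threshold = avg_age_flag_threshold,
              pruning_enabled = pruning_enabled,
              pruning_fraction = pruning_fraction,
              pruning_interval = pruning_interval,
              seed = if (is.null(seed)) NULL else as.integer(seed))
  class(out) <- "lca_config"
  out
}

#' Carbon density per unit land cover
#'
#' @param total_carbon_ktC Carbon pool in kilotons of carbon.
#' @param area_ha Land-cover area in hectares; must be > 0.
#' @return Density in tC/ha (`total * 1000 / area`).
#' @export
carbon_density <- function(total_carbon_ktC, area_ha) {
  if (any(area_ha <= 0)) stop("area must be > 0")
  total_carbon_ktC * 1000 / area_ha
}

#' High-uncertainty flag for an average tree age
#'
#' An average population age above the threshold (strictly greater; 80 years
#' exactly is not flagged) is unlikely for most urban trees and marks the
#' report entry as highly uncertain. Empty populations have no defined
#' average age and return `NA`.
#'
#' @param average_age Average age in years; vectorised; `NA` for empty
#'   populations.
#' @param threshold Flag threshold in years (default 80).
#' @return Logical flag(s).
#' @export
flag_average_age <- function(average_age, threshold = 80) {
  ifelse(is.na(average_age), NA, average_age > threshold)
}

# Vectorised per-tree DBH from class-specific curves at given ages.
inventory_dbh_at_age <- function(species, age, registry) {
  dbh <- numeric(length(age))
  for (sp in unique(species)) {
    idx <- species == sp
    if (sp == "mix") {
      dbh[idx] <- mix_dbh_at_age(registry, age[idx])
    } else {
      dbh[idx] <- dbh_at_age(species_class(registry, sp), age[idx])
    }
  }
  dbh
}

# Vectorised per-tree carbon (kg C) from DBH through each tree's allometric
# model; mix trees take the mean of the ten class models.
inventory_carbon <- function(species, dbh, registry, allometry, fraction) {
  kg <- numeric(length(dbh))
  for (sp in unique(species)) {
    idx <- species == sp
    if (sp == "mix") {
      kg[idx] <- mix_biomass_from_dbh(allometry, dbh[idx], registry)
    } else {
      key <- species_class(registry, sp)$allometry_key
      kg[idx] <- biomass_from_dbh(resolve_allometry(allometry, key), dbh[idx],
                                  warn_range = FALSE)
    }
  }
  carbon_from_biomass(kg, fraction)
}

lca_classes <- c("street", "mixed", "park")

# One row per land-use class plus "total" for the current state.
lca_snapshot <- function(year, cal_year, land_use, weight, age, carbon_kg,
                         dead_kg, config) {
  per_class <- function(lu) {
    if (lu == "total") sel <- rep(TRUE, length(land_use))
    else sel <- land_use == lu
    w <- weight[sel]
    pop <- sum(w)
    avg_age <- if (pop > 0) sum(w * age[sel]) / pop else NA_real_
    alive_kt <- sum(w * carbon_kg[sel]) / 1e6
    dead_kt <- if (lu == "total") sum(dead_kg) / 1e6 else dead_kg[[lu]] / 1e6
    data.frame(year = year, calendar_year = cal_year, land_use = lu,
               population = pop, average_age_years = avg_age,
               alive_ktC = alive_kt, dead_ktC = dead_kt,
               alive_tC_per_ha = carbon_density(alive_kt, config$land_cover_area_ha),
               dead_tC_per_ha = carbon_density(dead_kt, config$land_cover_area_ha),
               high_uncertainty_flag = flag_average_age(
                 avg_age, config$avg_age_flag_threshold),
               stringsAsFactors = FALSE)
  }
  do.call(rbind, lapply(c(lca_classes, "total"), per_class))
}

#' Run the annual carbon life-cycle simulation
#'
#' Simulates the inventory year by year over the configured horizon. Within
#' each year, in order: (1) every tree's age increments and its DBH is
#' re-evaluated on its growth curve; (2) on pruning years (if enabled) each
#' alive tree loses `pruning_fraction` of its above-ground carbon to the
#' dead/residual pool; (3) mortality is applied, and dying trees move their
#' full current carbon into the accumulated dead pool. The dying-after-
#' growing order means a tree killed in year t contributes its year-t
#' biomass. Reports are emitted at the start and at every report interval
#' (plus a trailing partial interval).
#'
#' In stochastic mode each tree dies independently with its land-use rate;
#' in expected-value mode every tree instead carries a continuous survival
#' weight multiplied by `(1 - rate)` each year, so class populations equal
#' `n (1 - m)^t` exactly and runs are deterministic.
#'
#' The engine is age-driven: DBH is always evaluated on the curve at the
#' tree's current age (ages read from an external inventory should therefore
#' come from [age_from_dbh()] / [mix_age_from_dbh()] if only DBH was
#' measured).
#'
#' @param inventory A `tree_inventory`.
#' @param registry A [species_registry()].
#' @param allometry An [allometry_table()]; every registry key must resolve.
#' @param mortality A [mortality_model()].
#' @param config An [lca_config()].
#' @return An `lca_result` list: `reports` (interval rows per class and
#'   total), `yearly` (per-year per-class alive/dead series used by
#'   [compensation_analysis()]), plus the inputs echoed back.
#' @export
run_lca <- function(inventory, registry = species_registry(),
                    allometry = allometry_table(),
                    mortality = mortality_model(), config = lca_config()) {
  stopifnot(inherits(mortality, "mortality_model"),
            inherits(config, "lca_config"))
  check_allometry_keys(allometry, registry)
  bad_sp <- setdiff(unique(inventory$species_class), registry$class_id)
  if (length(bad_sp)) {
    stop("species class(es) not in registry: ", paste(bad_sp, collapse = ", "))
  }
  bad_lu <- setdiff(unique(inventory$land_use), lca_classes)
  if (length(bad_lu)) {
    stop("unknown land_use label(s): ", paste(bad_lu, collapse = ", "))
  }
  seed <- if (!is.null(config$seed)) config$seed else mortality$seed
  if (!is.null(seed)) set.seed(seed)

  n <- nrow(inventory)
  species <- inventory$species_class
  land_use <- inventory$land_use
  age <- inventory$age
  weight <- rep(1, n)            # survival weight; {0,1} in stochastic mode
  expected <- mortality$mode == "expected_value"
  prune_mult <- rep(1, n)        # cumulative pruning retention per tree
  dead_kg <- c(street = 0, mixed = 0, park = 0)

  carbon_kg <- prune_mult * inventory_carbon(
    species, inventory_dbh_at_age(species, age, registry),
    registry, allometry, config$carbon_fraction)

  report_years <- unique(c(seq(0, config$horizon, by = config$report_interval),
                           config$horizon))
  snapshots <- vector("list", length(report_years))
  yearly <- vector("list", config$horizon + 1)
  snap0 <- lca_snapshot(0, config$start_year, land_use, weight, age,
                        carbon_kg, dead_kg, config)
  snapshots[[1]] <- snap0
  yearly[[1]] <- snap0[snap0$land_use != "total",
                       c("year", "land_use", "population", "alive_ktC", "dead_ktC")]

  rates <- mortality$rates
  for (t in seq_len(config$horizon)) {
    age <- age + 1
    carbon_kg <- prune_mult * inventory_carbon(
      species, inventory_dbh_at_age(species, age, registry),
      registry, allometry, config$carbon_fraction)
    if (config$pruning_enabled && t %% config$pruning_interval == 0) {
      removed <- config$pruning_fraction * carbon_kg
      for (lu in lca_classes) {
        sel <- land_use == lu
        dead_kg[[lu]] <- dead_kg[[lu]] + sum(weight[sel] * removed[sel])
      }
      prune_mult <- prune_mult * (1 - config$pruning_fraction)
      carbon_kg <- carbon_kg - removed
    }
    if (expected) {
      for (lu in lca_classes) {
        sel <- land_use == lu
        dying_w <- weight[sel] * rates[[lu]]
        dead_kg[[lu]] <- dead_kg[[lu]] + sum(dying_w * carbon_kg[sel])
        weight[sel] <- weight[sel] - dying_w
      }
    } else {
      alive_idx <- which(weight > 0)
      if (length(alive_idx)) {
        p <- rates[land_use[alive_idx]]
        dies <- alive_idx[stats::runif(length(alive_idx)) < p]
        if (length(dies)) {
          for (lu in lca_classes) {
            d <- dies[land_use[dies] == lu]
            dead_kg[[lu]] <- dead_kg[[lu]] + sum(carbon_kg[d])
          }
          weight[dies] <- 0
        }
      }
    }
    yr <- lca_snapshot(t, config$start_year + t, land_use, weight, age,
                       carbon_kg, dead_kg, config)
    yearly[[t + 1]] <- yr[yr$land_use != "total",
                          c("year", "land_use", "population", "alive_ktC", "dead_ktC")]
    if (t %in% report_years) snapshots[[match(t, report_years)]] <- yr
  }

  out <- list(reports = do.call(rbind, snapshots),
              yearly = do.call(rbind, yearly),
              config = config, mortality = mortality,
              n_trees_initial = n)
  rownames(out$reports) <- NULL
  rownames(out$yearly) <- NULL
  class(out) <- "lca_result"
  out
}

#' @export
print.lca_result <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Carbon LCA: %s trees, %d-year horizon from %d (%s mortality)\n",
              format(x$n_trees_initial, big.mark = ","), cfg$horizon,
              cfg$start_year, x$mortality$mode))
  tot <- x$reports[x$reports$land_use == "total", ]
  shown <- data.frame(year = tot$calendar_year,
                      alive_tC_ha = round(tot$alive_tC_per_ha, 2),
                      dead_tC_ha = round(tot$dead_tC_per_ha, 2),
                      avg_age = round(tot$average_age_years, 1),
                      flagged = tot$high_uncertainty_flag)
  print.data.frame(shown, row.names = FALSE)
  invisible(x)
}

#' @export
summary.lca_result <- function(object, ...) {
  tot <- object$reports[object$reports$land_use == "total", ]
  list(horizon = object$config$horizon,
       start_alive_tC_per_ha = tot$alive_tC_per_ha[1],
       end_alive_tC_per_ha = tot$alive_tC_per_ha[nrow(tot)],
       end_dead_tC_per_ha = tot$dead_tC_per_ha[nrow(tot)],
       peak_alive_year = tot$calendar_year[which.max(tot$alive_tC_per_ha)],
       flagged_from_year = {
         fl <- tot$calendar_year[which(tot$high_uncertainty_flag)]
         if (length(fl)) min(fl) else NA_integer_
       })
}

#' @export
plot.lca_result <- function(x, ...) {
  yr <- x$yearly
  classes <- c("street", "mixed", "park")
  cols <- c(street = "firebrick", mixed = "darkorange", park = "forestgreen")
  rng <- range(yr$alive_ktC, yr$dead_ktC)
  graphics::plot(NULL, xlim = range(yr$year), ylim = rng,
                 xlab = "simulation year", ylab = "carbon (ktC)", ...)
  for (lu in classes) {
    sub <- yr[yr$land_use == lu, ]
    graphics::lines(sub$year, sub$alive_ktC, col = cols[[lu]], lty = 1)
    graphics::lines(sub$year, sub$dead_ktC, col = cols[[lu]], lty = 2)
  }
  graphics::legend("topleft", bty = "n", col = cols, lty = 1, legend = classes)
  invisible(x)
}

#' Write interval reports to CSV
#'
#' One row per reporting year and land-use class (plus totals), with
#' populations, average ages, alive and accumulated-dead carbon in ktC,
#' densities in tC/ha, and the high-uncertainty flag.
#'
#' @param lca_result A [run_lca()] result.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_report <- function(lca_result, path) {
  stopifnot(inherits(lca_result, "lca_result"))
  utils::write.csv(lca_result$reports, path, row.names = FALSE, na = "")
  invisible(path)
}
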