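#' Stratified annual mortality model
#'
#' Annual static mortality rates per land-use class. The defaults follow the
#' usual urban stress gradient: 3.5 percent per year for street trees
#' (pollution, sealed surfaces, traffic), 2 percent for mixed
#' residential/commercial areas, 1 percent for parks.
#'
#' Two selection modes are provided. `"stochastic"` kills each alive tree
#' independently with its class rate (Bernoulli thinning), an annual
#' stratified random selection. `"expected_value"` is a deterministic
#' companion: record-level updates kill exactly `round(rate * alive)` trees
#' per class by seeded draw, while the simulation engines account for pools
#' with continuous survival weights \eqn{(1-m)^t} so that survival matches
#' the closed form exactly (useful for half-life checks and regression
#' tests).
#'
#' @param rate_street,rate_mixed,rate_park Annual mortality fractions in
#'   `[0, 1)`.
#' @param mode `"stochastic"` or `"expected_value"`.
#' @param seed Optional seed for the selection draws; combined with the
#'   simulation year so repeated calls stay reproducible.
#' @return A `mortality_model` list.
#' @export
mortality_model <- function(rate_street = 0.035, rate_mixed = 0.02,
                            rate_park = 0.01,
                            mode = c("stochastic", "expected_value"),
                            seed = NULL) {
  mode <- match.arg(mode)
  rates <- c(street = rate_street, mixed = rate_mixed, park = rate_park)
  if (any(rates < 0) || any(rates >= 1)) {
    stop("mortality rates must lie in [0, 1)")
  }
  out <- list(rates = rates, mode = mode,
              seed = if (is.null(seed)) NULL else as.integer(seed))
  class(out) <- "mortality_model"
  out
}

#' @export
print.mortality_model <- function(x, ...) {
  cat(sprintf("Mortality model (%s): street %.1f%%, mixed %.1f%%, park %.1f%% per year\n",
              x$mode, 100 * x$rates[["street"]], 100 * x$rates[["mixed"]],
              100 * x$rates[["park"]]))
  invisible(x)
}

#' Apply one year of stratified mortality to an inventory
#'
#' Stochastic mode kills each alive tree independently with its land-use
#' rate; expected-value mode kills exactly `round(rate * alive)` trees per
#' class, selected by seeded draw. Dead trees receive `death_year = year`;
#' trees already dead are never touched.
#'
#' @param inventory A `tree_inventory`.
#' @param model A [mortality_model()].
#' @param year Simulation or calendar year recorded on the newly dead.
#' @return A list with elements `inventory` (updated) and `dead` (the newly
#'   dead records).
#' @export
apply_annual_mortality <- function(inventory, model, year) {
  stopifnot(inherits(model, "mortality_model"))
  unknown <- !inventory$land_use %in% names(model$rates)
  if (any(unknown)) {
    stop("unknown land_use for tree_id ",
         inventory$tree_id[which(unknown)[1]])
  }
  if (!is.null(model$seed)) set.seed(model$seed + as.integer(year))
  dying <- logical(nrow(inventory))
  for (lu in names(model$rates)) {
    idx <- which(inventory$alive & inventory$land_use == lu)
    if (!length(idx)) next
    rate <- model$rates[[lu]]
    if (model$mode == "stochastic") {
      dying[idx] <- stats::runif(length(idx)) < rate
    } else {
      k <- round(rate * length(idx))
      if (k > 0) dying[sample(idx, k)] <- TRUE
    }
  }
  inventory$alive[dying] <- FALSE
  inventory$death_year[dying] <- as.integer(year)
  list(inventory = inventory, dead = inventory[dying, , drop = FALSE])
}

#' Population half-life under a static annual mortality rate
#'
#' The number of years until half the cohort is dead: the smallest integer
#' `t` with `(1 - rate)^t <= 0.5`, i.e. `ceiling(log(0.5)/log(1 - rate))`.
#' The canonical urban rates give 20 years at 3.5 percent, 35 at 2 percent
#' and 69 at 1 percent.
#'
#' @param rate Annual mortality fraction; vectorised; must be > 0. Rates at
#'   or above 1 return 1 (the whole cohort dies in the first year).
#' @return Half-life in whole years.
#' @export
population_half_life <- function(rate) {
  if (!is.numeric(rate) || any(!is.finite(rate)) || any(rate <= 0)) {
    stop("rate must be > 0")
  }
  out <- rep(1, length(rate))
  sub <- rate < 1
  # tiny slack so exact solutions like rate = 0.5 are not pushed up a year
  out[sub] <- ceiling(log(0.5) / log(1 - rate[sub]) - 1e-9)
  out
}

#' Define a tree-planting scenario
#'
#' A single cohort of identical mix-class trees planted at once and followed
#' over a growth horizon (reference case: 100,000 trees over 70 years under
#' one static annual mortality rate).
#'
#' @param n_trees Cohort size.
#' @param growth_horizon Years simulated (>= 1).
#' @param mortality_rate Annual mortality fraction in `[0, 1)`.
#' @param start_age Age at planting, years (default 0).
#' @return A `planting_scenario` list.
#' @export
planting_scenario <- function(n_trees = 100000, growth_horizon = 70,
                              mortality_rate = 0.035, start_age = 0) {
  if (n_trees < 0) stop("n_trees must be >= 0")
  if (growth_horizon < 1) stop("growth_horizon must be >= 1")
  if (mortality_rate < 0 || mortality_rate >= 1) {
    stop("mortality_rate must lie in [0, 1)")
  }
  out <- list(n_trees = n_trees, growth_horizon = growth_horizon,
              mortality_rate = mortality_rate, start_age = start_age)
  class(out) <- "planting_scenario"
  out
}

#' Run a planting scenario
#'
#' Simulates the cohort year by year: age increments, DBH follows the
#' mix-class growth curve, per-tree carbon is the mix-class allometric
#' biomass times the carbon fraction, and mortality is applied after growth.
#' Because the cohort is homogeneous, stochastic thinning is drawn at the
#' population level as `Binomial(alive, rate)`, which is distributionally
#' identical to per-tree Bernoulli thinning; expected-value mode tracks the
#' continuous survivor count `n (1 - rate)^t`. The half-life year from
#' [population_half_life()] is marked on the trajectory.
#'
#' @param scenario A [planting_scenario()].
#' @param allometry An [allometry_table()].
#' @param registry A [species_registry()].
#' @param mode `"expected_value"` or `"stochastic"`.
#' @param carbon_fraction Carbon fraction of dry biomass.
#' @param seed Seed for stochastic mode.
#' @return A `planting_trajectory` data frame with columns `year`,
#'   `alive_count`, `alive_carbon_ktC`, `is_half_life_year`, and attributes
#'   `half_life_years` and `scenario`.
#' @export
run_planting_scenario <- function(scenario,
                                  allometry = allometry_table(),
                                  registry = species_registry(),
                                  mode = c("expected_value", "stochastic"),
                                  carbon_fraction = 0.5, seed = NULL) {
  stopifnot(inherits(scenario, "planting_scenario"))
  mode <- match.arg(mode)
  if (mode == "stochastic" && !is.null(seed)) set.seed(as.integer(seed))
  horizon <- scenario$growth_horizon
  rate <- scenario$mortality_rate
  years <- 0:horizon
  ages <- scenario$start_age + years
  dbh <- mix_dbh_at_age(registry, ages)
  kg_per_tree <- carbon_from_biomass(
    mix_biomass_from_dbh(allometry, dbh, registry), carbon_fraction)
  alive <- numeric(horizon + 1)
  alive[1] <- scenario$n_trees
  for (t in seq_len(horizon)) {
    prev <- alive[t]
    alive[t + 1] <- if (rate == 0) prev
      else if (mode == "expected_value") prev * (1 - rate)
      else prev - stats::rbinom(1, prev, rate)
  }
  half_life <- if (rate > 0) population_half_life(rate) else NA_real_
  out <- data.frame(year = years,
                    alive_count = alive,
                    alive_carbon_ktC = alive * kg_per_tree / 1e6,
                    is_half_life_year = !is.na(half_life) & years == half_life)
  attr(out, "half_life_years") <- half_life
  attr(out, "scenario") <- scenario
  attr(out, "mode") <- mode
  class(out) <- c("planting_trajectory", "data.frame")
  out
}

#' @export
print.planting_trajectory <- function(x, ...) {
  sc <- attr(x, "scenario")
  hl <- attr(x, "half_life_years")
  cat(sprintf("Planting scenario: %s trees, %.1f%%/y mortality, %d-year horizon (%s mode)\n",
              format(sc$n_trees, big.mark = ","), 100 * sc$mortality_rate,
              sc$growth_horizon, attr(x, "mode")))
  if (!is.na(hl)) {
    i <- match(hl, x$year)
    if (!is.na(i)) {
      cat(sprintf("  half-life: %d years (%.0f trees alive, %.2f ktC)\n",
                  hl, x$alive_count[i], x$alive_carbon_ktC[i]))
    } else {
      cat(sprintf("  half-life: %d years (beyond horizon)\n", hl))
    }
  }
  final <- nrow(x)
  cat(sprintf("  final year %d: %.0f trees alive, %.2f ktC alive carbon\n",
              x$year[final], x$alive_count[final], x$alive_carbon_ktC[final]))
  invisible(x)
}

#' @export
plot.planting_trajectory <- function(x, ...) {
  graphics::plot(x$year, x$alive_carbon_ktC, type = "l",
                 xlab = "years since planting", ylab = "alive carbon (ktC)",
                 ...)
  hl <- attr(x, "half_life_years")
  if (!is.na(hl) && hl <= max(x$year)) {
    graphics::abline(v = hl, lty = 2)
    graphics::mtext("half-life", at = hl, side = 3, cex = 0.8)
  }
  invisible(x)
}

#' Compare alive-carbon losses with a planting scenario's gain
#'
#' For each land-use class, takes the alive-carbon decline over the window
#' from simulation start to the class's population half-life (clamped to the
#' simulated horizon) and divides it by the scenario's alive carbon at that
#' half-life year. A ratio above 1 means the planting initiative, at the
#' point where half its trees have died, does not compensate the class's
#' loss; the ratio also reads as "how many times larger the initiative would
#' need to be".
#'
#' @param lca_result An [run_lca()] result (its yearly series is used).
#' @param trajectory A [run_planting_scenario()] trajectory.
#' @return A data frame with one row per land-use class: `land_use`,
#'   `half_life_years`, `window_years`, `alive_carbon_decline_ktC`,
#'   `scenario_carbon_at_half_life_ktC`, `compensation_ratio`.
#' @export
compensation_analysis <- function(lca_result, trajectory) {
  stopifnot(inherits(lca_result, "lca_result"),
            inherits(trajectory, "planting_trajectory"))
  yearly <- lca_result$yearly
  classes <- c("street", "mixed", "park")
  rates <- lca_result$mortality$rates
  out <- lapply(classes, function(lu) {
    rate <- rates[[lu]]
    hl <- if (rate > 0) population_half_life(rate) else NA_real_
    if (is.na(hl)) stop("compensation undefined for zero mortality in ", lu)
    if (!hl %in% trajectory$year) {
      stop("trajectory does not cover the half-life year ", hl, " for ", lu)
    }
    window_end <- min(hl, max(yearly$year))
    cls <- yearly[yearly$land_use == lu, ]
    start_c <- cls$alive_ktC[cls$year == 0]
    end_c <- cls$alive_ktC[cls$year == window_end]
    decline <- max(0, start_c - end_c)
    scen <- trajectory$alive_carbon_ktC[trajectory$year == hl]
    data.frame(land_use = lu, half_life_years = hl, window_years = window_end,
               alive_carbon_decline_ktC = decline,
               scenario_carbon_at_half_life_ktC = scen,
               compensation_ratio = if (scen > 0) decline / scen else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
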