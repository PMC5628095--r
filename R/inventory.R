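#' Configuration for the synthetic tree inventory generator
#'
#' The generator emulates the statistical structure of a large remotely
#' sensed city tree inventory (about 1.4 million trees, mean height 15 m,
#' mean DBH 36 cm) so the whole simulation pipeline is testable without that
#' dataset. Species classes are drawn from the canopy fractions of the
#' species registry; land-use classes (street / mixed / park) from
#' `class_proportions`; ages from per-class truncated normal distributions
#' (defaults: means 49/52/56 y, SDs 15/17/15 y, truncated below at 1 y); DBH
#' is then derived from age through the class growth curve, so the growth
#' relationship the simulation depends on is preserved rather than forcing a
#' DBH moment independently.
#'
#' `class_proportions` has no published value; the shipped 0.20/0.45/0.35
#' split is a package default, not a reported quantity.
#'
#' @param n_trees Number of trees to generate.
#' @param species_probabilities Named probabilities per class id; default the
#'   registry canopy fractions (classes 9--10, which lack a fraction, are
#'   reached through the mix class).
#' @param class_proportions Named street/mixed/park fractions summing to 1.
#' @param age_means,age_sds Named per-land-use truncated-normal parameters
#'   (years).
#' @param age_min Lower truncation bound in years (default 1).
#' @param dbh_noise If `TRUE`, add mean-zero normal noise with SD equal to
#'   the class's residual curve error to the generated DBH (floored at 0);
#'   applied once at construction, never per simulated year. The mix class
#'   uses the mean of the ten residual errors.
#' @param include_height Generate a height column from a monotone
#'   height--DBH rule (never used by the carbon computation).
#' @param include_coords Generate uniform planar coordinates.
#' @param seed RNG seed making the inventory reproducible.
#' @param registry A [species_registry()].
#' @return An `inventory_config` list.
#' @export
inventory_config <- function(n_trees = 50000,
                             species_probabilities = NULL,
                             class_proportions = c(street = 0.20, mixed = 0.45,
                                                   park = 0.35),
                             age_means = c(street = 49, mixed = 52, park = 56),
                             age_sds = c(street = 15, mixed = 17, park = 15),
                             age_min = 1,
                             dbh_noise = FALSE,
                             include_height = TRUE,
                             include_coords = FALSE,
                             seed = 1L,
                             registry = species_registry()) {
  if (is.null(species_probabilities)) {
    cf <- registry$canopy_fraction_pct
    keep <- !is.na(cf)
    species_probabilities <- stats::setNames(cf[keep] / sum(cf[keep]),
                                             registry$class_id[keep])
  }
  cfg <- list(n_trees = n_trees,
              species_probabilities = species_probabilities,
              class_proportions = class_proportions,
              age_means = age_means, age_sds = age_sds, age_min = age_min,
              dbh_noise = dbh_noise,
              include_height = include_height,
              include_coords = include_coords,
              seed = as.integer(seed))
  validate_inventory_config(cfg)
  class(cfg) <- "inventory_config"
  cfg
}

validate_inventory_config <- function(cfg) {
  if (!is.numeric(cfg$n_trees) || cfg$n_trees < 0) {
    stop("invalid field 'n_trees': must be a count >= 0")
  }
  sp <- cfg$species_probabilities
  if (is.null(names(sp)) || any(sp < 0) || abs(sum(sp) - 1) > 1e-9) {
    stop("invalid field 'species_probabilities': named, non-negative, sum 1")
  }
  cp <- cfg$class_proportions
  if (!setequal(names(cp), c("street", "mixed", "park")) ||
      any(cp < 0) || abs(sum(cp) - 1) > 1e-9) {
    stop("invalid field 'class_proportions': street/mixed/park summing to 1")
  }
  for (fld in c("age_means", "age_sds")) {
    v <- cfg[[fld]]
    if (!setequal(names(v), c("street", "mixed", "park"))) {
      stop("invalid field '", fld, "': needs street/mixed/park entries")
    }
  }
  if (any(cfg$age_sds <= 0)) stop("invalid field 'age_sds': SDs must be > 0")
  if (cfg$age_min < 0) stop("invalid field 'age_min': must be >= 0")
  invisible(cfg)
}

# Truncated normal (lower bound only) by inverse-CDF sampling.
rtruncnorm_lower <- function(n, mean, sd, lower) {
  p_lo <- stats::pnorm(lower, mean, sd)
  stats::qnorm(stats::runif(n, p_lo, 1), mean, sd)
}

empty_inventory <- function(include_height, include_coords) {
  inv <- data.frame(tree_id = integer(0), species_class = character(0),
                    land_use = character(0), age = numeric(0),
                    dbh = numeric(0), stringsAsFactors = FALSE)
  if (include_height) inv$height <- numeric(0)
  if (include_coords) { inv$x <- numeric(0); inv$y <- numeric(0) }
  inv$alive <- logical(0)
  inv$death_year <- integer(0)
  class(inv) <- c("tree_inventory", "data.frame")
  inv
}

#' Generate a synthetic tree inventory
#'
#' Draws a per-tree inventory under an [inventory_config()]: species class,
#' land-use class, age and curve-derived DBH, optional height and
#' coordinates. All generated trees are alive with no death year. The same
#' seed yields an identical inventory.
#'
#' @param config An [inventory_config()].
#' @param registry A [species_registry()].
#' @return A `tree_inventory` data frame.
#' @export
generate_inventory <- function(config, registry = species_registry()) {
  stopifnot(inherits(config, "inventory_config"))
  validate_inventory_config(config)
  n <- as.integer(config$n_trees)
  if (n == 0L) {
    return(empty_inventory(config$include_height, config$include_coords))
  }
  set.seed(config$seed)
  species <- sample(names(config$species_probabilities), n, replace = TRUE,
                    prob = config$species_probabilities)
  land_use <- sample(names(config$class_proportions), n, replace = TRUE,
                     prob = config$class_proportions)
  age <- numeric(n)
  for (lu in unique(land_use)) {
    idx <- land_use == lu
    age[idx] <- rtruncnorm_lower(sum(idx), config$age_means[[lu]],
                                 config$age_sds[[lu]], config$age_min)
  }
  dbh <- numeric(n)
  resid <- numeric(n)
  mean_resid <- mean(growth_classes(registry)$residual_error_cm)
  for (sp in unique(species)) {
    idx <- species == sp
    if (sp == "mix") {
      dbh[idx] <- mix_dbh_at_age(registry, age[idx])
      resid[idx] <- mean_resid
    } else {
      row <- species_class(registry, sp)
      dbh[idx] <- dbh_at_age(row, age[idx])
      resid[idx] <- row$residual_error_cm
    }
  }
  if (isTRUE(config$dbh_noise)) {
    dbh <- pmax(0, dbh + stats::rnorm(n, 0, resid))
  }
  inv <- data.frame(tree_id = seq_len(n), species_class = species,
                    land_use = land_use, age = age, dbh = dbh,
                    stringsAsFactors = FALSE)
  if (config$include_height) {
    # monotone height-DBH rule, cosmetic only (carbon path is DBH-only)
    inv$height <- 1.3 + 20 * (1 - exp(-0.04 * dbh))
  }
  if (config$include_coords) {
    inv$x <- stats::runif(n, 0, 30000)
    inv$y <- stats::runif(n, 0, 30000)
  }
  inv$alive <- TRUE
  inv$death_year <- NA_integer_
  class(inv) <- c("tree_inventory", "data.frame")
  inv
}

#' Summarise a tree inventory
#'
#' Exact arithmetic summaries: counts, mean age overall and per land-use
#' class, mean DBH, and species frequencies. An empty inventory yields an
#' explicit empty summary rather than an error.
#'
#' @param inventory A `tree_inventory`.
#' @return An `inventory_summary` list.
#' @export
summarize_inventory <- function(inventory) {
  if (nrow(inventory) == 0L) {
    out <- list(n_trees = 0L, n_alive = 0L, mean_age = NA_real_,
                mean_dbh = NA_real_, mean_age_by_class = numeric(0),
                species_frequencies = numeric(0))
    class(out) <- "inventory_summary"
    return(out)
  }
  out <- list(
    n_trees = nrow(inventory),
    n_alive = sum(inventory$alive),
    mean_age = mean(inventory$age),
    mean_dbh = mean(inventory$dbh),
    mean_age_by_class = tapply(inventory$age, inventory$land_use, mean),
    species_frequencies = table(inventory$species_class) / nrow(inventory))
  class(out) <- "inventory_summary"
  out
}

#' @export
summary.tree_inventory <- function(object, ...) summarize_inventory(object)

#' @export
print.inventory_summary <- function(x, ...) {
  cat("Tree inventory:", x$n_trees, "trees (", x$n_alive, "alive )\n")
  if (x$n_trees > 0) {
    cat(sprintf("  mean age %.1f y, mean DBH %.1f cm\n", x$mean_age, x$mean_dbh))
    cat("  mean age by land use:\n")
    for (lu in names(x$mean_age_by_class)) {
      cat(sprintf("    %-6s %.1f y\n", lu, x$mean_age_by_class[[lu]]))
    }
  }
  invisible(x)
}

#' @export
print.tree_inventory <- function(x, n = 6L, ...) {
  cat("Tree inventory:", nrow(x), "trees\n")
  print.data.frame(utils::head(x, n), row.names = FALSE, ...)
  if (nrow(x) > n) cat("... and", nrow(x) - n, "more rows\n")
  invisible(x)
}

inventory_columns <- c("tree_id", "species_class", "land_use", "age", "dbh")

#' Read a tree inventory from CSV
#'
#' Validates invariants row by row (non-negative age and DBH, known land-use
#' labels, dead trees carry a death year and alive trees do not) and reports
#' offending line numbers. Optional columns (`height`, `x`, `y`, `alive`,
#' `death_year`) are filled with defaults when absent.
#'
#' @param path CSV path.
#' @return A `tree_inventory`.
#' @export
read_inventory <- function(path) {
  if (!file.exists(path)) stop("inventory file not found: ", path)
  inv <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(species_class = "character"))
  missing_cols <- setdiff(inventory_columns, names(inv))
  if (length(missing_cols)) {
    stop("inventory lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!"alive" %in% names(inv)) inv$alive <- TRUE
  if (!"death_year" %in% names(inv)) inv$death_year <- NA_integer_
  line_of <- function(i) i + 1L   # header occupies line 1
  bad <- which(!is.finite(inv$age) | inv$age < 0)
  if (length(bad)) stop("invalid age at line ", line_of(bad[1]))
  bad <- which(!is.finite(inv$dbh) | inv$dbh < 0)
  if (length(bad)) stop("invalid dbh at line ", line_of(bad[1]))
  bad <- which(!inv$land_use %in% c("street", "mixed", "park"))
  if (length(bad)) stop("unknown land_use at line ", line_of(bad[1]))
  bad <- which(!inv$alive & is.na(inv$death_year))
  if (length(bad)) stop("dead tree without death_year at line ", line_of(bad[1]))
  bad <- which(inv$alive & !is.na(inv$death_year))
  if (length(bad)) stop("alive tree with death_year at line ", line_of(bad[1]))
  class(inv) <- c("tree_inventory", "data.frame")
  inv
}

#' Write a tree inventory to CSV
#'
#' @param inventory A `tree_inventory`.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_inventory <- function(inventory, path) {
  utils::write.csv(as.data.frame(inventory), path, row.names = FALSE, na = "")
  invisible(path)
}
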