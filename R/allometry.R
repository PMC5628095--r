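#' Load an allometric biomass table
#'
#' Allometric models convert a tree's DBH (cm) to above-ground dry biomass
#' (kg). Species-specific urban equations vary widely between studies, so the
#' table is pluggable: the packaged default ships two generic temperate
#' power laws (`biomass = a * dbh^c`), one broadleaf and one conifer
#' parameterisation. These defaults are package choices for a self-contained
#' simulation, not values from any single study; users reproducing a specific
#' assessment should supply their own table keyed by the registry's
#' `allometry_key` column.
#'
#' @param path Path to a replacement CSV with columns `allometry_key`,
#'   `form`, `coeff_a`, `exponent_c`, `dbh_min_cm`, `dbh_max_cm`, `source`.
#'   `NULL` loads the packaged default.
#' @return An `allometry_table` data frame, one row per model.
#' @export
allometry_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "allometry_default.csv", package = "urbancarbon")
  }
  if (!file.exists(path)) stop("allometry table not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("allometry_key", "form", "coeff_a", "exponent_c",
              "dbh_min_cm", "dbh_max_cm", "source")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols)) {
    stop("allometry table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(tab$allometry_key)) stop("duplicate allometry_key values")
  if (!all(tab$form == "power_law")) {
    stop("only power_law allometric models are supported")
  }
  if (any(tab$coeff_a <= 0) || any(tab$exponent_c <= 0)) {
    stop("power-law coefficients must be positive")
  }
  class(tab) <- c("allometry_table", "data.frame")
  tab
}

#' @export
print.allometry_table <- function(x, ...) {
  cat("Allometry table:", nrow(x), "model(s)\n")
  print.data.frame(x[, c("allometry_key", "form", "coeff_a", "exponent_c")],
                   row.names = FALSE, ...)
  invisible(x)
}

#' Resolve an allometry key to its model row
#'
#' @param table An [allometry_table()].
#' @param key Key to look up.
#' @return A one-row `allometry_table`.
#' @export
resolve_allometry <- function(table, key) {
  row <- table[table$allometry_key == key, , drop = FALSE]
  if (nrow(row) != 1L) stop("unresolved allometry_key: ", key)
  row
}

#' Check that every registry key resolves in an allometry table
#'
#' The mix key resolves through the ten class models rather than a row of its
#' own.
#'
#' @param table An [allometry_table()].
#' @param registry A [species_registry()].
#' @return Invisibly `TRUE`; errors on the first unresolved key.
#' @export
check_allometry_keys <- function(table, registry) {
  keys <- setdiff(unique(registry$allometry_key), "mix")
  for (key in keys) resolve_allometry(table, key)
  invisible(TRUE)
}

#' Above-ground dry biomass from DBH
#'
#' Evaluates the power law `a * dbh^c`. Diameters outside the model's stated
#' validity range are still evaluated (so totals stay smooth) but reported
#' with a warning.
#'
#' @param model A one-row allometric model (from [resolve_allometry()]).
#' @param dbh DBH in cm; vectorised; >= 0.
#' @param warn_range Warn when diameters fall outside the validity range.
#' @return Biomass in kg dry matter.
#' @export
biomass_from_dbh <- function(model, dbh, warn_range = TRUE) {
  if (!is.numeric(dbh) || any(!is.finite(dbh)) || any(dbh < 0)) {
    stop("dbh must be finite and >= 0")
  }
  if (warn_range) {
    out <- dbh < model$dbh_min_cm | dbh > model$dbh_max_cm
    if (any(out)) {
      warning(sum(out), " dbh value(s) outside the validity range [",
              model$dbh_min_cm, ", ", model$dbh_max_cm, "] cm of '",
              model$allometry_key, "'; evaluated anyway")
    }
  }
  model$coeff_a * dbh^model$exponent_c
}

#' Mix-class biomass from DBH
#'
#' Mix-class trees take the unweighted mean of the ten dominant-class biomass
#' estimates at the same DBH (average of biomasses, not biomass of an
#' averaged model).
#'
#' @param table An [allometry_table()].
#' @param dbh DBH in cm; vectorised.
#' @param registry A [species_registry()] supplying the ten class keys.
#' @param warn_range Warn on out-of-range diameters.
#' @return Biomass in kg dry matter.
#' @export
mix_biomass_from_dbh <- function(table, dbh, registry = species_registry(),
                                 warn_range = FALSE) {
  cls <- growth_classes(registry)
  vals <- vapply(cls$allometry_key, function(key) {
    biomass_from_dbh(resolve_allometry(table, key), dbh, warn_range = warn_range)
  }, numeric(length(dbh)))
  if (length(dbh) == 1L) mean(vals) else rowMeans(vals)
}

#' Carbon content of dry biomass
#'
#' Above-ground dry biomass is converted to carbon with a fixed fraction,
#' 0.5 by default, the standard factor for woody biomass.
#'
#' @param biomass Dry biomass in kg; vectorised; >= 0.
#' @param fraction Carbon fraction of dry biomass, in (0, 1].
#' @return Carbon in kg C.
#' @export
carbon_from_biomass <- function(biomass, fraction = 0.5) {
  if (!is.numeric(biomass) || any(!is.finite(biomass)) || any(biomass < 0)) {
    stop("biomass must be finite and >= 0")
  }
  if (fraction <= 0 || fraction > 1) stop("carbon fraction must be in (0, 1]")
  fraction * biomass
}
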