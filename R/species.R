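#' Load the species growth-class registry
#'
#' Reads the packaged table of diameter growth curves for the ten dominant
#' urban tree species classes plus the residual "mix" class. Classes 1--10
#' carry a nonlinear DBH--age curve of one of two families: a saturating
#' Chapman--Richards form \eqn{A (1 - e^{-k\,age})^p} or a Gompertz form
#' \eqn{A e^{-b e^{-k\,age}}}, both bounded above by the asymptote \eqn{A}
#' (cm). The mix class has no coefficients of its own; it is modelled as the
#' average of the ten class curves (see [mix_dbh_at_age()]).
#'
#' Each row also carries the curve's residual error (cm), the class's fraction
#' of the total tree canopy (percent; absent for classes 9--10, which are
#' folded into the mix fraction), and an `allometry_key` naming the biomass
#' model to use for the class (see [allometry_table()]).
#'
#' @param path Path to a replacement species table CSV with the same columns
#'   as the packaged one (`class_id`, `label`, `family`, `A`, `k`, `p`, `b`,
#'   `residual_error_cm`, `canopy_fraction_pct`, `allometry_key`). `NULL`
#'   (default) loads the packaged registry.
#' @return A `species_registry`, a data frame with one row per class.
#' @examples
#' reg <- species_registry()
#' dbh_at_age(species_class(reg, "7"), 52)
#' @export
species_registry <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "species_growth.csv", package = "urbancarbon")
  }
  if (!file.exists(path)) stop("species table not found: ", path)
  reg <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(class_id = "character"))
  validate_species_registry(reg)
  class(reg) <- c("species_registry", "data.frame")
  reg
}

validate_species_registry <- function(reg) {
  needed <- c("class_id", "label", "family", "A", "k", "p", "b",
              "residual_error_cm", "canopy_fraction_pct", "allometry_key")
  missing_cols <- setdiff(needed, names(reg))
  if (length(missing_cols)) {
    stop("species table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(reg$class_id)) stop("species table has duplicate class_id values")
  if (!all(reg$family %in% c("saturating", "gompertz", "mix"))) {
    stop("unknown growth family in species table")
  }
  curves <- reg[reg$family != "mix", ]
  if (any(!is.finite(curves$A) | curves$A <= 0)) stop("asymptote A must be > 0")
  if (any(!is.finite(curves$k) | curves$k <= 0)) stop("rate k must be > 0")
  sat <- curves[curves$family == "saturating", ]
  gom <- curves[curves$family == "gompertz", ]
  if (any(!is.finite(sat$p) | sat$p <= 0)) stop("shape p must be > 0 for saturating curves")
  if (any(!is.finite(gom$b) | gom$b <= 0)) stop("offset b must be > 0 for gompertz curves")
  cf <- reg$canopy_fraction_pct
  if (abs(sum(cf[!is.na(cf)]) - 100) > 0.1) {
    stop("canopy fractions present must sum to 100 +/- 0.1, got ",
         sum(cf[!is.na(cf)]))
  }
  invisible(reg)
}

#' Extract one species class from a registry
#'
#' @param registry A [species_registry()].
#' @param class_id Class identifier (`"1"`..`"10"` or `"mix"`); integers are
#'   accepted and converted.
#' @return A one-row `species_registry` data frame.
#' @export
species_class <- function(registry, class_id) {
  stopifnot(inherits(registry, "species_registry"))
  id <- as.character(class_id)
  row <- registry[registry$class_id == id, , drop = FALSE]
  if (nrow(row) != 1L) stop("unknown species class_id: ", id)
  row
}

#' @export
print.species_registry <- function(x, ...) {
  cat("Species growth registry:", nrow(x), "classes\n")
  shown <- data.frame(class_id = x$class_id, family = x$family,
                      A_cm = x$A, k = x$k,
                      canopy_pct = x$canopy_fraction_pct)
  print.data.frame(shown, row.names = FALSE, ...)
  invisible(x)
}

# Curve kernel shared by the forward and inverse operations; `species` is a
# one-row registry slice.
growth_eval <- function(species, age) {
  switch(species$family,
         saturating = species$A * (1 - exp(-species$k * age))^species$p,
         gompertz   = species$A * exp(-species$b * exp(-species$k * age)),
         stop("species class '", species$class_id,
              "' has no curve of its own; use mix_dbh_at_age()"))
}

#' Diameter at breast height predicted at a given age
#'
#' Evaluates the class's growth curve. The saturating family passes through
#' DBH 0 at age 0; the Gompertz family starts at the small positive value
#' \eqn{A e^{-b}}. Both are strictly increasing in age and approach the
#' asymptote \eqn{A} from below.
#'
#' @param species A one-row species class (from [species_class()]).
#' @param age Age in years; vectorised; must be >= 0.
#' @return DBH in cm.
#' @seealso [age_from_dbh()] for the inverse, [mix_dbh_at_age()] for the mix
#'   class.
#' @export
dbh_at_age <- function(species, age) {
  if (!is.numeric(age) || any(!is.finite(age)) || any(age < 0)) {
    stop("age must be finite and >= 0")
  }
  if (species$family == "mix") {
    stop("mix class has no curve of its own; use mix_dbh_at_age()")
  }
  growth_eval(species, age)
}

#' Age recovered from a diameter by closed-form curve inversion
#'
#' Inverts the class's growth curve: for the saturating family
#' \eqn{age = -\ln(1 - (dbh/A)^{1/p})/k}, for the Gompertz family
#' \eqn{age = -\ln(-\ln(dbh/A)/b)/k}. Round-trips with [dbh_at_age()] to
#' within 1e-6 years over the curve's range.
#'
#' Diameters at or above the asymptote are not attainable at finite age.
#' Under `policy = "cap"` (default) such trees are assigned the age at which
#' the curve reaches \eqn{(1-\epsilon) A}, with a warning, so that real large
#' trees remain usable while the distortion stays visible; `policy = "strict"`
#' raises an error instead. Gompertz diameters below the age-0 value
#' \eqn{A e^{-b}} are clamped to age 0 with a warning.
#'
#' @param species A one-row species class.
#' @param dbh DBH in cm; vectorised; must be >= 0.
#' @param policy `"cap"` or `"strict"`, the above-asymptote policy.
#' @param cap_epsilon Fraction of the asymptote left unreached when capping
#'   (default 1e-3).
#' @return Age in years.
#' @export
age_from_dbh <- function(species, dbh, policy = c("cap", "strict"),
                         cap_epsilon = 1e-3) {
  policy <- match.arg(policy)
  if (!is.numeric(dbh) || any(!is.finite(dbh)) || any(dbh < 0)) {
    stop("dbh must be finite and >= 0")
  }
  if (species$family == "mix") {
    stop("mix class has no closed-form inverse; use mix_age_from_dbh()")
  }
  A <- species$A
  over <- dbh >= A
  if (any(over)) {
    if (policy == "strict") {
      stop("dbh ", max(dbh), " cm is at/above the asymptote ", A,
           " cm for class ", species$class_id)
    }
    warning(sum(over), " dbh value(s) at/above the asymptote for class ",
            species$class_id, "; age capped at DBH = (1 - ", cap_epsilon,
            ") * A")
    dbh[over] <- (1 - cap_epsilon) * A
  }
  if (species$family == "saturating") {
    -log(1 - (dbh / A)^(1 / species$p)) / species$k
  } else {
    floor_dbh <- A * exp(-species$b)
    under <- dbh < floor_dbh
    if (any(under)) {
      warning(sum(under), " dbh value(s) below the age-0 diameter ",
              signif(floor_dbh, 4), " cm for class ", species$class_id,
              "; age clamped to 0")
      dbh[under] <- floor_dbh
    }
    -log(-log(dbh / A) / species$b) / species$k
  }
}

growth_classes <- function(registry) {
  registry[registry$family != "mix", , drop = FALSE]
}

mix_weights <- function(registry, weighted) {
  cls <- growth_classes(registry)
  if (!weighted) return(rep(1 / nrow(cls), nrow(cls)))
  w <- cls$canopy_fraction_pct
  w[is.na(w)] <- 0
  if (sum(w) <= 0) stop("no canopy fractions available for weighting")
  w / sum(w)
}

#' Mix-class diameter at a given age
#'
#' The mix class (unclassifiable species, 26.5 percent of the canopy) is
#' modelled as the average of the ten dominant-class curves. The default is
#' the unweighted arithmetic mean of the curve outputs; `weighted = TRUE`
#' weights by canopy fraction instead (classes without a printed fraction get
#' weight 0).
#'
#' @param registry A [species_registry()].
#' @param age Age in years; vectorised; >= 0.
#' @param weighted Use canopy-fraction weights instead of the plain mean.
#' @return DBH in cm.
#' @export
mix_dbh_at_age <- function(registry, age, weighted = FALSE) {
  if (!is.numeric(age) || any(!is.finite(age)) || any(age < 0)) {
    stop("age must be finite and >= 0")
  }
  cls <- growth_classes(registry)
  w <- mix_weights(registry, weighted)
  vals <- vapply(seq_len(nrow(cls)),
                 function(i) growth_eval(cls[i, ], age),
                 numeric(length(age)))
  if (length(age) == 1L) sum(vals * w) else as.numeric(vals %*% w)
}

#' Age recovered from a diameter on the mix curve
#'
#' The averaged curve has no closed-form inverse; the unique root of
#' `mix_dbh_at_age(age) = dbh` is found by bracketed root finding to a
#' diameter tolerance of 1e-6 cm. Diameters outside the attainable range are
#' handled with the same cap/clamp policy as [age_from_dbh()]: above the
#' averaged asymptote the age is capped at the age reaching
#' \eqn{(1-\epsilon)} of it, below the age-0 value the age is clamped to 0,
#' each with a warning.
#'
#' @inheritParams mix_dbh_at_age
#' @param dbh DBH in cm; vectorised.
#' @param policy `"cap"` or `"strict"`.
#' @param cap_epsilon Fraction of the averaged asymptote left unreached when
#'   capping.
#' @param tol Diameter tolerance of the root search, cm.
#' @return Age in years.
#' @export
mix_age_from_dbh <- function(registry, dbh, weighted = FALSE,
                             policy = c("cap", "strict"),
                             cap_epsilon = 1e-3, tol = 1e-6) {
  policy <- match.arg(policy)
  if (!is.numeric(dbh) || any(!is.finite(dbh)) || any(dbh < 0)) {
    stop("dbh must be finite and >= 0")
  }
  cls <- growth_classes(registry)
  w <- mix_weights(registry, weighted)
  sup <- sum(cls$A * w)                      # supremum of the averaged curve
  floor_dbh <- mix_dbh_at_age(registry, 0, weighted = weighted)
  over <- dbh >= sup
  if (any(over)) {
    if (policy == "strict") {
      stop("dbh at/above the averaged asymptote ", signif(sup, 6), " cm")
    }
    warning(sum(over), " dbh value(s) at/above the averaged asymptote; ",
            "age capped at DBH = (1 - ", cap_epsilon, ") * asymptote")
    dbh[over] <- (1 - cap_epsilon) * sup
  }
  under <- dbh < floor_dbh
  if (any(under)) {
    if (any(dbh[under] > 0)) {
      warning(sum(under), " dbh value(s) below the mix age-0 diameter ",
              signif(floor_dbh, 4), " cm; age clamped to 0")
    } else {
      warning("dbh 0 is below the mix age-0 diameter; age clamped to 0")
    }
  }
  solve_one <- function(d) {
    if (d <= floor_dbh) return(0)
    upper <- 100
    while (mix_dbh_at_age(registry, upper, weighted = weighted) < d) {
      upper <- upper * 2
      if (upper > 1e7) stop("root bracket expansion failed")
    }
    # age tolerance 1e-10 keeps the diameter residual far below `tol` cm
    root <- stats::uniroot(
      function(a) mix_dbh_at_age(registry, a, weighted = weighted) - d,
      lower = 0, upper = upper, tol = 1e-10)
    if (abs(root$f.root) > tol) {
      stop("mix inverse did not reach the diameter tolerance")
    }
    root$root
  }
  vapply(dbh, solve_one, numeric(1))
}
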