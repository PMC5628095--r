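# Shared fixtures: the packaged tables are cheap to load once per file.
REG <- species_registry()
ALLO <- allometry_table()

# Independent brute-force bisection inverse of a single-class growth curve,
# kept deliberately separate from the closed-form inverses under test.
bisect_age <- function(species, dbh, lo = 0, hi = 5000, tol = 1e-8) {
  f <- function(a) dbh_at_age(species, a) - dbh
  stopifnot(f(lo) <= 0, f(hi) >= 0)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Small deterministic inventory for engine tests.
small_inventory <- function(n = 300, seed = 42, ...) {
  generate_inventory(inventory_config(n_trees = n, seed = seed, ...), REG)
}

# Hand-built homogeneous inventory (single class/land use) for closed-form
# checks.
uniform_inventory <- function(n, species = "8", land_use = "mixed", age = 30) {
  inv <- data.frame(tree_id = seq_len(n), species_class = species,
                    land_use = land_use, age = age,
                    dbh = dbh_at_age(species_class(REG, species), age),
                    alive = TRUE, death_year = NA_integer_,
                    stringsAsFactors = FALSE)
  class(inv) <- c("tree_inventory", "data.frame")
  inv
}
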