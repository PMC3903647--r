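# Shared fixtures, built once per test run.

DEMO_SEED <- 1L

.demo_cache <- new.env(parent = emptyenv())

demo_landscape <- function() {
  if (is.null(.demo_cache$land))
    .demo_cache$land <- generate_landscape(grid_spec(60, 60), seed = DEMO_SEED)
  .demo_cache$land
}

demo_classification <- function() {
  if (is.null(.demo_cache$cl))
    .demo_cache$cl <- classify_landscape(demo_landscape())
  .demo_cache$cl
}

demo_incidence <- function() {
  if (is.null(.demo_cache$inc)) {
    cl <- demo_classification()
    .demo_cache$inc <- build_incidence(cl$class_maps, cl$full_bins)
  }
  .demo_cache$inc
}

demo_networks <- function() {
  if (is.null(.demo_cache$nets)) {
    cfg <- solver_config(n_runs = 5, n_iterations = 30000,
                         n_temp_decreases = 300, n_probe = 300, seed = 7)
    .demo_cache$nets <- design_nested(demo_incidence(),
                                      species_statuses(demo_landscape()), cfg)
  }
  .demo_cache$nets
}

# a small solver test configuration
tiny_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_runs = 20L, n_iterations = 2000L, n_temp_decreases = 100L,
         n_probe = 200L, audit_every = 500L, seed = 1L),
    list(...))
  do.call(solver_config, args)
}

# random small solver instance (units x features incidence + targets)
random_instance <- function(max_units = 15, max_features = 6, max_target = 2) {
  n_u <- sample(4:max_units, 1)
  n_f <- sample(2:max_features, 1)
  m <- matrix(stats::runif(n_u * n_f) < 0.35, n_u, n_f)
  list(inc = as_feature_incidence(m),
       targets = sample(0:max_target, n_f, replace = TRUE))
}

# grid with explicit values (NA = nodata)
grid_from <- function(v) suitability_grid(v)

# binary map straight from a logical matrix
bin_from <- function(m) {
  structure(list(presence = m, tau = NA_real_, provenance = NULL),
            class = "binary_map")
}
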