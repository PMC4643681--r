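# Shared fixtures for the test suite. Everything is built in code; grids are
# kept small so the whole suite stays fast.

tiny_grid <- function(shape = c(5, 5, 5), spacing = 2) volume_grid(shape, spacing)

random_scalar <- function(grid, seed) {
  set.seed(seed)
  scalar_volume(array(rnorm(prod(grid$shape)), grid$shape), grid)
}

random_mask <- function(grid, seed, p = 0.3) {
  set.seed(seed)
  mask_volume(array(runif(prod(grid$shape)) < p, grid$shape), grid)
}

# A record with a given set of features present (presence credit only).
record_with_present <- function(ids) {
  reg <- figure_elements()
  drawing_record(data.frame(element_id = reg$element_id,
                            present = reg$element_id %in% ids,
                            shape_correct = FALSE, placement_correct = FALSE))
}

# Small cached asymmetric cohort (no images) for table-level tests.
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_cohort(cohort_spec(n_patients = 15, n_controls = 5, seed = 11),
                                include_images = FALSE)
    cache
  }
})
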