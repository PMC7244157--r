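# Geometric fixtures and cached simulations shared across test files.

disk_mask <- function(r, n = 2 * r + 5, center = c((n + 1) / 2, (n + 1) / 2)) {
  outer(seq_len(n), seq_len(n), function(i, j) {
    sqrt((i - center[1])^2 + (j - center[2])^2) <= r
  })
}

two_disk_mask <- function(r, sep, n = 4 * r + sep + 10) {
  c1 <- c(n / 2, n / 2 - sep / 2)
  c2 <- c(n / 2, n / 2 + sep / 2)
  disk_mask(r, n, c1) | disk_mask(r, n, c2)
}

# A clean small simulation (no degradations) reused by several files.
.sim_cache <- new.env(parent = emptyenv())
cached_sim <- function(key, spec) {
  if (is.null(.sim_cache[[key]])) {
    .sim_cache[[key]] <- simulate_cytospin(spec)
  }
  .sim_cache[[key]]
}

clean_spec <- function(n_cells = 12, rng_seed = 3, ...) {
  synthetic_spec(
    n_cells = n_cells, image_size = c(420, 420), rng_seed = rng_seed,
    frac_burst_nuclei = 0, frac_burst_bodies = 0, frac_clumped_pairs = 0,
    frac_border_touching = 0, ...
  )
}
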