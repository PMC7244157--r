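test_that("a single seed claims all reachable uniform foreground", {
  seeds <- matrix(0L, 20, 20)
  seeds[10, 10] <- 1L
  mask <- matrix(FALSE, 20, 20)
  mask[4:17, 4:17] <- TRUE
  lab <- propagate_secondary(seeds, matrix(0.5, 20, 20),
                             secondary_params(fill_holes = FALSE), mask = mask)
  expect_true(all(lab[mask] == 1L))
  expect_true(all(lab[!mask & !(seeds > 0)] == 0L))
})

test_that("uniform-intensity propagation equals nearest-seed geodesic partition", {
  seeds <- matrix(0L, 30, 30)
  seeds[8, 8] <- 1L
  seeds[22, 22] <- 2L
  int <- matrix(0.4, 30, 30)
  mask <- matrix(TRUE, 30, 30)
  p <- secondary_params(regularization_lambda = 0.1, fill_holes = FALSE)
  lab <- propagate_secondary(seeds, int, p, mask = mask)
  expect_equal(lab, oracle_propagate(seeds, int, mask, 0.1))
  # with uniform intensity the partition is by Euclidean-like geodesic
  # distance: each seed's own pixel neighbourhood belongs to it
  expect_true(all(lab[1:10, 1:10] == 1L))
  expect_true(all(lab[20:30, 20:30] == 2L))
})

test_that("with lambda 0 the dividing line follows a dark ridge", {
  n <- 31
  seeds <- matrix(0L, n, n)
  seeds[16, 4] <- 1L
  seeds[16, 28] <- 2L
  int <- matrix(0.8, n, n)
  int[, 12] <- 0.05  # dark ridge, nearer seed 1 than the midline
  mask <- matrix(TRUE, n, n)
  lab <- propagate_secondary(seeds, int,
                             secondary_params(regularization_lambda = 0,
                                              fill_holes = FALSE),
                             mask = mask)
  expect_equal(lab, oracle_propagate(seeds, int, mask, 0))
  # crossing the ridge costs ~0.75 twice; flat walks cost 0, so seed 2
  # claims everything up to the ridge despite seed 1 being closer
  expect_true(all(lab[, 13:27] == 2L))
})

test_that("large lambda converges to the pure nearest-seed partition", {
  set.seed(41)
  n <- 40
  seeds <- matrix(0L, n, n)
  seeds[10, 10] <- 1L
  seeds[30, 32] <- 2L
  int <- matrix(runif(n * n), n, n)
  mask <- matrix(TRUE, n, n)
  lab_big <- propagate_secondary(seeds, int,
                                 secondary_params(regularization_lambda = 1e6,
                                                  fill_holes = FALSE),
                                 mask = mask)
  lab_geo <- propagate_secondary(seeds, matrix(0, n, n),
                                 secondary_params(regularization_lambda = 1,
                                                  fill_holes = FALSE),
                                 mask = mask)
  expect_gt(mean(lab_big == lab_geo), 0.99)
})

test_that("propagation equals the brute-force shortest-path oracle on random images", {
  set.seed(42)
  for (i in 1:6) {
    h <- sample(20:40, 1); w <- sample(20:40, 1)
    int <- matrix(runif(h * w), h, w)
    mask <- matrix(runif(h * w) < 0.85, h, w)
    seeds <- matrix(0L, h, w)
    for (s in seq_len(sample(2:4, 1))) {
      seeds[sample(h, 1), sample(w, 1)] <- s
    }
    for (lambda in c(0, 0.1, 1)) {
      lab <- propagate_secondary(seeds, int,
                                 secondary_params(regularization_lambda = lambda,
                                                  fill_holes = FALSE),
                                 mask = mask)
      expect_identical(lab, oracle_propagate(seeds, int, mask | seeds > 0, lambda))
    }
  }
})

test_that("bodies contain their seeds, stay disjoint and keep seed labels", {
  sim <- cached_sim("clean12", clean_spec())
  cfg <- pipeline_config()
  nuclei <- segment_nuclei(sim$image$channels$DAPI, cfg$primary)
  bodies <- propagate_secondary(nuclei, sim$image$channels$VIME, cfg$secondary)
  ids <- sort(setdiff(unique(as.integer(nuclei)), 0L))
  expect_setequal(sort(setdiff(unique(as.integer(bodies)), 0L)), ids)
  for (L in ids) {
    expect_true(all(bodies[nuclei == L] == L))  # body contains its seed
  }
})

test_that("no seeds yields an empty labeling with a warning", {
  expect_warning(
    lab <- propagate_secondary(matrix(0L, 10, 10), matrix(0.5, 10, 10),
                               secondary_params()),
    "no seeds"
  )
  expect_true(all(lab == 0L))
})

test_that("intact-cell filter applies the area, shape and intensity cut-offs", {
  body_tab <- tibble::tibble(
    label = 1:5,
    area = c(27, 28, 100, 100, 100),
    form_factor = c(0.9, 0.9, 0.34, 0.36, 0.9),
    mean_VIME = c(0.5, 0.5, 0.5, 0.5, 0)
  )
  nuc_tab <- tibble::tibble(label = 1:5)
  bodies <- matrix(0L, 6, 30)
  for (L in 1:5) bodies[2:4, (L * 5 - 3):(L * 5 - 1)] <- L
  out <- filter_intact_cells(bodies, body_tab, nuc_tab, secondary_params())
  # area 27 removed / 28 kept; FF 0.34 removed / 0.36 kept; VIME 0 removed
  expect_equal(out$nuclei$has_intact_body, c(FALSE, TRUE, FALSE, TRUE, FALSE))
  expect_setequal(setdiff(unique(as.integer(out$bodies)), 0L), c(2L, 4L))
  # body label without parent nucleus is an internal consistency error
  expect_error(filter_intact_cells(bodies, body_tab, nuc_tab[1:3, ],
                                   secondary_params()),
               "parent")
})

test_that("a burst-body cell ends without an intact body", {
  sim <- cached_sim("burstbody", synthetic_spec(
    n_cells = 8, image_size = c(420, 420), rng_seed = 13,
    frac_burst_nuclei = 0, frac_burst_bodies = 0.25, frac_clumped_pairs = 0,
    frac_border_touching = 0
  ))
  res <- run_pipeline(sim$image, pipeline_config())
  truth <- sim$truth$expected_counts
  expect_equal(res$counts$n_real_cells, truth$real_cells)
  expect_equal(res$counts$n_real_nuclei, sim$spec$n_cells)  # nuclei intact
})
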