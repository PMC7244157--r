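test_that("expected counts follow the spec arithmetic and nesting rules", {
  sim <- cached_sim("clean100", synthetic_spec(
    n_cells = 100, frac_sox10_pos = 0.7, frac_edu_pos_given_sox10 = 0.5,
    frac_burst_nuclei = 0, frac_burst_bodies = 0, frac_clumped_pairs = 0,
    frac_border_touching = 0, rng_seed = 5
  ))
  ec <- sim$truth$expected_counts
  expect_equal(ec$real_cells, 100)
  expect_equal(ec$sox10_cells, 70)
  expect_equal(ec$sox10_edu_cells, 35)
  cells <- sim$truth$cells
  expect_true(all(!cells$is_edu_pos | cells$is_sox10_pos))  # EdU+ subset of SOX10+
  expect_equal(nrow(cells), 100)
  expect_setequal(setdiff(unique(as.integer(sim$truth$nucleus_label_map)), 0L),
                  cells$cell)
})

test_that("zero cells give background-only channels and empty truth", {
  sim <- simulate_cytospin(synthetic_spec(n_cells = 0, image_size = c(128, 128),
                                          noise_sd = 0, rng_seed = 1))
  expect_equal(nrow(sim$truth$cells), 0L)
  expect_equal(sim$truth$expected_counts$real_cells, 0)
  for (ch in sim$image$channels) {
    expect_true(all(ch == sim$spec$background_level))
  }
})

test_that("generation is bit-identical for identical seeds, different otherwise", {
  sp <- clean_spec(n_cells = 6, rng_seed = 17)
  a <- simulate_cytospin(sp)
  b <- simulate_cytospin(sp)
  expect_identical(a$image$channels, b$image$channels)
  expect_identical(a$truth$cells, b$truth$cells)
  c <- simulate_cytospin(clean_spec(n_cells = 6, rng_seed = 18))
  expect_false(identical(a$image$channels$DAPI, c$image$channels$DAPI))
})

test_that("burst nuclei are low-circularity, intact nuclei round and in-gate", {
  sim <- cached_sim("calib", synthetic_spec(
    n_cells = 40, image_size = c(900, 900), rng_seed = 23,
    frac_burst_nuclei = 0.5, frac_burst_bodies = 0, frac_clumped_pairs = 0,
    frac_border_touching = 0
  ))
  tab <- measure_shape(sim$truth$nucleus_label_map)
  burst <- sim$truth$cells$is_burst_nucleus[tab$label]
  expect_gte(mean(tab$form_factor[burst] < 0.599), 0.95)
  expect_true(all(tab$form_factor[!burst] >= 0.7))
  expect_true(all(tab$equivalent_diameter[!burst] >= 16))
  expect_true(all(tab$equivalent_diameter[!burst] <= 60))
})

test_that("marker intensities separate positives from negatives by >= 5 noise sd", {
  sim <- cached_sim("clean12", clean_spec())
  nl <- sim$truth$nucleus_label_map
  cells <- sim$truth$cells
  sox <- measure_intensity(nl, sim$image$channels$SOX10, "SOX10")
  pos <- cells$is_sox10_pos[sox$label]
  expect_gte(min(sox$mean_SOX10[pos]) - max(sox$mean_SOX10[!pos]),
             5 * sim$spec$noise_sd)
  edu <- measure_intensity(nl, sim$image$channels$EdU, "EdU")
  epos <- cells$is_edu_pos[edu$label]
  expect_gte(min(edu$mean_EdU[epos]) - max(edu$mean_EdU[!epos]),
             5 * sim$spec$noise_sd)
})

test_that("border and clump fractions are realized in the rendered truth", {
  sim <- cached_sim("degraded", synthetic_spec(rng_seed = 2))
  cells <- sim$truth$cells
  expect_equal(sum(cells$touches_border), 5)
  expect_equal(sum(cells$is_clumped), 10)
  expect_equal(sum(cells$is_burst_nucleus), 10)
  expect_equal(sum(cells$is_burst_body), 10)
  # statuses are mutually exclusive
  expect_true(all(rowSums(cbind(cells$is_burst_nucleus, cells$is_burst_body,
                                cells$touches_border, cells$is_clumped)) <= 1))
})

test_that("fixtures round-trip through disk byte-identically", {
  sim <- cached_sim("clean12", clean_spec())
  d1 <- withr::local_tempdir()
  write_fixture(sim, d1)
  files <- c("dapi.tif", "sox10.tif", "edu.tif", "vime.tif",
             "nuclei_gt.tif", "bodies_gt.tif", "truth.csv",
             "expected_counts.csv", "spec.yaml")
  expect_true(all(file.exists(file.path(d1, files))))
  # channel round trip within 16-bit quantization
  for (pair in list(c("DAPI", "dapi.tif"), c("VIME", "vime.tif"))) {
    reread <- load_channel(file.path(d1, pair[2]))
    expect_lte(max(abs(reread - sim$image$channels[[pair[1]]])), 1 / 65535)
  }
  # label maps round-trip exactly
  expect_identical(read_label_tiff(file.path(d1, "nuclei_gt.tif")),
                   sim$truth$nucleus_label_map)
  # re-run is byte-identical
  d2 <- withr::local_tempdir()
  write_fixture(sim, d2)
  for (f in c("truth.csv", "expected_counts.csv", "spec.yaml", "dapi.tif")) {
    expect_identical(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))))
  }
})

test_that("invalid specs are rejected", {
  expect_error(synthetic_spec(frac_sox10_pos = 1.2))
  expect_error(synthetic_spec(nucleus_radius_range = c(10, 5)))
  expect_error(synthetic_spec(nucleus_radius_range = c(4, 6)), "16-60")
  expect_error(synthetic_spec(noise_sd = -0.1))
  expect_error(
    simulate_cytospin(synthetic_spec(n_cells = 500, image_size = c(512, 512))),
    "placed"
  )
})
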