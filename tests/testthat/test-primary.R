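test_that("otsu threshold separates a two-delta histogram and handles degeneracy", {
  t2 <- otsu_threshold(c(rep(0.2, 50), rep(0.8, 50)))
  expect_gt(t2, 0.2)
  expect_lt(t2, 0.8)
  # constant image: threshold equals the constant, strict > gives empty fg
  x <- matrix(0.37, 5, 5)
  tc <- otsu_threshold(x)
  expect_equal(tc, 0.37)
  expect_false(any(x > tc))
})

test_that("otsu threshold matches exhaustive between-class-variance scan", {
  set.seed(11)
  for (i in 1:20) {
    v <- switch(1 + i %% 3,
      runif(1000),
      c(rnorm(500, 0.3, 0.05), rnorm(500, 0.7, 0.08)),
      rbeta(1000, 2, 5)
    )
    v <- pmin(pmax(v, 0), 1)
    expect_equal(round(otsu_threshold(v) * 256), oracle_otsu_bin(v))
  }
})

test_that("threshold correction scales and bounds clamp the effective threshold", {
  set.seed(2)
  img <- matrix(pmin(pmax(c(rnorm(2000, 0.2, 0.05), rnorm(2096, 0.7, 0.05)), 0), 1), 64, 64)
  m1 <- threshold_mask(img, primary_params(threshold_correction = 1))
  expect_equal(attr(m1, "threshold"), attr(m1, "otsu"))
  m07 <- threshold_mask(img, primary_params(threshold_correction = 0.7))
  expect_equal(attr(m07, "threshold"), attr(m07, "otsu") * 0.7)
  mfix <- threshold_mask(img, primary_params(threshold_bounds = c(0.5, 0.5)))
  expect_equal(attr(mfix, "threshold"), 0.5)
})

test_that("increasing the threshold correction never increases foreground area", {
  set.seed(3)
  img <- matrix(runif(64 * 64), 64, 64)
  areas <- vapply(c(0.5, 0.7, 0.9, 1.1, 1.3), function(k) {
    sum(threshold_mask(img, primary_params(threshold_correction = k)))
  }, numeric(1))
  expect_true(all(diff(areas) <= 0))
})

test_that("shape declumping separates touching disks and keeps isolated ones whole", {
  p <- primary_params(min_diameter = 10)
  # single isolated disk: one label covering the disk
  m1 <- disk_mask(12, 40)
  l1 <- declump_by_shape(m1, p)
  expect_equal(sort(unique(as.integer(l1))), c(0L, 1L))
  expect_equal(sum(l1 > 0), sum(m1))
  # two overlapping disks (r = 10, centers 14 px apart): exactly two labels,
  # seed count verified against a brute-force smoothed-distance-maxima scan
  m2 <- two_disk_mask(10, 14)
  l2 <- declump_by_shape(m2, p)
  expect_equal(length(label_count <- setdiff(unique(as.integer(l2)), 0L)), 2L)
  expect_equal(sum(l2 > 0), sum(m2))
  expect_equal(
    oracle_seed_count(m2, sigma = max(1, p$min_diameter / 7), min_sep = p$min_diameter),
    2L
  )
  # the dividing line lies in the indentation (waist) region of the peanut
  n <- nrow(m2)
  seam <- which(l2 > 0 & (cbind(l2[, -1], 0L) > 0) & l2 != cbind(l2[, -1], 0L),
                arr.ind = TRUE)
  expect_true(all(abs(seam[, 2] - n / 2) <= 3))
  # two separated disks: labels equal the connected components
  m3 <- two_disk_mask(8, 40)
  l3 <- declump_by_shape(m3, p)
  expect_equal(length(setdiff(unique(as.integer(l3)), 0L)), 2L)
  # empty mask
  expect_equal(sum(declump_by_shape(matrix(FALSE, 20, 20), p)), 0)
})

test_that("every mask pixel gets exactly one label and labels are contiguous", {
  set.seed(5)
  for (i in 1:5) {
    m <- matrix(FALSE, 80, 80)
    for (k in 1:4) {
      ctr <- runif(2, 15, 65)
      m <- m | disk_mask(runif(1, 6, 11), 80, ctr)
    }
    lab <- declump_by_shape(m, primary_params(min_diameter = 8, fill_holes = FALSE))
    expect_true(all(lab[m] > 0))
    expect_true(all(lab[!m] == 0))
    ids <- sort(unique(as.integer(lab[lab > 0])))
    expect_equal(ids, seq_along(ids))
  }
})

test_that("size gate and border exclusion follow the 16-60 px diameter rule", {
  p <- primary_params()
  n <- 120
  lab <- matrix(0L, n, n)
  lab[disk_mask(5, n, c(20, 20))] <- 1L    # equiv diameter ~10 < 16: removed
  lab[disk_mask(20, n, c(60, 60))] <- 2L   # equiv diameter ~40: kept
  lab[disk_mask(10, n, c(3, 100))] <- 3L   # touches row 1: removed
  got <- gate_primary_objects(lab, p)
  expect_equal(sort(unique(as.integer(got))), c(0L, 1L))
  expect_equal(sum(got == 1L), sum(lab == 2L))
  # border object kept if exclusion is off (still passes size gate)
  got2 <- gate_primary_objects(lab, primary_params(exclude_border = FALSE))
  expect_equal(length(setdiff(unique(as.integer(got2)), 0L)), 2L)
})

test_that("real-nucleus filter keeps FormFactor >= 0.599 and relabels consistently", {
  tab <- tibble::tibble(
    label = 1:3,
    area = c(100, 100, 100),
    form_factor = c(0.60, 0.58, 0.95)
  )
  lab <- matrix(0L, 10, 30)
  lab[3:6, 2:6] <- 1L; lab[3:6, 12:16] <- 2L; lab[3:6, 22:26] <- 3L
  out <- filter_real_nuclei(lab, tab, 0.599)
  expect_equal(out$table$label, c(1L, 2L))
  expect_equal(out$table$form_factor, c(0.60, 0.95))
  expect_equal(sort(setdiff(unique(as.integer(out$labels)), 0L)), c(1L, 2L))
  expect_true(all(out$table$is_real_nucleus))
  # empty input stays empty
  empty <- filter_real_nuclei(matrix(0L, 4, 4), tab[0, ], 0.599)
  expect_equal(nrow(empty$table), 0L)
  # missing measurement errors
  expect_error(filter_real_nuclei(lab, tab[1:2, ], 0.599), "every label")
})

test_that("a generated burst nucleus fails the circularity filter", {
  sim <- cached_sim("burst", synthetic_spec(
    n_cells = 6, image_size = c(420, 420), rng_seed = 9,
    frac_burst_nuclei = 0.5, frac_burst_bodies = 0, frac_clumped_pairs = 0,
    frac_border_touching = 0
  ))
  truth_tab <- measure_shape(sim$truth$nucleus_label_map)
  burst <- sim$truth$cells$is_burst_nucleus[truth_tab$label]
  expect_true(all(truth_tab$form_factor[burst] < 0.599))
  expect_true(all(truth_tab$form_factor[!burst] >= 0.7))
})
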