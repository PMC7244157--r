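test_that("measurement filter keeps rows at or above the minimum", {
  set.seed(31)
  tab <- tibble::tibble(label = 1:50, v = runif(50))
  got <- filter_by_measurement(tab, "v", 0.4)
  # brute-force row scan oracle
  keep <- vapply(seq_len(50), function(i) tab$v[i] >= 0.4, logical(1))
  expect_equal(got, tab[keep, ])
  # identity at 0 for nonnegative values, empty-in empty-out, unknown column
  expect_equal(filter_by_measurement(tab, "v", 0), tab)
  expect_equal(nrow(filter_by_measurement(tab[0, ], "v", 0.1)), 0L)
  expect_error(filter_by_measurement(tab, "nope", 0), "unknown")
})

test_that("SOX10/EdU classification respects thresholds and nesting", {
  tab <- tibble::tibble(
    label = 1:4,
    mean_SOX10 = c(0.9, 0.05, 0.8, 0.1),
    mean_EdU = c(0.9, 0.95, 0.1, 0.2)
  )
  th <- marker_thresholds(0.5, 0.5)
  out <- tab |> classify_sox10(th) |> classify_edu(th)
  expect_equal(out$is_sox10_pos, c(TRUE, FALSE, TRUE, FALSE))
  # nucleus 2 has saturated EdU but is SOX10-negative: stays EdU-negative
  expect_equal(out$is_edu_pos, c(TRUE, FALSE, FALSE, FALSE))
  # zero EdU threshold: EdU flag collapses onto the SOX10 flag
  out0 <- tab |> classify_sox10(th) |> classify_edu(marker_thresholds(0.5, 0))
  expect_equal(out0$is_edu_pos, out0$is_sox10_pos)
  # threshold below the global minimum: everything positive
  all_pos <- classify_sox10(tab, marker_thresholds(0, 0))
  expect_true(all(all_pos$is_sox10_pos))
  # all means zero with positive threshold: zero positives
  tab0 <- tab; tab0$mean_SOX10 <- 0
  expect_false(any(classify_sox10(tab0, marker_thresholds(0.1, 0.1))$is_sox10_pos))
  # EdU before SOX10 errors
  expect_error(classify_edu(tab, th), "classify_sox10")
})

test_that("classification is monotone, nested and idempotent", {
  set.seed(32)
  tab <- tibble::tibble(
    label = 1:200,
    mean_SOX10 = runif(200),
    mean_EdU = runif(200)
  )
  prev_sox <- Inf
  for (thr in seq(0, 1, by = 0.1)) {
    out <- tab |> classify_sox10(marker_thresholds(thr, 0.5)) |>
      classify_edu(marker_thresholds(thr, 0.5))
    expect_lte(sum(out$is_edu_pos), sum(out$is_sox10_pos))
    expect_lte(sum(out$is_sox10_pos), nrow(out))
    expect_lte(sum(out$is_sox10_pos), prev_sox)
    prev_sox <- sum(out$is_sox10_pos)
    again <- out |> classify_sox10(marker_thresholds(thr, 0.5)) |>
      classify_edu(marker_thresholds(thr, 0.5))
    expect_identical(again$is_sox10_pos, out$is_sox10_pos)
    expect_identical(again$is_edu_pos, out$is_edu_pos)
  }
})

test_that("classification recovers the synthetic ground truth exactly", {
  sim <- cached_sim("clean12", clean_spec())
  res <- run_pipeline(sim$image, pipeline_config())
  truth <- sim$truth$cells
  expect_equal(res$counts$n_sox10_cells, sum(truth$is_sox10_pos))
  expect_equal(res$counts$n_sox10_edu_cells, sum(truth$is_edu_pos))
})

test_that("suggest_threshold matches the brute-force Otsu split", {
  v <- c(rep(0.1, 50), rep(0.9, 50))
  s <- suggest_threshold(v)
  expect_gt(s, 0.1)
  expect_lt(s, 0.9)
  set.seed(33)
  vb <- pmin(pmax(c(rnorm(100, 0.2, 0.05), rnorm(100, 0.75, 0.05)), 0), 1)
  expect_equal(round(suggest_threshold(vb) * 256), oracle_otsu_bin(vb))
  expect_error(suggest_threshold(0.5), "at least 2")
  expect_error(suggest_threshold(rep(0.4, 10)), "identical")
})
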