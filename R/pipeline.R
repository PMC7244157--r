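#' Full pipeline configuration
#'
#' Aggregates the primary-segmentation, secondary-segmentation and
#' marker-threshold parameter sets (all defaulting to the published
#' settings) with orchestration options.
#'
#' @param primary A [primary_params()] object.
#' @param secondary A [secondary_params()] object.
#' @param markers A [marker_thresholds()] object.
#' @param proliferation_denominator Denominator of the proliferation rate:
#'   `"real_cells"` (default; proliferating SCs as a percentage of all
#'   real cells) or `"sox10_cells"` (as a percentage of SCs).
#' @param output_dir Optional directory for overlays/exports.
#' @param save_debug_images Write intermediate masks/label maps when
#'   running with an `output_dir`.
#' @param rng_seed Seed used only by synthetic fixtures.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(primary = primary_params(),
                            secondary = secondary_params(),
                            markers = marker_thresholds(),
                            proliferation_denominator = c("real_cells", "sox10_cells"),
                            output_dir = NULL,
                            save_debug_images = FALSE,
                            rng_seed = 1L) {
  proliferation_denominator <- match.arg(proliferation_denominator)
  stopifnot(inherits(primary, "primary_params"),
            inherits(secondary, "secondary_params"),
            inherits(markers, "marker_thresholds"))
  structure(
    list(
      primary = primary, secondary = secondary, markers = markers,
      proliferation_denominator = proliferation_denominator,
      output_dir = output_dir,
      save_debug_images = isTRUE(save_debug_images),
      rng_seed = as.integer(rng_seed)
    ),
    class = "pipeline_config"
  )
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config A [pipeline_config()] object.
#' @param path YAML file path.
#' @return `write_config()` returns `path` invisibly; `read_config()`
#'   returns a [pipeline_config()].
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  plain <- list(
    primary = unclass(config$primary),
    secondary = unclass(config$secondary),
    markers = unclass(config$markers),
    proliferation_denominator = config$proliferation_denominator,
    save_debug_images = config$save_debug_images,
    rng_seed = config$rng_seed
  )
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  pipeline_config(
    primary = do.call(primary_params, y$primary),
    secondary = do.call(secondary_params, y$secondary),
    markers = do.call(marker_thresholds, y$markers),
    proliferation_denominator = y$proliferation_denominator %||% "real_cells",
    save_debug_images = isTRUE(y$save_debug_images),
    rng_seed = y$rng_seed %||% 1L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Construct a counts report row, asserting the nesting invariant
# edu <= sox10 <= real cells <= real nuclei <= primary nuclei.
counts_report <- function(image_id, n_primary_nuclei, n_real_nuclei,
                          n_real_cells, n_sox10_cells, n_sox10_edu_cells,
                          denominator = "real_cells") {
  counts <- c(n_sox10_edu_cells, n_sox10_cells, n_real_cells,
              n_real_nuclei, n_primary_nuclei)
  if (any(diff(counts) < 0)) {
    abort("count nesting violated: expected EdU+ <= SOX10+ <= real cells <= real nuclei <= primary nuclei")
  }
  report <- tibble(
    image_id = image_id,
    n_primary_nuclei = n_primary_nuclei,
    n_real_nuclei = n_real_nuclei,
    n_real_cells = n_real_cells,
    n_sox10_cells = n_sox10_cells,
    n_sox10_edu_cells = n_sox10_edu_cells
  )
  compute_rates(report, denominator)
}

#' Derive purity and proliferation percentages for a counts report
#'
#' `purity_pct = 100 * n_sox10_cells / n_real_cells`;
#' `proliferation_pct = 100 * n_sox10_edu_cells / denominator`, where the
#' denominator is `n_real_cells` or `n_sox10_cells` per configuration.
#' Zero denominators yield 0 with `zero_denominator = TRUE`.
#'
#' @param report A counts tibble with the `n_*` columns populated.
#' @param denominator `"real_cells"` or `"sox10_cells"`.
#' @return The report with `purity_pct`, `proliferation_pct` and
#'   `zero_denominator` columns.
#' @export
compute_rates <- function(report, denominator = c("real_cells", "sox10_cells")) {
  denominator <- match.arg(denominator)
  den_prolif <- if (denominator == "real_cells") report$n_real_cells else report$n_sox10_cells
  zero <- report$n_real_cells == 0 | den_prolif == 0
  if (any(zero)) warn("zero denominator; reporting 0% rates")
  report$purity_pct <- ifelse(report$n_real_cells > 0,
                              100 * report$n_sox10_cells / report$n_real_cells, 0)
  report$proliferation_pct <- ifelse(den_prolif > 0,
                                     100 * report$n_sox10_edu_cells / den_prolif, 0)
  report$zero_denominator <- zero
  as_tibble(report)
}

#' Run the full cytospin analysis on one multi-channel image
#'
#' Executes, in order: primary segmentation of the DAPI channel
#' (threshold, shape declumping, size gate, border exclusion), shape and
#' intensity measurement, the FormFactor filter for real nuclei, SOX10 and
#' EdU mean-intensity classification, seeded propagation of cell bodies on
#' the vimentin channel, the intact-cell filter, and nested counting
#' restricted to nuclei with an intact body.  Deterministic for fixed
#' inputs and configuration.  A stage yielding zero objects short-circuits
#' later stages with zero counts.
#'
#' @param image A [cyto_image()].
#' @param config A [pipeline_config()].
#' @param image_id Identifier used in the counts report.
#' @return A list of class `cyto_result`: `counts` (one-row tibble),
#'   `objects` (per-nucleus measurement tibble with classification
#'   flags), `nuclei_labels`, `body_labels`, `thresholds` (marker
#'   thresholds used), and `stage_log` (objects entering/leaving each
#'   stage).
#' @examples
#' sim <- simulate_cytospin(synthetic_spec(n_cells = 12, image_size = c(420, 420),
#'   frac_burst_nuclei = 0, frac_burst_bodies = 0, frac_clumped_pairs = 0,
#'   frac_border_touching = 0))
#' res <- run_pipeline(sim$image, pipeline_config())
#' res$counts
#' @export
run_pipeline <- function(image, config = pipeline_config(), image_id = "image") {
  stopifnot(inherits(image, "cyto_image"), inherits(config, "pipeline_config"))
  h <- image$height; w <- image$width
  log <- list()
  note <- function(stage, n_in, n_out) {
    log[[length(log) + 1L]] <<- tibble(stage = stage, n_in = n_in, n_out = n_out)
  }
  empty_result <- function(n_primary = 0L, n_real = 0L, objects = NULL,
                           nuclei = NULL, bodies = NULL) {
    structure(list(
      counts = counts_report(image_id, n_primary, n_real, 0L, 0L, 0L,
                             config$proliferation_denominator),
      objects = objects %||% measure_objects(matrix(0L, h, w)),
      nuclei_labels = nuclei %||% matrix(0L, h, w),
      body_labels = bodies %||% matrix(0L, h, w),
      thresholds = config$markers,
      stage_log = dplyr::bind_rows(log)
    ), class = "cyto_result")
  }

  mask <- threshold_mask(image$channels$DAPI, config$primary)
  raw_labels <- declump_by_shape(mask, config$primary)
  labels <- gate_primary_objects(raw_labels, config$primary)
  n_primary <- length(label_ids(labels))
  note("primary_segmentation", length(label_ids(raw_labels)), n_primary)
  if (n_primary == 0L) return(empty_result())

  tab <- measure_objects(labels, image)
  real <- filter_real_nuclei(labels, tab, config$primary$min_form_factor)
  n_real <- nrow(real$table)
  note("form_factor_filter", n_primary, n_real)
  if (n_real == 0L) return(empty_result(n_primary))

  thresholds <- config$markers
  if (thresholds$auto_suggest && n_real >= 2) {
    thresholds$sox10_min_mean_intensity <- suggest_threshold(real$table$mean_SOX10)
    thresholds$edu_min_mean_intensity <- suggest_threshold(real$table$mean_EdU)
  }
  objects <- real$table |>
    classify_sox10(thresholds) |>
    classify_edu(thresholds)
  note("sox10_classification", n_real, sum(objects$is_sox10_pos))
  note("edu_classification", sum(objects$is_sox10_pos), sum(objects$is_edu_pos))

  bodies <- propagate_secondary(real$labels, image$channels$VIME, config$secondary)
  body_tab <- measure_objects(bodies, image)
  filt <- filter_intact_cells(bodies, body_tab, objects, config$secondary)
  objects <- filt$nuclei
  note("intact_cell_filter", length(label_ids(bodies)),
       sum(objects$has_intact_body))

  n_real_cells <- sum(objects$has_intact_body)
  n_sox10 <- sum(objects$has_intact_body & objects$is_sox10_pos)
  n_edu <- sum(objects$has_intact_body & objects$is_edu_pos)
  res <- structure(list(
    counts = counts_report(image_id, n_primary, n_real, n_real_cells,
                           n_sox10, n_edu, config$proliferation_denominator),
    objects = objects,
    nuclei_labels = real$labels,
    body_labels = filt$bodies,
    thresholds = thresholds,
    stage_log = dplyr::bind_rows(log)
  ), class = "cyto_result")
  if (!is.null(config$output_dir)) {
    render_overlays(res, image, config$output_dir)
    if (config$save_debug_images) {
      tiff::writeTIFF(matrix(as.numeric(mask), h, w),
                      file.path(config$output_dir, "dapi_mask.tif"),
                      bits.per.sample = 16L)
      tiff::writeTIFF(res$nuclei_labels / 65535,
                      file.path(config$output_dir, "nuclei_labels.tif"),
                      bits.per.sample = 16L)
      tiff::writeTIFF(res$body_labels / 65535,
                      file.path(config$output_dir, "body_labels.tif"),
                      bits.per.sample = 16L)
    }
  }
  res
}

#' @export
print.cyto_result <- function(x, ...) {
  c <- x$counts
  cat(sprintf(
    paste0("<cyto_result> %s: %d primary nuclei -> %d real nuclei -> %d real cells; ",
           "%d SOX10+ (purity %.1f%%), %d SOX10+/EdU+ (proliferation %.1f%%)\n"),
    c$image_id, c$n_primary_nuclei, c$n_real_nuclei, c$n_real_cells,
    c$n_sox10_cells, c$purity_pct, c$n_sox10_edu_cells, c$proliferation_pct
  ))
  invisible(x)
}

#' Export counts reports to a spreadsheet
#'
#' Writes one row per image with all counts and rates as tab-delimited
#' text, plus a CSV twin next to it (same basename, `.csv` extension).
#' Column order is stable and re-export is byte-identical.
#'
#' @param reports A counts tibble (rows from one or more [run_pipeline()]
#'   results, e.g. `dplyr::bind_rows(lapply(results, \(r) r$counts))`).
#' @param path Output `.txt` path.
#' @return `path`, invisibly.
#' @export
export_spreadsheet <- function(reports, path) {
  if (!nrow(reports)) abort("need at least one report row")
  cols <- c("image_id", "n_primary_nuclei", "n_real_nuclei", "n_real_cells",
            "n_sox10_cells", "n_sox10_edu_cells", "purity_pct",
            "proliferation_pct")
  out <- as.data.frame(reports[, cols])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  csv <- sub("\\.[^.]*$", ".csv", path)
  if (identical(csv, path)) csv <- paste0(path, ".csv")
  write.table(out, csv, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Paired comparison of automated and manual counts
#'
#' Paired t-test on the per-donor differences `d = auto - manual`:
#' `t = mean(d) / (sd(d) / sqrt(n))` with `n - 1` degrees of freedom and a
#' two-sided p-value; significance is declared at p < 0.05.  Degenerate
#' zero-variance differences are handled by convention: all-zero
#' differences give `t = 0, p = 1`; constant nonzero differences give
#' `t = +/-Inf, p = 0`.
#'
#' @param auto,manual Equal-length numeric vectors of per-donor values
#'   (n >= 2).
#' @return A list of class `cyto_paired_test` with `statistic`, `p_value`,
#'   `mean_difference`, `df`, `n` and `significant`.
#' @examples
#' compare_to_manual(c(10, 20, 30), c(12, 19, 33))
#' @export
compare_to_manual <- function(auto, manual) {
  if (length(auto) != length(manual)) abort("`auto` and `manual` must be paired")
  n <- length(auto)
  if (n < 2) abort("need at least 2 paired observations")
  d <- auto - manual
  if (sd(d) == 0) {
    if (mean(d) == 0) {
      t_stat <- 0; p <- 1
    } else {
      t_stat <- sign(mean(d)) * Inf; p <- 0
    }
  } else {
    tt <- stats::t.test(auto, manual, paired = TRUE)
    t_stat <- unname(tt$statistic)
    p <- tt$p.value
  }
  structure(
    list(statistic = t_stat, p_value = p, mean_difference = mean(d),
         df = n - 1L, n = n, significant = p < 0.05),
    class = "cyto_paired_test"
  )
}

#' @export
print.cyto_paired_test <- function(x, ...) {
  cat(sprintf(
    "Paired t-test (n = %d): t = %.4g, df = %d, p = %.4g (%ssignificant at 0.05); mean difference %.4g\n",
    x$n, x$statistic, x$df, x$p_value,
    if (x$significant) "" else "not ", x$mean_difference
  ))
  invisible(x)
}
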