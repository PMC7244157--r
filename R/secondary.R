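#' Parameters for secondary (cell-body) segmentation
#'
#' Defaults reproduce the published pipeline settings for identifying
#' vimentin-positive cell bodies around each real nucleus: Otsu threshold
#' with a 0.9 correction factor, propagation regularization
#' `lambda = 0.1` (small lambda lets intensity gradients shape the
#' dividing lines; large lambda approaches a pure nearest-seed geodesic
#' partition), and intact-cell filters of minimum area 28 px^2, minimum
#' FormFactor 0.35 and minimum vimentin mean intensity 9e-6.  Bodies
#' touching the image border are kept.
#'
#' @param threshold_correction Otsu correction factor (default 0.9).
#' @param regularization_lambda Propagation regularization `lambda >= 0`
#'   (default 0.1).
#' @param min_body_area Minimum body area in pixels^2 (default 28).
#' @param min_body_form_factor Minimum body circularity (default 0.35).
#' @param min_body_mean_intensity Minimum vimentin mean intensity
#'   (default 0.000009).
#' @param smoothing_scale Pre-threshold smoothing scale (default 1.3488,
#'   i.e. sigma = 1 px).
#' @param threshold_bounds Lower/upper clamp for the corrected threshold.
#' @param fill_holes Fill holes inside each body (default `TRUE`).
#' @param exclude_border Drop bodies touching the border (default `FALSE`:
#'   bodies cut by the border are kept, only nuclei were border-filtered).
#' @return A list of class `secondary_params`.
#' @export
secondary_params <- function(threshold_correction = 0.9,
                             regularization_lambda = 0.1,
                             min_body_area = 28,
                             min_body_form_factor = 0.35,
                             min_body_mean_intensity = 0.000009,
                             smoothing_scale = 1.3488,
                             threshold_bounds = c(0, 1),
                             fill_holes = TRUE,
                             exclude_border = FALSE) {
  stopifnot(
    threshold_correction > 0,
    regularization_lambda >= 0,
    min_body_area >= 1,
    length(threshold_bounds) == 2,
    threshold_bounds[1] >= 0, threshold_bounds[1] <= threshold_bounds[2],
    threshold_bounds[2] <= 1
  )
  structure(
    list(
      threshold_correction = threshold_correction,
      regularization_lambda = regularization_lambda,
      min_body_area = min_body_area,
      min_body_form_factor = min_body_form_factor,
      min_body_mean_intensity = min_body_mean_intensity,
      smoothing_scale = smoothing_scale,
      threshold_bounds = threshold_bounds,
      fill_holes = fill_holes,
      exclude_border = exclude_border
    ),
    class = "secondary_params"
  )
}

#' Seeded propagation segmentation of cell bodies
#'
#' Grows each seed object (real nucleus) outwards over the foreground of
#' the intensity image, assigning every reachable foreground pixel to the
#' seed minimizing the accumulated path cost.  Each 8-connected step from
#' pixel p to q costs `sqrt((I(p) - I(q))^2 + lambda * d(p, q)^2)` with
#' `d` the Euclidean step length (1 or sqrt(2)): small `lambda` places
#' dividing lines along intensity ridges, large `lambda` approaches the
#' nearest-seed geodesic partition.  Ties in accumulated cost are broken
#' toward the lower seed label (then row-major order); seed pixels always
#' keep their seed's label, even below threshold.
#'
#' When `mask` is `NULL` the foreground is computed as in
#' [threshold_mask()]: the intensity image is smoothed
#' (sigma = `smoothing_scale / 1.3488`) and thresholded at the clamped,
#' corrected Otsu value.  Holes are filled per object when
#' `params$fill_holes`.
#'
#' @param seeds Integer label matrix of seed objects (real nuclei).
#' @param intensity Numeric matrix in \[0, 1\] (the vimentin channel);
#'   path costs use these raw intensities.
#' @param params A [secondary_params()] object.
#' @param mask Optional logical foreground mask overriding the Otsu mask.
#' @return Integer label matrix of cell bodies; each body carries the
#'   label of its seed nucleus.
#' @export
propagate_secondary <- function(seeds, intensity, params = secondary_params(),
                                mask = NULL) {
  assert_intensity_matrix(intensity, "intensity")
  if (!all(dim(seeds) == dim(intensity))) {
    abort("`seeds` and `intensity` must share the same shape")
  }
  if (!any(seeds > 0L)) {
    warn("no seeds supplied; returning an empty label map")
    return(matrix(0L, nrow(seeds), ncol(seeds)))
  }
  if (is.null(mask)) {
    mask <- threshold_mask(intensity, params)
  }
  region <- mask | seeds > 0L
  res <- cpp_propagate(
    matrix(as.integer(seeds), nrow(seeds), ncol(seeds)),
    intensity, region, params$regularization_lambda
  )
  labels <- res$labels
  if (params$fill_holes) labels <- fill_label_holes(labels)
  labels
}

#' Filter cell bodies to retain intact cells
#'
#' A body survives iff its area is at least `min_body_area`, its
#' FormFactor at least `min_body_form_factor` and its vimentin mean
#' intensity at least `min_body_mean_intensity`.  The parent nucleus of
#' each surviving body (bodies carry their seed nucleus label) gets
#' `has_intact_body = TRUE`; all other nuclei `FALSE`.
#'
#' @param bodies Integer label matrix from [propagate_secondary()].
#' @param body_table Measurement tibble for `bodies` with `area`,
#'   `form_factor` and `mean_VIME` columns.
#' @param nuclei_table Measurement tibble of the seed nuclei.
#' @param params A [secondary_params()] object.
#' @return List with `bodies` (filtered label map, original labels kept)
#'   and `nuclei` (`nuclei_table` with `has_intact_body` set).
#' @export
filter_intact_cells <- function(bodies, body_table, nuclei_table,
                                params = secondary_params()) {
  ids <- label_ids(bodies)
  if (!all(ids %in% nuclei_table$label)) {
    abort("body label without a parent nucleus")
  }
  kept <- body_table |>
    filter_by_measurement("area", params$min_body_area) |>
    filter_by_measurement("form_factor", params$min_body_form_factor) |>
    filter_by_measurement("mean_VIME", params$min_body_mean_intensity)
  if (params$exclude_border) {
    h <- nrow(bodies); w <- ncol(bodies)
    border <- unique(c(bodies[1, ], bodies[h, ], bodies[, 1], bodies[, w]))
    kept <- kept[!kept$label %in% border, , drop = FALSE]
  }
  out <- bodies
  out[!out %in% kept$label] <- 0L
  nuclei_table$has_intact_body <- nuclei_table$label %in% kept$label
  list(bodies = out, nuclei = as_tibble(nuclei_table))
}
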