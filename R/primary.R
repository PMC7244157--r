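#' Parameters for primary (nucleus) segmentation
#'
#' Defaults reproduce the published pipeline settings: objects of
#' 16--60 px equivalent diameter, global two-class Otsu threshold with a
#' 0.7 correction factor and \[0, 1\] bounds, smoothing scale 1.3488
#' (mapping to a Gaussian sigma of 1 px), shape-based declumping, border
#' exclusion, hole filling, and a minimum FormFactor of 0.599 for intact
#' ("real") nuclei.
#'
#' @param min_diameter,max_diameter Allowed equivalent-diameter range in
#'   pixels (default 16 and 60).
#' @param smoothing_scale Pre-threshold smoothing scale; the Gaussian sigma
#'   used is `smoothing_scale / 1.3488`, so the default 1.3488 means
#'   sigma = 1 px.
#' @param threshold_correction Multiplicative correction applied to the
#'   Otsu threshold (default 0.7; < 1 is more lenient).
#' @param threshold_bounds Length-2 numeric, lower/upper clamp for the
#'   corrected threshold (default `c(0, 1)`).
#' @param min_form_factor Minimum circularity `4*pi*Area/Perimeter^2` for a
#'   nucleus to count as intact (default 0.599).
#' @param exclude_border Drop objects touching the image border
#'   (default `TRUE`).
#' @param fill_holes Fill holes inside each object (default `TRUE`).
#' @param distance_smoothing Sigma for smoothing the distance transform
#'   before seed detection; `NULL` (default) uses
#'   `max(1, min_diameter / 7)`.
#' @return A list of class `primary_params`.
#' @export
primary_params <- function(min_diameter = 16,
                           max_diameter = 60,
                           smoothing_scale = 1.3488,
                           threshold_correction = 0.7,
                           threshold_bounds = c(0, 1),
                           min_form_factor = 0.599,
                           exclude_border = TRUE,
                           fill_holes = TRUE,
                           distance_smoothing = NULL) {
  stopifnot(
    min_diameter > 0, min_diameter <= max_diameter,
    threshold_correction > 0,
    length(threshold_bounds) == 2,
    threshold_bounds[1] >= 0, threshold_bounds[1] <= threshold_bounds[2],
    threshold_bounds[2] <= 1,
    min_form_factor >= 0
  )
  if (is.null(distance_smoothing)) distance_smoothing <- max(1, min_diameter / 7)
  structure(
    list(
      min_diameter = min_diameter, max_diameter = max_diameter,
      smoothing_scale = smoothing_scale,
      threshold_correction = threshold_correction,
      threshold_bounds = threshold_bounds,
      min_form_factor = min_form_factor,
      exclude_border = exclude_border, fill_holes = fill_holes,
      distance_smoothing = distance_smoothing
    ),
    class = "primary_params"
  )
}

#' Two-class Otsu threshold on a 256-bin histogram
#'
#' Bins the intensities into `bins` uniform bins over \[0, 1\] and returns
#' the threshold maximizing the between-class variance of the two-class
#' split, evaluated at bin midpoints.  The threshold is reported at the
#' upper edge of the selected bin; pixels strictly above it are foreground.
#' A constant input returns that constant (empty foreground); ties are
#' broken toward the lowest bin.
#'
#' @param x Numeric vector or matrix of intensities in \[0, 1\].
#' @param bins Number of histogram bins (default 256).
#' @return Threshold value in \[0, 1\].
#' @examples
#' otsu_threshold(c(rep(0.2, 50), rep(0.8, 50)))
#' @export
otsu_threshold <- function(x, bins = 256L) {
  v <- as.numeric(x)
  if (!length(v)) abort("`x` must be non-empty")
  if (anyNA(v) || min(v) < 0 || max(v) > 1) abort("`x` must lie in [0, 1]")
  if (min(v) == max(v)) return(min(v))
  b <- pmin(floor(v * bins) + 1L, bins)
  h <- tabulate(b, nbins = bins)
  if (sum(h > 0L) == 1L) return(which(h > 0L) / bins)
  p <- h / length(v)
  mid <- (seq_len(bins) - 0.5) / bins
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mid)
  mu_t <- mu0[bins]
  k <- seq_len(bins - 1L)
  w0k <- w0[k]
  valid <- w0k > 0 & w0k < 1
  sigma_b <- rep(-Inf, bins - 1L)
  sigma_b[valid] <- (mu_t * w0k[valid] - mu0[k][valid])^2 /
    (w0k[valid] * (1 - w0k[valid]))
  which.max(sigma_b) / bins
}

#' Smooth and threshold an intensity image
#'
#' The image is Gaussian-smoothed with sigma `smoothing_scale / 1.3488`,
#' an Otsu threshold is computed on the smoothed image, multiplied by the
#' threshold correction factor and clamped to the threshold bounds; pixels
#' strictly above the effective threshold form the mask.
#'
#' @param image Numeric matrix in \[0, 1\].
#' @param params A [primary_params()] or [secondary_params()] object (only
#'   `smoothing_scale`, `threshold_correction` and `threshold_bounds` are
#'   used).
#' @return Logical mask matrix with attributes `threshold` (effective
#'   threshold) and `otsu` (uncorrected Otsu value).
#' @export
threshold_mask <- function(image, params = primary_params()) {
  assert_intensity_matrix(image)
  sm <- gaussian_smooth(image, params$smoothing_scale / 1.3488)
  sm <- clamp(sm, 0, 1)
  ot <- otsu_threshold(sm)
  thr <- clamp(ot * params$threshold_correction,
               params$threshold_bounds[1], params$threshold_bounds[2])
  # degenerate constant image: no foreground exists regardless of the
  # correction factor
  mask <- if (min(sm) == max(sm)) matrix(FALSE, nrow(sm), ncol(sm)) else sm > thr
  attr(mask, "threshold") <- thr
  attr(mask, "otsu") <- ot
  mask
}

# Seed detection: local maxima of the smoothed Euclidean distance
# transform, then greedy suppression (descending value, ties by row-major
# position) of maxima closer than min_diameter to an accepted one.
find_declump_seeds <- function(mask, params) {
  dm <- EBImage::distmap(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
  dm <- matrix(as.numeric(dm), nrow(mask), ncol(mask))
  sm <- gaussian_smooth(dm, params$distance_smoothing)
  sm[!mask] <- 0
  is_max <- mask
  for (i in seq_len(nrow(NEIGH8))) {
    nb <- shift_matrix(sm, NEIGH8[i, 1], NEIGH8[i, 2], fill = -Inf)
    is_max <- is_max & (sm >= nb)
  }
  is_max <- is_max & sm > 0
  idx <- which(is_max)
  if (!length(idx)) return(matrix(numeric(0), 0, 2))
  r <- ((idx - 1L) %% nrow(mask)) + 1L
  c <- ((idx - 1L) %/% nrow(mask)) + 1L
  val <- sm[idx]
  ord <- order(-val, row_major_index(r, c, ncol(mask)))
  r <- r[ord]; c <- c[ord]
  acc_r <- numeric(0); acc_c <- numeric(0)
  min_d2 <- params$min_diameter^2
  for (i in seq_along(r)) {
    if (!length(acc_r) || all((acc_r - r[i])^2 + (acc_c - c[i])^2 >= min_d2)) {
      acc_r <- c(acc_r, r[i]); acc_c <- c(acc_c, c[i])
    }
  }
  cbind(row = acc_r, col = acc_c)
}

#' Split clumped objects by shape and label the result
#'
#' Converts the binary mask to a Euclidean distance transform, smooths it,
#' takes local maxima as object seeds (maxima closer together than the
#' minimum object diameter are suppressed greedily in descending value
#' order, ties broken by row-major position), and assigns every mask pixel
#' to a seed by synchronous 8-connected ring growing: one pixel layer per
#' iteration, the lower label winning when two labels reach a pixel in the
#' same iteration.  Holes are then filled within each object when
#' `params$fill_holes` is set.
#'
#' @param mask Logical matrix from [threshold_mask()].
#' @param params A [primary_params()] object.
#' @return Integer label matrix (0 = background); labels are assigned in
#'   seed acceptance order.
#' @export
declump_by_shape <- function(mask, params = primary_params()) {
  stopifnot(is.matrix(mask))
  mask <- mask > 0
  labels <- matrix(0L, nrow(mask), ncol(mask))
  if (!any(mask)) return(labels)
  seeds <- find_declump_seeds(mask, params)
  if (!nrow(seeds)) return(labels)
  labels[cbind(seeds[, 1], seeds[, 2])] <- seq_len(nrow(seeds))
  labels <- cpp_ring_grow(labels, mask)
  if (params$fill_holes) labels <- fill_label_holes(labels)
  labels
}

# Per-object hole filling: background components (4-connected) not
# reaching the image border are assigned to the surrounding object.
fill_label_holes <- function(labels) {
  filled <- EBImage::fillHull(labels)
  matrix(as.integer(filled), nrow(labels), ncol(labels))
}

#' Gate objects by equivalent diameter and border contact
#'
#' Removes objects whose equivalent diameter `2*sqrt(Area/pi)` falls
#' outside `[min_diameter, max_diameter]` and, when
#' `params$exclude_border`, objects with any pixel on the image border.
#' Survivors are relabeled 1..K preserving the original label order.
#'
#' @param labels Integer label matrix.
#' @param params A [primary_params()] object.
#' @return Relabeled integer label matrix.
#' @export
gate_primary_objects <- function(labels, params = primary_params()) {
  ids <- label_ids(labels)
  if (!length(ids)) return(labels)
  areas <- label_areas(labels)
  eqd <- 2 * sqrt(areas / pi)
  keep <- ids[eqd >= params$min_diameter & eqd <= params$max_diameter]
  if (params$exclude_border) {
    h <- nrow(labels); w <- ncol(labels)
    border <- unique(c(labels[1, ], labels[h, ], labels[, 1], labels[, w]))
    keep <- setdiff(keep, border)
  }
  relabel_map(labels, keep)
}

#' Filter segmented nuclei by circularity to retain real nuclei
#'
#' Keeps exactly the objects whose FormFactor (`4*pi*Area/Perimeter^2`) is
#' at least `min_form_factor`; burst nuclei have reduced circularity and
#' are removed.  Surviving objects are relabeled 1..K preserving order and
#' the measurement table is updated consistently (its `label` column is
#' rewritten to the new labels).
#'
#' @param labels Integer label matrix.
#' @param table Measurement tibble from [measure_objects()] containing a
#'   `form_factor` value for every label.
#' @param min_form_factor Circularity cut-off (default 0.599).
#' @return List with elements `labels` (relabeled map) and `table`
#'   (filtered tibble, `is_real_nucleus` set to `TRUE`).
#' @export
filter_real_nuclei <- function(labels, table, min_form_factor = 0.599) {
  ids <- label_ids(labels)
  if (!all(ids %in% table$label)) {
    abort("`table` must contain a row for every label")
  }
  tab <- table[match(ids, table$label), , drop = FALSE]
  keep <- ids[tab$form_factor >= min_form_factor]
  new_labels <- relabel_map(labels, keep)
  out <- tab[tab$label %in% keep, , drop = FALSE]
  out$label <- match(out$label, keep)
  out$is_real_nucleus <- TRUE
  list(labels = new_labels, table = as_tibble(out))
}

#' Segment intact nuclei from a DAPI channel
#'
#' Convenience wrapper chaining [threshold_mask()], [declump_by_shape()]
#' and [gate_primary_objects()].
#'
#' @param dapi Numeric matrix in \[0, 1\].
#' @param params A [primary_params()] object.
#' @return Integer label matrix of gated primary objects.
#' @export
segment_nuclei <- function(dapi, params = primary_params()) {
  mask <- threshold_mask(dapi, params)
  labels <- declump_by_shape(mask, params)
  gate_primary_objects(labels, params)
}
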