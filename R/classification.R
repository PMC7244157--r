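#' Marker positivity thresholds
#'
#' Mean-intensity cut-offs for SOX10 and EdU positivity.  Staining
#' intensity varies between preparations and donors, so these are meant to
#' be set by the operator per analysed cytospin; [suggest_threshold()] can
#' propose a starting value, applied automatically only when
#' `auto_suggest = TRUE`.
#'
#' @param sox10_min_mean_intensity Minimum mean SOX10 intensity of a real
#'   nucleus to be called SOX10-positive (in \[0, 1\]).
#' @param edu_min_mean_intensity Minimum mean EdU intensity (within the
#'   SOX10-positive subset) to be called EdU-positive.
#' @param auto_suggest If `TRUE`, [run_pipeline()] replaces both
#'   thresholds by Otsu splits of the per-nucleus mean intensities.
#' @return A list of class `marker_thresholds`.
#' @export
marker_thresholds <- function(sox10_min_mean_intensity = 0.4,
                              edu_min_mean_intensity = 0.4,
                              auto_suggest = FALSE) {
  stopifnot(
    sox10_min_mean_intensity >= 0, sox10_min_mean_intensity <= 1,
    edu_min_mean_intensity >= 0, edu_min_mean_intensity <= 1
  )
  structure(
    list(
      sox10_min_mean_intensity = sox10_min_mean_intensity,
      edu_min_mean_intensity = edu_min_mean_intensity,
      auto_suggest = isTRUE(auto_suggest)
    ),
    class = "marker_thresholds"
  )
}

#' Keep table rows at or above a minimum measurement value
#'
#' The generic measurement filter used by every pipeline stage: rows whose
#' `measurement` column is `>= min_value` are kept, in their original
#' order.
#'
#' @param table A data frame of per-object measurements.
#' @param measurement Column name to filter on.
#' @param min_value Minimum value (comparison is `>=`, i.e. the value is a
#'   "minimum value" in the inclusive sense).
#' @return The filtered table (a tibble).
#' @export
filter_by_measurement <- function(table, measurement, min_value) {
  if (!measurement %in% names(table)) {
    abort(sprintf("unknown measurement column '%s'", measurement))
  }
  as_tibble(table[table[[measurement]] >= min_value, , drop = FALSE])
}

#' Classify real nuclei as SOX10-positive (Schwann cells)
#'
#' Sets `is_sox10_pos` to whether the mean SOX10 intensity of each nucleus
#' is at least the configured threshold.
#'
#' @param table Measurement tibble with a `mean_SOX10` column.
#' @param thresholds A [marker_thresholds()] object.
#' @return `table` with `is_sox10_pos` set.
#' @export
classify_sox10 <- function(table, thresholds = marker_thresholds()) {
  if (!"mean_SOX10" %in% names(table)) abort("missing `mean_SOX10` measurement")
  table$is_sox10_pos <- table$mean_SOX10 >= thresholds$sox10_min_mean_intensity
  as_tibble(table)
}

#' Classify SOX10-positive nuclei as EdU-positive (proliferating)
#'
#' EdU positivity is only ever asserted within the SOX10-positive subset:
#' `is_edu_pos = is_sox10_pos & (mean_EdU >= threshold)`.  [classify_sox10()]
#' must have been applied first.
#'
#' @inheritParams classify_sox10
#' @return `table` with `is_edu_pos` set.
#' @export
classify_edu <- function(table, thresholds = marker_thresholds()) {
  if (!"mean_EdU" %in% names(table)) abort("missing `mean_EdU` measurement")
  if (!"is_sox10_pos" %in% names(table) || anyNA(table$is_sox10_pos)) {
    abort("`classify_sox10()` must be applied before `classify_edu()`")
  }
  table$is_edu_pos <- table$is_sox10_pos &
    table$mean_EdU >= thresholds$edu_min_mean_intensity
  as_tibble(table)
}

#' Suggest a marker threshold from per-object mean intensities
#'
#' Proposes the two-class Otsu split of the supplied values.  This is a
#' convenience beyond the manual workflow (where the operator reads the
#' displayed per-nucleus mean intensities and picks a cut-off); it is never
#' applied without confirmation unless `auto_suggest` is set in
#' [marker_thresholds()].
#'
#' @param values Numeric vector of at least 2 per-object mean intensities
#'   in \[0, 1\].
#' @return Suggested threshold.
#' @export
suggest_threshold <- function(values) {
  if (length(values) < 2) abort("need at least 2 values to suggest a threshold")
  if (min(values) == max(values)) {
    abort("all values identical; no threshold can be suggested")
  }
  otsu_threshold(values)
}
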