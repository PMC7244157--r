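#' Circularity (FormFactor) from area and perimeter
#'
#' `form_factor(area, perimeter) = 4 * pi * area / perimeter^2`; a value of
#' 1 corresponds to a perfect circle (area `pi r^2`, perimeter `2 pi r`).
#' The value is not clamped: small rasterized objects may slightly
#' exceed 1.
#'
#' @param area Object area (pixels^2).
#' @param perimeter Object perimeter (pixels).
#' @return Dimensionless circularity.
#' @examples
#' form_factor(pi * 10^2, 2 * pi * 10)  # circle: 1
#' form_factor(4^2, 4 * 4)              # square: pi / 4
#' @export
form_factor <- function(area, perimeter) 4 * pi * area / perimeter^2

# Clockwise Moore neighbourhood around a pixel, starting West
# (image coordinates, row increases downwards).
MOORE_CW <- cbind(
  dr = c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L),
  dc = c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
)

# Trace the outer boundary of a single 8-connected object (logical matrix,
# padded with background) by Moore-neighbour tracing and return the counts
# of straight and diagonal chain steps.  The walk terminates when the
# (pixel, backtrack) state repeats; the counts are taken over that cycle,
# which is the closed boundary chain.
trace_boundary_chain <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  start <- NULL
  for (r in seq_len(h)) {
    cc <- which(mask[r, ])
    if (length(cc)) { start <- c(r, cc[1]); break }
  }
  if (is.null(start)) return(c(straight = 0L, diagonal = 0L))
  p <- start
  bdir <- 1L  # backtrack = West of the scan-order start pixel
  state_keys <- integer(0)
  steps_dr <- integer(0); steps_dc <- integer(0)
  max_iter <- 8L * sum(mask) + 16L
  for (iter in seq_len(max_iter)) {
    key <- ((p[1] * w + p[2]) * 8L) + bdir
    hit <- match(key, state_keys)
    if (!is.na(hit)) {
      sel <- seq(hit, length(steps_dr))
      diag <- steps_dr[sel] != 0L & steps_dc[sel] != 0L
      return(c(straight = sum(!diag), diagonal = sum(diag)))
    }
    state_keys <- c(state_keys, key)
    found <- FALSE
    for (s in seq_len(8L)) {
      j <- ((bdir - 1L + s - 1L) %% 8L) + 1L
      rr <- p[1] + MOORE_CW[j, 1]; cc <- p[2] + MOORE_CW[j, 2]
      if (rr >= 1 && rr <= h && cc >= 1 && cc <= w && mask[rr, cc]) {
        steps_dr <- c(steps_dr, MOORE_CW[j, 1])
        steps_dc <- c(steps_dc, MOORE_CW[j, 2])
        # new backtrack: the neighbour examined just before the move,
        # expressed relative to the new pixel
        prev_j <- ((bdir - 1L + s - 2L) %% 8L) + 1L
        br <- p[1] + MOORE_CW[prev_j, 1]; bc <- p[2] + MOORE_CW[prev_j, 2]
        p <- c(rr, cc)
        rel <- c(br - rr, bc - cc)
        bdir <- which(MOORE_CW[, 1] == rel[1] & MOORE_CW[, 2] == rel[2])
        found <- TRUE
        break
      }
    }
    if (!found) return(c(straight = 0L, diagonal = 0L))  # isolated pixel
  }
  abort("boundary tracing did not terminate")  # nocov
}

# Corner-corrected chain weights (straight / diagonal step lengths chosen
# so digital contour length is an unbiased estimate of true length).
CHAIN_W_STRAIGHT <- 0.948
CHAIN_W_DIAGONAL <- 1.340

perimeter_of_mask <- function(mask) {
  ch <- trace_boundary_chain(mask)
  p <- CHAIN_W_STRAIGHT * ch[["straight"]] + CHAIN_W_DIAGONAL * ch[["diagonal"]]
  max(p, 1)  # 1-2 pixel objects get perimeter >= 1 by convention
}

#' Per-object shape measurements
#'
#' Computes, for every label: area (pixel count), perimeter (boundary-chain
#' estimator with corner-corrected step weights), FormFactor
#' (`4*pi*Area/Perimeter^2`), equivalent diameter (`2*sqrt(Area/pi)`) and
#' centroid (row/col, 0-based pixel-center coordinates).
#'
#' @param labels Integer label matrix (0 = background).
#' @return A tibble with one row per label, sorted by label.
#' @export
measure_shape <- function(labels) {
  ids <- label_ids(labels)
  if (!length(ids)) {
    return(tibble(label = integer(0), area = numeric(0), perimeter = numeric(0),
                  form_factor = numeric(0), equivalent_diameter = numeric(0),
                  centroid_row = numeric(0), centroid_col = numeric(0)))
  }
  h <- nrow(labels)
  rows <- purrr::map(ids, function(L) {
    idx <- which(labels == L)
    r <- ((idx - 1L) %% h) + 1L
    c <- ((idx - 1L) %/% h) + 1L
    r1 <- min(r); r2 <- max(r); c1 <- min(c); c2 <- max(c)
    sub <- matrix(FALSE, r2 - r1 + 3L, c2 - c1 + 3L)
    sub[cbind(r - r1 + 2L, c - c1 + 2L)] <- TRUE
    per <- perimeter_of_mask(sub)
    area <- length(idx)
    tibble(
      label = L, area = area, perimeter = per,
      form_factor = form_factor(area, per),
      equivalent_diameter = 2 * sqrt(area / pi),
      centroid_row = mean(r) - 1, centroid_col = mean(c) - 1
    )
  })
  dplyr::bind_rows(rows)
}

#' Per-object mean intensity in one channel
#'
#' @param labels Integer label matrix.
#' @param channel Numeric intensity matrix in \[0, 1\], same shape as
#'   `labels`.
#' @param channel_name Name used for the output column `mean_<name>`.
#' @return A tibble with columns `label` and `mean_<channel_name>`.
#' @export
measure_intensity <- function(labels, channel, channel_name) {
  if (!all(dim(labels) == dim(channel))) {
    abort("`channel` shape must match `labels`")
  }
  ids <- label_ids(labels)
  out <- tibble(label = ids)
  if (length(ids)) {
    fg <- labels > 0L
    sums <- rowsum(as.numeric(channel[fg]), group = as.integer(labels[fg]))
    cnts <- rowsum(rep(1, sum(fg)), group = as.integer(labels[fg]))
    means <- as.numeric(sums) / as.numeric(cnts)
    out[[paste0("mean_", channel_name)]] <- means[match(ids, as.integer(rownames(sums)))]
  } else {
    out[[paste0("mean_", channel_name)]] <- numeric(0)
  }
  out
}

#' Full per-object measurement table
#'
#' Shape measurements joined with per-channel mean intensities for every
#' channel of a [cyto_image()] (or a named list of matrices), plus
#' initialized classification flags (`is_real_nucleus`, `is_sox10_pos`,
#' `is_edu_pos`, `has_intact_body`, all `FALSE`).
#'
#' @param labels Integer label matrix.
#' @param image A [cyto_image()] or named list of intensity matrices;
#'   `NULL` for shape-only measurement.
#' @return A tibble with one row per label.
#' @export
measure_objects <- function(labels, image = NULL) {
  tab <- measure_shape(labels)
  chans <- if (inherits(image, "cyto_image")) image$channels else image
  for (ch in names(chans)) {
    tab <- dplyr::left_join(tab, measure_intensity(labels, chans[[ch]], ch),
                            by = "label")
  }
  tab$is_real_nucleus <- rep(FALSE, nrow(tab))
  tab$is_sox10_pos <- rep(FALSE, nrow(tab))
  tab$is_edu_pos <- rep(FALSE, nrow(tab))
  tab$has_intact_body <- rep(FALSE, nrow(tab))
  tab
}
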