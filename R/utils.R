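# Shared low-level helpers (matrices use the row-major, 0-based,
# pixel-center coordinate convention throughout the package).

# Shift a matrix by (dr, dc), filling vacated cells with `fill`.
shift_matrix <- function(m, dr, dc, fill = 0) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  rs <- max(1, 1 + dr):min(h, h + dr)
  cs <- max(1, 1 + dc):min(w, w + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# The 8-connected neighbourhood offsets, row-major order.
NEIGH8 <- cbind(
  dr = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
  dc = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
)

# Clamp x into [lo, hi].
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Gaussian smoothing; sigma = 0 is the identity.  EBImage's gblur needs a
# window larger than the image for very small inputs, so fall back to a
# direct separable convolution there.
gaussian_smooth <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- 2 * ceiling(3 * sigma) + 1
  if (min(dim(x)) > 2 * r) {
    m <- EBImage::gblur(x, sigma = sigma)
    return(matrix(as.numeric(m), nrow(x), ncol(x)))
  }
  k <- stats::dnorm(seq(-ceiling(3 * sigma), ceiling(3 * sigma)), sd = sigma)
  k <- k / sum(k)
  conv1 <- function(v) {
    n <- length(v); half <- (length(k) - 1L) / 2L
    idx <- clamp(outer(seq_len(n), seq(-half, half), "+"), 1L, n)
    as.numeric(matrix(v[idx], n) %*% k)
  }
  sm <- apply(x, 2, conv1)
  t(apply(sm, 1, conv1))
}

# Row-major linear index of matrix positions (1-based rows/cols).
row_major_index <- function(r, c, width) (r - 1L) * width + c

# Labels present in a label map (sorted, excluding background).
label_ids <- function(labels) {
  u <- sort(unique(as.integer(labels)))
  u[u > 0L]
}

# Relabel a label map so the kept labels become 1..K, preserving the
# ascending order of the original labels.  `keep` defaults to all labels.
relabel_map <- function(labels, keep = NULL) {
  ids <- label_ids(labels)
  if (!is.null(keep)) ids <- ids[ids %in% keep]
  out <- matrix(0L, nrow(labels), ncol(labels))
  if (length(ids)) {
    m <- match(as.integer(labels), ids)
    out[!is.na(m)] <- m[!is.na(m)]
  }
  out
}

# Pixel areas per label, as a named integer vector.
label_areas <- function(labels) {
  ids <- label_ids(labels)
  tab <- tabulate(as.integer(labels), nbins = max(ids, 0L))
  stats::setNames(tab[ids], ids)
}

# Boundary pixels: object pixels with an 8-neighbour of a different value
# (background and image edge count as different).
boundary_mask <- function(labels) {
  lab <- labels
  out <- matrix(FALSE, nrow(lab), ncol(lab))
  for (i in seq_len(nrow(NEIGH8))) {
    nb <- shift_matrix(lab, NEIGH8[i, 1], NEIGH8[i, 2], fill = -1L)
    out <- out | (lab > 0L & nb != lab)
  }
  out
}

assert_intensity_matrix <- function(x, name = "image") {
  if (!is.matrix(x) || !is.numeric(x)) {
    abort(sprintf("`%s` must be a numeric matrix", name))
  }
  if (anyNA(x) || min(x) < 0 || max(x) > 1) {
    abort(sprintf("`%s` must have values in [0, 1] with no NAs", name))
  }
  invisible(x)
}
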