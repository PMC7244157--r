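#' Specification for a synthetic cytospin image
#'
#' Describes the study conditions a generated four-channel cytospin image
#' emulates: uniformly rounded, well-separated nuclei on a dark
#' background, a vimentin-positive cell body around each nucleus,
#' marker-positive subsets (SOX10, and EdU nested within SOX10), plus the
#' degradations the real preparation shows -- burst nuclei (irregular,
#' low-circularity shapes), burst/deformed cell bodies, clumped nucleus
#' pairs with a boundary indentation, and cells cut by the image border.
#'
#' Defaults model one image of 100 cells at 70% SOX10-positive with 50%
#' EdU-positive among them, 10% burst nuclei, 10% burst bodies, 10% of
#' cells in clumped pairs and 5% border-touching.
#'
#' @param n_cells Number of cells.
#' @param frac_sox10_pos Fraction of cells that are SOX10-positive.
#' @param frac_edu_pos_given_sox10 Fraction of SOX10-positive cells that
#'   are EdU-positive.
#' @param frac_burst_nuclei Fraction of cells with a burst (star-shaped,
#'   low-circularity) nucleus.
#' @param frac_burst_bodies Fraction of cells with a deformed
#'   (thin-spiked, FormFactor < 0.35) cell body.
#' @param frac_clumped_pairs Fraction of cells that belong to a touching
#'   pair (rounded down to whole pairs).
#' @param frac_border_touching Fraction of cells cut by the image border.
#' @param nucleus_radius_range Min/max nucleus radius in pixels; the
#'   implied equivalent diameters must fall inside the 16--60 px gate.
#' @param body_radius_range Min/max cell-body radius in pixels.
#' @param noise_sd Standard deviation of the additive Gaussian noise
#'   (clipped to \[0, 1\]).
#' @param background_level Background intensity of every channel.
#' @param image_size Height/width in pixels.
#' @param rng_seed Integer seed; identical spec and seed give
#'   bit-identical output.
#' @param marker_levels Named list of rendered intensities: `dapi`,
#'   `vime`, `sox10_pos`, `sox10_neg`, `edu_pos`, `edu_neg`.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_cells = 100,
                           frac_sox10_pos = 0.7,
                           frac_edu_pos_given_sox10 = 0.5,
                           frac_burst_nuclei = 0.1,
                           frac_burst_bodies = 0.1,
                           frac_clumped_pairs = 0.1,
                           frac_border_touching = 0.05,
                           nucleus_radius_range = c(14, 18),
                           body_radius_range = c(22, 28),
                           noise_sd = 0.01,
                           background_level = 0.01,
                           image_size = c(1024, 1024),
                           rng_seed = 1L,
                           marker_levels = list(
                             dapi = 0.85, vime = 0.55,
                             sox10_pos = 0.8, sox10_neg = 0.05,
                             edu_pos = 0.8, edu_neg = 0.03
                           )) {
  fracs <- c(frac_sox10_pos, frac_edu_pos_given_sox10, frac_burst_nuclei,
             frac_burst_bodies, frac_clumped_pairs, frac_border_touching)
  stopifnot(
    n_cells >= 0,
    all(fracs >= 0 & fracs <= 1),
    length(nucleus_radius_range) == 2, all(nucleus_radius_range > 0),
    nucleus_radius_range[1] <= nucleus_radius_range[2],
    length(body_radius_range) == 2, all(body_radius_range > 0),
    body_radius_range[1] <= body_radius_range[2],
    noise_sd >= 0, background_level >= 0, background_level <= 1,
    length(image_size) == 2, all(image_size >= 64)
  )
  if (2 * nucleus_radius_range[1] < 16 || 2 * nucleus_radius_range[2] > 60) {
    abort("nucleus diameters must fall inside the 16-60 px object gate")
  }
  structure(
    list(
      n_cells = as.integer(n_cells),
      frac_sox10_pos = frac_sox10_pos,
      frac_edu_pos_given_sox10 = frac_edu_pos_given_sox10,
      frac_burst_nuclei = frac_burst_nuclei,
      frac_burst_bodies = frac_burst_bodies,
      frac_clumped_pairs = frac_clumped_pairs,
      frac_border_touching = frac_border_touching,
      nucleus_radius_range = nucleus_radius_range,
      body_radius_range = body_radius_range,
      noise_sd = noise_sd,
      background_level = background_level,
      image_size = as.integer(image_size),
      rng_seed = as.integer(rng_seed),
      marker_levels = marker_levels
    ),
    class = "synthetic_spec"
  )
}

# Radial shape functions, vectorized over theta.
shape_round <- function(r, amp, k, phase) {
  function(theta) r * (1 + amp * sin(k * theta + phase))
}
# Star polygon: m spikes between r_in and r_out (triangle wave, sharpened).
shape_star <- function(r_in, r_out, m, phase) {
  function(theta) {
    frac <- (m * theta / (2 * pi) + phase) %% 1
    tri <- 1 - 2 * abs(frac - 0.5)
    r_in + (r_out - r_in) * tri^1.5
  }
}
# Thin-spiked deformed body: round core of radius r_core with m narrow
# spikes reaching r_tip.
shape_spiky <- function(r_core, r_tip, m, phase) {
  function(theta) {
    lobe <- pmax(0, cos(m * (theta + phase) / 2))^18
    r_core + (r_tip - r_core) * lobe
  }
}

# Rasterize a radial shape centered at (cr, cc) (1-based, fractional) into
# the running label/distance maps; pixels claimed by a nearer center win.
rasterize_shape <- function(state, shape_fn, cr, cc, r_max, id) {
  h <- nrow(state$labels); w <- ncol(state$labels)
  rs <- max(1, floor(cr - r_max - 2)):min(h, ceiling(cr + r_max + 2))
  cs <- max(1, floor(cc - r_max - 2)):min(w, ceiling(cc + r_max + 2))
  if (!length(rs) || !length(cs)) return(state)
  dr <- rs - cr
  dc <- cs - cc
  dist <- sqrt(outer(dr^2, dc^2, "+"))
  theta <- atan2(outer(dr, rep(1, length(cs))), outer(rep(1, length(rs)), dc))
  inside <- dist <= shape_fn(theta)
  closer <- inside & dist < state$dist[rs, cs]
  sub_l <- state$labels[rs, cs]
  sub_d <- state$dist[rs, cs]
  sub_l[closer] <- id
  sub_d[closer] <- dist[closer]
  state$labels[rs, cs] <- sub_l
  state$dist[rs, cs] <- sub_d
  state
}

#' Generate a synthetic cytospin image with exact ground truth
#'
#' Renders the four channels (DAPI, SOX10, EdU, VIME) plus ground-truth
#' nucleus and body label maps from a [synthetic_spec()].  All stochastic
#' choices are drawn from one generator seeded with `spec$rng_seed`, in a
#' fixed order (statuses, marker flags, radii, placement, shapes,
#' per-cell brightness, then per-channel noise), so identical spec and
#' seed give bit-identical output.
#'
#' @param spec A [synthetic_spec()].
#' @return A list of class `cyto_simulation` with elements `image`
#'   (a [cyto_image()]), `truth` (list with `nucleus_label_map`,
#'   `body_label_map`, per-cell tibble `cells` and `expected_counts`) and
#'   `spec`.
#' @export
simulate_cytospin <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$rng_seed, simulate_cytospin_impl(spec))
}

simulate_cytospin_impl <- function(spec) {
  h <- spec$image_size[1]; w <- spec$image_size[2]
  n <- spec$n_cells
  lv <- spec$marker_levels
  empty_truth <- function(cells) {
    intact <- !cells$is_burst_nucleus & !cells$is_burst_body & !cells$touches_border
    list(
      nucleus_label_map = matrix(0L, h, w),
      body_label_map = matrix(0L, h, w),
      cells = cells,
      expected_counts = list(
        real_cells = sum(intact),
        sox10_cells = sum(intact & cells$is_sox10_pos),
        sox10_edu_cells = sum(intact & cells$is_edu_pos)
      )
    )
  }
  cells0 <- tibble(
    cell = integer(0), centroid_row = numeric(0), centroid_col = numeric(0),
    nucleus_radius = numeric(0), body_radius = numeric(0),
    is_burst_nucleus = logical(0), is_burst_body = logical(0),
    touches_border = logical(0), is_clumped = logical(0),
    is_sox10_pos = logical(0), is_edu_pos = logical(0)
  )
  noisy <- function(base) {
    clamp(base + matrix(rnorm(h * w, 0, spec$noise_sd), h, w), 0, 1)
  }
  if (n == 0L) {
    bg <- matrix(spec$background_level, h, w)
    channels <- list(DAPI = noisy(bg), SOX10 = noisy(bg),
                     EdU = noisy(bg), VIME = noisy(bg))
    image <- cyto_image(channels,
                        stats::setNames(rep("synthetic", 4), names(channels)))
    return(structure(list(image = image, truth = empty_truth(cells0),
                          spec = spec), class = "cyto_simulation"))
  }

  # 1. degradation statuses (mutually exclusive), assigned over a single
  #    permutation of cell ids
  n_border <- round(spec$frac_border_touching * n)
  n_burst_nuc <- round(spec$frac_burst_nuclei * n)
  n_burst_body <- round(spec$frac_burst_bodies * n)
  n_clump <- 2L * (round(spec$frac_clumped_pairs * n) %/% 2L)
  if (n_border + n_burst_nuc + n_burst_body + n_clump > n) {
    abort("degradation fractions sum to more than the cell count")
  }
  perm <- sample.int(n)
  take <- function(k) {
    ids <- perm[seq_len(k)]
    perm <<- perm[-seq_len(k)]
    ids
  }
  border_ids <- if (n_border) take(n_border) else integer(0)
  burst_nuc_ids <- if (n_burst_nuc) take(n_burst_nuc) else integer(0)
  burst_body_ids <- if (n_burst_body) take(n_burst_body) else integer(0)
  clump_ids <- if (n_clump) take(n_clump) else integer(0)
  clump_primary <- clump_ids[seq_len(n_clump / 2)]
  clump_partner <- clump_ids[seq_len(n_clump / 2) + n_clump / 2]

  # 2. marker flags (EdU nested within SOX10)
  sox_ids <- sample.int(n, round(spec$frac_sox10_pos * n))
  edu_ids <- if (length(sox_ids)) {
    sample(sox_ids, round(spec$frac_edu_pos_given_sox10 * length(sox_ids)))
  } else integer(0)

  # 3. radii
  r_nuc <- runif(n, spec$nucleus_radius_range[1], spec$nucleus_radius_range[2])
  r_body <- pmax(r_nuc + 4,
                 runif(n, spec$body_radius_range[1], spec$body_radius_range[2]))
  r_nuc[clump_partner] <- r_nuc[clump_primary]

  # 4. placement: interior cells on a jittered grid whose pitch reserves
  #    room for the widest cell (or clumped pair); border cells on spaced
  #    slots along the four borders
  max_body <- max(r_body)
  pair_ext <- max_body + 0.8 * max(r_nuc)
  pitch <- 2 * pair_ext + 6
  margin <- 2 * max_body + 12
  grid_r <- seq(margin, h - margin, by = pitch)
  grid_c <- seq(margin, w - margin, by = pitch)
  interior_ids <- setdiff(seq_len(n), c(border_ids, clump_partner))
  if (length(grid_r) * length(grid_c) < length(interior_ids)) {
    abort("cells cannot be placed: image too small for the requested cell count")
  }
  slots <- sample.int(length(grid_r) * length(grid_c), length(interior_ids))
  cr <- numeric(n); cc <- numeric(n)
  cr[interior_ids] <- grid_r[((slots - 1L) %% length(grid_r)) + 1L] + runif(length(slots), -2, 2)
  cc[interior_ids] <- grid_c[((slots - 1L) %/% length(grid_r)) + 1L] + runif(length(slots), -2, 2)
  if (length(clump_primary)) {
    theta <- runif(length(clump_primary), 0, 2 * pi)
    dfac <- runif(length(clump_primary), 1.2, 1.6)
    d <- dfac * r_nuc[clump_primary]
    # symmetric about the grid site so the pair stays inside its slot
    cr[clump_partner] <- cr[clump_primary] + d * sin(theta) / 2
    cc[clump_partner] <- cc[clump_primary] + d * cos(theta) / 2
    cr[clump_primary] <- cr[clump_primary] - d * sin(theta) / 2
    cc[clump_primary] <- cc[clump_primary] - d * cos(theta) / 2
  }
  if (length(border_ids)) {
    per_side <- split(border_ids, rep_len(1:4, length(border_ids)))
    for (side in seq_along(per_side)) {
      ids <- per_side[[side]]
      if (!length(ids)) next
      along_slots <- seq(margin, (if (side %in% c(1, 2)) w else h) - margin,
                         by = pitch)
      pos <- along_slots[sample.int(length(along_slots), length(ids))] +
        runif(length(ids), -2, 2)
      depth <- runif(length(ids), 0.2, 0.6) * r_nuc[ids]
      if (side == 1) { cr[ids] <- depth; cc[ids] <- pos }
      else if (side == 2) { cr[ids] <- h - depth; cc[ids] <- pos }
      else if (side == 3) { cr[ids] <- pos; cc[ids] <- depth }
      else { cr[ids] <- pos; cc[ids] <- w - depth }
    }
  }

  # 5. ground-truth label maps (overlaps resolved toward the nearer
  #    center, which draws the true dividing line of clumped pairs)
  is_burst_nuc <- seq_len(n) %in% burst_nuc_ids
  is_burst_body <- seq_len(n) %in% burst_body_ids
  nuc_state <- list(labels = matrix(0L, h, w), dist = matrix(Inf, h, w))
  body_state <- list(labels = matrix(0L, h, w), dist = matrix(Inf, h, w))
  phase_n <- runif(n, 0, 2 * pi)
  k_n <- sample(3:6, n, replace = TRUE)
  m_star <- sample(4:7, n, replace = TRUE)
  phase_b <- runif(n, 0, 2 * pi)
  k_b <- sample(3:6, n, replace = TRUE)
  m_spike <- sample(10:12, n, replace = TRUE)
  for (i in seq_len(n)) {
    fn <- if (is_burst_nuc[i]) {
      shape_star(0.35 * r_nuc[i], r_nuc[i], m_star[i], phase_n[i] / (2 * pi))
    } else {
      shape_round(r_nuc[i], 0.04, k_n[i], phase_n[i])
    }
    nuc_state <- rasterize_shape(nuc_state, fn, cr[i], cc[i],
                                 1.05 * r_nuc[i], i)
    bfn <- if (is_burst_body[i]) {
      shape_spiky(r_nuc[i] + 2, r_body[i] + 14, m_spike[i], phase_b[i])
    } else {
      shape_round(r_body[i], 0.04, k_b[i], phase_b[i])
    }
    body_state <- rasterize_shape(body_state, bfn, cr[i], cc[i],
                                  r_body[i] + 16, i)
  }
  nl <- nuc_state$labels
  bl <- body_state$labels
  bl[nl > 0L] <- nl[nl > 0L]  # the body of a cell contains its nucleus

  touches_border <- vapply(seq_len(n), function(i) {
    any(nl[1, ] == i) || any(nl[h, ] == i) ||
      any(nl[, 1] == i) || any(nl[, w] == i)
  }, logical(1))

  # 6. channels: per-cell brightness jitter, then additive clipped noise
  #    (channel order DAPI, SOX10, EdU, VIME)
  jit_d <- runif(n, 0.92, 1.08)
  jit_v <- runif(n, 0.92, 1.08)
  bg <- spec$background_level
  nuc_idx <- which(nl > 0L)
  body_idx <- which(bl > 0L)
  nuc_cell <- nl[nuc_idx]
  body_cell <- bl[body_idx]
  dapi <- matrix(bg, h, w)
  dapi[nuc_idx] <- clamp(lv$dapi * jit_d[nuc_cell], 0, 1)
  sox <- matrix(bg, h, w)
  sox_level <- ifelse(seq_len(n) %in% sox_ids, lv$sox10_pos, lv$sox10_neg)
  sox[nuc_idx] <- sox_level[nuc_cell]
  edu <- matrix(bg, h, w)
  edu_level <- ifelse(seq_len(n) %in% edu_ids, lv$edu_pos, lv$edu_neg)
  edu[nuc_idx] <- edu_level[nuc_cell]
  vime <- matrix(bg, h, w)
  vime[body_idx] <- clamp(lv$vime * jit_v[body_cell], 0, 1)
  channels <- list(DAPI = noisy(dapi), SOX10 = noisy(sox),
                   EdU = noisy(edu), VIME = noisy(vime))

  cells <- tibble(
    cell = seq_len(n),
    centroid_row = cr - 1, centroid_col = cc - 1,
    nucleus_radius = r_nuc, body_radius = r_body,
    is_burst_nucleus = is_burst_nuc,
    is_burst_body = is_burst_body,
    touches_border = touches_border,
    is_clumped = seq_len(n) %in% clump_ids,
    is_sox10_pos = seq_len(n) %in% sox_ids,
    is_edu_pos = seq_len(n) %in% edu_ids
  )
  truth <- empty_truth(cells)
  truth$nucleus_label_map <- nl
  truth$body_label_map <- bl
  image <- cyto_image(channels,
                      stats::setNames(rep("synthetic", 4), names(channels)))
  structure(list(image = image, truth = truth, spec = spec),
            class = "cyto_simulation")
}

#' @export
print.cyto_simulation <- function(x, ...) {
  ec <- x$truth$expected_counts
  cat(sprintf(
    "<cyto_simulation> %d cells on %d x %d px; truth: %d real cells, %d SOX10+, %d SOX10+/EdU+\n",
    x$spec$n_cells, x$spec$image_size[1], x$spec$image_size[2],
    ec$real_cells, ec$sox10_cells, ec$sox10_edu_cells
  ))
  invisible(x)
}

#' Write a simulated cytospin to disk as a test fixture
#'
#' Writes the four channels as 16-bit TIFFs (`dapi.tif`, `sox10.tif`,
#' `edu.tif`, `vime.tif`), the ground-truth label maps as 16-bit TIFFs
#' (`nuclei_gt.tif`, `bodies_gt.tif`), the per-cell records as `truth.csv`,
#' the expected counts as `expected_counts.csv`, and the generating spec
#' as `spec.yaml`.  Re-running on the same inputs is byte-identical.
#'
#' @param sim A [simulate_cytospin()] result.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_fixture <- function(sim, out_dir) {
  stopifnot(inherits(sim, "cyto_simulation"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (file.access(out_dir, mode = 2) != 0) {
    abort(sprintf("directory not writable: %s", out_dir))
  }
  files <- c(DAPI = "dapi.tif", SOX10 = "sox10.tif", EdU = "edu.tif",
             VIME = "vime.tif")
  for (ch in names(files)) {
    write_channel(sim$image$channels[[ch]], file.path(out_dir, files[[ch]]))
  }
  write_label_tiff <- function(labels, path) {
    if (max(labels) > 65535) abort("label map exceeds 16-bit range")
    tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  }
  write_label_tiff(sim$truth$nucleus_label_map, file.path(out_dir, "nuclei_gt.tif"))
  write_label_tiff(sim$truth$body_label_map, file.path(out_dir, "bodies_gt.tif"))
  utils::write.csv(sim$truth$cells, file.path(out_dir, "truth.csv"),
                   row.names = FALSE)
  ec <- sim$truth$expected_counts
  utils::write.csv(
    data.frame(real_cells = ec$real_cells, sox10_cells = ec$sox10_cells,
               sox10_edu_cells = ec$sox10_edu_cells),
    file.path(out_dir, "expected_counts.csv"), row.names = FALSE
  )
  spec_plain <- unclass(sim$spec)
  yaml::write_yaml(spec_plain, file.path(out_dir, "spec.yaml"))
  invisible(out_dir)
}

#' Read a label map written by [write_fixture()]
#'
#' @param path Path to a 16-bit label TIFF.
#' @return Integer label matrix.
#' @export
read_label_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}
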