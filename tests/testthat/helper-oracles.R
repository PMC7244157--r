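# Independent oracles used to cross-check the package's algorithms.
# These deliberately re-derive results by brute force and share no code
# with the implementation paths they verify.

# Exhaustive two-class Otsu: scan every candidate split of a 256-bin
# histogram and return the bin index maximizing between-class variance.
oracle_otsu_bin <- function(v, bins = 256L) {
  b <- pmin(floor(v * bins) + 1L, bins)
  h <- tabulate(b, nbins = bins)
  mid <- (seq_len(bins) - 0.5) / bins
  best <- -Inf
  best_k <- 1L
  for (k in seq_len(bins - 1L)) {
    n0 <- sum(h[1:k]); n1 <- sum(h) - n0
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum(h[1:k] * mid[1:k]) / n0
    mu1 <- sum(h[(k + 1):bins] * mid[(k + 1):bins]) / n1
    w0 <- n0 / sum(h)
    sb <- w0 * (1 - w0) * (mu0 - mu1)^2
    if (sb > best) {
      best <- sb
      best_k <- k
    }
  }
  best_k
}

# Brute-force multi-source shortest path (Bellman-Ford to fixpoint) for
# the seeded propagation: lexicographic (accumulated cost, seed label)
# minimum over all 8-connected walks, with the same step-cost expression
# and frozen seed pixels as the implementation.
oracle_propagate <- function(seeds, intensity, region, lambda) {
  h <- nrow(seeds); w <- ncol(seeds)
  cost <- matrix(Inf, h, w)
  lab <- matrix(0L, h, w)
  seed_px <- seeds > 0L
  cost[seed_px] <- 0
  lab[seed_px] <- seeds[seed_px]
  shifts <- expand.grid(dr = -1:1, dc = -1:1)
  shifts <- shifts[!(shifts$dr == 0 & shifts$dc == 0), ]
  shift_o <- function(m, dr, dc, fill) {
    out <- matrix(fill, h, w)
    rs <- max(1, 1 + dr):min(h, h + dr)
    cs <- max(1, 1 + dc):min(w, w + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  repeat {
    changed <- FALSE
    for (s in seq_len(nrow(shifts))) {
      dr <- shifts$dr[s]; dc <- shifts$dc[s]
      dl <- if (dr != 0 && dc != 0) sqrt(2) else 1
      cu <- shift_o(cost, dr, dc, Inf)
      lu <- shift_o(lab, dr, dc, 0L)
      iu <- shift_o(intensity, dr, dc, 0)
      di <- iu - intensity
      nc <- cu + sqrt(di * di + lambda * dl * dl)
      upd <- region & !seed_px & is.finite(nc) &
        (nc < cost | (nc == cost & lu < lab & lu > 0L))
      if (any(upd)) {
        cost[upd] <- nc[upd]
        lab[upd] <- lu[upd]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  lab
}

# Brute-force Euclidean distance transform (distance to the nearest
# background pixel) for small masks.
oracle_distmap <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  bg <- which(!mask, arr.ind = TRUE)
  out <- matrix(0, h, w)
  fg <- which(mask, arr.ind = TRUE)
  for (i in seq_len(nrow(fg))) {
    out[fg[i, 1], fg[i, 2]] <-
      sqrt(min((bg[, 1] - fg[i, 1])^2 + (bg[, 2] - fg[i, 2])^2))
  }
  out
}

# Count local maxima (>= all 8 neighbours) of a kernel-smoothed distance
# map with greedy minimum-separation suppression; independent seed-count
# oracle for the declumping stage.
oracle_seed_count <- function(mask, sigma, min_sep) {
  dm <- oracle_distmap(mask)
  half <- ceiling(3 * sigma)
  k1 <- dnorm(-half:half, sd = sigma)
  k1 <- k1 / sum(k1)
  h <- nrow(dm); w <- ncol(dm)
  sm <- matrix(0, h, w)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    acc <- 0
    for (i in -half:half) for (j in -half:half) {
      rr <- min(max(r + i, 1), h); cc <- min(max(c + j, 1), w)
      acc <- acc + dm[rr, cc] * k1[i + half + 1] * k1[j + half + 1]
    }
    sm[r, c] <- acc
  }
  sm[!mask] <- 0
  cand <- NULL
  for (r in 2:(h - 1)) for (c in 2:(w - 1)) {
    if (!mask[r, c]) next
    nb <- sm[(r - 1):(r + 1), (c - 1):(c + 1)]
    if (sm[r, c] > 0 && sm[r, c] >= max(nb)) cand <- rbind(cand, c(r, c, sm[r, c]))
  }
  if (is.null(cand)) return(0L)
  cand <- cand[order(-cand[, 3], (cand[, 1] - 1) * w + cand[, 2]), , drop = FALSE]
  acc <- cand[1, 1:2, drop = FALSE]
  for (i in seq_len(nrow(cand))[-1]) {
    d2 <- (acc[, 1] - cand[i, 1])^2 + (acc[, 2] - cand[i, 2])^2
    if (all(d2 >= min_sep^2)) acc <- rbind(acc, cand[i, 1:2])
  }
  nrow(acc)
}

# Independent perimeter for convex objects: boundary pixels ordered by
# angle around the centroid, chain steps weighted like the estimator.
oracle_convex_perimeter <- function(mask) {
  px <- which(mask, arr.ind = TRUE)
  cen <- colMeans(px)
  # 4-connected boundary: the pixels an 8-connected contour walk visits
  is_bnd <- function(r, c) {
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      rr <- r + d[1]; cc <- c + d[2]
      if (rr < 1 || rr > nrow(mask) || cc < 1 || cc > ncol(mask) ||
          !mask[rr, cc]) return(TRUE)
    }
    FALSE
  }
  bnd <- px[apply(px, 1, function(p) is_bnd(p[1], p[2])), , drop = FALSE]
  ang <- atan2(bnd[, 1] - cen[1], bnd[, 2] - cen[2])
  bnd <- bnd[order(ang), , drop = FALSE]
  steps <- rbind(diff(bnd), bnd[1, ] - bnd[nrow(bnd), ])
  stopifnot(all(abs(steps) <= 1))  # consecutive-by-angle pixels are chain neighbours
  diag <- steps[, 1] != 0 & steps[, 2] != 0
  0.948 * sum(!diag) + 1.340 * sum(diag)
}

# Closed-form paired t-test on differences.
oracle_paired_t <- function(auto, manual) {
  d <- auto - manual
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(t = t, p = 2 * pt(-abs(t), df = n - 1))
}
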