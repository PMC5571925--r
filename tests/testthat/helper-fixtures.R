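# Fixture builders and independent brute-force oracles used across tests.
# The oracles are deliberately naive (triple loops, flood fills) so they
# share no code with the package implementations they check.

# Digital sphere mask of radius r_vox voxels on an isotropic grid.
mk_sphere_mask <- function(r_vox, spacing = 1, margin = 3L) {
  n <- as.integer(2 * r_vox + 2 * margin)
  ctr <- (n + 1) / 2
  g <- expand.grid(i = 1:n, j = 1:n, k = 1:n)
  a <- array((g$i - ctr)^2 + (g$j - ctr)^2 + (g$k - ctr)^2 <= r_vox^2,
             c(n, n, n))
  lesion_mask(a, rep(spacing, 3))
}

# Uniform-valued volume covering a given mask.
mk_uniform_volume <- function(mask, lesion_value, background = 0) {
  a <- array(background, dim(mask$values))
  a[mask$values] <- lesion_value
  suv_volume(a, mask$spacing)
}

# The 13 unique one-voxel displacement directions, written out literally.
ORACLE_DIRS <- rbind(
  c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
  c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1), c(0, 1, 1), c(0, 1, -1),
  c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1)
)

# Exhaustive pair enumeration for the co-occurrence matrix.
glcm_oracle <- function(lev, G) {
  dm <- dim(lev)
  cnt <- matrix(0, G, G)
  for (r in seq_len(nrow(ORACLE_DIRS))) {
    d <- ORACLE_DIRS[r, ]
    for (x in 1:dm[1]) for (y in 1:dm[2]) for (z in 1:dm[3]) {
      p2 <- c(x, y, z) + d
      if (all(p2 >= 1) && all(p2 <= dm) &&
          !is.na(lev[x, y, z]) && !is.na(lev[p2[1], p2[2], p2[3]])) {
        i <- lev[x, y, z]; j <- lev[p2[1], p2[2], p2[3]]
        cnt[i, j] <- cnt[i, j] + 1
        cnt[j, i] <- cnt[j, i] + 1
      }
    }
  }
  cnt
}

# Direct run-scanning oracle for the run-length matrix.
glrlm_oracle <- function(lev, G) {
  dm <- dim(lev)
  cnt <- matrix(0, G, max(dm))
  for (r in seq_len(nrow(ORACLE_DIRS))) {
    d <- ORACLE_DIRS[r, ]
    for (x in 1:dm[1]) for (y in 1:dm[2]) for (z in 1:dm[3]) {
      if (is.na(lev[x, y, z])) next
      pb <- c(x, y, z) - d
      starts_run <- !(all(pb >= 1) && all(pb <= dm) &&
                        !is.na(lev[pb[1], pb[2], pb[3]]) &&
                        lev[pb[1], pb[2], pb[3]] == lev[x, y, z])
      if (!starts_run) next
      len <- 0L
      p <- c(x, y, z)
      while (all(p >= 1) && all(p <= dm) && !is.na(lev[p[1], p[2], p[3]]) &&
             lev[p[1], p[2], p[3]] == lev[x, y, z]) {
        len <- len + 1L
        p <- p + d
      }
      cnt[lev[x, y, z], len] <- cnt[lev[x, y, z], len] + 1
    }
  }
  cnt
}

# Flood-fill oracle for the size-zone matrix (26-connected equal-level zones).
glszm_oracle <- function(lev, G) {
  dm <- dim(lev)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  lab <- array(0L, dm)
  sizes <- integer(0)
  levels <- integer(0)
  nz <- 0L
  for (x in 1:dm[1]) for (y in 1:dm[2]) for (z in 1:dm[3]) {
    if (is.na(lev[x, y, z]) || lab[x, y, z] > 0L) next
    nz <- nz + 1L
    queue <- matrix(c(x, y, z), 1)
    lab[x, y, z] <- nz
    size <- 1L
    while (nrow(queue) > 0L) {
      p <- queue[1, ]
      queue <- queue[-1, , drop = FALSE]
      for (r in seq_len(nrow(offs))) {
        q <- p + offs[r, ]
        if (all(q >= 1) && all(q <= dm) && !is.na(lev[q[1], q[2], q[3]]) &&
            lab[q[1], q[2], q[3]] == 0L &&
            lev[q[1], q[2], q[3]] == lev[x, y, z]) {
          lab[q[1], q[2], q[3]] <- nz
          size <- size + 1L
          queue <- rbind(queue, q)
        }
      }
    }
    sizes <- c(sizes, size)
    levels <- c(levels, lev[x, y, z])
  }
  cnt <- matrix(0, G, max(sizes))
  for (k in seq_along(sizes)) {
    cnt[levels[k], sizes[k]] <- cnt[levels[k], sizes[k]] + 1
  }
  cnt
}

# Brute-force SUVpeak: for every mask voxel, average over every grid voxel
# whose center lies within the sphere radius, take the maximum mean.
suv_peak_oracle <- function(vol, mask, radius_mm = SUVPEAK_RADIUS_MM) {
  dm <- dim(vol$values)
  sp <- vol$spacing
  centers <- which(mask$values, arr.ind = TRUE)
  allv <- which(array(TRUE, dm), arr.ind = TRUE)
  best <- -Inf
  for (c8 in seq_len(nrow(centers))) {
    d2 <- ((allv[, 1] - centers[c8, 1]) * sp[1])^2 +
      ((allv[, 2] - centers[c8, 2]) * sp[2])^2 +
      ((allv[, 3] - centers[c8, 3]) * sp[3])^2
    inside <- d2 <= radius_mm^2
    best <- max(best, mean(vol$values[inside]))
  }
  best
}

# Random masked phantom on a small grid, for property checks.
mk_random_quantized_case <- function(seed, dm = c(4L, 4L, 4L), Gmax = 4L,
                                     p_mask = 0.7) {
  set.seed(seed)
  G <- sample(2:Gmax, 1)
  vol <- suv_volume(array(runif(prod(dm), 0, 10), dm), c(1, 1, 1))
  mask <- lesion_mask(array(runif(prod(dm)) < p_mask, dm), c(1, 1, 1))
  if (sum(mask$values) < 2) mask$values[1:2] <- TRUE
  list(vol = vol, mask = mask, G = G,
       q = quantize(vol, mask, G = G))
}
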