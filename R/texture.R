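#' Grey-level quantization of a masked volume
#'
#' Resamples the masked SUV values to `G` grey levels before texture-matrix
#' construction. The default min--max scheme maps the masked range onto
#' `1..G` as `level = min(G, floor(G * (v - min) / (max - min)) + 1)`, which
#' makes every downstream texture feature invariant under positive affine
#' transforms of the raw intensities; a constant region maps entirely to
#' level 1. A fixed-bin-width alternative is available.
#'
#' @inheritParams suv_basic
#' @param G number of grey levels, >= 2 (default 64).
#' @param method `"minmax"` (default) or `"fixed_width"`.
#' @param bin_width bin width in SUV for `method = "fixed_width"`.
#' @return An object of class `quantized_volume`: integer `levels` array
#'   (`NA` outside the mask), `G`, and the `bounds` (masked min, max) used.
#' @export
quantize <- function(vol, mask, G = 64L, method = c("minmax", "fixed_width"),
                     bin_width = 0.25) {
  method <- match.arg(method)
  check_aligned(vol, mask)
  check_nonempty(mask)
  G <- as.integer(G)
  if (G < 2L) stopf("G must be >= 2")
  x <- vol$values[mask$values]
  lo <- min(x); hi <- max(x)
  lev <- if (method == "minmax") {
    if (hi == lo) rep(1L, length(x))
    else pmin(G, as.integer(floor(G * (x - lo) / (hi - lo))) + 1L)
  } else {
    if (bin_width <= 0) stopf("bin_width must be > 0")
    pmin(G, as.integer(floor((x - lo) / bin_width)) + 1L)
  }
  levels <- array(NA_integer_, dim(vol$values))
  levels[mask$values] <- lev
  structure(list(levels = levels, G = G, bounds = c(lo, hi),
                 spacing = vol$spacing, method = method),
            class = "quantized_volume")
}

#' 3-D grey-level co-occurrence matrix
#'
#' Counts ordered pairs of masked voxels at one-voxel displacement along the
#' 13 unique 3-D directions (half of the 26-neighborhood), aggregated into a
#' single matrix; each pair is accumulated in both orientations so the
#' matrix is symmetric, then normalized to probabilities.
#'
#' @param q a [quantize()]d volume.
#' @return An object of class `glcm`: `counts` (G x G), `p` (probabilities),
#'   `G`.
#' @export
build_glcm <- function(q) {
  stopifnot(inherits(q, "quantized_volume"))
  G <- q$G
  dm <- dim(q$levels)
  in_mask <- !is.na(q$levels)
  counts <- numeric(G * G)
  for (r in seq_len(nrow(DIRECTIONS_13))) {
    pr <- offset_pairs(dm, DIRECTIONS_13[r, ])
    if (is.null(pr)) next
    ok <- in_mask[pr$from] & in_mask[pr$to]
    if (!any(ok)) next
    i <- q$levels[pr$from[ok]]
    j <- q$levels[pr$to[ok]]
    counts <- counts + tabulate(i + (j - 1L) * G, G * G) +
      tabulate(j + (i - 1L) * G, G * G)
  }
  counts <- matrix(counts, G, G)
  if (sum(counts) == 0) stopf("no voxel pairs: mask has < 2 voxels in every direction")
  structure(list(counts = counts, p = counts / sum(counts), G = G),
            class = "glcm")
}

#' GLCM texture features
#'
#' Homogeneity `sum p(i,j) / (1 + |i-j|)`, entropy `-sum p log2 p` (bits)
#' and dissimilarity `sum |i-j| p(i,j)` of a normalized co-occurrence
#' matrix.
#'
#' @param m a [build_glcm()] result.
#' @return Named numeric vector `c(homogeneity =, entropy =, dissimilarity =)`.
#' @export
glcm_features <- function(m) {
  stopifnot(inherits(m, "glcm"))
  p <- m$p
  if (abs(sum(p) - 1) > 1e-8) stopf("co-occurrence matrix is not normalized")
  dij <- abs(row(p) - col(p))
  pos <- p > 0
  c(homogeneity = sum(p / (1 + dij)),
    entropy = -sum(p[pos] * log2(p[pos])),
    dissimilarity = sum(dij * p))
}

#' 3-D grey-level run-length matrix
#'
#' Maximal runs of constant grey level along each of the 13 one-voxel
#' displacement directions, confined to the mask (a gap in the mask breaks a
#' run), accumulated into a single matrix `r(i, l)` of grey level by run
#' length.
#'
#' @param q a [quantize()]d volume.
#' @return An object of class `glrlm`: `counts` (G x Lmax), `Nr` (total run
#'   count), `G`.
#' @export
build_glrlm <- function(q) {
  stopifnot(inherits(q, "quantized_volume"))
  G <- q$G
  dm <- dim(q$levels)
  vox <- which(!is.na(q$levels), arr.ind = TRUE)
  if (nrow(vox) == 0L) stopf("empty mask")
  lev <- q$levels[vox]
  lmax <- max(dm)
  counts <- matrix(0, G, lmax)
  for (r in seq_len(nrow(DIRECTIONS_13))) {
    d <- DIRECTIONS_13[r, ]
    dd <- sum(d^2)
    s <- as.vector(vox %*% d)
    # line identifier: the rejection of the voxel position from the
    # direction, scaled to stay integer -- constant along a line, distinct
    # across parallel lines; packed into one exact double for ordering
    id <- dd * vox - outer(s, d)
    M <- 16 * lmax + 8
    B <- 2 * M + 1
    key <- ((id[, 1L] + M) * B + (id[, 2L] + M)) * B + (id[, 3L] + M)
    ord <- order(key, s)
    k <- key[ord]; ss <- s[ord]; ll <- lev[ord]
    n <- length(k)
    brk <- c(TRUE, k[-1L] != k[-n] | ss[-1L] - ss[-n] != dd | ll[-1L] != ll[-n])
    run_id <- cumsum(brk)
    run_len <- tabulate(run_id)
    run_lev <- ll[brk]
    inc <- table(factor(run_lev, levels = 1:G), factor(run_len, levels = 1:lmax))
    counts <- counts + unclass(inc)
  }
  structure(list(counts = counts, Nr = sum(counts), G = G), class = "glrlm")
}

#' High grey-level run emphasis
#'
#' `HGRE = (1/Nr) sum_{i,l} r(i,l) * i^2`: large when runs concentrate at
#' high grey levels.
#'
#' @param m a [build_glrlm()] result.
#' @return Scalar HGRE.
#' @export
hgre <- function(m) {
  stopifnot(inherits(m, "glrlm"))
  sum(rowSums(m$counts) * (seq_len(m$G))^2) / m$Nr
}

#' 3-D grey-level size-zone matrix
#'
#' Zones are maximal 26-connected sets of voxels sharing one grey level
#' within the mask; `z(i, s)` counts zones of level `i` and size `s`
#' voxels. Zone sizes tile the mask: `sum_s s * z(i, s)` equals the masked
#' voxel count.
#'
#' @param q a [quantize()]d volume.
#' @return An object of class `glszm`: `counts` (G x Smax), `Nz` (zone
#'   count), `G`.
#' @export
build_glszm <- function(q) {
  stopifnot(inherits(q, "quantized_volume"))
  in_mask <- !is.na(q$levels)
  if (!any(in_mask)) stopf("empty mask")
  vals <- q$levels
  vals[!in_mask] <- 0L
  lab <- label_components(in_mask, connectivity = 26L, values = vals)
  zl <- lab[in_mask]
  zone_size <- tabulate(zl)
  # grey level of each zone: the level of its first member voxel
  zone_level <- q$levels[in_mask][match(seq_len(max(zl)), zl)]
  smax <- max(zone_size)
  counts <- unclass(table(factor(zone_level, levels = 1:q$G),
                          factor(zone_size, levels = 1:smax)))
  structure(list(counts = counts, Nz = length(zone_size), G = q$G),
            class = "glszm")
}

#' Zone length non-uniformity
#'
#' `ZLNU = (1/Nz) sum_s (sum_i z(i,s))^2`: large when zone sizes are
#' homogeneous (many zones share the same size).
#'
#' @param m a [build_glszm()] result.
#' @return Scalar ZLNU.
#' @export
zlnu <- function(m) {
  stopifnot(inherits(m, "glszm"))
  sum(colSums(m$counts)^2) / m$Nz
}

#' Short-zone high grey-level emphasis
#'
#' `SZHGE = (1/Nz) sum_{i,s} z(i,s) * i^2 / s^2`: large when small zones of
#' high grey level dominate.
#'
#' @param m a [build_glszm()] result.
#' @return Scalar SZHGE.
#' @export
szhge <- function(m) {
  stopifnot(inherits(m, "glszm"))
  G <- m$G
  smax <- ncol(m$counts)
  w <- outer((1:G)^2, 1 / (1:smax)^2)
  sum(m$counts * w) / m$Nz
}

#' All six heterogeneity features of a lesion
#'
#' Convenience wrapper: quantizes the masked volume and returns the three
#' GLCM features, HGRE, ZLNU and SZHGE as one named vector.
#'
#' @inheritParams suv_basic
#' @inheritParams quantize
#' @return Named numeric vector with `homogeneity`, `entropy`,
#'   `dissimilarity`, `hgre`, `zlnu`, `szhge`.
#' @export
texture_features <- function(vol, mask, G = 64L,
                             method = c("minmax", "fixed_width"),
                             bin_width = 0.25) {
  q <- quantize(vol, mask, G = G, method = method, bin_width = bin_width)
  gl <- glcm_features(build_glcm(q))
  rl <- build_glrlm(q)
  sz <- build_glszm(q)
  c(gl, hgre = hgre(rl), zlnu = zlnu(sz), szhge = szhge(sz))
}
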