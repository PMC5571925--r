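test_that("quantization matches the level formula and its edge cases", {
  m <- lesion_mask(array(c(rep(TRUE, 3), rep(FALSE, 24)), c(3, 3, 3)),
                   c(1, 1, 1))
  v <- suv_volume(array(c(0, 0.5, 1, rep(0, 24)), c(3, 3, 3)), c(1, 1, 1))
  q <- quantize(v, m, G = 2)
  expect_identical(q$levels[1:3, 1, 1], c(1L, 2L, 2L))
  expect_true(all(is.na(q$levels[!m$values])))

  const <- quantize(mk_uniform_volume(m, 4), m, G = 64)
  expect_true(all(const$levels[m$values] == 1L))

  expect_error(quantize(v, m, G = 1), "G")
})

test_that("quantization absorbs positive affine intensity transforms", {
  set.seed(9)
  for (rep in 1:10) {
    v <- suv_volume(array(runif(125, 0, 10), c(5, 5, 5)), c(1, 1, 1))
    m <- lesion_mask(array(runif(125) < 0.6, c(5, 5, 5)), c(1, 1, 1))
    if (sum(m$values) < 2) next
    a <- runif(1, 0.2, 3)
    b <- runif(1, 0, 5)
    v2 <- suv_volume(a * v$values + b, c(1, 1, 1))
    q1 <- quantize(v, m, G = 8)
    q2 <- quantize(v2, m, G = 8)
    expect_identical(q1$levels, q2$levels)
  }
})

test_that("GLCM handles the trivial and hand-computable cases", {
  m <- lesion_mask(array(TRUE, c(3, 3, 3)), c(1, 1, 1))
  q <- quantize(mk_uniform_volume(m, 5), m, G = 64)
  g <- build_glcm(q)
  expect_equal(g$p[1, 1], 1)
  expect_equal(sum(g$p), 1)
  feats <- glcm_features(g)
  expect_equal(unname(feats),
               c(1, 0, 0))  # homogeneity, entropy, dissimilarity

  # 1x1x2 mask with levels (1, 2): one symmetrized pair
  v2 <- suv_volume(array(c(0, 1), c(1, 1, 2)), c(1, 1, 1))
  m2 <- lesion_mask(array(TRUE, c(1, 1, 2)), c(1, 1, 1))
  g2 <- build_glcm(quantize(v2, m2, G = 2))
  expect_equal(g2$p, matrix(c(0, 0.5, 0.5, 0), 2, 2))
  f2 <- glcm_features(g2)
  expect_equal(unname(f2["homogeneity"]), 0.5)
  expect_equal(unname(f2["entropy"]), 1)
  expect_equal(unname(f2["dissimilarity"]), 1)

  # single voxel: no pairs in any direction
  m1 <- lesion_mask(array(c(TRUE, rep(FALSE, 26)), c(3, 3, 3)), c(1, 1, 1))
  expect_error(build_glcm(quantize(mk_uniform_volume(m1, 1), m1, G = 2)),
               "no voxel pairs")
})

test_that("GLCM equals exhaustive pair enumeration on random phantoms", {
  for (seed in 1:15) {
    cs <- mk_random_quantized_case(seed)
    g <- tryCatch(build_glcm(cs$q), error = function(e) NULL)
    if (is.null(g)) next
    expect_equal(unname(g$counts), unname(glcm_oracle(cs$q$levels, cs$G)))
    expect_identical(g$counts, t(g$counts))
    expect_equal(sum(g$p), 1, tolerance = 1e-12)
  }
})

test_that("GLCM entropy respects the maximum-entropy bound", {
  for (seed in 16:25) {
    cs <- mk_random_quantized_case(seed)
    g <- tryCatch(build_glcm(cs$q), error = function(e) NULL)
    if (is.null(g)) next
    e <- glcm_features(g)[["entropy"]]
    expect_gte(e, 0)
    expect_lte(e, 2 * log2(cs$G))
  }
})

test_that("GLRLM counts runs as the direct scan does", {
  # uniform 1x1x4 mask: one run of length 4 on its axis, singletons elsewhere
  v <- suv_volume(array(2, c(1, 1, 4)), c(1, 1, 1))
  m <- lesion_mask(array(TRUE, c(1, 1, 4)), c(1, 1, 1))
  r <- build_glrlm(quantize(v, m, G = 64))
  expect_equal(r$counts[1, 4], 1)
  expect_equal(hgre(r), 1)  # all runs at level 1

  for (seed in 1:15) {
    cs <- mk_random_quantized_case(seed)
    r <- build_glrlm(cs$q)
    o <- glrlm_oracle(cs$q$levels, cs$G)
    expect_equal(unname(r$counts[, seq_len(ncol(o)), drop = FALSE]),
                 unname(o))
    if (ncol(r$counts) > ncol(o)) {
      expect_true(all(r$counts[, -seq_len(ncol(o))] == 0))
    }
  }
})

test_that("HGRE weights runs by squared grey level", {
  # force every masked voxel to the top level via a two-point range
  a <- array(0, c(3, 3, 3))
  msk <- array(FALSE, c(3, 3, 3))
  msk[1:2, 1, 1] <- TRUE
  a[1, 1, 1] <- 0    # level 1
  a[2, 1, 1] <- 10   # level 64
  v <- suv_volume(a, c(1, 1, 1))
  m64 <- lesion_mask(msk, c(1, 1, 1))
  r <- build_glrlm(quantize(v, m64, G = 64))
  # 13 singleton runs at level 1 and 13 at level 64
  expect_equal(hgre(r), (13 * 1 + 13 * 64^2) / 26)
})

test_that("GLSZM zones match the flood-fill oracle and conserve mass", {
  # uniform region: a single zone
  m <- lesion_mask(array(TRUE, c(3, 3, 3)), c(1, 1, 1))
  s <- build_glszm(quantize(mk_uniform_volume(m, 5), m, G = 64))
  expect_equal(s$Nz, 1L)
  expect_equal(zlnu(s), 1)
  expect_equal(szhge(s), 1 / 27^2)  # level 1, zone size 27

  # two-level parity checkerboard: under 26-connectivity the equal-parity
  # diagonals connect, so exactly two zones remain (flood-fill oracle agrees)
  g <- expand.grid(1:4, 1:4, 1:4)
  chk <- array((g[, 1] + g[, 2] + g[, 3]) %% 2, c(4, 4, 4))
  vc <- suv_volume(chk, c(1, 1, 1))
  mc <- lesion_mask(array(TRUE, c(4, 4, 4)), c(1, 1, 1))
  q2 <- quantize(vc, mc, G = 2)
  sc <- build_glszm(q2)
  expect_equal(sc$Nz, 2L)
  expect_equal(unname(sc$counts), unname(glszm_oracle(q2$levels, 2)))

  # strict checkerboard (no equal-level contact): the 8-level parity
  # pattern makes every voxel its own zone
  oct <- array(1 + (g[, 1] %% 2) + 2 * (g[, 2] %% 2) + 4 * (g[, 3] %% 2),
               c(4, 4, 4))
  vo <- suv_volume(oct, c(1, 1, 1))
  so <- build_glszm(quantize(vo, mc, G = 8))
  expect_equal(so$Nz, 64L)
  expect_equal(zlnu(so), 64)

  for (seed in 1:15) {
    cs <- mk_random_quantized_case(seed)
    s <- build_glszm(cs$q)
    o <- glszm_oracle(cs$q$levels, cs$G)
    expect_equal(unname(s$counts[, seq_len(ncol(o)), drop = FALSE]),
                 unname(o))
    # zone sizes tile the mask
    sizes <- col(s$counts)
    expect_equal(sum(sizes * s$counts), sum(cs$mask$values))
  }
})

test_that("texture features are invariant to axis permutation", {
  set.seed(77)
  v <- suv_volume(array(runif(6 * 5 * 4, 0, 10), c(6, 5, 4)), c(1, 1, 1))
  m <- lesion_mask(array(runif(120) < 0.7, c(6, 5, 4)), c(1, 1, 1))
  f1 <- texture_features(v, m, G = 8)
  vp <- suv_volume(aperm(v$values, c(3, 1, 2)), c(1, 1, 1))
  mp <- lesion_mask(aperm(m$values, c(3, 1, 2)), c(1, 1, 1))
  f2 <- texture_features(vp, mp, G = 8)
  expect_equal(f1, f2, tolerance = 1e-12)
})

test_that("all six features are invariant under affine intensity maps", {
  set.seed(55)
  v <- suv_volume(array(runif(125, 1, 9), c(5, 5, 5)), c(1, 1, 1))
  m <- lesion_mask(array(runif(125) < 0.8, c(5, 5, 5)), c(1, 1, 1))
  f1 <- texture_features(v, m, G = 16)
  v2 <- suv_volume(2.5 * v$values + 3, c(1, 1, 1))
  f2 <- texture_features(v2, m, G = 16)
  expect_equal(f1, f2, tolerance = 1e-12)
})
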