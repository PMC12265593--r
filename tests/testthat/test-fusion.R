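# Fusion: softmax attention identities, agreement with a dense loop-based
# oracle, and the permutation/pooling symmetries of the scale embeddings.

test_that("single-key cross-attention puts weight 1 on that key", {
  p <- cross_attn_params(8L, 2L, seed = 1L)
  set.seed(1)
  Q <- matrix(rnorm(24), 3, 8)
  K <- matrix(rnorm(8), 1, 8)
  res <- cross_attention(Q, K, K, p)
  for (w in res$weights) expect_equal(w, matrix(1, 3, 1))
  # identical queries give identical output rows
  Q2 <- matrix(rep(Q[1, ], 3), 3, byrow = TRUE)
  res2 <- cross_attention(Q2, K, K, p)
  expect_equal(res2$output[1, ], res2$output[2, ])
})

test_that("attention weight rows sum to one and match the dense oracle", {
  for (seed in 1:3) {
    p <- cross_attn_params(8L, 4L, seed = seed)
    set.seed(seed)
    Q <- matrix(rnorm(5 * 8), 5, 8)
    K <- matrix(rnorm(6 * 8), 6, 8)
    V <- matrix(rnorm(6 * 8), 6, 8)
    res <- cross_attention(Q, K, V, p)
    for (w in res$weights) {
      expect_equal(rowSums(w), rep(1, 5), tolerance = 1e-12)
    }
    expect_equal(res$output, oracle_attention(Q, K, V, p), tolerance = 1e-5)
  }
})

test_that("duplicating a key/value row renormalizes weights but preserves output", {
  p <- cross_attn_params(4L, 1L, seed = 2L)
  set.seed(2)
  Q <- matrix(rnorm(8), 2, 4)
  K <- matrix(rnorm(12), 3, 4)
  V <- matrix(rnorm(12), 3, 4)
  # oracle on the duplicated problem
  Kd <- rbind(K, K[2, ]); Vd <- rbind(V, V[2, ])
  res <- cross_attention(Q, Kd, Vd, p)
  expect_equal(res$output, oracle_attention(Q, Kd, Vd, p), tolerance = 1e-5)
  w <- res$weights[[1]]
  expect_equal(w[, 2], w[, 4]) # the duplicate shares its weight
})

test_that("fuse_cell reads the CLS row and is invariant to gene-token order", {
  m <- stw_model_new(tiny_model_config(seed = 7L))
  set.seed(7)
  crop <- matrix(sample(0:255, 1024, replace = TRUE), 32, 32)
  g <- rpois(20, 8)
  Xc <- encode_cell_image(crop, m)
  Xg <- encode_genes(g, m)
  z <- fuse_cell(Xc, Xg, m, source_id = "c1")
  expect_s3_class(z, "scale_embedding")
  expect_identical(z$level, "cell")
  expect_length(z$vector, 16L)
  perm <- sample(20)
  Xg_perm <- Xg
  Xg_perm$tokens <- Xg$tokens[perm, ]
  z2 <- fuse_cell(Xc, Xg_perm, m)
  expect_equal(z2$vector, z$vector, tolerance = 1e-12)
  # matches the dense block oracle
  zo <- oracle_xblock(m$fuse$cell, Xc$tokens, Xg$tokens)[1, ]
  expect_equal(z$vector, zo, tolerance = 1e-5)
  Xc$has_cls <- FALSE
  expect_error(fuse_cell(Xc, Xg, m), "CLS")
})

test_that("pool_niche_context is the arithmetic mean with its symmetries", {
  v <- c(1, 2, 3)
  expect_equal(pool_niche_context(matrix(v, 1)), v)
  m <- rbind(c(1, 0, 2), c(-1, 0, -2))
  expect_equal(pool_niche_context(m), c(0, 0, 0))
  expect_equal(pool_niche_context(m[2:1, ]), pool_niche_context(m))
  expect_error(pool_niche_context(m[0, , drop = FALSE]), "empty")
})

test_that("fuse_niche and fuse_tissue match the dense oracle on tiny dims", {
  m <- stw_model_new(tiny_model_config(seed = 9L))
  set.seed(9)
  zbar <- rnorm(16)
  Xn <- encode_niche_image(matrix(sample(0:255, 4096, replace = TRUE), 64, 64), m)
  zn <- fuse_niche(zbar, Xn, m)
  expect_identical(zn$level, "niche")
  expect_equal(zn$vector,
               oracle_xblock(m$fuse$niche, matrix(zbar, 1), Xn$tokens)[1, ],
               tolerance = 1e-5)
  # deterministic
  expect_identical(fuse_niche(zbar, Xn, m)$vector, zn$vector)

  Xt <- list(tokens = matrix(rnorm(3 * 16), 3, 16), has_cls = FALSE,
             grid_shape = NA)
  zt <- fuse_tissue(zn, Xt, m)
  expect_equal(zt$vector,
               oracle_xblock(m$fuse$tissue, matrix(zn$vector, 1), Xt$tokens)[1, ],
               tolerance = 1e-5)
  # duplicated tissue token: oracle agreement still holds
  Xt2 <- list(tokens = Xt$tokens[c(1, 2, 3, 2), ], has_cls = FALSE,
              grid_shape = NA)
  expect_equal(fuse_tissue(zn, Xt2, m)$vector,
               oracle_xblock(m$fuse$tissue, matrix(zn$vector, 1), Xt2$tokens)[1, ],
               tolerance = 1e-5)
  # distinct niche embeddings give distinct tissue embeddings
  zn_b <- fuse_niche(zbar + 1, Xn, m)
  expect_gt(max(abs(fuse_tissue(zn_b, Xt, m)$vector - zt$vector)), 1e-8)
})

test_that("fuse_unified matches the 3-key oracle and supports level fallback", {
  m <- stw_model_new(tiny_model_config(seed = 11L))
  set.seed(11)
  zc <- rnorm(16); zn <- rnorm(16); zt <- rnorm(16)
  z <- fuse_unified(zc, zn, zt, model = m)
  expect_identical(z$level, "unified")
  expect_equal(z$vector,
               oracle_xblock(m$fuse$unified, matrix(zc, 1),
                             rbind(zc, zn, zt))[1, ],
               tolerance = 1e-5)
  # identical keys: output is a function of zc alone (equals 1-key attention)
  zsame <- fuse_unified(zc, zc, zc, model = m)
  zone <- oracle_xblock(m$fuse$unified, matrix(zc, 1), rbind(zc, zc, zc))[1, ]
  expect_equal(zsame$vector, zone, tolerance = 1e-5)
  # 2-key fallback without tissue still returns length D
  z2 <- fuse_unified(zc, zn, model = m)
  expect_length(z2$vector, 16L)
  expect_true(all(is.finite(z2$vector)))
})
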