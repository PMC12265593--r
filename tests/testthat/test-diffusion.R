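# Diffusion machinery: schedule algebra, CFG identities, importance scores,
# merge-plan laws, VAE contracts, U-Net shape/determinism, DDIM sampling.

test_that("noise schedule satisfies its invariants", {
  sc <- noise_schedule(100L)
  expect_identical(sc$T, 100L)
  expect_true(all(diff(sc$alpha_bar) < 0))
  expect_gt(sc$alpha_bar[1], 0.9)
  expect_true(all(sc$betas > 0 & sc$betas < 1))
  expect_identical(stweave:::abar_at(sc, 0L), 1)
})

test_that("q_sample follows the closed form and inverts algebraically", {
  sc <- noise_schedule(50L)
  x0 <- array(rnorm(8), c(2, 2, 2, 1))
  noise <- array(rnorm(8), c(2, 2, 2, 1))
  expect_equal(q_sample(x0, 0L, noise, sc), x0)
  t <- 20L
  xt <- q_sample(x0, t, noise, sc)
  ab <- sc$alpha_bar[t]
  expect_equal((xt - sqrt(ab) * x0) / sqrt(1 - ab), noise, tolerance = 1e-12)
  # hand-computed scalar case at alpha_bar = 0.25
  fake <- structure(list(T = 1L, alpha_bar = 0.25), class = "noise_schedule")
  expect_equal(q_sample(array(1, c(1, 1, 1, 1)), 1L, array(2, c(1, 1, 1, 1)),
                        fake)[1],
               0.5 + sqrt(0.75) * 2)
  expect_error(q_sample(x0, 51L, noise, sc), "range")
})

test_that("cfg_combine identities hold bitwise at w = 0 and w = 1", {
  set.seed(1)
  eu <- array(rnorm(32), c(4, 4, 2, 1))
  ec <- array(rnorm(32), c(4, 4, 2, 1))
  expect_identical(cfg_combine(eu, ec, 0), eu)
  expect_identical(cfg_combine(eu, ec, 1), ec)
  expect_equal(cfg_combine(array(0, c(1, 2, 1, 1)),
                           array(c(1, 2), c(1, 2, 1, 1)), 2),
               array(c(2, 4), c(1, 2, 1, 1)))
  expect_error(cfg_combine(eu, ec[, , 1, , drop = FALSE], 1), "shape")
})

test_that("token importance is |difference| summed over channels, pooled, symmetric", {
  eu <- array(0, c(2, 2, 2))
  ec <- eu
  expect_true(all(token_importance(eu, ec)$scores == 0))
  ec[1, 2, ] <- c(1, -2)
  s <- token_importance(eu, ec)$scores
  # row-major flatten: position 2 is row 1, col 2
  expect_equal(s, c(0, 3, 0, 0))
  expect_equal(token_importance(ec, eu)$scores, s) # symmetry under swap
  # average pooling to a 1x1 grid
  expect_equal(token_importance(eu, ec, c(1L, 1L))$scores, 3 / 4)
  expect_error(token_importance(array(0, c(3, 3, 1)), array(0, c(3, 3, 1)),
                                c(2L, 2L)), "divide")
})

test_that("anchor selection keeps the top scores with lower-index ties, sorted", {
  expect_identical(select_anchors(c(3, 1, 2), 0), 1:3)
  expect_identical(select_anchors(c(3, 1, 2), 1 / 3), c(1L, 3L))
  expect_identical(select_anchors(rep(1, 4), 0.5), 1:2)
  expect_error(select_anchors(numeric(0), 0.5), "empty")
  expect_error(select_anchors(c(1, 2), 1), "")
})

test_that("merge plans are row-normalized, non-exclusive, and match a dense oracle", {
  set.seed(2)
  Q <- matrix(rnorm(6 * 4), 6, 4)
  K <- matrix(rnorm(6 * 4), 6, 4)
  plan <- build_merge_plan(Q, K, anchors = c(2L, 5L), n_heads = 2L)
  expect_identical(plan$anchor_indices, c(2L, 5L))
  expect_equal(rowSums(plan$assignment), rep(1, 4), tolerance = 1e-12)
  # dense softmax oracle, head-averaged logits
  non <- plan$non_anchor_indices
  for (jj in seq_along(non)) {
    j <- non[jj]
    lg <- sapply(c(2L, 5L), function(a) {
      mean(sapply(1:2, function(h) {
        cols <- ((h - 1) * 2 + 1):(h * 2)
        sum(Q[j, cols] * K[a, cols]) / sqrt(2)
      }))
    })
    w <- exp(lg - max(lg)); w <- w / sum(w)
    expect_equal(plan$assignment[jj, ], w, tolerance = 1e-10)
  }
  # one anchor: every assignment row is exactly 1
  p1 <- build_merge_plan(Q, K, anchors = 3L)
  expect_equal(p1$assignment, matrix(1, 5, 1))
  # orthogonal query to equal-norm keys: uniform row
  K2 <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0), c(0, 0, 1, 0))
  Q2 <- rbind(K2[1:2, ], c(0, 0, 0, 1))
  p2 <- build_merge_plan(Q2, K2, anchors = c(1L, 2L))
  expect_equal(p2$assignment[1, ], c(0.5, 0.5))
  expect_error(build_merge_plan(Q, K, integer(0)), "empty")
})

test_that("merge/unmerge honor the weighted-mean and identity laws", {
  set.seed(3)
  tokens <- matrix(rnorm(5 * 3), 5, 3)
  Q <- matrix(rnorm(15), 5, 3); K <- matrix(rnorm(15), 5, 3)
  # all tokens anchors: identity
  pid <- build_merge_plan(Q, K, anchors = 1:5)
  expect_identical(merge_tokens(tokens, pid), tokens)
  expect_equal(unmerge_outputs(tokens, pid), tokens)
  # assignment fully concentrated on anchor 1 with identical tokens:
  # merged_1 is the plain mean of the anchor and its absorbed tokens
  tk <- tokens
  tk[2, ] <- tk[1, ]; tk[3, ] <- tk[1, ]
  plan <- build_merge_plan(Q, K, anchors = c(1L, 4L))
  plan$assignment <- rbind(c(1, 0), c(1, 0), c(0, 1))
  merged <- merge_tokens(tk, plan)
  expect_equal(merged[1, ], colMeans(tk[1:3, ]))
  expect_identical(nrow(merged), 2L)
  # unmerge maps anchors back verbatim and mixes non-anchors
  out <- unmerge_outputs(merged, plan)
  expect_equal(out[1, ], merged[1, ])
  expect_equal(out[5, ], merged[2, ])
})

test_that("merged self-attention equals the dense oracle computed from the plan", {
  p <- cross_attn_params(4L, 2L, seed = 4L)
  set.seed(4)
  tn <- matrix(rnorm(8 * 4), 8, 4)
  scores <- runif(8)
  r <- 0.5
  got <- stweave:::merged_self_attention(p, tn, scores, r)
  anchors <- select_anchors(scores, r)
  lin <- function(x, l) x %*% l$W$v + matrix(l$b$v, nrow(x), 4, byrow = TRUE)
  plan <- build_merge_plan(lin(tn, p$Wq), lin(tn, p$Wk), anchors, n_heads = 2L)
  tm <- merge_tokens(tn, plan)
  dense <- oracle_attention(tm, tm, tm, p)
  expect_equal(got, unmerge_outputs(dense, plan), tolerance = 1e-5)
  # r = 0 path is bitwise the plain attention
  expect_identical(stweave:::merged_self_attention(p, tn, scores, 0),
                   stweave:::vv(stweave:::mha_fwd(p, tn, tn, tn)$out))
})

test_that("VAE has the factor-4 latent geometry and deterministic decode", {
  vae <- vae_new(seed = 1L)
  x <- matrix(runif(64 * 64), 64, 64)
  z <- vae_encode(vae, x)
  expect_identical(dim(z), c(16L, 16L, 4L, 1L))
  y1 <- vae_decode(vae, z)
  y2 <- vae_decode(vae, z)
  expect_identical(y1, y2)
  expect_identical(dim(y1), c(64L, 64L, 1L, 1L))
  # diffusion training refuses an unfrozen VAE
  dd <- diffusion_new(unet_new(8L, seed = 2L), vae, noise_schedule(10L))
  expect_error(diffusion_train(dd, array(0, c(16, 16, 4, 2)),
                               matrix(0, 2, 8), steps = 1L),
               "frozen")
})

test_that("U-Net preserves latent shape and distinguishes null from conditional", {
  vae <- vae_new(seed = 1L)
  vae$frozen <- TRUE
  dd <- diffusion_new(unet_new(8L, ch = 8L, seed = 3L), vae,
                      noise_schedule(10L))
  set.seed(3)
  x <- array(rnorm(16 * 16 * 4 * 2), c(16, 16, 4, 2))
  z <- rnorm(8)
  e1 <- predict_noise(dd, x, 5L, condition_signal(z))
  expect_identical(dim(e1), dim(x))
  expect_identical(predict_noise(dd, x, 5L, condition_signal(z)), e1)
  e0 <- predict_noise(dd, x, 5L, condition_signal(z, is_null = TRUE))
  expect_gt(max(abs(e1 - e0)), 1e-9) # null token differs from the signal
})

test_that("sampling is seed-reproducible, merge telemetry reports M, steps=1 works", {
  vae <- vae_new(seed = 5L)
  vae$frozen <- TRUE
  dd <- diffusion_new(unet_new(8L, ch = 8L, seed = 6L), vae,
                      noise_schedule(20L))
  z <- matrix(rnorm(2 * 8), 2, 8)
  img1 <- diffusion_sample(dd, z, steps = 4L, merge_ratio = 0, seed = 11L)
  img2 <- diffusion_sample(dd, z, steps = 4L, merge_ratio = 0, seed = 11L)
  expect_identical(img1, img2)
  expect_identical(dim(img1), c(64L, 64L, 1L, 2L))
  one <- diffusion_sample(dd, z, steps = 1L, seed = 2L)
  expect_true(all(is.finite(one)))
  for (r in c(0.25, 0.5, 0.75)) {
    im <- diffusion_sample(dd, z[1, , drop = FALSE], steps = 3L,
                           merge_ratio = r, seed = 7L, telemetry = TRUE)
    tel <- attr(im, "telemetry")
    expect_gt(length(tel), 0L)
    for (entry in tel) {
      m_expect <- max(1L, as.integer(ceiling((1 - r) * entry$tokens_before)))
      expect_identical(entry$tokens_after, m_expect)
    }
  }
})

test_that("gene perturbation edits exactly the named genes", {
  g <- c(1, 2, 3, 4)
  ids <- paste0("g", 1:4)
  expect_identical(perturb_genes(g, list(g3 = list(mode = "knockout")), ids),
                   c(1, 2, 0, 4))
  expect_identical(perturb_genes(g, list(), ids), g)
  expect_identical(perturb_genes(g, list(g2 = list(mode = "overexpress",
                                                   factor = 1)), ids), g)
  expect_identical(perturb_genes(g, list(g1 = list(mode = "overexpress",
                                                   factor = 3)), ids),
                   c(3, 2, 3, 4))
  expect_error(perturb_genes(g, list(gX = list(mode = "knockout")), ids),
               "unknown gene")
})
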