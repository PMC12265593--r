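# Dual-decoder objectives and the training loop: exact loss identities,
# masking contract, linearity of the total loss, seeded optimization.

test_that("image reconstruction loss is zero at the decoder's own output and delta^2 off it", {
  m <- stw_model_new(tiny_model_config(seed = 1L))
  set.seed(1)
  z <- rnorm(16)
  dec <- stweave:::vv(stweave:::fwd_img_decode(m, matrix(z, 1)))
  target <- matrix(dec[, , 1, 1], m$config$recon_px)
  expect_equal(image_recon_loss(z, target, m), 0, tolerance = 1e-14)
  delta <- 0.03
  expect_equal(image_recon_loss(z, target + delta, m), delta^2,
               tolerance = 1e-10)
  expect_gt(image_recon_loss(z, target * 0, m), 0)
})

test_that("masked-gene loss matches a hand-computed MSE and ignores unmasked targets", {
  m <- stw_model_new(tiny_model_config(n_genes = 3L, seed = 2L))
  set.seed(2)
  z <- rnorm(16)
  g <- c(4, 0, 9)
  plan <- list(mask = c(TRUE, FALSE, TRUE), mask_rate = 2 / 3, seed = 1L)
  # hand-compute from the decoder's printed predictions
  dec <- m$gene_dec
  mem <- stweave:::vv(stweave:::ln_fwd(dec$ln, matrix(z, 1)))
  h <- dec$queries$v +
    stweave:::vv(stweave:::mha_fwd(dec$attn, dec$queries$v, mem, mem)$out)
  pred <- rowSums(h * dec$headW$v) + dec$headb$v
  by_hand <- mean((pred[c(1, 3)] - log1p(g[c(1, 3)]))^2)
  expect_equal(gene_recon_loss(z, g, plan, m), by_hand, tolerance = 1e-10)
  # perturbing an unmasked target leaves the loss unchanged
  g2 <- g; g2[2] <- 1000
  expect_identical(gene_recon_loss(z, g2, plan, m),
                   gene_recon_loss(z, g, plan, m))
  expect_error(gene_recon_loss(z, g, list(mask = rep(FALSE, 3)), m), "mask")
})

test_that("mask plans are seeded, bounded and never empty", {
  p1 <- mask_plan(20L, 0.15, seed = 5L)
  p2 <- mask_plan(20L, 0.15, seed = 5L)
  expect_identical(p1, p2)
  expect_identical(sum(p1$mask), 3L)
  expect_true(any(mask_plan(3L, 0.01, seed = 1L)$mask))
  expect_error(mask_plan(10L, 0), "mask_rate")
})

test_that("total loss is the exact weighted sum", {
  w <- loss_weights(0.5, 0.1)
  expect_identical(total_loss(2, 3, w), 1.3)
  expect_identical(total_loss(2, 3, loss_weights(1, 0)), 2)
  expect_identical(total_loss(2, 3, loss_weights(0, 1)), 3)
  expect_error(loss_weights(0, 0), "")
})

small_built <- function() {
  cfg <- tiny_slide_config(seed = 17L, n_cells = 30L)
  dir <- file.path(tempdir(), "obj_slide")
  if (!dir.exists(dir)) simulate_slide(cfg, dir = dir)
  build_dataset(dir, file.path(tempdir(), "obj_ds"), tile = 64L,
                tissue_tile = 256L)
}

test_that("short training reduces the total loss deterministically", {
  built <- small_built()
  m <- stw_model_new(tiny_model_config(seed = 3L))
  res <- stw_train(m, built, steps = 25L, batch_size = 6L, seed = 4L)
  expect_lt(res$trace$total[25], res$trace$total[1])
  expect_true(all(is.finite(res$trace$total)))
  # identical seeds reproduce the trace exactly
  m2 <- stw_model_new(tiny_model_config(seed = 3L))
  res2 <- stw_train(m2, built, steps = 25L, batch_size = 6L, seed = 4L)
  expect_identical(res$trace, res2$trace)
})

test_that("zero gene weight leaves the gene decoder at initialization", {
  built <- small_built()
  m <- stw_model_new(tiny_model_config(seed = 5L))
  before <- lapply(stweave:::collect_params(m$gene_dec), function(p) p$v)
  img_before <- m$img_dec$fc$W$v
  stw_train(m, built, steps = 5L, batch_size = 4L,
            weights = loss_weights(1, 0), seed = 6L)
  after <- lapply(stweave:::collect_params(m$gene_dec), function(p) p$v)
  expect_identical(before, after)
  expect_gt(max(abs(m$img_dec$fc$W$v - img_before)), 0)
})

test_that("resuming from an epoch-boundary checkpoint reproduces the loss trace", {
  built <- small_built() # 30 cells, batch 4 -> 8 steps per epoch
  m <- stw_model_new(tiny_model_config(seed = 7L))
  full <- stw_train(m, built, steps = 16L, batch_size = 4L, seed = 8L)

  m2 <- stw_model_new(tiny_model_config(seed = 7L))
  part <- stw_train(m2, built, steps = 8L, batch_size = 4L, seed = 8L)
  ck <- withr::local_tempfile(fileext = ".rds")
  stw_checkpoint_save(part$model, part$opt, ck)
  loaded <- stw_checkpoint_load(ck)
  rest <- stw_train(loaded$model, built, steps = 8L, batch_size = 4L,
                    seed = 8L, start_step = 9L, opt = loaded$opt)
  expect_equal(rest$trace$total, full$trace$total[9:16], tolerance = 1e-10)
})

test_that("training aborts on an empty dataset", {
  expect_error(stw_train(stw_model_new(tiny_model_config()),
                         list(cells = list())), "empty")
})
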