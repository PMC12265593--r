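# Shared heavy fixtures: the pretraining corpus and trained models are built
# once per test session and reused by the tests that probe them.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- build()
  .fixture_cache[[name]]
}

# Pretraining corpus: four slides of 500 cells (640 px, 4 types, 50 genes),
# combined into one 2,000-cell dataset with ground-truth type labels.
fixture_corpus <- function() {
  memo("corpus", function() {
    builts <- list()
    labels <- integer()
    for (s in 1:4) {
      cfg <- synthetic_config(n_cell_types = 4L, n_genes = 50L,
                              slide_height = 640L, slide_width = 640L,
                              n_cells = 500L, niche_mixing = 0.1,
                              seed = 100L + s)
      dir <- file.path(tempdir(), paste0("acc_slide_", s))
      slide <- simulate_slide(cfg, dir = dir)
      labels <- c(labels, vapply(slide$cells, `[[`, 1L, "type_label"))
      builts[[s]] <- build_dataset(dir, file.path(tempdir(), paste0("acc_ds_", s)),
                                   tile = 160L, tissue_tile = 640L)
    }
    corpus <- combine_datasets(builts)
    corpus$labels <- labels
    corpus
  })
}

# 200-step self-supervised pretraining of the D = 64 model on the corpus.
fixture_training <- function() {
  memo("training", function() {
    corpus <- fixture_corpus()
    model <- stw_model_new(stw_config(embed_dim = 64L, n_heads = 4L,
                                      depth = 2L, n_genes = 50L, seed = 42L))
    res <- stw_train(model, corpus, steps = 200L, batch_size = 8L,
                     lr = 1e-3, seed = 11L)
    list(model = res$model, trace = res$trace, corpus = corpus)
  })
}

fixture_embeddings <- function() {
  memo("embeddings", function() {
    tr <- fixture_training()
    embed_dataset(tr$corpus, tr$model)
  })
}

# Two-type corpus plus frozen VAE and trained conditional denoiser for the
# generation fidelity tests.
fixture_diffusion <- function() {
  memo("diffusion", function() {
    builts <- list(); labels <- integer()
    for (s in 1:2) {
      cfg <- synthetic_config(
        n_cell_types = 2L, n_genes = 50L, slide_height = 512L,
        slide_width = 512L, n_cells = 150L, niche_mixing = 0.05,
        morphology_link = list(weights = seq(1, 2, length.out = 50) / 50,
                               radius = c(10, 4), eccentricity = c(0.4, 0.3),
                               texture_freq = c(0.25, 0.2)),
        seed = 200L + s)
      dir <- file.path(tempdir(), paste0("diff_slide_", s))
      slide <- simulate_slide(cfg, dir = dir)
      labels <- c(labels, vapply(slide$cells, `[[`, 1L, "type_label"))
      builts[[s]] <- build_dataset(dir, file.path(tempdir(), paste0("diff_ds_", s)),
                                   tile = 128L, tissue_tile = 512L)
    }
    corpus <- combine_datasets(builts)
    crops <- lapply(corpus$cells, function(r) resize_bilinear(r$crop / 255, 64L))
    vt <- vae_train(vae_new(seed = 5L), crops, steps = 250L, batch_size = 8L,
                    seed = 6L)
    model <- stw_model_new(stw_config(embed_dim = 64L, n_heads = 4L,
                                      depth = 1L, n_genes = 50L, seed = 3L))
    stw_train(model, corpus, steps = 120L, batch_size = 8L, seed = 4L)
    emb <- embed_dataset(corpus, model)
    n <- length(crops)
    lats <- array(0, c(16L, 16L, 4L, n))
    for (i in seq_len(n)) lats[, , , i] <- vae_encode(vt$vae, crops[[i]])
    dd <- diffusion_new(unet_new(64L, ch = 16L, seed = 8L), vt$vae,
                        noise_schedule(100L))
    dt <- diffusion_train(dd, lats, emb$unified, steps = 800L,
                          batch_size = 8L, lr = 2e-3, p_uncond = 0.15,
                          seed = 9L)
    list(dd = dt$dd, vae = vt$vae, vae_trace = vt$trace,
         unet_trace = dt$trace, crops = crops, labels = labels,
         conds = emb$unified, corpus = corpus)
  })
}
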