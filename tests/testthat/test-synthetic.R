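# Synthetic slide generator: seeded determinism, spatial type clustering,
# expression/morphology coupling, rendering geometry, and on-disk round
# trips.

test_that("config invariants are enforced", {
  expect_error(tiny_slide_config(n_cells = 0L), "n_cells")
  mm <- matrix(2, 2, 10)
  expect_error(synthetic_config(n_cell_types = 2L, n_genes = 10L,
                                expression_model = list(mean_matrix = mm,
                                                        dispersion = 0.1)),
               "distinct")
  expect_error(synthetic_config(slide_height = 32L, slide_width = 32L,
                                morphology_link = list(
                                  weights = rep(1 / 50, 50),
                                  radius = c(20, 0), eccentricity = c(0.4, 0),
                                  texture_freq = c(0.3, 0))),
               "radius")
})

test_that("sampling is deterministic given the seed", {
  cfg <- tiny_slide_config(seed = 7L, n_cells = 10L)
  expect_identical(sample_cells(cfg), sample_cells(cfg))
  slide1 <- render_slide(sample_cells(cfg), cfg)
  slide2 <- render_slide(sample_cells(cfg), cfg)
  expect_identical(slide1$zstack, slide2$zstack)
})

test_that("with niche_mixing 0 each cell's type is its nearest latent center's", {
  cfg <- tiny_slide_config(seed = 3L, n_cells = 40L, n_types = 2L,
                           px = 384L)
  cfg$niche_mixing <- 0
  cells <- sample_cells(cfg)
  centers <- attr(cells, "niche_centers")
  for (cell in cells) {
    d <- sqrt((centers[, 1] - cell$centroid[1])^2 +
                (centers[, 2] - cell$centroid[2])^2)
    expect_identical(cell$type_label, which.min(d))
  }
})

test_that("boundaries are valid polygons containing their centroid, in bounds", {
  cfg <- tiny_slide_config(seed = 5L, n_cells = 30L)
  cells <- sample_cells(cfg)
  for (cell in cells) {
    b <- cell$boundary
    expect_gte(nrow(b), 6L)
    expect_true(all(b[, 1] >= 0 & b[, 1] < cfg$slide_width))
    expect_true(all(b[, 2] >= 0 & b[, 2] < cfg$slide_height))
    expect_true(oracle_point_in_polygon(cell$centroid[1], cell$centroid[2], b))
    expect_true(all(is.finite(cell$gene_counts)), info = cell$cell_id)
  }
})

test_that("an overcrowded configuration fails with a clear error", {
  cfg <- synthetic_config(n_cell_types = 1L, n_genes = 5L, slide_height = 64L,
                          slide_width = 64L, n_cells = 400L,
                          morphology_link = list(weights = rep(0.2, 5),
                                                 radius = c(8, 0),
                                                 eccentricity = c(0.3, 0),
                                                 texture_freq = c(0.3, 0)),
                          seed = 1L)
  expect_error(sample_cells(cfg), "overcrowded")
})

test_that("rendering: empty list gives pure noise; blob peaks inside boundary; areas follow radii", {
  cfg <- tiny_slide_config(seed = 9L, n_cells = 2L, n_types = 2L, noise = 0)
  empty <- render_slide(list(), cfg)
  expect_true(all(empty$zstack == 0))
  expect_identical(dim(empty$zstack), c(3L, 256L, 256L))

  cells <- sample_cells(cfg)
  slide <- render_slide(cells, cfg)
  expect_true(all(slide$zstack >= 0))
  mip <- max_intensity_projection(slide$zstack)
  # the brightest pixel of each cell's local window sits inside its boundary
  for (cell in cells) {
    b <- cell$boundary
    rows <- floor(min(b[, 2])):ceiling(max(b[, 2]))
    cols <- floor(min(b[, 1])):ceiling(max(b[, 1]))
    win <- mip[rows + 1L, cols + 1L]
    peak <- which(win == max(win), arr.ind = TRUE)[1, ]
    px <- cols[peak[2]] + 0.5
    py <- rows[peak[1]] + 0.5
    expect_true(oracle_point_in_polygon(px, py, b))
  }
  # two types with different radii: above-half-max areas ordered as radii
  radii <- vapply(cells, function(cell) cell$morphology_params[["radius"]], 0)
  areas <- vapply(cells, function(cell) {
    b <- cell$boundary
    rows <- floor(min(b[, 2]) - 2):ceiling(max(b[, 2]) + 2)
    cols <- floor(min(b[, 1]) - 2):ceiling(max(b[, 1]) + 2)
    win <- mip[rows + 1L, cols + 1L]
    sum(win > max(win) / 2)
  }, 0)
  if (radii[1] != radii[2]) {
    expect_identical(order(areas), order(radii))
  }
})

test_that("z-planes are attenuated so the max projection recovers plane 1", {
  cfg <- tiny_slide_config(seed = 2L, n_cells = 5L, noise = 0)
  slide <- render_slide(sample_cells(cfg), cfg)
  mip <- max_intensity_projection(slide$zstack)
  expect_equal(mip, slide$zstack[1, , ])
})

test_that("write/read round-trips counts exactly and geometry to 1e-6 px", {
  cfg <- tiny_slide_config(seed = 4L, n_cells = 12L)
  slide <- simulate_slide(cfg)
  dir <- withr::local_tempdir()
  write_slide(slide, dir)
  rt <- read_slide(dir)
  for (cell in slide$cells) {
    expect_equal(unname(rt$expression[cell$cell_id, ]),
                 as.numeric(cell$gene_counts))
    expect_lt(max(abs(rt$boundaries[[cell$cell_id]] - cell$boundary)), 1e-6)
  }
  expect_lt(max(abs(rt$zstack - slide$zstack)), 1e-6)
  # n_z_planes in -> same number of TIFF pages out
  pages <- tiff::readTIFF(file.path(dir, "zstack.tif"), all = TRUE)
  expect_length(pages, cfg$n_z_planes)
})

test_that("expression couples to type: nearest-centroid genes recover labels on 500 cells", {
  cfg <- synthetic_config(n_cell_types = 4L, n_genes = 50L,
                          slide_height = 640L, slide_width = 640L,
                          n_cells = 500L, seed = 31L)
  cells <- sample_cells(cfg)
  g <- log1p(do.call(rbind, lapply(cells, `[[`, "gene_counts")))
  ty <- vapply(cells, `[[`, 1L, "type_label")
  half <- seq_len(250L)
  cent <- do.call(rbind, lapply(1:4, function(k) {
    colMeans(g[half, ][ty[half] == k, , drop = FALSE])
  }))
  pred <- apply(g[-half, ], 1L, function(x) {
    which.min(colSums((t(cent) - x)^2))
  })
  expect_gt(mean(pred == ty[-half]), 0.9)
})

test_that("morphology link separates distinct type means", {
  cfg <- tiny_slide_config(n_types = 4L, n_genes = 30L, seed = 8L)
  tm <- cfg$type_morphology
  expect_identical(nrow(unique(tm)), 4L)
  expect_true(all(tm[, "radius"] > 0))
})
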