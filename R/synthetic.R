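# Synthetic segmented-slide generator.
#
# Cells are placed on a slide, assigned one of K types by proximity to latent
# niche centers (so types are spatially clustered), given negative-binomial
# gene counts from a type-specific mean vector, and rendered as textured
# elliptical intensity blobs whose geometry (radius, eccentricity, texture
# frequency) is an affine function of the type-mean expression profile.
# Morphology is therefore a known, invertible function of expression, which is
# the ground truth every downstream stage is tested against.

#' Configuration for the synthetic slide generator
#'
#' @param n_cell_types number of distinct cell types (latent niche centers).
#' @param n_genes size G of the gene panel.
#' @param slide_height,slide_width slide dimensions in pixels.
#' @param n_z_planes number of z planes in the rendered stack.
#' @param n_cells number of cells to place (must be >= 1).
#' @param niche_mixing probability in \code{[0,1]} that a cell ignores its
#'   nearest latent center and draws its type uniformly; 0 gives perfectly
#'   clustered types, 1 gives spatially random types.
#' @param expression_model list with \code{mean_matrix} (n_cell_types x G
#'   nonnegative type means) and \code{dispersion} (> 0; negative-binomial
#'   overdispersion, variance = mu + dispersion * mu^2). Generated from the
#'   seed when \code{NULL}: each type elevates its own block of marker genes
#'   over a shared baseline.
#' @param morphology_link list mapping type-mean expression to rendering
#'   parameters: \code{weights} (length-G projection), and
#'   \code{radius}, \code{eccentricity}, \code{texture_freq}, each
#'   \code{c(intercept, slope)} applied to the standardized projection score.
#' @param background_noise per-plane additive noise amplitude (>= 0).
#' @param pixel_size_um physical pixel size in micrometers.
#' @param seed integer seed; all sampling is deterministic given the config.
#' @return object of class \code{synthetic_config}.
#' @export
synthetic_config <- function(n_cell_types = 4L, n_genes = 50L,
                             slide_height = 512L, slide_width = 512L,
                             n_z_planes = 3L, n_cells = 500L,
                             niche_mixing = 0.1,
                             expression_model = NULL,
                             morphology_link = NULL,
                             background_noise = 0.02,
                             pixel_size_um = 0.2125,
                             seed = 1L) {
  stopifnot(n_cells >= 1L, n_cell_types >= 1L, n_genes >= 1L,
            n_z_planes >= 1L, niche_mixing >= 0, niche_mixing <= 1,
            background_noise >= 0)
  if (is.null(expression_model)) {
    expression_model <- with_seed(seed + 1000L, {
      base <- 2
      mm <- matrix(base, n_cell_types, n_genes)
      block <- max(1L, n_genes %/% n_cell_types)
      for (t in seq_len(n_cell_types)) {
        lo <- (t - 1L) * block + 1L
        hi <- min(n_genes, t * block)
        mm[t, lo:hi] <- 20 + stats::runif(hi - lo + 1L, 0, 10)
      }
      list(mean_matrix = mm, dispersion = 0.1)
    })
  }
  mm <- expression_model$mean_matrix
  stopifnot(is.matrix(mm), nrow(mm) == n_cell_types, ncol(mm) == n_genes,
            all(mm >= 0), expression_model$dispersion > 0)
  if (nrow(unique(mm)) != nrow(mm)) stop("mean_matrix rows must be distinct")
  if (is.null(morphology_link)) {
    morphology_link <- list(
      weights = seq(1, 2, length.out = n_genes) / n_genes,
      radius = c(9, 3),
      eccentricity = c(0.4, 0.2),
      texture_freq = c(0.25, 0.12)
    )
  }
  cfg <- list(
    n_cell_types = as.integer(n_cell_types), n_genes = as.integer(n_genes),
    slide_height = as.integer(slide_height), slide_width = as.integer(slide_width),
    n_z_planes = as.integer(n_z_planes), n_cells = as.integer(n_cells),
    niche_mixing = niche_mixing, expression_model = expression_model,
    morphology_link = morphology_link, background_noise = background_noise,
    pixel_size_um = pixel_size_um, seed = as.integer(seed)
  )
  cfg$type_morphology <- morphology_params_for_types(cfg)
  rmax <- max(cfg$type_morphology[, "radius"])
  if (!(rmax > 0 && rmax < min(slide_height, slide_width) / 4)) {
    stop("cell radius must satisfy 0 < radius < min(slide dims)/4")
  }
  class(cfg) <- "synthetic_config"
  cfg
}

# Map each type's mean expression vector to (radius, eccentricity,
# texture_freq) through the configured affine link on a standardized
# projection score. Distinct mean rows give distinct scores (generic weights),
# hence distinct morphology.
#' @noRd
morphology_params_for_types <- function(config) {
  ml <- config$morphology_link
  mm <- config$expression_model$mean_matrix
  score <- as.vector(log1p(mm) %*% ml$weights)
  if (nrow(mm) > 1L && stats::sd(score) > 0) {
    score <- (score - mean(score)) / stats::sd(score)
  } else {
    score <- score * 0
  }
  out <- cbind(
    radius = ml$radius[1] + ml$radius[2] * score,
    eccentricity = pmin(0.85, pmax(0, ml$eccentricity[1] + ml$eccentricity[2] * score)),
    texture_freq = pmax(0.02, ml$texture_freq[1] + ml$texture_freq[2] * score)
  )
  rownames(out) <- paste0("type_", seq_len(nrow(mm)))
  out
}

#' Sample ground-truth cells for a synthetic slide
#'
#' Places \code{n_cells} non-overlapping cells, assigns spatially clustered
#' type labels (nearest latent niche center with probability
#' \code{1 - niche_mixing}, uniform otherwise), draws negative-binomial gene
#' counts from the type's mean vector, and builds a closed, non-intersecting
#' boundary polygon per cell.
#'
#' @param config a \code{\link{synthetic_config}}.
#' @return list of ground-truth cells; each has \code{cell_id},
#'   \code{type_label}, \code{centroid} (x, y in 0-based px), \code{boundary}
#'   (n x 2 vertex matrix, implicitly closed), \code{gene_counts}, and
#'   \code{morphology_params} (radius, eccentricity, texture_freq).
#' @export
sample_cells <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  tm <- config$type_morphology
  H <- config$slide_height; W <- config$slide_width
  K <- config$n_cell_types
  with_seed(config$seed, {
    margin <- max(tm[, "radius"]) * 1.6 + 2
    centers <- cbind(stats::runif(K, margin, W - margin),
                     stats::runif(K, margin, H - margin))
    cells <- vector("list", config$n_cells)
    pos <- matrix(NA_real_, config$n_cells, 2L)
    rad <- numeric(config$n_cells)
    accepted <- 0L
    tries <- 0L
    max_tries <- 400L * config$n_cells
    while (accepted < config$n_cells) {
      tries <- tries + 1L
      if (tries > max_tries) {
        stop("could not place ", config$n_cells, " non-overlapping cells; ",
             "config is overcrowded (placed ", accepted, ")")
      }
      p <- c(stats::runif(1, margin, W - margin), stats::runif(1, margin, H - margin))
      d2 <- (centers[, 1] - p[1])^2 + (centers[, 2] - p[2])^2
      type <- if (stats::runif(1) < config$niche_mixing) {
        sample.int(K, 1L)
      } else {
        which.min(d2)
      }
      r <- tm[type, "radius"]
      if (accepted > 0L) {
        dd <- sqrt((pos[seq_len(accepted), 1] - p[1])^2 +
                     (pos[seq_len(accepted), 2] - p[2])^2)
        if (any(dd < 0.95 * (rad[seq_len(accepted)] + r))) next
      }
      accepted <- accepted + 1L
      pos[accepted, ] <- p
      rad[accepted] <- r
      g <- stats::rnbinom(config$n_genes,
                          mu = config$expression_model$mean_matrix[type, ],
                          size = 1 / config$expression_model$dispersion)
      cells[[accepted]] <- list(
        cell_id = sprintf("cell_%05d", accepted),
        type_label = as.integer(type),
        centroid = p,
        boundary = cell_boundary_polygon(p, tm[type, ], H, W),
        gene_counts = as.integer(g),
        morphology_params = tm[type, ]
      )
    }
    attr(cells, "niche_centers") <- centers
    cells
  })
}

# Star-convex boundary polygon: a rotated ellipse with mild radial jitter.
# Star-convexity about the centroid guarantees no self-intersection and that
# the centroid lies inside.
#' @noRd
cell_boundary_polygon <- function(center, morph, H, W, n_vert = 14L) {
  r <- morph[["radius"]]
  ecc <- morph[["eccentricity"]]
  a <- r * (1 + ecc / 2)
  b <- r * (1 - ecc / 2)
  theta <- stats::runif(1, 0, pi)
  ang <- seq(0, 2 * pi, length.out = n_vert + 1L)[-(n_vert + 1L)]
  jit <- 1 + stats::runif(n_vert, -0.05, 0.05)
  ex <- a * cos(ang) * jit
  ey <- b * sin(ang) * jit
  x <- center[1] + ex * cos(theta) - ey * sin(theta)
  y <- center[2] + ex * sin(theta) + ey * cos(theta)
  cbind(x = pmin(pmax(x, 0), W - 1e-6), y = pmin(pmax(y, 0), H - 1e-6))
}

#' Render sampled cells into a z-stack intensity image
#'
#' Each cell becomes an anisotropic Gaussian blob (axes set by radius and
#' eccentricity, random orientation) carrying a sinusoidal texture at its
#' \code{texture_freq}. Foreground intensity is partitioned over z planes with
#' plane-specific attenuation whose maximum over z is 1, so the
#' maximum-intensity projection recovers the full blob; additive nonnegative
#' background noise is applied per plane.
#'
#' @param cells output of \code{\link{sample_cells}}.
#' @param config the same \code{\link{synthetic_config}}.
#' @return object of class \code{synthetic_slide}: list with \code{zstack}
#'   (n_z_planes x H x W nonnegative array), \code{cells},
#'   \code{pixel_size_um}, and the config.
#' @export
render_slide <- function(cells, config) {
  stopifnot(inherits(config, "synthetic_config"))
  H <- config$slide_height; W <- config$slide_width
  fg <- matrix(0, H, W)
  with_seed(config$seed + 1L, {
    for (cell in cells) {
      m <- cell$morphology_params
      r <- m[["radius"]]; ecc <- m[["eccentricity"]]; tf <- m[["texture_freq"]]
      a <- r * (1 + ecc / 2); b <- r * (1 - ecc / 2)
      sa <- a / 2.2; sb <- b / 2.2
      theta <- stats::runif(1, 0, pi)
      ext <- ceiling(3 * max(sa, sb))
      cx <- cell$centroid[1]; cy <- cell$centroid[2]
      cols <- max(1L, floor(cx - ext)):min(W, ceiling(cx + ext))
      rows <- max(1L, floor(cy - ext)):min(H, ceiling(cy + ext))
      px <- outer(rep(1, length(rows)), cols - 0.5) - cx
      py <- outer(rows - 0.5, rep(1, length(cols)))  - cy
      xr <- px * cos(theta) + py * sin(theta)
      yr <- -px * sin(theta) + py * cos(theta)
      d2 <- (xr / sa)^2 + (yr / sb)^2
      tex <- 0.75 + 0.25 * sin(2 * pi * tf * xr)
      blob <- 0.9 * exp(-0.5 * d2) * tex
      fg[rows, cols] <- pmax(fg[rows, cols], blob)
    }
    atten <- 0.5 + 0.5 * rev(seq_len(config$n_z_planes)) / config$n_z_planes
    atten[1L] <- 1
    zstack <- array(0, c(config$n_z_planes, H, W))
    for (z in seq_len(config$n_z_planes)) {
      noise <- if (config$background_noise > 0) {
        matrix(abs(stats::rnorm(H * W, sd = config$background_noise)), H, W)
      } else {
        0
      }
      zstack[z, , ] <- fg * atten[z] + noise
    }
    out <- list(zstack = zstack, cells = cells,
                pixel_size_um = config$pixel_size_um, config = config)
    class(out) <- "synthetic_slide"
    out
  })
}

#' Write a synthetic slide to open on-disk formats
#'
#' Writes a multi-page 32-bit float TIFF z-stack (intensities max-scaled to
#' \code{[0,1]}; the scale is recorded in the metadata so readers can restore
#' raw values), a boundaries CSV (\code{cell_id, vertex_index, x, y}, 0-based
#' pixel coordinates), an expression CSV (\code{cell_id} x gene), a cells CSV
#' (centroids, ground-truth type labels, morphology), and a JSON metadata
#' file.
#'
#' @param slide a \code{synthetic_slide}.
#' @param dir output directory (created if missing).
#' @return invisibly, the vector of file paths written.
#' @export
write_slide <- function(slide, dir) {
  stopifnot(inherits(slide, "synthetic_slide"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  zs <- slide$zstack
  sc <- max(zs, 1e-12)
  pages <- lapply(seq_len(dim(zs)[1]), function(z) zs[z, , ] / sc)
  tif <- file.path(dir, "zstack.tif")
  tiff::writeTIFF(pages, tif, bits.per.sample = 32L)

  bnd <- do.call(rbind, lapply(slide$cells, function(cell) {
    data.frame(cell_id = cell$cell_id,
               vertex_index = seq_len(nrow(cell$boundary)) - 1L,
               x = cell$boundary[, 1], y = cell$boundary[, 2])
  }))
  bfile <- file.path(dir, "boundaries.csv")
  utils::write.csv(format(bnd, digits = 17, scientific = FALSE, trim = TRUE),
                   bfile, row.names = FALSE, quote = FALSE)

  G <- slide$config$n_genes
  expr <- do.call(rbind, lapply(slide$cells, function(cell) cell$gene_counts))
  expr_df <- data.frame(cell_id = vapply(slide$cells, `[[`, "", "cell_id"), expr)
  names(expr_df) <- c("cell_id", sprintf("gene_%04d", seq_len(G)))
  efile <- file.path(dir, "expression.csv")
  utils::write.csv(expr_df, efile, row.names = FALSE, quote = FALSE)

  cells_df <- do.call(rbind, lapply(slide$cells, function(cell) {
    data.frame(cell_id = cell$cell_id, type_label = cell$type_label,
               centroid_x = cell$centroid[1], centroid_y = cell$centroid[2],
               radius = cell$morphology_params[["radius"]],
               eccentricity = cell$morphology_params[["eccentricity"]],
               texture_freq = cell$morphology_params[["texture_freq"]])
  }))
  cfile <- file.path(dir, "cells.csv")
  utils::write.csv(format(cells_df, digits = 17, scientific = FALSE, trim = TRUE),
                   cfile, row.names = FALSE, quote = FALSE)

  meta <- list(
    slide_id = basename(normalizePath(dir)),
    pixel_size_um = slide$pixel_size_um,
    seed = slide$config$seed,
    intensity_scale = sc,
    n_z_planes = dim(zs)[1],
    slide_height = dim(zs)[2],
    slide_width = dim(zs)[3],
    n_cells = length(slide$cells),
    n_genes = G,
    gene_ids = sprintf("gene_%04d", seq_len(G)),
    config = list(
      n_cell_types = slide$config$n_cell_types,
      niche_mixing = slide$config$niche_mixing,
      background_noise = slide$config$background_noise,
      dispersion = slide$config$expression_model$dispersion
    )
  )
  mfile <- file.path(dir, "metadata.json")
  jsonlite::write_json(meta, mfile, auto_unbox = TRUE, digits = NA)
  invisible(c(tif, bfile, efile, cfile, mfile))
}

#' Generate and write one synthetic slide in a single call
#'
#' @param config a \code{\link{synthetic_config}}.
#' @param dir output directory.
#' @return the in-memory \code{synthetic_slide}, invisibly.
#' @export
simulate_slide <- function(config, dir = NULL) {
  cells <- sample_cells(config)
  slide <- render_slide(cells, config)
  if (!is.null(dir)) write_slide(slide, dir)
  invisible(slide)
}
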