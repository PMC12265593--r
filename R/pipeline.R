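# Multi-scale dataset construction from a segmented slide:
# z-stack -> maximum-intensity projection -> 8-bit normalization ->
# minimal-square cell crops -> non-overlapping niche tiles (default 256 px)
# -> tissue tiles (default 1024 px), with exact gene-mass pooling at every
# scale, serialized into a sorted key-value store.
#
# Conventions: 0-based pixel coordinates, x = column, y = row; pixel (r, c)
# of a matrix covers the half-open square [c-1, c) x [r-1, r); tiles are
# half-open [origin, origin + tile).

#' Read a slide directory written by \code{\link{write_slide}}
#'
#' @param dir directory holding \code{zstack.tif}, \code{boundaries.csv},
#'   \code{expression.csv}, \code{cells.csv} and \code{metadata.json}.
#' @return list with \code{zstack} (Z x H x W raw intensities),
#'   \code{boundaries} (named list of n x 2 vertex matrices),
#'   \code{expression} (cells x genes matrix), \code{cells} data frame,
#'   \code{gene_ids}, \code{pixel_size_um} and \code{slide_id}.
#' @export
read_slide <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(file.path(dir, "zstack.tif"), all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  Z <- length(pages)
  H <- nrow(pages[[1]]); W <- ncol(pages[[1]])
  zstack <- array(0, c(Z, H, W))
  for (z in seq_len(Z)) zstack[z, , ] <- pages[[z]] * meta$intensity_scale
  bnd <- utils::read.csv(file.path(dir, "boundaries.csv"), stringsAsFactors = FALSE)
  boundaries <- lapply(split(bnd, bnd$cell_id), function(d) {
    d <- d[order(d$vertex_index), ]
    cbind(x = d$x, y = d$y)
  })
  expr_df <- utils::read.csv(file.path(dir, "expression.csv"), stringsAsFactors = FALSE)
  expr <- as.matrix(expr_df[, -1, drop = FALSE])
  rownames(expr) <- expr_df$cell_id
  cells <- utils::read.csv(file.path(dir, "cells.csv"), stringsAsFactors = FALSE)
  list(zstack = zstack, boundaries = boundaries, expression = expr,
       cells = cells, gene_ids = meta$gene_ids,
       pixel_size_um = meta$pixel_size_um, slide_id = meta$slide_id)
}

#' Maximum-intensity projection over z
#'
#' @param zstack Z x H x W array (Z >= 1).
#' @return H x W matrix, the per-pixel maximum across planes.
#' @export
max_intensity_projection <- function(zstack) {
  d <- dim(zstack)
  if (is.null(d) || length(d) != 3L || d[1] < 1L) {
    stop("zstack must be a Z x H x W array with Z >= 1")
  }
  out <- matrix(zstack[1, , ], d[2], d[3])
  if (d[1] > 1L) {
    for (z in 2:d[1]) out <- pmax(out, matrix(zstack[z, , ], d[2], d[3]))
  }
  out
}

#' Min-max normalization to 8-bit
#'
#' Affine map of the value range onto \code{[0, 255]} followed by
#' round-half-to-even and cast to integer. A constant image maps to all
#' zeros.
#'
#' @param image numeric matrix/array with finite values.
#' @return integer matrix with values in 0..255.
#' @export
normalize_uint8 <- function(image) {
  if (any(!is.finite(image))) stop("image contains NaN/Inf")
  lo <- min(image); hi <- max(image)
  if (hi == lo) {
    out <- image * 0L
    storage.mode(out) <- "integer"
    return(out)
  }
  out <- round((image - lo) / (hi - lo) * 255)
  storage.mode(out) <- "integer"
  out
}

#' Extract the minimal square crop containing a cell boundary
#'
#' The crop side is \code{S = ceil(max(bbox_width, bbox_height))} of the
#' boundary's axis-aligned bounding box; the square is centered on the bbox
#' center and regions outside the slide are zero-padded.
#'
#' @param image H x W integer (8-bit) projected image.
#' @param boundary n x 2 matrix of polygon vertices (>= 3 rows, x then y).
#' @return list with \code{crop} (S x S integer matrix), \code{S},
#'   \code{origin} = the continuous (x, y) coordinate of the minimal
#'   square's top-left corner (the square centered on the bbox center, which
#'   contains every vertex by construction), and \code{pixel_origin} = the
#'   integer pixel offset at which the crop was sampled
#'   (\code{floor(origin)}; sampling is pixel-grid aligned, so the sampled
#'   window can sit up to one pixel down-left of the mathematical square).
#' @export
extract_cell_crop <- function(image, boundary) {
  stopifnot(is.matrix(boundary), nrow(boundary) >= 3L)
  bw <- max(boundary[, 1]) - min(boundary[, 1])
  bh <- max(boundary[, 2]) - min(boundary[, 2])
  if (bw <= 0 && bh <= 0) stop("degenerate zero-area boundary")
  S <- as.integer(ceiling(max(bw, bh)))
  if (S < 1L) S <- 1L
  cx <- (min(boundary[, 1]) + max(boundary[, 1])) / 2
  cy <- (min(boundary[, 2]) + max(boundary[, 2])) / 2
  x0 <- as.integer(floor(cx - S / 2))
  y0 <- as.integer(floor(cy - S / 2))
  crop <- matrix(0L, S, S)
  H <- nrow(image); W <- ncol(image)
  rs <- max(y0 + 1L, 1L):min(y0 + S, H)
  cs <- max(x0 + 1L, 1L):min(x0 + S, W)
  if (length(rs) > 0L && length(cs) > 0L && rs[1] <= rs[length(rs)] && cs[1] <= cs[length(cs)]) {
    crop[rs - y0, cs - x0] <- image[rs, cs]
  }
  list(crop = crop, S = S, origin = c(cx - S / 2, cy - S / 2),
       pixel_origin = c(x0, y0))
}

#' Build per-cell records from a projected slide
#'
#' @param projected H x W 8-bit projected image (see
#'   \code{\link{normalize_uint8}}).
#' @param boundaries named list of boundary polygons (one per cell).
#' @param expression cells x genes count matrix, rows named by cell id.
#' @param cells data frame with \code{cell_id}, \code{centroid_x},
#'   \code{centroid_y} (0-based px).
#' @param slide_id slide identifier string.
#' @param crop_px optional side length; when given, a bilinear-resized copy of
#'   each raw crop is attached as \code{crop_resized} (the raw S x S crop is
#'   always kept).
#' @return list of cell records (\code{cell_id}, \code{crop}, \code{S},
#'   \code{gene}, \code{centroid}, \code{slide_id}).
#' @export
build_cell_records <- function(projected, boundaries, expression, cells,
                               slide_id, crop_px = NULL) {
  lapply(seq_len(nrow(cells)), function(i) {
    id <- cells$cell_id[i]
    cc <- extract_cell_crop(projected, boundaries[[id]])
    rec <- list(cell_id = id, crop = cc$crop, S = cc$S,
                gene = as.numeric(expression[id, ]),
                centroid = c(cells$centroid_x[i], cells$centroid_y[i]),
                slide_id = slide_id)
    if (!is.null(crop_px)) rec$crop_resized <- resize_bilinear(cc$crop, crop_px)
    rec
  })
}

#' Bilinear resample of a square image matrix
#'
#' Samples at output pixel centers (align-corners = FALSE convention).
#'
#' @param img numeric matrix.
#' @param out_px output side length.
#' @return out_px x out_px numeric matrix.
#' @export
resize_bilinear <- function(img, out_px) {
  H <- nrow(img); W <- ncol(img)
  if (H == out_px && W == out_px) return(img + 0)
  ys <- (seq_len(out_px) - 0.5) * H / out_px - 0.5
  xs <- (seq_len(out_px) - 0.5) * W / out_px - 0.5
  y0 <- pmin(pmax(floor(ys), 0), H - 1); x0 <- pmin(pmax(floor(xs), 0), W - 1)
  y1 <- pmin(y0 + 1, H - 1); x1 <- pmin(x0 + 1, W - 1)
  wy <- pmin(pmax(ys - y0, 0), 1); wx <- pmin(pmax(xs - x0, 0), 1)
  A <- img[y0 + 1, x0 + 1, drop = FALSE]
  B <- img[y0 + 1, x1 + 1, drop = FALSE]
  C <- img[y1 + 1, x0 + 1, drop = FALSE]
  D <- img[y1 + 1, x1 + 1, drop = FALSE]
  WY <- matrix(wy, out_px, out_px); WX <- matrix(wx, out_px, out_px, byrow = TRUE)
  A * (1 - WY) * (1 - WX) + B * (1 - WY) * WX + C * WY * (1 - WX) + D * WY * WX
}

#' Place a raw cell crop on a fixed-size canvas, preserving scale
#'
#' Centers the S x S crop on a \code{px} x \code{px} zero canvas (center-crops
#' when S > px). Unlike resizing, this keeps absolute cell size — a
#' morphological feature — visible to downstream models.
#'
#' @param crop square image matrix.
#' @param px canvas side length.
#' @return px x px numeric matrix.
#' @export
crop_to_canvas <- function(crop, px) {
  S <- nrow(crop)
  if (S > px) {
    o <- (S - px) %/% 2L
    return(crop[(o + 1L):(o + px), (o + 1L):(o + px)] + 0)
  }
  out <- matrix(0, px, px)
  o <- (px - S) %/% 2L
  out[(o + 1L):(o + S), (o + 1L):(o + S)] <- crop
  out
}

#' Tile a slide into non-overlapping niches and pool member genes
#'
#' Cells are assigned to exactly one tile by centroid
#' (\code{row = floor(y/tile)}, \code{col = floor(x/tile)}); border tiles are
#' zero-padded to \code{tile x tile}; tiles without cells are dropped. The
#' pooled gene vector of a niche is the exact elementwise sum of its members'
#' vectors.
#'
#' @param projected H x W 8-bit projected image.
#' @param cell_records list from \code{\link{build_cell_records}}.
#' @param tile tile side in px (default 256).
#' @param slide_id slide identifier.
#' @return list of niche records (\code{niche_id}, \code{grid_index} = (row,
#'   col), \code{image}, \code{pooled_gene}, \code{member_cell_ids},
#'   \code{position} = tile origin (x, y)).
#' @export
tile_niches <- function(projected, cell_records, tile = 256L, slide_id = "slide") {
  stopifnot(tile >= 1L)
  H <- nrow(projected); W <- ncol(projected)
  cx <- vapply(cell_records, function(r) r$centroid[1], 0)
  cy <- vapply(cell_records, function(r) r$centroid[2], 0)
  if (any(cx < 0 | cx >= W | cy < 0 | cy >= H)) {
    stop("cell centroid outside slide bounds")
  }
  row <- floor(cy / tile)
  col <- floor(cx / tile)
  key <- paste(row, col)
  idx <- split(seq_along(cell_records), key)
  out <- vector("list", length(idx))
  ord <- order(vapply(strsplit(names(idx), " "), function(p) {
    as.numeric(p[1]) * 1e6 + as.numeric(p[2])
  }, 0))
  k <- 0L
  for (nm in names(idx)[ord]) {
    members <- idx[[nm]]
    rc <- as.integer(strsplit(nm, " ")[[1]])
    x0 <- rc[2] * tile; y0 <- rc[1] * tile
    img <- matrix(0L, tile, tile)
    rs <- (y0 + 1L):min(y0 + tile, H)
    cs <- (x0 + 1L):min(x0 + tile, W)
    img[rs - y0, cs - x0] <- projected[rs, cs]
    pooled <- Reduce(`+`, lapply(cell_records[members], `[[`, "gene"))
    k <- k + 1L
    out[[k]] <- list(
      niche_id = sprintf("%s_niche_r%03d_c%03d", slide_id, rc[1], rc[2]),
      grid_index = rc,
      image = img,
      pooled_gene = pooled,
      member_cell_ids = vapply(cell_records[members], `[[`, "", "cell_id"),
      position = c(x0, y0),
      slide_id = slide_id
    )
  }
  out[seq_len(k)]
}

#' Group niches into tissue tiles
#'
#' Applies the same floor rule to niche origins at the tissue tile size
#' (default 1024 px). The tissue pooled gene vector is the exact sum of the
#' member niches' pooled vectors.
#'
#' @param projected H x W 8-bit projected image.
#' @param niches list from \code{\link{tile_niches}}.
#' @param tissue_tile tile side in px (default 1024).
#' @param slide_id slide identifier.
#' @return list of tissue records (\code{tissue_id}, \code{image},
#'   \code{niche_ids}, \code{niche_grid}, \code{pooled_gene},
#'   \code{slide_id}).
#' @export
build_tissue <- function(projected, niches, tissue_tile = 1024L,
                         slide_id = "slide") {
  H <- nrow(projected); W <- ncol(projected)
  row <- vapply(niches, function(n) floor(n$position[2] / tissue_tile), 0)
  col <- vapply(niches, function(n) floor(n$position[1] / tissue_tile), 0)
  key <- paste(row, col)
  idx <- split(seq_along(niches), key)
  out <- vector("list", length(idx))
  k <- 0L
  for (nm in names(idx)) {
    members <- idx[[nm]]
    rc <- as.integer(strsplit(nm, " ")[[1]])
    x0 <- rc[2] * tissue_tile; y0 <- rc[1] * tissue_tile
    img <- matrix(0L, tissue_tile, tissue_tile)
    rs <- (y0 + 1L):min(y0 + tissue_tile, H)
    cs <- (x0 + 1L):min(x0 + tissue_tile, W)
    img[rs - y0, cs - x0] <- projected[rs, cs]
    k <- k + 1L
    out[[k]] <- list(
      tissue_id = sprintf("%s_tissue_r%03d_c%03d", slide_id, rc[1], rc[2]),
      image = img,
      niche_ids = vapply(niches[members], `[[`, "", "niche_id"),
      niche_grid = do.call(rbind, lapply(niches[members], `[[`, "grid_index")),
      pooled_gene = Reduce(`+`, lapply(niches[members], `[[`, "pooled_gene")),
      slide_id = slide_id
    )
  }
  out[seq_len(k)]
}

#' Combine datasets from several slides into one training corpus
#'
#' Cell ids are prefixed with their slide id so they stay unique across
#' slides; niche membership lists are rewritten accordingly (niche and
#' tissue ids already embed the slide id).
#'
#' @param builts list of \code{\link{build_dataset}} outputs.
#' @return a combined dataset list (\code{cells}, \code{niches},
#'   \code{tissues}, \code{manifest}).
#' @export
combine_datasets <- function(builts) {
  cells <- list(); niches <- list(); tissues <- list()
  for (b in builts) {
    sid <- b$manifest$slide_id %||% b$cells[[1]]$slide_id
    bc <- lapply(b$cells, function(r) {
      r$cell_id <- paste0(sid, ":", r$cell_id)
      r
    })
    bn <- lapply(b$niches, function(r) {
      r$member_cell_ids <- paste0(sid, ":", r$member_cell_ids)
      r
    })
    cells <- c(cells, bc)
    niches <- c(niches, bn)
    tissues <- c(tissues, b$tissues)
  }
  list(cells = cells, niches = niches, tissues = tissues,
       manifest = list(slide_id = "combined",
                       n_genes = length(cells[[1]]$gene)))
}

# ---- key-value dataset store -------------------------------------------------
# A sorted-key, memory-mapped-style store: one append-only data file of
# length-prefixed binary records plus a plain-text index (key, offset, size).
# Records serialize as: uint8 image bytes with a shape header, little-endian
# float32 gene vectors, and length-prefixed UTF-8 ids.

#' Open (or create) a dataset store
#'
#' @param path store directory; one store per scale (cell/niche/tissue).
#' @param scale one of \code{"cell"}, \code{"niche"}, \code{"tissue"}.
#' @param create create an empty store, truncating any existing one.
#' @return a store handle.
#' @export
store_open <- function(path, scale = c("cell", "niche", "tissue"),
                       create = FALSE) {
  scale <- match.arg(scale)
  st <- new.env(parent = emptyenv())
  st$path <- path
  st$scale <- scale
  st$data_file <- file.path(path, "data.bin")
  st$index_file <- file.path(path, "index.tsv")
  if (create) {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    file.create(st$data_file)
    utils::write.table(
      data.frame(key = character(), offset = integer(), size = integer(),
                 stringsAsFactors = FALSE),
      st$index_file, sep = "\t", row.names = FALSE, quote = FALSE)
    st$index <- list()
  } else {
    if (!file.exists(st$index_file)) stop("no store at ", path)
    idx <- utils::read.table(st$index_file, sep = "\t", header = TRUE,
                             colClasses = c("character", "numeric", "numeric"))
    st$index <- stats::setNames(
      lapply(seq_len(nrow(idx)), function(i) c(idx$offset[i], idx$size[i])),
      idx$key)
  }
  class(st) <- "dataset_store"
  st
}

#' Write records to a dataset store
#'
#' Keys are zero-padded decimal indices joined with the slide id, so
#' lexicographic key order equals write order within a slide.
#'
#' @param records list of records at the store's scale.
#' @param store a handle from \code{\link{store_open}}.
#' @return the number of records written.
#' @export
store_write <- function(records, store) {
  con <- file(store$data_file, "ab")
  on.exit(close(con), add = TRUE)
  offset <- file.size(store$data_file)
  rows <- vector("list", length(records))
  for (i in seq_along(records)) {
    rec <- records[[i]]
    blob <- serialize_record(rec, store$scale)
    key <- sprintf("%s/%08d", rec$slide_id, length(store$index) + 1L)
    writeBin(length(blob), con, size = 4L, endian = "little")
    writeBin(blob, con)
    store$index[[key]] <- c(offset, length(blob) + 4L)
    rows[[i]] <- data.frame(key = key, offset = offset,
                            size = length(blob) + 4L, stringsAsFactors = FALSE)
    offset <- offset + length(blob) + 4L
  }
  utils::write.table(do.call(rbind, rows), store$index_file, sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE,
                     append = TRUE)
  length(records)
}

#' Read one record back from a dataset store
#'
#' @param store a handle from \code{\link{store_open}}.
#' @param key record key.
#' @return the deserialized record.
#' @export
store_read <- function(store, key) {
  ent <- store$index[[key]]
  if (is.null(ent)) stop("missing key: ", key)
  con <- file(store$data_file, "rb")
  on.exit(close(con), add = TRUE)
  seek(con, ent[1])
  n <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  blob <- readBin(con, "raw", n)
  if (length(blob) != n) stop("corrupt record at key ", key)
  deserialize_record(blob, store$scale)
}

#' Number of records in a store
#' @param store a store handle.
#' @return integer count.
#' @export
store_count <- function(store) length(store$index)

#' Keys of a store, in lexicographic order
#' @param store a store handle.
#' @return character vector of keys.
#' @export
store_keys <- function(store) sort(names(store$index), method = "radix")

#' @noRd
put_str <- function(con, s) {
  b <- charToRaw(enc2utf8(s))
  writeBin(length(b), con, size = 4L, endian = "little")
  writeBin(b, con)
}

#' @noRd
get_str <- function(con) {
  n <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  rawToChar(readBin(con, "raw", n))
}

#' @noRd
put_f32 <- function(con, x) {
  writeBin(length(x), con, size = 4L, endian = "little")
  writeBin(as.numeric(x), con, size = 4L, endian = "little")
}

#' @noRd
get_f32 <- function(con) {
  n <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  readBin(con, "numeric", n, size = 4L, endian = "little")
}

#' @noRd
put_img <- function(con, img) {
  writeBin(c(nrow(img), ncol(img)), con, size = 4L, endian = "little")
  writeBin(as.raw(as.vector(t(img))), con)
}

#' @noRd
get_img <- function(con) {
  hw <- readBin(con, "integer", 2L, size = 4L, endian = "little")
  b <- readBin(con, "raw", hw[1] * hw[2])
  matrix(as.integer(b), hw[1], hw[2], byrow = TRUE)
}

#' @noRd
serialize_record <- function(rec, scale) {
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con), add = TRUE)
  if (scale == "cell") {
    put_str(con, rec$cell_id); put_str(con, rec$slide_id)
    put_img(con, rec$crop)
    put_f32(con, rec$gene)
    put_f32(con, rec$centroid)
  } else if (scale == "niche") {
    put_str(con, rec$niche_id); put_str(con, rec$slide_id)
    put_img(con, rec$image)
    put_f32(con, rec$pooled_gene)
    writeBin(as.integer(rec$grid_index), con, size = 4L, endian = "little")
    put_f32(con, rec$position)
    writeBin(length(rec$member_cell_ids), con, size = 4L, endian = "little")
    for (id in rec$member_cell_ids) put_str(con, id)
  } else {
    put_str(con, rec$tissue_id); put_str(con, rec$slide_id)
    put_img(con, rec$image)
    put_f32(con, rec$pooled_gene)
    writeBin(length(rec$niche_ids), con, size = 4L, endian = "little")
    for (id in rec$niche_ids) put_str(con, id)
    writeBin(as.integer(t(rec$niche_grid)), con, size = 4L, endian = "little")
  }
  rawConnectionValue(con)
}

#' @noRd
deserialize_record <- function(blob, scale) {
  con <- rawConnection(blob, "rb")
  on.exit(close(con), add = TRUE)
  if (scale == "cell") {
    rec <- list(cell_id = get_str(con), slide_id = get_str(con))
    rec$crop <- get_img(con)
    rec$S <- nrow(rec$crop)
    rec$gene <- get_f32(con)
    rec$centroid <- get_f32(con)
    rec[c("cell_id", "crop", "S", "gene", "centroid", "slide_id")]
  } else if (scale == "niche") {
    rec <- list(niche_id = get_str(con), slide_id = get_str(con))
    rec$image <- get_img(con)
    rec$pooled_gene <- get_f32(con)
    rec$grid_index <- readBin(con, "integer", 2L, size = 4L, endian = "little")
    rec$position <- get_f32(con)
    nm <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    rec$member_cell_ids <- vapply(seq_len(nm), function(i) get_str(con), "")
    rec[c("niche_id", "grid_index", "image", "pooled_gene",
          "member_cell_ids", "position", "slide_id")]
  } else {
    rec <- list(tissue_id = get_str(con), slide_id = get_str(con))
    rec$image <- get_img(con)
    rec$pooled_gene <- get_f32(con)
    nn <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    rec$niche_ids <- vapply(seq_len(nn), function(i) get_str(con), "")
    rec$niche_grid <- matrix(readBin(con, "integer", 2L * nn, size = 4L,
                                     endian = "little"), nn, 2L, byrow = TRUE)
    rec[c("tissue_id", "image", "niche_ids", "niche_grid", "pooled_gene",
          "slide_id")]
  }
}

#' Run the full dataset build for one slide directory
#'
#' Projection, normalization, cell/niche/tissue record construction and
#' store serialization, with a manifest JSON of counts and configuration.
#'
#' @param slide_dir directory readable by \code{\link{read_slide}}.
#' @param out_dir output directory; one store per scale is created under it.
#' @param tile niche tile size (px).
#' @param tissue_tile tissue tile size (px).
#' @param crop_px optional model input side; resized crops attached at build
#'   time (raw crops always stored).
#' @return list with the three record lists and store paths, invisibly.
#' @export
build_dataset <- function(slide_dir, out_dir, tile = 256L, tissue_tile = 1024L,
                          crop_px = NULL) {
  sl <- read_slide(slide_dir)
  proj <- normalize_uint8(max_intensity_projection(sl$zstack))
  cellrec <- build_cell_records(proj, sl$boundaries, sl$expression, sl$cells,
                                sl$slide_id, crop_px = crop_px)
  nicherec <- tile_niches(proj, cellrec, tile = tile, slide_id = sl$slide_id)
  tissuerec <- build_tissue(proj, nicherec, tissue_tile = tissue_tile,
                            slide_id = sl$slide_id)
  stores <- list(
    cell = store_open(file.path(out_dir, "cell"), "cell", create = TRUE),
    niche = store_open(file.path(out_dir, "niche"), "niche", create = TRUE),
    tissue = store_open(file.path(out_dir, "tissue"), "tissue", create = TRUE)
  )
  counts <- c(cell = store_write(cellrec, stores$cell),
              niche = store_write(nicherec, stores$niche),
              tissue = store_write(tissuerec, stores$tissue))
  manifest <- list(slide_id = sl$slide_id, counts = as.list(counts),
                   tile = tile, tissue_tile = tissue_tile,
                   n_genes = ncol(sl$expression), gene_ids = sl$gene_ids)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(cells = cellrec, niches = nicherec, tissues = tissuerec,
                 projected = proj, stores = stores, manifest = manifest))
}
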