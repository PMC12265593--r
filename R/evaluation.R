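# Image-fidelity metrics and downstream harnesses over embeddings:
# PSNR/SSIM, cross-modal correlation through a small perceptron regressor,
# k-means clustering agreement (ARI/NMI) and perceptron classification
# (macro F1/precision).

#' Peak signal-to-noise ratio
#'
#' \code{10 * log10(max_val^2 / MSE)}. Identical images (MSE 0) are reported
#' as the capped sentinel 100 with attribute \code{identical = TRUE}.
#'
#' @param a,b images of identical shape.
#' @param max_val dynamic range (255 for 8-bit).
#' @return PSNR in dB.
#' @export
psnr <- function(a, b, max_val = 255) {
  if (!identical(dim(a), dim(b))) stop("shape mismatch")
  mse <- mean((as.numeric(a) - as.numeric(b))^2)
  if (mse == 0) {
    return(structure(100, identical = TRUE))
  }
  10 * log10(max_val^2 / mse)
}

#' @noRd
gauss_kernel <- function(size = 11L, sigma = 1.5) {
  half <- (size - 1) / 2
  g <- exp(-((-half:half)^2) / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

# valid-region 2-D convolution with a small kernel (loop over kernel taps)
#' @noRd
filter2_valid <- function(x, k) {
  n <- nrow(k)
  oh <- nrow(x) - n + 1L
  ow <- ncol(x) - n + 1L
  out <- matrix(0, oh, ow)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    out <- out + k[i, j] * x[i:(i + oh - 1L), j:(j + ow - 1L)]
  }
  out
}

#' Structural similarity index
#'
#' Standard SSIM with an 11x11 Gaussian window (sigma 1.5) and stabilizing
#' constants \code{k1 = 0.01}, \code{k2 = 0.03}; the mean over the valid
#' window positions is returned.
#'
#' @param a,b images of identical shape.
#' @param max_val dynamic range (255 for 8-bit).
#' @return SSIM in [-1, 1]; exactly 1 for identical images.
#' @export
ssim <- function(a, b, max_val = 255) {
  if (!identical(dim(a), dim(b))) stop("shape mismatch")
  x <- matrix(as.numeric(a), nrow(a)); y <- matrix(as.numeric(b), nrow(b))
  k <- gauss_kernel()
  c1 <- (0.01 * max_val)^2
  c2 <- (0.03 * max_val)^2
  mx <- filter2_valid(x, k); my <- filter2_valid(y, k)
  sxx <- filter2_valid(x * x, k) - mx^2
  syy <- filter2_valid(y * y, k) - my^2
  sxy <- filter2_valid(x * y, k) - mx * my
  s <- ((2 * mx * my + c1) * (2 * sxy + c2)) /
    ((mx^2 + my^2 + c1) * (sxx + syy + c2))
  mean(s)
}

# ---- two-layer perceptron harness -------------------------------------------

#' @noRd
mlp_new <- function(d_in, d_hidden, d_out, seed = 1L) {
  with_seed(seed, list(fc1 = linear_new(d_in, d_hidden),
                       fc2 = linear_new(d_hidden, d_out)))
}

#' @noRd
mlp_fwd <- function(m, x) linear_fwd(m$fc2, ag_relu(linear_fwd(m$fc1, x)))

# full-batch AdamW training; loss_fn(pred_node) -> scalar node
#' @noRd
mlp_train <- function(m, X, loss_fn, epochs = 200L, lr = 1e-2) {
  params <- collect_params(m)
  opt <- opt_adamw(params, lr = lr)
  for (e in seq_len(epochs)) {
    zero_grads(params)
    ag_tape_start()
    loss <- loss_fn(mlp_fwd(m, X))
    ag_backward(loss)
    ag_tape_stop()
    opt_step(opt)
  }
  m
}

#' Cross-modal prediction harness
#'
#' Trains a two-layer perceptron to predict one modality from the other on a
#' train split and reports the mean per-target Pearson and Spearman
#' correlation on the held-out test split. Constant test targets (undefined
#' correlation) are excluded and counted.
#'
#' @param embeddings n x D embedding matrix.
#' @param genes n x G expression matrix (log1p applied internally when
#'   predicting genes).
#' @param direction \code{"z2g"} (embedding to expression) or \code{"g2z"}.
#' @param split fraction of samples used for training.
#' @param hidden,epochs,lr perceptron settings.
#' @param seed split/initialization seed.
#' @return list with \code{pearson}, \code{spearman} (means over usable
#'   targets), per-target vectors, \code{n_test}, and
#'   \code{n_excluded_constant}.
#' @export
cross_modal_fit <- function(embeddings, genes, direction = c("z2g", "g2z"),
                            split = 0.7, hidden = 64L, epochs = 200L,
                            lr = 1e-2, seed = 1L) {
  direction <- match.arg(direction)
  stopifnot(nrow(embeddings) == nrow(genes))
  n <- nrow(embeddings)
  if (direction == "z2g") {
    X <- embeddings; Y <- log1p(genes)
  } else {
    X <- log1p(genes); Y <- embeddings
  }
  idx <- with_seed(seed, sample.int(n))
  ntr <- max(2L, floor(split * n))
  tr <- idx[seq_len(ntr)]; te <- idx[(ntr + 1L):n]
  mu <- colMeans(X[tr, , drop = FALSE])
  sdv <- pmax(apply(X[tr, , drop = FALSE], 2L, stats::sd), 1e-8)
  Xs <- sweep(sweep(X, 2L, mu), 2L, sdv, "/")
  m <- mlp_new(ncol(X), hidden, ncol(Y), seed = seed + 1L)
  m <- mlp_train(m, Xs[tr, , drop = FALSE],
                 function(pred) ag_mse(pred, Y[tr, , drop = FALSE]),
                 epochs = epochs, lr = lr)
  pred <- vv(mlp_fwd(m, Xs[te, , drop = FALSE]))
  truth <- Y[te, , drop = FALSE]
  pt_p <- rep(NA_real_, ncol(Y)); pt_s <- rep(NA_real_, ncol(Y))
  for (j in seq_len(ncol(Y))) {
    if (stats::sd(truth[, j]) > 0 && stats::sd(pred[, j]) > 0) {
      pt_p[j] <- stats::cor(pred[, j], truth[, j])
      pt_s[j] <- stats::cor(pred[, j], truth[, j], method = "spearman")
    }
  }
  usable <- !is.na(pt_p)
  list(name = paste0("cross_modal_", direction),
       pearson = mean(pt_p[usable]), spearman = mean(pt_s[usable]),
       per_target_pearson = pt_p, per_target_spearman = pt_s,
       n_test = length(te), n_excluded_constant = sum(!usable))
}

#' @noRd
nmi_score <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  p <- tab / n
  pa <- rowSums(p); pb <- colSums(p)
  nz <- p > 0
  mi <- sum(p[nz] * log(p[nz] / outer(pa, pb)[nz]))
  ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  if (ha == 0 && hb == 0) return(1)
  mi / ((ha + hb) / 2)
}

#' Clustering agreement of embeddings with labels
#'
#' Embeddings are first projected onto their leading principal components
#' and whitened to unit variance — the standard preprocessing before
#' k-means in single-cell embedding analysis, which removes the arbitrary
#' anisotropy of learned representation spaces. Seeded k-means (k = number
#' of classes unless given) is then scored by adjusted Rand index and
#' normalized mutual information (arithmetic-mean normalization).
#'
#' @param embeddings n x D matrix.
#' @param labels length-n ground-truth labels (>= 2 classes).
#' @param k number of clusters (defaults to \code{nlevels(labels)}).
#' @param n_pcs principal components retained before k-means (capped at the
#'   effective rank); set to \code{NULL} to cluster the raw embeddings.
#' @param seed k-means seed.
#' @return named vector \code{c(ARI =, NMI =)}.
#' @export
cluster_metrics <- function(embeddings, labels, k = NULL, n_pcs = 10L,
                            seed = 1L) {
  labels <- as.integer(factor(labels))
  if (length(unique(labels)) < 2L) stop("need >= 2 classes")
  if (is.null(k)) k <- length(unique(labels))
  X <- as.matrix(embeddings)
  if (!is.null(n_pcs)) {
    p <- stats::prcomp(X)
    keep <- which(p$sdev > 1e-8 * p$sdev[1])
    keep <- keep[seq_len(min(length(keep), n_pcs))]
    X <- sweep(p$x[, keep, drop = FALSE], 2L, p$sdev[keep], "/")
  }
  cl <- with_seed(seed, stats::kmeans(X, centers = k, nstart = 10L,
                                      iter.max = 50L))$cluster
  c(ARI = mclust::adjustedRandIndex(cl, labels), NMI = nmi_score(cl, labels))
}

#' Classification quality of embeddings
#'
#' Two-layer perceptron (softmax cross-entropy) on a train split; macro F1
#' and macro precision on the test split.
#'
#' @param embeddings n x D matrix.
#' @param labels length-n class labels (>= 2 classes).
#' @param split train fraction.
#' @param hidden,epochs,lr perceptron settings.
#' @param seed split/init seed.
#' @return named vector \code{c(F1_macro =, precision_macro =)}.
#' @export
classify_metrics <- function(embeddings, labels, split = 0.7, hidden = 32L,
                             epochs = 200L, lr = 1e-2, seed = 1L) {
  f <- factor(labels)
  y <- as.integer(f)
  K <- nlevels(f)
  if (K < 2L) stop("need >= 2 classes")
  n <- nrow(embeddings)
  idx <- with_seed(seed, sample.int(n))
  ntr <- max(2L, floor(split * n))
  tr <- idx[seq_len(ntr)]; te <- idx[(ntr + 1L):n]
  mu <- colMeans(embeddings[tr, , drop = FALSE])
  sdv <- pmax(apply(embeddings[tr, , drop = FALSE], 2L, stats::sd), 1e-8)
  Xs <- sweep(sweep(embeddings, 2L, mu), 2L, sdv, "/")
  onehot <- matrix(0, length(tr), K)
  onehot[cbind(seq_along(tr), y[tr])] <- 1
  m <- mlp_new(ncol(Xs), hidden, K, seed = seed + 1L)
  m <- mlp_train(m, Xs[tr, , drop = FALSE], function(logits) {
    p <- ag_softmax_rows(logits)
    ag_scale(ag_sum(ag_mul(ag_log(ag_add(p, 1e-12)), onehot)), -1 / length(tr))
  }, epochs = epochs, lr = lr)
  pred <- max.col(vv(mlp_fwd(m, Xs[te, , drop = FALSE])), ties.method = "first")
  truth <- y[te]
  f1 <- numeric(K); prec <- numeric(K)
  for (k in seq_len(K)) {
    tp <- sum(pred == k & truth == k)
    fp <- sum(pred == k & truth != k)
    fn <- sum(pred != k & truth == k)
    prec[k] <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[k] <- if (prec[k] + rec > 0) 2 * prec[k] * rec / (prec[k] + rec) else 0
  }
  c(F1_macro = mean(f1), precision_macro = mean(prec))
}
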