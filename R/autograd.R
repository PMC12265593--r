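# Tape-based reverse-mode automatic differentiation on dense R arrays.
#
# A "node" is an environment holding a value (`v`), an accumulated gradient
# (`g`), and a backward closure (`bw`) that pushes gradients into its parents.
# Ops accept nodes or plain numeric arrays interchangeably; when the tape is
# off (inference) every op degrades to its plain numeric computation, so model
# code has a single forward path for training and evaluation.

.ag <- new.env(parent = emptyenv())
.ag$on <- FALSE
.ag$tape <- NULL
.ag$n <- 0L

#' @noRd
ag_is_node <- function(x) is.environment(x) && isTRUE(x$.ag_node)

#' @noRd
vv <- function(x) if (ag_is_node(x)) x$v else x

ag_tape_start <- function() {
  .ag$on <- TRUE
  .ag$tape <- vector("list", 1024L)
  .ag$n <- 0L
  invisible(NULL)
}

ag_tape_stop <- function() {
  .ag$on <- FALSE
  .ag$tape <- NULL
  .ag$n <- 0L
  invisible(NULL)
}

#' Evaluate an expression with gradient recording enabled
#' @noRd
with_tape <- function(expr) {
  ag_tape_start()
  on.exit(ag_tape_stop(), add = TRUE)
  expr
}

# Create a leaf node (parameter). Leaves are never put on the tape; their
# gradients are filled in by the backward sweep of downstream op nodes.
ag_param <- function(v) {
  e <- new.env(parent = emptyenv())
  e$.ag_node <- TRUE
  e$v <- v
  e$g <- NULL
  e$bw <- NULL
  e
}

#' @noRd
ag_record <- function(v, bw) {
  if (!.ag$on) return(v)
  e <- new.env(parent = emptyenv())
  e$.ag_node <- TRUE
  e$v <- v
  e$g <- NULL
  e$bw <- bw
  n <- .ag$n + 1L
  if (n > length(.ag$tape)) .ag$tape <- c(.ag$tape, vector("list", length(.ag$tape)))
  .ag$tape[[n]] <- e
  .ag$n <- n
  e
}

#' @noRd
ag_acc <- function(node, grad) {
  if (!ag_is_node(node)) return(invisible(NULL))
  node$g <- if (is.null(node$g)) grad else node$g + grad
  invisible(NULL)
}

# Backward sweep from a scalar loss node over the active tape.
ag_backward <- function(loss) {
  stopifnot(ag_is_node(loss), length(loss$v) == 1L)
  loss$g <- 1
  if (.ag$n < 1L) return(invisible(NULL))
  for (i in seq.int(.ag$n, 1L)) {
    nd <- .ag$tape[[i]]
    if (!is.null(nd$g) && !is.null(nd$bw)) nd$bw(nd$g)
  }
  invisible(NULL)
}

# ---- elementwise & broadcast arithmetic --------------------------------------

# add with broadcasting: equal shapes, matrix + length-ncol vector (bias over
# rows), or scalar on either side.
ag_add <- function(a, b) {
  va <- vv(a); vb <- vv(b)
  if (length(vb) == 1L || identical(dim(va), dim(vb)) ||
      (is.null(dim(va)) && is.null(dim(vb)) && length(va) == length(vb))) {
    v <- va + vb
    ag_record(v, function(g) {
      ag_acc(a, if (length(va) == 1L && length(g) > 1L) sum(g) else g)
      ag_acc(b, if (length(vb) == 1L && length(g) > 1L) sum(g) else g)
    })
  } else if (is.matrix(va) && is.null(dim(vb)) && length(vb) == ncol(va)) {
    v <- va + matrix(vb, nrow(va), ncol(va), byrow = TRUE)
    ag_record(v, function(g) {
      ag_acc(a, g)
      ag_acc(b, colSums(g))
    })
  } else stop("ag_add: incompatible shapes")
}

ag_sub <- function(a, b) {
  va <- vv(a); vb <- vv(b)
  v <- va - vb
  ag_record(v, function(g) {
    ag_acc(a, if (length(va) == 1L && length(g) > 1L) sum(g) else g)
    ag_acc(b, if (length(vb) == 1L && length(g) > 1L) -sum(g) else -g)
  })
}

# elementwise product; same shape or scalar on either side
ag_mul <- function(a, b) {
  va <- vv(a); vb <- vv(b)
  v <- va * vb
  ag_record(v, function(g) {
    da <- g * vb
    db <- g * va
    ag_acc(a, if (length(va) == 1L && length(da) > 1L) sum(da) else da)
    ag_acc(b, if (length(vb) == 1L && length(db) > 1L) sum(db) else db)
  })
}

# multiply by a plain numeric scalar constant
ag_scale <- function(a, s) {
  v <- vv(a) * s
  ag_record(v, function(g) ag_acc(a, g * s))
}

ag_matmul <- function(a, b) {
  va <- vv(a); vb <- vv(b)
  v <- va %*% vb
  ag_record(v, function(g) {
    ag_acc(a, g %*% t(vb))
    ag_acc(b, t(va) %*% g)
  })
}

ag_t <- function(a) {
  v <- t(vv(a))
  ag_record(v, function(g) ag_acc(a, t(g)))
}

# ---- nonlinearities ----------------------------------------------------------

ag_relu <- function(a) {
  va <- vv(a)
  v <- pmax(va, 0)
  ag_record(v, function(g) ag_acc(a, g * (va > 0)))
}

ag_gelu <- function(a) {
  va <- vv(a)
  ph <- stats::pnorm(va)
  v <- va * ph
  ag_record(v, function(g) ag_acc(a, g * (ph + va * stats::dnorm(va))))
}

ag_sigmoid <- function(a) {
  v <- 1 / (1 + exp(-vv(a)))
  ag_record(v, function(g) ag_acc(a, g * v * (1 - v)))
}

ag_log <- function(a) {
  va <- vv(a)
  v <- log(va)
  ag_record(v, function(g) ag_acc(a, g / va))
}

ag_tanh <- function(a) {
  v <- tanh(vv(a))
  ag_record(v, function(g) ag_acc(a, g * (1 - v * v)))
}

# ---- softmax / layer norm ----------------------------------------------------

# row-wise softmax of a matrix
ag_softmax_rows <- function(a) {
  va <- vv(a)
  m <- va - apply(va, 1L, max)
  e <- exp(m)
  v <- e / rowSums(e)
  ag_record(v, function(g) {
    dot <- rowSums(g * v)
    ag_acc(a, v * (g - dot))
  })
}

# row-wise layer normalization with affine (gamma, beta length-ncol vectors)
ag_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  vx <- vv(x); vg <- vv(gamma); vb <- vv(beta)
  mu <- rowMeans(vx)
  xc <- vx - mu
  va <- rowMeans(xc * xc)
  istd <- 1 / sqrt(va + eps)
  xhat <- xc * istd
  v <- xhat * matrix(vg, nrow(vx), ncol(vx), byrow = TRUE) +
    matrix(vb, nrow(vx), ncol(vx), byrow = TRUE)
  ag_record(v, function(g) {
    ag_acc(beta, colSums(g))
    ag_acc(gamma, colSums(g * xhat))
    dxh <- g * matrix(vg, nrow(g), ncol(g), byrow = TRUE)
    m1 <- rowMeans(dxh)
    m2 <- rowMeans(dxh * xhat)
    ag_acc(x, istd * (dxh - m1 - xhat * m2))
  })
}

# ---- reductions --------------------------------------------------------------

ag_mean <- function(a) {
  va <- vv(a)
  v <- mean(va)
  ag_record(v, function(g) ag_acc(a, 0 * va + g / length(va)))
}

ag_sum <- function(a) {
  va <- vv(a)
  v <- sum(va)
  ag_record(v, function(g) ag_acc(a, 0 * va + g))
}

# column means of a matrix, returned as 1 x ncol matrix
ag_colmeans <- function(a) {
  va <- vv(a)
  v <- matrix(colMeans(va), 1L)
  ag_record(v, function(g) {
    ag_acc(a, matrix(g, nrow(va), ncol(va), byrow = TRUE) / nrow(va))
  })
}

# row sums of a matrix, returned as n x 1 matrix
ag_rowsums <- function(a) {
  va <- vv(a)
  v <- matrix(rowSums(va), ncol = 1L)
  ag_record(v, function(g) {
    ag_acc(a, matrix(g, nrow(va), ncol(va)))
  })
}

# mean squared error between a and a constant (or node) target
ag_mse <- function(a, target) {
  d <- ag_sub(a, target)
  ag_mean(ag_mul(d, d))
}

# ---- structural ops ----------------------------------------------------------

ag_rows <- function(a, idx) {
  va <- vv(a)
  v <- va[idx, , drop = FALSE]
  ag_record(v, function(g) {
    da <- 0 * va
    if (anyDuplicated(idx)) {
      for (k in seq_along(idx)) da[idx[k], ] <- da[idx[k], ] + g[k, ]
    } else {
      da[idx, ] <- g
    }
    ag_acc(a, da)
  })
}

ag_cols <- function(a, idx) {
  va <- vv(a)
  v <- va[, idx, drop = FALSE]
  ag_record(v, function(g) {
    da <- 0 * va
    da[, idx] <- g
    ag_acc(a, da)
  })
}

ag_rbind <- function(parts) {
  vals <- lapply(parts, vv)
  v <- do.call(rbind, vals)
  nr <- vapply(vals, nrow, 1L)
  ends <- cumsum(nr)
  starts <- ends - nr + 1L
  ag_record(v, function(g) {
    for (k in seq_along(parts)) {
      ag_acc(parts[[k]], g[starts[k]:ends[k], , drop = FALSE])
    }
  })
}

ag_cbind <- function(parts) {
  vals <- lapply(parts, vv)
  v <- do.call(cbind, vals)
  nc <- vapply(vals, ncol, 1L)
  ends <- cumsum(nc)
  starts <- ends - nc + 1L
  ag_record(v, function(g) {
    for (k in seq_along(parts)) {
      ag_acc(parts[[k]], g[, starts[k]:ends[k], drop = FALSE])
    }
  })
}

ag_reshape <- function(a, dims) {
  va <- vv(a)
  stopifnot(prod(dims) == length(va))
  v <- array(va, dim = dims)
  ag_record(v, function(g) {
    od <- dim(va)
    ag_acc(a, if (is.null(od)) as.vector(g) else array(g, dim = od))
  })
}

# ---- convolutions ------------------------------------------------------------
# Layout: activations are 4-D arrays (H, W, C, B); weights are (k, k, Cin, Cout).
# Both directions are realized as k*k strided gather/scatter + matmul passes,
# which keeps every inner operation a vectorized array op.

#' @noRd
pad4 <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1] + 2L * p, d[2] + 2L * p, d[3], d[4]))
  xp[(p + 1L):(p + d[1]), (p + 1L):(p + d[2]), , ] <- x
  xp
}

#' @noRd
unpad4 <- function(xp, p, H, W) {
  if (p == 0L) return(xp)
  xp[(p + 1L):(p + H), (p + 1L):(p + W), , , drop = FALSE]
}

# gather strided offset window as ((oh*ow*B) x C) matrix, rows: position
# fastest, then batch
#' @noRd
gath4 <- function(xp, ki, kj, s, oh, ow) {
  hs <- (seq_len(oh) - 1L) * s + ki
  ws <- (seq_len(ow) - 1L) * s + kj
  sub <- xp[hs, ws, , , drop = FALSE] # (oh, ow, C, B)
  d <- dim(sub)
  m <- aperm(sub, c(1L, 2L, 4L, 3L)) # (oh, ow, B, C)
  dim(m) <- c(d[1] * d[2] * d[4], d[3])
  m
}

#' @noRd
scat4_add <- function(xp, ki, kj, s, oh, ow, m) {
  # inverse of gath4: add matrix back into strided positions
  hs <- (seq_len(oh) - 1L) * s + ki
  ws <- (seq_len(ow) - 1L) * s + kj
  C <- ncol(m)
  B <- dim(xp)[4]
  a <- array(m, c(oh, ow, B, C))
  a <- aperm(a, c(1L, 2L, 4L, 3L))
  xp[hs, ws, , ] <- xp[hs, ws, , , drop = FALSE] + a
  xp
}

# strided 2-D convolution. x: (H,W,Cin,B); w: (k,k,Cin,Cout); b: length-Cout
ag_conv2d <- function(x, w, b, stride = 1L, pad = 0L) {
  vx <- vv(x); vw <- vv(w); vb <- vv(b)
  d <- dim(vx)
  k <- dim(vw)[1]
  oh <- (d[1] + 2L * pad - k) %/% stride + 1L
  ow <- (d[2] + 2L * pad - k) %/% stride + 1L
  B <- d[4]; cout <- dim(vw)[4]
  xp <- pad4(vx, pad)
  acc <- matrix(0, oh * ow * B, cout)
  gmats <- vector("list", k * k)
  for (ki in seq_len(k)) for (kj in seq_len(k)) {
    gm <- gath4(xp, ki, kj, stride, oh, ow)
    gmats[[(ki - 1L) * k + kj]] <- gm
    acc <- acc + gm %*% matrix(vw[ki, kj, , ], dim(vw)[3], cout)
  }
  acc <- acc + matrix(vb, nrow(acc), cout, byrow = TRUE)
  v <- aperm(array(acc, c(oh, ow, B, cout)), c(1L, 2L, 4L, 3L))
  ag_record(v, function(g) {
    gm_out <- aperm(g, c(1L, 2L, 4L, 3L))
    dim(gm_out) <- c(oh * ow * B, cout)
    ag_acc(b, colSums(gm_out))
    dw <- 0 * vw
    dxp <- array(0, dim(xp))
    need_dx <- ag_is_node(x)
    for (ki in seq_len(k)) for (kj in seq_len(k)) {
      gm <- gmats[[(ki - 1L) * k + kj]]
      dw[ki, kj, , ] <- t(gm) %*% gm_out
      if (need_dx) {
        dcol <- gm_out %*% t(matrix(vw[ki, kj, , ], dim(vw)[3], cout))
        dxp <- scat4_add(dxp, ki, kj, stride, oh, ow, dcol)
      }
    }
    ag_acc(w, dw)
    if (need_dx) ag_acc(x, unpad4(dxp, pad, d[1], d[2]))
  })
}

# strided 2-D transposed convolution (the adjoint of ag_conv2d).
# x: (oh,ow,Cin,B); w: (k,k,Cin,Cout); output (H,W,Cout,B) with
# H = (oh-1)*stride - 2*pad + k
ag_convt2d <- function(x, w, b, stride = 2L, pad = 1L) {
  vx <- vv(x); vw <- vv(w); vb <- vv(b)
  d <- dim(vx)
  k <- dim(vw)[1]; cin <- dim(vw)[3]; cout <- dim(vw)[4]
  oh <- d[1]; ow <- d[2]; B <- d[4]
  H <- (oh - 1L) * stride - 2L * pad + k
  W <- (ow - 1L) * stride - 2L * pad + k
  xm <- aperm(vx, c(1L, 2L, 4L, 3L))
  dim(xm) <- c(oh * ow * B, cin)
  yp <- array(0, c(H + 2L * pad, W + 2L * pad, cout, B))
  for (ki in seq_len(k)) for (kj in seq_len(k)) {
    contrib <- xm %*% matrix(vw[ki, kj, , ], cin, cout)
    yp <- scat4_add(yp, ki, kj, stride, oh, ow, contrib)
  }
  v <- unpad4(yp, pad, H, W)
  v <- v + array(rep(vb, each = H * W), c(H, W, cout, B))
  ag_record(v, function(g) {
    gp <- pad4(g, pad)
    ag_acc(b, as.vector(apply(g, 3L, sum)))
    dw <- 0 * vw
    dxm <- matrix(0, oh * ow * B, cin)
    need_dx <- ag_is_node(x)
    for (ki in seq_len(k)) for (kj in seq_len(k)) {
      gm <- gath4(gp, ki, kj, stride, oh, ow) # (oh*ow*B) x cout
      dw[ki, kj, , ] <- t(xm) %*% gm
      if (need_dx) dxm <- dxm + gm %*% t(matrix(vw[ki, kj, , ], cin, cout))
    }
    ag_acc(w, dw)
    if (need_dx) {
      dx <- array(dxm, c(oh, ow, B, cin))
      ag_acc(x, aperm(dx, c(1L, 2L, 4L, 3L)))
    }
  })
}

# concatenate two (H,W,C,B) activations along the channel axis
ag_concat_ch <- function(a, b) {
  va <- vv(a); vb <- vv(b)
  da <- dim(va); db <- dim(vb)
  v <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  v[, , seq_len(da[3]), ] <- va
  v[, , da[3] + seq_len(db[3]), ] <- vb
  ag_record(v, function(g) {
    ag_acc(a, g[, , seq_len(da[3]), , drop = FALSE])
    ag_acc(b, g[, , da[3] + seq_len(db[3]), , drop = FALSE])
  })
}

# take batch element b of an (H,W,C,B) activation, keeping a singleton batch
ag_slice_b <- function(x, b) {
  vx <- vv(x)
  v <- vx[, , , b, drop = FALSE]
  ag_record(v, function(g) {
    dx <- 0 * vx
    dx[, , , b] <- g
    ag_acc(x, dx)
  })
}

# stack (H,W,C,1) activations along the batch axis
ag_stack_b <- function(parts) {
  vals <- lapply(parts, vv)
  d <- dim(vals[[1]])
  v <- array(0, c(d[1], d[2], d[3], length(vals)))
  for (b in seq_along(vals)) v[, , , b] <- vals[[b]]
  ag_record(v, function(g) {
    for (b in seq_along(parts)) {
      ag_acc(parts[[b]], g[, , , b, drop = FALSE])
    }
  })
}

# (H,W,C,1) feature map -> (H*W) x C token matrix, pixels in row-major order
# (column fastest within a row)
ag_tokens_from_map <- function(x) {
  vx <- vv(x)
  d <- dim(vx)
  v <- matrix(aperm(array(vx, d[1:3]), c(2L, 1L, 3L)), d[1] * d[2], d[3])
  ag_record(v, function(g) {
    a <- aperm(array(g, c(d[2], d[1], d[3])), c(2L, 1L, 3L))
    dim(a) <- c(d[1], d[2], d[3], 1L)
    ag_acc(x, a)
  })
}

# inverse of ag_tokens_from_map
ag_map_from_tokens <- function(tok, H, W) {
  vt <- vv(tok)
  C <- ncol(vt)
  v <- aperm(array(vt, c(W, H, C)), c(2L, 1L, 3L))
  dim(v) <- c(H, W, C, 1L)
  ag_record(v, function(g) {
    m <- matrix(aperm(array(g, c(H, W, C)), c(2L, 1L, 3L)), H * W, C)
    ag_acc(tok, m)
  })
}

# add a (C x B) matrix to an (H,W,C,B) activation, broadcast over H and W
ag_add_chmat <- function(x, m) {
  vx <- vv(x); vm <- vv(m)
  d <- dim(vx)
  v <- vx + aperm(array(vm, c(d[3], d[4], d[1], d[2])), c(3L, 4L, 1L, 2L))
  ag_record(v, function(g) {
    ag_acc(x, g)
    ag_acc(m, apply(g, c(3L, 4L), sum))
  })
}

# ---- optimizer ---------------------------------------------------------------

#' AdamW optimizer over a flat list of parameter nodes
#' @noRd
opt_adamw <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  st <- new.env(parent = emptyenv())
  st$params <- params
  st$lr <- lr; st$b1 <- beta1; st$b2 <- beta2; st$eps <- eps; st$wd <- weight_decay
  st$t <- 0L
  st$m <- lapply(params, function(p) 0 * p$v)
  st$u <- lapply(params, function(p) 0 * p$v)
  st
}

#' @noRd
opt_step <- function(opt) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$b1^opt$t
  bc2 <- 1 - opt$b2^opt$t
  for (i in seq_along(opt$params)) {
    p <- opt$params[[i]]
    if (is.null(p$g)) next
    opt$m[[i]] <- opt$b1 * opt$m[[i]] + (1 - opt$b1) * p$g
    opt$u[[i]] <- opt$b2 * opt$u[[i]] + (1 - opt$b2) * p$g * p$g
    step <- (opt$m[[i]] / bc1) / (sqrt(opt$u[[i]] / bc2) + opt$eps)
    p$v <- p$v - opt$lr * (step + opt$wd * p$v)
  }
  invisible(NULL)
}

#' @noRd
zero_grads <- function(params) {
  for (p in params) p$g <- NULL
  invisible(NULL)
}

# collect all parameter nodes from a nested list structure
#' @noRd
collect_params <- function(x) {
  if (ag_is_node(x)) return(list(x))
  if (is.list(x)) return(do.call(c, lapply(x, collect_params)))
  list()
}

# run `expr` under a temporary RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}
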