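# The autodiff engine under the model code is validated against central
# finite differences; everything downstream (encoders, fusion, objectives,
# diffusion) relies on these gradients.

num_grad <- function(fn, x, eps = 1e-5) {
  g <- 0 * x
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (fn(xp) - fn(xm)) / (2 * eps)
  }
  g
}

ag <- asNamespace("stweave")

test_that("composite matmul/layernorm/softmax gradients match finite differences", {
  set.seed(1)
  A0 <- matrix(rnorm(12), 3, 4)
  B0 <- matrix(rnorm(8), 4, 2)
  gam <- rnorm(2); bet <- rnorm(2)
  Tg <- matrix(rnorm(6), 3, 2)
  ref <- function(av) {
    A <- matrix(av, 3, 4)
    h <- pmax(A %*% B0, 0)
    mu <- rowMeans(h); xc <- h - mu
    xhat <- xc / sqrt(rowMeans(xc^2) + 1e-5)
    y <- xhat * matrix(gam, 3, 2, byrow = TRUE) + matrix(bet, 3, 2, byrow = TRUE)
    sm <- exp(y - apply(y, 1, max)); sm <- sm / rowSums(sm)
    mean((sm - Tg)^2)
  }
  An <- ag$ag_param(A0)
  ag$with_tape({
    l <- ag$ag_mse(ag$ag_softmax_rows(
      ag$ag_layernorm(ag$ag_relu(ag$ag_matmul(An, B0)),
                      ag$ag_param(gam), ag$ag_param(bet))), Tg)
    ag$ag_backward(l)
    expect_equal(ag$vv(l), ref(as.vector(A0)), tolerance = 1e-12)
  })
  expect_lt(max(abs(as.vector(An$g) - num_grad(ref, as.vector(A0)))), 1e-7)
})

test_that("conv2d and transposed conv gradients match finite differences", {
  set.seed(2)
  x0 <- array(rnorm(6 * 6 * 2 * 2), c(6, 6, 2, 2))
  w0 <- array(rnorm(3 * 3 * 2 * 3), c(3, 3, 2, 3)) * 0.3
  b0 <- rnorm(3) * 0.1
  xn <- ag$ag_param(x0); wn <- ag$ag_param(w0)
  ag$with_tape({
    y <- ag$ag_conv2d(xn, wn, ag$ag_param(b0), stride = 2L, pad = 1L)
    expect_identical(dim(ag$vv(y)), c(3L, 3L, 3L, 2L))
    l <- ag$ag_mean(ag$ag_mul(y, y))
    ag$ag_backward(l)
  })
  ref_x <- function(xv) {
    y <- ag$ag_conv2d(array(xv, dim(x0)), w0, b0, 2L, 1L)
    mean(y^2)
  }
  ref_w <- function(wv) {
    y <- ag$ag_conv2d(x0, array(wv, dim(w0)), b0, 2L, 1L)
    mean(y^2)
  }
  expect_lt(max(abs(as.vector(xn$g) - num_grad(ref_x, as.vector(x0)))), 1e-7)
  expect_lt(max(abs(as.vector(wn$g) - num_grad(ref_w, as.vector(w0)))), 1e-7)

  x1 <- array(rnorm(4 * 4 * 3 * 2), c(4, 4, 3, 2))
  w1 <- array(rnorm(4 * 4 * 3 * 2), c(4, 4, 3, 2)) * 0.3
  b1 <- rnorm(2) * 0.1
  xt <- ag$ag_param(x1); wt <- ag$ag_param(w1)
  ag$with_tape({
    y <- ag$ag_convt2d(xt, wt, ag$ag_param(b1), stride = 2L, pad = 1L)
    expect_identical(dim(ag$vv(y)), c(8L, 8L, 2L, 2L))
    l <- ag$ag_mean(ag$ag_mul(y, y))
    ag$ag_backward(l)
  })
  rt_x <- function(xv) mean(ag$ag_convt2d(array(xv, dim(x1)), w1, b1, 2L, 1L)^2)
  rt_w <- function(wv) mean(ag$ag_convt2d(x1, array(wv, dim(w1)), b1, 2L, 1L)^2)
  expect_lt(max(abs(as.vector(xt$g) - num_grad(rt_x, as.vector(x1)))), 1e-7)
  expect_lt(max(abs(as.vector(wt$g) - num_grad(rt_w, as.vector(w1)))), 1e-7)
})

test_that("structural ops (row gather with duplicates, batch slice/stack, token reshape) are exact adjoints", {
  set.seed(3)
  C0 <- matrix(rnorm(20), 5, 4)
  cn <- ag$ag_param(C0)
  ref <- function(cv) {
    C <- matrix(cv, 5, 4)
    R <- C[c(1, 3, 3), , drop = FALSE]
    mean(R %*% t(R))
  }
  ag$with_tape({
    R <- ag$ag_rows(cn, c(1, 3, 3))
    l <- ag$ag_mean(ag$ag_matmul(R, ag$ag_t(R)))
    ag$ag_backward(l)
  })
  expect_lt(max(abs(as.vector(cn$g) - num_grad(ref, as.vector(C0)))), 1e-7)

  # tokens_from_map / map_from_tokens round trip and row-major order
  x <- array(seq_len(2 * 3 * 2), c(2, 3, 2, 1))
  tok <- ag$vv(ag$ag_tokens_from_map(x))
  expect_identical(dim(tok), c(6L, 2L))
  expect_equal(tok[1, 1], x[1, 1, 1, 1]) # first row, first col
  expect_equal(tok[2, 1], x[1, 2, 1, 1]) # row-major: next column
  back <- ag$vv(ag$ag_map_from_tokens(tok, 2L, 3L))
  expect_equal(array(back, dim(x)), x)

  xb <- array(rnorm(2 * 2 * 2 * 3), c(2, 2, 2, 3))
  parts <- lapply(1:3, function(b) ag$vv(ag$ag_slice_b(xb, b)))
  expect_equal(ag$vv(ag$ag_stack_b(parts)), xb)
})

test_that("AdamW reduces a convex objective and leaves grad-free parameters untouched", {
  set.seed(4)
  w <- ag$ag_param(matrix(rnorm(4), 2, 2))
  frozen <- ag$ag_param(matrix(1, 2, 2))
  target <- matrix(c(1, 2, 3, 4), 2, 2)
  opt <- ag$opt_adamw(list(w, frozen), lr = 0.05)
  l0 <- NULL
  for (i in 1:100) {
    ag$zero_grads(list(w, frozen))
    ag$with_tape({
      l <- ag$ag_mse(w, target)
      if (is.null(l0)) l0 <- ag$vv(l)
      ag$ag_backward(l)
    })
    ag$opt_step(opt)
  }
  ag$with_tape({
    expect_lt(ag$vv(ag$ag_mse(w, target)), 0.01 * l0)
  })
  expect_equal(frozen$v, matrix(1, 2, 2))
})
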