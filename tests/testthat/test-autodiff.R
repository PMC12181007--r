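# The reverse-mode engine is the foundation of every encoder; each primitive's
# backward pass is checked against central finite differences.

ssum <- function(x) {
  # reduce any node to a scalar via sum, staying on the tape
  ones_r <- matrix(1, 1, nrow(ddifuse:::ad_val(x)))
  ones_c <- matrix(1, ncol(ddifuse:::ad_val(x)), 1)
  ddifuse:::ad_matmul(ddifuse:::ad_matmul(ones_r, x), ones_c)
}

test_that("elementwise and matmul primitives backpropagate correctly", {
  set.seed(11)
  ps <- list(a = matrix(rnorm(12), 3, 4), b = matrix(rnorm(12), 4, 3),
             c = matrix(rnorm(9), 3, 3), bias = matrix(rnorm(3), 1, 3))
  expect_grad_match(function(n) {
    x <- ddifuse:::ad_matmul(n$a, n$b)
    x <- ddifuse:::ad_add(x, n$bias)
    x <- ddifuse:::ad_mul(ddifuse:::ad_tanh(x), ddifuse:::ad_sigmoid(n$c))
    x <- ddifuse:::ad_sub(x, ddifuse:::ad_relu(n$c))
    x <- ddifuse:::ad_div(x, ddifuse:::ad_add(ddifuse:::ad_exp(n$c), 2))
    ssum(x)
  }, ps, tol = 1e-6)
})

test_that("gather, segment sum and rowscale backpropagate correctly", {
  set.seed(12)
  ps <- list(tab = matrix(rnorm(20), 5, 4), w = matrix(rnorm(6), 6, 1))
  idx <- c(2L, 2L, 5L, 1L, 3L, 2L)
  seg <- c(1L, 1L, 1L, 2L, 2L, 2L)
  expect_grad_match(function(n) {
    x <- ddifuse:::ad_gather(n$tab, idx)
    x <- ddifuse:::ad_rowscale(x, n$w)
    ssum(ddifuse:::ad_tanh(ddifuse:::ad_segment_sum(x, seg, 3L)))
  }, ps, tol = 1e-6)
})

test_that("softmax, layernorm, concat and column slice backpropagate", {
  set.seed(13)
  ps <- list(a = matrix(rnorm(12), 4, 3), g = matrix(rnorm(3) + 1, 1, 3),
             b = matrix(rnorm(3), 1, 3))
  expect_grad_match(function(n) {
    s <- ddifuse:::ad_softmax_rows(n$a)
    l <- ddifuse:::ad_layernorm(n$a, n$g, n$b)
    x <- ddifuse:::ad_concat_cols(s, l)
    ssum(ddifuse:::ad_mul(ddifuse:::ad_col(x, 2L), ddifuse:::ad_col(x, 5L)))
  }, ps, tol = 1e-5)
})

test_that("binary cross-entropy node matches its closed form and gradient", {
  p <- matrix(c(0.9, 0.1, 0.5, 0.7), ncol = 1)
  y <- c(1, 0, 1, 0)
  tape <- ddifuse:::ad_tape()
  pn <- ddifuse:::ad_leaf(tape, p)
  loss <- ddifuse:::ad_bce(pn, y)
  expect_equal(ddifuse:::ad_val(loss),
               -mean(y * log(p) + (1 - y) * log(1 - p)), tolerance = 1e-12)
  expect_grad_match(function(n) ddifuse:::ad_bce(n$p, y),
                    list(p = p), tol = 1e-6)
})

test_that("fused multi-head attention gradients match finite differences", {
  set.seed(14)
  n1 <- 4L; n2 <- 3L
  N <- n1 + n2
  d <- 8L
  seg <- rep(1:2, c(n1, n2))
  ps <- list(q = matrix(rnorm(N * d), N, d), k = matrix(rnorm(N * d), N, d),
             v = matrix(rnorm(N * d), N, d),
             bias = matrix(rnorm((n1^2 + n2^2) * 2) * 0.3, n1^2 + n2^2, 2))
  expect_grad_match(function(n) {
    o <- ddifuse:::ad_attention(n$q, n$k, n$v, nheads = 2L, seg = seg,
                                bias = n$bias)
    ssum(ddifuse:::ad_tanh(o))
  }, ps, tol = 1e-4)
})

test_that("attention respects key masking and ProbSparse mean fallback", {
  set.seed(15)
  N <- 5L; d <- 4L
  q <- matrix(rnorm(N * d), N, d); k <- matrix(rnorm(N * d), N, d)
  v <- matrix(rnorm(N * d), N, d)
  seg <- rep(1L, N)
  # masked keys contribute nothing: perturbing a masked key's value row is inert
  km <- c(1, 1, 1, 0, 0)
  o1 <- ddifuse:::ad_attention(q, k, v, 1L, seg, keymask = km)
  v2 <- v; v2[4, ] <- 99
  o2 <- ddifuse:::ad_attention(q, k, v2, 1L, seg, keymask = km)
  expect_equal(o1, o2)
  # with query budget >= n, ProbSparse equals full attention
  full <- ddifuse:::ad_attention(q, k, v, 1L, seg)
  ps_full <- ddifuse:::ad_attention(q, k, v, 1L, seg, psu = 5L)
  expect_equal(full, ps_full)
  # with budget u < n, exactly n - u query rows equal the value mean
  ps2 <- ddifuse:::ad_attention(q, k, v, 1L, seg, psu = 2L)
  vbar <- colMeans(v)
  is_mean <- apply(ps2, 1L, function(r) max(abs(r - vbar)) < 1e-12)
  expect_equal(sum(is_mean), 3L)
  # ProbSparse gradients still match finite differences
  expect_grad_match(function(n) {
    o <- ddifuse:::ad_attention(n$q, n$k, n$v, 1L, seg, psu = 2L)
    ssum(ddifuse:::ad_tanh(o))
  }, list(q = q, k = k, v = v), tol = 1e-4)
})

test_that("Adam takes a descent step on a quadratic", {
  params <- list(w = matrix(c(3, -2), 1, 2))
  st <- ddifuse:::adam_init(params)
  for (i in 1:200) {
    g <- list(w = 2 * params$w)
    up <- ddifuse:::adam_step(params, g, st, lr = 0.05)
    params <- up$params; st <- up$state
  }
  expect_lt(sum(params$w^2), 0.5)
})

test_that("fused transformer block matches finite-difference gradients", {
  set.seed(16)
  d <- 8L; n1 <- 5L; n2 <- 3L
  N <- n1 + n2
  seg <- rep(1:2, c(n1, n2))
  mk <- function(a, b) matrix(rnorm(a * b, sd = 0.4), a, b)
  ps <- list(x = mk(N, d),
             b_ln1_g = matrix(1, 1, d) + mk(1, d) * 0.1, b_ln1_b = mk(1, d),
             b_wq = mk(d, d), b_bq = mk(1, d), b_wk = mk(d, d),
             b_bk = mk(1, d), b_wv = mk(d, d), b_bv = mk(1, d),
             b_wo = mk(d, d), b_bo = mk(1, d),
             b_ln2_g = matrix(1, 1, d) + mk(1, d) * 0.1, b_ln2_b = mk(1, d),
             b_ff1_w = mk(d, 2L * d), b_ff1_b = mk(1, 2L * d),
             b_ff2_w = mk(2L * d, d), b_ff2_b = mk(1, d),
             bias = mk(n1^2 + n2^2, 2L) * 0.3)
  expect_grad_match(function(n) {
    o <- ddifuse:::ad_block(n$x, n, "b", nheads = 2L, seg = seg,
                            bias = n$bias, psu = c(3L, 3L))
    ones_r <- matrix(1, 1, N); ones_c <- matrix(1, d, 1)
    ddifuse:::ad_matmul(ddifuse:::ad_matmul(ones_r, ddifuse:::ad_tanh(o)),
                        ones_c)
  }, ps, tol = 5e-4)
})

test_that("fused block with key masking ignores padded keys", {
  set.seed(17)
  d <- 4L; N <- 6L
  seg <- rep(1L, N)
  km <- c(1, 1, 1, 1, 0, 0)
  mk <- function(a, b) matrix(rnorm(a * b, sd = 0.4), a, b)
  P <- list(b_ln1_g = matrix(1, 1, d), b_ln1_b = mk(1, d),
            b_wq = mk(d, d), b_bq = mk(1, d), b_wk = mk(d, d),
            b_bk = mk(1, d), b_wv = mk(d, d), b_bv = mk(1, d),
            b_wo = mk(d, d), b_bo = mk(1, d),
            b_ln2_g = matrix(1, 1, d), b_ln2_b = mk(1, d),
            b_ff1_w = mk(d, d), b_ff1_b = mk(1, d),
            b_ff2_w = mk(d, d), b_ff2_b = mk(1, d))
  x <- mk(N, d)
  o1 <- ddifuse:::ad_block(x, P, "b", 1L, seg, keymask = km)
  x2 <- x; x2[5, ] <- x2[5, ] + 10  # masked row perturbed
  o2 <- ddifuse:::ad_block(x2, P, "b", 1L, seg, keymask = km)
  expect_equal(o1[1:4, ], o2[1:4, ], tolerance = 1e-12)
})
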