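# Minimal reverse-mode automatic differentiation on dense matrices.
#
# A tape records nodes in creation order; ad_backward() walks it in reverse.
# Nodes are environments so gradient accumulation mutates in place. Plain
# matrices/vectors passed to an op are treated as constants (no gradient).
# Every op accepts a mix of nodes and constants; if no argument is a node the
# op returns a plain matrix, so the same forward code serves inference.

ad_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 1024L)
  tp$n <- 0L
  tp
}

ad_is_node <- function(x) is.environment(x)

ad_val <- function(x) if (is.environment(x)) x$value else x

ad_register <- function(tape, nd) {
  n <- tape$n + 1L
  if (n > length(tape$nodes)) length(tape$nodes) <- 2L * length(tape$nodes)
  tape$nodes[[n]] <- nd
  tape$n <- n
  nd
}

#' @noRd
ad_leaf <- function(tape, value) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- NULL
  nd$backfn <- NULL
  nd$tape <- tape
  ad_register(tape, nd)
}

# Find the tape among arguments; NULL means all-constant.
ad_tape_of <- function(...) {
  for (x in list(...)) if (is.environment(x)) return(x$tape)
  NULL
}

ad_make <- function(value, parents, backfn) {
  tape <- NULL
  for (p in parents) if (is.environment(p)) { tape <- p$tape; break }
  if (is.null(tape)) return(value)
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backfn <- backfn
  nd$tape <- tape
  ad_register(tape, nd)
}

#' @noRd
ad_backward <- function(loss) {
  stopifnot(is.environment(loss))
  tape <- loss$tape
  loss$grad <- 1
  for (i in rev(seq_len(tape$n))) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$backfn)) next
    gs <- nd$backfn(nd$grad)
    ps <- nd$parents
    for (j in seq_along(ps)) {
      p <- ps[[j]]
      g <- gs[[j]]
      if (is.environment(p) && !is.null(g)) {
        p$grad <- if (is.null(p$grad)) g else p$grad + g
      }
    }
  }
  invisible(loss)
}

## ---- primitive ops ---------------------------------------------------------

ad_matmul <- function(a, b) {
  av <- ad_val(a); bv <- ad_val(b)
  an <- is.environment(a); bn <- is.environment(b)
  ad_make(av %*% bv, list(a, b), function(g) {
    list(if (an) tcrossprod(g, bv) else NULL,
         if (bn) crossprod(av, g) else NULL)
  })
}

# Fused affine map x %*% w + b (b a 1-row bias, broadcast over rows).
ad_linear <- function(x, w, b) {
  xv <- ad_val(x); wv <- ad_val(w); bv <- ad_val(b)
  v <- xv %*% wv
  v <- v + rep(as.numeric(bv), each = nrow(v))
  xn <- is.environment(x); wn <- is.environment(w); bn <- is.environment(b)
  ad_make(v, list(x, w, b), function(g) {
    list(if (xn) tcrossprod(g, wv) else NULL,
         if (wn) crossprod(xv, g) else NULL,
         if (bn) matrix(colSums(g), 1L) else NULL)
  })
}

# Fused two-input affine map x1 %*% w1 + x2 %*% w2 + b (GRU gate shape).
ad_linear2 <- function(x1, w1, x2, w2, b) {
  x1v <- ad_val(x1); w1v <- ad_val(w1)
  x2v <- ad_val(x2); w2v <- ad_val(w2)
  bv <- ad_val(b)
  v <- x1v %*% w1v + x2v %*% w2v
  v <- v + rep(as.numeric(bv), each = nrow(v))
  nn <- c(is.environment(x1), is.environment(w1), is.environment(x2),
          is.environment(w2), is.environment(b))
  ad_make(v, list(x1, w1, x2, w2, b), function(g) {
    list(if (nn[1L]) tcrossprod(g, w1v) else NULL,
         if (nn[2L]) crossprod(x1v, g) else NULL,
         if (nn[3L]) tcrossprod(g, w2v) else NULL,
         if (nn[4L]) crossprod(x2v, g) else NULL,
         if (nn[5L]) matrix(colSums(g), 1L) else NULL)
  })
}

# Elementwise add; `b` may be a 1-row matrix broadcast over rows of `a`.
ad_add <- function(a, b) {
  av <- ad_val(a); bv <- ad_val(b)
  bcast <- is.matrix(bv) && nrow(bv) == 1L && nrow(av) > 1L
  v <- if (bcast) av + rep(as.numeric(bv), each = nrow(av)) else av + bv
  ad_make(v, list(a, b), function(g) {
    gb <- if (bcast) matrix(colSums(g), 1L) else g
    list(g, gb)
  })
}

ad_sub <- function(a, b) {
  av <- ad_val(a); bv <- ad_val(b)
  ad_make(av - bv, list(a, b), function(g) list(g, -g))
}

# Elementwise product (same shape), or one side a scalar constant.
ad_mul <- function(a, b) {
  av <- ad_val(a); bv <- ad_val(b)
  ad_make(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

ad_div <- function(a, b) {
  av <- ad_val(a); bv <- ad_val(b)
  v <- av / bv
  ad_make(v, list(a, b), function(g) list(g / bv, -g * v / bv))
}

ad_tanh <- function(a) {
  v <- tanh(ad_val(a))
  ad_make(v, list(a), function(g) list(g * (1 - v * v)))
}

ad_sigmoid <- function(a) {
  v <- 1 / (1 + exp(-ad_val(a)))
  ad_make(v, list(a), function(g) list(g * v * (1 - v)))
}

ad_relu <- function(a) {
  av <- ad_val(a)
  v <- pmax(av, 0)
  ad_make(v, list(a), function(g) list(g * (av > 0)))
}

ad_exp <- function(a) {
  v <- exp(ad_val(a))
  ad_make(v, list(a), function(g) list(g * v))
}

# Row gather: out[i, ] = p[idx[i], ]. Backward scatter-adds.
ad_gather <- function(p, idx) {
  pv <- ad_val(p)
  idx <- as.integer(idx)
  v <- pv[idx, , drop = FALSE]
  ad_make(v, list(p), function(g) {
    gp <- matrix(0, nrow(pv), ncol(pv))
    rs <- rowsum(g, idx)
    gp[as.integer(rownames(rs)), ] <- rs
    list(gp)
  })
}

# Segment sum: out[s, ] = sum over rows i with ids[i] == s; nseg rows out.
ad_segment_sum <- function(x, ids, nseg) {
  xv <- ad_val(x)
  ids <- as.integer(ids)
  v <- matrix(0, nseg, ncol(xv))
  rs <- rowsum(xv, ids)
  v[as.integer(rownames(rs)), ] <- rs
  ad_make(v, list(x), function(g) list(g[ids, , drop = FALSE]))
}

# Scale row i of x by scalar w[i]; w is a length-n node (n x 1) or constant.
ad_rowscale <- function(x, w) {
  xv <- ad_val(x); wv <- as.numeric(ad_val(w))
  v <- xv * wv
  ad_make(v, list(x, w), function(g) {
    list(g * wv, matrix(rowSums(g * xv), ncol = 1L))
  })
}

ad_concat_cols <- function(a, b) {
  av <- ad_val(a); bv <- ad_val(b)
  na <- ncol(av)
  ad_make(cbind(av, bv), list(a, b), function(g) {
    list(g[, seq_len(na), drop = FALSE], g[, -seq_len(na), drop = FALSE])
  })
}

ad_col <- function(a, j) {
  av <- ad_val(a)
  ad_make(av[, j, drop = FALSE], list(a), function(g) {
    ga <- matrix(0, nrow(av), ncol(av))
    ga[, j] <- g
    list(ga)
  })
}

# Row-wise softmax with optional additive mask constant (-Inf for excluded).
ad_softmax_rows <- function(a, mask = NULL) {
  av <- ad_val(a)
  if (!is.null(mask)) av <- av + mask
  m <- apply(av, 1L, max)
  e <- exp(av - m)
  v <- e / rowSums(e)
  ad_make(v, list(a), function(g) {
    list(v * (g - rowSums(g * v)))
  })
}

# Row-wise layer normalisation with learned gain/bias (1 x d each).
ad_layernorm <- function(x, gamma, beta) {
  xv <- ad_val(x); gv <- ad_val(gamma); bv <- ad_val(beta)
  fw <- ln_forward_cpp(xv, gv, bv)
  ad_make(fw$y, list(x, gamma, beta), function(g) {
    bw <- ln_backward_cpp(g, fw$xh, fw$istd, gv)
    list(bw$gx, matrix(bw$ggain, 1L), matrix(bw$gbias, 1L))
  })
}

# Sum of embedding table rows over the feature slots of each item:
# out[i, ] = sum_j table[idx[i, j], ].
ad_emb_sum <- function(table, idx) {
  tv <- ad_val(table)
  v <- emb_sum_forward_cpp(tv, idx)
  ad_make(v, list(table), function(g) {
    list(emb_sum_backward_cpp(g, idx, nrow(tv)))
  })
}

# Inverted dropout: scales kept units by 1/(1-rate). No-op when rate == 0.
ad_dropout <- function(x, rate) {
  if (rate <= 0) return(x)
  xv <- ad_val(x)
  keep <- (matrix(stats::runif(length(xv)), nrow(xv)) >= rate) / (1 - rate)
  ad_make(xv * keep, list(x), function(g) list(g * keep))
}

# Mean binary cross-entropy of probabilities against 0/1 labels, with the
# probabilities clamped to [eps, 1-eps] before the logs.
ad_bce <- function(p, y, eps = 1e-7) {
  pv <- as.numeric(ad_val(p))
  y <- as.numeric(y)
  n <- length(y)
  pc <- pmin(pmax(pv, eps), 1 - eps)
  v <- -mean(y * log(pc) + (1 - y) * log(1 - pc))
  inner <- pv > eps & pv < 1 - eps
  ad_make(v, list(p), function(g) {
    gp <- ifelse(inner, (-y / pc + (1 - y) / (1 - pc)) / n, 0)
    list(matrix(g * gp, ncol = 1L))
  })
}

## ---- fused multi-head attention -------------------------------------------

# Segmented multi-head scaled-dot-product attention (C++ kernels).
#   q, k, v : N x d (d divisible by nheads); rows MUST be segment-contiguous
#   seg     : integer segment id per row (attention never crosses segments)
#   keymask : optional 0/1 vector; rows with 0 are excluded as keys
#   bias    : optional (sum of n_s^2) x nheads additive logit bias, stored
#             per segment in query-major order
#   psu     : optional integer per segment: ProbSparse query budget u. Queries
#             outside the top-u by the sparsity measure (max minus mean logit)
#             fall back to the mean of the segment's (unmasked) value rows.
ad_attention <- function(q, k, v, nheads, seg, keymask = NULL, bias = NULL,
                         psu = NULL) {
  qv <- ad_val(q); kv <- ad_val(k); vv <- ad_val(v)
  bv <- if (is.null(bias)) NULL else ad_val(bias)
  ns <- tabulate(as.integer(seg))
  fw <- attention_forward_cpp(
    qv, kv, vv, as.integer(nheads), as.integer(ns),
    if (is.null(keymask)) numeric(0) else as.numeric(keymask),
    if (is.null(bv)) matrix(0, 0, 0) else bv,
    if (is.null(psu)) integer(0) else as.integer(psu)
  )
  ad_make(fw$O, list(q, k, v, bias), function(g) {
    bw <- attention_backward_cpp(g, qv, kv, vv, as.integer(nheads),
                                 as.integer(ns), fw$A, fw$sel, !is.null(bv))
    list(bw$gq, bw$gk, bw$gv, if (is.null(bv)) NULL else bw$gb)
  })
}

# Fused pre-LN transformer block (C++ kernels): LN -> multi-head attention
# -> projection -> residual -> LN -> feed-forward -> residual. Parameters are
# looked up in P by `prefix`; see attn_layer_params() for the slot names.
ad_block <- function(x, P, prefix, nheads, seg, keymask = NULL, bias = NULL,
                     psu = NULL, dropout = 0) {
  nms <- c("ln1_g", "ln1_b", "wq", "bq", "wk", "bk", "wv", "bv", "wo", "bo",
           "ln2_g", "ln2_b", "ff1_w", "ff1_b", "ff2_w", "ff2_b")
  pars <- lapply(nms, function(nm) P[[paste0(prefix, "_", nm)]])
  vals <- lapply(pars, ad_val)
  ns <- tabulate(as.integer(seg))
  fw <- block_forward_cpp(
    ad_val(x), vals[[1L]], vals[[2L]], vals[[3L]], vals[[4L]], vals[[5L]],
    vals[[6L]], vals[[7L]], vals[[8L]], vals[[9L]], vals[[10L]], vals[[11L]],
    vals[[12L]], vals[[13L]], vals[[14L]], vals[[15L]], vals[[16L]],
    as.integer(nheads), as.integer(ns),
    if (is.null(keymask)) numeric(0) else as.numeric(keymask),
    if (is.null(bias)) matrix(0, 0, 0) else ad_val(bias),
    if (is.null(psu)) integer(0) else as.integer(psu),
    dropout
  )
  ad_make(fw$out, c(list(x), pars, list(bias)), function(g) {
    bw <- block_backward_cpp(g, fw$cache, vals[[3L]], vals[[5L]], vals[[7L]],
                             vals[[9L]], vals[[1L]], vals[[11L]],
                             vals[[13L]], vals[[15L]], as.integer(nheads),
                             as.integer(ns), !is.null(bias), dropout)
    c(list(bw$gx),
      lapply(c("gln1_g", "gln1_b", "gwq", "gbq", "gwk", "gbk", "gwv", "gbv",
               "gwo", "gbo", "gln2_g", "gln2_b", "gff1_w", "gff1_b",
               "gff2_w", "gff2_b"),
             function(nm) {
               gr <- bw[[nm]]
               if (is.matrix(gr)) gr else matrix(gr, 1L)
             }),
      list(if (is.null(bias)) NULL else bw$gb))
  })
}

## ---- parameter handling ----------------------------------------------------

# Wrap a named list of parameter matrices as leaves on a fresh tape.
ad_params_to_nodes <- function(tape, params) {
  lapply(params, function(p) ad_leaf(tape, p))
}

# Parameters never touched in the forward pass keep a NULL gradient; the
# Adam kernel skips them (their moments are zero, so the update is zero).
ad_collect_grads <- function(nodes) {
  lapply(nodes, function(nd) nd$grad)
}

# Adam optimiser over a named list of parameter matrices. The moment vectors
# are kept flattened so the update is a handful of vectorized passes.
adam_init <- function(params) {
  n <- sum(vapply(params, length, integer(1)))
  list(m = numeric(n), v = numeric(n), t = 0L)
}

# NOTE: updates `params` matrices and the moment vectors IN PLACE (the C++
# kernel writes through). Callers own a private copy of the parameter list.
adam_step <- function(params, grads, state, lr = 1e-4, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  adam_update_cpp(params, grads, state$m, state$v, lr, state$t, beta1,
                  beta2, eps)
  list(params = params, state = state)
}

# Deep copy of a parameter list (needed around the in-place Adam update).
copy_params <- function(params) lapply(params, function(p) p + 0)
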