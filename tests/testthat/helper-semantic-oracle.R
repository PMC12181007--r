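# Plain-R reimplementation of the semantic channel with FULL softmax
# attention (no ProbSparse, no C++ kernels): the oracle the ProbSparse
# encoder must reproduce whenever the query budget covers all atoms.

semantic_forward_oracle <- function(P, prep, cfg) {
  n <- prep$n
  H <- cfg$semantic$n_heads
  d <- cfg$semantic$hidden
  dh <- d / H
  x <- ddifuse:::emb_sum_forward_cpp(P$s_atom, prep$atom_idx9) +
    P$s_in[prep$deg_idx, , drop = FALSE] +
    P$s_out[prep$deg_idx, , drop = FALSE]
  bias <- prep$C %*% P$s_edgeb + P$s_spatb[prep$sp_idx, , drop = FALSE]
  ln <- function(z, g, b) {
    mu <- rowMeans(z)
    va <- rowMeans((z - mu)^2)
    xh <- (z - mu) / sqrt(va + 1e-5)
    sweep(sweep(xh, 2, as.numeric(g), "*"), 2, as.numeric(b), "+")
  }
  lin <- function(z, w, b) z %*% w + rep(as.numeric(b), each = nrow(z))
  for (l in seq_len(cfg$semantic$n_blocks)) {
    p <- function(nm) P[[paste0("s", l, "_", nm)]]
    h1 <- ln(x, p("ln1_g"), p("ln1_b"))
    q <- lin(h1, p("wq"), p("bq"))
    k <- lin(h1, p("wk"), p("bk"))
    v <- lin(h1, p("wv"), p("bv"))
    O <- matrix(0, n, d)
    for (h in seq_len(H)) {
      cols <- (h - 1) * dh + seq_len(dh)
      S <- tcrossprod(q[, cols, drop = FALSE], k[, cols, drop = FALSE]) /
        sqrt(dh)
      S <- S + t(matrix(bias[, h], n, n))  # query-major bias
      A <- exp(S - apply(S, 1, max))
      A <- A / rowSums(A)
      O[, cols] <- A %*% v[, cols, drop = FALSE]
    }
    x <- x + lin(O, p("wo"), p("bo"))
    h2 <- ln(x, p("ln2_g"), p("ln2_b"))
    x <- x + lin(pmax(lin(h2, p("ff1_w"), p("ff1_b")), 0), p("ff2_w"),
                 p("ff2_b"))
  }
  x <- ln(x, P$s_lnf_g, P$s_lnf_b)
  colMeans(x) %*% P$s_proj_w + as.numeric(P$s_proj_b)
}
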