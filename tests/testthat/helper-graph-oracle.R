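# Plain-R reimplementation of the graph channel's forward pass, written
# directly from the layer definitions (no autodiff, no C++). Serves as the
# independent oracle for the encoder tests.

graph_forward_oracle <- function(P, prep, cfg, return_states = FALSE) {
  n <- prep$n
  h0 <- ddifuse:::emb_sum_forward_cpp(P$g_atom, prep$atom_idx9)
  E <- length(prep$src)
  e <- if (E) ddifuse:::emb_sum_forward_cpp(P$g_edge, prep$bond_flat2) else
    matrix(0, 0, cfg$graph$edge_dim)
  h <- h0
  for (k in seq_len(cfg$graph$K)) {
    m <- matrix(0, n, cfg$graph$msg)
    if (E) {
      hw <- h[prep$src, , drop = FALSE]
      hv <- h[prep$dst, , drop = FALSE]
      cand <- tanh(cbind(hw, e) %*% P$g_msg_w +
                     rep(as.numeric(P$g_msg_b), each = E))
      logit <- tanh(cbind(hv, hw, e) %*% P$g_att_w +
                      rep(as.numeric(P$g_att_b), each = E)) %*% P$g_att_u
      for (v in unique(prep$dst)) {
        rows <- which(prep$dst == v)
        w <- exp(logit[rows] - max(logit[rows]))
        alpha <- w / sum(w)
        m[v, ] <- colSums(cand[rows, , drop = FALSE] * alpha)
      }
    }
    z <- 1 / (1 + exp(-(m %*% P$g_wz + h %*% P$g_uz +
                          rep(as.numeric(P$g_bz), each = n))))
    r <- 1 / (1 + exp(-(m %*% P$g_wr + h %*% P$g_ur +
                          rep(as.numeric(P$g_br), each = n))))
    hh <- tanh(m %*% P$g_wh + (r * h) %*% P$g_uh +
                 rep(as.numeric(P$g_bh), each = n))
    h <- (1 - z) * h + z * hh
  }
  if (return_states) return(list(h = h, h0 = h0))
  cat_ <- cbind(h, h0)
  fn <- tanh(cat_ %*% P$g_fnn_w + rep(as.numeric(P$g_fnn_b), each = n))
  gn <- cat_ %*% P$g_gnn_w + rep(as.numeric(P$g_gnn_b), each = n)
  a <- exp(sweep(gn, 2L, apply(gn, 2L, max)))
  alpha <- sweep(a, 2L, colSums(a), "/")
  list(f_graph = colSums(alpha * fn), alpha = alpha)
}
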