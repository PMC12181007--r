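#' @section Model:
#' Each drug is encoded independently (Siamese weight sharing) by up to three
#' channels: (1) a transformer over its substructure token sequence, pooled by
#' a PAD-masked mean; (2) a message-passing attention network over the
#' molecular graph — additive attention weights over neighbors, candidate
#' messages linear in the neighbor state and bond embedding, GRU node updates,
#' and a self-attention graph-pooling readout over the concatenated final and
#' initial node states; (3) a spatial-semantic encoder that adds degree-based
#' centrality embeddings to the atom features and attends with per-pair
#' additive logit biases built from the shortest-path distance embedding and
#' the mean bond embedding along one deterministic shortest path, under
#' ProbSparse self-attention. A softmax attention gate fuses the per-view
#' embeddings into one vector per drug; a pair is scored by a three-layer
#' fully connected decoder with a final sigmoid.
#' @name ddi-model
NULL

glorot <- function(nin, nout) {
  s <- sqrt(6 / (nin + nout))
  matrix(runif(nin * nout, -s, s), nin, nout)
}

emb_init <- function(nrow, ncol) matrix(rnorm(nrow * ncol, sd = 0.1), nrow, ncol)
zeros <- function(nrow, ncol) matrix(0, nrow, ncol)
ones_row <- function(ncol) matrix(1, 1, ncol)

n_spatial_buckets <- function(cfg) cfg$semantic$spatial_clip + 3L  # -1, 0..clip, >clip
n_degree_buckets <- function(cfg) cfg$semantic$degree_clip + 1L    # 0..clip (clipped)

spatial_bucket <- function(s, clip) {
  ifelse(s < 0L, 1L, ifelse(s > clip, clip + 3L, s + 2L))
}

attn_layer_params <- function(prefix, d, dff) {
  p <- list()
  p[[paste0(prefix, "_ln1_g")]] <- ones_row(d)
  p[[paste0(prefix, "_ln1_b")]] <- zeros(1, d)
  for (w in c("wq", "wk", "wv", "wo")) p[[paste0(prefix, "_", w)]] <- glorot(d, d)
  for (b in c("bq", "bk", "bv", "bo")) p[[paste0(prefix, "_", b)]] <- zeros(1, d)
  p[[paste0(prefix, "_ln2_g")]] <- ones_row(d)
  p[[paste0(prefix, "_ln2_b")]] <- zeros(1, d)
  p[[paste0(prefix, "_ff1_w")]] <- glorot(d, dff)
  p[[paste0(prefix, "_ff1_b")]] <- zeros(1, dff)
  p[[paste0(prefix, "_ff2_w")]] <- glorot(dff, d)
  p[[paste0(prefix, "_ff2_b")]] <- zeros(1, d)
  p
}

init_params <- function(cfg, vocab_size, dict) {
  P <- list()
  # sequence channel
  d <- cfg$seq$d_model
  P$seq_tok <- emb_init(vocab_size, d)
  P$seq_pos <- emb_init(cfg$seq$k, d)
  for (l in seq_len(cfg$seq$n_layers)) {
    P <- c(P, attn_layer_params(paste0("seq", l), d, cfg$seq$d_ff))
  }
  P$seq_lnf_g <- ones_row(d); P$seq_lnf_b <- zeros(1, d)
  P$seq_proj_w <- glorot(d, cfg$seq$d_out); P$seq_proj_b <- zeros(1, cfg$seq$d_out)
  # graph channel
  r <- cfg$graph$hidden; ed <- cfg$graph$edge_dim; ms <- cfg$graph$msg
  P$g_atom <- emb_init(dict$atom_flat, r)
  P$g_edge <- emb_init(dict$bond_flat, ed)
  P$g_att_w <- glorot(2L * r + ed, cfg$graph$att_hidden)
  P$g_att_b <- zeros(1, cfg$graph$att_hidden)
  P$g_att_u <- glorot(cfg$graph$att_hidden, 1L)
  P$g_msg_w <- glorot(r + ed, ms); P$g_msg_b <- zeros(1, ms)
  for (g in c("z", "r", "h")) {
    P[[paste0("g_w", g)]] <- glorot(ms, r)
    P[[paste0("g_u", g)]] <- glorot(r, r)
    P[[paste0("g_b", g)]] <- zeros(1, r)
  }
  gnn_out <- if (isTRUE(cfg$graph$scalar_gate)) 1L else cfg$graph$d_out
  P$g_fnn_w <- glorot(2L * r, cfg$graph$d_out); P$g_fnn_b <- zeros(1, cfg$graph$d_out)
  P$g_gnn_w <- glorot(2L * r, gnn_out); P$g_gnn_b <- zeros(1, gnn_out)
  # semantic channel
  h <- cfg$semantic$hidden
  P$s_atom <- emb_init(dict$atom_flat, h)
  P$s_in <- emb_init(n_degree_buckets(cfg), h)
  P$s_out <- emb_init(n_degree_buckets(cfg), h)
  P$s_edgeb <- emb_init(dict$bond_flat, cfg$semantic$n_heads) * 0.1
  P$s_spatb <- emb_init(n_spatial_buckets(cfg), cfg$semantic$n_heads) * 0.1
  for (l in seq_len(cfg$semantic$n_blocks)) {
    P <- c(P, attn_layer_params(paste0("s", l), h, cfg$semantic$d_ff))
  }
  P$s_lnf_g <- ones_row(h); P$s_lnf_b <- zeros(1, h)
  P$s_proj_w <- glorot(h, cfg$semantic$d_out); P$s_proj_b <- zeros(1, cfg$semantic$d_out)
  # fusion + decoder
  w <- cfg$fusion$width
  P$f_w1 <- glorot(w, w); P$f_b <- zeros(1, w); P$f_w2 <- glorot(w, 1L)
  P$d_w1 <- glorot(2L * w, cfg$decoder$hidden1); P$d_b1 <- zeros(1, cfg$decoder$hidden1)
  P$d_w2 <- glorot(cfg$decoder$hidden1, cfg$decoder$hidden2)
  P$d_b2 <- zeros(1, cfg$decoder$hidden2)
  P$d_w3 <- glorot(cfg$decoder$hidden2, 1L); P$d_b3 <- zeros(1, 1)
  P
}

#' Construct an untrained three-channel DDI model
#'
#' @param drugs A drug table (`drug_id`, `smiles`); its SMILES corpus is used
#'   to mine the substructure vocabulary.
#' @param config A [model_config()].
#' @param vocab Optionally a pre-built [build_vocabulary()] result.
#' @return An object of class `ddi_model` holding the config, vocabulary,
#'   feature dictionaries and the (randomly initialized, seeded) parameters.
#' @export
ddi_model <- function(drugs, config = model_config(), vocab = NULL) {
  check_drug_table(drugs)
  if (is.null(vocab)) {
    vocab <- build_vocabulary(drugs$smiles,
                              max_merges = config$tokenizer$max_merges,
                              min_frequency = config$tokenizer$min_frequency)
  }
  dict <- feature_dictionaries()
  set.seed(config$train$seed)
  params <- init_params(config, nrow(vocab$vocab), dict)
  structure(list(config = config, vocab = vocab, dict = dict,
                 params = params), class = "ddi_model")
}

#' @export
print.ddi_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1)))
  cat("<ddi_model> ", format(np, big.mark = ","), " parameters, vocabulary ",
      nrow(x$vocab$vocab), " tokens\n", sep = "")
  print(x$config)
  invisible(x)
}

## ---- per-drug feature preparation -----------------------------------------

# Precompute everything static about one drug: token ids, flattened embedding
# indices for atoms/bonds, directed edges, degree buckets, and the per-pair
# spatial buckets and mean path-bond one-hot counts for the semantic bias.
prepare_drug <- function(graph, smiles, vocab, cfg, dict) {
  ts <- encode_tokens(smiles, vocab, k = cfg$seq$k)
  n <- graph$n
  atom_flat <- flatten_codes(graph$atom_codes, dict$atom_offsets)
  if (nrow(graph$bonds)) {
    bm <- as.matrix(graph$bonds[, c("bond_type", "stereo", "conjugated")])
    bond_flat <- flatten_codes(bm, dict$bond_offsets)
    src <- c(graph$bonds$a1, graph$bonds$a2)
    dst <- c(graph$bonds$a2, graph$bonds$a1)
    bond_flat2 <- rbind(bond_flat, bond_flat)
  } else {
    bond_flat <- matrix(integer(0), 0L, 3L)
    src <- dst <- integer(0)
    bond_flat2 <- bond_flat
  }
  # semantic bias inputs, row-major over (query x, key y)
  spd_t <- t(graph$spd)
  sp_idx <- spatial_bucket(as.vector(spd_t), cfg$semantic$spatial_clip)
  C <- matrix(0, n * n, dict$bond_flat)
  if (nrow(graph$bonds)) {
    for (x in seq_len(n)) for (y in seq_len(n)) {
      if (x == y) next
      pb <- graph$paths[[x]][[y]]
      if (!length(pb)) next
      row <- (x - 1L) * n + y
      for (b in pb) C[row, bond_flat[b, ]] <- C[row, bond_flat[b, ]] + 1
      C[row, ] <- C[row, ] / length(pb)
    }
  }
  u <- if (n < cfg$semantic$probsparse_min_atoms) n else
    min(n, as.integer(ceiling(cfg$semantic$probsparse_c * log(n))))
  list(n = n, ids = ts$ids, tlen = ts$true_length,
       atom_idx9 = atom_flat,
       src = as.integer(src), dst = as.integer(dst),
       bond_flat2 = bond_flat2,
       deg_idx = pmin(graph$degree, cfg$semantic$degree_clip) + 1L,
       sp_idx = as.integer(sp_idx), C = C, psu = as.integer(u))
}

prepare_drugs <- function(drugs, vocab, cfg, dict = feature_dictionaries()) {
  graphs <- parse_drugs(drugs, dict)
  setNames(lapply(seq_len(nrow(drugs)), function(i) {
    prepare_drug(graphs[[i]], drugs$smiles[i], vocab, cfg, dict)
  }), drugs$drug_id)
}

# Concatenate prepared drugs into one batch with global indexing.
assemble_batch <- function(preps, cfg) {
  B <- length(preps)
  ns <- vapply(preps, `[[`, integer(1), "n")
  offs <- c(0L, cumsum(ns))[seq_len(B)]
  tlens <- vapply(preps, `[[`, integer(1), "tlen")
  L <- max(1L, min(cfg$seq$k, max(tlens)))  # trim shared PAD tail
  ids <- unlist(lapply(preps, function(p) p$ids[seq_len(L)]))
  list(
    B = B, ns = ns, N = sum(ns), L = L,
    tok_ids = ids + 1L,                      # to 1-based table rows
    tok_pos = rep(seq_len(L), B),
    tok_seg = rep(seq_len(B), each = L),
    tok_mask = as.numeric(ids != PAD_ID),
    tok_w = unlist(lapply(seq_len(B), function(i) {
      m <- preps[[i]]$ids[seq_len(L)] != PAD_ID
      m / max(1L, sum(m))
    })),
    atom_seg = rep(seq_len(B), ns),
    atom_idx9 = do.call(rbind, lapply(preps, `[[`, "atom_idx9")),
    src = unlist(lapply(seq_len(B), function(i) preps[[i]]$src + offs[i])),
    dst = unlist(lapply(seq_len(B), function(i) preps[[i]]$dst + offs[i])),
    bond_flat2 = do.call(rbind, lapply(preps, `[[`, "bond_flat2")),
    deg_idx = unlist(lapply(preps, `[[`, "deg_idx")),
    sp_idx = unlist(lapply(preps, `[[`, "sp_idx")),
    C = do.call(rbind, lapply(preps, `[[`, "C")),
    psu = vapply(preps, `[[`, integer(1), "psu"),
    atom_w = unlist(lapply(ns, function(n) rep(1 / n, n)))
  )
}

## ---- channel forwards ------------------------------------------------------

encode_seq_batch <- function(P, bt, cfg, training = FALSE) {
  x <- ad_add(ad_gather(P$seq_tok, bt$tok_ids),
              ad_gather(P$seq_pos, bt$tok_pos))
  drop <- if (training) cfg$seq$dropout else 0
  for (l in seq_len(cfg$seq$n_layers)) {
    x <- ad_block(x, P, paste0("seq", l), cfg$seq$n_heads, bt$tok_seg,
                  keymask = bt$tok_mask, dropout = drop)
  }
  x <- ad_layernorm(x, P$seq_lnf_g, P$seq_lnf_b)
  pooled <- ad_segment_sum(ad_rowscale(x, bt$tok_w), bt$tok_seg, bt$B)
  ad_linear(pooled, P$seq_proj_w, P$seq_proj_b)
}

encode_graph_batch <- function(P, bt, cfg) {
  h0 <- ad_emb_sum(P$g_atom, bt$atom_idx9)
  h <- h0
  has_edges <- length(bt$src) > 0L
  if (has_edges) {
    e <- ad_emb_sum(P$g_edge, bt$bond_flat2)
  }
  for (k in seq_len(cfg$graph$K)) {
    if (!has_edges) { m <- zeros(bt$N, cfg$graph$msg) } else {
      hw <- ad_gather(h, bt$src)
      hv <- ad_gather(h, bt$dst)
      cand <- ad_tanh(ad_linear(ad_concat_cols(hw, e), P$g_msg_w, P$g_msg_b))
      logit <- ad_matmul(
        ad_tanh(ad_linear(ad_concat_cols(ad_concat_cols(hv, hw), e),
                          P$g_att_w, P$g_att_b)), P$g_att_u)
      # numerically centered segment softmax over each atom's neighborhood
      lmax <- rep(-Inf, bt$N)
      lv <- as.numeric(ad_val(logit))
      for (i in seq_along(bt$dst)) {
        if (lv[i] > lmax[bt$dst[i]]) lmax[bt$dst[i]] <- lv[i]
      }
      ex <- ad_exp(ad_sub(logit, matrix(lmax[bt$dst], ncol = 1L)))
      Z <- ad_segment_sum(ex, bt$dst, bt$N)
      alpha <- ad_div(ex, ad_gather(Z, bt$dst))
      m <- ad_segment_sum(ad_rowscale(cand, alpha), bt$dst, bt$N)
    }
    z <- ad_sigmoid(ad_linear2(m, P$g_wz, h, P$g_uz, P$g_bz))
    r <- ad_sigmoid(ad_linear2(m, P$g_wr, h, P$g_ur, P$g_br))
    hh <- ad_tanh(ad_linear2(m, P$g_wh, ad_mul(r, h), P$g_uh, P$g_bh))
    h <- ad_add(ad_mul(ad_sub(1, z), h), ad_mul(z, hh))
  }
  cat_ <- ad_concat_cols(h, h0)
  fn <- ad_tanh(ad_linear(cat_, P$g_fnn_w, P$g_fnn_b))
  gn <- ad_linear(cat_, P$g_gnn_w, P$g_gnn_b)
  gv <- ad_val(gn)
  gmax <- apply(gv, 2L, function(col) {
    tapply(col, bt$atom_seg, max)[as.character(seq_len(bt$B))]
  })
  gmax <- matrix(gmax, bt$B, ncol(gv))
  ex <- ad_exp(ad_sub(gn, gmax[bt$atom_seg, , drop = FALSE]))
  Z <- ad_segment_sum(ex, bt$atom_seg, bt$B)
  alpha <- ad_div(ex, ad_gather(Z, bt$atom_seg))
  if (isTRUE(cfg$graph$scalar_gate)) {
    ad_segment_sum(ad_rowscale(fn, alpha), bt$atom_seg, bt$B)
  } else {
    ad_segment_sum(ad_mul(alpha, fn), bt$atom_seg, bt$B)
  }
}

encode_semantic_batch <- function(P, bt, cfg) {
  a <- ad_emb_sum(P$s_atom, bt$atom_idx9)
  a <- ad_add(a, ad_add(ad_gather(P$s_in, bt$deg_idx),
                        ad_gather(P$s_out, bt$deg_idx)))
  bias <- ad_add(ad_matmul(bt$C, P$s_edgeb), ad_gather(P$s_spatb, bt$sp_idx))
  x <- a
  for (l in seq_len(cfg$semantic$n_blocks)) {
    pre <- function(nm) P[[paste0("s", l, "_", nm)]]
    h <- ad_layernorm(x, pre("ln1_g"), pre("ln1_b"))
    q <- ad_linear(h, pre("wq"), pre("bq"))
    k <- ad_linear(h, pre("wk"), pre("bk"))
    v <- ad_linear(h, pre("wv"), pre("bv"))
    att <- ad_attention(q, k, v, cfg$semantic$n_heads, bt$atom_seg,
                        bias = bias, psu = bt$psu)
    x <- ad_add(x, ad_add(ad_matmul(att, pre("wo")), pre("bo")))
    h <- ad_layernorm(x, pre("ln2_g"), pre("ln2_b"))
    f <- ad_add(ad_matmul(ad_relu(ad_add(ad_matmul(h, pre("ff1_w")),
                                         pre("ff1_b"))), pre("ff2_w")),
                pre("ff2_b"))
    x <- ad_add(x, f)
  }
  x <- ad_layernorm(x, P$s_lnf_g, P$s_lnf_b)
  pooled <- ad_segment_sum(ad_rowscale(x, bt$atom_w), bt$atom_seg, bt$B)
  ad_linear(pooled, P$s_proj_w, P$s_proj_b)
}

# Softmax attention fusion over the enabled views (Siamese: same parameters
# for every drug). Returns list(F, alpha) with alpha a B x n_views matrix.
fuse_batch <- function(P, views) {
  stopifnot(length(views) >= 1L)
  logits <- NULL
  for (f in views) {
    w <- ad_matmul(ad_tanh(ad_linear(f, P$f_w1, P$f_b)), P$f_w2)
    logits <- if (is.null(logits)) w else ad_concat_cols(logits, w)
  }
  if (length(views) == 1L) {
    return(list(F = views[[1L]],
                alpha = matrix(1, nrow(ad_val(views[[1L]])), 1L)))
  }
  alpha <- ad_softmax_rows(logits)
  fused <- NULL
  for (i in seq_along(views)) {
    term <- ad_rowscale(views[[i]], ad_col(alpha, i))
    fused <- if (is.null(fused)) term else ad_add(fused, term)
  }
  list(F = fused, alpha = ad_val(alpha))
}

decoder_logit <- function(P, x) {
  h1 <- ad_relu(ad_linear(x, P$d_w1, P$d_b1))
  h2 <- ad_relu(ad_linear(h1, P$d_w2, P$d_b2))
  ad_linear(h2, P$d_w3, P$d_b3)
}

decode_pairs <- function(P, Fmat, i_idx, j_idx, symmetric = FALSE) {
  Fi <- ad_gather(Fmat, i_idx)
  Fj <- ad_gather(Fmat, j_idx)
  logit <- decoder_logit(P, ad_concat_cols(Fi, Fj))
  if (symmetric) {
    logit2 <- decoder_logit(P, ad_concat_cols(Fj, Fi))
    logit <- ad_mul(ad_add(logit, logit2), 0.5)
  }
  ad_sigmoid(logit)
}

# Full forward pass for a batch of pairs over deduplicated drugs.
# preps: named list of prepared drugs; pair_idx: 2-col matrix into preps.
forward_pairs <- function(P, preps, pair_idx, cfg, training = FALSE) {
  bt <- assemble_batch(preps, cfg)
  views <- list()
  if (cfg$channels$seq) views$seq <- encode_seq_batch(P, bt, cfg, training)
  if (cfg$channels$graph) views$graph <- encode_graph_batch(P, bt, cfg)
  if (cfg$channels$semantic) views$semantic <- encode_semantic_batch(P, bt, cfg)
  fz <- fuse_batch(P, views)
  p <- decode_pairs(P, fz$F, pair_idx[, 1L], pair_idx[, 2L],
                    symmetric = isTRUE(cfg$decoder$symmetric))
  list(p = p, fused = fz$F, alpha = fz$alpha, views = views)
}

#' Binary cross-entropy loss
#'
#' Mean of `-(y log p + (1-y) log(1-p))` with predictions clamped to
#' `[1e-7, 1 - 1e-7]`.
#'
#' @param predicted Numeric vector of probabilities in `(0, 1)`.
#' @param labels Binary 0/1 labels of the same length.
#' @return A single number.
#' @export
#' @examples
#' bce_loss(0.5, 1)  # -log(0.5) = 0.6931
bce_loss <- function(predicted, labels) {
  stopifnot(length(predicted) == length(labels), length(labels) >= 1L)
  if (!all(labels %in% c(0, 1))) {
    abort("Labels must be binary.", class = "ddifuse_non_binary_label")
  }
  as.numeric(ad_bce(matrix(predicted, ncol = 1L), labels))
}
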