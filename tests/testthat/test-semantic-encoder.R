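# Spatial-semantic channel: centrality encoding, shortest-path bias,
# ProbSparse attention.

test_that("centrality encoding adds degree embeddings to atom features", {
  fxt <- tiny_fixture()
  cfg <- fxt$cfg
  P <- fxt$model$params
  g <- parse_smiles("CC(C)(C)C")  # neopentane
  prep <- ddifuse:::prepare_drug(g, "CC(C)(C)C", fxt$model$vocab, cfg,
                                 fxt$model$dict)
  # the central carbon has degree 4 -> degree bucket index 5 (0-based 4)
  expect_equal(prep$deg_idx[2], 5L)
  a <- ddifuse:::emb_sum_forward_cpp(P$s_atom, prep$atom_idx9) +
    P$s_in[prep$deg_idx, ] + P$s_out[prep$deg_idx, ]
  # two terminal carbons with identical features and equal degree encode equal
  expect_equal(a[1, ], a[3, ], tolerance = 1e-12)
  # undirected graph: in- and out-degree tables are indexed identically, so
  # zeroing both removes exactly the centrality term
  P0 <- P
  P0$s_in[] <- 0; P0$s_out[] <- 0
  a0 <- ddifuse:::emb_sum_forward_cpp(P0$s_atom, prep$atom_idx9) +
    P0$s_in[prep$deg_idx, ] + P0$s_out[prep$deg_idx, ]
  expect_equal(a - a0, P$s_in[prep$deg_idx, ] + P$s_out[prep$deg_idx, ],
               tolerance = 1e-12)
})

test_that("edge-plus-spatial bias is symmetric and uses the -1 bucket", {
  fxt <- tiny_fixture()
  cfg <- fxt$cfg
  P <- fxt$model$params
  for (smi in c("CCO", "CC(C)CC(=O)O", "c1ccccc1CCN")) {
    g <- parse_smiles(smi)
    prep <- ddifuse:::prepare_drug(g, smi, fxt$model$vocab, cfg,
                                   fxt$model$dict)
    bias <- prep$C %*% P$s_edgeb + P$s_spatb[prep$sp_idx, ]
    n <- prep$n
    for (h in seq_len(ncol(bias))) {
      B <- t(matrix(bias[, h], n, n))  # query-major storage
      expect_equal(B, t(B), tolerance = 1e-12)
    }
  }
  # disconnected pair: bias reduces to the -1 spatial bucket only
  g2 <- parse_smiles("[Na+].[Cl-]")
  prep2 <- ddifuse:::prepare_drug(g2, "[Na+].[Cl-]", fxt$model$vocab, cfg,
                                  fxt$model$dict)
  cross <- 2L  # query 1, key 2 in query-major order
  expect_equal(prep2$sp_idx[cross], 1L)  # the reserved -1 bucket
  expect_true(all(prep2$C[cross, ] == 0))
  bias2 <- prep2$C %*% P$s_edgeb + P$s_spatb[prep2$sp_idx, ]
  expect_equal(bias2[cross, ], P$s_spatb[1L, ], tolerance = 1e-12)
})

test_that("adjacent atoms with zero spatial table recover the bond embedding", {
  fxt <- tiny_fixture()
  cfg <- fxt$cfg
  P <- fxt$model$params
  g <- parse_smiles("CCO")
  prep <- ddifuse:::prepare_drug(g, "CCO", fxt$model$vocab, cfg,
                                 fxt$model$dict)
  P0 <- P; P0$s_spatb[] <- 0
  bias <- prep$C %*% P0$s_edgeb + P0$s_spatb[prep$sp_idx, ]
  # pair (1,2) is one bond apart: k = 1, so the mean equals that bond's
  # projected features
  row12 <- (1L - 1L) * prep$n + 2L
  bond_emb <- colSums(P0$s_edgeb[prep$bond_flat2[1L, ], ])
  expect_equal(bias[row12, ], bond_emb, tolerance = 1e-12)
  # diagonal has no edge term
  row11 <- (1L - 1L) * prep$n + 1L
  expect_true(all(bias[row11, ] == 0))
  expect_equal(prep$sp_idx[row11], 2L)  # distance-0 bucket
})

test_that("ProbSparse equals a full-attention oracle when the budget covers all atoms", {
  fxt <- tiny_fixture()
  cfg <- fxt$cfg
  P <- fxt$model$params
  # u = ceil(c ln n) with c = 5 covers these molecule sizes, so the ProbSparse
  # encoder must agree with an independent plain-R full-softmax implementation
  count_checked <- 0L
  for (i in seq_along(fxt$preps)) {
    prep <- fxt$preps[[i]]
    if (prep$psu < prep$n) next  # would genuinely sparsify; skipped here
    a <- encode_one(P, prep, cfg, "semantic")
    b <- semantic_forward_oracle(P, prep, cfg)
    expect_lt(max(abs(a - b)), 1e-5)
    count_checked <- count_checked + 1L
  }
  expect_gt(count_checked, 10L)
})

test_that("a sparsified molecule differs from full attention only via the mean shortcut", {
  fxt <- tiny_fixture()
  cfg <- fxt$cfg
  P <- fxt$model$params
  # a long chain has many atoms; force a small query budget
  smi <- paste(rep("C", 30), collapse = "")
  g <- parse_smiles(smi)
  prep <- ddifuse:::prepare_drug(g, smi, fxt$model$vocab, cfg, fxt$model$dict)
  sparse <- prep; sparse$psu <- 5L
  full <- prep; full$psu <- prep$n
  a <- encode_one(P, sparse, cfg, "semantic")
  b <- encode_one(P, full, cfg, "semantic")
  expect_gt(max(abs(a - b)), 0)  # the approximation is active
  expect_true(all(is.finite(a)))
})

test_that("f_semantic is invariant under atom renumbering", {
  fxt <- tiny_fixture()
  cfg <- fxt$cfg
  P <- fxt$model$params
  set.seed(44)
  for (i in sample(length(fxt$preps), 8)) {
    prep <- fxt$preps[[i]]
    base <- encode_one(P, prep, cfg, "semantic")
    for (r in 1:3) {
      perm <- sample(prep$n)
      out <- encode_one(P, permute_prep(prep, perm), cfg, "semantic")
      expect_lt(max(abs(out - base)), 1e-5)
    }
  }
})

test_that("batching molecules together leaves each embedding unchanged", {
  # segment masking: a molecule encoded alone equals the same molecule encoded
  # in a batch with others
  fxt <- tiny_fixture()
  cfg <- fxt$cfg
  P <- fxt$model$params
  alone <- encode_one(P, fxt$preps[[3]], cfg, "semantic")
  bt <- ddifuse:::assemble_batch(fxt$preps[1:6], cfg)
  batched <- ddifuse:::encode_semantic_batch(P, bt, cfg)
  expect_lt(max(abs(batched[3, ] - alone)), 1e-10)
  # same contract for the other channels
  alone_g <- encode_one(P, fxt$preps[[3]], cfg, "graph")
  expect_lt(max(abs(ddifuse:::encode_graph_batch(P, bt, cfg)[3, ] - alone_g)),
            1e-10)
  alone_s <- encode_one(P, fxt$preps[[3]], cfg, "seq")
  expect_lt(max(abs(ddifuse:::encode_seq_batch(P, bt, cfg, FALSE)[3, ] -
                      alone_s)), 1e-10)
})
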