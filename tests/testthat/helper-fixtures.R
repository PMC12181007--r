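# Shared small fixtures, built once per test run.

fx <- new.env()

# A small synthetic dataset + tiny-config model, reused across encoder tests.
tiny_config <- function(...) {
  model_config(
    seq = list(k = 30L, n_layers = 1L),
    semantic = list(n_blocks = 2L),
    train = list(epochs = 2L, batch_size = 8L, n_repeats = 1L, seed = 42L),
    ...
  )
}

tiny_fixture <- function() {
  if (is.null(fx$tiny)) {
    drugs <- generate_drugs(n_drugs = 30L, seed = 7L)
    cfg <- tiny_config()
    model <- ddi_model(drugs, cfg)
    preps <- ddifuse:::prepare_drugs(drugs, model$vocab, cfg, model$dict)
    fx$tiny <- list(drugs = drugs, cfg = cfg, model = model, preps = preps)
  }
  fx$tiny
}

# Random parseable SMILES used for oracle sweeps.
random_smiles <- function(n, seed = 1L, max_atoms = 12L) {
  drugs <- generate_drugs(n_drugs = n, scaffold_range = c(2L, 5L), seed = seed)
  drugs$smiles
}

# Forward one drug through a channel encoder with raw (numeric) parameters.
encode_one <- function(params, prep, cfg, channel) {
  bt <- ddifuse:::assemble_batch(list(prep), cfg)
  switch(channel,
         seq = ddifuse:::encode_seq_batch(params, bt, cfg, FALSE),
         graph = ddifuse:::encode_graph_batch(params, bt, cfg),
         semantic = ddifuse:::encode_semantic_batch(params, bt, cfg))
}

# Apply an atom permutation to a prepared drug's graph-level fields, as if the
# molecule had been numbered differently. perm[new_index] = old_index.
permute_prep <- function(prep, perm) {
  n <- prep$n
  inv <- integer(n)
  inv[perm] <- seq_len(n)  # old -> new
  out <- prep
  out$atom_idx9 <- prep$atom_idx9[perm, , drop = FALSE]
  out$deg_idx <- prep$deg_idx[perm]
  out$src <- inv[prep$src]
  out$dst <- inv[prep$dst]
  # pair-indexed fields are stored query-major: row (x-1)*n + y
  old_row <- function(x, y) (x - 1L) * n + y
  map <- integer(n * n)
  for (x in seq_len(n)) for (y in seq_len(n)) {
    map[old_row(x, y)] <- old_row(perm[x], perm[y])
  }
  out$sp_idx <- prep$sp_idx[map]
  out$C <- prep$C[map, , drop = FALSE]
  out
}
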