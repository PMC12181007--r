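# Split protocol, training loop contracts, evaluation, ablation variants.

test_that("8:1:1 split of 100 pairs gives sizes (80, 10, 10)", {
  drugs <- generate_drugs(n_drugs = 40, seed = 20)
  pairs <- generate_pairs(drugs, n_pairs = 100, seed = 21)
  sp <- split_dataset(pairs, seed = 1)
  expect_equal(vapply(sp, nrow, integer(1)),
               c(train = 80L, valid = 10L, test = 10L))
  # disjoint and exhaustive over unordered pairs
  key <- function(p) paste(pmin(p$drug_id_1, p$drug_id_2),
                           pmax(p$drug_id_1, p$drug_id_2))
  all_keys <- c(key(sp$train), key(sp$valid), key(sp$test))
  expect_false(any(duplicated(all_keys)))
  expect_setequal(all_keys, key(pairs))
})

test_that("fractional subsampling reduces the pool before splitting", {
  drugs <- generate_drugs(n_drugs = 40, seed = 20)
  pairs <- generate_pairs(drugs, n_pairs = 100, seed = 21)
  sp <- split_dataset(pairs, seed = 2, fraction = 0.5)
  expect_equal(sum(vapply(sp, nrow, integer(1))), 50L)
  sp75 <- split_dataset(pairs, seed = 2, fraction = 0.75)
  expect_equal(sum(vapply(sp75, nrow, integer(1))), 75L)
})

test_that("splits are deterministic and duplicated unordered pairs collapse", {
  drugs <- generate_drugs(n_drugs = 40, seed = 20)
  pairs <- generate_pairs(drugs, n_pairs = 60, seed = 22)
  dup <- pairs[c(seq_len(60), 1:5), ]
  dup[61:65, c("drug_id_1", "drug_id_2")] <-
    dup[61:65, c("drug_id_2", "drug_id_1")]  # reversed duplicates
  s1 <- split_dataset(dup, seed = 5)
  s2 <- split_dataset(dup, seed = 5)
  expect_identical(s1, s2)
  expect_equal(sum(vapply(s1, nrow, integer(1))), 60L)
  expect_error(split_dataset(pairs[1:5, ], seed = 1),
               class = "ddifuse_dataset_too_small")
})

test_that("training reduces the loss on a separable planted-rule set", {
  ds <- synthetic_dataset(n_drugs = 60, n_pairs = 120, seed = 23)
  cfg <- tiny_config()
  cfg$train$epochs <- 3L
  sp <- split_dataset(ds$pairs, seed = 23)
  fit <- fit_ddi(ds$drugs, sp$train, sp$valid, config = cfg)
  h <- fit$history
  expect_equal(nrow(h), 3L)
  expect_lt(h$train_loss[3], h$train_loss[1])
  expect_true(all(is.finite(h$train_loss)))
  expect_true(fit$best_epoch >= 1L)
})

test_that("identical seeds give identical loss curves and predictions", {
  ds <- synthetic_dataset(n_drugs = 30, n_pairs = 60, seed = 24)
  cfg <- tiny_config()
  sp <- split_dataset(ds$pairs, seed = 24)
  f1 <- fit_ddi(ds$drugs, sp$train, sp$valid, config = cfg)
  f2 <- fit_ddi(ds$drugs, sp$train, sp$valid, config = cfg)
  expect_identical(f1$history$train_loss, f2$history$train_loss)
  p1 <- predict(f1, sp$test)
  p2 <- predict(f2, sp$test)
  expect_identical(p1$probability, p2$probability)
})

test_that("gradients reach every enabled channel in the first step", {
  ds <- synthetic_dataset(n_drugs = 20, n_pairs = 24, seed = 25)
  cfg <- tiny_config()
  model <- ddi_model(ds$drugs, cfg)
  preps <- ddifuse:::prepare_drugs(ds$drugs, model$vocab, cfg, model$dict)
  pairs <- ds$pairs[1:8, ]
  ids <- unique(c(pairs$drug_id_1, pairs$drug_id_2))
  idx <- cbind(match(pairs$drug_id_1, ids), match(pairs$drug_id_2, ids))
  tape <- ddifuse:::ad_tape()
  Pn <- ddifuse:::ad_params_to_nodes(tape, model$params)
  fw <- ddifuse:::forward_pairs(Pn, preps[ids], idx, cfg)
  ddifuse:::ad_backward(ddifuse:::ad_bce(fw$p, pairs$label))
  for (nm in c("seq_tok", "g_atom", "s_atom", "f_w1", "d_w1", "s_edgeb",
               "s_spatb", "s_in", "g_edge")) {
    expect_gt(max(abs(Pn[[nm]]$grad)), 0)
  }
})

test_that("evaluation metrics and single-class AUROC handling", {
  ds <- synthetic_dataset(n_drugs = 50, n_pairs = 60, seed = 26)
  cfg <- tiny_config()
  sp <- split_dataset(ds$pairs, seed = 26)
  fit <- fit_ddi(ds$drugs, sp$train, NULL, config = cfg)
  m <- evaluate_ddi(fit, sp$test)
  expect_true(all(c("acc", "auroc", "f1", "n") %in% names(m)))
  expect_equal(m$n, nrow(sp$test))
  one_class <- sp$test[sp$test$label == sp$test$label[1], ]
  m1 <- evaluate_ddi(fit, one_class)
  expect_true(is.na(m1$auroc))   # undefined, reported as missing
  expect_false(is.na(m1$acc))
})

test_that("repeated runs average per-run metrics arithmetically", {
  ds <- synthetic_dataset(n_drugs = 30, n_pairs = 60, seed = 27)
  cfg <- tiny_config()
  cfg$train$n_repeats <- 2L
  cfg$train$epochs <- 1L
  rep <- run_experiment(ds$drugs, ds$pairs, cfg)
  expect_equal(nrow(rep$runs), 2L)
  expect_equal(rep$summary$auroc, mean(rep$runs$auroc))
  expect_equal(rep$summary$acc, mean(rep$runs$acc))
  # n_repeats = 1: summary equals the single run
  cfg$train$n_repeats <- 1L
  rep1 <- run_experiment(ds$drugs, ds$pairs, cfg)
  expect_equal(rep1$summary$auroc, rep1$runs$auroc)
})

test_that("the seven ablation variants toggle the documented channel sets", {
  defs <- ablation_variants()
  expect_named(defs, c("full", "no_seq", "no_graph", "no_semantic",
                       "seq_only", "graph_only", "semantic_only"))
  expect_equal(unname(defs$full), c(TRUE, TRUE, TRUE))
  expect_equal(unname(defs$no_seq), c(FALSE, TRUE, TRUE))
  expect_equal(unname(defs$no_graph), c(TRUE, FALSE, TRUE))
  expect_equal(unname(defs$no_semantic), c(TRUE, TRUE, FALSE))
  expect_equal(unname(defs$seq_only), c(TRUE, FALSE, FALSE))
  expect_equal(unname(defs$graph_only), c(FALSE, TRUE, FALSE))
  expect_equal(unname(defs$semantic_only), c(FALSE, FALSE, TRUE))
  expect_error(model_config(channels = list(seq = FALSE, graph = FALSE,
                                            semantic = FALSE)),
               class = "ddifuse_config_error")
})

test_that("checkpoints round-trip through save and load", {
  ds <- synthetic_dataset(n_drugs = 25, n_pairs = 40, seed = 28)
  cfg <- tiny_config()
  cfg$train$epochs <- 1L
  sp <- split_dataset(ds$pairs, seed = 28)
  fit <- fit_ddi(ds$drugs, sp$train, sp$valid, config = cfg)
  ck <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(fit, ck)
  fit2 <- load_checkpoint(ck, ds$drugs)
  expect_equal(predict(fit2, sp$test)$probability,
               predict(fit, sp$test)$probability, tolerance = 1e-12)
})

test_that("config YAML round-trips and validates", {
  cfg <- model_config(train = list(epochs = 7L, seed = 3L),
                      channels = list(seq = FALSE))
  f <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, f)
  cfg2 <- read_config(f)
  expect_equal(cfg2$train$epochs, 7L)
  expect_false(cfg2$channels$seq)
  expect_equal(cfg2$train$split, cfg$train$split)
  expect_error(model_config(train = list(split = c(0.5, 0.2, 0.2))),
               class = "ddifuse_config_error")
  expect_error(model_config(train = list(dataset_fraction = 0)),
               class = "ddifuse_config_error")
})

test_that("tidiers and plots expose the fit in tabular form", {
  ds <- synthetic_dataset(n_drugs = 25, n_pairs = 40, seed = 29)
  cfg <- tiny_config()
  cfg$train$epochs <- 2L
  sp <- split_dataset(ds$pairs, seed = 29)
  fit <- fit_ddi(ds$drugs, sp$train, sp$valid, config = cfg)
  td <- tidy(fit)
  expect_true(all(c("epoch", "metric", "value") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$epochs, 2L)
  expect_gt(gl$n_parameters, 1e5)
  expect_s3_class(autoplot(fit), "ggplot")
})
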