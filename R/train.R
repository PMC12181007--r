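#' @section Training protocol:
#' Pairs are deduplicated (unordered), optionally subsampled to a fraction
#' for robustness analysis, shuffled under the run seed and split 8:1:1 into
#' train/validation/test. Training uses Adam (learning rate 1e-4, batch size
#' 16) on the binary cross-entropy for up to the configured number of epochs;
#' the checkpoint with the best validation AUROC is retained. Experiments are
#' repeated over consecutive seeds and metrics averaged; the seven channel
#' ablation variants toggle encoders while keeping everything else fixed.
#' @name train-eval
NULL

#' Split a pair table into train / validation / test
#'
#' Deduplicates unordered pairs (the same two drugs never land in two
#' splits), optionally retains a uniform random fraction, shuffles under the
#' seed, and partitions contiguously at floor boundaries with the remainder
#' going to train.
#'
#' @param pairs Pair tibble (`drug_id_1`, `drug_id_2`, `label`).
#' @param ratios Numeric length-3 split proportions summing to 1.
#' @param seed Integer seed.
#' @param fraction Fraction of pairs retained before splitting, in `(0, 1]`.
#' @return A list with tibbles `train`, `valid`, `test`.
#' @export
#' @examples
#' \dontrun{
#' sp <- split_dataset(pairs, seed = 1)
#' vapply(sp, nrow, integer(1))
#' }
split_dataset <- function(pairs, ratios = c(0.8, 0.1, 0.1), seed = 1L,
                          fraction = 1.0) {
  stopifnot(abs(sum(ratios) - 1) < 1e-8, fraction > 0, fraction <= 1)
  key <- paste(pmin(pairs$drug_id_1, pairs$drug_id_2),
               pmax(pairs$drug_id_1, pairs$drug_id_2))
  pairs <- pairs[!duplicated(key), ]
  set.seed(seed)
  n <- nrow(pairs)
  if (fraction < 1) {
    n <- max(1L, floor(n * fraction))
    pairs <- pairs[sample(nrow(pairs), n), ]
  }
  if (n < 10L) {
    abort(sprintf("Need at least 10 pairs after deduplication, got %d.", n),
          class = "ddifuse_dataset_too_small")
  }
  pairs <- pairs[sample(n), ]
  n_va <- floor(n * ratios[2L])
  n_te <- floor(n * ratios[3L])
  n_tr <- n - n_va - n_te
  list(train = pairs[seq_len(n_tr), ],
       valid = pairs[n_tr + seq_len(n_va), ],
       test = pairs[n_tr + n_va + seq_len(n_te), ])
}

# Encode every drug once (numeric, no tape) and return the fused embeddings
# plus per-view embeddings; params are raw matrices so all ops are plain.
encode_all_drugs <- function(params, preps, cfg, chunk = 32L) {
  nd <- length(preps)
  Fm <- NULL
  alpha <- NULL
  starts <- seq(1L, nd, by = chunk)
  for (s in starts) {
    sub <- preps[s:min(nd, s + chunk - 1L)]
    bt <- assemble_batch(sub, cfg)
    views <- list()
    if (cfg$channels$seq) views$seq <- encode_seq_batch(params, bt, cfg, FALSE)
    if (cfg$channels$graph) views$graph <- encode_graph_batch(params, bt, cfg)
    if (cfg$channels$semantic) {
      views$semantic <- encode_semantic_batch(params, bt, cfg)
    }
    fz <- fuse_batch(params, views)
    Fm <- rbind(Fm, fz$F)
    alpha <- rbind(alpha, fz$alpha)
  }
  rownames(Fm) <- names(preps)
  list(F = Fm, alpha = alpha)
}

predict_scores <- function(params, preps, pairs, cfg) {
  enc <- encode_all_drugs(params, preps, cfg)
  i <- match(pairs$drug_id_1, names(preps))
  j <- match(pairs$drug_id_2, names(preps))
  as.numeric(decode_pairs(params, enc$F, i, j,
                          symmetric = isTRUE(cfg$decoder$symmetric)))
}

#' Train the three-channel model
#'
#' @param drugs Drug table covering every id referenced by the pairs.
#' @param train_pairs,valid_pairs Pair tibbles; `valid_pairs` may be `NULL`.
#' @param config A [model_config()]; `config$train` carries the optimizer
#'   settings and seed.
#' @param model Optionally a pre-built [ddi_model()] (e.g. to share a
#'   vocabulary across runs).
#' @param quiet Suppress per-epoch console logging.
#' @return A `ddi_fit`: the trained model (best-validation-AUROC checkpoint),
#'   the final-epoch parameters, and a per-epoch `history` tibble.
#' @export
fit_ddi <- function(drugs, train_pairs, valid_pairs = NULL,
                    config = model_config(), model = NULL, quiet = TRUE) {
  check_drug_table(drugs)
  check_pair_refs(train_pairs, drugs)
  if (!is.null(valid_pairs) && nrow(valid_pairs)) {
    check_pair_refs(valid_pairs, drugs)
  }
  if (is.null(model)) model <- ddi_model(drugs, config)
  cfg <- model$config
  preps <- prepare_drugs(drugs, model$vocab, cfg, model$dict)
  params <- copy_params(model$params)  # Adam updates these in place
  opt <- adam_init(params)
  set.seed(cfg$train$seed)
  ntr <- nrow(train_pairs)
  bs <- cfg$train$batch_size
  history <- NULL
  best <- list(auroc = -Inf, params = NULL, epoch = 0L)
  for (epoch in seq_len(cfg$train$epochs)) {
    ord <- sample(ntr)
    losses <- numeric(0)
    for (start in seq(1L, ntr, by = bs)) {
      rows <- ord[start:min(ntr, start + bs - 1L)]
      ids <- unique(c(train_pairs$drug_id_1[rows], train_pairs$drug_id_2[rows]))
      sub <- preps[ids]
      pair_idx <- cbind(match(train_pairs$drug_id_1[rows], ids),
                        match(train_pairs$drug_id_2[rows], ids))
      y <- train_pairs$label[rows]
      tape <- ad_tape()
      Pn <- ad_params_to_nodes(tape, params)
      fw <- forward_pairs(Pn, sub, pair_idx, cfg, training = TRUE)
      loss <- ad_bce(fw$p, y)
      lv <- ad_val(loss)
      if (!is.finite(lv)) {
        abort(sprintf("Non-finite training loss at epoch %d.", epoch),
              class = "ddifuse_nan_loss")
      }
      ad_backward(loss)
      grads <- ad_collect_grads(Pn)
      up <- adam_step(params, grads, opt, lr = cfg$train$learning_rate)
      params <- up$params
      opt <- up$state
      losses <- c(losses, lv)
    }
    ep <- tibble::tibble(epoch = epoch, train_loss = mean(losses),
                         valid_acc = NA_real_, valid_auroc = NA_real_,
                         valid_f1 = NA_real_)
    if (!is.null(valid_pairs) && nrow(valid_pairs)) {
      sc <- predict_scores(params, preps, valid_pairs, cfg)
      ep$valid_acc <- metric_acc(sc, valid_pairs$label)
      ep$valid_auroc <- metric_auroc(sc, valid_pairs$label)
      ep$valid_f1 <- metric_f1(sc, valid_pairs$label)
      if (!is.na(ep$valid_auroc) && ep$valid_auroc > best$auroc) {
        best <- list(auroc = ep$valid_auroc, params = copy_params(params),
                     epoch = epoch)
      }
    }
    history <- dplyr::bind_rows(history, ep)
    if (!quiet) {
      message(sprintf("[%s] epoch %3d  loss %.4f  valid AUROC %s",
                      format(Sys.time(), "%H:%M:%S"), epoch,
                      ep$train_loss,
                      ifelse(is.na(ep$valid_auroc), "-",
                             sprintf("%.4f", ep$valid_auroc))))
    }
  }
  if (is.null(best$params)) best <- list(auroc = NA_real_, params = params,
                                         epoch = cfg$train$epochs)
  model$params <- best$params
  structure(list(model = model, params_final = params, history = history,
                 best_epoch = best$epoch, config = cfg,
                 drug_ids = drugs$drug_id, preps = preps),
            class = "ddi_fit")
}

#' @export
print.ddi_fit <- function(x, ...) {
  cat("<ddi_fit> trained", max(x$history$epoch), "epochs; best epoch",
      x$best_epoch, "\n")
  print(utils::tail(x$history, 3))
  invisible(x)
}

#' Predict interaction probabilities for drug pairs
#'
#' @param object A `ddi_fit`.
#' @param pairs Pair tibble (`label` optional).
#' @param ... Unused.
#' @return The pair tibble with `probability` and `predicted_label`
#'   (threshold 0.5) columns appended.
#' @export
predict.ddi_fit <- function(object, pairs, ...) {
  sc <- predict_scores(object$model$params, object$preps, pairs,
                       object$config)
  dplyr::mutate(tibble::as_tibble(pairs), probability = sc,
                predicted_label = as.integer(sc >= 0.5))
}

#' Evaluate a fitted model on a test split
#'
#' Accuracy and F1 at threshold 0.5; AUROC by the rank statistic (ties count
#' half). AUROC is reported as `NA` if the test split has one class only.
#'
#' @param fit A `ddi_fit`.
#' @param test_pairs Pair tibble with labels.
#' @return A one-row tibble: `acc`, `auroc`, `f1`, `n`.
#' @export
evaluate_ddi <- function(fit, test_pairs) {
  stopifnot(nrow(test_pairs) >= 1L)
  sc <- predict_scores(fit$model$params, fit$preps, test_pairs, fit$config)
  metric_row(sc, test_pairs$label)
}

#' Run the full repeated-split experiment
#'
#' For each of `n_repeats` consecutive seeds: split the pairs 8:1:1, train,
#' and evaluate on the held-out test split; metrics are averaged across runs.
#'
#' @param drugs Drug table.
#' @param pairs Full pair table.
#' @param config A [model_config()].
#' @param quiet Suppress per-epoch logging.
#' @return A `ddi_report`: tibbles `runs` (per-run metrics) and `summary`
#'   (their arithmetic means), plus the resolved config.
#' @export
run_experiment <- function(drugs, pairs, config = model_config(),
                           quiet = TRUE) {
  runs <- NULL
  fits <- list()
  for (i in seq_len(config$train$n_repeats)) {
    seed_i <- config$train$seed + i - 1L
    cfg_i <- config
    cfg_i$train$seed <- seed_i
    sp <- split_dataset(pairs, ratios = cfg_i$train$split, seed = seed_i,
                        fraction = cfg_i$train$dataset_fraction)
    fit <- fit_ddi(drugs, sp$train, sp$valid, config = cfg_i, quiet = quiet)
    m <- evaluate_ddi(fit, sp$test)
    runs <- dplyr::bind_rows(runs, dplyr::mutate(m, run = i, seed = seed_i,
                                                 .before = 1))
    fits[[i]] <- fit
  }
  structure(list(
    runs = runs,
    summary = dplyr::summarise(runs, dplyr::across(c(acc, auroc, f1), mean),
                               n_runs = dplyr::n()),
    config = config, fits = fits
  ), class = "ddi_report")
}

#' @export
print.ddi_report <- function(x, ...) {
  cat("<ddi_report>", nrow(x$runs), "run(s)\n")
  print(x$summary)
  invisible(x)
}

#' Channel ablation study
#'
#' Runs the seven channel-toggle variants — the full three-channel model, the
#' three dual-view models (`no_seq`, `no_graph`, `no_semantic`) and the three
#' single-view models (`seq_only`, `graph_only`, `semantic_only`) — under an
#' identical seed and split, and tabulates their test metrics.
#'
#' @inheritParams run_experiment
#' @param variants Subset of variant names to run (default: all seven).
#' @return A `ddi_ablation`: tibble `results` with one row per variant
#'   (metrics and final training loss) and the list of fits.
#' @export
ablation_variants <- function() {
  list(
    full = c(seq = TRUE, graph = TRUE, semantic = TRUE),
    no_seq = c(seq = FALSE, graph = TRUE, semantic = TRUE),
    no_graph = c(seq = TRUE, graph = FALSE, semantic = TRUE),
    no_semantic = c(seq = TRUE, graph = TRUE, semantic = FALSE),
    seq_only = c(seq = TRUE, graph = FALSE, semantic = FALSE),
    graph_only = c(seq = FALSE, graph = TRUE, semantic = FALSE),
    semantic_only = c(seq = FALSE, graph = FALSE, semantic = TRUE)
  )
}

#' @rdname ablation_variants
#' @export
ablate <- function(drugs, pairs, config = model_config(),
                   variants = names(ablation_variants()), quiet = TRUE) {
  defs <- ablation_variants()[variants]
  sp <- split_dataset(pairs, ratios = config$train$split,
                      seed = config$train$seed,
                      fraction = config$train$dataset_fraction)
  res <- NULL
  fits <- list()
  for (nm in names(defs)) {
    cfg <- config
    cfg$channels <- as.list(defs[[nm]])
    cfg <- validate_config(cfg)
    fit <- fit_ddi(drugs, sp$train, sp$valid, config = cfg, quiet = quiet)
    m <- evaluate_ddi(fit, sp$test)
    res <- dplyr::bind_rows(res, dplyr::mutate(
      m, variant = nm,
      channels = paste(names(defs[[nm]])[defs[[nm]]], collapse = "+"),
      train_loss_final = fit$history$train_loss[nrow(fit$history)],
      .before = 1))
    fits[[nm]] <- fit
  }
  structure(list(results = res, splits = sp, config = config, fits = fits),
            class = "ddi_ablation")
}

#' @export
print.ddi_ablation <- function(x, ...) {
  cat("<ddi_ablation>\n")
  print(x$results)
  invisible(x)
}

#' Save / load a checkpoint
#'
#' A checkpoint bundles the trained parameters, the resolved configuration
#' and the substructure vocabulary in one file.
#'
#' @param fit A `ddi_fit`.
#' @param path Destination file.
#' @export
save_checkpoint <- function(fit, path) {
  saveRDS(list(params = fit$model$params, config = fit$config,
               vocab = fit$model$vocab, best_epoch = fit$best_epoch,
               history = fit$history), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @param drugs Drug table used to rebuild per-drug features.
#' @export
load_checkpoint <- function(path, drugs) {
  ck <- readRDS(path)
  model <- ddi_model(drugs, ck$config, vocab = ck$vocab)
  model$params <- ck$params
  preps <- prepare_drugs(drugs, ck$vocab, ck$config, model$dict)
  structure(list(model = model, params_final = ck$params,
                 history = ck$history, best_epoch = ck$best_epoch,
                 config = ck$config, drug_ids = drugs$drug_id, preps = preps),
            class = "ddi_fit")
}
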