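#' Model configuration
#'
#' Collects every hyperparameter of the three-channel model and the training
#' protocol, including the gap-filling defaults, so a run is fully described
#' by its config. Defaults: Adam with learning rate 1e-4, batch size 16,
#' 50 epochs; sequence channel = transformer with 8 heads (internal width 80 =
#' 8 x 10, projected to 75), 2 layers, token length k = 50; graph channel =
#' 2 message-passing layers, message size 25, output 75; semantic channel =
#' 3 attention blocks, 8 heads, hidden 256, ProbSparse factor c = 5; fusion
#' width 75; random 8:1:1 splits, 5 repeated runs.
#'
#' @param ... Named overrides of any default (nested lists are merged).
#' @return An object of class `ddi_config`.
#' @export
#' @examples
#' cfg <- model_config(train = list(epochs = 5), channels = list(seq = FALSE))
#' cfg$train$epochs
model_config <- function(...) {
  cfg <- list(
    seq = list(
      k = 50L,            # max substructure tokens per drug
      d_model = 80L,      # 8 heads x 10; projected to d_out after pooling
      n_heads = 8L,
      n_layers = 2L,
      d_ff = 160L,
      dropout = 0.1,
      d_out = 75L
    ),
    graph = list(
      hidden = 75L,       # node state size r
      msg = 25L,          # message vector size
      edge_dim = 25L,
      att_hidden = 32L,
      K = 2L,             # message-passing layers (MP-num)
      d_out = 75L,
      scalar_gate = FALSE # Hadamard (per-dimension) readout gate by default
    ),
    semantic = list(
      hidden = 256L,
      n_heads = 8L,
      n_blocks = 3L,
      d_ff = 256L,
      degree_clip = 10L,  # degrees above this share a bucket
      spatial_clip = 20L, # shortest-path distances above this share a bucket
      probsparse_c = 5,   # query budget u = ceil(c * ln n)
      probsparse_min_atoms = 8L,  # below this, full attention
      d_out = 75L
    ),
    fusion = list(width = 75L),
    decoder = list(hidden1 = 256L, hidden2 = 64L, symmetric = FALSE),
    channels = list(seq = TRUE, graph = TRUE, semantic = TRUE),
    tokenizer = list(max_merges = 3000L, min_frequency = 2L),
    train = list(
      learning_rate = 1e-4,
      batch_size = 16L,
      epochs = 50L,
      n_repeats = 5L,
      split = c(train = 0.8, valid = 0.1, test = 0.1),
      dataset_fraction = 1.0,
      seed = 1L
    ),
    dictionaries_version = "1"
  )
  overrides <- list(...)
  for (nm in names(overrides)) {
    if (is.list(cfg[[nm]]) && is.list(overrides[[nm]])) {
      cfg[[nm]] <- modifyList(cfg[[nm]], overrides[[nm]])
    } else {
      cfg[[nm]] <- overrides[[nm]]
    }
  }
  validate_config(structure(cfg, class = "ddi_config"))
}

validate_config <- function(cfg) {
  with(cfg, {
    if (seq$d_model %% seq$n_heads != 0L) {
      abort("seq$d_model must be divisible by seq$n_heads.",
            class = "ddifuse_config_error")
    }
    if (semantic$hidden %% semantic$n_heads != 0L) {
      abort("semantic$hidden must be divisible by semantic$n_heads.",
            class = "ddifuse_config_error")
    }
    if (!any(unlist(channels))) {
      abort("At least one channel must be enabled.",
            class = "ddifuse_config_error")
    }
    if (abs(sum(train$split) - 1) > 1e-8) {
      abort("Split ratios must sum to 1.", class = "ddifuse_config_error")
    }
    if (train$dataset_fraction <= 0 || train$dataset_fraction > 1) {
      abort("dataset_fraction must be in (0, 1].",
            class = "ddifuse_config_error")
    }
  })
  cfg
}

#' @export
print.ddi_config <- function(x, ...) {
  ch <- names(x$channels)[unlist(x$channels)]
  cat("<ddi_config> channels:", paste(ch, collapse = "+"),
      "| lr", x$train$learning_rate, "| batch", x$train$batch_size,
      "| epochs", x$train$epochs, "\n")
  invisible(x)
}

#' Read / write a configuration as YAML
#'
#' @param cfg A `ddi_config`.
#' @param path File path.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$train$split <- setNames(as.numeric(unlist(raw$train$split)),
                              c("train", "valid", "test"))
  do.call(model_config, raw)
}
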