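#' @section Synthetic benchmark:
#' The generator builds chemically valid toy drugs from a motif grammar:
#' a random alkyl scaffold (a carbon chain) with zero to two functional-group
#' motifs grafted at valence-legal positions (as branches or chain ends).
#' Pair labels come from a planted, symmetric interaction rule — by default a
#' pair interacts iff one drug carries a carboxyl group and the other an
#' amine — with negatives sampled to exact class balance. Because the signal
#' is substructure presence, it is in principle detectable by all three
#' encoding channels, making the benchmark a fair end-to-end learnability
#' probe; it makes no attempt to mimic real pharmaceutical chemistry.
#' @name synthetic-data
NULL

default_motifs <- function() {
  c(carboxyl = "C(=O)O", amine = "N", hydroxyl = "O", chloro = "Cl",
    aryl = "c1ccccc1")
}

#' Generate a synthetic drug table
#'
#' @param n_drugs Number of drugs (>= 4).
#' @param motifs Named character vector of SMILES fragments.
#' @param scaffold_range Length range (in carbons) of the alkyl scaffold.
#' @param max_motifs Maximum motifs grafted per drug (0 to 2 are sampled).
#' @param seed Integer seed; the output is a deterministic function of it.
#' @return A tibble with `drug_id`, `smiles` and one logical `has_<motif>`
#'   column per motif (construction metadata used by [generate_pairs()]).
#' @export
#' @examples
#' drugs <- generate_drugs(n_drugs = 10, seed = 1)
#' drugs$smiles[1:3]
generate_drugs <- function(n_drugs = 200L, motifs = default_motifs(),
                           scaffold_range = c(3L, 8L), max_motifs = 2L,
                           seed = 1L) {
  stopifnot(n_drugs >= 4L, length(motifs) >= 1L)
  set.seed(seed)
  ids <- sprintf("D%04d", seq_len(n_drugs))
  has <- matrix(FALSE, n_drugs, length(motifs),
                dimnames = list(NULL, names(motifs)))
  smiles <- character(n_drugs)
  for (i in seq_len(n_drugs)) {
    len <- sample(seq(scaffold_range[1L], scaffold_range[2L]), 1L)
    k <- sample(0:max_motifs, 1L, prob = c(0.3, 0.4, 0.3)[1:(max_motifs + 1L)])
    picked <- if (k > 0L) sample(names(motifs), k) else character(0)
    branches <- rep("", len)
    tail_frag <- ""
    for (m in picked) {
      pos <- sample(len, 1L)
      frag <- motifs[[m]]
      if (pos == len && tail_frag == "") {
        tail_frag <- frag                   # continue the chain end
      } else {
        branches[pos] <- paste0(branches[pos], "(", frag, ")")
      }
      has[i, m] <- TRUE
    }
    smiles[i] <- paste0(paste(paste0("C", branches), collapse = ""), tail_frag)
  }
  out <- tibble::tibble(drug_id = ids, smiles = smiles)
  for (m in names(motifs)) out[[paste0("has_", m)]] <- has[, m]
  out
}

#' Generate a balanced pair table from a planted interaction rule
#'
#' Positives are unordered drug pairs satisfying the rule (drug A carries
#' `rule[1]` and drug B carries `rule[2]`, symmetrized); negatives are drawn
#' uniformly from non-satisfying pairs to exact balance. Optional label noise
#' flips each label independently.
#'
#' @param drugs A [generate_drugs()] table with its `has_*` metadata.
#' @param n_pairs Total pairs (half positive, half negative).
#' @param rule Character vector of two motif names.
#' @param noise Label flip probability in `[0, 1)` (default 0).
#' @param seed Integer seed.
#' @return A tibble `drug_id_1`, `drug_id_2`, `label`, with an attribute
#'   `rule` recording the planted rule.
#' @export
generate_pairs <- function(drugs, n_pairs = 2000L, rule = c("carboxyl", "amine"),
                           noise = 0, seed = 1L) {
  stopifnot(length(rule) == 2L, noise >= 0, noise < 1)
  set.seed(seed)
  cols <- paste0("has_", rule)
  miss <- setdiff(cols, names(drugs))
  if (length(miss)) {
    abort(paste0("Drug table lacks motif metadata column(s): ",
                 paste(miss, collapse = ", ")),
          class = "ddifuse_missing_column")
  }
  n <- nrow(drugs)
  a <- drugs[[cols[1L]]]
  b <- drugs[[cols[2L]]]
  sat <- (outer(a, b, `&`) | outer(b, a, `&`))
  idx <- which(upper.tri(sat), arr.ind = TRUE)
  pos_idx <- idx[sat[idx], , drop = FALSE]
  neg_idx <- idx[!sat[idx], , drop = FALSE]
  half <- n_pairs %/% 2L
  if (nrow(pos_idx) < half) {
    abort(sprintf("Only %d positive pairs available, %d needed.",
                  nrow(pos_idx), half),
          class = "ddifuse_insufficient_positives")
  }
  if (nrow(neg_idx) < n_pairs - half) {
    abort(sprintf("Only %d negative pairs available, %d needed.",
                  nrow(neg_idx), n_pairs - half),
          class = "ddifuse_insufficient_negatives")
  }
  pos <- pos_idx[sample(nrow(pos_idx), half), , drop = FALSE]
  neg <- neg_idx[sample(nrow(neg_idx), n_pairs - half), , drop = FALSE]
  tbl <- tibble::tibble(
    drug_id_1 = drugs$drug_id[c(pos[, 1L], neg[, 1L])],
    drug_id_2 = drugs$drug_id[c(pos[, 2L], neg[, 2L])],
    label = rep(c(1L, 0L), c(nrow(pos), nrow(neg)))
  )
  tbl <- tbl[sample(nrow(tbl)), ]
  if (noise > 0) {
    flip <- runif(nrow(tbl)) < noise
    tbl$label <- ifelse(flip, 1L - tbl$label, tbl$label)
  }
  attr(tbl, "rule") <- rule
  tbl
}

#' Generate a full synthetic benchmark
#'
#' Convenience wrapper producing the drug table, the balanced pair table and
#' a metadata record (motif assignments and the planted rule).
#'
#' @inheritParams generate_drugs
#' @inheritParams generate_pairs
#' @return A list with `drugs`, `pairs`, and `meta`.
#' @export
synthetic_dataset <- function(n_drugs = 200L, n_pairs = 2000L,
                              rule = c("carboxyl", "amine"), noise = 0,
                              seed = 1L) {
  drugs <- generate_drugs(n_drugs = n_drugs, seed = seed)
  pairs <- generate_pairs(drugs, n_pairs = n_pairs, rule = rule,
                          noise = noise, seed = seed + 1L)
  list(drugs = drugs, pairs = pairs,
       meta = list(rule = rule, noise = noise, seed = seed))
}

#' Write drug/pair tables and the metadata sidecar
#'
#' @param x A [synthetic_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly. Files: `drugs.csv` (`drug_id,smiles`),
#'   `pairs.csv`, and `meta.yaml` (motif assignments and the planted rule).
#' @export
write_synthetic_dataset <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(x$drugs[, c("drug_id", "smiles")],
                   file.path(dir, "drugs.csv"))
  readr::write_csv(x$pairs, file.path(dir, "pairs.csv"))
  meta <- x$meta
  hascols <- grep("^has_", names(x$drugs), value = TRUE)
  meta$motifs <- setNames(
    lapply(hascols, function(cc) x$drugs$drug_id[x$drugs[[cc]]]),
    sub("^has_", "", hascols)
  )
  yaml::write_yaml(meta, file.path(dir, "meta.yaml"))
  invisible(dir)
}
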