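#' @section Substructure tokenization:
#' SMILES strings are first split into base symbols (multi-character element
#' symbols such as `Cl`/`Br`, bracket atoms `[...]` as a single symbol,
#' two-digit ring closures `%nn`, and every other character on its own), then
#' a frequent-consecutive-subsequence vocabulary is mined by greedy adjacent
#' pair merging: at each step the most frequent adjacent token pair across the
#' corpus is merged into one token, until `max_merges` merges have been made
#' or no pair reaches `min_frequency`. Ties break lexicographically, so the
#' vocabulary is a deterministic function of the corpus and parameters.
#' Merges never cross the `.` fragment separator, keeping substructures
#' chemically contiguous.
#' @name fcs-tokenizer
NULL

# PAD and UNK occupy ids 0 and 1; real tokens start at id 2.
PAD_ID <- 0L
UNK_ID <- 1L

# Pair keys join two tokens with the unit separator so boundaries between
# multi-character tokens stay unambiguous.
PAIR_SEP <- "\x1f"

#' Split a SMILES string into base symbols
#'
#' Concatenating the returned tokens reproduces the input exactly.
#'
#' @param smiles A single SMILES string.
#' @return Character vector of base tokens.
#' @export
#' @examples
#' base_tokenize("CCl")      # c("C", "Cl")
#' base_tokenize("[Na+].O")  # c("[Na+]", ".", "O")
base_tokenize <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || !nzchar(smiles)) {
    abort("`smiles` must be a non-empty string.",
          class = "ddifuse_unparsable_smiles")
  }
  pattern <- "\\[[^\\]]*\\]|Cl|Br|%[0-9]{2}|."
  m <- gregexpr(pattern, smiles, perl = TRUE)[[1L]]
  toks <- regmatches(smiles, list(m))[[1L]]
  if (paste(toks, collapse = "") != smiles) {
    abort(paste0("SMILES could not be tokenized: ", smiles),
          class = "ddifuse_unparsable_smiles")
  }
  toks
}

# Count adjacent token pairs in a list of token vectors, never across ".".
count_pairs <- function(seqs) {
  keys <- unlist(lapply(seqs, function(s) {
    if (length(s) < 2L) return(character(0))
    a <- s[-length(s)]; b <- s[-1L]
    ok <- a != "." & b != "."
    paste(a[ok], b[ok], sep = PAIR_SEP)
  }))
  if (!length(keys)) return(integer(0))
  table(keys)
}

apply_merge <- function(s, left, right, merged) {
  n <- length(s)
  if (n < 2L) return(s)
  out <- character(n)
  i <- 1L; j <- 0L
  while (i <= n) {
    if (i < n && s[i] == left && s[i + 1L] == right) {
      j <- j + 1L; out[j] <- merged; i <- i + 2L
    } else {
      j <- j + 1L; out[j] <- s[i]; i <- i + 1L
    }
  }
  out[seq_len(j)]
}

#' Build a frequent-consecutive-subsequence vocabulary
#'
#' @param corpus Character vector of SMILES strings.
#' @param max_merges Maximum number of pair merges (default 3000).
#' @param min_frequency A pair must occur at least this often to merge
#'   (default 2).
#' @return An object of class `fcs_vocabulary`: a token table (tibble with
#'   `token`, `id`, `frequency`), the ordered merge history (tibble with
#'   `left`, `right`, `frequency` at merge time), and the mining parameters.
#'   Ids 0 and 1 are reserved for PAD and UNK.
#' @export
#' @examples
#' v <- build_vocabulary(c("CCO", "CCN", "CCC"), max_merges = 1)
#' v$merges  # the single merge is "C" + "C" -> "CC"
build_vocabulary <- function(corpus, max_merges = 3000L, min_frequency = 2L) {
  if (!length(corpus)) {
    abort("Corpus is empty.", class = "ddifuse_empty_corpus")
  }
  stopifnot(max_merges >= 0L, min_frequency >= 1L)
  seqs <- lapply(corpus, base_tokenize)
  merges <- tibble::tibble(left = character(0), right = character(0),
                           frequency = integer(0))
  for (step in seq_len(max_merges)) {
    pc <- count_pairs(seqs)
    if (!length(pc)) break
    best_n <- max(pc)
    if (best_n < min_frequency) break
    cand <- sort(names(pc)[pc == best_n])[1L]  # lexicographic tie-break
    lr <- strsplit(cand, PAIR_SEP, fixed = TRUE)[[1L]]
    merges <- tibble::add_row(merges, left = lr[1L], right = lr[2L],
                              frequency = as.integer(best_n))
    seqs <- lapply(seqs, apply_merge, left = lr[1L], right = lr[2L],
                   merged = paste0(lr[1L], lr[2L]))
  }
  tok_freq <- table(unlist(seqs))
  tokens <- sort(names(tok_freq))
  vocab <- tibble::tibble(
    token = c("<pad>", "<unk>", tokens),
    id = seq(0L, length(tokens) + 1L),
    frequency = c(0L, 0L, as.integer(tok_freq[tokens]))
  )
  structure(list(vocab = vocab, merges = merges,
                 max_merges = as.integer(max_merges),
                 min_frequency = as.integer(min_frequency)),
            class = "fcs_vocabulary")
}

#' @export
print.fcs_vocabulary <- function(x, ...) {
  cat("<fcs_vocabulary> ", nrow(x$vocab), " tokens (", nrow(x$merges),
      " merges, min_frequency=", x$min_frequency, ")\n", sep = "")
  invisible(x)
}

# Tokenize a SMILES with a vocabulary's merge history (greedy, in order).
merge_tokenize <- function(smiles, vocab) {
  s <- base_tokenize(smiles)
  m <- vocab$merges
  for (i in seq_len(nrow(m))) {
    s <- apply_merge(s, m$left[i], m$right[i], paste0(m$left[i], m$right[i]))
  }
  s
}

#' Encode a SMILES as a fixed-length substructure token sequence
#'
#' Applies the vocabulary's merge history, maps tokens to ids (unknown base
#' symbols become UNK), truncates to length `k` and pads with PAD.
#'
#' @param smiles A single SMILES string.
#' @param vocab A [build_vocabulary()] result.
#' @param k Fixed sequence length (default 50).
#' @return A `token_sequence`: list with integer `ids` (length `k`),
#'   `true_length`, and the pre-truncation `tokens`.
#' @export
encode_tokens <- function(smiles, vocab, k = 50L) {
  stopifnot(inherits(vocab, "fcs_vocabulary"), k >= 1L)
  toks <- merge_tokenize(smiles, vocab)
  ids <- vocab$vocab$id[match(toks, vocab$vocab$token)]
  ids[is.na(ids)] <- UNK_ID
  tl <- min(length(ids), k)
  out <- rep(PAD_ID, k)
  out[seq_len(tl)] <- ids[seq_len(tl)]
  structure(list(ids = as.integer(out), true_length = as.integer(tl),
                 tokens = toks), class = "token_sequence")
}

#' Decode token ids back to a string
#'
#' Concatenates the token strings of non-PAD ids; with no truncation this
#' reproduces the encoded SMILES exactly.
#'
#' @param ids Integer token ids.
#' @param vocab The vocabulary used to encode.
#' @return A single string.
#' @export
decode_tokens <- function(ids, vocab) {
  ids <- ids[ids != PAD_ID]
  paste(vocab$vocab$token[match(ids, vocab$vocab$id)], collapse = "")
}

#' Write / read a vocabulary file
#'
#' Plain text: header lines (`#` prefixed) record the mining parameters and
#' merge history; then one `token<TAB>id<TAB>frequency` line per token.
#'
#' @param vocab An `fcs_vocabulary`.
#' @param path File path.
#' @export
write_vocabulary <- function(vocab, path) {
  hdr <- c(paste0("#max_merges\t", vocab$max_merges),
           paste0("#min_frequency\t", vocab$min_frequency),
           sprintf("#merge\t%s\t%s\t%d", vocab$merges$left,
                   vocab$merges$right, vocab$merges$frequency))
  body <- sprintf("%s\t%d\t%d", vocab$vocab$token, vocab$vocab$id,
                  vocab$vocab$frequency)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  getv <- function(key) {
    x <- hdr[startsWith(hdr, paste0("#", key, "\t"))]
    sub(paste0("^#", key, "\t"), "", x)
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  mp <- strsplit(getv("merge"), "\t", fixed = TRUE)
  structure(list(
    vocab = tibble::tibble(
      token = vapply(parts, `[`, "", 1L),
      id = as.integer(vapply(parts, `[`, "", 2L)),
      frequency = as.integer(vapply(parts, `[`, "", 3L))
    ),
    merges = tibble::tibble(
      left = vapply(mp, `[`, "", 1L),
      right = vapply(mp, `[`, "", 2L),
      frequency = as.integer(vapply(mp, `[`, "", 3L))
    ),
    max_merges = as.integer(getv("max_merges")),
    min_frequency = as.integer(getv("min_frequency"))
  ), class = "fcs_vocabulary")
}
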