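#' @section Molecular graphs:
#' SMILES strings are parsed with RDKit (through the system `python`
#' interpreter) into heavy-atom molecular graphs: hydrogens stay implicit and
#' enter only through the per-atom bonded-hydrogen count. "Spatial" structure
#' is graph-topological — all-pairs shortest-path distances over bonds, with
#' the sentinel -1 for atoms in different connected components.
#' @name chem-io
NULL

python_bin <- function() {
  p <- Sys.which("python")
  if (!nzchar(p)) p <- Sys.which("python3")
  if (!nzchar(p)) {
    abort("No 'python' interpreter with RDKit found on PATH.",
          class = "ddifuse_missing_python")
  }
  p
}

featurize_script <- function() {
  system.file("python", "featurize_smiles.py", package = "ddifuse",
              mustWork = TRUE)
}

run_featurizer <- function(args, input_tbl) {
  infile <- tempfile(fileext = ".csv")
  on.exit(unlink(infile), add = TRUE)
  readr::write_csv(input_tbl, infile)
  out <- suppressWarnings(
    system2(python_bin(), c(featurize_script(), args[1L], shQuote(infile),
                            args[-1L]), stdout = TRUE, stderr = FALSE)
  )
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    abort("RDKit featurizer subprocess failed.", class = "ddifuse_rdkit_error")
  }
  out
}

# One batched RDKit call for a set of SMILES; per-SMILES results are cached
# for the session so repeated parses cost nothing.
rdkit_featurize <- function(smiles) {
  if (is.null(the_cache$feat)) the_cache$feat <- new.env(parent = emptyenv())
  todo <- unique(smiles[!vapply(smiles, function(s) {
    !is.null(the_cache$feat[[s]])
  }, logical(1))])
  if (length(todo)) {
    outdir <- tempfile("rdkit")
    on.exit(unlink(outdir, recursive = TRUE), add = TRUE)
    ids <- paste0("s", seq_along(todo))
    run_featurizer(c("featurize", shQuote(outdir)),
                   tibble::tibble(drug_id = ids, smiles = todo))
    ctypes_m <- readr::cols(drug_id = "c", status = "c", n_atoms = "i",
                            canonical_smiles = "c")
    mols <- readr::read_csv(file.path(outdir, "mols.csv"),
                            col_types = ctypes_m, progress = FALSE)
    atoms <- readr::read_csv(file.path(outdir, "atoms.csv"),
                             col_types = readr::cols(drug_id = "c",
                                                     hybridization = "c",
                                                     .default = "i"),
                             progress = FALSE)
    bonds <- readr::read_csv(file.path(outdir, "bonds.csv"),
                             col_types = readr::cols(drug_id = "c",
                                                     bond_type = "c",
                                                     stereo = "c",
                                                     .default = "i"),
                             progress = FALSE)
    for (i in seq_along(todo)) {
      id <- ids[i]
      the_cache$feat[[todo[i]]] <- list(
        mol = mols[mols$drug_id == id, ],
        atoms = atoms[atoms$drug_id == id, ],
        bonds = bonds[bonds$drug_id == id, ]
      )
    }
  }
  lapply(smiles, function(s) the_cache$feat[[s]])
}

#' Parse a SMILES string into an annotated molecular graph
#'
#' Produces a `mol_graph`: per-atom categorical feature codes (nine slots),
#' per-bond feature codes (three slots), symmetric adjacency, and the
#' all-pairs shortest-path structure from [all_pairs_shortest_paths()].
#' Atom order follows RDKit's ordering for the input SMILES. Unseen category
#' values map to the reserved UNK code of each slot.
#'
#' @param smiles A single SMILES string.
#' @param dictionaries Feature dictionaries, see [feature_dictionaries()].
#' @return An object of class `mol_graph` with fields `n`, `atom_codes`
#'   (n x 9), `bonds` (tibble: a1, a2 and three code columns), `adj`
#'   (neighbor lists sorted ascending), `adj_bond` (matching bond row ids),
#'   `spd`, `paths`, `degree`, and `canonical_smiles`.
#' @export
#' @examples
#' \dontrun{
#' g <- parse_smiles("CCO")
#' g$spd
#' }
parse_smiles <- function(smiles, dictionaries = feature_dictionaries()) {
  if (!is.character(smiles) || length(smiles) != 1L || !nzchar(smiles)) {
    abort("`smiles` must be a non-empty string.",
          class = "ddifuse_unparsable_smiles")
  }
  ft <- rdkit_featurize(smiles)[[1L]]
  status <- ft$mol$status
  if (identical(status, "unparsable")) {
    abort(paste0("SMILES does not parse: ", smiles),
          class = "ddifuse_unparsable_smiles")
  }
  if (identical(status, "empty")) {
    abort(paste0("SMILES parses to zero atoms: ", smiles),
          class = "ddifuse_empty_molecule")
  }
  n <- ft$mol$n_atoms
  atom_codes <- encode_atom_codes(ft$atoms)
  bonds <- ft$bonds
  bond_codes <- if (nrow(bonds)) encode_bond_codes(bonds) else
    matrix(integer(0), 0L, 3L, dimnames = list(NULL, c("bond_type", "stereo",
                                                       "conjugated")))
  adj <- replicate(n, integer(0), simplify = FALSE)
  adj_bond <- replicate(n, integer(0), simplify = FALSE)
  if (nrow(bonds)) {
    for (b in seq_len(nrow(bonds))) {
      a1 <- bonds$a1[b]; a2 <- bonds$a2[b]
      adj[[a1]] <- c(adj[[a1]], a2); adj_bond[[a1]] <- c(adj_bond[[a1]], b)
      adj[[a2]] <- c(adj[[a2]], a1); adj_bond[[a2]] <- c(adj_bond[[a2]], b)
    }
  }
  for (i in seq_len(n)) {
    o <- order(adj[[i]])
    adj[[i]] <- as.integer(adj[[i]][o])
    adj_bond[[i]] <- as.integer(adj_bond[[i]][o])
  }
  g <- structure(list(
    n = n,
    atom_codes = atom_codes,
    bonds = tibble::tibble(a1 = as.integer(bonds$a1 %||% integer(0)),
                           a2 = as.integer(bonds$a2 %||% integer(0)),
                           bond_type = as.integer(bond_codes[, "bond_type"]),
                           stereo = as.integer(bond_codes[, "stereo"]),
                           conjugated = as.integer(bond_codes[, "conjugated"])),
    adj = adj,
    adj_bond = adj_bond,
    degree = vapply(adj, length, integer(1)),
    canonical_smiles = ft$mol$canonical_smiles,
    smiles = smiles
  ), class = "mol_graph")
  sp <- all_pairs_shortest_paths(g)
  g$spd <- sp$spd
  g$paths <- sp$paths
  g
}

#' @export
print.mol_graph <- function(x, ...) {
  cat("<mol_graph> ", x$n, " atoms, ", nrow(x$bonds), " bonds: ",
      x$smiles, "\n", sep = "")
  invisible(x)
}

#' Parse every drug in a drug table
#'
#' @param drugs A tibble/data frame with columns `drug_id` and `smiles`.
#' @param dictionaries See [feature_dictionaries()].
#' @return A named list of `mol_graph` objects keyed by `drug_id`.
#' @export
parse_drugs <- function(drugs, dictionaries = feature_dictionaries()) {
  check_drug_table(drugs)
  rdkit_featurize(drugs$smiles)  # one batched subprocess call warms the cache
  setNames(lapply(drugs$smiles, parse_smiles, dictionaries = dictionaries),
           drugs$drug_id)
}

#' All-pairs shortest paths over the bond graph
#'
#' Breadth-first search from every atom, visiting neighbors in ascending atom
#' index so tie-breaking is deterministic. For each ordered reachable pair one
#' shortest path is returned as the list of traversed bond row indices; the
#' path for (x, y) is computed from min(x, y) and mirrored, so the per-pair
#' path choice is symmetric. Unreachable pairs get distance -1 and an empty
#' path; the diagonal is 0 with an empty path.
#'
#' @param graph A `mol_graph` (the `spd`/`paths` fields are ignored).
#' @return A list with `spd` (n x n integer matrix) and `paths` (list of
#'   lists of integer vectors of bond row ids).
#' @export
all_pairs_shortest_paths <- function(graph) {
  n <- graph$n
  spd <- matrix(-1L, n, n)
  diag(spd) <- 0L
  paths <- replicate(n, replicate(n, integer(0), simplify = FALSE),
                     simplify = FALSE)
  for (r in seq_len(n)) {
    dist <- rep(-1L, n)
    par <- integer(n)
    par_bond <- integer(n)
    dist[r] <- 0L
    queue <- integer(n); qh <- 1L; qt <- 1L
    queue[1L] <- r
    while (qh <= qt) {
      v <- queue[qh]; qh <- qh + 1L
      nb <- graph$adj[[v]]
      for (j in seq_along(nb)) {
        w <- nb[j]
        if (dist[w] < 0L) {
          dist[w] <- dist[v] + 1L
          par[w] <- v
          par_bond[w] <- graph$adj_bond[[v]][j]
          qt <- qt + 1L
          queue[qt] <- w
        }
      }
    }
    for (y in seq_len(n)) {
      if (y == r || dist[y] < 0L) next
      if (y < r) next  # fill from the lower root and mirror below
      spd[r, y] <- dist[y]
      spd[y, r] <- dist[y]
      pb <- integer(dist[y])
      v <- y
      for (s in seq(dist[y], 1L)) {
        pb[s] <- par_bond[v]
        v <- par[v]
      }
      paths[[r]][[y]] <- pb
      paths[[y]][[r]] <- rev(pb)
    }
  }
  list(spd = spd, paths = paths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_drug_table <- function(drugs) {
  miss <- setdiff(c("drug_id", "smiles"), names(drugs))
  if (length(miss)) {
    abort(paste0("Drug table is missing column(s): ",
                 paste(miss, collapse = ", ")),
          class = "ddifuse_missing_column")
  }
  dup <- unique(drugs$drug_id[duplicated(drugs$drug_id)])
  if (length(dup)) {
    abort(paste0("Duplicate drug_id(s): ", paste(head(dup, 5), collapse = ", ")),
          class = "ddifuse_duplicate_drug_id")
  }
  invisible(drugs)
}

#' Read drug and pair tables
#'
#' Drug tables are delimited text with header columns `drug_id,smiles`; pair
#' tables have `drug_id_1,drug_id_2,label` with binary integer labels. The
#' delimiter (comma or tab) is detected from the file.
#'
#' @param path Path to the file.
#' @param drugs For `read_pair_table`, an optional drug table used to check
#'   that every referenced id resolves.
#' @return A tibble of drug or pair records, in file order.
#' @export
read_drug_table <- function(path) {
  tbl <- readr::read_delim(path, delim = detect_delim(path),
                           col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  check_drug_table(tbl)
  tibble::tibble(drug_id = tbl$drug_id, smiles = tbl$smiles)
}

#' @rdname read_drug_table
#' @export
read_pair_table <- function(path, drugs = NULL) {
  tbl <- readr::read_delim(path, delim = detect_delim(path),
                           col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  miss <- setdiff(c("drug_id_1", "drug_id_2", "label"), names(tbl))
  if (length(miss)) {
    abort(paste0("Pair table is missing column(s): ",
                 paste(miss, collapse = ", ")),
          class = "ddifuse_missing_column")
  }
  lab <- suppressWarnings(as.integer(tbl$label))
  bad <- is.na(lab) | !(lab %in% c(0L, 1L)) | tbl$label != as.character(lab)
  if (any(bad)) {
    abort(paste0("Non-binary label(s) in pair table, e.g. '",
                 tbl$label[which(bad)[1L]], "'"),
          class = "ddifuse_non_binary_label")
  }
  pairs <- tibble::tibble(drug_id_1 = tbl$drug_id_1,
                          drug_id_2 = tbl$drug_id_2, label = lab)
  if (!is.null(drugs)) check_pair_refs(pairs, drugs)
  pairs
}

check_pair_refs <- function(pairs, drugs) {
  unknown <- setdiff(unique(c(pairs$drug_id_1, pairs$drug_id_2)),
                     drugs$drug_id)
  if (length(unknown)) {
    abort(paste0("Pair table references unknown drug id(s): ",
                 paste(head(unknown, 5), collapse = ", ")),
          class = "ddifuse_unknown_drug_reference")
  }
  invisible(pairs)
}

detect_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}
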