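#' Categorical feature dictionaries for atoms and bonds
#'
#' Atoms carry nine integer category slots (atomic number class, chirality
#' tag, heavy-atom degree, formal charge, bonded-hydrogen count, radical
#' electron count, hybridization, aromatic flag, in-ring flag); bonds carry
#' three (bond type, stereochemistry, conjugation flag). Each slot is a fixed
#' enumeration with a reserved UNK code for out-of-dictionary values, so the
#' embedding tables have a stable, versioned layout.
#'
#' @return A list with elements `atom` and `bond` (each a named list of slot
#'   definitions with `size`; raw toolkit values map to 1-based codes
#'   internally), `atom_flat` / `bond_flat` (total one-hot widths), slot
#'   offsets for flattened embedding tables, and a `version` string.
#' @export
#' @examples
#' d <- feature_dictionaries()
#' d$atom_flat
feature_dictionaries <- function() {
  atom <- list(
    atomic_num    = list(size = 101L), # Z = 1..100, then UNK
    chirality     = list(size = 5L),   # unspecified, CW, CCW, other, UNK
    degree        = list(size = 8L),   # 0..6, UNK
    formal_charge = list(size = 8L),   # -3..+3, UNK
    num_h         = list(size = 6L),   # 0..4, UNK
    radicals      = list(size = 4L),   # 0..2, UNK
    hybridization = list(size = 7L),   # s, sp, sp2, sp3, sp3d, sp3d2, other
    aromatic      = list(size = 2L),
    in_ring       = list(size = 2L)
  )
  bond <- list(
    bond_type  = list(size = 5L),      # single, double, triple, aromatic, UNK
    stereo     = list(size = 7L),      # none, any, Z, E, cis, trans, UNK
    conjugated = list(size = 2L)
  )
  sizes_a <- vapply(atom, `[[`, integer(1), "size")
  sizes_b <- vapply(bond, `[[`, integer(1), "size")
  list(
    atom = atom,
    bond = bond,
    atom_sizes = sizes_a,
    bond_sizes = sizes_b,
    atom_offsets = c(0L, cumsum(sizes_a))[seq_along(sizes_a)],
    bond_offsets = c(0L, cumsum(sizes_b))[seq_along(sizes_b)],
    atom_flat = sum(sizes_a),
    bond_flat = sum(sizes_b),
    version = "1"
  )
}

# Map raw RDKit atom properties (a data frame) to an n x 9 matrix of 1-based
# codes within each slot's dictionary; out-of-range values get the UNK code.
encode_atom_codes <- function(raw) {
  clampi <- function(x, lo, hi, unk) ifelse(x >= lo & x <= hi, x - lo + 1L, unk)
  hyb_levels <- c("S", "SP", "SP2", "SP3", "SP3D", "SP3D2")
  hyb <- match(raw$hybridization, hyb_levels)
  hyb[is.na(hyb)] <- 7L
  cbind(
    atomic_num    = clampi(raw$atomic_num, 1L, 100L, 101L),
    chirality     = ifelse(raw$chirality %in% 0:2, raw$chirality + 1L,
                           ifelse(raw$chirality >= 0, 4L, 5L)),
    degree        = clampi(raw$degree, 0L, 6L, 8L),
    formal_charge = clampi(raw$formal_charge, -3L, 3L, 8L),
    num_h         = clampi(raw$num_h, 0L, 4L, 6L),
    radicals      = clampi(raw$radicals, 0L, 2L, 4L),
    hybridization = hyb,
    aromatic      = raw$aromatic + 1L,
    in_ring       = raw$in_ring + 1L
  )
}

# Map raw RDKit bond properties to an m x 3 matrix of 1-based codes.
encode_bond_codes <- function(raw) {
  bt <- match(raw$bond_type, c("SINGLE", "DOUBLE", "TRIPLE", "AROMATIC"))
  bt[is.na(bt)] <- 5L
  st <- match(raw$stereo, c("STEREONONE", "STEREOANY", "STEREOZ", "STEREOE",
                            "STEREOCIS", "STEREOTRANS"))
  st[is.na(st)] <- 7L
  cbind(bond_type = bt, stereo = st, conjugated = raw$conjugated + 1L)
}

# Flattened 1-based indices into a single embedding table whose rows stack all
# slots: index = slot offset + within-slot code.
flatten_codes <- function(codes, offsets) {
  out <- sweep(codes, 2L, as.integer(offsets), `+`)
  storage.mode(out) <- "integer"
  out
}
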