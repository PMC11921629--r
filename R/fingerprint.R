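# Binary 2048-bit fingerprints and Tanimoto similarity.
#
# Two kinds, matching the two uses downstream: a linear-path fingerprint
# (all simple bond paths of 1-7 bonds, hashed) feeding the confidence
# score, and a circular (Morgan-style, radius 2) fingerprint feeding the
# chemical-space projection and the similarity networks.

FP_NBITS <- 2048L

# deterministic, platform-independent string hash (31-adic, mod 2^31-1)
str_hash <- function(s) {
  h <- 0
  for (v in utf8ToInt(s)) h <- (h * 31 + v) %% 2147483647
  h
}

atom_label <- function(g, a) {
  paste0(g$elem[a], if (g$arom[a]) "a" else "", g$charge[a])
}

bond_label <- function(g, bi) {
  if (g$bonds$arom[bi]) "a" else as.character(g$bonds$order[bi])
}

enumerate_paths <- function(g, max_len = 7L) {
  ab <- atom_bonds(g)
  # atom-level (length-0) features keep single-atom molecules non-empty, so
  # identical molecules always reach similarity 1
  paths <- paste0("atom:", vapply(seq_len(n_atoms(g)), function(a)
    atom_label(g, a), character(1)))
  # DFS over simple bond paths; each path counted once (canonical direction)
  walk <- function(atoms, bonds) {
    if (length(bonds) >= 1L) {
      fwd <- paste(
        unlist(Map(function(i) c(atom_label(g, atoms[i]),
                                 if (i <= length(bonds)) bond_label(g, bonds[i])),
                   seq_along(atoms))), collapse = "|")
      rev_ <- paste(
        unlist(Map(function(i) c(atom_label(g, rev(atoms)[i]),
                                 if (i <= length(bonds)) bond_label(g, rev(bonds)[i])),
                   seq_along(atoms))), collapse = "|")
      paths <<- c(paths, if (fwd <= rev_) fwd else rev_)
    }
    if (length(bonds) == max_len) return()
    a <- atoms[length(atoms)]
    for (bi in ab[[a]]) {
      if (bi %in% bonds) next
      x <- if (g$bonds$a1[bi] == a) g$bonds$a2[bi] else g$bonds$a1[bi]
      if (x %in% atoms) next
      walk(c(atoms, x), c(bonds, bi))
    }
  }
  for (a in seq_len(n_atoms(g))) walk(a, integer(0))
  # each path was found from both ends; canonical direction dedups the label,
  # unique() dedups the enumeration
  unique(paths)
}

morgan_ids <- function(g, radius = 2L) {
  rm_ <- ring_membership(g)
  deg <- heavy_degree(g)
  ids <- vapply(seq_len(n_atoms(g)), function(a)
    str_hash(paste(g$elem[a], g$charge[a], deg[a], g$hcount[a],
                   g$arom[a], rm_$atom[a], sep = ",")), numeric(1))
  all_ids <- ids
  ab <- atom_bonds(g)
  for (r in seq_len(radius)) {
    ids <- vapply(seq_len(n_atoms(g)), function(a) {
      env <- sort(vapply(ab[[a]], function(bi) {
        x <- if (g$bonds$a1[bi] == a) g$bonds$a2[bi] else g$bonds$a1[bi]
        str_hash(paste(bond_label(g, bi), ids[x], sep = ":"))
      }, numeric(1)))
      str_hash(paste(c(ids[a], env), collapse = ";"))
    }, numeric(1))
    all_ids <- c(all_ids, ids)
  }
  all_ids
}

#' Compute a 2048-bit binary fingerprint
#'
#' @param mol a [MoleculeRecord] (or SMILES, sanitized on the fly)
#' @param kind `"path"` (simple bond paths of length 1-7, the confidence-score
#'   fingerprint) or `"circular"` (Morgan-style atom environments to radius 2)
#' @return a `Fingerprint`: logical vector of length 2048 with attributes
#'   `kind` and `params`
#' @export
fingerprint <- function(mol, kind = c("path", "circular")) {
  kind <- match.arg(kind)
  if (is.character(mol)) mol <- sanitize_molecule(mol)
  stopifnot(inherits(mol, "MoleculeRecord"), mol$heavy_atom_count >= 1L)
  g <- mol$graph
  feats <- if (kind == "path") vapply(enumerate_paths(g, 7L), str_hash, numeric(1))
           else morgan_ids(g, 2L)
  bits <- logical(FP_NBITS)
  if (length(feats)) bits[(feats %% FP_NBITS) + 1L] <- TRUE
  structure(bits, class = "Fingerprint", kind = kind,
            params = if (kind == "path") c(min_len = 1, max_len = 7)
                     else c(radius = 2))
}

#' Tanimoto similarity of two fingerprints
#'
#' `|A & B| / |A | B|`; defined as 0 (with a warning) when both bitsets are
#' empty.  Mismatched kinds or parameters are an error.
#'
#' @param a,b `Fingerprint` objects of the same kind and parameters
#' @return similarity in \[0, 1\]
#' @export
tanimoto <- function(a, b) {
  stopifnot(inherits(a, "Fingerprint"), inherits(b, "Fingerprint"))
  if (!identical(attr(a, "kind"), attr(b, "kind")) ||
      !identical(attr(a, "params"), attr(b, "params")))
    stop("tanimoto: fingerprints have different kind or parameters")
  u <- sum(a | b)
  if (u == 0L) {
    warning("tanimoto: both fingerprints empty; similarity defined as 0")
    return(0)
  }
  sum(a & b) / u
}
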