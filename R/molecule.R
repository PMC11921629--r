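# Molecule sanitization and the MoleculeRecord container.

#' MoleculeRecord: a sanitized small molecule
#'
#' A `MoleculeRecord` is the chemical unit every other module consumes:
#' the largest organic fragment of the input, dummy atoms replaced by
#' carbon, stereochemistry removed, charges neutralized where a
#' valence-legal neutral form exists, and the structure re-expressed as a
#' canonical stereo-free Kekulé SMILES (OpenBabel canonical order).
#'
#' @section Fields:
#' * `identifier` — caller-supplied id
#' * `structure` — canonical Kekulé SMILES; re-sanitizing it is a no-op
#' * `formula` — named integer vector, element -> count (hydrogens included)
#' * `heavy_atom_count` — number of non-hydrogen atoms
#' * `sanitized` — always `TRUE` for a constructed record
#' * `flags` — character vector of applied fixups (`salt_stripped`,
#'   `dummy_replaced`, `neutralized`, `permanent_charge`)
#' * `graph` — internal molecular graph (normalized aromatic form)
#' @name MoleculeRecord
NULL

normalize_graph <- function(g) {
  # graph -> (canonical kekulé string, canonical aromatic string, normalized graph)
  w <- write_smiles(g, with_maps = FALSE)
  # the aromatic canonical form is the unique representation; the Kekulé
  # structure string is derived from it (kekulizing the already-canonical
  # string keeps it unique per molecular graph)
  can_a <- ob_canonical_cached(w, kekule = FALSE)
  can_k <- if (is.na(can_a)) NA_character_
           else ob_canonical_cached(can_a, kekule = TRUE)
  if (is.na(can_k) || is.na(can_a) || !nzchar(can_k))
    mol_error("OpenBabel canonicalization failed", w)
  ng <- assign_hydrogens(kekulize(parse_smiles(can_a)))
  list(kekule = can_k, aromatic = can_a, graph = ng)
}

neutralize_graph <- function(g) {
  nb <- neighbors_of(g)
  changed <- FALSE
  permanent <- FALSE
  for (a in seq_len(n_atoms(g))) {
    ch <- g$charge[a]
    if (ch == 0L) next
    opp <- any(sign(g$charge[nb[[a]]]) == -sign(ch))
    if (opp) { permanent <- TRUE; next }   # charge-separated group (nitro, N-oxide)
    el <- g$elem[a]
    if (ch < 0L && el %in% c("O", "N", "S")) {
      g$hcount[a] <- g$hcount[a] + abs(ch)
      g$charge[a] <- 0L
      changed <- TRUE
    } else if (ch > 0L && el %in% c("N", "P") && g$hcount[a] >= ch) {
      g$hcount[a] <- g$hcount[a] - ch
      g$charge[a] <- 0L
      changed <- TRUE
    } else {
      permanent <- TRUE                    # e.g. quaternary ammonium
    }
  }
  list(graph = g, neutralized = changed, permanent = permanent)
}

#' Sanitize a structure string into a MoleculeRecord
#'
#' Applies, in order: SMILES parsing (stereochemistry dropped), dummy-atom
#' replacement by carbon, kekulization of flagged aromatic systems, salt
#' stripping (largest organic fragment kept), charge neutralization where a
#' valence-legal neutral form exists, and canonicalization.  Idempotent:
#' sanitizing the resulting `structure` reproduces it.
#'
#' @param raw structure string (SMILES; multi-fragment allowed)
#' @param identifier optional id carried into the record
#' @return a [MoleculeRecord]
#' @export
#' @examples
#' sanitize_molecule("CC(=O)[O-].[Na+]")$structure   # acetic acid
sanitize_molecule <- function(raw, identifier = NA_character_) {
  if (inherits(raw, "MoleculeRecord")) return(raw)
  g <- parse_smiles(raw)
  flags <- character(0)

  if (any(g$elem == "*")) {
    dummies <- g$elem == "*"
    g$elem[dummies] <- "C"
    g$hcount[dummies] <- NA_integer_   # refill from carbon valence
    flags <- c(flags, "dummy_replaced")
  }
  g$map <- rep(0L, n_atoms(g))
  g <- kekulize(g)
  g <- assign_hydrogens(g)

  comp <- mol_components(g)
  if (max(comp) > 1L) {
    sizes <- tabulate(comp)
    best <- which(sizes == max(sizes))
    if (length(best) > 1L) {
      has_c <- vapply(best, function(ci) any(g$elem[comp == ci] == "C"), logical(1))
      if (any(has_c)) best <- best[has_c]
    }
    if (length(best) > 1L) {
      keys <- vapply(best, function(ci)
        ob_canonical_cached(write_smiles(subgraph_mol(g, which(comp == ci)),
                                         with_maps = FALSE), kekule = TRUE),
        character(1))
      best <- best[order(keys)][1]
    }
    g <- subgraph_mol(g, which(comp == best[1]))
    flags <- c(flags, "salt_stripped")
  }

  nz <- neutralize_graph(g)
  g <- nz$graph
  if (nz$neutralized) flags <- c(flags, "neutralized")
  if (nz$permanent) flags <- c(flags, "permanent_charge")

  norm <- normalize_graph(g)
  structure(
    list(identifier = identifier,
         structure = norm$kekule,
         smiles_aromatic = norm$aromatic,
         formula = mol_formula(norm$graph),
         heavy_atom_count = n_atoms(norm$graph),
         sanitized = TRUE,
         flags = flags,
         graph = norm$graph),
    class = "MoleculeRecord"
  )
}

#' @export
print.MoleculeRecord <- function(x, ...) {
  cat("<MoleculeRecord> ", if (!is.na(x$identifier)) x$identifier else "",
      "\n  structure: ", x$structure,
      "\n  formula:   ", formula_string(x$formula),
      "  (", x$heavy_atom_count, " heavy atoms)\n", sep = "")
  if (length(x$flags)) cat("  flags:     ", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Canonical key of a molecule
#'
#' Two inputs receive the same key iff they describe the same molecular
#' graph after sanitization (atom-order permutations, alternative Kekulé
#' forms and aromatic/Kekulé spellings collapse).  Raw SMILES strings are
#' sanitized first.
#'
#' @param mol a [MoleculeRecord] or a SMILES string
#' @return character scalar, stable across runs
#' @export
canonical_key <- function(mol) {
  if (is.character(mol)) mol <- sanitize_molecule(mol)
  stopifnot(inherits(mol, "MoleculeRecord"))
  mol$structure
}
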