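# Rule application: rewrite a query molecule according to a reaction rule.
#
# Semantics (given one embedding phi of the rule's query pattern):
#   * bonds of the query between matched atom pairs that the pattern
#     constrains are removed, then the template's bonds are installed;
#   * template atoms without an atom map are created ex nihilo (they stem
#     from co-substrates, e.g. the water oxygen of a hydrolysis);
#   * pattern atoms whose map is absent from the template are deleted
#     (leaving groups fully contained in the reaction center);
#   * charges/elements of mapped atoms are taken from the template and
#     hydrogen counts of every touched atom are recomputed from standard
#     valences; untouched atoms keep their hydrogens;
#   * the rewritten graph is split into fragments, each fragment is
#     sanitized, and fragments are labelled main/secondary by the template
#     role of the atoms they contain.
# Chemically invalid outcomes (valence violations, canonicalization
# failures) are discarded and reported, never silently kept.

delete_atoms <- function(g, drop) {
  keep <- setdiff(seq_len(n_atoms(g)), drop)
  subgraph_mol(g, keep)
}

#' Apply a parsed rule to a query graph at one embedding
#'
#' @param qg normalized query molgraph
#' @param rule a `ReactionRule`
#' @param phi integer vector: pattern atom -> query atom
#' @return list(ok, main_graph, main_atoms, secondary_graphs, reason)
#' @keywords internal
apply_transform <- function(qg, rule, phi) {
  p <- rule$qpat
  tg <- rule$template
  n0 <- n_atoms(qg)
  g <- qg

  # map index -> query atom (via pattern), map index -> template atom
  pat_of_map <- stats::setNames(seq_along(p$map), p$map)
  timg <- integer(n_atoms(tg))        # template atom -> result-graph atom
  new_atoms <- integer(0)
  for (t in seq_len(n_atoms(tg))) {
    m <- tg$map[t]
    if (m > 0L) {
      pi_ <- pat_of_map[[as.character(m)]]
      if (is.null(pi_)) return(list(ok = FALSE, reason = "template map not in pattern"))
      timg[t] <- phi[pi_]
    } else {
      g$elem <- c(g$elem, tg$elem[t]); g$arom <- c(g$arom, FALSE)
      g$charge <- c(g$charge, tg$charge[t])
      g$hcount <- c(g$hcount, NA_integer_)
      g$map <- c(g$map, 0L)
      timg[t] <- length(g$elem)
      new_atoms <- c(new_atoms, timg[t])
    }
  }

  # Bonds whose mapped atom pair is present on both sides and unchanged keep
  # the query's bond (crucial for aromatic rings: the template's arbitrary
  # Kekulé alternation must not be spliced into a ring partially retained
  # from the query).  Everything else: pattern bonds are removed, template
  # bonds installed.
  pair_key <- function(x, y) paste(pmin(x, y), pmax(x, y))
  tpl_pairs <- if (nrow(tg$bonds))
    pair_key(timg[tg$bonds$a1], timg[tg$bonds$a2]) else character(0)
  kept <- character(0)
  if (nrow(p$bonds)) {
    pat_pairs <- pair_key(phi[p$bonds$a1], phi[p$bonds$a2])
    tpl_at <- match(pat_pairs, tpl_pairs)
    unchanged <- !is.na(tpl_at) &
      (p$bonds$arom |
       (!is.na(p$bonds$order) & tg$bonds$order[tpl_at] == p$bonds$order))
    kept <- pat_pairs[unchanged]
    drop_pairs <- pat_pairs[!unchanged]
    if (nrow(g$bonds) && length(drop_pairs)) {
      g$bonds <- g$bonds[!(pair_key(g$bonds$a1, g$bonds$a2) %in% drop_pairs),
                         , drop = FALSE]
    }
  }
  install <- if (nrow(tg$bonds)) !(tpl_pairs %in% kept) else logical(0)
  if (any(install)) {
    add <- data.frame(a1 = timg[tg$bonds$a1[install]],
                      a2 = timg[tg$bonds$a2[install]],
                      order = tg$bonds$order[install],
                      arom = rep(FALSE, sum(install)))
    {
      if (nrow(g$bonds)) {
        # drop any residual query bond on the same pair (e.g. the template
        # closes a ring over an unconstrained query bond)
        g$bonds <- g$bonds[!(pair_key(g$bonds$a1, g$bonds$a2) %in%
                             pair_key(add$a1, add$a2)), , drop = FALSE]
      }
      g$bonds <- rbind(g$bonds, add)
    }
  }
  rownames(g$bonds) <- NULL

  # element / charge rewrites; touched atoms get hydrogens recomputed
  touched <- new_atoms
  for (t in seq_len(n_atoms(tg))) {
    a <- timg[t]
    if (tg$map[t] > 0L) {
      g$elem[a] <- tg$elem[t]
      g$charge[a] <- tg$charge[t]
      touched <- c(touched, a)
    }
  }
  g$hcount[touched] <- NA_integer_

  # deletions: pattern maps without template counterpart
  gone <- setdiff(p$map, tg$map)
  drop <- phi[match(gone, p$map)]
  role_of <- rep(NA_character_, length(g$elem))
  role_of[timg] <- rule$frag_roles[mol_components(tg)]
  matched_atoms <- phi
  if (length(drop)) {
    keep <- setdiff(seq_along(g$elem), drop)
    g <- delete_atoms(g, drop)
    role_of <- role_of[keep]
  }

  g <- tryCatch(assign_hydrogens(g), error = function(e) NULL)
  if (is.null(g)) return(list(ok = FALSE, reason = "hydrogen assignment failed"))
  if (!valence_ok(g)) return(list(ok = FALSE, reason = "valence violation"))

  comp <- mol_components(g)
  frag_role <- vapply(seq_len(max(comp)), function(ci) {
    r <- role_of[comp == ci]
    if (any(r == "main", na.rm = TRUE)) "main"
    else if (any(!is.na(r))) "secondary"
    else "secondary"
  }, character(1))
  mains <- which(frag_role == "main")
  if (!length(mains)) return(list(ok = FALSE, reason = "no main-product fragment"))
  if (length(mains) > 1L) {
    sizes <- tabulate(comp)[mains]
    mains <- mains[which.max(sizes)]
  }
  list(ok = TRUE,
       main_graph = subgraph_mol(g, which(comp == mains)),
       secondary_graphs = lapply(setdiff(seq_len(max(comp)), mains),
                                 function(ci) subgraph_mol(g, which(comp == ci))),
       matched_atoms = sort(unique(matched_atoms)),
       reason = NA_character_)
}

# graph -> sanitized MoleculeRecord (NULL on failure)
graph_to_record <- function(g, identifier = NA_character_) {
  tryCatch(sanitize_molecule(write_smiles(g, with_maps = FALSE), identifier),
           error = function(e) NULL)
}
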