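# Reaction-pattern query side: constrained subgraph patterns and matching.
#
# Rules serialize their query side in a restricted SMARTS dialect that
# encodes exactly the per-atom context the rule generator records: element,
# aromaticity, charge, hydrogen count, heavy-atom degree and ring
# membership, e.g. `[c;H1;D2;+0;R:3]`.  The matcher is a VF2-style
# backtracking subgraph-embedding search over the package's molecular
# graphs.  (Catalog SMARTS for structural alerts use OpenBabel's full
# SMARTS engine instead; this dialect is only for rules.)

new_patgraph <- function(n = 0L) {
  structure(list(
    elem = rep(NA_character_, n), arom = rep(NA, n),
    charge = rep(NA_integer_, n), hcount = rep(NA_integer_, n),
    degree = rep(NA_integer_, n), inring = rep(NA, n),
    map = rep(0L, n),
    bonds = data.frame(a1 = integer(0), a2 = integer(0),
                       order = integer(0), arom = logical(0))
  ), class = "patgraph")
}

# build a fully-constrained pattern from `atoms` of a source molecule,
# recording each atom's context in the *whole* molecule (so boundary
# truncation shows up as a degree constraint, and severed ring-closure
# bonds are implied by degree + ring membership)
pattern_from_graph <- function(g, atoms) {
  deg <- heavy_degree(g)
  rm_ <- ring_membership(g)
  p <- new_patgraph(length(atoms))
  p$elem <- g$elem[atoms]
  p$arom <- g$arom[atoms]
  p$charge <- g$charge[atoms]
  p$hcount <- g$hcount[atoms]
  p$degree <- deg[atoms]
  p$inring <- rm_$atom[atoms]
  p$map <- seq_along(atoms)
  idx <- match(seq_len(n_atoms(g)), atoms)
  keep <- which(!is.na(idx[g$bonds$a1]) & !is.na(idx[g$bonds$a2]))
  p$bonds <- data.frame(a1 = idx[g$bonds$a1[keep]], a2 = idx[g$bonds$a2[keep]],
                        order = g$bonds$order[keep], arom = g$bonds$arom[keep])
  p
}

pat_atom_token <- function(p, a) {
  sym <- if (is.na(p$elem[a])) "*"
         else if (isTRUE(p$arom[a])) tolower(p$elem[a]) else p$elem[a]
  parts <- c(sym,
             if (!is.na(p$hcount[a])) paste0("H", p$hcount[a]),
             if (!is.na(p$degree[a])) paste0("D", p$degree[a]),
             if (!is.na(p$charge[a]))
               paste0(if (p$charge[a] >= 0) "+" else "-", abs(p$charge[a])),
             if (!is.na(p$inring[a])) if (p$inring[a]) "R" else "R0")
  paste0("[", paste(parts, collapse = ";"),
         if (p$map[a] > 0L) paste0(":", p$map[a]), "]")
}

pattern_to_smarts <- function(p) {
  atom_token <- function(a) pat_atom_token(p, a)
  bond_token <- function(bi) {
    if (p$bonds$arom[bi]) ":"
    else if (is.na(p$bonds$order[bi])) "~"
    else switch(p$bonds$order[bi], "-", "=", "#", "$")
  }
  g <- list(elem = p$elem, arom = p$arom, charge = p$charge,
            hcount = p$hcount, map = p$map, bonds = p$bonds)
  linearize_graph(g, atom_token, bond_token)
}

parse_smarts_bracket <- function(content, raw) {
  out <- list(elem = NA_character_, arom = NA, charge = NA_integer_,
              hcount = NA_integer_, degree = NA_integer_, inring = NA,
              map = 0L)
  mp <- regmatches(content, regexpr(":\\d+$", content))
  if (length(mp) && nzchar(mp)) {
    out$map <- as.integer(substring(mp, 2))
    content <- sub(":\\d+$", "", content)
  }
  # note: specific primitives (R, R0, Hn, Dn, charge) take precedence over
  # the element interpretation — 'R' alone is ring membership, never an element
  for (piece in strsplit(content, ";", fixed = TRUE)[[1]]) {
    if (piece == "*") next
    else if (piece == "R") out$inring <- TRUE
    else if (piece == "R0") out$inring <- FALSE
    else if (grepl("^H\\d*$", piece))
      out$hcount <- if (piece == "H") 1L else as.integer(substring(piece, 2))
    else if (grepl("^D\\d+$", piece)) out$degree <- as.integer(substring(piece, 2))
    else if (grepl("^[+-]\\d*$", piece)) {
      v <- if (nchar(piece) == 1L) 1L else as.integer(substring(piece, 2))
      out$charge <- if (substring(piece, 1, 1) == "-") -v else v
    }
    else if (grepl("^[A-Z][a-z]?$", piece)) { out$elem <- piece; out$arom <- FALSE }
    else if (grepl("^[a-z]{1,2}$", piece)) {
      out$elem <- paste0(toupper(substring(piece, 1, 1)), substring(piece, 2))
      out$arom <- TRUE
    }
    else mol_error(paste0("unsupported SMARTS primitive '", piece, "'"), raw)
  }
  out
}

#' Parse the rule SMARTS dialect into a pattern graph
#' @keywords internal
parse_smarts <- function(smarts) {
  s <- trimws(smarts)
  tok_re <- "\\[[^\\]]*\\]|Br|Cl|[BCNOPSFI]|[bcnops]|\\*|%\\d{2}|\\d|[-=#:~.()]"
  toks <- regmatches(s, gregexpr(tok_re, s, perl = TRUE))[[1]]
  if (sum(nchar(toks)) != nchar(s)) mol_error("unparseable SMARTS", s)

  p <- new_patgraph(0L)
  add <- function(at) {
    for (f in c("elem", "arom", "charge", "hcount", "degree", "inring", "map"))
      p[[f]] <<- c(p[[f]], at[[f]])
    length(p$elem)
  }
  prev <- NA_integer_; stack <- integer(0); pending <- NULL; ring <- list()
  bond_rows <- list()
  add_bond <- function(a1, a2, sym) {
    if (is.null(sym)) {
      both_arom <- isTRUE(p$arom[a1]) && isTRUE(p$arom[a2])
      row <- list(a1 = a1, a2 = a2,
                  order = if (both_arom) NA_integer_ else 1L, arom = both_arom)
    } else {
      row <- list(a1 = a1, a2 = a2,
                  order = switch(sym, "-" = 1L, "=" = 2L, "#" = 3L,
                                 ":" = NA_integer_, "~" = NA_integer_),
                  arom = identical(sym, ":"))
    }
    bond_rows[[length(bond_rows) + 1L]] <<- row
  }
  for (tok in toks) {
    if (tok == "(") stack <- c(stack, prev)
    else if (tok == ")") { prev <- stack[length(stack)]; stack <- stack[-length(stack)] }
    else if (tok == ".") { prev <- NA_integer_; pending <- NULL }
    else if (tok %in% c("-", "=", "#", ":", "~")) pending <- tok
    else if (grepl("^%?\\d+$", tok)) {
      lab <- sub("^%", "", tok)
      if (!is.null(ring[[lab]])) {
        op <- ring[[lab]]
        add_bond(op$atom, prev, if (!is.null(pending)) pending else op$sym)
        ring[[lab]] <- NULL; pending <- NULL
      } else { ring[[lab]] <- list(atom = prev, sym = pending); pending <- NULL }
    } else {
      at <- if (grepl("^\\[", tok))
        parse_smarts_bracket(substring(tok, 2, nchar(tok) - 1L), s)
      else {
        ar <- grepl("^[a-z]", tok) && tok != "*"
        el <- if (tok == "*") NA_character_
              else paste0(toupper(substring(tok, 1, 1)), substring(tok, 2))
        list(elem = el, arom = if (tok == "*") NA else ar,
             charge = NA_integer_, hcount = NA_integer_,
             degree = NA_integer_, inring = NA, map = 0L)
      }
      idx <- add(at)
      if (!is.na(prev)) add_bond(prev, idx, pending)
      pending <- NULL
      prev <- idx
    }
  }
  if (length(ring)) mol_error("unclosed ring bond in SMARTS", s)
  p$bonds <- if (length(bond_rows))
    do.call(rbind.data.frame, c(bond_rows, list(stringsAsFactors = FALSE)))
  else data.frame(a1 = integer(0), a2 = integer(0), order = integer(0),
                  arom = logical(0))
  p
}

#' Find all embeddings of a pattern in a molecular graph
#'
#' VF2-style backtracking; pattern components are matched sequentially on
#' disjoint atom sets.  Returns a list of integer vectors phi (pattern atom
#' -> molecule atom), deterministic in order.
#'
#' @param p patgraph
#' @param g kekulized molgraph with hydrogens assigned
#' @param max_embeddings cap on returned embeddings
#' @keywords internal
match_pattern <- function(p, g, max_embeddings = 256L) {
  np <- length(p$elem)
  if (np == 0L) return(list())
  deg <- heavy_degree(g)
  rm_ <- ring_membership(g)
  ab_g <- atom_bonds(g)

  atom_ok <- function(i, a) {
    (is.na(p$elem[i]) || p$elem[i] == g$elem[a]) &&
    (is.na(p$arom[i]) || p$arom[i] == g$arom[a]) &&
    (is.na(p$charge[i]) || p$charge[i] == g$charge[a]) &&
    (is.na(p$hcount[i]) || p$hcount[i] == g$hcount[a]) &&
    (is.na(p$degree[i]) || p$degree[i] == deg[a]) &&
    (is.na(p$inring[i]) || p$inring[i] == rm_$atom[a])
  }
  bond_ok <- function(bi_p, bi_g) {
    if (p$bonds$arom[bi_p]) return(g$bonds$arom[bi_g])
    if (is.na(p$bonds$order[bi_p])) return(TRUE)
    !g$bonds$arom[bi_g] && g$bonds$order[bi_g] == p$bonds$order[bi_p]
  }
  g_bond_between <- function(a, b) {
    for (bi in ab_g[[a]])
      if (g$bonds$a1[bi] + g$bonds$a2[bi] - a == b) return(bi)
    0L
  }

  # order pattern atoms: per component, BFS so each atom (after the first)
  # touches an earlier one
  pcomp <- mol_components(p)
  order_ <- integer(0)
  p_nb <- neighbors_of(p)
  for (ci in seq_len(max(pcomp))) {
    members <- which(pcomp == ci)
    queue <- members[1]; seen <- members[1]
    while (length(queue)) {
      a <- queue[1]; queue <- queue[-1]
      order_ <- c(order_, a)
      for (x in p_nb[[a]]) if (!(x %in% seen)) { seen <- c(seen, x); queue <- c(queue, x) }
    }
  }
  # pattern bonds from each atom to earlier-ordered atoms
  pos <- match(seq_len(np), order_)
  back_bonds <- lapply(seq_len(np), function(i) {
    bs <- which((p$bonds$a1 == i & pos[p$bonds$a2] < pos[i]) |
                (p$bonds$a2 == i & pos[p$bonds$a1] < pos[i]))
    bs
  })

  res <- list()
  phi <- rep(NA_integer_, np)
  used <- logical(n_atoms(g))
  recurse <- function(step) {
    if (length(res) >= max_embeddings) return()
    if (step > np) { res[[length(res) + 1L]] <<- phi; return() }
    i <- order_[step]
    bb <- back_bonds[[i]]
    cands <- if (length(bb)) {
      bi <- bb[1]
      anchor <- phi[p$bonds$a1[bi] + p$bonds$a2[bi] - i]
      nbrs <- ab_g[[anchor]]
      vapply(nbrs, function(x) g$bonds$a1[x] + g$bonds$a2[x] - anchor, integer(1))
    } else seq_len(n_atoms(g))
    for (a in cands) {
      if (used[a] || !atom_ok(i, a)) next
      ok <- TRUE
      for (bi in bb) {
        other <- phi[p$bonds$a1[bi] + p$bonds$a2[bi] - i]
        gb <- g_bond_between(a, other)
        if (gb == 0L || !bond_ok(bi, gb)) { ok <- FALSE; break }
      }
      if (!ok) next
      phi[i] <<- a; used[a] <<- TRUE
      recurse(step + 1L)
      phi[i] <<- NA_integer_; used[a] <<- FALSE
    }
  }
  recurse(1L)
  res
}
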