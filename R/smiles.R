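# Minimal molecular-graph kernel: SMILES tokenizer, parser and writer.
#
# The graph is heavy-atom only; hydrogens live in the per-atom `hcount`
# column (NA until assigned from valence rules).  Stereochemistry is
# deliberately dropped at parse time: every structure in this package is
# stereo-free by construction.  Aromaticity is carried as atom/bond flags;
# bond orders for aromatic bonds are assigned by `kekulize()`.

SMILES_TOKEN_RE <- paste0(
  "\\[[^\\]]*\\]|Br|Cl|", # bracket atoms, two-letter organic subset
  "[BCNOPSFI]|[bcnops]|\\*|", # one-letter organic subset, wildcard
  "%\\d{2}|\\d|", # ring bond labels
  "[-=#:$/\\\\.()]" # bonds, dot, branches
)

new_molgraph <- function() {
  list(
    elem = character(0), arom = logical(0), charge = integer(0),
    hcount = integer(0), map = integer(0),
    bonds = data.frame(a1 = integer(0), a2 = integer(0),
                       order = integer(0), arom = logical(0)),
    flags = character(0)
  )
}

n_atoms <- function(g) length(g$elem)

mol_error <- function(msg, smiles = NULL) {
  stop(structure(
    class = c("metabolizr_mol_error", "error", "condition"),
    list(message = paste0(msg, if (!is.null(smiles)) paste0(" [", smiles, "]")),
         call = NULL, smiles = smiles)
  ))
}

# parse the content of a bracket atom, e.g. "13CH2+:5"; chirality ignored
parse_bracket <- function(content, raw) {
  rest <- content
  eat <- function(re) {
    m <- regmatches(rest, regexpr(re, rest, perl = TRUE))
    if (length(m) && nzchar(m)) {
      rest <<- substring(rest, nchar(m) + 1L)
      m
    } else ""
  }
  eat("^\\d+")                                   # isotope, dropped
  sym <- eat("^([A-Z][a-z]?|[a-z]{1,2}|\\*)")
  if (!nzchar(sym)) mol_error(paste0("bad bracket atom [", content, "]"), raw)
  eat("^@@?((TH|AL|SP|TB|OH)\\d+)?")             # chirality, dropped
  h <- eat("^H\\d*")
  hcount <- if (!nzchar(h)) 0L else if (h == "H") 1L else as.integer(substring(h, 2))
  ch <- eat("^(\\+\\d+|-\\d+|\\++|-+)")
  charge <- if (!nzchar(ch)) 0L
    else if (grepl("^\\+\\d", ch)) as.integer(substring(ch, 2))
    else if (grepl("^-\\d", ch)) -as.integer(substring(ch, 2))
    else if (grepl("\\+", ch)) nchar(ch)
    else -nchar(ch)
  mp <- eat("^:\\d+")
  map <- if (nzchar(mp)) as.integer(substring(mp, 2)) else 0L
  if (nzchar(rest)) mol_error(paste0("trailing bracket content '", rest, "'"), raw)
  arom <- grepl("^[a-z]", sym)
  elem <- if (sym == "*") "*" else paste0(toupper(substring(sym, 1, 1)), substring(sym, 2))
  list(elem = elem, arom = arom, hcount = hcount, charge = charge, map = map)
}

#' Parse a SMILES string into a molecular graph
#'
#' Internal parser covering the organic subset, bracket atoms (isotope and
#' chirality are dropped), branches, ring closures (including `%nn`), dots,
#' explicit bonds and atom maps.  Aromatic atoms/bonds are flagged but bond
#' orders for them are only fixed by [kekulize()].
#'
#' @param smiles a single SMILES string
#' @return a `molgraph` list (atoms as parallel vectors plus a bond table)
#' @keywords internal
parse_smiles <- function(smiles) {
  if (length(smiles) != 1L || is.na(smiles) || !nzchar(trimws(smiles)))
    mol_error("empty or missing SMILES", smiles)
  s <- trimws(smiles)
  toks <- regmatches(s, gregexpr(SMILES_TOKEN_RE, s, perl = TRUE))[[1]]
  if (sum(nchar(toks)) != nchar(s))
    mol_error("unparseable SMILES", s)

  g <- new_molgraph()
  elem <- character(0); arom <- logical(0); charge <- integer(0)
  hcount <- integer(0); map <- integer(0)
  b_a1 <- integer(0); b_a2 <- integer(0); b_ord <- integer(0); b_arom <- logical(0)

  prev <- NA_integer_
  stack <- integer(0)
  pending <- NULL            # explicit bond symbol awaiting next atom
  ring <- list()             # label -> list(atom, sym)

  add_bond <- function(a1, a2, sym) {
    if (a1 == a2) mol_error("self bond", s)
    if (is.null(sym)) {
      if (arom[a1] && arom[a2]) { ord <- NA_integer_; ar <- TRUE }
      else { ord <- 1L; ar <- FALSE }
    } else {
      ord <- switch(sym, "-" = 1L, "/" = 1L, "\\" = 1L, "=" = 2L,
                    "#" = 3L, "$" = 4L, ":" = NA_integer_)
      ar <- identical(sym, ":")
    }
    b_a1 <<- c(b_a1, a1); b_a2 <<- c(b_a2, a2)
    b_ord <<- c(b_ord, ord); b_arom <<- c(b_arom, ar)
  }

  add_atom <- function(a) {
    elem <<- c(elem, a$elem); arom <<- c(arom, a$arom)
    charge <<- c(charge, a$charge); hcount <<- c(hcount, a$hcount)
    map <<- c(map, a$map)
    idx <- length(elem)
    if (!is.na(prev)) add_bond(prev, idx, pending)
    pending <<- NULL
    prev <<- idx
    idx
  }

  for (tok in toks) {
    if (tok == "(") {
      if (is.na(prev)) mol_error("branch with no preceding atom", s)
      stack <- c(stack, prev)
    } else if (tok == ")") {
      if (!length(stack)) mol_error("unmatched ')'", s)
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
    } else if (tok == ".") {
      prev <- NA_integer_; pending <- NULL
    } else if (tok %in% c("-", "=", "#", "$", ":", "/", "\\")) {
      pending <- tok
    } else if (grepl("^%?\\d+$", tok)) {
      lab <- sub("^%", "", tok)
      if (is.na(prev)) mol_error("ring closure with no preceding atom", s)
      if (!is.null(ring[[lab]])) {
        op <- ring[[lab]]
        sym <- if (!is.null(pending)) pending else op$sym
        if (!is.null(pending) && !is.null(op$sym) && pending != op$sym)
          mol_error(paste0("conflicting ring-bond symbols for label ", lab), s)
        add_bond(op$atom, prev, sym)
        ring[[lab]] <- NULL
        pending <- NULL
      } else {
        ring[[lab]] <- list(atom = prev, sym = pending)
        pending <- NULL
      }
    } else if (grepl("^\\[", tok)) {
      add_atom(parse_bracket(substring(tok, 2, nchar(tok) - 1L), s))
    } else {
      ar <- grepl("^[a-z]", tok)
      el <- if (tok == "*") "*" else paste0(toupper(substring(tok, 1, 1)), substring(tok, 2))
      add_atom(list(elem = el, arom = ar, hcount = NA_integer_, charge = 0L, map = 0L))
    }
  }
  if (length(stack)) mol_error("unmatched '('", s)
  if (length(ring)) mol_error("unclosed ring bond", s)
  if (!length(elem)) mol_error("no atoms", s)

  g$elem <- elem; g$arom <- arom; g$charge <- charge
  g$hcount <- hcount; g$map <- map
  g$bonds <- data.frame(a1 = b_a1, a2 = b_a2, order = b_ord, arom = b_arom)
  class(g) <- "molgraph"
  g
}

# adjacency as list of integer vectors (bond row indices per atom)
atom_bonds <- function(g) {
  ab <- vector("list", n_atoms(g))
  for (i in seq_len(nrow(g$bonds))) {
    ab[[g$bonds$a1[i]]] <- c(ab[[g$bonds$a1[i]]], i)
    ab[[g$bonds$a2[i]]] <- c(ab[[g$bonds$a2[i]]], i)
  }
  ab
}

neighbors_of <- function(g, ab = atom_bonds(g)) {
  lapply(seq_len(n_atoms(g)), function(a) {
    bs <- ab[[a]]
    ifelse(g$bonds$a1[bs] == a, g$bonds$a2[bs], g$bonds$a1[bs])
  })
}

heavy_degree <- function(g) {
  d <- integer(n_atoms(g))
  if (nrow(g$bonds)) {
    t1 <- tabulate(g$bonds$a1, n_atoms(g))
    t2 <- tabulate(g$bonds$a2, n_atoms(g))
    d <- t1 + t2
  }
  d
}

# connected components; returns integer component id per atom
mol_components <- function(g) {
  n <- n_atoms(g)
  comp <- integer(n)
  nb <- neighbors_of(g)
  cid <- 0L
  for (start in seq_len(n)) {
    if (comp[start] > 0L) next
    cid <- cid + 1L
    queue <- start
    comp[start] <- cid
    while (length(queue)) {
      a <- queue[1]; queue <- queue[-1]
      for (x in nb[[a]]) if (comp[x] == 0L) { comp[x] <- cid; queue <- c(queue, x) }
    }
  }
  comp
}

# extract induced subgraph on `atoms` (preserving their order)
subgraph_mol <- function(g, atoms) {
  idx <- match(seq_len(n_atoms(g)), atoms)
  keep <- !is.na(idx[g$bonds$a1]) & !is.na(idx[g$bonds$a2])
  out <- g
  out$elem <- g$elem[atoms]; out$arom <- g$arom[atoms]
  out$charge <- g$charge[atoms]; out$hcount <- g$hcount[atoms]
  out$map <- g$map[atoms]
  b <- g$bonds[keep, , drop = FALSE]
  b$a1 <- idx[b$a1]; b$a2 <- idx[b$a2]
  rownames(b) <- NULL
  out$bonds <- b
  out
}

ring_membership <- function(g) {
  # an atom/bond is in a ring iff the bond is not a bridge
  n <- n_atoms(g)
  nb <- atom_bonds(g)
  disc <- integer(n); low <- integer(n); timer <- 0L
  bridge <- logical(nrow(g$bonds))
  # iterative DFS with parent-bond tracking
  for (root in seq_len(n)) {
    if (disc[root] > 0L) next
    stack <- list(list(a = root, pb = 0L, i = 1L))
    timer <- timer + 1L; disc[root] <- low[root] <- timer
    while (length(stack)) {
      fr <- stack[[length(stack)]]
      a <- fr$a
      bs <- nb[[a]]
      if (fr$i <= length(bs)) {
        stack[[length(stack)]]$i <- fr$i + 1L
        bi <- bs[fr$i]
        if (bi == fr$pb) next
        x <- if (g$bonds$a1[bi] == a) g$bonds$a2[bi] else g$bonds$a1[bi]
        if (disc[x] == 0L) {
          timer <- timer + 1L; disc[x] <- low[x] <- timer
          stack[[length(stack) + 1L]] <- list(a = x, pb = bi, i = 1L)
        } else {
          low[a] <- min(low[a], disc[x])
          stack[[length(stack)]]$a <- a
        }
      } else {
        stack[[length(stack)]] <- NULL
        if (length(stack)) {
          pa <- stack[[length(stack)]]$a
          low[pa] <- min(low[pa], low[a])
          if (low[a] > disc[pa]) bridge[fr$pb] <- TRUE
        }
      }
    }
  }
  in_ring_bond <- !bridge & nrow(g$bonds) > 0
  in_ring_atom <- logical(n)
  if (nrow(g$bonds)) {
    rb <- which(in_ring_bond)
    in_ring_atom[g$bonds$a1[rb]] <- TRUE
    in_ring_atom[g$bonds$a2[rb]] <- TRUE
  }
  list(atom = in_ring_atom, bond = in_ring_bond)
}

#' Write a molecular graph as a (Kekulé) SMILES string
#'
#' All atoms are written in bracket form with explicit hydrogen counts so the
#' output is valence-unambiguous for any downstream reader.  Requires bond
#' orders to be assigned (run [kekulize()] and [assign_hydrogens()] first).
#'
#' @param g molgraph with assigned `hcount` and integer bond orders
#' @param with_maps write `:n` atom maps when present
#' @return single SMILES string (dot-separated if multi-fragment)
#' @keywords internal
write_smiles <- function(g, with_maps = TRUE) {
  if (any(is.na(g$bonds$order))) mol_error("write_smiles needs kekulized graph")
  if (any(is.na(g$hcount))) mol_error("write_smiles needs assigned hydrogens")
  atom_token <- function(a) {
    h <- g$hcount[a]
    ch <- g$charge[a]
    mp <- g$map[a]
    paste0("[", g$elem[a],
           if (h == 1L) "H" else if (h > 1L) paste0("H", h) else "",
           if (ch == 1L) "+" else if (ch > 1L) paste0("+", ch)
           else if (ch == -1L) "-" else if (ch < -1L) paste0("-", abs(ch)) else "",
           if (with_maps && mp > 0L) paste0(":", mp) else "",
           "]")
  }
  bond_token <- function(bi) switch(g$bonds$order[bi], "", "=", "#", "$")
  linearize_graph(g, atom_token, bond_token)
}

# shared DFS linearizer for molecule SMILES and pattern SMARTS output;
# token functions receive an atom index / bond row index
linearize_graph <- function(g, atom_token, bond_token) {
  n <- n_atoms(g)
  ab <- atom_bonds(g)

  # pass 1: classify bonds into DFS-tree bonds and ring-closure bonds
  visited <- logical(n)
  tree <- logical(max(nrow(g$bonds), 0L))
  seen_bond <- logical(max(nrow(g$bonds), 0L))
  roots <- integer(0)
  for (start in seq_len(n)) {
    if (visited[start]) next
    roots <- c(roots, start)
    stack <- start
    visited[start] <- TRUE
    while (length(stack)) {
      a <- stack[length(stack)]
      advanced <- FALSE
      for (bi in ab[[a]]) {
        if (seen_bond[bi]) next
        x <- if (g$bonds$a1[bi] == a) g$bonds$a2[bi] else g$bonds$a1[bi]
        seen_bond[bi] <- TRUE
        if (!visited[x]) {
          tree[bi] <- TRUE
          visited[x] <- TRUE
          stack <- c(stack, x)
          advanced <- TRUE
          break
        }
      }
      if (!advanced) stack <- stack[-length(stack)]
    }
  }
  ring_bonds <- which(!tree & seq_along(tree) <= nrow(g$bonds))
  ring_label <- integer(max(nrow(g$bonds), 0L))
  ring_label[ring_bonds] <- seq_along(ring_bonds)
  lab_tok <- function(lab) if (lab > 9L) paste0("%", sprintf("%02d", lab)) else as.character(lab)

  # pass 2: emit along tree bonds (iteratively — chains can be long);
  # ring-closure tokens at both endpoints
  emit <- function(root) {
    toks <- character(0)
    # frames: atom + its remaining child bonds
    child_bonds <- function(a, from_bond) {
      out <- integer(0)
      for (bi in ab[[a]]) {
        if (!tree[bi] || bi == from_bond) next
        x <- if (g$bonds$a1[bi] == a) g$bonds$a2[bi] else g$bonds$a1[bi]
        if (!is.na(parent_bond[x]) && parent_bond[x] == bi) out <- c(out, bi)
      }
      out
    }
    atom_out <- function(a) {
      s <- atom_token(a)
      for (bi in ab[[a]]) {
        if (ring_label[bi] > 0L)
          s <- paste0(s, bond_token(bi), lab_tok(ring_label[bi]))
      }
      s
    }
    stack <- list(list(a = root, kids = child_bonds(root, 0L)))
    toks <- atom_out(root)
    while (length(stack)) {
      fr <- stack[[length(stack)]]
      if (!length(fr$kids)) {
        stack[[length(stack)]] <- NULL
        if (length(stack)) {
          par <- stack[[length(stack)]]
          if (length(par$kids)) toks <- c(toks, ")")   # closed a branch
        }
        next
      }
      bi <- fr$kids[1]
      stack[[length(stack)]]$kids <- fr$kids[-1]
      x <- if (g$bonds$a1[bi] == fr$a) g$bonds$a2[bi] else g$bonds$a1[bi]
      if (length(fr$kids) > 1L) toks <- c(toks, "(")   # not the last child
      toks <- c(toks, bond_token(bi), atom_out(x))
      stack[[length(stack) + 1L]] <- list(a = x, kids = child_bonds(x, bi))
    }
    paste(toks, collapse = "")
  }

  # orient tree bonds: parent_bond[x] = tree bond connecting x to its parent
  parent_bond <- rep(NA_integer_, n)
  for (root in roots) {
    queue <- root
    while (length(queue)) {
      a <- queue[1]; queue <- queue[-1]
      for (bi in ab[[a]]) {
        if (!tree[bi]) next
        x <- if (g$bonds$a1[bi] == a) g$bonds$a2[bi] else g$bonds$a1[bi]
        if (x != root && is.na(parent_bond[x]) &&
            (is.na(parent_bond[a]) || parent_bond[a] != bi)) {
          parent_bond[x] <- bi
          queue <- c(queue, x)
        }
      }
    }
  }

  paste(vapply(roots, emit, character(1)), collapse = ".")
}
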