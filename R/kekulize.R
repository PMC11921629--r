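# Kekulization, implicit-hydrogen assignment and valence bookkeeping.
#
# Aromatic perception itself is delegated to OpenBabel (molecules are
# normalized through its canonical writer, so aromatic flags always arrive
# via lowercase SMILES); this module only has to turn flagged aromatic
# systems back into alternating single/double bonds so that valences and
# hydrogen counts are well defined.

DEFAULT_VALENCE <- list(
  B = 3L, C = 4L, N = 3L, O = 2L, P = c(3L, 5L), S = c(2L, 4L, 6L),
  F = 1L, Cl = 1L, Br = 1L, I = c(1L), Se = c(2L, 4L, 6L), Si = 4L,
  As = c(3L, 5L)
)

STANDARD_WEIGHTS <- c(
  H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Na = 22.990, Mg = 24.305, Si = 28.086, P = 30.974, S = 32.06,
  Cl = 35.453, K = 39.098, Ca = 40.078, Se = 78.971, Br = 79.904,
  I = 126.904, Fe = 55.845, Zn = 65.38, As = 74.922, Li = 6.94
)

valence_targets <- function(elem, charge) {
  base <- DEFAULT_VALENCE[[elem]]
  if (is.null(base)) return(0L)   # metals etc.: no implicit H
  if (charge == 0L) return(base)
  if (elem == "C") return(max(4L - abs(charge), 0L))
  if (elem == "B") return(if (charge < 0) 3L + abs(charge) else max(3L - charge, 0L))
  # N, P, O, S and congeners: cations gain a bond, anions lose one
  v <- base + charge
  v[v >= 0L]
}

#' Assign Kekulé bond orders to flagged aromatic systems
#'
#' Atoms that must carry one in-ring double bond are identified from element,
#' charge, hydrogen count and exocyclic bonds; a perfect matching over the
#' aromatic bonds then fixes alternation.  Fails (with a condition of class
#' `metabolizr_kekulize_error`) when no valid alternation exists.
#'
#' @param g molgraph from [parse_smiles()]
#' @return molgraph with all bond orders integer (aromatic flags retained)
#' @keywords internal
kekulize <- function(g) {
  arom_bonds <- which(g$bonds$arom | is.na(g$bonds$order))
  if (!length(arom_bonds)) return(g)
  # a flagged bond outside any ring (e.g. the biphenyl bridge, written as a
  # default bond between two aromatic atoms) is a plain single bond
  rm_ <- ring_membership(g)
  off_ring <- arom_bonds[!rm_$bond[arom_bonds]]
  if (length(off_ring)) {
    g$bonds$order[off_ring] <- 1L
    g$bonds$arom[off_ring] <- FALSE
    arom_bonds <- setdiff(arom_bonds, off_ring)
    if (!length(arom_bonds)) return(g)
  }
  g$bonds$arom[arom_bonds] <- TRUE
  deg <- heavy_degree(g)
  ab <- atom_bonds(g)

  # does atom a need one double bond within the aromatic system?
  needy <- vapply(seq_len(n_atoms(g)), function(a) {
    if (!g$arom[a]) return(FALSE)
    exo_double <- any(!is.na(g$bonds$order[ab[[a]]]) &
                      g$bonds$order[ab[[a]]] >= 2L)
    if (exo_double) return(FALSE)
    el <- g$elem[a]; ch <- g$charge[a]
    h <- g$hcount[a]; if (is.na(h)) h <- 0L
    sigma <- deg[a] + h
    if (el == "C") return(ch == 0L)
    if (el %in% c("N", "P", "As")) {
      if (ch == 0L) return(sigma == 2L)
      if (ch == 1L) return(sigma == 3L)
      return(FALSE)
    }
    if (el %in% c("O", "S", "Se")) return(ch == 1L)
    FALSE
  }, logical(1))

  # backtracking perfect matching over aromatic bonds restricted to needy atoms
  cand <- lapply(seq_len(n_atoms(g)), function(a) {
    if (!needy[a]) return(integer(0))
    bs <- ab[[a]][ab[[a]] %in% arom_bonds]
    bs[vapply(bs, function(bi) {
      x <- if (g$bonds$a1[bi] == a) g$bonds$a2[bi] else g$bonds$a1[bi]
      needy[x]
    }, logical(1))]
  })
  matched <- rep(NA_integer_, n_atoms(g))  # atom -> bond index
  solve <- function() {
    a <- which(needy & is.na(matched))[1]
    if (is.na(a)) return(TRUE)
    for (bi in cand[[a]]) {
      x <- if (g$bonds$a1[bi] == a) g$bonds$a2[bi] else g$bonds$a1[bi]
      if (!is.na(matched[x])) next
      matched[a] <<- bi; matched[x] <<- bi
      if (solve()) return(TRUE)
      matched[a] <<- NA_integer_; matched[x] <<- NA_integer_
    }
    FALSE
  }
  if (any(needy) && !solve())
    stop(structure(
      class = c("metabolizr_kekulize_error", "metabolizr_mol_error",
                "error", "condition"),
      list(message = "kekulization failed: no alternating bond assignment",
           call = NULL)
    ))
  dbl <- unique(matched[!is.na(matched)])
  g$bonds$order[arom_bonds] <- 1L
  g$bonds$order[dbl] <- 2L
  g
}

#' Fill implicit hydrogen counts from standard valences
#'
#' Atoms parsed from bracket notation keep their explicit counts; organic
#' subset atoms get the smallest standard valence that accommodates their
#' bond-order sum (charge-adjusted).
#'
#' @param g kekulized molgraph
#' @return molgraph with `hcount` fully assigned
#' @keywords internal
assign_hydrogens <- function(g) {
  if (any(is.na(g$bonds$order))) mol_error("assign_hydrogens needs kekulized graph")
  bsum <- numeric(n_atoms(g))
  for (i in seq_len(nrow(g$bonds))) {
    bsum[g$bonds$a1[i]] <- bsum[g$bonds$a1[i]] + g$bonds$order[i]
    bsum[g$bonds$a2[i]] <- bsum[g$bonds$a2[i]] + g$bonds$order[i]
  }
  for (a in seq_len(n_atoms(g))) {
    if (!is.na(g$hcount[a])) next
    tv <- valence_targets(g$elem[a], g$charge[a])
    fit <- tv[tv >= bsum[a]]
    g$hcount[a] <- if (length(fit)) as.integer(min(fit) - bsum[a]) else 0L
  }
  g
}

# TRUE when every atom's bond-order sum + hydrogens fits an allowed valence
valence_ok <- function(g) {
  bsum <- numeric(n_atoms(g))
  for (i in seq_len(nrow(g$bonds))) {
    bsum[g$bonds$a1[i]] <- bsum[g$bonds$a1[i]] + g$bonds$order[i]
    bsum[g$bonds$a2[i]] <- bsum[g$bonds$a2[i]] + g$bonds$order[i]
  }
  for (a in seq_len(n_atoms(g))) {
    tv <- valence_targets(g$elem[a], g$charge[a])
    if (identical(tv, 0L) && is.null(DEFAULT_VALENCE[[g$elem[a]]])) next
    tot <- bsum[a] + g$hcount[a]
    if (!tot %in% tv) return(FALSE)
  }
  TRUE
}

#' Elemental formula of a molecular graph
#'
#' @param g molgraph with assigned hydrogens
#' @return named integer vector, element -> count (includes H)
#' @keywords internal
mol_formula <- function(g) {
  f <- table(g$elem)
  out <- stats::setNames(as.integer(f), names(f))
  h <- sum(g$hcount)
  if (h > 0L) out["H"] <- (if ("H" %in% names(out)) out[["H"]] else 0L) + h
  out <- out[order(names(out))]
  # Hill order: C first, H second, rest alphabetical
  nm <- names(out)
  hill <- c(intersect(c("C", "H"), nm), setdiff(nm, c("C", "H")))
  out[hill]
}

formula_string <- function(f) {
  paste0(vapply(names(f), function(el)
    paste0(el, if (f[[el]] > 1L) f[[el]] else ""), character(1)), collapse = "")
}

mol_weight <- function(f) {
  w <- STANDARD_WEIGHTS[names(f)]
  if (anyNA(w)) mol_error(paste("no standard weight for",
                                paste(names(f)[is.na(w)], collapse = ",")))
  sum(w * as.numeric(f))
}
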