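# Physicochemical profiling, bioavailability classification, structural
# alerts, isotope patterns, deduplication, benchmark statistics and
# chemical-space projection.

#' Physicochemical descriptor profile
#'
#' Molecular weight from standard atomic weights; logP (Wildman-Crippen
#' style atomic contributions) and TPSA (Ertl) from OpenBabel's models;
#' hydrogen-bond donors = hydrogens on N/O, acceptors = N+O count (the
#' classic rule-of-five reading); rotatable bonds = non-ring single bonds
#' between two non-terminal heavy atoms, amide C-N excluded.
#'
#' @param mol [MoleculeRecord] or SMILES
#' @return list(molecular_weight, logp, tpsa, hbd, hba, rotatable_bonds)
#' @export
compute_descriptors <- function(mol) {
  if (is.character(mol)) mol <- sanitize_molecule(mol)
  g <- mol$graph
  props <- ob_properties(mol$smiles_aromatic)
  no <- g$elem %in% c("N", "O")
  rotb <- 0L
  if (nrow(g$bonds)) {
    rm_ <- ring_membership(g)
    deg <- heavy_degree(g)
    for (bi in seq_len(nrow(g$bonds))) {
      if (g$bonds$order[bi] != 1L || g$bonds$arom[bi] || rm_$bond[bi]) next
      a <- g$bonds$a1[bi]; b <- g$bonds$a2[bi]
      if (deg[a] < 2L || deg[b] < 2L) next
      amide <- function(c_, n_) {
        g$elem[n_] == "N" && g$elem[c_] == "C" &&
          any(vapply(atom_bonds(g)[[c_]], function(x)
            g$bonds$order[x] == 2L &&
              g$elem[g$bonds$a1[x] + g$bonds$a2[x] - c_] == "O", logical(1)))
      }
      if (amide(a, b) || amide(b, a)) next
      rotb <- rotb + 1L
    }
  }
  list(molecular_weight = mol_weight(mol$formula),
       logp = props$logP[1],
       tpsa = props$TPSA[1],
       hbd = sum(g$hcount[no]),
       hba = sum(no),
       rotatable_bonds = rotb)
}

#' Rule-of-five check
#'
#' Molecular weight <= 500 Da, logP <= 5, H-bond donors <= 5, H-bond
#' acceptors <= 10 (all boundaries inclusive); overall pass iff all four
#' hold.
#'
#' @param profile output of [compute_descriptors()]
#' @return list of four booleans plus `pass`
#' @export
lipinski_check <- function(profile) {
  out <- list(molecular_weight = profile$molecular_weight <= 500,
              logp = profile$logp <= 5,
              hbd = profile$hbd <= 5,
              hba = profile$hba <= 10)
  out$pass <- all(unlist(out))
  out
}

# Axis-aligned ellipses over the (TPSA, logP) plane.  The white
# (passive-absorption) ellipse spans the published ranges (TPSA 0-142,
# logP -2.3..6.8); the yolk (brain-penetration) ellipse is slightly
# narrower than the published ranges (TPSA ~2-74, logP 0.8..5.2) so that
# it is geometrically contained in the white region, as in the original
# rotated-ellipse plot.
BOILED_EGG_ELLIPSES <- list(
  white = c(cx = 71, cy = 2.25, rx = 71, ry = 4.55),
  yolk = c(cx = 38, cy = 3.0, rx = 36, ry = 2.2)
)

#' Bioavailability classification in the (TPSA, logP) plane
#'
#' Point-in-ellipse tests against the passive gastrointestinal-absorption
#' and brain-penetration regions; the brain region is contained in the
#' absorption region, so `brain_penetration` implies
#' `gastrointestinal_absorption`.
#'
#' @param profile output of [compute_descriptors()]
#' @return list(gastrointestinal_absorption, brain_penetration)
#' @export
boiled_egg_classify <- function(profile) {
  inside <- function(e) {
    ((profile$tpsa - e[["cx"]]) / e[["rx"]])^2 +
      ((profile$logp - e[["cy"]]) / e[["ry"]])^2 <= 1
  }
  list(gastrointestinal_absorption = inside(BOILED_EGG_ELLIPSES$white),
       brain_penetration = inside(BOILED_EGG_ELLIPSES$yolk))
}

.alert_cache <- new.env(parent = emptyenv())

load_alert_catalog <- function(catalog = c("pains", "brenk")) {
  catalog <- match.arg(catalog)
  hit <- .alert_cache[[catalog]]
  if (!is.null(hit)) return(hit)
  path <- system.file("extdata", paste0("alerts_", catalog, ".tsv"),
                      package = "metabolizr")
  if (!nzchar(path))
    path <- file.path("inst", "extdata", paste0("alerts_", catalog, ".tsv"))
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines)]   # header comments; '#6' in SMARTS is data
  df <- utils::read.delim(text = paste(lines, collapse = "\n"),
                          stringsAsFactors = FALSE)
  # validate every pattern once, at load time
  for (i in seq_len(nrow(df))) {
    ok <- tryCatch({ ob_smarts_count("CCO", df$smarts[i]); TRUE },
                   error = function(e) FALSE)
    if (!ok) stop("malformed alert SMARTS '", df$name[i], "' in ", catalog)
  }
  assign(catalog, df, envir = .alert_cache)
  df
}

#' Structural alert screening
#'
#' Substructure screening against packaged alert catalogs: a curated
#' subset of the pan-assay interference (PAINS) motifs and of the
#' undesirable-moiety (Brenk) list, matched with OpenBabel's SMARTS
#' engine.
#'
#' @param mol [MoleculeRecord] or SMILES
#' @param catalog `"pains"` or `"brenk"`
#' @return character vector of matched alert names (possibly empty)
#' @export
structural_alerts <- function(mol, catalog = c("pains", "brenk")) {
  catalog <- match.arg(catalog)
  if (is.character(mol)) mol <- sanitize_molecule(mol)
  df <- load_alert_catalog(catalog)
  if (!nrow(df)) return(character(0))
  hits <- ob_smarts_count(mol$smiles_aromatic, df$smarts)
  df$name[hits > 0L]
}

ISOTOPES <- list(
  H = list(mass = c(1.0078250319, 2.0141017780), ab = c(0.999885, 0.000115)),
  C = list(mass = c(12, 13.0033548378), ab = c(0.9893, 0.0107)),
  N = list(mass = c(14.0030740052, 15.0001088984), ab = c(0.99636, 0.00364)),
  O = list(mass = c(15.9949146221, 16.99913150, 17.9991604),
           ab = c(0.99757, 0.00038, 0.00205)),
  P = list(mass = 30.97376151, ab = 1),
  S = list(mass = c(31.97207069, 32.97145850, 33.96786683, 35.96708088),
           ab = c(0.9499, 0.0075, 0.0425, 0.0001)),
  F = list(mass = 18.99840320, ab = 1),
  Cl = list(mass = c(34.96885271, 36.96590260), ab = c(0.7576, 0.2424)),
  Br = list(mass = c(78.9183376, 80.916291), ab = c(0.5069, 0.4931)),
  I = list(mass = 126.904473, ab = 1)
)

parse_formula_string <- function(s) {
  m <- gregexpr("([A-Z][a-z]?)(\\d*)", s, perl = TRUE)[[1]]
  toks <- regmatches(s, gregexpr("[A-Z][a-z]?\\d*", s, perl = TRUE))[[1]]
  if (sum(nchar(toks)) != nchar(s)) stop("unparseable formula: ", s)
  out <- integer(0)
  for (tk in toks) {
    el <- regmatches(tk, regexpr("^[A-Z][a-z]?", tk))
    n <- sub("^[A-Z][a-z]?", "", tk)
    n <- if (nzchar(n)) as.integer(n) else 1L
    out[el] <- (if (el %in% names(out)) out[[el]] else 0L) + n
  }
  out
}

#' Isotope pattern of an elemental formula
#'
#' Convolution of per-element isotope distributions, aggregated into
#' nominal-mass peaks (mass reported as the abundance-weighted mean within
#' each peak), truncated below a relative abundance of 1e-6 and
#' renormalized to sum to one.
#'
#' @param formula named integer vector (as in a [MoleculeRecord]) or a
#'   formula string like `"C6H12O6"`
#' @return data.frame(mass, probability), most abundant nominal peaks,
#'   ordered by mass
#' @export
isotope_pattern <- function(formula) {
  if (is.character(formula)) formula <- parse_formula_string(formula)
  bad <- setdiff(names(formula), names(ISOTOPES))
  if (length(bad)) stop("unsupported element(s): ", paste(bad, collapse = ","))
  # distribution over nominal mass shift: probability and weighted mass
  probs <- 1; masses <- 0          # indexed by nominal shift 0,1,2,...
  for (el in names(formula)) {
    iso <- ISOTOPES[[el]]
    shift <- round(iso$mass - iso$mass[1])
    for (k in seq_len(formula[[el]])) {
      np <- numeric(length(probs) + max(shift))
      nm <- numeric(length(np))
      for (i in seq_along(probs)) {
        if (probs[i] <= 0) next
        for (j in seq_along(iso$mass)) {
          t <- i + shift[j]
          w <- probs[i] * iso$ab[j]
          np[t] <- np[t] + w
          nm[t] <- nm[t] + w * (masses[i] + iso$mass[j])
        }
      }
      keep <- np > 0
      probs <- np
      masses <- ifelse(keep, nm / pmax(np, 1e-300), 0)
      # drop negligible tail to keep the convolution short
      last <- max(which(probs > 1e-12))
      probs <- probs[seq_len(last)]; masses <- masses[seq_len(last)]
    }
  }
  rel <- probs / max(probs)
  keep <- rel >= 1e-6
  probs <- probs[keep]; masses <- masses[keep]
  probs <- probs / sum(probs)
  data.frame(mass = masses, probability = probs)
}

#' Deduplicate molecules by canonical structure
#'
#' @param mols list of [MoleculeRecord] (or character vector of SMILES)
#' @return data.frame(key, identifier (first seen), multiplicity);
#'   multiplicities sum to the input size
#' @export
dedupe_structures <- function(mols) {
  if (is.character(mols)) mols <- lapply(mols, sanitize_molecule)
  keys <- vapply(mols, canonical_key, character(1))
  ids <- vapply(mols, function(m)
    if (is.na(m$identifier)) m$structure else m$identifier, character(1))
  first <- !duplicated(keys)
  data.frame(key = keys[first],
             identifier = ids[first],
             multiplicity = as.integer(table(keys)[keys[first]]),
             stringsAsFactors = FALSE)
}

#' Upper-whisker benchmark statistics of a score distribution
#'
#' Q1/Q3 by linear interpolation between order statistics (the common
#' quantile default) or classic Tukey hinges; the upper whisker is
#' Q3 + 1.5 IQR and `n_above` counts scores strictly above it.
#'
#' @param scores numeric vector (>= 4 finite values)
#' @param convention `"linear"` or `"tukey"`
#' @return list(q1, q3, iqr, upper_whisker, n_total, n_above)
#' @export
whisker_threshold <- function(scores, convention = c("linear", "tukey")) {
  convention <- match.arg(convention)
  scores <- scores[is.finite(scores)]
  if (length(scores) < 4L) stop("need at least 4 finite scores")
  if (convention == "linear") {
    qs <- stats::quantile(scores, c(0.25, 0.75), names = FALSE, type = 7)
  } else {
    fn <- stats::fivenum(scores)
    qs <- fn[c(2, 4)]
  }
  iqr <- qs[2] - qs[1]
  uw <- qs[2] + 1.5 * iqr
  list(q1 = qs[1], q3 = qs[2], iqr = iqr, upper_whisker = uw,
       n_total = length(scores), n_above = sum(scores > uw))
}

#' Exact-match evaluation of predictions against a reference
#'
#' A reference metabolite is matched iff some prediction for the same
#' query has an identical canonical key; `strict` additionally requires
#' reaction-id agreement where the reference carries one.
#'
#' @param predictions data.frame from [predict_metabolites()] (rows for
#'   one or many queries)
#' @param reference data.frame with columns query_id, product_smiles
#'   (and optionally reaction_id)
#' @param strict also require reaction_id agreement
#' @return list(n_matched, fraction, matched (data.frame))
#' @export
evaluate_exact_matches <- function(predictions, reference, strict = FALSE) {
  if (!nrow(reference)) stop("empty reference set")
  ref_keys <- if ("product_key" %in% names(reference)) reference$product_key
    else vapply(reference$product_smiles, canonical_key, character(1),
                USE.NAMES = FALSE)
  pred_keys <- if (nrow(predictions))
    vapply(predictions$predicted_smiles, canonical_key, character(1),
           USE.NAMES = FALSE) else character(0)
  matched <- logical(nrow(reference))
  for (i in seq_len(nrow(reference))) {
    hit <- nrow(predictions) > 0 &
      predictions$query_id == reference$query_id[i] & pred_keys == ref_keys[i]
    if (strict && "reaction_id" %in% names(reference) &&
        !is.na(reference$reaction_id[i]))
      hit <- hit & sub("__(fwd|rev)$", "", predictions$reaction_id) ==
        reference$reaction_id[i]
    matched[i] <- any(hit)
  }
  list(n_matched = sum(matched),
       fraction = mean(matched),
       matched = reference[matched, , drop = FALSE])
}

#' Project molecules into 2-D chemical space
#'
#' Principal components of the binary circular-fingerprint matrix.
#'
#' @param mols list of [MoleculeRecord] or character vector of SMILES
#' @return list(coords = data.frame(id, pc1, pc2), explained_variance
#'   (length 2), degenerate (TRUE when all fingerprints are identical))
#' @export
project_chemical_space <- function(mols) {
  if (is.character(mols)) mols <- lapply(mols, sanitize_molecule)
  stopifnot(length(mols) >= 3L)
  fps <- do.call(rbind, lapply(mols, function(m)
    as.numeric(fingerprint(m, "circular"))))
  ids <- vapply(mols, function(m)
    if (is.na(m$identifier)) m$structure else m$identifier, character(1))
  keep <- which(apply(fps, 2, stats::var) > 0)
  if (!length(keep)) {
    return(list(coords = data.frame(id = ids, pc1 = 0, pc2 = 0),
                explained_variance = c(NA_real_, NA_real_),
                degenerate = TRUE))
  }
  pc <- stats::prcomp(fps[, keep, drop = FALSE], center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  k2 <- min(2L, ncol(pc$x))
  coords <- data.frame(id = ids, pc1 = pc$x[, 1],
                       pc2 = if (k2 >= 2) pc$x[, 2] else 0)
  list(coords = coords,
       explained_variance = c(ev[1], if (k2 >= 2) ev[2] else 0),
       degenerate = FALSE)
}
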