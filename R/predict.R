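# Metabolite prediction: rule application, confidence scoring, and
# per-atom metabolic accessibility.

.fp_cache <- new.env(parent = emptyenv())

path_fp_of <- function(smiles_or_record) {
  key <- if (inherits(smiles_or_record, "MoleculeRecord"))
    smiles_or_record$structure else smiles_or_record
  hit <- .fp_cache[[key]]
  if (!is.null(hit)) return(hit)
  fp <- fingerprint(smiles_or_record, "path")
  assign(key, fp, envir = .fp_cache)
  fp
}

#' Apply one reaction rule to a query molecule
#'
#' Every distinct embedding of the rule's query pattern yields one
#' application (symmetric sites give distinct outcomes); duplicates with
#' the same main-product key and matched-atom set are collapsed.
#' Chemically invalid products are discarded and reported via the
#' `dropped` attribute.  A non-matching query returns an empty list.
#'
#' @param query [MoleculeRecord] or SMILES
#' @param rule ReactionRule
#' @return list of applications: `main` (MoleculeRecord), `secondary`
#'   (list of MoleculeRecord), `matched_atoms` (query atom indices,
#'   1-based on the canonical structure)
#' @export
apply_rule <- function(query, rule) {
  if (is.character(query)) query <- sanitize_molecule(query)
  stopifnot(inherits(query, "MoleculeRecord"), inherits(rule, "ReactionRule"))
  embeddings <- match_pattern(rule$qpat, query$graph)
  out <- list()
  dropped <- character(0)
  seen <- character(0)
  for (phi in embeddings) {
    res <- apply_transform(query$graph, rule, phi)
    if (!isTRUE(res$ok)) {
      dropped <- c(dropped, paste0(rule$rule_id, ": ", res$reason))
      next
    }
    main <- graph_to_record(res$main_graph)
    if (is.null(main)) {
      dropped <- c(dropped, paste0(rule$rule_id, ": main product rejected"))
      next
    }
    key <- paste(main$structure, paste(res$matched_atoms, collapse = ","))
    if (key %in% seen) next
    seen <- c(seen, key)
    secondary <- Filter(Negate(is.null),
                        lapply(res$secondary_graphs, graph_to_record))
    out[[length(out) + 1L]] <- list(main = main, secondary = secondary,
                                    matched_atoms = res$matched_atoms)
  }
  attr(out, "dropped") <- dropped
  out
}

#' Score one successful rule application
#'
#' Three components, each in \[0,1\]: Tanimoto (path fingerprint) between
#' query and the rule's source substrate; Tanimoto between the predicted
#' and the rule's source main product; and atom efficiency, the fraction
#' of query heavy atoms covered by the matched substructure.  The total is
#' their sum (maximum 3); three components of 0.40 give 1.2, the
#' recommended high-confidence cutoff.
#'
#' @param query [MoleculeRecord]
#' @param rule ReactionRule
#' @param main_product predicted main product ([MoleculeRecord])
#' @param matched_atoms integer vector of matched query atoms
#' @return list(substrate_similarity, product_similarity, atom_efficiency,
#'   total)
#' @export
score_prediction <- function(query, rule, main_product, matched_atoms) {
  ss <- tanimoto(path_fp_of(query), path_fp_of(rule$substrate_smiles))
  ps <- tanimoto(path_fp_of(main_product), path_fp_of(rule$product_smiles))
  ae <- length(matched_atoms) / query$heavy_atom_count
  list(substrate_similarity = ss, product_similarity = ps,
       atom_efficiency = ae, total = ss + ps + ae)
}

prediction_row <- function(query, rule, app, score) {
  data.frame(
    query_id = if (is.na(query$identifier)) query$structure else query$identifier,
    rule_id = rule$rule_id, reaction_id = rule$reaction_id,
    predicted_smiles = app$main$structure,
    secondary_smiles = paste(vapply(app$secondary, function(m) m$structure,
                                    character(1)), collapse = ";"),
    substrate_similarity = score$substrate_similarity,
    product_similarity = score$product_similarity,
    atom_efficiency = score$atom_efficiency,
    confidence_score = score$total,
    biosystem = rule$biosystem,
    enzyme_name = if (is.na(rule$enzyme_name)) "" else rule$enzyme_name,
    ec_numbers = paste(rule$ec_numbers, collapse = ";"),
    subsystem = if (is.na(rule$subsystem)) "" else rule$subsystem,
    organism_refs = paste(rule$organism_refs, collapse = ";"),
    matched_atoms = paste(app$matched_atoms, collapse = ","),
    stringsAsFactors = FALSE)
}

empty_predictions <- function() {
  cols <- c("query_id", "rule_id", "reaction_id", "predicted_smiles",
            "secondary_smiles", "substrate_similarity", "product_similarity",
            "atom_efficiency", "confidence_score", "biosystem", "enzyme_name",
            "ec_numbers", "subsystem", "organism_refs", "matched_atoms")
  num <- c("substrate_similarity", "product_similarity", "atom_efficiency",
           "confidence_score")
  as.data.frame(stats::setNames(
    lapply(cols, function(cc) if (cc %in% num) numeric(0) else character(0)),
    cols))
}

#' Predict metabolites of a query molecule
#'
#' Applies every rule of the database (optionally restricted to one
#' biosystem), scores each application, drops predictions below the
#' confidence cutoff, and returns one row per (rule, main product), sorted
#' by descending confidence then rule id.
#'
#' @param query [MoleculeRecord] or SMILES
#' @param rule_db list of ReactionRule or path to a rule database
#' @param cutoff confidence-score cutoff (default 0.6)
#' @param biosystem_filter optional `"human"` or `"microbe"`; rules tagged
#'   `"both"` always apply
#' @return data.frame of predictions (may have zero rows)
#' @export
predict_metabolites <- function(query, rule_db, cutoff = 0.6,
                                biosystem_filter = NULL) {
  if (is.character(rule_db) && length(rule_db) == 1L && file.exists(rule_db))
    rule_db <- rule_db_io(path = rule_db, mode = "read")
  if (!length(rule_db)) stop("empty rule database")
  if (is.character(query)) query <- sanitize_molecule(query)
  if (!is.null(biosystem_filter)) {
    stopifnot(biosystem_filter %in% c("human", "microbe"))
    rule_db <- Filter(function(r) r$biosystem %in% c(biosystem_filter, "both"),
                      rule_db)
  }
  rows <- list()
  for (rule in rule_db) {
    apps <- apply_rule(query, rule)
    for (app in apps) {
      sc <- score_prediction(query, rule, app$main, app$matched_atoms)
      rows[[length(rows) + 1L]] <- prediction_row(query, rule, app, sc)
    }
  }
  if (!length(rows)) return(empty_predictions())
  df <- do.call(rbind, rows)
  # one row per (query, rule, main-product key): keep the best-scoring
  key <- paste(df$query_id, df$rule_id, df$predicted_smiles)
  df <- do.call(rbind, lapply(split(df, key), function(d)
    d[order(-d$confidence_score)[1], , drop = FALSE]))
  df <- df[df$confidence_score >= cutoff, , drop = FALSE]
  df <- df[order(-df$confidence_score, df$rule_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Reduce predictions to the best row per drug-reaction pair
#'
#' Several rules of one reaction frequently produce the same metabolite;
#' this post-processing keeps the highest-confidence row per
#' (query, reaction) pair.
#'
#' @param predictions data.frame from [predict_metabolites()]
#' @return reduced data.frame
#' @export
best_per_pair <- function(predictions) {
  if (!nrow(predictions)) return(predictions)
  key <- paste(predictions$query_id, predictions$reaction_id)
  out <- do.call(rbind, lapply(split(predictions, key), function(d)
    d[order(-d$confidence_score)[1], , drop = FALSE]))
  out <- out[order(-out$confidence_score, out$rule_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-atom metabolic accessibility of a query
#'
#' The frequency with which each query atom falls inside the matched rule
#' substructure, over all successful rule applications.  Atom indices are
#' 1-based positions in the canonical query structure.
#'
#' @param query [MoleculeRecord] or SMILES
#' @param predictions data.frame of predictions for this query
#' @return list(frequencies = numeric vector (one per heavy atom),
#'   n_matches = number of predictions); empty profile if no predictions
#' @export
accessibility_profile <- function(query, predictions) {
  if (is.character(query)) query <- sanitize_molecule(query)
  if (!nrow(predictions))
    return(list(frequencies = numeric(0), n_matches = 0L))
  qid <- if (is.na(query$identifier)) query$structure else query$identifier
  stopifnot(all(predictions$query_id == qid))
  counts <- numeric(query$heavy_atom_count)
  for (s in predictions$matched_atoms) {
    idx <- as.integer(strsplit(s, ",", fixed = TRUE)[[1]])
    counts[idx] <- counts[idx] + 1
  }
  list(frequencies = counts / nrow(predictions), n_matches = nrow(predictions))
}
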