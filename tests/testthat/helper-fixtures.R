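# Shared fixture state, built once per test run.

.fx <- new.env(parent = emptyenv())

fx_set <- function() {
  if (is.null(.fx$set)) .fx$set <- make_fixture_set(1L)
  .fx$set
}

fx_retained <- function() {
  if (is.null(.fx$retained))
    .fx$retained <- filter_reactions(fx_set()$reactions, "strict")$retained
  .fx$retained
}

# all CSRRs generated from the fixture biotransformations
fx_rules <- function() {
  if (is.null(.fx$rules)) {
    rules <- list()
    for (rec in fx_retained()) {
      mr <- map_atoms(rec)
      for (srr in decompose_to_srrs(mr))
        rules <- c(rules, generate_csrrs(srr))
    }
    .fx$rules <- rules
  }
  .fx$rules
}

fx_srrs <- function() {
  if (is.null(.fx$srrs)) {
    .fx$srrs <- lapply(fx_retained(), function(rec)
      decompose_to_srrs(map_atoms(rec)))
    names(.fx$srrs) <- vapply(fx_retained(), function(r) r$reaction_id,
                              character(1))
  }
  .fx$srrs
}

fx_query <- function(id) {
  q <- fx_set()$queries
  sanitize_molecule(q$smiles[q$query_id == id], id)
}

# canonical keys of a reaction's substrate side
side_keys_of <- function(rec) {
  idx <- which(rec$participants$role == "substrate")
  vapply(rec$records[idx], function(r) r$structure, character(1))
}

# random atom-order relabeling of a SMILES (same molecular graph)
permute_smiles <- function(smiles) {
  g <- metabolizr:::parse_smiles(smiles)
  g <- metabolizr:::assign_hydrogens(metabolizr:::kekulize(g))
  perm <- sample(metabolizr:::n_atoms(g))
  metabolizr:::write_smiles(metabolizr:::subgraph_mol(g, perm),
                            with_maps = FALSE)
}
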