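# Deterministic toy fixture set: five balanced, fully atom-mapped gut/host
# biotransformations plus three deliberately invalid records, query drugs,
# and the reference metabolites the pipeline must recover.  Everything is
# generated in code (no checked-in data files), so schema changes cannot
# desynchronize fixtures from readers.
#
# Chemistry chosen to cover the classic xenobiotic reaction families:
# aromatic amino-acid decarboxylation, nitroreduction and azoreduction
# (balanced with formate as the two-electron donor), ester hydrolysis and
# O-demethylation (balanced hydrolytically, yielding methanol as the
# one-carbon co-product).

fixture_reaction_rows <- function() {
  rows <- list(
    list(reaction_id = "R_TYRDC",
         reaction_smiles = paste0(
           "[OH:1][c:2]1[cH:3][cH:4][c:5]([cH:6][cH:7]1)[CH2:8][CH:9]([NH2:10])[C:11](=[O:12])[OH:13]",
           ">>",
           "[OH:1][c:2]1[cH:3][cH:4][c:5]([cH:6][cH:7]1)[CH2:8][CH2:9][NH2:10].[C:11](=[O:12])=[O:13]"),
         direction = "forward", subsystem = "Tyrosine metabolism",
         biosystem = "microbe", enzyme_name = "tyrosine decarboxylase",
         ec_numbers = "4.1.1.25",
         organism_refs = "Enterococcus_faecalis;Lactobacillus_brevis",
         xrefs = "vmh:TYRDC"),
    list(reaction_id = "R_NITRORED",
         reaction_smiles = paste0(
           "[O-:1][N+:2](=[O:3])[c:4]1[cH:5][cH:6][cH:7][cH:8][cH:9]1",
           ".[CH:10](=[O:11])[OH:12].[CH:13](=[O:14])[OH:15].[CH:16](=[O:17])[OH:18]",
           ">>",
           "[NH2:2][c:4]1[cH:5][cH:6][cH:7][cH:8][cH:9]1.[OH2:1].[OH2:3]",
           ".[C:10](=[O:11])=[O:12].[C:13](=[O:14])=[O:15].[C:16](=[O:17])=[O:18]"),
         direction = "forward", subsystem = "Nitroaromatic reduction",
         biosystem = "microbe", enzyme_name = "nitroreductase",
         ec_numbers = "1.7.1.16",
         organism_refs = "Escherichia_coli;Clostridium_leptum",
         xrefs = "agora2:NTR"),
    list(reaction_id = "R_ESTHYD",
         reaction_smiles = paste0(
           "[CH3:1][C:2](=[O:3])[O:4][c:5]1[cH:6][cH:7][cH:8][cH:9][c:10]1[C:11](=[O:12])[OH:13]",
           ".[OH2:14]",
           ">>",
           "[OH:4][c:5]1[cH:6][cH:7][cH:8][cH:9][c:10]1[C:11](=[O:12])[OH:13]",
           ".[CH3:1][C:2](=[O:3])[OH:14]"),
         direction = "forward", subsystem = "Xenobiotic hydrolysis",
         biosystem = "human", enzyme_name = "carboxylesterase 1",
         ec_numbers = "3.1.1.1", organism_refs = "Homo_sapiens",
         xrefs = "recon3d:ESTHYD"),
    list(reaction_id = "R_ODEMETH",
         reaction_smiles = paste0(
           "[OH:1][c:2]1[cH:3][cH:4][cH:5][cH:6][c:7]1[O:8][CH3:9].[OH2:10]",
           ">>",
           "[OH:1][c:2]1[cH:3][cH:4][cH:5][cH:6][c:7]1[OH:8].[CH3:9][OH:10]"),
         direction = "forward", subsystem = "Methyl ether cleavage",
         biosystem = "microbe", enzyme_name = "O-demethylase",
         ec_numbers = "2.1.1.-", organism_refs = "Eubacterium_limosum",
         xrefs = "agora2:ODEM"),
    list(reaction_id = "R_AZORED",
         reaction_smiles = paste0(
           "[N:7](=[N:8][c:9]1[cH:10][cH:11][cH:12][cH:13][cH:14]1)",
           "[c:1]1[cH:2][cH:3][cH:4][cH:5][cH:6]1",
           ".[CH:15](=[O:16])[OH:17].[CH:18](=[O:19])[OH:20]",
           ">>",
           "[NH2:7][c:1]1[cH:2][cH:3][cH:4][cH:5][cH:6]1",
           ".[NH2:8][c:9]1[cH:10][cH:11][cH:12][cH:13][cH:14]1",
           ".[C:15](=[O:16])=[O:17].[C:18](=[O:19])=[O:20]"),
         direction = "forward", subsystem = "Azo dye reduction",
         biosystem = "microbe", enzyme_name = "azoreductase",
         ec_numbers = "1.7.1.17", organism_refs = "Clostridium_perfringens",
         xrefs = "agora2:AZOR"),
    # deliberately invalid records
    list(reaction_id = "R_GLCT",
         reaction_smiles = "OC1OC(CO)C(O)C(O)C1O[e]>>OC1OC(CO)C(O)C(O)C1O[c]",
         direction = "forward", subsystem = "Transport, extracellular",
         biosystem = "both", enzyme_name = "glucose transporter",
         ec_numbers = "", organism_refs = "", xrefs = ""),
    list(reaction_id = "R_UNBAL",
         reaction_smiles = "OC1OC(CO)C(O)C(O)C1O>>CC(O)C(=O)O",
         direction = "forward", subsystem = "Glycolysis (broken export)",
         biosystem = "microbe", enzyme_name = "", ec_numbers = "",
         organism_refs = "", xrefs = ""),
    list(reaction_id = "R_STEREO",
         reaction_smiles = "C[C@H](N)C(=O)O>>C[C@@H](N)C(=O)O",
         direction = "forward", subsystem = "Alanine racemase",
         biosystem = "microbe", enzyme_name = "alanine racemase",
         ec_numbers = "5.1.1.1", organism_refs = "", xrefs = "")
  )
  do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
}

fixture_queries <- function() {
  data.frame(
    query_id = c("levodopa", "nitrophenol", "phenylacetate"),
    smiles = c("NC(Cc1ccc(O)c(O)c1)C(=O)O",
               "O=[N+]([O-])c1ccc(O)cc1",
               "CC(=O)Oc1ccccc1"),
    stringsAsFactors = FALSE)
}

fixture_reference <- function() {
  data.frame(
    query_id = c("levodopa", "nitrophenol", "phenylacetate"),
    product_smiles = c("NCCc1ccc(O)c(O)c1",   # dopamine
                       "Nc1ccc(O)cc1",        # 4-aminophenol
                       "Oc1ccccc1"),          # phenol
    reaction_id = c("R_TYRDC", "R_NITRORED", "R_ESTHYD"),
    stringsAsFactors = FALSE)
}

# seeded decoy molecules: short branched alkanols that match no fixture rule
fixture_decoys <- function(seed, n = 3L) {
  set.seed(seed %% 2147483647L)
  vapply(seq_len(n), function(i) {
    len <- sample(3:6, 1)
    paste0(paste(rep("C", len), collapse = ""), "(C)O")
  }, character(1))
}

#' Build the deterministic fixture set
#'
#' Five balanced, atom-mapped biotransformations (decarboxylation,
#' nitroreduction, ester hydrolysis, O-demethylation, azoreduction), three
#' invalid records (transport, unbalanced, stereo-only), query drugs
#' (levodopa, 4-nitrophenol, phenyl acetate), the reference metabolites
#' they must yield, and seeded decoy molecules.  Identical seeds give
#' byte-identical serialized fixtures.
#'
#' @param seed integer seed (only the decoys are random)
#' @return a `FixtureSet` list: `reactions` (list of [reaction_record()]),
#'   `reaction_table` (data.frame in the reaction-TSV schema), `queries`,
#'   `reference_metabolites`, `decoys`, `seed`
#' @export
make_fixture_set <- function(seed = 1L) {
  tab <- fixture_reaction_rows()
  records <- lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    reaction_record(r$reaction_id, r$reaction_smiles,
                    direction = r$direction, subsystem = r$subsystem,
                    biosystem = r$biosystem, enzyme_name = r$enzyme_name,
                    ec_numbers = split_semi(r$ec_numbers),
                    organism_refs = split_semi(r$organism_refs),
                    xrefs = split_semi(r$xrefs))
  })
  ref <- fixture_reference()
  ref$product_key <- vapply(ref$product_smiles, canonical_key, character(1),
                            USE.NAMES = FALSE)
  structure(
    list(reactions = records, reaction_table = tab,
         queries = fixture_queries(), reference_metabolites = ref,
         decoys = fixture_decoys(seed), seed = seed),
    class = "FixtureSet")
}

#' Write fixture files to a directory
#'
#' Emits the reaction TSV, a cobra-style model JSON and a minimal SBML
#' document with the same content (metabolite instances get per-reaction
#' ids so atom maps survive all three routes), a query SMILES file and the
#' reference-metabolite TSV.
#'
#' @param fix a `FixtureSet`
#' @param dir output directory (created if needed)
#' @return named character vector of file paths
#' @export
write_fixture_files <- function(fix, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(reactions_tsv = file.path(dir, "reactions.tsv"),
             model_json = file.path(dir, "model.json"),
             model_sbml = file.path(dir, "model.xml"),
             queries = file.path(dir, "queries.smi"),
             reference = file.path(dir, "reference_metabolites.tsv"))
  utils::write.table(fix$reaction_table, paths[["reactions_tsv"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(paste(fix$queries$smiles, fix$queries$query_id, sep = "\t"),
             paths[["queries"]])
  utils::write.table(fix$reference_metabolites[
    c("query_id", "product_smiles", "reaction_id")],
    paths[["reference"]], sep = "\t", quote = FALSE, row.names = FALSE)
  write_fixture_model_json(fix, paths[["model_json"]])
  write_fixture_sbml(fix, paths[["model_sbml"]])
  paths
}

fixture_participants <- function(fix) {
  # long table of per-reaction participant instances with unique ids
  out <- list()
  for (i in seq_along(fix$reactions)) {
    rec <- fix$reactions[[i]]
    pp <- rec$participants
    for (j in seq_len(nrow(pp))) {
      out[[length(out) + 1L]] <- data.frame(
        rid = rec$reaction_id,
        met_id = sprintf("m_%s_%d", rec$reaction_id, j),
        role = pp$role[j], smiles = pp$smiles_raw[j], stoich = pp$stoich[j],
        compartment = pp$compartment[j], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

write_fixture_model_json <- function(fix, path) {
  pp <- fixture_participants(fix)
  mets <- lapply(seq_len(nrow(pp)), function(j) {
    m <- list(id = pp$met_id[j], smiles = pp$smiles[j])
    if (!is.na(pp$compartment[j])) m$compartment <- pp$compartment[j]
    m
  })
  rxns <- lapply(fix$reactions, function(rec) {
    mine <- pp[pp$rid == rec$reaction_id, , drop = FALSE]
    coefs <- as.list(stats::setNames(
      ifelse(mine$role == "product", mine$stoich, -mine$stoich), mine$met_id))
    list(id = rec$reaction_id, metabolites = coefs,
         lower_bound = if (rec$direction == "reversible") -1000 else 0,
         upper_bound = 1000,
         subsystem = rec$subsystem,
         annotation = list(biosystem = rec$biosystem,
                           enzyme_name = rec$enzyme_name,
                           ec_numbers = as.list(rec$ec_numbers),
                           organism_refs = as.list(rec$organism_refs),
                           xrefs = as.list(rec$xrefs)))
  })
  jsonlite::write_json(list(id = "toy_gem", metabolites = mets,
                            reactions = rxns),
                       path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

write_fixture_sbml <- function(fix, path) {
  pp <- fixture_participants(fix)
  lines <- c('<?xml version="1.0" encoding="UTF-8"?>',
             '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">',
             '<model id="toy_gem">',
             '<listOfCompartments><compartment id="c"/><compartment id="e"/><compartment id="x"/></listOfCompartments>',
             '<listOfSpecies>')
  for (j in seq_len(nrow(pp))) {
    comp <- if (is.na(pp$compartment[j])) "x" else pp$compartment[j]
    lines <- c(lines, sprintf(
      '<species id="%s" compartment="%s"><notes>SMILES: %s</notes></species>',
      pp$met_id[j], comp, xml_escape(pp$smiles[j])))
  }
  lines <- c(lines, '</listOfSpecies>', '<listOfReactions>')
  for (rec in fix$reactions) {
    mine <- pp[pp$rid == rec$reaction_id, , drop = FALSE]
    lines <- c(lines, sprintf(
      '<reaction id="%s" reversible="%s">',
      rec$reaction_id, if (rec$direction == "reversible") "true" else "false"))
    notes <- sprintf(
      "SUBSYSTEM: %s\nBIOSYSTEM: %s\nENZYME: %s\nEC: %s\nORGANISMS: %s",
      rec$subsystem, rec$biosystem, rec$enzyme_name,
      paste(rec$ec_numbers, collapse = ";"),
      paste(rec$organism_refs, collapse = ";"))
    lines <- c(lines, paste0("<notes>", xml_escape(notes), "</notes>"))
    for (role in c("substrate", "product")) {
      tag <- if (role == "substrate") "listOfReactants" else "listOfProducts"
      sub <- mine[mine$role == role, , drop = FALSE]
      lines <- c(lines, paste0("<", tag, ">"))
      for (j in seq_len(nrow(sub)))
        lines <- c(lines, sprintf(
          '<speciesReference species="%s" stoichiometry="%s"/>',
          sub$met_id[j], format(sub$stoich[j])))
      lines <- c(lines, paste0("</", tag, ">"))
    }
    lines <- c(lines, "</reaction>")
  }
  lines <- c(lines, "</listOfReactions>", "</model>", "</sbml>")
  writeLines(lines, path)
}
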