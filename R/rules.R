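# Rule generation: atom mapping, single-reactant decomposition, reaction
# centers, and graded chemically specific reaction rules (CSRRs).
#
# A CSRR is the reaction restricted to one substrate, trimmed to the
# reacting atoms plus a bounded bond-radius context, and serialized as a
# reaction pattern "querySMARTS>>templateSMILES".  Rules from one SRR are
# strictly nested (each wider context contains the narrower one), so the
# predictor can trade specificity against coverage via `num_atoms`.

# Normalize a raw (possibly atom-mapped) SMILES into the package's graph
# convention.  The molecule is canonicalized without its maps (canonical
# ordering with atom classes is not stable for symmetric molecules), then
# the maps are transferred onto the canonical graph through a
# deterministic isomorphism search constrained by element, charge,
# hydrogen count and degree.
mapped_graph <- function(raw) {
  g0 <- parse_smiles(raw)
  g0 <- assign_hydrogens(kekulize(g0))
  maps <- g0$map
  g0$map <- rep(0L, n_atoms(g0))
  ng <- normalize_graph(g0)$graph
  if (!any(maps > 0L)) return(ng)
  deg <- heavy_degree(g0)
  p <- new_patgraph(n_atoms(g0))
  p$elem <- g0$elem
  p$charge <- g0$charge
  p$hcount <- g0$hcount
  p$degree <- deg
  p$map <- seq_len(n_atoms(g0))
  p$bonds <- data.frame(a1 = g0$bonds$a1, a2 = g0$bonds$a2,
                        order = rep(NA_integer_, nrow(g0$bonds)),
                        arom = rep(FALSE, nrow(g0$bonds)))
  emb <- match_pattern(p, ng, max_embeddings = 1L)
  if (!length(emb)) mol_error("map transfer failed", raw)
  ng$map[emb[[1]]] <- maps
  ng
}

#' Atom-map a reaction record
#'
#' Input atom maps are validated and passed through (`mapper_source =
#' "input"`); reactions without maps get a deterministic greedy
#' maximum-common-substructure assignment, largest fragments first
#' (`mapper_source = "fallback_mcs"`, weaker than a learned mapper —
#' pre-mapped input is the recommended path).  Reactions at or above the
#' atom budget are skipped with reason `"atom budget"`.
#'
#' @param rec ReactionRecord (balanced biotransformation)
#' @param atom_budget total heavy-atom ceiling (default 1200)
#' @return a `MappedReaction`, or a `SkippedReaction` (empty, with
#'   attribute `reason`) when the reaction exceeds the atom budget
#' @export
map_atoms <- function(rec, atom_budget = 1200L) {
  subs_idx <- rxn_side(rec, "substrate")
  prod_idx <- rxn_side(rec, "product")
  raw <- rec$participants$smiles_raw[c(subs_idx, prod_idx)]
  total <- sum(vapply(raw, function(s) n_atoms(parse_smiles(s)), integer(1)))
  if (total >= atom_budget)
    return(structure(list(), class = "SkippedReaction",
                     reason = "atom budget",
                     reaction_id = rec$reaction_id))
  sub_graphs <- lapply(rec$participants$smiles_raw[subs_idx], mapped_graph)
  prod_graphs <- lapply(rec$participants$smiles_raw[prod_idx], mapped_graph)
  smaps <- unlist(lapply(sub_graphs, function(g) g$map[g$map > 0L]))
  pmaps <- unlist(lapply(prod_graphs, function(g) g$map[g$map > 0L]))
  if (length(smaps) || length(pmaps)) {
    dup <- c(smaps[duplicated(smaps)], pmaps[duplicated(pmaps)])
    if (length(dup))
      stop("inconsistent atom maps: duplicated indices ",
           paste(sort(unique(dup)), collapse = ","))
    lost <- setdiff(smaps, pmaps)
    extra <- setdiff(pmaps, smaps)
    if (length(lost) || length(extra))
      stop("inconsistent atom maps: one-sided indices ",
           paste(sort(unique(c(lost, extra))), collapse = ","))
    src <- "input"
  } else {
    mapped <- fallback_map(sub_graphs, prod_graphs)
    sub_graphs <- mapped$sub_graphs
    prod_graphs <- mapped$prod_graphs
    src <- "fallback_mcs"
  }
  structure(list(base = rec, sub_graphs = sub_graphs,
                 prod_graphs = prod_graphs, mapper_source = src),
            class = "MappedReaction")
}

# greedy connected common-substructure pairing (element identity, bond
# existence); deterministic: substrates by descending size then canonical
# key, seeds and extensions by ascending atom index
fallback_map <- function(sub_graphs, prod_graphs) {
  next_map <- 1L
  for (g in c(sub_graphs, prod_graphs)) if (any(g$map > 0L))
    stop("fallback mapper called on partially mapped input")
  p_avail <- lapply(prod_graphs, function(g) rep(TRUE, n_atoms(g)))
  sizes <- vapply(sub_graphs, n_atoms, integer(1))
  keys <- vapply(sub_graphs, function(g)
    ob_canonical_cached(write_smiles(g, with_maps = FALSE), kekule = TRUE),
    character(1))
  for (si in order(-sizes, keys)) {
    gs <- sub_graphs[[si]]
    s_avail <- rep(TRUE, n_atoms(gs))
    repeat {
      best <- NULL
      for (pi_ in seq_along(prod_graphs)) {
        m <- grow_common(gs, prod_graphs[[pi_]], s_avail, p_avail[[pi_]])
        if (length(m$s) && (is.null(best) || length(m$s) > length(best$s)))
          best <- c(m, list(pi_ = pi_))
      }
      if (is.null(best) || !length(best$s)) break
      for (k in seq_along(best$s)) {
        sub_graphs[[si]]$map[best$s[k]] <- next_map
        prod_graphs[[best$pi_]]$map[best$p[k]] <- next_map
        next_map <- next_map + 1L
      }
      s_avail[best$s] <- FALSE
      p_avail[[best$pi_]][best$p] <- FALSE
      if (!any(s_avail)) break
    }
  }
  list(sub_graphs = sub_graphs, prod_graphs = prod_graphs)
}

grow_common <- function(gs, gp, s_avail, p_avail) {
  nb_s <- neighbors_of(gs); nb_p <- neighbors_of(gp)
  best <- list(s = integer(0), p = integer(0))
  for (seed_s in which(s_avail)) {
    for (seed_p in which(p_avail)) {
      if (gs$elem[seed_s] != gp$elem[seed_p]) next
      ms <- seed_s; mp <- seed_p
      repeat {
        ext <- NULL
        for (k in seq_along(ms)) {
          for (xs in sort(nb_s[[ms[k]]])) {
            if (xs %in% ms || !s_avail[xs]) next
            for (xp in sort(nb_p[[mp[k]]])) {
              if (xp %in% mp || !p_avail[xp]) next
              if (gs$elem[xs] == gp$elem[xp]) { ext <- c(xs, xp); break }
            }
            if (!is.null(ext)) break
          }
          if (!is.null(ext)) break
        }
        if (is.null(ext)) break
        ms <- c(ms, ext[1]); mp <- c(mp, ext[2])
      }
      if (length(ms) > length(best$s)) best <- list(s = ms, p = mp)
    }
  }
  best
}

#' Decompose a mapped reaction into single-reactant reactions
#'
#' One SRR per distinct substrate (stoichiometric duplicates collapse);
#' each product records how many of its atoms originate in that substrate,
#' and the product inheriting the most atoms is the main product (ties:
#' heavy-atom count, then lexicographic canonical key).
#'
#' @param mr MappedReaction
#' @return list of `SRR` objects
#' @export
decompose_to_srrs <- function(mr) {
  sub_keys <- vapply(mr$sub_graphs, function(g)
    ob_canonical_cached(write_smiles(g, with_maps = FALSE), kekule = TRUE),
    character(1))
  prod_recs <- lapply(mr$prod_graphs, function(g)
    graph_to_record(g))
  out <- list()
  for (si in which(!duplicated(sub_keys))) {
    gs <- mr$sub_graphs[[si]]
    my_maps <- gs$map[gs$map > 0L]
    if (!length(my_maps))
      stop("mapping defect: substrate ", sub_keys[si], " carries no atom maps")
    inherited <- vapply(mr$prod_graphs, function(gp)
      sum(gp$map %in% my_maps), integer(1))
    if (sum(inherited) == 0L)
      stop("mapping defect: no atom of substrate ", sub_keys[si],
           " appears in any product")
    pkeys <- vapply(prod_recs, function(r)
      if (is.null(r)) NA_character_ else r$structure, character(1))
    psizes <- vapply(mr$prod_graphs, n_atoms, integer(1))
    ord <- order(-inherited, -psizes, pkeys)
    main_idx <- ord[1]
    out[[length(out) + 1L]] <- structure(
      list(substrate_graph = gs,
           substrate_record = graph_to_record(gs),
           product_graphs = mr$prod_graphs,
           product_records = prod_recs,
           inherited = inherited,
           main_idx = main_idx,
           reaction_id = mr$base$reaction_id,
           annotations = mr$base[c("biosystem", "enzyme_name", "ec_numbers",
                                   "subsystem", "organism_refs")]),
      class = "SRR")
  }
  out
}

# for each substrate atom, locate (product index, atom index) of its image
srr_images <- function(srr) {
  gs <- srr$substrate_graph
  img <- matrix(NA_integer_, nrow = n_atoms(gs), ncol = 2)
  for (pi_ in seq_along(srr$product_graphs)) {
    gp <- srr$product_graphs[[pi_]]
    hit <- match(gs$map, gp$map)
    hit[gs$map == 0L] <- NA_integer_
    take <- which(!is.na(hit) & is.na(img[, 1]))
    img[take, 1] <- pi_
    img[take, 2] <- hit[take]
  }
  img
}

neighbor_signature <- function(g, a, rm_) {
  ab <- atom_bonds(g)
  sig <- vapply(ab[[a]], function(bi) {
    x <- g$bonds$a1[bi] + g$bonds$a2[bi] - a
    paste0(g$map[x], "/", bond_label(g, bi))
  }, character(1))
  paste(sort(sig), collapse = ",")
}

#' Identify the reaction center of an SRR
#'
#' A substrate atom is a reacting atom iff its element, charge, hydrogen
#' count, aromatic/ring state, or bonded-neighbor multiset (by map index
#' and bond order) differs between the substrate and its product image, or
#' it has no image at all (leaving atoms).
#'
#' @param srr an SRR
#' @return integer vector of substrate atom indices; error if empty
#' @export
identify_reaction_center <- function(srr) {
  gs <- srr$substrate_graph
  img <- srr_images(srr)
  rm_s <- ring_membership(gs)
  rms_p <- lapply(srr$product_graphs, ring_membership)
  center <- integer(0)
  for (a in seq_len(n_atoms(gs))) {
    if (gs$map[a] == 0L || is.na(img[a, 1])) { center <- c(center, a); next }
    gp <- srr$product_graphs[[img[a, 1]]]
    b <- img[a, 2]
    changed <-
      gs$elem[a] != gp$elem[b] ||
      gs$charge[a] != gp$charge[b] ||
      gs$hcount[a] != gp$hcount[b] ||
      gs$arom[a] != gp$arom[b] ||
      ring_membership(gs)$atom[a] != rms_p[[img[a, 1]]]$atom[b] ||
      neighbor_signature(gs, a) != neighbor_signature(gp, b)
    if (changed) center <- c(center, a)
  }
  if (!length(center))
    stop(structure(class = c("metabolizr_no_change", "error", "condition"),
                   list(message = paste0("no chemical change in SRR of ",
                                         srr$reaction_id), call = NULL)))
  center
}

# grow bond-radius shells around the center, truncated at `cap` atoms;
# returns list of strictly nested, sorted atom sets (one per distinct set)
context_shells <- function(g, center, cap) {
  nb <- neighbors_of(g)
  s <- sort(center)
  if (length(s) > cap) s <- s[seq_len(cap)]
  sets <- list(s)
  while (length(s) < cap) {
    frontier <- sort(setdiff(unique(unlist(nb[s])), s))
    if (!length(frontier)) break
    room <- cap - length(s)
    if (length(frontier) > room) frontier <- frontier[seq_len(room)]
    s <- sort(c(s, frontier))
    sets[[length(sets) + 1L]] <- s
  }
  sets
}

build_template <- function(srr, included, fresh_map) {
  gs <- srr$substrate_graph
  inc_maps <- gs$map[included]
  sub_maps <- gs$map[gs$map > 0L]
  tpl <- NULL
  roles <- character(0)      # one per template fragment (component)
  offset <- 0L
  for (pi_ in which(srr$inherited > 0L)) {
    gp <- srr$product_graphs[[pi_]]
    is_image <- gp$map %in% inc_maps
    is_created <- !(gp$map %in% sub_maps)       # atoms from co-substrates
    keep <- which(is_image | is_created)
    if (!length(keep)) next
    # a created atom bonded to an out-of-context substrate image cannot be
    # expressed by the trimmed rule
    out_of_ctx <- which(!is_image & !is_created)
    if (length(out_of_ctx)) {
      bad <- (gp$bonds$a1 %in% which(is_created) & gp$bonds$a2 %in% out_of_ctx) |
             (gp$bonds$a2 %in% which(is_created) & gp$bonds$a1 %in% out_of_ctx)
      if (any(bad)) return(NULL)
    }
    part <- subgraph_mol(gp, keep)
    # remap: image atoms get the fresh pattern map of their substrate atom
    part$map <- vapply(part$map, function(m) {
      if (m %in% inc_maps) fresh_map[[as.character(m)]] else 0L
    }, integer(1))
    role <- if (pi_ == srr$main_idx) "main" else "secondary"
    if (is.null(tpl)) {
      tpl <- part
    } else {
      nb0 <- n_atoms(tpl)
      tpl$elem <- c(tpl$elem, part$elem); tpl$arom <- c(tpl$arom, part$arom)
      tpl$charge <- c(tpl$charge, part$charge)
      tpl$hcount <- c(tpl$hcount, part$hcount)
      tpl$map <- c(tpl$map, part$map)
      pb <- part$bonds; pb$a1 <- pb$a1 + nb0; pb$a2 <- pb$a2 + nb0
      tpl$bonds <- rbind(tpl$bonds, pb)
    }
    offset <- offset + length(keep)
    roles <- c(roles, role)
  }
  if (is.null(tpl)) return(NULL)
  comp <- mol_components(tpl)
  # role per component: carried over from the product that contributed it
  comp_role <- character(max(comp))
  ai <- 0L
  for (pi_ in which(srr$inherited > 0L)) {
    gp <- srr$product_graphs[[pi_]]
    is_image <- gp$map %in% inc_maps
    is_created <- !(gp$map %in% sub_maps)
    nk <- sum(is_image | is_created)
    if (!nk) next
    role <- if (pi_ == srr$main_idx) "main" else "secondary"
    comp_role[unique(comp[ai + seq_len(nk)])] <- role
    ai <- ai + nk
  }
  list(graph = tpl, frag_roles = comp_role)
}

new_rule <- function(srr, included, k_index) {
  gs <- srr$substrate_graph
  qpat <- pattern_from_graph(gs, included)
  fresh_map <- stats::setNames(as.list(seq_along(included)),
                               as.character(gs$map[included]))
  tp <- build_template(srr, included, fresh_map)
  if (is.null(tp)) return(NULL)
  smarts <- paste0(pattern_to_smarts(qpat), ">>",
                   write_smiles(tp$graph, with_maps = TRUE))
  main_rec <- srr$product_records[[srr$main_idx]]
  if (is.null(main_rec) || is.null(srr$substrate_record)) return(NULL)
  structure(
    list(rule_id = sprintf("%s_a%02d", srr$reaction_id, length(included)),
         reaction_id = srr$reaction_id,
         smarts = smarts,
         num_atoms = length(included),
         substrate_smiles = srr$substrate_record$structure,
         product_smiles = main_rec$structure,
         biosystem = srr$annotations$biosystem,
         enzyme_name = srr$annotations$enzyme_name,
         ec_numbers = srr$annotations$ec_numbers,
         subsystem = srr$annotations$subsystem,
         organism_refs = srr$annotations$organism_refs,
         product_roles = tp$frag_roles,
         qpat = qpat, template = tp$graph, frag_roles = tp$frag_roles),
    class = "ReactionRule")
}

#' @export
print.ReactionRule <- function(x, ...) {
  cat("<ReactionRule>", x$rule_id, "(", x$num_atoms, "atoms )\n ",
      x$smarts, "\n")
  invisible(x)
}

#' Generate graded CSRRs from an SRR
#'
#' Rules grow outward from the reaction center in bond-radius shells until
#' they cover `min(max_atoms, all substrate atoms)`; each distinct included
#' set yields one rule.  Every rule is validated by applying it back to its
#' own substrate (round-trip to the main product); rules that fail to
#' serialize or round-trip are dropped and reported via the `dropped`
#' attribute.
#'
#' @param srr an SRR
#' @param max_atoms context ceiling (default 40 heavy atoms)
#' @return list of `ReactionRule`, smallest context first
#' @export
generate_csrrs <- function(srr, max_atoms = 40L) {
  center <- identify_reaction_center(srr)
  cap <- min(max_atoms, n_atoms(srr$substrate_graph))
  sets <- context_shells(srr$substrate_graph, center, cap)
  rules <- list()
  dropped <- character(0)
  for (k in seq_along(sets)) {
    rule <- new_rule(srr, sets[[k]], k - 1L)
    if (is.null(rule)) {
      dropped <- c(dropped, sprintf("%s_a%02d: not serializable",
                                    srr$reaction_id, length(sets[[k]])))
      next
    }
    rt <- roundtrip_ok(rule, srr, sets[[k]])
    if (!rt) {
      dropped <- c(dropped, sprintf("%s: round-trip failed", rule$rule_id))
      next
    }
    rules[[length(rules) + 1L]] <- rule
  }
  attr(rules, "dropped") <- dropped
  rules
}

# apply the rule to its own source substrate at the identity embedding and
# check the main product is reproduced
roundtrip_ok <- function(rule, srr, included) {
  res <- apply_transform(srr$substrate_graph, rule, included)
  if (!isTRUE(res$ok)) return(FALSE)
  rec <- graph_to_record(res$main_graph)
  !is.null(rec) && identical(rec$structure, rule$product_smiles)
}

RULE_DB_COLS <- c("rule_id", "reaction_id", "smarts", "num_atoms",
                  "substrate_smiles", "product_smiles", "biosystem",
                  "enzyme_name", "ec_numbers", "subsystem", "organism_refs",
                  "product_roles")

rules_to_df <- function(rules) {
  df <- do.call(rbind, lapply(rules, function(r) data.frame(
    rule_id = r$rule_id, reaction_id = r$reaction_id, smarts = r$smarts,
    num_atoms = r$num_atoms, substrate_smiles = r$substrate_smiles,
    product_smiles = r$product_smiles, biosystem = r$biosystem,
    enzyme_name = if (is.na(r$enzyme_name)) "" else r$enzyme_name,
    ec_numbers = paste(r$ec_numbers, collapse = ";"),
    subsystem = if (is.na(r$subsystem)) "" else r$subsystem,
    organism_refs = paste(r$organism_refs, collapse = ";"),
    product_roles = paste(r$product_roles, collapse = ";"),
    stringsAsFactors = FALSE)))
  if (is.null(df)) df <- as.data.frame(
    stats::setNames(rep(list(character(0)), length(RULE_DB_COLS)), RULE_DB_COLS))
  df
}

df_to_rules <- function(df) {
  lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    sides <- strsplit(r$smarts, ">>", fixed = TRUE)[[1]]
    if (length(sides) != 2L)
      stop("corrupted rule row: ", r$rule_id)
    qpat <- parse_smarts(sides[1])
    template <- parse_smiles(sides[2])
    template$bonds$arom <- rep(FALSE, nrow(template$bonds))
    frag_roles <- split_semi(r$product_roles)
    structure(
      list(rule_id = r$rule_id, reaction_id = r$reaction_id,
           smarts = r$smarts, num_atoms = as.integer(r$num_atoms),
           substrate_smiles = r$substrate_smiles,
           product_smiles = r$product_smiles, biosystem = r$biosystem,
           enzyme_name = if (nzchar(r$enzyme_name)) r$enzyme_name else NA_character_,
           ec_numbers = split_semi(r$ec_numbers),
           subsystem = if (nzchar(r$subsystem)) r$subsystem else NA_character_,
           organism_refs = split_semi(r$organism_refs),
           product_roles = frag_roles,
           qpat = qpat, template = template, frag_roles = frag_roles),
      class = "ReactionRule")
  })
}

#' Write or read a rule database
#'
#' TSV (or JSON, by file extension) with one row per rule; duplicate rules
#' (same pattern and source substrate/product) are stored once with merged
#' annotations; rows are ordered by (reaction_id, num_atoms, rule_id) so a
#' database written twice is byte-identical.
#'
#' @param rules list of ReactionRule (write mode)
#' @param path file path (`.tsv` or `.json`)
#' @param mode `"write"` or `"read"`
#' @return invisibly the path (write) or the rule list (read)
#' @export
rule_db_io <- function(rules = NULL, path, mode = c("write", "read")) {
  mode <- match.arg(mode)
  json <- grepl("\\.json$", path)
  if (mode == "write") {
    df <- rules_to_df(rules)
    if (nrow(df)) {
      key <- paste(df$smarts, df$substrate_smiles, df$product_smiles)
      merged <- lapply(split(seq_len(nrow(df)), key), function(ix) {
        row <- df[ix[1], , drop = FALSE]
        if (length(ix) > 1L) {
          row$ec_numbers <- paste(sort(unique(unlist(
            lapply(df$ec_numbers[ix], split_semi)))), collapse = ";")
          row$organism_refs <- paste(sort(unique(unlist(
            lapply(df$organism_refs[ix], split_semi)))), collapse = ";")
          if (length(unique(df$biosystem[ix])) > 1L) row$biosystem <- "both"
        }
        row
      })
      df <- do.call(rbind, merged)
      df <- df[order(df$reaction_id, df$num_atoms, df$rule_id), , drop = FALSE]
      rownames(df) <- NULL
    }
    if (json) jsonlite::write_json(df, path, dataframe = "rows", digits = NA)
    else utils::write.table(df, path, sep = "\t", quote = FALSE,
                            row.names = FALSE, na = "")
    invisible(path)
  } else {
    if (!file.exists(path)) stop("no such rule database: ", path)
    df <- if (json) jsonlite::fromJSON(path)
    else utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
    if (!nrow(df)) return(list())
    missing <- setdiff(RULE_DB_COLS, names(df))
    if (length(missing))
      stop("rule database ", path, " lacks column(s): ",
           paste(missing, collapse = ","))
    df_to_rules(df)
  }
}
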