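# Reading, classifying and filtering reaction schemes from genome-scale
# model exports.
#
# Three on-disk shapes are read into the same ReactionRecord: a delimited
# reaction table (the package's native schema), a cobra-style model JSON
# (id / metabolites / stoichiometry dictionaries) and a minimal SBML
# document.  Only elementally balanced biotransformations survive
# `filter_reactions()`; everything else lands in the audit log with its
# class, never silently dropped.

REACTION_TSV_COLS <- c("reaction_id", "reaction_smiles", "direction",
                       "subsystem", "biosystem", "enzyme_name", "ec_numbers",
                       "organism_refs", "xrefs")

split_semi <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0)
  else trimws(strsplit(x, ";", fixed = TRUE)[[1]])
}

parse_participant <- function(token) {
  token <- trimws(token)
  stoich <- 1
  m <- regmatches(token, regexpr("^\\d+(\\.\\d+)?\\s+", token))
  if (length(m) && nzchar(m)) {
    stoich <- as.numeric(trimws(m))
    token <- substring(token, nchar(m) + 1L)
  }
  compartment <- NA_character_
  # trailing [tag]: a compartment iff the tag is a short lowercase word
  # (bracket atoms like [NH3+] or [nH] never match this shape)
  m <- regmatches(token, regexpr("\\[[a-z][a-z0-9_]*\\]$", token))
  if (length(m) && nzchar(m) && nchar(token) > nchar(m)) {
    compartment <- substring(m, 2, nchar(m) - 1L)
    token <- substring(token, 1, nchar(token) - nchar(m))
  }
  list(smiles = token, stoich = stoich, compartment = compartment)
}

parse_reaction_smiles <- function(rxn_smiles) {
  sides <- strsplit(rxn_smiles, ">>", fixed = TRUE)[[1]]
  if (length(sides) > 2L) mol_error("more than one '>>' separator", rxn_smiles)
  if (length(sides) == 1L) sides <- c(sides, "")
  parse_side <- function(s, role) {
    s <- trimws(s)
    if (!nzchar(s)) return(NULL)
    toks <- strsplit(s, ".", fixed = TRUE)[[1]]
    do.call(rbind, lapply(toks, function(tk) {
      p <- parse_participant(tk)
      data.frame(role = role, smiles_raw = p$smiles, stoich = p$stoich,
                 compartment = p$compartment, stringsAsFactors = FALSE)
    }))
  }
  rbind(parse_side(sides[1], "substrate"), parse_side(sides[2], "product"))
}

#' Construct a ReactionRecord
#'
#' Participants are sanitized through [sanitize_molecule()]; a participant
#' that fails to parse leaves an `NA` record and marks the reaction
#' `incomplete` at classification time.  Raw (possibly atom-mapped) SMILES
#' are retained for the rule generator.
#'
#' @param reaction_id,reaction_smiles,direction,subsystem,biosystem scalar fields
#' @param enzyme_name,ec_numbers,organism_refs,xrefs annotation fields
#' @param boundary logical: source model marks this as a boundary/exchange
#' @return a `ReactionRecord`
#' @export
reaction_record <- function(reaction_id, reaction_smiles,
                            direction = c("forward", "reversible"),
                            subsystem = NA_character_,
                            biosystem = c("human", "microbe", "both"),
                            enzyme_name = NA_character_,
                            ec_numbers = character(0),
                            organism_refs = character(0),
                            xrefs = character(0),
                            boundary = FALSE) {
  direction <- match.arg(direction)
  biosystem <- match.arg(biosystem)
  participants <- tryCatch(parse_reaction_smiles(reaction_smiles),
                           error = function(e) NULL)
  if (is.null(participants))
    participants <- data.frame(role = character(0), smiles_raw = character(0),
                               stoich = numeric(0), compartment = character(0))
  records <- lapply(seq_len(nrow(participants)), function(i)
    tryCatch(sanitize_molecule(participants$smiles_raw[i]),
             error = function(e) NULL))
  structure(
    list(reaction_id = reaction_id, reaction_smiles = reaction_smiles,
         direction = direction, subsystem = subsystem, biosystem = biosystem,
         enzyme_name = enzyme_name, ec_numbers = ec_numbers,
         organism_refs = organism_refs, xrefs = xrefs, boundary = boundary,
         participants = participants, records = records),
    class = "ReactionRecord"
  )
}

#' @export
print.ReactionRecord <- function(x, ...) {
  cat("<ReactionRecord>", x$reaction_id, "(", x$direction, ",", x$biosystem, ")\n")
  cat(" ", x$reaction_smiles, "\n")
  invisible(x)
}

rxn_side <- function(rec, role) which(rec$participants$role == role)

side_keys <- function(rec, role) {
  idx <- rxn_side(rec, role)
  unlist(lapply(idx, function(i) {
    r <- rec$records[[i]]
    if (is.null(r)) NA_character_
    else rep(r$structure, rec$participants$stoich[i])
  }))
}

#' Classify a reaction record
#'
#' Classes: `incomplete` (unparseable or missing participants), `exchange`
#' (boundary flag or an empty side), `biomass` (designated by id or
#' subsystem), `transport` (identical structures both sides, different
#' compartment tags; also covers passive diffusion), `stereo_only`
#' (sides identical after stereo-removing sanitization although the raw
#' strings differed), otherwise `biotransformation` (balance is checked
#' separately by [check_balance()]).
#'
#' @param rec ReactionRecord
#' @return scalar character, one of the classes above
#' @export
classify_reaction <- function(rec) {
  subs <- rxn_side(rec, "substrate"); prods <- rxn_side(rec, "product")
  if (isTRUE(rec$boundary)) return("exchange")
  if (!length(subs) || !length(prods)) {
    if (!length(subs) && !length(prods)) return("incomplete")
    return("exchange")
  }
  if (any(vapply(rec$records, is.null, logical(1)))) return("incomplete")
  if (grepl("biomass", paste(rec$reaction_id, rec$subsystem), ignore.case = TRUE))
    return("biomass")
  sk <- sort(side_keys(rec, "substrate")); pk <- sort(side_keys(rec, "product"))
  if (identical(sk, pk)) {
    scomp <- rec$participants$compartment[subs]
    pcomp <- rec$participants$compartment[prods]
    if (!identical(sort(paste(scomp)), sort(paste(pcomp)))) return("transport")
    sraw <- sort(rec$participants$smiles_raw[subs])
    praw <- sort(rec$participants$smiles_raw[prods])
    if (!identical(sraw, praw)) return("stereo_only")
    return("stereo_only")   # identity reaction: no chemical change either
  }
  "biotransformation"
}

#' Check elemental balance of a reaction
#'
#' Sums stoichiometry-weighted formulas on both sides.  In `slack` mode
#' hydrogen and net formal charge are exempt (genome-scale exports
#' routinely omit protons); `strict` mode requires every element including
#' H to balance exactly.
#'
#' @param rec ReactionRecord with all participants parsed
#' @param mode `"slack"` or `"strict"`
#' @return list(balanced = logical, deltas = named numeric (product minus
#'   substrate, per element), mode)
#' @export
check_balance <- function(rec, mode = c("slack", "strict")) {
  mode <- match.arg(mode)
  if (any(vapply(rec$records, is.null, logical(1))))
    return(list(balanced = NA, deltas = NULL, mode = mode,
                reason = "incomplete"))
  acc <- new.env(parent = emptyenv())
  bump <- function(f, w) for (el in names(f))
    assign(el, (if (is.null(acc[[el]])) 0 else acc[[el]]) + w * f[[el]], envir = acc)
  for (i in seq_len(nrow(rec$participants))) {
    w <- rec$participants$stoich[i] *
      (if (rec$participants$role[i] == "product") 1 else -1)
    bump(rec$records[[i]]$formula, w)
  }
  deltas <- vapply(ls(acc), function(el) acc[[el]], numeric(1))
  considered <- if (mode == "slack") deltas[names(deltas) != "H"] else deltas
  list(balanced = all(abs(considered) < 1e-9), deltas = deltas, mode = mode)
}

#' Filter reaction records down to balanced biotransformations
#'
#' @param records list of ReactionRecord
#' @param balance_mode passed to [check_balance()]
#' @return list(retained = list of records (with `$class` set), audit =
#'   data.frame(reaction_id, class, detail)); every input lands in exactly
#'   one of the two
#' @export
filter_reactions <- function(records, balance_mode = c("slack", "strict")) {
  balance_mode <- match.arg(balance_mode)
  retained <- list()
  audit <- list()
  for (rec in records) {
    cls <- if (!is.null(rec$class) && rec$class == "biotransformation")
      "biotransformation" else classify_reaction(rec)
    if (cls == "biotransformation") {
      bal <- check_balance(rec, balance_mode)
      if (!isTRUE(bal$balanced)) {
        nz <- bal$deltas[abs(bal$deltas) > 1e-9]
        audit[[length(audit) + 1L]] <- data.frame(
          reaction_id = rec$reaction_id, class = "unbalanced",
          detail = paste(names(nz), round(nz, 3), sep = "=", collapse = ";"),
          stringsAsFactors = FALSE)
        next
      }
      rec$class <- "biotransformation"
      retained[[length(retained) + 1L]] <- rec
    } else {
      audit[[length(audit) + 1L]] <- data.frame(
        reaction_id = rec$reaction_id, class = cls, detail = "",
        stringsAsFactors = FALSE)
    }
  }
  audit <- if (length(audit)) do.call(rbind, audit)
    else data.frame(reaction_id = character(0), class = character(0),
                    detail = character(0))
  list(retained = retained, audit = audit)
}

#' Expand reversible reactions into two directed records
#'
#' Rules are directional, so each reversible record is split into
#' `<id>__fwd` and `<id>__rev` (sides swapped) before rule generation.
#'
#' @param records list of ReactionRecord
#' @return list of forward-only ReactionRecord
#' @export
expand_reversible <- function(records) {
  out <- list()
  for (rec in records) {
    if (rec$direction == "forward") { out[[length(out) + 1L]] <- rec; next }
    sides <- strsplit(rec$reaction_smiles, ">>", fixed = TRUE)[[1]]
    fwd <- rec; fwd$direction <- "forward"
    fwd$reaction_id <- paste0(rec$reaction_id, "__fwd")
    out[[length(out) + 1L]] <- fwd
    rev_ <- reaction_record(paste0(rec$reaction_id, "__rev"),
                            paste0(sides[2], ">>", sides[1]),
                            direction = "forward", subsystem = rec$subsystem,
                            biosystem = rec$biosystem,
                            enzyme_name = rec$enzyme_name,
                            ec_numbers = rec$ec_numbers,
                            organism_refs = rec$organism_refs,
                            xrefs = rec$xrefs)
    rev_$class <- rec$class
    out[[length(out) + 1L]] <- rev_
  }
  out
}

read_reaction_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", check.names = FALSE)
  missing <- setdiff(REACTION_TSV_COLS[1:2], names(df))
  if (length(missing))
    stop("reaction TSV ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "))
  for (cc in setdiff(REACTION_TSV_COLS, names(df))) df[[cc]] <- NA_character_
  empty2na <- function(x) if (is.na(x) || !nzchar(x)) NA_character_ else x
  lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    reaction_record(
      r$reaction_id, r$reaction_smiles,
      direction = if (!is.na(r$direction) && r$direction == "reversible")
        "reversible" else "forward",
      subsystem = empty2na(r$subsystem),
      biosystem = if (!is.na(r$biosystem) &&
                      r$biosystem %in% c("human", "microbe", "both"))
        r$biosystem else "both",
      enzyme_name = empty2na(r$enzyme_name),
      ec_numbers = split_semi(r$ec_numbers),
      organism_refs = split_semi(r$organism_refs),
      xrefs = split_semi(r$xrefs))
  })
}

read_reaction_model_json <- function(path) {
  mod <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  mets <- stats::setNames(mod$metabolites,
                          vapply(mod$metabolites, `[[`, character(1), "id"))
  lapply(mod$reactions, function(rx) {
    side <- function(sign_) {
      toks <- character(0)
      for (mid in names(rx$metabolites)) {
        coef <- rx$metabolites[[mid]]
        if (sign(coef) != sign_) next
        met <- mets[[mid]]
        smi <- met$smiles
        if (is.null(smi)) smi <- met$annotation$smiles
        if (is.null(smi)) smi <- ""
        comp <- if (!is.null(met$compartment)) paste0("[", met$compartment, "]") else ""
        st <- abs(coef)
        toks <- c(toks, paste0(if (st != 1) paste0(st, " ") else "", smi, comp))
      }
      paste(toks, collapse = ".")
    }
    lb <- if (!is.null(rx$lower_bound)) rx$lower_bound else 0
    ub <- if (!is.null(rx$upper_bound)) rx$upper_bound else 1000
    ann <- if (!is.null(rx$annotation)) rx$annotation else list()
    reaction_record(
      rx$id, paste0(side(-1), ">>", side(1)),
      direction = if (lb < 0 && ub > 0) "reversible" else "forward",
      subsystem = if (!is.null(rx$subsystem)) rx$subsystem else NA_character_,
      biosystem = if (!is.null(ann$biosystem)) ann$biosystem else "both",
      enzyme_name = if (!is.null(ann$enzyme_name) && nzchar(ann$enzyme_name))
        ann$enzyme_name else NA_character_,
      ec_numbers = as.character(unlist(ann$ec_numbers)),
      organism_refs = as.character(unlist(ann$organism_refs)),
      xrefs = as.character(unlist(ann$xrefs)),
      boundary = isTRUE(rx$boundary) || grepl("^EX_", rx$id))
  })
}

read_reaction_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  sp_nodes <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  species <- list()
  for (sp in sp_nodes) {
    id <- xml2::xml_attr(sp, "id")
    notes <- xml2::xml_text(xml2::xml_find_first(sp, ".//notes"))
    smi <- regmatches(notes, regexpr("SMILES:\\s*\\S+", notes))
    species[[id]] <- list(
      smiles = if (length(smi) && nzchar(smi)) sub("SMILES:\\s*", "", smi) else "",
      compartment = xml2::xml_attr(sp, "compartment"))
  }
  lapply(xml2::xml_find_all(doc, ".//listOfReactions/reaction"), function(rx) {
    side <- function(tag) {
      refs <- xml2::xml_find_all(rx, paste0("./", tag, "/speciesReference"))
      toks <- vapply(refs, function(ref) {
        sid <- xml2::xml_attr(ref, "species")
        st <- xml2::xml_attr(ref, "stoichiometry")
        st <- if (is.na(st)) 1 else as.numeric(st)
        sp <- species[[sid]]
        paste0(if (st != 1) paste0(st, " ") else "", sp$smiles,
               if (!is.na(sp$compartment)) paste0("[", sp$compartment, "]") else "")
      }, character(1))
      paste(toks, collapse = ".")
    }
    notes <- xml2::xml_text(xml2::xml_find_first(rx, ".//notes"))
    grab <- function(key) {
      m <- regmatches(notes, regexpr(paste0(key, ":[ \t]*[^\n<]*"), notes))
      if (!length(m)) return(NA_character_)
      v <- trimws(sub(paste0(key, ":[ \t]*"), "", m))
      if (nzchar(v)) v else NA_character_
    }
    bios <- grab("BIOSYSTEM")
    reaction_record(
      xml2::xml_attr(rx, "id"), paste0(side("listOfReactants"), ">>",
                                       side("listOfProducts")),
      direction = if (isTRUE(xml2::xml_attr(rx, "reversible") == "true"))
        "reversible" else "forward",
      subsystem = grab("SUBSYSTEM"),
      biosystem = if (!is.na(bios) && bios %in% c("human", "microbe", "both"))
        bios else "both",
      enzyme_name = grab("ENZYME"),
      ec_numbers = split_semi(grab("EC")),
      organism_refs = split_semi(grab("ORGANISMS")))
  })
}

#' Read reaction schemes from a file
#'
#' @param path file path
#' @param format `"tsv"` (native reaction table), `"model_json"`
#'   (cobra-style model export) or `"sbml"`
#' @return list of [reaction_record()] objects
#' @export
read_reaction_table <- function(path, format = c("tsv", "model_json", "sbml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  switch(format,
         tsv = read_reaction_tsv(path),
         model_json = read_reaction_model_json(path),
         sbml = read_reaction_sbml(path))
}
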