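# In-process bridge to OpenBabel via ChemmineOB.
#
# ChemmineOB's exported `convertFormat()` cannot pass SMILES writer options,
# so the conversion object is driven directly through the package's swig
# bindings.  Everything here is batched: one conversion call per vector of
# molecules, with index titles so failures stay attributable.

ob_convert_raw <- function(src, from, to, outoptions = character(0)) {
  inStr <- ChemmineOB:::istreamFromString(src)
  outStr <- ChemmineOB:::ostreamToString()
  conv <- ChemmineOB:::OBConversion(inStr, outStr)
  if (!ChemmineOB:::OBConversion_SetInAndOutFormats(conv, from, to))
    stop("OpenBabel: cannot set formats ", from, " -> ", to)
  for (opt in outoptions)
    ChemmineOB:::OBConversion_AddOption(conv, opt, "OUTOPTIONS", "")
  ChemmineOB:::OBConversion_Convert(conv)
  ChemmineOB:::stringFromOstream(outStr)
}

#' Canonical SMILES via OpenBabel (vectorized)
#'
#' @param smiles character vector
#' @param kekule write Kekulé (uppercase) form instead of aromatic form
#' @param keep_maps retain atom-map classes (`[CH3:2]`) in the output
#' @return character vector of canonical SMILES; NA where conversion failed
#' @keywords internal
ob_canonical <- function(smiles, kekule = FALSE, keep_maps = FALSE) {
  if (!length(smiles)) return(character(0))
  opts <- c("i", if (kekule) "k", if (keep_maps) "a")
  src <- paste0(smiles, " m", seq_along(smiles), collapse = "\n")
  out <- ob_convert_raw(paste0(src, "\n"), "SMI", "CAN", opts)
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  res <- rep(NA_character_, length(smiles))
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2L) next
    idx <- suppressWarnings(as.integer(sub("^m", "", trimws(parts[2]))))
    if (!is.na(idx)) res[idx] <- parts[1]
  }
  res
}

# cache canonical conversions; rule application re-canonicalizes the same
# products many times over
.ob_cache <- new.env(parent = emptyenv())

ob_canonical_cached <- function(smiles, kekule = FALSE) {
  key_pref <- if (kekule) "k|" else "a|"
  keys <- paste0(key_pref, smiles)
  res <- vapply(keys, function(k) {
    v <- .ob_cache[[k]]
    if (is.null(v)) NA_character_ else v
  }, character(1), USE.NAMES = FALSE)
  todo <- which(is.na(res))
  if (length(todo)) {
    conv <- ob_canonical(smiles[todo], kekule = kekule)
    for (i in seq_along(todo)) {
      if (!is.na(conv[i])) assign(keys[todo[i]], conv[i], envir = .ob_cache)
    }
    res[todo] <- conv
  }
  res
}

#' OpenBabel physicochemical properties (logP, TPSA, MW, ...)
#'
#' Thin vectorized wrapper over `ChemmineOB::prop_OB`, used for the
#' atomic-contribution logP and the Ertl TPSA behind the bioavailability
#' classifiers.
#'
#' @param smiles character vector of sanitized SMILES
#' @return data.frame with one row per molecule
#' @keywords internal
ob_properties <- function(smiles) {
  res <- ChemmineOB::forEachMol("SMILES", paste0(smiles, collapse = "\n"),
                                function(mol) ChemmineOB::prop_OB(mol))
  do.call(rbind, lapply(res, as.data.frame))
}

#' Count SMARTS matches via OpenBabel
#'
#' @param smiles single SMILES string
#' @param smarts character vector of SMARTS patterns
#' @return integer vector of unique-match counts, one per pattern
#' @keywords internal
ob_smarts_count <- function(smiles, smarts) {
  ChemmineOB::forEachMol("SMILES", smiles, function(mol) {
    vapply(smarts, function(p)
      as.integer(ChemmineOB::smartsSearch_OB(list(mol), p, uniqueMatches = TRUE)),
      integer(1), USE.NAMES = FALSE)
  })[[1]]
}
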