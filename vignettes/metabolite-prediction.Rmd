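---
title: "Reaction rules from genome-scale models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reaction rules from genome-scale models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabolizr)
```

## The problem

Genome-scale metabolic models (GEMs) catalogue the enzymatic reactions an
organism — or a whole gut community — can carry out, but they describe
those reactions over a fixed metabolite namespace.  A drug or dietary
xenobiotic is usually not in that namespace, so the models cannot say
directly whether the gut microbiota or host tissue will transform it.
metabolizr bridges that gap: it distils each curated biotransformation
into a family of *chemically specific reaction rules* (CSRRs) — trimmed
reaction patterns that retain the reacting atoms plus a bounded chemical
context — and applies those rules to arbitrary query molecules, scoring
every predicted metabolite by how closely the query situation resembles
the reaction the rule came from.

## From reactions to rules

The pipeline is, in order:

1. **Filtering.**  Reactions classed as transport (identical structures on
   both sides, different compartment tags — passive diffusion falls out of
   the same test), exchange (a boundary flag or an empty side), biomass
   (by id/subsystem designation, since biomass pseudo-metabolites carry no
   structures), or stereo-only conversions (sides identical once
   stereochemistry is stripped; this package is stereo-free throughout)
   are excluded, as are elementally unbalanced reactions.  Balance is
   checked per element from stoichiometry-weighted formulas; the default
   `slack` mode exempts hydrogen and net charge because GEM exports
   routinely omit protons, and a `strict` mode requires exact balance.
   Every exclusion is written to an audit log with its class — no record
   is ever dropped silently.

2. **Atom mapping.**  Reactions that arrive with atom maps are validated
   (indices unique per side, no one-sided indices) and used as-is; this is
   the recommended path.  Unmapped reactions get a deterministic greedy
   fallback: substrates in order of decreasing size are matched to
   products by repeatedly extracting the largest connected common
   substructure (element identity, bond existence).  The fallback is
   deliberately simple and documented as weaker than a learned mapper; it
   exists so that the pipeline is runnable end-to-end without one.
   Reactions with 1200 or more heavy atoms in total are skipped with
   reason `"atom budget"`.

3. **Single-reactant reactions (SRRs).**  A mapped reaction with *k*
   distinct substrates yields *k* SRRs; each SRR pairs one substrate with
   all products, recording how many atoms each product inherits from that
   substrate.  The product inheriting the most atoms is the *main
   product* (ties: heavy-atom count, then lexicographic canonical key);
   the rest are co-products (CO2, water, cofactor fragments).
   Stoichiometric duplicates of one substrate collapse into a single SRR.

4. **Reaction center.**  A substrate atom is *reacting* iff its element,
   charge, hydrogen count, aromatic or ring state, or bonded-neighbor
   multiset (by map index and bond order, with aromatic bonds compared as
   aromatic rather than by their arbitrary Kekulé order) differs between
   the substrate and its mapped product image; atoms with no image
   (leaving groups) are reacting by definition.  An empty center — an
   identity transformation — is an error, not a rule.

5. **Context trimming.**  Rules grow outward from the center in
   bond-radius shells: rule *k* contains the center plus all atoms within
   *k* bonds, until the included set reaches `min(40, all substrate
   atoms)`; when a shell would overshoot the 40-atom cap the shell is
   truncated deterministically so the largest rule has exactly 40 atoms.
   Shell growth gives the nesting property the predictor relies on: the
   included-atom sets of one SRR form a chain under inclusion, so atom
   efficiency is monotone in rule size.  All atom counts are heavy atoms
   (hydrogens are implicit everywhere in this package).

6. **Serialization.**  Each rule is stored as
   `querySMARTS>>templateSMILES`.  The query side constrains, per atom:
   element, aromaticity, charge, hydrogen count, heavy-atom degree and
   ring membership (e.g. `[c;H1;D2;+0;R:3]`).  Degree and ring constraints
   are taken from the *whole* source substrate, so a ring bond severed at
   the context boundary survives as a degree constraint on the boundary
   atoms.  The template side holds the product-side images of the included
   atoms plus any product atoms contributed by co-substrates (these are
   created ex nihilo on application, e.g. the water oxygen of a
   hydrolysis), with fragment roles (`main`/`secondary`) stored alongside.
   Rules that fail to serialize or to reproduce their own source main
   product on re-application are dropped and logged.

## Applying rules and the confidence score

A rule application enumerates every distinct embedding of the query
pattern (a VF2-style backtracking search), rewrites the matched bonds to
the template's bonds, deletes leaving atoms, recomputes hydrogen counts of
touched atoms from standard valences, and splits the result into
fragments.  Bonds whose mapped atom pair is unchanged between pattern and
template keep the query's own bond — essential for partially included
aromatic rings, where splicing in the template's arbitrary Kekulé
alternation would corrupt the ring.  Valence-violating outcomes are
discarded with a log entry.  Symmetric sites produce distinct embeddings
and hence distinct predictions; duplicates are collapsed only when both
the main-product key and the matched-atom set coincide.

Each surviving prediction is scored with three components, each in [0, 1]:

* substrate similarity — Tanimoto similarity between the query and the
  rule's source substrate, on 2048-bit binary fingerprints of linear bond
  paths of length 1–7 (plus atom-level features, so single-heavy-atom
  molecules are non-empty and identical molecules always reach 1);
* product similarity — the same comparison between the predicted and the
  source main product;
* atom efficiency — matched query atoms divided by all query heavy atoms.

The total is their sum, maximum 3 (attained exactly when a rule's own
source substrate is scored against its all-atom rule).  The default
reporting cutoff is 0.6; 1.2 — three components of 0.40 — is the
recommended high-confidence threshold.  Both are `run_config()` defaults.
*Metabolic accessibility* summarizes all successful applications per
query: the frequency with which each atom falls inside a matched
substructure, normalized by the number of predictions (an empty
prediction set gives an empty profile, not zeros).

Two readings of atom efficiency circulate (matched/total query heavy
atoms versus a heteroatom-based ratio); this package implements the
former, which is the one consistent with a [0, 1] component and a maximum
total of 3.

## Downstream analyses

* **Descriptors and bioavailability.**  Molecular weight from standard
  atomic weights; logP and TPSA from OpenBabel's atomic-contribution
  models; donors = hydrogens on N/O, acceptors = N+O count (the classic
  rule-of-five reading, boundaries inclusive: MW ≤ 500, logP ≤ 5,
  HBD ≤ 5, HBA ≤ 10).  The absorption/brain-penetration classifier tests
  the (TPSA, logP) point against two ellipses.  The original
  publication's rotated best-fit ellipse coefficients are not printed in
  an accessible form, so the package uses axis-aligned ellipses spanning
  the published ranges (absorption: TPSA 0–142, logP −2.3–6.8); the brain
  ellipse is slightly narrower (TPSA ≈ 2–74, logP 0.8–5.2) than the
  published ranges so that it is geometrically contained in the
  absorption region, as in the original plot.  A boundary-sampling test
  enforces that containment.
* **Structural alerts.**  Curated subsets of the PAINS and Brenk
  catalogs are packaged as SMARTS data files (with provenance headers
  noting they are subsets) and matched with OpenBabel's full SMARTS
  engine.
* **Isotope patterns.**  Per-element isotope distributions convolved
  per atom, aggregated at nominal-mass resolution (peak mass =
  abundance-weighted mean), truncated below 1e-6 relative abundance and
  renormalized.
* **Benchmark statistics.**  The upper whisker Q3 + 1.5·IQR of a score
  distribution selects confident predictions; Q1/Q3 use linear
  interpolation between order statistics by default, with classic Tukey
  hinges as an option, because a single published whisker value cannot
  disambiguate the convention.  Exact-match evaluation compares canonical
  keys per query, optionally also requiring reaction-id agreement.
* **Similarity networks.**  Pairwise Tanimoto on circular (Morgan-style,
  radius 2) fingerprints; an edge is kept iff similarity ≥ cutoff (≥, not
  >, where the choice matters), self-pairs are excluded by construction
  and isolated nodes are kept.  Export to GraphML (lossless) or SIF.

## The chemistry kernel and canonicalization

No RDKit binding exists for R, so the package carries its own molecular
graph kernel: a SMILES parser/writer (organic subset, bracket atoms, ring
closures, atom maps; stereochemistry and isotopes dropped at parse time),
kekulization by perfect matching over flagged aromatic systems, implicit
hydrogen assignment from standard valences, fingerprints, substructure
matching and the transform engine.  Aromaticity *perception* and
canonical ordering are delegated to OpenBabel (via ChemmineOB, in
process): every molecule is normalized by writing it out and re-reading
OpenBabel's canonical aromatic SMILES.  The canonical Kekulé `structure`
string is obtained by kekulizing that already-canonical aromatic string —
kekulizing first and canonicalizing second is *not* stable across
resonance spellings, which is why the aromatic form is the true key.
Canonical ordering with atom-map classes is likewise not stable for
symmetric molecules, so mapped reactions are canonicalized without their
maps and the maps are transferred back through a deterministic
isomorphism search constrained by element, charge, hydrogen count and
degree.

Two identical runs produce byte-identical rule databases; a test enforces
this, and the duplicate-rule merge (same pattern, substrate and product —
e.g. the formate-to-CO2 rule arising from several reactions) keeps the
union of annotations.

## The fixture generator

`make_fixture_set()` is first-class, tested code, not a checked-in file.
It emulates, at toy scale, what the full pipeline extracts from
human/microbial reconstructions: five balanced, fully atom-mapped
biotransformations covering classic xenobiotic chemistry — aromatic
amino-acid decarboxylation (tyrosine → tyramine + CO2), nitroreduction
(nitrobenzene → aniline), azoreduction (azobenzene → 2 aniline), ester
hydrolysis (aspirin + water → salicylic + acetic acid) and
O-demethylation (guaiacol → catechol) — plus three deliberately invalid
records (a transport, an unbalanced, a stereo-only reaction), query drugs
(levodopa, 4-nitrophenol, phenyl acetate), and the reference metabolites
they must yield (dopamine, 4-aminophenol, phenol).  Two balancing choices
are worth recording: the reductions use formate as the two-electron donor
(3 HCOOH per nitro group, 2 per azo bridge) because molecular hydrogen
has no heavy atoms and cannot be a molecule record in a heavy-atom-only
kernel; and O-demethylation is balanced hydrolytically (water in,
methanol out) because the formaldehyde route is not heavy-atom balanced
without an oxygen donor.  All five balance strictly, hydrogens included.
Seeded randomness affects only optional decoy molecules; the chemistry is
fixed, and equal seeds give byte-identical files.

What passing on the fixture does and does not show: the fixture reactions
are small, fully mapped, and chemically clean, so end-to-end recovery
demonstrates the machinery (filtering, mapping, trimming, matching,
transforming, scoring), not performance on real reconstructions, whose
scale (thousands of reactions, hundreds of thousands of rules) and noise
(missing structures, inconsistent protonation, unmapped atoms) require
the external model downloads that are outside this package's scope.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run the full pipeline on the
fixture set (8 reactions → 5 retained → 33 rules → 3 queries), a 60-atom
synthetic substrate for the 40-atom cap, 1000 random arrays for the
quantile oracle, and 50 random bitset pairs for the Tanimoto oracle —
sizes chosen so the whole suite exercises every path in about a minute.
Other fixed choices: fingerprints are binary (bit counts per feature are
not used); balance tolerance 1e-9; matrix symmetry tolerance 1e-9 in
network construction; embeddings per rule application capped at 256;
`n_above` counts scores strictly above the whisker.

## Known limitations

Single-step metabolism only; no transformation-rate prediction; no
organism-abundance weighting.  The kernel's aromaticity handling is
OpenBabel's; exotic aromatic systems that fail kekulization are rejected
with a reason code rather than guessed at.  The fallback atom mapper is
greedy and can underestimate the common substructure on heavily
rearranged reactions — pre-mapped input is always preferred.  The alert
catalogs are curated subsets, not the full published lists.  Rules cannot
represent transport or stereo conversions by construction, since both are
filtered out before rule generation.
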