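# Rule application, confidence scoring, prediction filtering,
# metabolic accessibility.

test_that("applying a rule to its own substrate reproduces the stored product at score (1,1,1)", {
  for (rule in fx_rules()[seq(1, length(fx_rules()), by = 3)]) {
    q <- sanitize_molecule(rule$substrate_smiles)
    apps <- apply_rule(q, rule)
    hit <- which(vapply(apps, function(a) a$main$structure, character(1)) ==
                   rule$product_smiles)
    expect_gt(length(hit), 0L)
    # the all-atom rule covers the whole substrate: components all exactly 1
    if (rule$num_atoms == q$heavy_atom_count) {
      sc <- score_prediction(q, rule, apps[[hit[1]]]$main,
                             apps[[hit[1]]]$matched_atoms)
      expect_identical(sc$substrate_similarity, 1)
      expect_identical(sc$product_similarity, 1)
      expect_identical(sc$atom_efficiency, 1)
      expect_identical(sc$total, 3)
    }
  }
})

test_that("a non-matching query returns an empty result, not an error", {
  ester_rules <- Filter(function(r)
    r$substrate_smiles == canonical_key("CC(=O)Oc1ccccc1C(=O)O"), fx_rules())
  expect_gt(length(ester_rules), 0L)
  expect_length(apply_rule(sanitize_molecule("c1ccccc1"), ester_rules[[1]]), 0L)
})

test_that("the decarboxylation rule converts levodopa to dopamine with CO2 as co-product", {
  tdc <- Filter(function(r) r$reaction_id == "R_TYRDC", fx_rules())
  q <- fx_query("levodopa")
  hits <- list()
  for (rule in tdc) {
    for (app in apply_rule(q, rule))
      if (app$main$structure == canonical_key("NCCc1ccc(O)c(O)c1"))
        hits[[length(hits) + 1L]] <- app
  }
  expect_gt(length(hits), 0L)
  secs <- unlist(lapply(hits, function(a)
    vapply(a$secondary, function(m) m$structure, character(1))))
  expect_true(canonical_key("O=C=O") %in% secs)
})

test_that("three components of 0.40 sum to the 1.2 high-confidence threshold", {
  expect_equal(0.40 + 0.40 + 0.40, 1.2)
  cfg <- run_config()
  expect_identical(cfg$high_confidence, 1.2)
  expect_identical(cfg$cutoff, 0.6)
})

test_that("atom efficiency is non-decreasing in rule context size for a matching query", {
  q <- fx_query("nitrophenol")
  nr <- Filter(function(r) r$reaction_id == "R_NITRORED" &&
                 grepl("N", r$substrate_smiles), fx_rules())
  nr <- nr[order(vapply(nr, function(r) r$num_atoms, integer(1)))]
  effs <- c()
  for (rule in nr) {
    apps <- apply_rule(q, rule)
    if (!length(apps)) next
    sc <- score_prediction(q, rule, apps[[1]]$main, apps[[1]]$matched_atoms)
    effs <- c(effs, sc$atom_efficiency)
  }
  expect_gt(length(effs), 2L)
  expect_true(all(diff(effs) >= 0))
})

test_that("prediction filtering is anti-monotone in the cutoff and sorted by confidence", {
  rules <- fx_rules()
  q <- fx_query("levodopa")
  cuts <- c(0, 0.6, 1.2, 1.9, 3.01)
  counts <- vapply(cuts, function(ct)
    nrow(predict_metabolites(q, rules, cutoff = ct)), integer(1))
  expect_true(all(diff(counts) <= 0))
  expect_identical(counts[length(counts)], 0L)  # cutoff beyond the maximum
  p <- predict_metabolites(q, rules, cutoff = 0.6)
  expect_true(all(diff(p$confidence_score) <= 0))
  expect_true(all(p$confidence_score >= 0.6))
  expect_true(all(p$substrate_similarity >= 0 & p$substrate_similarity <= 1))
  expect_true(all(p$atom_efficiency > 0 & p$atom_efficiency <= 1))
})

test_that("the biosystem filter excludes rules from other biosystems but keeps 'both'", {
  rules <- fx_rules()
  q <- fx_query("phenylacetate")
  all_p <- predict_metabolites(q, rules, cutoff = 0)
  human <- predict_metabolites(q, rules, cutoff = 0, biosystem_filter = "human")
  microbe <- predict_metabolites(q, rules, cutoff = 0, biosystem_filter = "microbe")
  expect_true(all(human$biosystem %in% c("human", "both")))
  expect_true(all(microbe$biosystem %in% c("microbe", "both")))
  expect_lte(nrow(human), nrow(all_p))
  # the ester rule is human: dropping humans removes the phenol prediction
  expect_true(canonical_key("Oc1ccccc1") %in% human$predicted_smiles)
  expect_false(canonical_key("Oc1ccccc1") %in% microbe$predicted_smiles)
})

test_that("prediction output is deterministic across runs", {
  rules <- fx_rules()
  q <- fx_query("nitrophenol")
  p1 <- predict_metabolites(q, rules, cutoff = 0.6)
  p2 <- predict_metabolites(q, rules, cutoff = 0.6)
  expect_identical(p1, p2)
})

test_that("an empty rule database is an error", {
  expect_error(predict_metabolites(fx_query("levodopa"), list()), "empty")
})

test_that("accessibility profiles count matched-atom membership per prediction", {
  q <- sanitize_molecule("CCCCC", "penta")
  fake <- function(atoms) data.frame(
    query_id = "penta", rule_id = "r", reaction_id = "rx",
    predicted_smiles = "C", secondary_smiles = "",
    substrate_similarity = 1, product_similarity = 1, atom_efficiency = 1,
    confidence_score = 3, biosystem = "both", enzyme_name = "",
    ec_numbers = "", subsystem = "", organism_refs = "",
    matched_atoms = paste(atoms, collapse = ","), stringsAsFactors = FALSE)
  one <- accessibility_profile(q, fake(c(1, 2)))
  expect_identical(one$frequencies, c(1, 1, 0, 0, 0))
  two <- accessibility_profile(q, rbind(fake(c(1, 2)), fake(c(2, 3))))
  expect_identical(two$frequencies, c(0.5, 1, 0.5, 0, 0))
  empty <- accessibility_profile(q, fake(1)[0, ])
  expect_identical(empty$n_matches, 0L)
  expect_length(empty$frequencies, 0L)
})

test_that("accessibility over the fixture rules highlights the reacting site", {
  # 4-nitrophenol: the nitro group is the reaction center, so its atoms are
  # covered by every matching nitroreduction rule
  q <- fx_query("nitrophenol")
  p <- predict_metabolites(q, fx_rules(), cutoff = 0.6)
  prof <- accessibility_profile(q, p)
  expect_identical(prof$n_matches, nrow(p))
  g <- q$graph
  nitro <- which(g$elem == "N" | (g$elem == "O" & g$charge != 0) |
                   (g$elem == "O" & vapply(seq_along(g$elem), function(a)
                     any(g$bonds$order[metabolizr:::atom_bonds(g)[[a]]] == 2 &
                           !g$bonds$arom[metabolizr:::atom_bonds(g)[[a]]]),
                     logical(1)) & g$elem == "O"))
  # every nitro atom is matched at the maximal frequency
  expect_true(all(prof$frequencies[g$elem == "N"] == max(prof$frequencies)))
  expect_true(all(prof$frequencies >= 0 & prof$frequencies <= 1))
})

test_that("best_per_pair keeps one highest-confidence row per query-reaction pair", {
  q <- fx_query("nitrophenol")
  p <- predict_metabolites(q, fx_rules(), cutoff = 0.6)
  b <- best_per_pair(p)
  expect_identical(nrow(b), length(unique(p$reaction_id)))
  for (rid in unique(p$reaction_id))
    expect_identical(b$confidence_score[b$reaction_id == rid],
                     max(p$confidence_score[p$reaction_id == rid]))
})
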