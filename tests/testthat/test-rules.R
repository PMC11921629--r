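# Atom mapping, SRR decomposition, reaction centers, CSRR generation,
# rule database round trips.

test_that("pre-mapped reactions pass through with validated maps", {
  for (rec in fx_retained()) {
    mr <- map_atoms(rec)
    expect_identical(mr$mapper_source, "input")
    smaps <- unlist(lapply(mr$sub_graphs, function(g) g$map[g$map > 0]))
    pmaps <- unlist(lapply(mr$prod_graphs, function(g) g$map[g$map > 0]))
    expect_false(any(duplicated(smaps)))
    expect_setequal(smaps, pmaps)
    # heavy-atom conservation for balanced reactions
    expect_identical(sum(vapply(mr$sub_graphs, metabolizr:::n_atoms, integer(1))),
                     sum(vapply(mr$prod_graphs, metabolizr:::n_atoms, integer(1))))
  }
})

test_that("inconsistent input maps are rejected naming the indices", {
  dup <- reaction_record("BADMAP", "[CH3:1][OH:1]>>[CH3:1][OH:2]")
  expect_error(map_atoms(dup), "duplicate")
  onesided <- reaction_record("BADMAP2", "[CH3:1][OH:2]>>[CH4:1].[OH2:9]")
  expect_error(map_atoms(onesided), "9")
})

test_that("the fallback mapper distributes tyrosine atoms 10 to tyramine, 3 to CO2", {
  rec <- reaction_record("TDC_NOMAP",
                         "OC1=CC=C(CC(N)C(=O)O)C=C1>>OC1=CC=C(CCN)C=C1.O=C=O")
  mr <- map_atoms(rec)
  expect_identical(mr$mapper_source, "fallback_mcs")
  # every substrate atom mapped, partition 10 + 3
  gs <- mr$sub_graphs[[1]]
  expect_true(all(gs$map > 0))
  sizes <- sort(vapply(mr$prod_graphs, function(g) sum(g$map > 0), integer(1)))
  expect_identical(sizes, c(3L, 10L))
  # and the SRR main product is tyramine
  srr <- decompose_to_srrs(mr)[[1]]
  expect_identical(srr$product_records[[srr$main_idx]]$structure,
                   canonical_key("NCCc1ccc(O)cc1"))
})

test_that("reactions at or above the atom budget are skipped with a reason", {
  big <- paste0(paste0(sprintf("[CH2:%d]", 1:649), collapse = ""), "[CH3:650]")
  rec <- reaction_record("POLY", paste0(big, ">>", big))
  mr <- map_atoms(rec, atom_budget = 1200L)
  expect_s3_class(mr, "SkippedReaction")
  expect_identical(attr(mr, "reason"), "atom budget")
  # under the budget the same (pre-mapped) reaction maps fine
  expect_s3_class(map_atoms(rec, atom_budget = 2000L), "MappedReaction")
})

test_that("SRR cardinality equals the number of distinct substrates", {
  expected <- c(R_TYRDC = 1L, R_NITRORED = 2L, R_ESTHYD = 2L,
                R_ODEMETH = 2L, R_AZORED = 2L)
  srrs <- fx_srrs()
  for (id in names(expected))
    expect_length(srrs[[id]], expected[[id]])
})

test_that("main products inherit the most substrate atoms (aspirin hydrolysis: 10 vs 3)", {
  srr <- fx_srrs()$R_ESTHYD[[1]]   # aspirin's SRR
  expect_identical(srr$substrate_record$structure,
                   canonical_key("CC(=O)Oc1ccccc1C(=O)O"))
  inh <- sort(srr$inherited[srr$inherited > 0], decreasing = TRUE)
  expect_identical(unname(inh), c(10L, 3L))
  expect_identical(srr$product_records[[srr$main_idx]]$structure,
                   canonical_key("OC(=O)c1ccccc1O"))
})

test_that("reaction centers match a bond-table diff", {
  # decarboxylation: alpha-C, carboxyl C, leaving O (subset of the carboxyl group)
  srr <- fx_srrs()$R_TYRDC[[1]]
  center <- identify_reaction_center(srr)
  gs <- srr$substrate_graph
  expect_setequal(gs$map[center], c(9L, 11L, 13L))
  # nitro reduction: N and both O
  srr2 <- fx_srrs()$R_NITRORED[[1]]
  center2 <- identify_reaction_center(srr2)
  gs2 <- srr2$substrate_graph
  expect_setequal(gs2$map[center2], c(1L, 2L, 3L))
  # identity transformation has no center
  rec <- reaction_record("IDEN", "[CH3:1][OH:2]>>[CH3:1][OH:2]")
  expect_error(decompose_to_srrs(map_atoms(rec)) |>
                 (\(s) identify_reaction_center(s[[1]]))(),
               class = "metabolizr_no_change")
})

test_that("rule atom sets are strictly nested and capped", {
  for (srrs in fx_srrs()) for (srr in srrs) {
    rules <- generate_csrrs(srr)
    sizes <- vapply(rules, function(r) r$num_atoms, integer(1))
    expect_identical(sizes, sort(sizes))
    expect_identical(max(sizes), min(40L, metabolizr:::n_atoms(srr$substrate_graph)))
    # nesting: parse each query side, compare included map sets via patterns
    sets <- lapply(rules, function(r) sort(r$qpat$map))
    for (k in seq_along(sets)[-1])
      expect_true(length(sets[[k - 1]]) < length(sets[[k]]))
  }
  # smallest rule equals the reaction center
  srr <- fx_srrs()$R_TYRDC[[1]]
  expect_identical(generate_csrrs(srr)[[1]]$num_atoms,
                   length(identify_reaction_center(srr)))
})

test_that("a substrate larger than 40 atoms caps at a 40-atom rule", {
  # hydrolysis of a 60-heavy-atom methyl ester
  chain_s <- paste0(sprintf("[CH2:%d]", 5:59), collapse = "")
  rec <- reaction_record("BIGHYD", paste0(
    "[CH3:1][O:2][C:3](=[O:4])", chain_s, "[CH3:60]", ".[OH2:61]",
    ">>",
    "[C:3](=[O:4])([OH:61])", chain_s, "[CH3:60]", ".[CH3:1][OH:2]"))
  expect_identical(classify_reaction(rec), "biotransformation")
  expect_true(check_balance(rec, "strict")$balanced)
  mr <- map_atoms(rec)
  srr <- decompose_to_srrs(mr)[[1]]          # the ester's SRR (60 atoms)
  expect_identical(metabolizr:::n_atoms(srr$substrate_graph), 60L)
  rules <- generate_csrrs(srr, max_atoms = 40L)
  expect_identical(max(vapply(rules, function(r) r$num_atoms, integer(1))), 40L)
  expect_true(all(vapply(rules, function(r) r$num_atoms, integer(1)) <= 40L))
})

test_that("every generated rule reproduces its source main product (round trip)", {
  rules <- fx_rules()
  expect_gt(length(rules), 20L)
  for (rule in rules) {
    apps <- apply_rule(rule$substrate_smiles, rule)
    keys <- vapply(apps, function(a) a$main$structure, character(1))
    expect_true(rule$product_smiles %in% keys)
  }
})

test_that("the rule database round-trips losslessly and deterministically", {
  rules <- fx_rules()
  dir <- withr::local_tempdir()
  p1 <- file.path(dir, "rules1.tsv"); p2 <- file.path(dir, "rules2.tsv")
  rule_db_io(rules, p1, "write")
  rule_db_io(rules, p2, "write")
  expect_identical(readLines(p1), readLines(p2))       # byte-identical
  back <- rule_db_io(path = p1, mode = "read")
  # identical (pattern, substrate, product) rules from different reactions
  # merge on write, so the stored count can be smaller, never larger
  expect_lte(length(back), length(rules))
  expect_gt(length(back), 20L)
  # serialization is a fixed point: write(read(db)) == db, field for field
  p3 <- file.path(dir, "rules3.tsv")
  rule_db_io(back, p3, "write")
  expect_identical(readLines(p1), readLines(p3))
  back2 <- rule_db_io(path = p3, mode = "read")
  for (k in seq_along(back)) {
    a <- back[[k]]; b <- back2[[k]]
    for (f in c("rule_id", "reaction_id", "smarts", "num_atoms",
                "substrate_smiles", "product_smiles", "biosystem",
                "enzyme_name", "ec_numbers", "subsystem", "organism_refs",
                "product_roles"))
      expect_identical(a[[f]], b[[f]])
  }
  # every re-read rule still functions: round-trip application
  for (r0 in back) {
    apps <- apply_rule(r0$substrate_smiles, r0)
    expect_true(r0$product_smiles %in%
                  vapply(apps, function(a) a$main$structure, character(1)))
  }
  # JSON variant
  pj <- file.path(dir, "rules.json")
  rule_db_io(rules, pj, "write")
  expect_length(rule_db_io(path = pj, mode = "read"), length(back))
  # duplicates merge annotations
  dup <- rules[[1]]
  dup$organism_refs <- c("Extra_bug")
  rule_db_io(c(rules[1], list(dup)), file.path(dir, "dup.tsv"), "write")
  merged <- rule_db_io(path = file.path(dir, "dup.tsv"), mode = "read")
  expect_length(merged, 1L)
  expect_true("Extra_bug" %in% merged[[1]]$organism_refs)
  # empty database round trip
  rule_db_io(list(), file.path(dir, "empty.tsv"), "write")
  expect_length(rule_db_io(path = file.path(dir, "empty.tsv"), mode = "read"), 0L)
})

test_that("per-element counts are conserved between SRR substrate and mapped products", {
  for (srrs in fx_srrs()) for (srr in srrs) {
    gs <- srr$substrate_graph
    my_maps <- gs$map[gs$map > 0]
    sub_elems <- sort(gs$elem)
    prod_elems <- sort(unlist(lapply(srr$product_graphs, function(gp)
      gp$elem[gp$map %in% my_maps])))
    expect_identical(sub_elems, prod_elems)
  }
})
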