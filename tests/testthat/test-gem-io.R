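# Reaction table reading, classification, balance, filtering.

test_that("the reaction TSV reads with no silent drops and routes across formats identically", {
  fix <- fx_set()
  dir <- withr::local_tempdir()
  paths <- write_fixture_files(fix, dir)
  recs_tsv <- read_reaction_table(paths[["reactions_tsv"]], "tsv")
  expect_length(recs_tsv, nrow(fix$reaction_table))
  recs_json <- read_reaction_table(paths[["model_json"]], "model_json")
  recs_sbml <- read_reaction_table(paths[["model_sbml"]], "sbml")
  expect_length(recs_json, length(recs_tsv))
  expect_length(recs_sbml, length(recs_tsv))
  for (i in seq_along(recs_tsv)) {
    a <- recs_tsv[[i]]; b <- recs_json[[i]]; c_ <- recs_sbml[[i]]
    for (f in c("reaction_id", "direction", "subsystem", "biosystem",
                "enzyme_name")) {
      expect_identical(a[[f]], b[[f]])
      expect_identical(a[[f]], c_[[f]])
    }
    expect_identical(a$ec_numbers, b$ec_numbers)
    expect_identical(a$ec_numbers, c_$ec_numbers)
    expect_identical(a$participants$smiles_raw, b$participants$smiles_raw)
    expect_identical(a$participants$smiles_raw, c_$participants$smiles_raw)
    expect_identical(a$participants$stoich, b$participants$stoich)
    expect_identical(a$participants$compartment, b$participants$compartment)
    # SBML requires a compartment on every species (the fixture writes "x"
    # where the table has none); compare only tagged participants
    tagged <- !is.na(a$participants$compartment)
    expect_identical(a$participants$compartment[tagged],
                     c_$participants$compartment[tagged])
  }
})

test_that("classification covers transport, exchange, stereo-only and incomplete", {
  transport <- reaction_record("T1", "OC1OC(CO)C(O)C(O)C1O[e]>>OC1OC(CO)C(O)C(O)C1O[c]")
  expect_identical(classify_reaction(transport), "transport")
  exch <- reaction_record("E1", "CCO[c]>>")
  expect_identical(classify_reaction(exch), "exchange")
  stereo <- reaction_record("S1", "C[C@H](N)C(=O)O>>C[C@@H](N)C(=O)O")
  expect_identical(classify_reaction(stereo), "stereo_only")
  bad <- reaction_record("B1", "QQQ>>CCO")
  expect_identical(classify_reaction(bad), "incomplete")
  biomass <- reaction_record("biomass_core", "CCO>>CC=O",
                             subsystem = "Biomass production")
  expect_identical(classify_reaction(biomass), "biomass")
  ok <- reaction_record("G1", "CCO>>CC=O")
  expect_identical(classify_reaction(ok), "biotransformation")
})

test_that("balance bookkeeping matches elemental sums and reports deltas", {
  # glucose -> 2 lactic acid: C6H12O6 vs 2x C3H6O3
  r2 <- reaction_record("F1", "OC1OC(CO)C(O)C(O)C1O>>2 CC(O)C(=O)O")
  b2 <- check_balance(r2, "strict")
  expect_true(b2$balanced)
  expect_true(all(abs(b2$deltas) < 1e-9))
  # glucose -> 1 lactic acid: three carbons missing
  r1 <- reaction_record("F2", "OC1OC(CO)C(O)C(O)C1O>>CC(O)C(=O)O")
  b1 <- check_balance(r1, "strict")
  expect_false(b1$balanced)
  expect_identical(abs(b1$deltas[["C"]]), 3)
  # identity reaction balances with all-zero deltas
  rid <- reaction_record("F3", "CCO>>CCO")
  expect_true(check_balance(rid, "strict")$balanced)
  # slack mode forgives hydrogen imbalance (exports routinely omit protons)
  rh <- reaction_record("F4", "CCO>>CC=O")
  expect_false(check_balance(rh, "strict")$balanced)
  expect_identical(check_balance(rh, "strict")$deltas[["H"]], -2)
  expect_true(check_balance(rh, "slack")$balanced)
})

test_that("filtering partitions the input and is idempotent and order-independent", {
  fix <- fx_set()
  fl <- filter_reactions(fix$reactions, "strict")
  expect_length(fl$retained, 5L)
  expect_identical(nrow(fl$audit), 3L)
  expect_setequal(fl$audit$class, c("transport", "unbalanced", "stereo_only"))
  ids_in <- vapply(fix$reactions, function(r) r$reaction_id, character(1))
  ids_out <- c(vapply(fl$retained, function(r) r$reaction_id, character(1)),
               fl$audit$reaction_id)
  expect_setequal(ids_in, ids_out)
  expect_length(ids_out, length(ids_in))
  # shuffled input: same classes
  set.seed(7)
  fl2 <- filter_reactions(sample(fix$reactions), "strict")
  expect_setequal(vapply(fl2$retained, function(r) r$reaction_id, character(1)),
                  vapply(fl$retained, function(r) r$reaction_id, character(1)))
  # fixed point
  fl3 <- filter_reactions(fl$retained, "strict")
  expect_length(fl3$retained, 5L)
  expect_identical(nrow(fl3$audit), 0L)
  # empty input
  fl0 <- filter_reactions(list())
  expect_length(fl0$retained, 0L)
  expect_identical(nrow(fl0$audit), 0L)
})

test_that("a reaction and its reversed form receive the same class and balance verdict", {
  fwd <- reaction_record("D1", "CCO.O=O>>CC(=O)O.O", direction = "reversible")
  both <- expand_reversible(list(fwd))
  expect_length(both, 2L)
  expect_identical(classify_reaction(both[[1]]), classify_reaction(both[[2]]))
  expect_identical(check_balance(both[[1]], "strict")$balanced,
                   check_balance(both[[2]], "strict")$balanced)
})

test_that("a row with an empty product side is excluded through the audit log", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "r.tsv")
  writeLines(c("reaction_id\treaction_smiles\tdirection",
               "RX1\tCCO>>CC=O\tforward",
               "RX2\tCCO>>\tforward"), path)
  recs <- read_reaction_table(path, "tsv")
  expect_length(recs, 2L)
  fl <- filter_reactions(recs)
  expect_identical(fl$audit$reaction_id, "RX2")
  expect_identical(fl$audit$class, "exchange")
})
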