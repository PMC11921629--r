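# Descriptors, rule-of-five, bioavailability ellipses, alerts, isotopes,
# deduplication, whisker statistics, exact matching, chemical-space PCA.

test_that("descriptor profiles match elemental arithmetic", {
  methane <- compute_descriptors("C")
  expect_identical(methane$hbd, 0L)
  expect_identical(methane$hba, 0L)
  expect_identical(methane$rotatable_bonds, 0L)
  aspirin <- compute_descriptors("CC(=O)Oc1ccccc1C(=O)O")
  # sum of standard atomic weights of C9H8O4
  expect_equal(aspirin$molecular_weight, 9 * 12.011 + 8 * 1.008 + 4 * 15.999,
               tolerance = 1e-6)
  expect_equal(aspirin$molecular_weight, 180.16, tolerance = 1e-3)
  glucose <- compute_descriptors("OC1OC(CO)C(O)C(O)C1O")
  expect_identical(glucose$hbd, 5L)   # five hydroxyls
  expect_identical(glucose$hba, 6L)   # N+O count
  ethane <- compute_descriptors("CC")
  expect_identical(ethane$rotatable_bonds, 0L)  # terminal bond doesn't rotate
  butane <- compute_descriptors("CCCC")
  expect_identical(butane$rotatable_bonds, 1L)
  acetamide <- compute_descriptors("CC(=O)NC")   # amide bond excluded
  expect_identical(acetamide$rotatable_bonds, 0L)
})

test_that("rule-of-five boundaries are inclusive and rules independent", {
  boundary <- list(molecular_weight = 500, logp = 5, hbd = 5, hba = 10)
  lip <- lipinski_check(boundary)
  expect_true(lip$pass)
  heavy <- lipinski_check(list(molecular_weight = 600, logp = 5, hbd = 5, hba = 10))
  expect_false(heavy$molecular_weight)
  expect_true(heavy$logp && heavy$hbd && heavy$hba)
  expect_false(heavy$pass)
  expect_true(lipinski_check(compute_descriptors("CC(=O)Oc1ccccc1C(=O)O"))$pass)
})

test_that("bioavailability ellipses behave like the published regions", {
  # very polar: outside both, for any logp in range
  for (lp in c(-3, 0, 3, 7))
    expect_false(any(unlist(boiled_egg_classify(list(tpsa = 200, logp = lp)))))
  # moderately polar, moderately lipophilic: inside both
  both <- boiled_egg_classify(list(tpsa = 60, logp = 1.5))
  expect_true(both$gastrointestinal_absorption)
  expect_true(both$brain_penetration)
  # purely a function of the profile: same input, same output
  expect_identical(boiled_egg_classify(list(tpsa = 60, logp = 1.5)), both)
  # yolk is contained in the white: sample the yolk boundary
  y <- metabolizr:::BOILED_EGG_ELLIPSES$yolk
  for (th in seq(0, 2 * pi, length.out = 41)) {
    pt <- list(tpsa = y[["cx"]] + y[["rx"]] * cos(th) * 0.999,
               logp = y[["cy"]] + y[["ry"]] * sin(th) * 0.999)
    cl <- boiled_egg_classify(pt)
    expect_true(cl$gastrointestinal_absorption)
  }
})

test_that("structural alerts flag nitro groups and pass clean molecules", {
  expect_length(structural_alerts("CCO", "brenk"), 0L)
  expect_length(structural_alerts("CCO", "pains"), 0L)
  expect_true("nitro_group" %in% structural_alerts("O=[N+]([O-])c1ccccc1", "brenk"))
  expect_true("catechol" %in% structural_alerts("Oc1ccccc1O", "pains"))
  expect_true("azo_aromatic" %in%
                structural_alerts("c1ccc(N=Nc2ccccc2)cc1", "pains"))
})

test_that("isotope patterns normalize and match closed-form expectations", {
  for (f in c("CH4", "C6H12O6", "C8H10N4O2", "CCl4", "C2H5Br"))
    expect_equal(sum(isotope_pattern(f)$probability), 1, tolerance = 1e-9)
  ch4 <- isotope_pattern("CH4")
  expect_equal(ch4$mass[1], 12 + 4 * 1.007825, tolerance = 1e-3)
  # (M+1)/M for C100: binomial with 13C abundance 1.07%
  c100 <- isotope_pattern("C100")
  expect_equal(c100$probability[2] / c100$probability[1],
               100 * (0.0107 / 0.9893), tolerance = 1e-6)
  # chlorine pattern in CCl4: M+1 is the lone 13C peak, M+2 the 37Cl peak
  ccl4 <- isotope_pattern("CCl4")
  expect_equal(ccl4$probability[2] / ccl4$probability[1],
               0.0107 / 0.9893, tolerance = 1e-9)
  expect_equal(ccl4$probability[3] / ccl4$probability[1],
               4 * 0.2424 / 0.7576, tolerance = 1e-9)
  expect_error(isotope_pattern("C2Si3"), "Si")
  expect_error(isotope_pattern(c(C = 1L, Xx = 2L)))
})

test_that("structure deduplication conserves counts", {
  d <- dedupe_structures(c("CCO", "OCC", "CCO"))
  expect_identical(nrow(d), 1L)
  expect_identical(d$multiplicity, 3L)
  n <- dedupe_structures(c("C", "CC", "CCC", "CCCC"))
  expect_identical(nrow(n), 4L)
  expect_true(all(n$multiplicity == 1L))
  mixed <- c("c1ccccc1O", "OC1=CC=CC=C1", "Oc1ccccc1", "CCO")
  dm <- dedupe_structures(mixed)
  expect_identical(sum(dm$multiplicity), length(mixed))
  expect_identical(nrow(dm), 2L)
})

test_that("whisker statistics follow the stated quantile rule", {
  s <- c(0.2, 0.4, 0.6, 0.8, 1.0, 3.0)
  st <- whisker_threshold(s)
  expect_equal(st$q1, 0.45)
  expect_equal(st$q3, 0.95)
  expect_equal(st$iqr, 0.5)
  expect_equal(st$upper_whisker, 1.70)
  expect_identical(st$n_above, 1L)
  # constant array: whisker at the constant, nothing above
  cst <- whisker_threshold(c(2, 2, 2, 2))
  expect_equal(cst$upper_whisker, 2)
  expect_identical(cst$n_above, 0L)
  # permutation invariance
  set.seed(11)
  x <- stats::runif(50)
  expect_identical(whisker_threshold(x), whisker_threshold(sample(x)))
  expect_error(whisker_threshold(c(1, 2, 3)), "at least 4")
})

test_that("whisker statistics agree with a brute-force sort-and-interpolate oracle", {
  # independent oracle: manual linear interpolation between order statistics
  oracle <- function(x, p) {
    x <- sort(x)
    h <- (length(x) - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    x[lo] + (h - lo) * (x[hi] - x[lo])
  }
  set.seed(99)
  for (i in 1:1000) {
    n <- sample(4:60, 1)
    x <- stats::rnorm(n, mean = stats::runif(1, -5, 5),
                      sd = stats::runif(1, 0.1, 4))
    st <- whisker_threshold(x)
    q1 <- oracle(x, 0.25); q3 <- oracle(x, 0.75)
    expect_equal(st$q1, q1, tolerance = 1e-12)
    expect_equal(st$q3, q3, tolerance = 1e-12)
    expect_equal(st$upper_whisker, q3 + 1.5 * (q3 - q1), tolerance = 1e-12)
    expect_identical(st$n_above, sum(x > st$upper_whisker))
  }
})

test_that("exact-match evaluation compares canonical keys per query", {
  preds <- data.frame(
    query_id = c("a", "a", "b"),
    predicted_smiles = c("OCC", "C", "Oc1ccccc1"),
    reaction_id = c("R1", "R2", "R3"),
    stringsAsFactors = FALSE)
  ref <- data.frame(query_id = c("a", "b"),
                    product_smiles = c("CCO", "C1=CC=CC=C1O"),
                    reaction_id = c("R1", "R9"),
                    stringsAsFactors = FALSE)
  ev <- evaluate_exact_matches(preds, ref)
  expect_identical(ev$n_matched, 2L)
  expect_identical(ev$fraction, 1)
  # strict mode also requires the reaction id
  evs <- evaluate_exact_matches(preds, ref, strict = TRUE)
  expect_identical(evs$n_matched, 1L)
  expect_identical(evs$fraction, 0.5)
  # disjoint
  ev0 <- evaluate_exact_matches(preds, data.frame(
    query_id = "a", product_smiles = "CCCCCCCC", stringsAsFactors = FALSE))
  expect_identical(ev0$fraction, 0)
  expect_error(evaluate_exact_matches(preds, ref[0, ]), "empty")
})

test_that("chemical-space projection matches an eigendecomposition oracle", {
  panel <- c("CCO", "CCCO", "CCCCO", "c1ccccc1", "Oc1ccccc1",
             "CC(=O)O", "CCN", "CCCN", "O=[N+]([O-])c1ccccc1", "CCOC")
  pr <- project_chemical_space(panel)
  expect_false(pr$degenerate)
  expect_lte(sum(pr$explained_variance), 1 + 1e-9)
  # oracle: eigenvalues of the covariance of the same fingerprint matrix
  fps <- do.call(rbind, lapply(panel, function(s)
    as.numeric(fingerprint(s, "circular"))))
  fps <- fps[, apply(fps, 2, stats::var) > 0, drop = FALSE]
  ev <- eigen(stats::cov(fps), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(pr$explained_variance[1], ev[1] / sum(ev), tolerance = 1e-9)
  expect_equal(pr$explained_variance[2], ev[2] / sum(ev), tolerance = 1e-9)
  # duplicated molecules project to identical coordinates
  pr2 <- project_chemical_space(c("CCO", "OCC", "c1ccccc1"))
  expect_equal(pr2$coords$pc1[1], pr2$coords$pc1[2], tolerance = 1e-9)
  expect_equal(pr2$coords$pc2[1], pr2$coords$pc2[2], tolerance = 1e-9)
  # all-identical fingerprints: degenerate, flagged
  prd <- project_chemical_space(c("CCO", "CCO", "CCO"))
  expect_true(prd$degenerate)
})
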