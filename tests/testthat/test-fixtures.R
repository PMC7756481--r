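smallCfg <- function(seed = 1, ...) {
  fixtureConfig(seed = seed,
                ontology = list(depth = 4, branching = 3, extra_parent_prob = 0.2),
                kb = list(n_genes = 40, n_diseases = 25),
                exome = list(n_background = 100), ...)
}

test_that("toy ontology has the expected shape and level depths", {
  cfg <- fixtureConfig(ontology = list(depth = 2, branching = 2,
                                       extra_parent_prob = 0))
  g <- makeToyOntology(cfg)
  expect_length(ontoTerms(g), 7L)  # 1 + 2 + 4
  expect_identical(max(termDepth(g, ontoTerms(g))), 2L)

  # extra parents never change the longest-path depth of a levelled node
  cfg2 <- fixtureConfig(ontology = list(depth = 4, branching = 2,
                                        extra_parent_prob = 1))
  g2 <- makeToyOntology(cfg2)
  nmulti <- sum(vapply(g2@parents, length, integer(1)) >= 2L)
  deepterms <- sum(termDepth(g2, ontoTerms(g2)) >= 2L)
  expect_identical(nmulti, deepterms)  # every node at level >= 2 has 2 parents
  expect_identical(max(termDepth(g2, ontoTerms(g2))), 4L)
})

test_that("generators are byte-deterministic per seed", {
  d1 <- tempfile(); d2 <- tempfile()
  writeFixtures(smallCfg(seed = 5), d1)
  writeFixtures(smallCfg(seed = 5), d2)
  for (f in c("hp.obo", "sample.vcf", "ann.tsv", "freq.tsv", "diseases.tsv",
              "disease_hpo.tsv", "truth.json"))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  d3 <- tempfile()
  writeFixtures(smallCfg(seed = 6), d3)
  expect_false(identical(unname(tools::md5sum(file.path(d1, "sample.vcf"))),
                         unname(tools::md5sum(file.path(d3, "sample.vcf")))))
})

test_that("toy knowledge base draws deep terms and valid structure", {
  cfg <- smallCfg(seed = 2)
  g <- makeToyOntology(cfg)
  kb <- makeToyKB(cfg, g)
  dd <- kbDiseases(kb)
  expect_identical(nrow(dd), 25L)
  tl <- lengths(kb@hpo[dd$disease_id])
  expect_true(all(tl >= 4L & tl <= 8L))
  maxd <- max(termDepth(g, ontoTerms(g)))
  allterms <- unlist(kb@hpo, use.names = FALSE)
  expect_true(all(termDepth(g, allterms) >= ceiling(maxd / 2)))
  expect_true(validObject(kb))
})

test_that("inheritance mix approximates AD 70 / AR 24 / XL 6", {
  cfg <- fixtureConfig(seed = 3,
                       ontology = list(depth = 4, branching = 3,
                                       extra_parent_prob = 0),
                       kb = list(n_genes = 400, n_diseases = 1000))
  g <- makeToyOntology(cfg)
  kb <- makeToyKB(cfg, g)
  frac <- table(kbDiseases(kb)$inheritance) / 1000
  expect_lt(abs(frac[["AD"]] - 0.70), 0.05)
  expect_lt(abs(frac[["AR"]] - 0.24), 0.05)
  expect_lt(abs(frac[["XL"]] - 0.06), 0.05)
})

test_that("noise-free patients are subsets of their disease terms", {
  cfg <- smallCfg(seed = 4,
                  patient = list(parent_swap_prob = 0, n_noise_terms = 0))
  g <- makeToyOntology(cfg)
  kb <- makeToyKB(cfg, g)
  d <- kbDiseases(kb)$disease_id[1]
  ps <- simulatePatient(g, kb, d, cfg)
  expect_true(all(psTerms(ps) %in% kbPhenotypes(kb, d)))
})

test_that("patients score their own disease above random diseases", {
  cfg <- smallCfg(seed = 8,
                  patient = list(parent_swap_prob = 0, n_noise_terms = 0))
  g <- makeToyOntology(cfg)
  kb <- makeToyKB(cfg, g)
  dd <- kbDiseases(kb)$disease_id
  set.seed(123)
  wins <- 0L
  n <- 200L
  for (i in seq_len(n)) {
    d <- sample(dd, 1L)
    other <- sample(setdiff(dd, d), 1L)
    ps <- simulatePatient(g, kb, d, cfg, seed = 5000L + i)
    own <- scoreValue(similarityScore(g, ps, kbPhenotypes(kb, d)))
    rnd <- scoreValue(similarityScore(g, ps, kbPhenotypes(kb, other)))
    wins <- wins + (own >= rnd)
  }
  expect_gte(wins / n, 0.95)
})

test_that("full ancestor-swapping lowers similarity to the true disease", {
  base <- smallCfg(seed = 9, patient = list(parent_swap_prob = 0,
                                            n_noise_terms = 0))
  swapped <- smallCfg(seed = 9, patient = list(parent_swap_prob = 1,
                                               n_noise_terms = 0))
  g <- makeToyOntology(base)
  kb <- makeToyKB(base, g)
  d <- kbDiseases(kb)$disease_id[3]
  ps0 <- simulatePatient(g, kb, d, base, seed = 77)
  ps1 <- simulatePatient(g, kb, d, swapped, seed = 77)
  s0 <- similarityScore(g, ps0, kbPhenotypes(kb, d))
  s1 <- similarityScore(g, ps1, kbPhenotypes(kb, d))
  expect_equal(s0@s1, 1, tolerance = 1e-12)  # exact terms fully covered
  expect_equal(s1@s1, 1, tolerance = 1e-12)  # ancestors still cover S1 ...
  expect_lt(scoreValue(s1), scoreValue(s0))  # ... but S2 loses specificity

  # a patient without any true disease term is rejected at config time
  expect_error(smallCfg(seed = 9, patient = list(n_true_terms = 0)),
               "n_true_terms")
})

test_that("exome spectrum: exact common count, spiked variant evidence", {
  cfg <- fixtureConfig(seed = 12)  # defaults: 500 background, 90% common
  g <- makeToyOntology(cfg)
  kb <- makeToyKB(cfg, g)
  # pick a dominant loss-of-function disease for a clean PVS1 spike
  dd <- kbDiseases(kb)
  d <- dd$disease_id[dd$mechanism == "LoF" & dd$inheritance == "AD"][1]
  exo <- simulateExome(g, kb, d, cfg)

  keymax <- tapply(exo$frequencies$af,
                   paste(exo$frequencies$chrom, exo$frequencies$pos,
                         exo$frequencies$ref, exo$frequencies$alt, sep = ":"),
                   max)
  expect_identical(sum(keymax > 0.05), 450L)
  expect_false(exo$truth$key %in% names(keymax))  # spike absent from controls

  av <- annotateVariants(exo$variants, exo$annotations, exo$freq_map)
  causal <- av[av$key == exo$truth$key, , drop = FALSE]
  expect_identical(causal$consequence, "stop_gained")
  expect_identical(causal$zygosity, "het")
  rules <- evaluateRules(causal, kb, d)
  expect_true(all(c("PVS1", "PM2") %in% rules))
})

test_that("generated fixture files pass their own readers cleanly", {
  dir <- tempfile()
  case <- writeFixtures(smallCfg(seed = 13), dir)
  expect_no_warning({
    g <- loadOBO(file.path(dir, "hp.obo"))
    kb <- loadKnowledgeBase(dir, g = g)
    vars <- readVariants(file.path(dir, "sample.vcf"))
    ann <- readAnnotationTable(file.path(dir, "ann.tsv"))
    frq <- readFrequencyTable(file.path(dir, "freq.tsv"))
  })
  expect_identical(nrow(vars), 101L)  # 100 background + 1 spike
  truth <- jsonlite::fromJSON(file.path(dir, "truth.json"))
  res <- runPipeline(vars, ann, frq, kb, g, truth$patient_terms)
  expect_gte(nrow(res$candidates), 1L)
  expect_identical(res$candidates$key[1], truth$key)
})
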