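test_that("posterior combiner matches the closed form", {
  # independent hand calculation: odds = 350^e; post = odds*0.1/((odds-1)*0.1+1)
  expect_equal(combinePosterior(character()), 0.10, tolerance = 1e-12)
  expect_equal(combinePosterior(c("PVS1", "PM2")), bfPosterior(1 + 1 / 4),
               tolerance = 1e-12)
  expect_equal(combinePosterior(c("PVS1", "PM2")), 0.9941, tolerance = 1e-4)
  expect_equal(combinePosterior("PM2"), bfPosterior(1 / 4), tolerance = 1e-12)
  expect_equal(combinePosterior("PM2"), 0.325, tolerance = 2e-3)
  expect_equal(combinePosterior(c("PM2", "BP4")),
               bfPosterior(1 / 4 - 1 / 8), tolerance = 1e-12)
  expect_error(combinePosterior("PS4"), "unknown ACMG rule")
})

test_that("BA1 is stand-alone benign and short-circuits to 0", {
  expect_identical(combinePosterior(c("BA1", "PM1")), 0)
  expect_identical(combinePosterior(c("PVS1", "PS1", "BA1")), 0)
  prof <- evidenceProfile(c("BA1", "PM1"))
  expect_identical(acmgClass(prof), "B")
})

test_that("posterior is monotone and order-independent in evidence items", {
  path_rules <- c("PVS1", "PS1", "PM1", "PM2", "PP2", "PP3")
  benign_rules <- c("BS1", "BP4", "BP7", "BA1")
  set.seed(99)
  for (rep in 1:50) {
    base <- sample(c(path_rules, benign_rules[1:3]), sample(0:5, 1L))
    p0 <- combinePosterior(base)
    extraP <- sample(setdiff(path_rules, base), 1L)
    expect_gte(combinePosterior(c(base, extraP)), p0)
    extraB <- sample(setdiff(benign_rules, base), 1L)
    expect_lte(combinePosterior(c(base, extraB)), p0)
    expect_equal(combinePosterior(sample(base)), p0, tolerance = 1e-15)
  }
})

test_that("five-class boundaries sit exactly where specified", {
  expect_identical(classifyPosterior(c(0.999, 0.99)), c("P", "P"))
  expect_identical(classifyPosterior(c(0.9899, 0.90)), c("LP", "LP"))
  expect_identical(classifyPosterior(c(0.8999, 0.101, 0.5)), c("VUS", "VUS", "VUS"))
  expect_identical(classifyPosterior(c(0.10, 0.0011)), c("LB", "LB"))
  expect_identical(classifyPosterior(c(0.001, 0)), c("B", "B"))
  # monotone in posterior
  p <- sort(runif(50))
  cls <- factor(classifyPosterior(p), levels = c("B", "LB", "VUS", "LP", "P"))
  expect_true(all(diff(as.integer(cls)) >= 0))
})

test_that("rule engine fires the documented evidence items", {
  kb <- toyKB(mechanism = "LoF", inheritance = "AD")
  cfg <- bayesConfig()

  r <- evaluateRules(avRecord(pop_af = c(gnomad = 0.08)), kb, "DIS:0001", cfg)
  expect_true("BA1" %in% r)

  r <- evaluateRules(avRecord(insilico = c(missense_meta = 0.9)), kb, "DIS:0001", cfg)
  expect_true("PP3" %in% r)

  r <- evaluateRules(avRecord(consequence = "stop_gained"), kb, "DIS:0001", cfg)
  expect_true(all(c("PVS1", "PM2") %in% r))

  r <- evaluateRules(avRecord(consequence = "synonymous_variant",
                              insilico = c(splice_ada = 0.1, splice_rf = 0.2)),
                     kb, "DIS:0001", cfg)
  expect_true(all(c("BP7", "BP4", "PM2") %in% r))
  expect_false(any(c("PP3", "PVS1") %in% r))

  r <- evaluateRules(avRecord(known = "same_change", hotspot = TRUE), kb,
                     "DIS:0001", cfg)
  expect_true(all(c("PS1", "PM1", "PP2") %in% r))
  r <- evaluateRules(avRecord(known = "same_residue"), kb, "DIS:0001", cfg)
  expect_true("PM5" %in% r)
  expect_false("PS1" %in% r)

  r <- evaluateRules(avRecord(consequence = "inframe_indel"), kb, "DIS:0001", cfg)
  expect_true("PM4" %in% r)

  # BS1: above disease-credible frequency but below the BA1 cutoff
  r <- evaluateRules(avRecord(pop_af = c(gnomad = 0.004)), kb, "DIS:0001", cfg)
  expect_true("BS1" %in% r)
  expect_false(any(c("BA1", "PM2") %in% r))

  # PVS1 requires a loss-of-function disease mechanism
  kbGoF <- toyKB(mechanism = "GoF")
  r <- evaluateRules(avRecord(consequence = "stop_gained"), kbGoF, "DIS:0001", cfg)
  expect_false("PVS1" %in% r)

  expect_error(
    evaluateRules(avRecord(gene = "OTHERGENE"), kb, "DIS:0001", cfg),
    "not linked")
})

test_that("PM2 uses inheritance-specific frequency cutoffs", {
  kb <- toyKB(inheritance = "AD")
  r <- evaluateRules(avRecord(pop_af = c(gnomad = 5e-5)), kb, "DIS:0001")
  expect_true("PM2" %in% r)
  r <- evaluateRules(avRecord(pop_af = c(gnomad = 5e-4)), kb, "DIS:0001")
  expect_false("PM2" %in% r)
  # DIS:0002 is recessive: the same frequency is below the AR cutoff
  r <- evaluateRules(avRecord(pop_af = c(gnomad = 5e-4)), kb, "DIS:0002")
  expect_true("PM2" %in% r)
})

test_that("PP4 fires at the similarity threshold and is idempotent", {
  prof <- evidenceProfile(c("PVS1", "PM2"))
  up <- applyPhenotypeRule(prof, 7.2)
  expect_true("PP4" %in% evidenceRules(up))
  expect_equal(posteriorProb(up), bfPosterior(1 + 1 / 4 + 1 / 8), tolerance = 1e-12)
  expect_gt(posteriorProb(up), posteriorProb(prof))

  expect_identical(evidenceRules(applyPhenotypeRule(prof, 3.0)),
                   evidenceRules(prof))
  expect_equal(posteriorProb(applyPhenotypeRule(up, 7.2)), posteriorProb(up))

  # uniqueness gate
  expect_false("PP4" %in%
    evidenceRules(applyPhenotypeRule(prof, 7.2, uniqueCandidate = FALSE)))
  cfg <- bayesConfig(pp4_require_unique = FALSE)
  prof2 <- evidenceProfile(c("PVS1", "PM2"), cfg)
  expect_true("PP4" %in%
    evidenceRules(applyPhenotypeRule(prof2, 7.2, uniqueCandidate = FALSE)))
})

test_that("family evidence updates: de novo, trans/cis, unaffected parent", {
  base <- evidenceProfile(c("PM2", "PP3"))

  denovo <- list(proband_zygosity = "het", mother_carrier = FALSE,
                 father_carrier = FALSE, mother_affected = FALSE,
                 father_affected = FALSE, confirmed_parentage = TRUE,
                 in_trans = NA)
  up <- applyFamilyEvidence(base, denovo, "AD")
  expect_true("PS2" %in% evidenceRules(up))
  expect_equal(posteriorProb(up), bfPosterior(1 / 4 + 1 / 8 + 1 / 2),
               tolerance = 1e-12)
  expect_false(isRejected(up))

  assumed <- denovo
  assumed$confirmed_parentage <- FALSE
  up <- applyFamilyEvidence(base, assumed, "AD")
  expect_true("PM6" %in% evidenceRules(up))
  expect_false("PS2" %in% evidenceRules(up))

  trans <- list(proband_zygosity = "het", mother_carrier = TRUE,
                father_carrier = FALSE, mother_affected = FALSE,
                father_affected = FALSE, confirmed_parentage = TRUE,
                in_trans = TRUE)
  up <- applyFamilyEvidence(base, trans, "AR")
  expect_true("PM3" %in% evidenceRules(up))
  expect_false(isRejected(up))

  cis <- trans
  cis$in_trans <- FALSE
  up <- applyFamilyEvidence(base, cis, "AR")
  expect_true("BP2" %in% evidenceRules(up))
  expect_true(isRejected(up))

  inherited <- list(proband_zygosity = "het", mother_carrier = FALSE,
                    father_carrier = TRUE, mother_affected = FALSE,
                    father_affected = FALSE, confirmed_parentage = TRUE,
                    in_trans = NA)
  up <- applyFamilyEvidence(base, inherited, "AD")
  expect_true("BS4" %in% evidenceRules(up))
  expect_true(isRejected(up))
  expect_lt(posteriorProb(up), posteriorProb(base))
})
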