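mkAv <- function(n, gene = "GENE0001", zygosity = "het",
                 consequence = "missense_variant", af = list(numeric())) {
  if (n == 0L) return(mkAv(1L, gene, zygosity, consequence, af)[0L, ])
  df <- data.frame(
    chrom = "chr1", pos = seq_len(n) * 100L, ref = "A", alt = "T",
    zygosity = zygosity, qual = 50, filter_status = "PASS",
    gene = gene, consequence = consequence, hgvs_p = "",
    known_pathogenic_aa_match = "none", in_hotspot_domain = FALSE,
    stringsAsFactors = FALSE)
  df$insilico <- I(rep(list(numeric()), n))
  df$pop_af <- I(rep(af, length.out = n))
  df$key <- paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
  df
}

test_that("frequency filter is strictly greater-than 5%", {
  av <- mkAv(3, af = list(c(gnomad = 0.051), c(gnomad = 0.05), numeric()))
  out <- frequencyFilter(av)
  expect_identical(out$pos, c(200L, 300L))  # 0.051 dropped, 0.05 and no-data kept
  expect_identical(nrow(frequencyFilter(mkAv(4, af = list(c(g = 0.3))))), 0L)
})

test_that("gene-disease matching fans out and drops unlinked genes", {
  kb <- toyKB()  # GENE0001 carries two diseases
  av <- mkAv(1)
  pairs <- geneDiseaseMatch(av, kb)
  expect_identical(nrow(pairs), 2L)
  expect_setequal(pairs$disease_id, c("DIS:0001", "DIS:0002"))

  expect_identical(nrow(geneDiseaseMatch(mkAv(1, gene = "NOGENE"), kb)), 0L)
  empty_kb <- new("KnowledgeBase",
                  diseases = kbDiseases(kb)[0, ], hpo = list())
  expect_identical(nrow(geneDiseaseMatch(av, empty_kb)), 0L)
})

test_that("impact filter drops benign classes and unrescued non-coding", {
  pairs <- mkAv(4)
  pairs$disease_id <- "DIS:0001"
  pairs$acmg_class <- c("LB", "VUS", "VUS", "B")
  pairs$consequence <- c("missense_variant", "intron_variant",
                         "intron_variant", "missense_variant")
  pairs$insilico <- I(list(numeric(), c(splice_ada = 0.7),
                           c(splice_ada = 0.2, splice_rf = 0.1), numeric()))
  out <- impactFilter(pairs)
  expect_identical(out$pos, 200L)  # rescued intron VUS only
})

test_that("inheritance filter applies zygosity rules per mode", {
  pairs <- mkAv(5)
  pairs$disease_id <- c("D1", "D1", "D2", "D3", "D4")
  pairs$gene <- c("G1", "G1", "G2", "G3", "G4")
  pairs$inheritance <- c("AR", "AR", "AR", "AD", "XL")
  pairs$zygosity <- c("het", "het", "het", "het", "het")
  out <- inheritanceFilter(pairs)
  # two AR hets in the same gene kept (phase unknown); lone AR het dropped;
  # AD het kept; XL het female dropped by default
  expect_setequal(out$pos, c(100L, 200L, 400L))
  expect_true(all(out$phase_unknown[out$inheritance == "AR"]))
  expect_false(any(out$phase_unknown[out$inheritance == "AD"]))

  out2 <- inheritanceFilter(pairs, keepHetFemale = TRUE)
  expect_true(500L %in% out2$pos)

  hom <- mkAv(1, zygosity = "hom")
  hom$disease_id <- "D1"; hom$inheritance <- "AR"
  expect_identical(nrow(inheritanceFilter(hom)), 1L)
})

test_that("tier assignment uses strict greater-than boundaries", {
  expect_identical(assignTier(c(0.95, 0.6, 0.2)), c(1L, 2L, 3L))
  expect_identical(assignTier(0.9), 2L)     # not > 0.9
  expect_identical(assignTier(0.499), 3L)   # not > 0.499
  expect_identical(assignTier(0.1), NA_integer_)
  expect_error(tierThresholds(t1 = 0.3, t2 = 0.5), "t1 > t2")
})

test_that("ranking is tier-first, similarity-second, fully deterministic", {
  cand <- mkAv(4)
  cand$disease_id <- c("D2", "D1", "D3", "D4")
  cand$disease_name <- cand$disease_id
  cand$inheritance <- "AD"
  cand$tier <- c(2L, 1L, 1L, 2L)
  cand$similarity <- c(9, 4, 4, 3)
  cand$posterior <- c(0.7, 0.95, 0.95, 0.6)
  ranked <- rankCandidates(cand)
  # tier 1 before tier 2 even when tier-2 similarity is higher
  expect_identical(ranked$tier, c(1L, 1L, 2L, 2L))
  # tie on (tier, similarity, posterior): disease id lexicographic
  expect_identical(ranked$disease_id, c("D1", "D3", "D2", "D4"))
  expect_identical(ranked$rank, 1:4)
})

test_that("pipeline on an empty VCF returns an empty report and full funnel", {
  g <- toyT()
  kb <- toyKB()
  vars <- mkAv(0)[, c("chrom", "pos", "ref", "alt", "zygosity", "qual",
                      "filter_status")]
  ann <- data.frame(chrom = character(), pos = integer(), ref = character(),
                    alt = character(), gene = character(),
                    consequence = character(), hgvs_p = character(),
                    missense_meta = numeric(), splice_ada = numeric(),
                    splice_rf = numeric(),
                    known_pathogenic_aa_match = character(),
                    in_hotspot_domain = logical(), stringsAsFactors = FALSE)
  res <- runPipeline(vars, ann, list(), kb, g, c("A1"))
  expect_identical(nrow(res$candidates), 0L)
  expect_identical(res$funnel$stage,
                   c("frequency_filter", "gene_disease_match", "impact_filter",
                     "inheritance_filter", "tier_assignment"))
  expect_true(all(res$funnel$variants_out <= res$funnel$variants_in))
})

test_that("identical inputs produce byte-identical reports", {
  case <- simulateCase(fixtureConfig(seed = 31))
  run <- function() {
    res <- runPipeline(case$exome$variants, case$exome$annotations,
                       case$exome$freq_map, case$kb, case$ontology,
                       case$patient)
    path <- tempfile(fileext = ".tsv")
    writeReport(res$candidates, path)
    list(res = res, md5 = unname(tools::md5sum(path)))
  }
  a <- run()
  b <- run()
  expect_identical(a$md5, b$md5)
  # funnel is monotone on a real simulated exome
  expect_true(all(a$res$funnel$variants_out <= a$res$funnel$variants_in))
})

test_that("segregation records must reference candidate variants", {
  case <- simulateCase(fixtureConfig(seed = 31))
  seg <- data.frame(key = "chrZ:1:A:T", mother_carrier = FALSE,
                    father_carrier = FALSE, mother_affected = FALSE,
                    father_affected = FALSE, confirmed_parentage = TRUE,
                    in_trans = NA, stringsAsFactors = FALSE)
  expect_error(
    runPipeline(case$exome$variants, case$exome$annotations,
                case$exome$freq_map, case$kb, case$ontology, case$patient,
                segregation = seg),
    "not among candidates")
})

test_that("confirmed de novo segregation raises the causal posterior", {
  case <- simulateCase(fixtureConfig(seed = 31))
  base <- runPipeline(case$exome$variants, case$exome$annotations,
                      case$exome$freq_map, case$kb, case$ontology,
                      case$patient)
  seg <- data.frame(key = case$truth$key, mother_carrier = FALSE,
                    father_carrier = FALSE, mother_affected = FALSE,
                    father_affected = FALSE, confirmed_parentage = TRUE,
                    in_trans = NA, stringsAsFactors = FALSE)
  fam <- runPipeline(case$exome$variants, case$exome$annotations,
                     case$exome$freq_map, case$kb, case$ontology,
                     case$patient, segregation = seg)
  i0 <- which(base$candidates$key == case$truth$key &
              base$candidates$disease_id == case$truth$disease_id)
  i1 <- which(fam$candidates$key == case$truth$key &
              fam$candidates$disease_id == case$truth$disease_id)
  expect_true("PS2" %in% fam$candidates$rules[[i1]])
  expect_gte(fam$candidates$posterior[i1], base$candidates$posterior[i0])
})
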