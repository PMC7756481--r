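# Self-contained synthetic inputs: toy ontologies, knowledge bases,
# patients with imprecision/irrelevance noise, and spiked exomes whose
# frequency spectrum is dominated by common variants so the BA1 stage does
# most of the filtering work, as on real exomes.

#' Fixture generator configuration
#'
#' One global `seed` fans out to fixed per-generator child seeds, so e.g.
#' changing the exome size does not perturb the ontology. All generators
#' are pure functions of (config, seed) and reproduce their output
#' byte-for-byte.
#'
#' @param seed integer master seed.
#' @param ontology list: `depth` (levels below the root, default 8),
#'   `branching` (children per node, default 3), `extra_parent_prob`
#'   (probability that a term at level >= 2 gains an extra `is_a` edge to a
#'   shallower term, default 0.1).
#' @param kb list: `n_genes` (default 200), `n_diseases` (default 150),
#'   `terms_per_disease` (range, default `c(4, 8)`).
#' @param patient list: `n_true_terms` (default 5), `parent_swap_prob`
#'   (imprecision noise: replace a term by one of its parents, default
#'   0.2), `n_noise_terms` (irrelevant findings, default 2).
#' @param exome list: `n_background` (default 500), `common_fraction`
#'   (fraction of background variants with allele frequency above 5\%,
#'   default 0.9).
#' @return nested list of class `fixtureConfig`.
#' @export
fixtureConfig <- function(seed = 1,
                          ontology = list(),
                          kb = list(),
                          patient = list(),
                          exome = list()) {
  cfg <- list(
    seed = as.integer(seed),
    ontology = utils::modifyList(
      list(depth = 8L, branching = 3L, extra_parent_prob = 0.1), ontology),
    kb = utils::modifyList(
      list(n_genes = 200L, n_diseases = 150L, terms_per_disease = c(4L, 8L)), kb),
    patient = utils::modifyList(
      list(n_true_terms = 5L, parent_swap_prob = 0.2, n_noise_terms = 2L), patient),
    exome = utils::modifyList(
      list(n_background = 500L, common_fraction = 0.9), exome)
  )
  stopifnot(cfg$ontology$depth >= 1, cfg$ontology$branching >= 1,
            cfg$kb$n_genes >= 1, cfg$kb$n_diseases >= 1,
            cfg$patient$n_true_terms >= 1,
            cfg$exome$n_background >= 0,
            cfg$exome$common_fraction >= 0, cfg$exome$common_fraction <= 1,
            cfg$ontology$extra_parent_prob >= 0, cfg$ontology$extra_parent_prob <= 1,
            cfg$patient$parent_swap_prob >= 0, cfg$patient$parent_swap_prob <= 1)
  structure(cfg, class = "fixtureConfig")
}

.childSeed <- function(cfg, offset)
  as.integer((abs(as.numeric(cfg$seed)) * 7919 + offset) %% 2147483000)

#' Generate a toy phenotype ontology
#'
#' A levelled DAG: the root spawns `branching` children per node down to
#' `depth` levels; each term at level >= 2 additionally acquires, with
#' probability `extra_parent_prob`, an `is_a` edge to a random strictly
#' shallower non-root term (multi-parent structure, as in real phenotype
#' ontologies). Extra edges never change a term's longest-path depth, which
#' stays equal to its level.
#'
#' @param cfg a [fixtureConfig()].
#' @return an [OntologyGraph-class].
#' @export
makeToyOntology <- function(cfg = fixtureConfig()) {
  oc <- cfg$ontology
  set.seed(.childSeed(cfg, 101L))
  n_per_level <- oc$branching^(0:oc$depth)
  total <- sum(n_per_level)
  ids <- sprintf("HP:%07d", seq_len(total))
  level <- rep(0:oc$depth, n_per_level)
  offset <- cumsum(c(0, n_per_level))  # index of first node per level - 1

  # pool_upto[[lv]]: ids at levels 1 .. lv-1 (candidates for extra parents)
  pool_upto <- lapply(1:max(2L, oc$depth), function(lv)
    if (lv >= 2L) ids[level >= 1L & level < lv] else character())
  wants_extra <- stats::runif(total) < oc$extra_parent_prob

  parents <- vector("list", total)
  names(parents) <- ids
  parents[[1L]] <- character()
  for (i in seq_len(total)[-1L]) {
    lv <- level[i]
    j <- i - offset[lv + 1L]             # position within its level
    primary <- ids[offset[lv] + ((j - 1L) %/% oc$branching) + 1L]
    ps <- primary
    if (lv >= 2L && wants_extra[i]) {
      pool <- pool_upto[[lv]]
      extra <- pool[sample.int(length(pool), 1L)]
      if (extra == primary && length(pool) > 1L)
        extra <- setdiff(pool, primary)[sample.int(length(pool) - 1L, 1L)]
      if (extra != primary) ps <- c(ps, extra)
    }
    parents[[i]] <- ps
  }
  labels <- stats::setNames(sprintf("synthetic term %d (level %d)",
                                    seq_len(total), level), ids)
  labels[1L] <- "synthetic phenotype root"
  ontologyGraph(parents, labels = labels)
}

#' Generate a toy gene-disease knowledge base
#'
#' Diseases draw their phenotype sets from deep ontology terms (depth at
#' least half the maximum), mimicking specific clinical findings.
#' Inheritance modes are sampled AD 70\% / AR 24\% / XL 6\%, matching the
#' mix observed in rare-disease diagnostic cohorts. Genes are sampled with
#' replacement, so some genes carry several diseases and some none.
#'
#' @param cfg a [fixtureConfig()].
#' @param g the [OntologyGraph-class] to draw phenotype terms from.
#' @return a [KnowledgeBase-class].
#' @export
makeToyKB <- function(cfg = fixtureConfig(), g) {
  kc <- cfg$kb
  set.seed(.childSeed(cfg, 202L))
  genes <- sprintf("GENE%04d", seq_len(kc$n_genes))
  ids <- sprintf("DIS:%04d", seq_len(kc$n_diseases))
  inheritance <- sample(c("AD", "AR", "XL"), kc$n_diseases, replace = TRUE,
                        prob = c(0.70, 0.24, 0.06))
  mechanism <- sample(c("LoF", "GoF", "unknown"), kc$n_diseases,
                      replace = TRUE, prob = c(0.6, 0.2, 0.2))
  dis <- data.frame(
    disease_id = ids,
    name = paste("synthetic disease", seq_len(kc$n_diseases)),
    gene = sample(genes, kc$n_diseases, replace = TRUE),
    inheritance = inheritance,
    mechanism = mechanism,
    missense_constrained = stats::runif(kc$n_diseases) < 0.3,
    max_credible_af = ifelse(inheritance == "AR", 2e-3, 2e-4),
    stringsAsFactors = FALSE
  )
  deep <- g@terms[g@depths >= ceiling(max(g@depths) / 2)]
  if (length(deep) < max(kc$terms_per_disease))
    stop("ontology too shallow for the requested disease term sets")
  hpo <- lapply(seq_len(kc$n_diseases), function(i) {
    k <- sample(seq(kc$terms_per_disease[1], kc$terms_per_disease[2]), 1L)
    sample(deep, k)
  })
  names(hpo) <- ids
  new("KnowledgeBase", diseases = dis, hpo = hpo)
}

#' Simulate a patient's phenotype term set for a disease
#'
#' Takes `n_true_terms` of the disease's terms; with probability
#' `parent_swap_prob` each is replaced by one of its (non-root) parents,
#' emulating the clinician recording a less specific ancestor term; then
#' `n_noise_terms` random unrelated terms are added (irrelevant findings).
#'
#' @param g an [OntologyGraph-class].
#' @param kb a [KnowledgeBase-class].
#' @param disease a disease identifier in `kb`.
#' @param cfg a [fixtureConfig()].
#' @param seed optional seed override (defaults to the config's patient
#'   child seed).
#' @return a patient [PhenotypeSet-class].
#' @export
simulatePatient <- function(g, kb, disease, cfg = fixtureConfig(),
                            seed = NULL) {
  pc <- cfg$patient
  if (pc$n_true_terms < 1L)
    stop("a simulated patient needs at least one true disease term")
  set.seed(if (is.null(seed)) .childSeed(cfg, 303L) else seed)
  dterms <- kbPhenotypes(kb, disease)
  truth <- sample(dterms, min(pc$n_true_terms, length(dterms)))
  swapped <- vapply(truth, function(t) {
    if (stats::runif(1) >= pc$parent_swap_prob) return(t)
    ps <- setdiff(g@parents[[get0(t, envir = g@cache$idx)]], g@root)
    if (!length(ps)) t else ps[sample.int(length(ps), 1L)]
  }, character(1))
  pool <- setdiff(g@terms[g@depths >= 1L], c(swapped, dterms))
  noise <- if (pc$n_noise_terms > 0L) sample(pool, pc$n_noise_terms) else character()
  phenotypeSet(g, unique(c(swapped, noise)), role = "patient")
}

.CSQ_POOL <- c(missense_variant = 0.45, synonymous_variant = 0.20,
               intron_variant = 0.15, inframe_indel = 0.05,
               stop_gained = 0.03, frameshift_variant = 0.03,
               splice_donor_variant = 0.02, splice_acceptor_variant = 0.02,
               start_lost = 0.01, stop_lost = 0.04)

#' Simulate a spiked exome
#'
#' Generates `n_background` background variants whose allele-frequency
#' spectrum is a two-component mixture -- a `common_fraction` share drawn
#' uniform on (0.05, 0.5\] (removed by the BA1 stage, as most real exome
#' variants are) and the rest rare, log-uniform on \[1e-6, 1e-3\] or absent
#' from the frequency table entirely -- plus one spiked causal variant
#' consistent with the target disease's mechanism and inheritance mode
#' (loss-of-function mechanism: stop gained; otherwise a hotspot missense
#' matching a known pathogenic change), absent from all population sources.
#'
#' @param g an [OntologyGraph-class] (unused directly; kept for signature
#'   symmetry with the other generators).
#' @param kb a [KnowledgeBase-class].
#' @param disease the causal disease identifier; its gene hosts the spike.
#' @param cfg a [fixtureConfig()].
#' @return list with `variants`, `annotations` (data.frames),
#'   `frequencies` (long data.frame), `freq_map` (list for
#'   [runPipeline()]), and `truth` (spiked key, gene, disease, consequence,
#'   zygosity).
#' @export
simulateExome <- function(g, kb, disease, cfg = fixtureConfig()) {
  ec <- cfg$exome
  set.seed(.childSeed(cfg, 404L))
  drow <- kb@diseases[kb@diseases$disease_id == disease, , drop = FALSE]
  if (nrow(drow) != 1L) stop("unknown disease: ", disease)

  n <- ec$n_background
  n_common <- as.integer(round(n * ec$common_fraction))
  genes <- unique(kb@diseases$gene)

  pos <- sort(sample.int(4e7L, n + 1L)) + 1000L
  chrom <- paste0("chr", sample(1:22, n + 1L, replace = TRUE))
  ref <- sample(c("A", "C", "G", "T"), n + 1L, replace = TRUE)
  alt <- unname(vapply(ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1L), character(1)))
  is_common <- c(sample(rep(c(TRUE, FALSE), c(n_common, n - n_common))), FALSE)
  csq <- c(sample(names(.CSQ_POOL), n, replace = TRUE, prob = .CSQ_POOL), NA)
  zyg <- c(sample(c("het", "hom"), n, replace = TRUE, prob = c(0.8, 0.2)), NA)
  gene <- c(ifelse(stats::runif(n) < 0.8,
                   sample(genes, n, replace = TRUE),
                   sprintf("NOGENE%03d", sample.int(50L, n, replace = TRUE))), NA)

  i_causal <- n + 1L
  causal_csq <- if (identical(drow$mechanism, "LoF")) "stop_gained" else "missense_variant"
  causal_zyg <- switch(drow$inheritance, AD = "het", AR = "hom", XL = "hemi")
  csq[i_causal] <- causal_csq
  zyg[i_causal] <- causal_zyg
  gene[i_causal] <- drow$gene

  variants <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                         zygosity = zyg, qual = round(stats::runif(n + 1L, 30, 99), 1),
                         filter_status = "PASS", stringsAsFactors = FALSE)
  o <- order(factor(variants$chrom, levels = paste0("chr", 1:22)), variants$pos)
  key_causal <- paste(chrom[i_causal], pos[i_causal], ref[i_causal],
                      alt[i_causal], sep = ":")

  miss <- csq == "missense_variant"
  spliceish <- csq %in% .SPLICE_REGION_CSQ
  ann <- data.frame(
    chrom = chrom, pos = pos, ref = ref, alt = alt, gene = gene,
    consequence = csq,
    hgvs_p = ifelse(miss, sprintf("p.Ala%dVal", (pos %% 800L) + 1L), ""),
    missense_meta = ifelse(miss, round(stats::runif(n + 1L), 3), NA_real_),
    splice_ada = ifelse(spliceish, round(stats::runif(n + 1L), 3), NA_real_),
    splice_rf = ifelse(spliceish, round(stats::runif(n + 1L), 3), NA_real_),
    known_pathogenic_aa_match = ifelse(
      miss, sample(c("none", "same_residue", "same_change"), n + 1L,
                   replace = TRUE, prob = c(0.985, 0.010, 0.005)), "none"),
    in_hotspot_domain = miss & stats::runif(n + 1L) < 0.05,
    stringsAsFactors = FALSE
  )
  if (causal_csq == "missense_variant") {
    ann$missense_meta[i_causal] <- round(stats::runif(1, 0.8, 1), 3)
    ann$known_pathogenic_aa_match[i_causal] <- "same_change"
    ann$in_hotspot_domain[i_causal] <- TRUE
    ann$hgvs_p[i_causal] <- "p.Arg123Trp"
  } else {
    ann$hgvs_p[i_causal] <- "p.Arg123Ter"
    ann$missense_meta[i_causal] <- NA_real_
  }

  # frequency spectrum: the causal spike is absent from every source.
  # Common variants always have a gnomad entry (forced above the BA1
  # cutoff), half also an internal-database entry; 70% of rare variants
  # appear in gnomad at log-uniform 1e-6..1e-3, the rest in no source.
  idx_c <- which(is_common[seq_len(n)])
  idx_r <- which(!is_common[seq_len(n)])
  af_c <- pmax(stats::runif(length(idx_c), 0.05, 0.5), 0.0501)
  has_int <- stats::runif(length(idx_c)) < 0.5
  idx_p <- idx_r[stats::runif(length(idx_r)) < 0.7]
  rows_i <- c(idx_c, idx_c[has_int], idx_p)
  freq <- data.frame(
    chrom = chrom[rows_i], pos = pos[rows_i], ref = ref[rows_i],
    alt = alt[rows_i],
    source = rep(c("gnomad", "internal", "gnomad"),
                 c(length(idx_c), sum(has_int), length(idx_p))),
    af = c(signif(af_c, 4),
           signif(af_c[has_int] * stats::runif(sum(has_int), 0.5, 1), 4),
           signif(10^stats::runif(length(idx_p), -6, -3), 4)),
    stringsAsFactors = FALSE
  )
  ckey <- paste(freq$chrom, freq$pos, freq$ref, freq$alt, sep = ":")

  freq_map <- if (nrow(freq)) {
    lapply(split(seq_len(nrow(freq)), ckey),
           function(idx) stats::setNames(freq$af[idx], freq$source[idx]))
  } else list()

  list(
    variants = variants[o, , drop = FALSE],
    annotations = ann[o, , drop = FALSE],
    frequencies = freq[order(factor(freq$chrom, levels = paste0("chr", 1:22)),
                             freq$pos), , drop = FALSE],
    freq_map = freq_map,
    truth = list(key = key_causal, gene = drow$gene, disease_id = disease,
                 consequence = causal_csq, zygosity = causal_zyg)
  )
}

#' Simulate a complete diagnostic case in memory
#'
#' Convenience wrapper: builds the ontology, knowledge base, a causal
#' disease (drawn uniformly), the patient's noisy phenotype set and the
#' spiked exome for one master seed.
#'
#' @param cfg a [fixtureConfig()].
#' @return list with `ontology`, `kb`, `disease_id`, `patient`, `exome`
#'   (the [simulateExome()] list) and `truth`.
#' @export
simulateCase <- function(cfg = fixtureConfig()) {
  g <- makeToyOntology(cfg)
  kb <- makeToyKB(cfg, g)
  set.seed(.childSeed(cfg, 505L))
  disease <- sample(kb@diseases$disease_id, 1L)
  patient <- simulatePatient(g, kb, disease, cfg)
  exo <- simulateExome(g, kb, disease, cfg)
  list(ontology = g, kb = kb, disease_id = disease, patient = patient,
       exome = exo, truth = exo$truth)
}

#' Write a VCF 4.2 file for simulated variants
#'
#' @param variants data.frame with `chrom`, `pos`, `ref`, `alt`,
#'   `zygosity`, `qual`, `filter_status`.
#' @param path output path.
#' @param sample sample name for the genotype column.
#' @return `path`, invisibly.
#' @export
writeVCF <- function(variants, path, sample = "SAMPLE1") {
  gtmap <- c(het = "0/1", hom = "1/1", hemi = "1")
  contigs <- unique(variants$chrom)
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("##contig=<ID=", contigs, ">"),
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t")
  )
  body <- if (nrow(variants)) {
    paste(variants$chrom, variants$pos, ".", variants$ref, variants$alt,
          ifelse(is.na(variants$qual), ".", variants$qual),
          variants$filter_status, ".", "GT", gtmap[variants$zygosity],
          sep = "\t")
  } else character()
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a knowledge base to its three-TSV directory layout
#'
#' @param kb a [KnowledgeBase-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeKnowledgeBase <- function(kb, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dd <- kb@diseases
  utils::write.table(dd[, c("gene", "disease_id")],
                     file.path(dir, "genes.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(dd[, c("disease_id", "name", "inheritance", "mechanism",
                            "missense_constrained", "max_credible_af")],
                     file.path(dir, "diseases.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  hpo <- data.frame(
    disease_id = rep(names(kb@hpo), lengths(kb@hpo)),
    term = unlist(kb@hpo, use.names = FALSE), stringsAsFactors = FALSE)
  utils::write.table(hpo, file.path(dir, "disease_hpo.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Generate and write a complete fixture directory
#'
#' Writes `hp.obo`, `genes.tsv`, `diseases.tsv`, `disease_hpo.tsv`,
#' `sample.vcf`, `ann.tsv`, `freq.tsv` and `truth.json` (the spiked
#' answer plus the simulated patient's terms, for tests) under `dir`.
#' Deterministic per config seed.
#'
#' @param cfg a [fixtureConfig()].
#' @param dir output directory (created if needed).
#' @return the [simulateCase()] list, invisibly.
#' @export
writeFixtures <- function(cfg = fixtureConfig(), dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  case <- simulateCase(cfg)
  writeOBO(case$ontology, file.path(dir, "hp.obo"))
  writeKnowledgeBase(case$kb, dir)
  writeVCF(case$exome$variants, file.path(dir, "sample.vcf"))
  utils::write.table(case$exome$annotations, file.path(dir, "ann.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(case$exome$frequencies, file.path(dir, "freq.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    c(case$truth, list(patient_terms = psTerms(case$patient), seed = cfg$seed)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(case)
}
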