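# The filtering funnel: population-frequency exclusion, gene-disease
# matching, ACMG classification, low-impact exclusion, inheritance-pattern
# filtering, phenotype similarity, tier assignment and within-tier ranking.

#' Bayesian tier thresholds
#'
#' Candidates are stratified by posterior probability of pathogenicity:
#' tier 1 above 0.9, tier 2 above 0.499, tier 3 above 0.1 (all strictly
#' greater-than); candidates at or below 0.1 are dropped from the report
#' but counted in the funnel.
#'
#' @param t1,t2,t3 tier boundaries; must satisfy `1 > t1 > t2 > t3 > 0`.
#' @return a named list.
#' @export
tierThresholds <- function(t1 = 0.9, t2 = 0.499, t3 = 0.1) {
  stopifnot(1 > t1, t1 > t2, t2 > t3, t3 > 0)
  list(t1 = t1, t2 = t2, t3 = t3)
}

#' Assign a candidate to a posterior tier
#'
#' @param posterior numeric vector of posteriors.
#' @param thresholds a [tierThresholds()] list.
#' @return integer vector: 1, 2, 3 or NA (below tier 3, to be dropped).
#' @export
assignTier <- function(posterior, thresholds = tierThresholds()) {
  ifelse(posterior > thresholds$t1, 1L,
  ifelse(posterior > thresholds$t2, 2L,
  ifelse(posterior > thresholds$t3, 3L, NA_integer_)))
}

#' Exclude common variants (BA1 frequency filter)
#'
#' Drops a variant when any population source reports an allele frequency
#' strictly greater than `cutoff` (default 5\%). Variants with no frequency
#' data are kept: absence from population controls is rarity evidence.
#'
#' @param avs annotated-variant data.frame (with `pop_af` list column).
#' @param cutoff allele-frequency cutoff (default 0.05).
#' @return the surviving rows.
#' @export
frequencyFilter <- function(avs, cutoff = 0.05) {
  if (nrow(avs) == 0L) return(avs)
  keep <- vapply(avs$pop_af, function(af) {
    length(af) == 0L || max(af) <= cutoff
  }, logical(1))
  avs[keep, , drop = FALSE]
}

#' Fan variants out to gene-linked diseases
#'
#' One candidate pair per disease linked to the variant's gene; variants in
#' genes with no disease entry (or with no gene annotation) are dropped.
#'
#' @param avs annotated-variant data.frame.
#' @param kb a [KnowledgeBase-class].
#' @return candidate data.frame: variant columns plus `disease_id`,
#'   `disease_name`, `inheritance`, `mechanism`.
#' @export
geneDiseaseMatch <- function(avs, kb) {
  dd <- kb@diseases
  out <- lapply(seq_len(nrow(avs)), function(i) {
    gene <- avs$gene[i]
    if (is.na(gene)) return(NULL)
    hits <- dd[dd$gene == gene, , drop = FALSE]
    if (nrow(hits) == 0L) return(NULL)
    row <- avs[rep(i, nrow(hits)), , drop = FALSE]
    row$disease_id <- hits$disease_id
    row$disease_name <- hits$name
    row$inheritance <- hits$inheritance
    row$mechanism <- hits$mechanism
    row
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- avs[0, , drop = FALSE]
    out$disease_id <- out$disease_name <- out$inheritance <- out$mechanism <- character(0)
  }
  rownames(out) <- NULL
  out
}

#' Exclude low-impact candidates
#'
#' Drops pairs classified benign or likely benign, and non-coding
#' (intronic/intergenic) consequences unless a splice in-silico score
#' reaches the deleteriousness cutoff. VUS are retained: they are
#' resolvable by family testing and phenotype reassessment.
#'
#' @param pairs candidate data.frame carrying `acmg_class`, `consequence`
#'   and `insilico`.
#' @param insilicoCutoff splice-score rescue threshold (default 0.5).
#' @return the surviving rows.
#' @export
impactFilter <- function(pairs, insilicoCutoff = 0.5) {
  if (nrow(pairs) == 0L) return(pairs)
  benign <- pairs$acmg_class %in% c("B", "LB")
  noncoding <- pairs$consequence %in% .NONCODING_CSQ
  rescued <- vapply(seq_len(nrow(pairs)), function(i) {
    s <- pairs$insilico[[i]]
    spl <- s[intersect(c("splice_ada", "splice_rf"), names(s))]
    length(spl) > 0L && any(spl >= insilicoCutoff)
  }, logical(1))
  pairs[!benign & (!noncoding | rescued), , drop = FALSE]
}

#' Filter candidates on the disease's inheritance pattern
#'
#' Dominant (AD) disease keeps any zygosity. Recessive (AR) disease keeps
#' homozygous calls, or heterozygous calls only when at least two surviving
#' heterozygous variants hit the same gene for that disease (phase unknown
#' until family testing; such rows are flagged `phase_unknown`). X-linked
#' (XL) keeps hemizygous (male) and homozygous calls; heterozygous female
#' carriers are kept only when `keepHetFemale` is set.
#'
#' @param pairs candidate data.frame.
#' @param keepHetFemale keep XL heterozygous calls (default FALSE).
#' @return the surviving rows, with a `phase_unknown` logical column.
#' @export
inheritanceFilter <- function(pairs, keepHetFemale = FALSE) {
  if (nrow(pairs) == 0L) {
    pairs$phase_unknown <- logical(0)
    return(pairs)
  }
  pairs$phase_unknown <- FALSE
  gd <- paste(pairs$gene, pairs$disease_id)
  het_counts <- table(gd[pairs$zygosity == "het"])
  keep <- logical(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    inh <- pairs$inheritance[i]
    zyg <- pairs$zygosity[i]
    if (inh == "AD") {
      keep[i] <- TRUE
    } else if (inh == "AR") {
      if (zyg %in% c("hom", "hemi")) {
        keep[i] <- TRUE
      } else if (zyg == "het" && !is.na(het_counts[gd[i]]) && het_counts[gd[i]] >= 2L) {
        keep[i] <- TRUE
        pairs$phase_unknown[i] <- TRUE
      }
    } else if (inh == "XL") {
      keep[i] <- zyg %in% c("hemi", "hom") || (zyg == "het" && keepHetFemale)
    }
  }
  pairs[keep, , drop = FALSE]
}

#' Rank candidates: tier first, then phenotype similarity
#'
#' Deterministic sort key: tier ascending, similarity score descending,
#' posterior descending, then gene, disease and variant key
#' lexicographically as tie-breaks. Assigns the `rank` column.
#'
#' @param candidates candidate data.frame with `tier`, `similarity`,
#'   `posterior` columns.
#' @return the data.frame in rank order with `rank` filled in.
#' @export
rankCandidates <- function(candidates) {
  if (nrow(candidates) == 0L) {
    candidates$rank <- integer(0)
    return(candidates)
  }
  o <- order(candidates$tier, -candidates$similarity, -candidates$posterior,
             candidates$gene, candidates$disease_id, candidates$key)
  candidates <- candidates[o, , drop = FALSE]
  candidates$rank <- seq_len(nrow(candidates))
  rownames(candidates) <- NULL
  candidates
}

.logStage <- function(log, stage, n_in, n_out, pairs_out = NA_integer_) {
  rbind(log, data.frame(stage = stage, variants_in = n_in,
                        variants_out = n_out, pairs_out = pairs_out,
                        stringsAsFactors = FALSE))
}

.nvar <- function(df) length(unique(df$key))

#' Run the full prioritization pipeline
#'
#' Composes the stages in fixed order: frequency filter (BA1), gene-disease
#' matching, ACMG rule evaluation + Bayesian classification, low-impact
#' exclusion, inheritance filtering, phenotype similarity scoring, tier
#' assignment, phenotype-specificity update (PP4), optional family-evidence
#' update, and final ranking. Every stage's in/out counts are recorded in
#' the funnel log.
#'
#' Inputs may be file paths or pre-loaded objects, so the pipeline runs
#' identically on disk fixtures and in-memory simulations.
#'
#' @param vcf VCF path or a variant data.frame from [readVariants()].
#' @param annotations annotation TSV path or data.frame.
#' @param frequencies frequency TSV path or list from [readFrequencyTable()].
#' @param kb knowledge-base directory path or [KnowledgeBase-class].
#' @param ontology OBO path or [OntologyGraph-class].
#' @param patientTerms character vector of patient phenotype term ids, or a
#'   [PhenotypeSet-class].
#' @param config a [bayesConfig()].
#' @param thresholds a [tierThresholds()] list.
#' @param segregation optional data.frame of family-testing records, one
#'   row per variant key (columns `key`, `mother_carrier`, `father_carrier`,
#'   `mother_affected`, `father_affected`, `confirmed_parentage`,
#'   `in_trans`); a record whose key matches no candidate variant is an
#'   error.
#' @param skipUnknownTerms drop unknown patient terms with a warning.
#' @return list with elements `candidates` (ranked data.frame) and
#'   `funnel` (per-stage count data.frame).
#' @export
runPipeline <- function(vcf, annotations, frequencies, kb, ontology,
                        patientTerms, config = bayesConfig(),
                        thresholds = tierThresholds(), segregation = NULL,
                        skipUnknownTerms = FALSE) {
  if (is.character(vcf)) vcf <- readVariants(vcf)
  if (is.character(annotations)) annotations <- readAnnotationTable(annotations)
  if (is.character(frequencies)) frequencies <- readFrequencyTable(frequencies)
  if (is.character(ontology)) ontology <- loadOBO(ontology)
  if (is.character(kb) && length(kb) == 1L && dir.exists(kb))
    kb <- loadKnowledgeBase(kb, g = ontology)
  patient <- if (is(patientTerms, "PhenotypeSet")) patientTerms
             else phenotypeSet(ontology, patientTerms, role = "patient",
                               skipUnknown = skipUnknownTerms)

  funnel <- data.frame(stage = character(), variants_in = integer(),
                       variants_out = integer(), stringsAsFactors = FALSE)
  av <- annotateVariants(vcf, annotations, frequencies)

  n0 <- .nvar(av)
  av <- frequencyFilter(av, cutoff = config$ba1_af)
  funnel <- .logStage(funnel, "frequency_filter", n0, .nvar(av))

  n1 <- .nvar(av)
  pairs <- geneDiseaseMatch(av, kb)
  funnel <- .logStage(funnel, "gene_disease_match", n1, .nvar(pairs),
                      pairs_out = nrow(pairs))

  # ACMG classification (consumed by the impact filter)
  if (nrow(pairs) > 0L) {
    rules <- vector("list", nrow(pairs))
    for (i in seq_len(nrow(pairs)))
      rules[[i]] <- as.character(evaluateRules(pairs[i, , drop = FALSE], kb,
                                               pairs$disease_id[i], config))
    pairs$rules <- I(rules)
    pairs$posterior <- vapply(rules, combinePosterior, numeric(1), cfg = config)
    pairs$acmg_class <- classifyPosterior(pairs$posterior)
  } else {
    pairs$rules <- I(list())
    pairs$posterior <- numeric(0)
    pairs$acmg_class <- character(0)
  }

  n2 <- .nvar(pairs)
  pairs <- impactFilter(pairs, insilicoCutoff = config$insilico_cutoff)
  funnel <- .logStage(funnel, "impact_filter", n2, .nvar(pairs),
                      pairs_out = nrow(pairs))

  n3 <- .nvar(pairs)
  pairs <- inheritanceFilter(pairs, keepHetFemale = config$xl_keep_het_female)
  funnel <- .logStage(funnel, "inheritance_filter", n3, .nvar(pairs),
                      pairs_out = nrow(pairs))

  # phenotype similarity per candidate disease
  if (nrow(pairs) > 0L) {
    scores <- lapply(unique(pairs$disease_id), function(d) {
      similarityScore(ontology, patient, kb@hpo[[d]])
    })
    names(scores) <- unique(pairs$disease_id)
    pairs$similarity <- vapply(pairs$disease_id,
                               function(d) scores[[d]]@value, numeric(1))
    pairs$s1 <- vapply(pairs$disease_id, function(d) scores[[d]]@s1, numeric(1))
    pairs$s2 <- vapply(pairs$disease_id, function(d) scores[[d]]@s2, numeric(1))
  } else {
    pairs$similarity <- pairs$s1 <- pairs$s2 <- numeric(0)
  }

  n4 <- .nvar(pairs)
  pairs$tier <- assignTier(pairs$posterior, thresholds)
  pairs <- pairs[!is.na(pairs$tier), , drop = FALSE]
  funnel <- .logStage(funnel, "tier_assignment", n4, .nvar(pairs),
                      pairs_out = nrow(pairs))

  # PP4: phenotype-specificity update (does not move tiers; see vignette)
  if (nrow(pairs) > 0L) {
    eligible <- unique(paste(pairs$gene, pairs$disease_id)[
      pairs$similarity >= config$pp4_threshold])
    for (i in seq_len(nrow(pairs))) {
      uniq <- length(eligible) == 1L &&
        identical(paste(pairs$gene[i], pairs$disease_id[i]), eligible)
      prof <- evidenceProfile(pairs$rules[[i]], config)
      prof <- applyPhenotypeRule(prof, pairs$similarity[i],
                                 uniqueCandidate = uniq)
      pairs$rules[[i]] <- prof@rules
      pairs$posterior[i] <- prof@posterior
      pairs$acmg_class[i] <- prof@acmgClass
    }
  }

  pairs$rejected <- rep(FALSE, nrow(pairs))
  if (!is.null(segregation) && nrow(pairs) > 0L) {
    unknown <- setdiff(segregation$key, pairs$key)
    if (length(unknown))
      stop("segregation record(s) for variant(s) not among candidates: ",
           paste(unknown, collapse = ", "))
    for (i in seq_len(nrow(pairs))) {
      srow <- segregation[segregation$key == pairs$key[i], , drop = FALSE]
      if (nrow(srow) == 0L) next
      prof <- evidenceProfile(pairs$rules[[i]], config)
      prof <- applyFamilyEvidence(prof, srow, pairs$inheritance[i])
      pairs$rules[[i]] <- prof@rules
      pairs$posterior[i] <- prof@posterior
      pairs$acmg_class[i] <- prof@acmgClass
      pairs$rejected[i] <- prof@rejected
    }
  }

  ranked <- rankCandidates(pairs)
  list(candidates = ranked, funnel = funnel)
}
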