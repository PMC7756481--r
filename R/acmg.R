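# ACMG/AMP evidence engine: deterministic rule firing from variant
# annotations, exponential Bayesian combination of evidence strengths into
# a posterior probability of pathogenicity, five-class labelling, and
# evidence updates from phenotype specificity (PP4) and family testing
# (PS2/PM6/PM3/BS4/BP2).

# Rule code -> default ACMG strength. The enum is closed: only rules
# computable from the modelled annotations are implemented.
.RULE_STRENGTH <- c(
  PVS1 = "very_strong",
  PS1 = "strong", PS2 = "strong",
  PM1 = "moderate", PM2 = "moderate", PM3 = "moderate", PM4 = "moderate",
  PM5 = "moderate", PM6 = "moderate",
  PP2 = "supporting", PP3 = "supporting", PP4 = "supporting",
  BA1 = "stand_alone_benign",
  BS1 = "strong_benign", BS4 = "strong_benign",
  BP2 = "supporting_benign", BP4 = "supporting_benign", BP7 = "supporting_benign"
)

# Evidence strength -> exponent in the odds-of-pathogenicity product;
# benign strengths subtract. BA1 is handled by short-circuit, not exponent.
.STRENGTH_EXP <- c(
  very_strong = 1, strong = 1 / 2, moderate = 1 / 4, supporting = 1 / 8,
  strong_benign = -1 / 2, supporting_benign = -1 / 8,
  stand_alone_benign = 0
)

.LOF_CSQ <- c("stop_gained", "frameshift_variant", "splice_acceptor_variant",
              "splice_donor_variant", "start_lost")
.SPLICE_REGION_CSQ <- c("splice_acceptor_variant", "splice_donor_variant",
                        "splice_region_variant", "intron_variant",
                        "synonymous_variant")
.NONCODING_CSQ <- c("intron_variant", "intergenic_variant",
                    "upstream_gene_variant", "downstream_gene_variant")

#' Configuration of the Bayesian evidence combiner and rule thresholds
#'
#' Evidence items multiply odds of pathogenicity: combined odds are
#' `odds_pvs ^ (sum of pathogenic exponents - sum of benign exponents)`
#' with exponents 1, 1/2, 1/4, 1/8 for very strong, strong, moderate and
#' supporting evidence, and the posterior is
#' `odds * prior / ((odds - 1) * prior + 1)`. BA1 is stand-alone benign and
#' short-circuits the posterior to 0.
#'
#' @param prior prior probability of pathogenicity (default 0.10).
#' @param odds_pvs odds of pathogenicity for one very strong item
#'   (default 350).
#' @param pm2_af_dominant maximum allele frequency treated as "rare enough"
#'   for PM2 in dominant/X-linked disease (default 1e-4).
#' @param pm2_af_recessive PM2 frequency cutoff for recessive disease
#'   (default 1e-3).
#' @param ba1_af stand-alone benign allele-frequency cutoff (strictly
#'   greater than; default 0.05).
#' @param insilico_cutoff per-tool deleteriousness threshold: scores at or
#'   above it count as predicted detrimental (default 0.5).
#' @param pp4_threshold minimum similarity score (0-10 scale) for the
#'   phenotype-specificity rule PP4 (default 5).
#' @param pp4_require_unique apply PP4 only when the disease-gene pair is
#'   the unique candidate explanation reaching the threshold (default TRUE).
#' @param xl_keep_het_female keep heterozygous female calls for X-linked
#'   disease in the inheritance filter (default FALSE).
#' @return a named list of class `bayesConfig`.
#' @export
bayesConfig <- function(prior = 0.10, odds_pvs = 350,
                        pm2_af_dominant = 1e-4, pm2_af_recessive = 1e-3,
                        ba1_af = 0.05, insilico_cutoff = 0.5,
                        pp4_threshold = 5, pp4_require_unique = TRUE,
                        xl_keep_het_female = FALSE) {
  stopifnot(prior > 0, prior < 1, odds_pvs > 1)
  structure(list(prior = prior, odds_pvs = odds_pvs,
                 pm2_af_dominant = pm2_af_dominant,
                 pm2_af_recessive = pm2_af_recessive,
                 ba1_af = ba1_af, insilico_cutoff = insilico_cutoff,
                 pp4_threshold = pp4_threshold,
                 pp4_require_unique = pp4_require_unique,
                 xl_keep_het_female = xl_keep_het_female),
            class = "bayesConfig")
}

#' Combine ACMG evidence items into a posterior probability
#'
#' @param rules character vector of fired rule codes (duplicates collapsed).
#' @param cfg a [bayesConfig()].
#' @return posterior probability of pathogenicity in \[0, 1\]; with no
#'   evidence the posterior equals the prior; BA1 forces 0.
#' @examples
#' combinePosterior(character())        # prior, 0.10
#' combinePosterior(c("PVS1", "PM2"))   # ~0.994
#' @export
combinePosterior <- function(rules, cfg = bayesConfig()) {
  rules <- unique(rules)
  bad <- setdiff(rules, names(.RULE_STRENGTH))
  if (length(bad)) stop("unknown ACMG rule(s): ", paste(bad, collapse = ", "))
  if ("BA1" %in% rules) return(0)
  expo <- sum(.STRENGTH_EXP[.RULE_STRENGTH[rules]])
  odds <- cfg$odds_pvs^expo
  (odds * cfg$prior) / ((odds - 1) * cfg$prior + 1)
}

#' Map a posterior probability to the five ACMG classes
#'
#' Boundaries: posterior >= 0.99 is pathogenic (P); \[0.90, 0.99) likely
#' pathogenic (LP); (0.10, 0.90) uncertain (VUS); (0.001, 0.10\] likely
#' benign (LB); <= 0.001 benign (B). Pathogenic-side boundaries are
#' inclusive upward, benign-side inclusive downward.
#'
#' @param posterior numeric vector of posteriors in \[0, 1\].
#' @return character vector of class labels.
#' @export
classifyPosterior <- function(posterior) {
  stopifnot(all(posterior >= 0 & posterior <= 1))
  ifelse(posterior >= 0.99, "P",
  ifelse(posterior >= 0.90, "LP",
  ifelse(posterior > 0.10, "VUS",
  ifelse(posterior > 0.001, "LB", "B"))))
}

#' Construct an evidence profile from a set of fired rules
#'
#' @param rules character vector of rule codes.
#' @param cfg a [bayesConfig()].
#' @param notes optional named character vector of provenance notes.
#' @param rejected logical rejection flag.
#' @return an [EvidenceProfile-class] with posterior and class computed.
#' @export
evidenceProfile <- function(rules = character(), cfg = bayesConfig(),
                            notes = character(), rejected = FALSE) {
  rules <- unique(rules)
  post <- combinePosterior(rules, cfg)
  new("EvidenceProfile", rules = rules, notes = notes,
      posterior = post, acmgClass = classifyPosterior(post),
      rejected = rejected, config = unclass(cfg))
}

#' Add an evidence item to a profile (idempotent)
#'
#' @param profile an [EvidenceProfile-class].
#' @param rule a rule code.
#' @param note optional provenance note.
#' @param rejected set the rejection flag as well.
#' @return the updated profile with posterior and class recomputed.
#' @export
addEvidence <- function(profile, rule, note = NULL, rejected = FALSE) {
  if (!rule %in% names(.RULE_STRENGTH)) stop("unknown ACMG rule: ", rule)
  rules <- union(profile@rules, rule)
  notes <- profile@notes
  if (!is.null(note)) notes[rule] <- note
  cfg <- do.call(bayesConfig, profile@config)
  evidenceProfile(rules, cfg, notes,
                  rejected = profile@rejected || rejected)
}

# In-silico tools relevant to a consequence: the missense metapredictor for
# missense changes, the two splice predictors for splice-region/synonymous/
# intronic changes. Truncating consequences have no applicable predictor.
.relevantScores <- function(consequence, insilico) {
  tools <- if (identical(consequence, "missense_variant")) {
    "missense_meta"
  } else if (consequence %in% .SPLICE_REGION_CSQ) {
    c("splice_ada", "splice_rf")
  } else {
    character()
  }
  s <- insilico[intersect(tools, names(insilico))]
  s[!is.na(s)]
}

#' Fire ACMG evidence rules for one variant-disease pair
#'
#' Deterministic mapping from the variant's annotations and the disease's
#' knowledge-base entry to evidence items:
#' \itemize{
#'   \item BA1: any population allele frequency above `ba1_af` (5\%).
#'   \item PVS1: null consequence (stop gained, frameshift, canonical
#'     splice, start lost) in a gene whose disease mechanism is
#'     loss-of-function.
#'   \item PS1 / PM5: same amino-acid change / same residue as a known
#'     pathogenic variant.
#'   \item PM1: missense in a mutational hotspot or critical domain.
#'   \item PM2: absent from all population sources, or maximum frequency
#'     below the inheritance-specific cutoff.
#'   \item PM4: protein-length change (in-frame indel, stop lost).
#'   \item PP2: missense in a missense-constrained gene.
#'   \item PP3 / BP4: all applicable in-silico scores at/above, resp.
#'     strictly below, the 0.5 cutoff.
#'   \item BS1: frequency above the disease's maximum credible allele
#'     frequency but not BA1-common.
#'   \item BP7: synonymous with no predicted splice impact.
#' }
#'
#' @param av a single annotated-variant record: a list or one-row
#'   data.frame with fields `consequence`, `pop_af` (named numeric vector,
#'   possibly empty), `insilico` (named numeric vector),
#'   `known_pathogenic_aa_match` (`"none"`, `"same_change"`,
#'   `"same_residue"`), `in_hotspot_domain` (logical).
#' @param kb a [KnowledgeBase-class].
#' @param disease a disease identifier linked to `av`'s gene.
#' @param cfg a [bayesConfig()].
#' @return character vector of fired rule codes, with a `notes` attribute.
#' @export
evaluateRules <- function(av, kb, disease, cfg = bayesConfig()) {
  av <- .asRecord(av)
  drow <- kb@diseases[kb@diseases$disease_id == disease, , drop = FALSE]
  if (nrow(drow) != 1L) stop("unknown disease: ", disease)
  if (!is.null(av$gene) && !identical(drow$gene, av$gene))
    stop("disease ", disease, " is not linked to gene ", av$gene)

  csq <- av$consequence
  af <- av$pop_af
  maxaf <- if (length(af)) max(af) else NA_real_
  rules <- character()
  notes <- character()
  fire <- function(rule, note) {
    rules <<- c(rules, rule)
    notes[rule] <<- note
  }

  if (length(af) && maxaf > cfg$ba1_af)
    fire("BA1", sprintf("allele frequency %.3g > %.3g", maxaf, cfg$ba1_af))

  if (csq %in% .LOF_CSQ && identical(drow$mechanism, "LoF"))
    fire("PVS1", paste0("null variant (", csq, ") in LoF-mechanism gene"))

  match_ <- av$known_pathogenic_aa_match
  if (identical(match_, "same_change"))
    fire("PS1", "same amino-acid change as established pathogenic variant")
  if (identical(match_, "same_residue"))
    fire("PM5", "novel change at residue with established pathogenic variant")

  if (isTRUE(av$in_hotspot_domain) && identical(csq, "missense_variant"))
    fire("PM1", "missense in mutational hotspot / critical domain")

  pm2_cut <- if (identical(drow$inheritance, "AR")) cfg$pm2_af_recessive else cfg$pm2_af_dominant
  if (length(af) == 0L)
    fire("PM2", "absent from all population frequency sources")
  else if (maxaf < pm2_cut)
    fire("PM2", sprintf("max allele frequency %.3g < %.3g", maxaf, pm2_cut))

  if (csq %in% c("inframe_indel", "inframe_insertion", "inframe_deletion", "stop_lost"))
    fire("PM4", paste0("protein length change (", csq, ")"))

  if (identical(csq, "missense_variant") && isTRUE(drow$missense_constrained))
    fire("PP2", "missense in missense-constrained gene")

  rel <- .relevantScores(csq, av$insilico)
  if (length(rel) && all(rel >= cfg$insilico_cutoff))
    fire("PP3", sprintf("all %d applicable in-silico scores >= %.2g",
                        length(rel), cfg$insilico_cutoff))
  if (length(rel) && all(rel < cfg$insilico_cutoff))
    fire("BP4", sprintf("all %d applicable in-silico scores < %.2g",
                        length(rel), cfg$insilico_cutoff))

  if (length(af) && !is.na(drow$max_credible_af) &&
      maxaf > drow$max_credible_af && maxaf <= cfg$ba1_af)
    fire("BS1", sprintf("allele frequency %.3g above disease-credible %.3g",
                        maxaf, drow$max_credible_af))

  if (identical(csq, "synonymous_variant")) {
    spl <- av$insilico[intersect(c("splice_ada", "splice_rf"), names(av$insilico))]
    spl <- spl[!is.na(spl)]
    if (!length(spl) || all(spl < cfg$insilico_cutoff))
      fire("BP7", "synonymous, no predicted splice impact")
  }

  structure(unique(rules), notes = notes)
}

# Normalize a one-row data.frame (possibly with list columns) into a plain
# list record.
.asRecord <- function(av) {
  if (is.data.frame(av)) {
    stopifnot(nrow(av) == 1L)
    av <- lapply(av, function(col) if (is.list(col)) col[[1L]] else col)
  }
  if (is.null(av$pop_af)) av$pop_af <- numeric()
  if (is.null(av$insilico)) av$insilico <- numeric()
  av$pop_af <- av$pop_af[!is.na(av$pop_af)]
  av
}

#' Add the phenotype-specificity rule PP4
#'
#' PP4 (supporting) fires when the candidate's phenotype similarity score
#' reaches `threshold` (default 5, the score above which confirmation was
#' markedly more likely) and, when required, the disease-gene pair is the
#' unique candidate explanation reaching that threshold for the patient's
#' phenotype (`uniqueCandidate`). Idempotent; posterior and class are
#' recomputed.
#'
#' @param profile an [EvidenceProfile-class].
#' @param similarity a [SimilarityScore-class] or a plain number (0-10).
#' @param threshold similarity threshold (default from the profile config).
#' @param uniqueCandidate is this disease-gene pair the unique candidate
#'   explanation? Only consulted when the config requires uniqueness.
#' @return the (possibly updated) profile.
#' @export
applyPhenotypeRule <- function(profile, similarity, threshold = NULL,
                               uniqueCandidate = TRUE) {
  sim <- if (is(similarity, "SimilarityScore")) similarity@value else similarity
  cfg <- profile@config
  if (is.null(threshold)) threshold <- cfg$pp4_threshold
  need_unique <- isTRUE(cfg$pp4_require_unique)
  if (sim >= threshold && (!need_unique || isTRUE(uniqueCandidate)))
    addEvidence(profile, "PP4",
                sprintf("phenotype similarity %.2f >= %.2f", sim, threshold))
  else
    profile
}

#' Update an evidence profile from family (segregation) testing
#'
#' Interprets a trio segregation record as evidence-update operations:
#' \itemize{
#'   \item variant absent in both parents with confirmed parentage: PS2
#'     (confirmed de novo); parentage unconfirmed: PM6 (assumed de novo).
#'   \item recessive disease, variant in trans with the partner variant:
#'     PM3; in cis: BP2 and the candidate is rejected.
#'   \item dominant high-penetrance disease with the variant inherited from
#'     an unaffected parent: BS4 and the candidate is rejected.
#' }
#'
#' @param profile an [EvidenceProfile-class].
#' @param seg a list or one-row data.frame with fields `proband_zygosity`,
#'   `mother_carrier`, `father_carrier` (logical or NA), `mother_affected`,
#'   `father_affected` (logical or NA), `confirmed_parentage` (logical),
#'   `in_trans` (logical or NA; recessive two-variant phase).
#' @param inheritance the disease inheritance mode (`"AD"`, `"AR"`, `"XL"`).
#' @param highPenetrance treat a dominant disease as highly penetrant when
#'   weighing transmission from an unaffected parent (default TRUE).
#' @return the updated profile; `isRejected()` reports contradiction.
#' @export
applyFamilyEvidence <- function(profile, seg, inheritance,
                                highPenetrance = TRUE) {
  seg <- .asRecord(seg)
  stopifnot(inheritance %in% c("AD", "AR", "XL"))
  mc <- seg$mother_carrier
  fc <- seg$father_carrier

  if (isFALSE(mc) && isFALSE(fc)) {
    if (isTRUE(seg$confirmed_parentage))
      profile <- addEvidence(profile, "PS2", "confirmed de novo (parentage confirmed)")
    else
      profile <- addEvidence(profile, "PM6", "assumed de novo (parentage not confirmed)")
  }

  if (identical(inheritance, "AR")) {
    if (isTRUE(seg$in_trans))
      profile <- addEvidence(profile, "PM3", "in trans with partner variant")
    else if (isFALSE(seg$in_trans))
      profile <- addEvidence(profile, "BP2", "in cis with partner variant",
                             rejected = TRUE)
  }

  if (identical(inheritance, "AD") && isTRUE(highPenetrance)) {
    from_unaffected <-
      (isTRUE(mc) && isFALSE(seg$mother_affected)) ||
      (isTRUE(fc) && isFALSE(seg$father_affected))
    if (from_unaffected)
      profile <- addEvidence(profile, "BS4",
                             "inherited from asymptomatic parent of high-penetrance dominant disease",
                             rejected = TRUE)
  }
  profile
}
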