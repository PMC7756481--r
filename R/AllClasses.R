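#' @import methods
NULL

#' Phenotype ontology as a rooted directed acyclic graph
#'
#' An `OntologyGraph` holds a set of phenotype terms connected by `is_a`
#' edges (child to parent), rooted at a single most-general term. Term depth
#' is defined as the number of edges on the *longest* path from the root to
#' the term, so that in a multi-parent DAG a term's depth reflects its most
#' specific placement. Depths are computed once at construction; ancestor
#' sets are memoised on first use.
#'
#' @slot terms character vector of term identifiers.
#' @slot parents named list mapping each term to the character vector of its
#'   `is_a` parents (empty for the root).
#' @slot children named list, the reverse of `parents`.
#' @slot root the single root term identifier.
#' @slot depths named integer vector of longest-path depths (root is 0).
#' @slot labels named character vector of human-readable term names.
#' @slot alts named character vector mapping alternative (superseded) term
#'   identifiers to their canonical identifier.
#' @slot cache environment used to memoise ancestor sets.
#'
#' @seealso [loadOBO()], [ontologyGraph()], [termDepth()], [termAncestors()],
#'   [mcaDepth()]
#' @export
setClass("OntologyGraph",
  representation(
    terms = "character",
    parents = "list",
    children = "list",
    root = "character",
    depths = "integer",
    labels = "character",
    alts = "character",
    cache = "environment"
  )
)

setValidity("OntologyGraph", function(object) {
  msg <- character()
  if (length(object@root) != 1L)
    msg <- c(msg, "exactly one root term is required")
  if (!all(object@terms %in% names(object@parents)))
    msg <- c(msg, "every term must have a parent entry")
  if (length(object@depths) != length(object@terms))
    msg <- c(msg, "depth vector must cover every term")
  if (length(object@root) == 1L && !identical(unname(object@depths[object@root]), 0L))
    msg <- c(msg, "root must have depth 0")
  if (length(msg)) msg else TRUE
})

#' A patient's or disease's set of phenotype terms
#'
#' @slot terms character vector of term identifiers, all present in the
#'   ontology the set was validated against, duplicates removed, root
#'   excluded.
#' @slot role `"patient"` or `"disease"`.
#'
#' @seealso [phenotypeSet()]
#' @export
setClass("PhenotypeSet",
  representation(terms = "character", role = "character")
)

setValidity("PhenotypeSet", function(object) {
  msg <- character()
  if (length(object@terms) == 0L)
    msg <- c(msg, "a phenotype set must contain at least one term")
  if (anyDuplicated(object@terms))
    msg <- c(msg, "duplicate terms in phenotype set")
  if (!object@role %in% c("patient", "disease"))
    msg <- c(msg, "role must be 'patient' or 'disease'")
  if (length(msg)) msg else TRUE
})

#' Gene-disease knowledge base
#'
#' Local stand-in for OMIM/ClinVar-style disease knowledge: a gene-to-disease
#' map plus, per disease, its inheritance mode, disease mechanism, phenotype
#' (HPO-style) term set, whether the gene is constrained against missense
#' variation, and the maximum credible population allele frequency for a
#' causal variant.
#'
#' @slot diseases data.frame with columns `disease_id`, `name`, `gene`,
#'   `inheritance` (AD/AR/XL), `mechanism` (LoF/GoF/unknown),
#'   `missense_constrained` (logical), `max_credible_af` (numeric).
#' @slot hpo named list mapping `disease_id` to a character vector of
#'   phenotype term identifiers.
#'
#' @seealso [loadKnowledgeBase()], [makeToyKB()]
#' @export
setClass("KnowledgeBase",
  representation(diseases = "data.frame", hpo = "list")
)

setValidity("KnowledgeBase", function(object) {
  msg <- character()
  need <- c("disease_id", "name", "gene", "inheritance", "mechanism",
            "missense_constrained", "max_credible_af")
  if (!all(need %in% names(object@diseases)))
    msg <- c(msg, paste("diseases table must have columns:",
                        paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(object@diseases$disease_id))
      msg <- c(msg, "duplicate disease identifiers")
    bad <- setdiff(unique(object@diseases$inheritance), c("AD", "AR", "XL"))
    if (length(bad))
      msg <- c(msg, paste("unknown inheritance code(s):", paste(bad, collapse = ", ")))
    if (!all(object@diseases$disease_id %in% names(object@hpo)))
      msg <- c(msg, "every disease must have at least one phenotype term")
    if (any(lengths(object@hpo[object@diseases$disease_id]) == 0L))
      msg <- c(msg, "every disease must have at least one phenotype term")
  }
  if (length(msg)) msg else TRUE
})

#' ACMG evidence profile with Bayesian posterior
#'
#' The set of ACMG evidence rules fired for one variant-disease pair,
#' together with the posterior probability of pathogenicity obtained by
#' combining the rules' evidence strengths, and the resulting five-class
#' label (P / LP / VUS / LB / B). The posterior is recomputed whenever the
#' rule set changes (see [addEvidence()]).
#'
#' @slot rules character vector of fired rule codes (e.g. `"PVS1"`,
#'   `"PM2"`); at most one instance of each rule.
#' @slot notes named character vector of provenance notes, one per rule.
#' @slot posterior posterior probability of pathogenicity in \[0, 1\].
#' @slot acmgClass one of `"P"`, `"LP"`, `"VUS"`, `"LB"`, `"B"`.
#' @slot rejected logical; set when family evidence contradicts causality
#'   (BS4 or BP2 fired).
#' @slot config the [bayesConfig()] list used to combine the evidence.
#'
#' @seealso [evidenceProfile()], [evaluateRules()], [combinePosterior()]
#' @export
setClass("EvidenceProfile",
  representation(
    rules = "character",
    notes = "character",
    posterior = "numeric",
    acmgClass = "character",
    rejected = "logical",
    config = "list"
  )
)

setValidity("EvidenceProfile", function(object) {
  msg <- character()
  if (anyDuplicated(object@rules))
    msg <- c(msg, "at most one instance of each rule is allowed")
  if (length(object@posterior) != 1L ||
      object@posterior < 0 || object@posterior > 1)
    msg <- c(msg, "posterior must be a single value in [0, 1]")
  if (!object@acmgClass %in% c("P", "LP", "VUS", "LB", "B"))
    msg <- c(msg, "acmgClass must be one of P, LP, VUS, LB, B")
  if (length(msg)) msg else TRUE
})

#' @describeIn OntologyGraph-class compact display
#' @param object object to display
#' @export
setMethod("show", "OntologyGraph", function(object) {
  cat("OntologyGraph with", length(object@terms), "terms\n")
  cat("  root:", object@root,
      if (nchar(object@labels[object@root])) paste0("(", object@labels[object@root], ")"),
      "\n")
  cat("  max depth:", max(object@depths), "\n")
})

#' @describeIn PhenotypeSet-class compact display
#' @param object object to display
#' @export
setMethod("show", "PhenotypeSet", function(object) {
  cat("PhenotypeSet (", object@role, "): ", length(object@terms), " terms\n",
      sep = "")
  cat(" ", paste(utils::head(object@terms, 8L), collapse = ", "),
      if (length(object@terms) > 8L) "...", "\n")
})

#' @describeIn KnowledgeBase-class compact display
#' @param object object to display
#' @export
setMethod("show", "KnowledgeBase", function(object) {
  cat("KnowledgeBase:", nrow(object@diseases), "diseases,",
      length(unique(object@diseases$gene)), "genes\n")
  print(table(object@diseases$inheritance))
})

#' @describeIn EvidenceProfile-class compact display
#' @param object object to display
#' @export
setMethod("show", "EvidenceProfile", function(object) {
  cat("EvidenceProfile:",
      if (length(object@rules)) paste(sort(object@rules), collapse = " + ")
      else "(no evidence)", "\n")
  cat("  posterior:", format(object@posterior, digits = 4),
      " class:", object@acmgClass,
      if (isTRUE(object@rejected)) " [rejected]", "\n")
})

# ---- accessors -------------------------------------------------------------

#' @rdname OntologyGraph-class
#' @param g an `OntologyGraph`
#' @export
ontoTerms <- function(g) g@terms

#' @rdname OntologyGraph-class
#' @export
ontoRoot <- function(g) g@root

#' @rdname OntologyGraph-class
#' @param term a term identifier
#' @export
termLabel <- function(g, term) unname(g@labels[resolveTerm(g, term)])

#' @rdname PhenotypeSet-class
#' @param x a `PhenotypeSet`
#' @export
psTerms <- function(x) x@terms

#' @rdname KnowledgeBase-class
#' @param kb a `KnowledgeBase`
#' @export
kbDiseases <- function(kb) kb@diseases

#' @rdname KnowledgeBase-class
#' @param disease a disease identifier
#' @export
kbPhenotypes <- function(kb, disease) {
  if (!disease %in% names(kb@hpo))
    stop("unknown disease: ", disease)
  kb@hpo[[disease]]
}

#' @rdname EvidenceProfile-class
#' @param p an `EvidenceProfile`
#' @export
evidenceRules <- function(p) sort(p@rules)

#' @rdname EvidenceProfile-class
#' @export
posteriorProb <- function(p) p@posterior

#' @rdname EvidenceProfile-class
#' @export
acmgClass <- function(p) p@acmgClass

#' @rdname EvidenceProfile-class
#' @export
isRejected <- function(p) isTRUE(p@rejected)
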