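# Patient-disease phenotype similarity on the 0-10 scale.
#
# Each symptom p is compared against every symptom s of the other set; the
# maximal depth of a common ancestor of (p, s) is a weight candidate, and
# the weight of p is the maximum candidate, normalised by depth(p) so that
# a symptom present in (or below a descendant path of) the other set scores
# 1. Per-term weights are averaged in each direction (S1: patient against
# disease; S2: disease against patient) and the score is 10 * (S1 + S2) / 2.

#' Directed (one-way) phenotype set similarity
#'
#' @slot value mean of the per-term weights, in \[0, 1\].
#' @slot weights named numeric vector, one normalised weight per source term.
#' @slot direction label, e.g. `"patient->disease"`.
#' @export
setClass("DirectedSimilarity",
  representation(value = "numeric", weights = "numeric", direction = "character")
)

#' Symmetric patient-disease similarity score
#'
#' @slot value the 0-10 score, `10 * (s1 + s2) / 2`.
#' @slot s1 mean patient-term weight against the disease set, in \[0, 1\].
#' @slot s2 mean disease-term weight against the patient set, in \[0, 1\].
#' @export
setClass("SimilarityScore",
  representation(value = "numeric", s1 = "numeric", s2 = "numeric")
)

#' @describeIn SimilarityScore-class compact display
#' @param object object to display
#' @export
setMethod("show", "SimilarityScore", function(object) {
  cat(sprintf("SimilarityScore %.2f (S1 = %.3f, S2 = %.3f)\n",
              object@value, object@s1, object@s2))
})

#' @rdname SimilarityScore-class
#' @param x a `SimilarityScore` or `DirectedSimilarity`
#' @export
scoreValue <- function(x) x@value

.termvec <- function(g, S, what) {
  terms <- if (is(S, "PhenotypeSet")) S@terms else unique(resolveTerm(g, as.character(S)))
  if (!length(terms)) stop(what, " set must be non-empty")
  if (g@root %in% terms)
    stop("the ontology root is not allowed in a phenotype set")
  terms
}

#' Weight of one symptom against a symptom set
#'
#' Raw weight is the maximum, over all terms `s` of `S`, of the maximal
#' common-ancestor depth of `(p, s)`; the returned weight is the raw weight
#' divided by `termDepth(g, p)`, so it lies in \[0, 1\] and equals 1 exactly
#' when some term of `S` is `p` itself or a descendant of `p` (the common
#' ancestor then attains `p`'s own depth).
#'
#' @param g an [OntologyGraph-class].
#' @param p a single term identifier of depth >= 1.
#' @param S a [PhenotypeSet-class] or character vector of term ids.
#' @return a single numeric weight in \[0, 1\].
#' @export
termSetWeight <- function(g, p, S) {
  p <- resolveTerm(g, p)
  S <- .termvec(g, S, "target")
  dp <- termDepth(g, p)
  if (dp == 0L)
    stop("term ", p, " is the ontology root (depth 0) and cannot be weighted")
  ap <- .ancIdx(g, p)
  raw <- 0L
  for (s in S) {
    m <- max(unname(g@depths[intersect(ap, .ancIdx(g, s))]))
    if (m > raw) raw <- m
  }
  raw / dp
}

#' One-way averaged similarity between two phenotype sets
#'
#' The mean of [termSetWeight()] of every source term against the target
#' set: `d(source, target)` in the two-directional score.
#'
#' @param g an [OntologyGraph-class].
#' @param source,target [PhenotypeSet-class] objects or character vectors.
#' @return a [DirectedSimilarity-class].
#' @export
directedSimilarity <- function(g, source, target) {
  src <- .termvec(g, source, "source")
  tgt <- .termvec(g, target, "target")
  w <- vapply(src, function(p) termSetWeight(g, p, tgt), numeric(1))
  dir <- paste0(
    if (is(source, "PhenotypeSet")) source@role else "set",
    "->",
    if (is(target, "PhenotypeSet")) target@role else "set")
  new("DirectedSimilarity", value = mean(w), weights = w, direction = dir)
}

#' Patient-disease phenotype similarity score (0-10)
#'
#' `10 * (S1 + S2) / 2`, where S1 averages patient-term weights against the
#' disease set and S2 averages disease-term weights against the patient
#' set. Symmetric in its two set arguments; equals 10 when the sets are
#' identical and 0 when the only common ancestor of every cross pair is
#' the root.
#'
#' @param g an [OntologyGraph-class].
#' @param patient,disease [PhenotypeSet-class] objects or character vectors.
#' @return a [SimilarityScore-class].
#' @examples
#' g <- ontologyGraph(list(R = character(), A = "R", A1 = "A", A2 = "A"))
#' scoreValue(similarityScore(g, "A1", "A1"))  # 10
#' scoreValue(similarityScore(g, "A1", "A2"))  # 5
#' @export
similarityScore <- function(g, patient, disease) {
  s1 <- directedSimilarity(g, patient, disease)@value
  s2 <- directedSimilarity(g, disease, patient)@value
  new("SimilarityScore", value = 10 * (s1 + s2) / 2, s1 = s1, s2 = s2)
}

#' Score a patient's phenotype against every disease in a knowledge base
#'
#' @param g an [OntologyGraph-class].
#' @param patientTerms patient [PhenotypeSet-class] or character vector.
#' @param kb a [KnowledgeBase-class].
#' @return data.frame with columns `disease_id`, `name`, `score`, `s1`,
#'   `s2`, sorted by decreasing score (ties broken by disease id).
#' @export
scoreAllDiseases <- function(g, patientTerms, kb) {
  pt <- .termvec(g, patientTerms, "patient")
  dd <- kb@diseases
  res <- lapply(dd$disease_id, function(d) {
    sc <- similarityScore(g, pt, kb@hpo[[d]])
    data.frame(disease_id = d, score = sc@value, s1 = sc@s1, s2 = sc@s2,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$name <- dd$name[match(out$disease_id, dd$disease_id)]
  out <- out[order(-out$score, out$disease_id), c("disease_id", "name", "score", "s1", "s2")]
  rownames(out) <- NULL
  out
}
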