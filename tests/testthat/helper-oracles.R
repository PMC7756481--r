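# Independent brute-force oracles over a raw parent list (never touching
# the package's cached graph machinery), plus small generators used by the
# property tests.

# toy ontology T: R -> {A, B}; A -> {A1, A2}; A1 -> {A1a}; B -> {B1}
toyTParents <- function() {
  list(R = character(), A = "R", B = "R",
       A1 = "A", A2 = "A", B1 = "B", A1a = "A1")
}
toyT <- function() ontologyGraph(toyTParents())

bfAncestors <- function(parents, t) {
  res <- t
  stack <- parents[[t]]
  while (length(stack)) {
    p <- stack[[1L]]
    stack <- stack[-1L]
    if (!p %in% res) {
      res <- c(res, p)
      stack <- c(stack, parents[[p]])
    }
  }
  res
}

# longest path to the root by exhaustive recursion
bfDepth <- function(parents, t) {
  ps <- parents[[t]]
  if (!length(ps)) return(0L)
  1L + max(vapply(ps, function(p) bfDepth(parents, p), integer(1)))
}

bfMcaDepth <- function(parents, p, s) {
  common <- intersect(bfAncestors(parents, p), bfAncestors(parents, s))
  max(vapply(common, function(a) bfDepth(parents, a), integer(1)))
}

bfTermSetWeight <- function(parents, p, S) {
  max(vapply(S, function(s) bfMcaDepth(parents, p, s), integer(1))) /
    bfDepth(parents, p)
}

# naive double-loop similarity score straight from the definition
bfSimilarityScore <- function(parents, Sp, Sd) {
  s1 <- mean(vapply(Sp, function(p) bfTermSetWeight(parents, p, Sd), numeric(1)))
  s2 <- mean(vapply(Sd, function(s) bfTermSetWeight(parents, s, Sp), numeric(1)))
  10 * (s1 + s2) / 2
}

# random rooted DAG as a parent list: node i picks a primary parent among
# 1..i-1, and with probability pExtra a second, distinct one
randomDAGParents <- function(nTerms, pExtra = 0.3) {
  ids <- paste0("T", seq_len(nTerms))
  parents <- vector("list", nTerms)
  names(parents) <- ids
  parents[[1L]] <- character()
  for (i in seq_len(nTerms)[-1L]) {
    prim <- ids[sample.int(i - 1L, 1L)]
    ps <- prim
    if (i > 2L && stats::runif(1) < pExtra) {
      extra <- ids[sample.int(i - 1L, 1L)]
      if (extra != prim) ps <- c(ps, extra)
    }
    parents[[i]] <- ps
  }
  parents
}

# independent closed-form posterior for a list of exponents
bfPosterior <- function(expSum, prior = 0.10, oddsPVS = 350) {
  odds <- oddsPVS^expSum
  odds * prior / ((odds - 1) * prior + 1)
}

# minimal annotated-variant record for rule-engine tests
avRecord <- function(consequence = "missense_variant", gene = "GENE0001",
                     pop_af = numeric(), insilico = numeric(),
                     known = "none", hotspot = FALSE) {
  list(gene = gene, consequence = consequence, pop_af = pop_af,
       insilico = insilico, known_pathogenic_aa_match = known,
       in_hotspot_domain = hotspot)
}

# two-disease toy knowledge base on toy ontology T
toyKB <- function(mechanism = "LoF", inheritance = "AD",
                  constrained = TRUE, max_af = 1e-3) {
  dis <- data.frame(
    disease_id = c("DIS:0001", "DIS:0002"),
    name = c("toy disease one", "toy disease two"),
    gene = c("GENE0001", "GENE0001"),
    inheritance = c(inheritance, "AR"),
    mechanism = c(mechanism, "unknown"),
    missense_constrained = c(constrained, FALSE),
    max_credible_af = c(max_af, 2e-3),
    stringsAsFactors = FALSE
  )
  new("KnowledgeBase", diseases = dis,
      hpo = list("DIS:0001" = c("A1", "A1a"), "DIS:0002" = c("B1")))
}
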