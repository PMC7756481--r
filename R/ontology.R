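# Ontology construction and DAG primitives: longest-path depth, memoised
# ancestor closure, and maximal common-ancestor depth -- the building blocks
# of the phenotype similarity score.

#' Build an ontology graph from a parent list
#'
#' Low-level constructor used by [loadOBO()] and [makeToyOntology()], also
#' handy for constructing small ontologies in code. The graph must be a
#' rooted DAG: exactly one term without parents, and no `is_a` cycles.
#' Depths (longest path from the root) are computed for every term during
#' construction by processing terms in topological order.
#'
#' @param parents named list mapping every term identifier to the character
#'   vector of its `is_a` parents; the root has `character(0)`.
#' @param labels optional named character vector of term names.
#' @param alts optional named character vector mapping alternative ids to
#'   canonical ids.
#' @return an [OntologyGraph-class] object.
#' @examples
#' g <- ontologyGraph(list(R = character(), A = "R", B = "R"))
#' termDepth(g, "A")
#' @export
ontologyGraph <- function(parents, labels = NULL, alts = character()) {
  terms <- names(parents)
  if (is.null(terms) || any(!nzchar(terms)))
    stop("'parents' must be a fully named list")
  if (anyDuplicated(terms))
    stop("duplicate term ids: ",
         paste(unique(terms[duplicated(terms)]), collapse = ", "))
  parents <- lapply(parents, function(p) unique(as.character(p)))
  refd <- unique(unlist(parents, use.names = FALSE))
  unknown <- setdiff(refd, terms)
  if (length(unknown))
    stop("is_a parent(s) not defined as terms: ",
         paste(unknown, collapse = ", "))

  nparents <- lengths(parents)
  roots <- terms[nparents == 0L]
  if (length(roots) == 0L)
    stop("no root term: every term has a parent (is_a cycle through the top?)")
  if (length(roots) > 1L)
    stop("multiple root terms: ", paste(roots, collapse = ", "))

  n <- length(terms)
  edge_child <- rep(seq_len(n), nparents)
  edge_parent <- match(unlist(parents, use.names = FALSE), terms)
  child_idx <- unname(split(edge_child, factor(edge_parent, levels = seq_len(n))))
  children <- stats::setNames(lapply(child_idx, function(i) terms[i]), terms)

  # Kahn's algorithm on integer ids; depth(child) = 1 + max over parents
  # already finalised.
  depths_i <- rep(-1L, n)
  remaining <- unname(nparents)
  root_i <- match(roots, terms)
  queue <- integer(n)
  queue[1L] <- root_i
  depths_i[root_i] <- 0L
  head_i <- 1L
  tail_i <- 1L
  while (head_i <= tail_i) {
    t <- queue[head_i]
    head_i <- head_i + 1L
    for (ch in child_idx[[t]]) {
      if (depths_i[ch] < depths_i[t] + 1L) depths_i[ch] <- depths_i[t] + 1L
      remaining[ch] <- remaining[ch] - 1L
      if (remaining[ch] == 0L) {
        tail_i <- tail_i + 1L
        queue[tail_i] <- ch
      }
    }
  }
  if (tail_i < n) {
    stuck <- terms[remaining > 0L][1L]
    unproc <- terms[remaining > 0L | depths_i < 0L]
    cyc_parent <- intersect(parents[[stuck]], unproc)
    stop("cycle detected in is_a graph, involving edge: ",
         stuck, " is_a ", cyc_parent[1L])
  }
  depths <- stats::setNames(depths_i, terms)

  lab <- stats::setNames(rep("", n), terms)
  if (!is.null(labels)) {
    keep <- intersect(names(labels), terms)
    lab[keep] <- labels[keep]
  }
  cache <- new.env(parent = emptyenv())
  cache$anc <- new.env(parent = emptyenv())   # term -> ancestor indices
  cache$idx <- new.env(parent = emptyenv())   # term -> integer position
  for (i in seq_len(n)) assign(terms[i], i, envir = cache$idx)
  new("OntologyGraph",
      terms = terms, parents = parents, children = children,
      root = roots, depths = depths, labels = lab,
      alts = alts, cache = cache)
}

#' Read an OBO 1.2 flat-file ontology
#'
#' Parses `[Term]` stanzas (`id:`, `name:`, `is_a:`, `alt_id:`,
#' `is_obsolete:` tags). Obsolete terms are dropped, along with any `is_a`
#' edges pointing at them; alternative ids are recorded so that term lookup
#' resolves them to the canonical id. The result must be a single-rooted
#' DAG; a cycle or a zero/multiple-root ontology is an error.
#'
#' @param path path to an OBO file.
#' @return an [OntologyGraph-class].
#' @export
loadOBO <- function(path) {
  if (!file.exists(path)) stop("OBO file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  stanza_at <- grep("^\\[", lines)
  if (!length(stanza_at)) stop("no stanzas found in OBO file: ", path)
  bounds <- c(stanza_at, length(lines) + 1L)

  ids <- character()
  parents <- list()
  labels <- character()
  alts <- character()
  for (k in seq_along(stanza_at)) {
    if (lines[stanza_at[k]] != "[Term]") next
    body <- lines[seq(stanza_at[k] + 1L, bounds[k + 1L] - 1L)]
    tagval <- function(tag) {
      v <- body[startsWith(body, paste0(tag, ":"))]
      v <- sub(paste0("^", tag, ":\\s*"), "", v)
      sub("\\s*!.*$", "", v)  # strip trailing OBO comments
    }
    id <- tagval("id")
    if (length(id) != 1L) stop("OBO [Term] stanza without a single id (stanza ", k, ")")
    if (any(grepl("true", tagval("is_obsolete")))) next
    ids <- c(ids, id)
    parents[[id]] <- tagval("is_a")
    nm <- tagval("name")
    labels[id] <- if (length(nm)) nm[1L] else ""
    for (a in tagval("alt_id")) alts[a] <- id
  }
  if (!length(ids)) stop("no non-obsolete [Term] stanzas in ", path)
  # drop edges into obsolete (absent) terms
  parents <- lapply(parents, function(p) intersect(p, ids))
  ontologyGraph(parents, labels = labels, alts = alts)
}

#' Write an ontology back to OBO 1.2 format
#'
#' @param g an [OntologyGraph-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeOBO <- function(g, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (t in g@terms) {
    writeLines(c(
      "[Term]",
      paste0("id: ", t),
      paste0("name: ", g@labels[t]),
      if (length(g@parents[[t]])) paste0("is_a: ", g@parents[[t]]),
      ""
    ), con)
  }
  invisible(path)
}

# Resolve a term id through the alt_id map; error on unknown terms.
resolveTerm <- function(g, term) {
  idx <- g@cache$idx
  hit <- vapply(term, function(t) !is.null(get0(t, envir = idx, inherits = FALSE)),
                logical(1), USE.NAMES = FALSE)
  if (all(hit)) return(term)
  out <- term
  out[!hit] <- g@alts[term[!hit]]
  if (anyNA(out))
    stop("unknown ontology term(s): ", paste(term[is.na(out)], collapse = ", "))
  out
}

# Integer position of a resolved term (O(1) environment lookup).
.tidx <- function(g, t) get0(t, envir = g@cache$idx, inherits = FALSE)

#' Term depth: longest is_a path from the root
#'
#' Depth is the edge count of the longest path from the root to the term.
#' In a DAG with multiple parents this is the most specific placement of
#' the term, which maximises the discriminative power of common-ancestor
#' depths. `termDepth(g, root)` is 0.
#'
#' @param g an [OntologyGraph-class].
#' @param term one or more term identifiers.
#' @return integer vector of depths.
#' @export
termDepth <- function(g, term) {
  term <- resolveTerm(g, term)
  ii <- vapply(term, function(t) .tidx(g, t), integer(1), USE.NAMES = FALSE)
  unname(g@depths[ii])
}

#' Ancestor closure of a term
#'
#' All terms reachable from `term` by following `is_a` edges, *including
#' the term itself* (so `mcaDepth(p, p)` equals `termDepth(p)`, and a term
#' contained in a phenotype set attains its full depth as weight). Always
#' contains the root. Results are memoised inside the graph object.
#'
#' @param g an [OntologyGraph-class].
#' @param term a term identifier.
#' @return character vector of ancestor term ids.
#' @export
termAncestors <- function(g, term) {
  t <- resolveTerm(g, term)
  if (length(t) != 1L) stop("'term' must be a single term id")
  .anc(g, t)
}

# Ancestor closure as integer indices, memoised per term.
.ancIdx <- function(g, t) {
  hit <- get0(t, envir = g@cache$anc, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  res <- .tidx(g, t)
  for (p in g@parents[[res[1L]]]) res <- union(res, .ancIdx(g, p))
  assign(t, res, envir = g@cache$anc)
  res
}

.anc <- function(g, t) g@terms[.ancIdx(g, t)]

#' Maximal common-ancestor depth of two terms
#'
#' The per-symptom weight primitive of the similarity score: among all
#' common ancestors of the two terms, the depth (longest root path) of the
#' deepest one. Symmetric; bounded above by `min(termDepth(p), termDepth(s))`,
#' with equality when one term is an ancestor of the other.
#'
#' @param g an [OntologyGraph-class].
#' @param p,s term identifiers.
#' @return a single non-negative integer.
#' @export
mcaDepth <- function(g, p, s) {
  p <- resolveTerm(g, p)
  s <- resolveTerm(g, s)
  common <- intersect(.ancIdx(g, p), .ancIdx(g, s))
  max(unname(g@depths[common]))
}

#' Construct a validated phenotype term set
#'
#' Terms are resolved through the ontology's alternative-id map, duplicates
#' collapsed, and unknown terms rejected with a listing (or dropped with a
#' warning when `skipUnknown = TRUE`). The root term is never allowed as a
#' member: it carries no phenotypic information and would have depth 0.
#'
#' @param g an [OntologyGraph-class].
#' @param terms character vector of term identifiers.
#' @param role `"patient"` or `"disease"`.
#' @param skipUnknown drop unknown terms with a warning instead of erroring.
#' @return a [PhenotypeSet-class].
#' @export
phenotypeSet <- function(g, terms, role = c("patient", "disease"),
                         skipUnknown = FALSE) {
  role <- match.arg(role)
  terms <- unique(as.character(terms))
  known <- terms %in% g@terms | terms %in% names(g@alts)
  if (any(!known)) {
    if (skipUnknown) {
      warning("dropping unknown ontology term(s): ",
              paste(terms[!known], collapse = ", "))
      terms <- terms[known]
    } else {
      stop("unknown ontology term(s): ", paste(terms[!known], collapse = ", "))
    }
  }
  if (!length(terms)) stop("phenotype set is empty after validation")
  terms <- unique(resolveTerm(g, terms))
  if (g@root %in% terms)
    stop("the ontology root (", g@root, ") is not allowed in a phenotype set")
  new("PhenotypeSet", terms = terms, role = role)
}
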