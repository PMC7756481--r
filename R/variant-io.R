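# Reading variant calls (VCF), annotation/frequency tables, and the
# knowledge base; writing the ranked candidate report.

#' Read a single-sample VCF into a variant record table
#'
#' One record per (site, alternate allele): multi-allelic sites are split
#' with allele-index bookkeeping, and zygosity is derived from the GT field
#' (`0/1` het, `1/1` hom, haploid calls hemi). Records whose genotype is
#' missing, or which do not carry the alternate allele, are skipped with a
#' warning count.
#'
#' @param path path to a VCF 4.x file (plain text or bgzipped).
#' @return data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `zygosity`, `qual`, `filter_status`.
#' @export
readVariants <- function(path) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  vcf <- tryCatch(
    suppressWarnings(VariantAnnotation::readVcf(path, genome = "synthetic")),
    error = function(e) stop("failed to parse VCF ", path, ": ",
                             conditionMessage(e)))
  empty <- data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      zygosity = character(), qual = numeric(),
                      filter_status = character(), stringsAsFactors = FALSE)
  if (nrow(vcf) == 0L) {
    warning("VCF has no variant records: ", path)
    return(empty)
  }
  gmat <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gmat)) {
    warning("VCF has no GT field; all ", nrow(vcf), " records skipped")
    return(empty)
  }
  if (ncol(gmat) != 1L)
    stop("expected a single-sample VCF, found ", ncol(gmat), " samples")
  gt <- gmat[, 1L]

  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  refs <- as.character(VariantAnnotation::ref(vcf))
  alts <- lapply(as.list(VariantAnnotation::alt(vcf)), as.character)
  quals <- VariantAnnotation::qual(vcf)
  filts <- VariantAnnotation::filt(vcf)

  out <- vector("list", length(gt))
  skipped <- 0L
  for (i in seq_along(gt)) {
    g <- gt[i]
    if (is.na(g) || g %in% c(".", "./.", ".|.")) {
      skipped <- skipped + 1L
      next
    }
    alleles <- suppressWarnings(as.integer(strsplit(g, "[/|]")[[1L]]))
    if (anyNA(alleles)) {
      skipped <- skipped + 1L
      next
    }
    rows <- lapply(seq_along(alts[[i]]), function(k) {
      n_k <- sum(alleles == k)
      if (n_k == 0L) return(NULL)
      zyg <- if (length(alleles) == 1L) "hemi"
             else if (n_k == 2L) "hom" else "het"
      data.frame(chrom = chrom[i], pos = pos[i], ref = refs[i],
                 alt = alts[[i]][k], zygosity = zyg,
                 qual = if (is.na(quals[i])) NA_real_ else quals[i],
                 filter_status = filts[i], stringsAsFactors = FALSE)
    })
    out[[i]] <- do.call(rbind, rows)
  }
  if (skipped > 0L)
    warning(skipped, " VCF record(s) skipped (missing or unparseable GT)")
  res <- do.call(rbind, out)
  if (is.null(res)) return(empty)
  bad <- res$ref == res$alt | res$pos < 1L
  if (any(bad)) stop("invalid variant record(s): ref == alt or pos < 1")
  rownames(res) <- NULL
  res
}

.variantKey <- function(df) paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")

#' Read a variant annotation table
#'
#' TSV with header columns `chrom`, `pos`, `ref`, `alt`, `gene`,
#' `consequence`, `hgvs_p`, `missense_meta`, `splice_ada`, `splice_rf`,
#' `known_pathogenic_aa_match`, `in_hotspot_domain`. Missing scores are
#' empty/NA, never zero-filled.
#'
#' @param path path to the TSV.
#' @return data.frame keyed by (chrom, pos, ref, alt).
#' @export
readAnnotationTable <- function(path) {
  # ref/alt alleles like "T" must never be read as logicals
  ann <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(chrom = "character",
                                          ref = "character",
                                          alt = "character"))
  need <- c("chrom", "pos", "ref", "alt", "gene", "consequence")
  miss <- setdiff(need, names(ann))
  if (length(miss))
    stop("annotation table missing column(s): ", paste(miss, collapse = ", "))
  for (tool in c("missense_meta", "splice_ada", "splice_rf"))
    if (!tool %in% names(ann)) ann[[tool]] <- NA_real_
  if (!"hgvs_p" %in% names(ann)) ann$hgvs_p <- ""
  ann$hgvs_p[is.na(ann$hgvs_p)] <- ""
  if (!"known_pathogenic_aa_match" %in% names(ann))
    ann$known_pathogenic_aa_match <- "none"
  if (!"in_hotspot_domain" %in% names(ann)) ann$in_hotspot_domain <- FALSE
  ann$in_hotspot_domain <- as.logical(ann$in_hotspot_domain)
  sc <- c("missense_meta", "splice_ada", "splice_rf")
  okr <- vapply(sc, function(t) all(is.na(ann[[t]]) | (ann[[t]] >= 0 & ann[[t]] <= 1)),
                logical(1))
  if (!all(okr)) stop("in-silico scores must lie in [0, 1]")
  if (anyDuplicated(.variantKey(ann)))
    stop("duplicate variant keys in annotation table")
  ann
}

#' Read a long-format population allele-frequency table
#'
#' TSV with header columns `chrom`, `pos`, `ref`, `alt`, `source`, `af`.
#' A variant absent from the table is treated as absent from all population
#' controls (rarity evidence), which is distinct from an observed frequency
#' of zero in a queried source.
#'
#' @param path path to the TSV.
#' @return named list mapping `chrom:pos:ref:alt` keys to named numeric
#'   vectors of per-source allele frequencies.
#' @export
readFrequencyTable <- function(path) {
  fr <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(chrom = "character",
                                         ref = "character",
                                         alt = "character"))
  need <- c("chrom", "pos", "ref", "alt", "source", "af")
  miss <- setdiff(need, names(fr))
  if (length(miss))
    stop("frequency table missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(fr) == 0L) return(list())
  if (any(fr$af < 0 | fr$af > 1)) stop("allele frequencies must lie in [0, 1]")
  key <- .variantKey(fr)
  lapply(split(seq_len(nrow(fr)), key),
         function(idx) stats::setNames(fr$af[idx], fr$source[idx]))
}

#' Load the gene-disease knowledge base from a directory of TSVs
#'
#' Expects `genes.tsv` (columns `gene`, `disease_id`), `diseases.tsv`
#' (columns `disease_id`, `name`, `inheritance`, `mechanism`,
#' `missense_constrained`, `max_credible_af`) and `disease_hpo.tsv`
#' (columns `disease_id`, `term`). Every disease must map to exactly one
#' gene via `genes.tsv`, carry a valid inheritance mode, and have at least
#' one phenotype term.
#'
#' @param dir directory containing the three TSV files.
#' @param g optional [OntologyGraph-class]; when supplied, disease terms
#'   are validated against it.
#' @return a [KnowledgeBase-class].
#' @export
loadKnowledgeBase <- function(dir, g = NULL) {
  pth <- function(f) file.path(dir, f)
  for (f in c("genes.tsv", "diseases.tsv", "disease_hpo.tsv"))
    if (!file.exists(pth(f))) stop("knowledge base file missing: ", pth(f))
  genes <- utils::read.delim(pth("genes.tsv"), stringsAsFactors = FALSE)
  dis <- utils::read.delim(pth("diseases.tsv"), stringsAsFactors = FALSE)
  hpo <- utils::read.delim(pth("disease_hpo.tsv"), stringsAsFactors = FALSE)

  if (anyDuplicated(dis$disease_id))
    stop("duplicate disease ID(s): ",
         paste(unique(dis$disease_id[duplicated(dis$disease_id)]), collapse = ", "))
  bad <- setdiff(unique(dis$inheritance), c("AD", "AR", "XL"))
  if (length(bad))
    stop("unknown inheritance code(s): ", paste(bad, collapse = ", "))

  m <- match(dis$disease_id, genes$disease_id)
  if (anyNA(m))
    stop("disease(s) without a gene mapping: ",
         paste(dis$disease_id[is.na(m)], collapse = ", "))
  dis$gene <- genes$gene[m]
  dis$missense_constrained <- as.logical(dis$missense_constrained)
  dis$max_credible_af <- as.numeric(dis$max_credible_af)

  hpolist <- split(hpo$term, hpo$disease_id)
  nohpo <- setdiff(dis$disease_id, names(hpolist))
  if (length(nohpo))
    stop("disease(s) without phenotype terms: ", paste(nohpo, collapse = ", "))
  hpolist <- lapply(hpolist, unique)
  if (!is.null(g)) {
    allterms <- unique(unlist(hpolist, use.names = FALSE))
    resolveTerm(g, allterms)  # errors on unknown terms
  }
  new("KnowledgeBase", diseases = dis, hpo = hpolist)
}

#' Join variant records with annotations and population frequencies
#'
#' Exact join on the normalised `(chrom, pos, ref, alt)` key. Variants
#' without an annotation row carry an empty annotation (dropped later by
#' the low-impact filter); variants absent from the frequency table carry
#' an empty frequency map ("absent from controls").
#'
#' @param variants data.frame from [readVariants()].
#' @param annotations data.frame from [readAnnotationTable()].
#' @param frequencies list from [readFrequencyTable()].
#' @return annotated-variant data.frame with list columns `pop_af` and
#'   `insilico`.
#' @export
annotateVariants <- function(variants, annotations, frequencies = list()) {
  av <- variants
  key <- .variantKey(av)
  m <- match(key, .variantKey(annotations))
  av$gene <- annotations$gene[m]
  av$consequence <- annotations$consequence[m]
  av$hgvs_p <- ifelse(is.na(m), "", annotations$hgvs_p[m])
  av$known_pathogenic_aa_match <-
    ifelse(is.na(m), "none", annotations$known_pathogenic_aa_match[m])
  av$in_hotspot_domain <- ifelse(is.na(m), FALSE, annotations$in_hotspot_domain[m])
  av$insilico <- I(lapply(seq_along(key), function(i) {
    if (is.na(m[i])) return(numeric())
    s <- c(missense_meta = annotations$missense_meta[m[i]],
           splice_ada = annotations$splice_ada[m[i]],
           splice_rf = annotations$splice_rf[m[i]])
    s[!is.na(s)]
  }))
  av$pop_af <- I(lapply(key, function(k) {
    f <- frequencies[[k]]
    if (is.null(f)) numeric() else f
  }))
  av$key <- key
  av
}

.REPORT_COLS <- c("rank", "tier", "posterior", "acmg_class", "evidence_items",
                  "similarity_score", "gene", "disease_id", "disease_name",
                  "inheritance", "chrom", "pos", "ref", "alt", "zygosity",
                  "consequence", "hgvs_p")

# Flatten a ranked candidate data.frame (list columns) to report columns.
.reportFrame <- function(candidates) {
  if (is.null(candidates) || nrow(candidates) == 0L) {
    df <- as.data.frame(stats::setNames(
      replicate(length(.REPORT_COLS), character(0), simplify = FALSE),
      .REPORT_COLS), stringsAsFactors = FALSE)
    return(df)
  }
  data.frame(
    rank = candidates$rank,
    tier = candidates$tier,
    posterior = candidates$posterior,
    acmg_class = candidates$acmg_class,
    evidence_items = vapply(candidates$rules,
                            function(r) paste(sort(r), collapse = ","), character(1)),
    similarity_score = candidates$similarity,
    gene = candidates$gene,
    disease_id = candidates$disease_id,
    disease_name = candidates$disease_name,
    inheritance = candidates$inheritance,
    chrom = candidates$chrom,
    pos = candidates$pos,
    ref = candidates$ref,
    alt = candidates$alt,
    zygosity = candidates$zygosity,
    consequence = candidates$consequence,
    hgvs_p = candidates$hgvs_p,
    stringsAsFactors = FALSE
  )
}

#' Write the ranked candidate report
#'
#' TSV mode writes one row per candidate in rank order (header-only file
#' for an empty candidate list). JSON mode serialises the same columns at
#' full precision and round-trips through [readReport()].
#'
#' @param candidates ranked candidate data.frame from [runPipeline()] /
#'   [rankCandidates()].
#' @param path output file path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
writeReport <- function(candidates, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  df <- .reportFrame(candidates)
  if (format == "tsv") {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  } else {
    jsonlite::write_json(df, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null")
  }
  invisible(path)
}

#' Read a report written by [writeReport()]
#'
#' @param path report file path.
#' @param format `"tsv"` or `"json"`.
#' @return data.frame with the report columns.
#' @export
readReport <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = c(hgvs_p = "character"))
  } else {
    df <- jsonlite::fromJSON(path)
    if (length(df) == 0L) df <- .reportFrame(NULL)
    df <- as.data.frame(df, stringsAsFactors = FALSE)
    if (nrow(df) > 0L && is.null(df$hgvs_p)) df$hgvs_p <- ""
    df$hgvs_p[is.na(df$hgvs_p)] <- ""
  }
  df
}
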