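# gwas_dataset module: keyword-driven construction of the cancer-variant
# dataset from a GWAS-catalog-style association table.

#' The seven cancer trait keywords
#'
#' Default keyword set used to carve the cancer-associated subset out of a
#' GWAS-catalog-style table: cancer, carcinoma, glioma, leukemia, lymphoma,
#' melanoma, sarcoma.
#'
#' @return lowercase character vector of length 7.
#' @export
cancerKeywords <- function() {
  c("cancer", "carcinoma", "glioma", "leukemia", "lymphoma", "melanoma",
    "sarcoma")
}

#' The closed consequence vocabulary
#'
#' @return character vector of the recognised consequence classes.
#' @export
consequenceClasses <- function() {
  c("nonsynonymous", "synonymous", "utr3", "utr5", "intronic", "intergenic",
    "stop_gained", "splice_region", "splice_acceptor", "regulatory", "tfbs",
    "noncoding_transcript", "inframe_insertion", "coding_other")
}

# Common annotation-dialect synonyms (Sequence Ontology terms and friends).
.CONSEQUENCE_SYNONYMS <- c(
  missense_variant = "nonsynonymous", missense = "nonsynonymous",
  nonsynonymous_variant = "nonsynonymous", nssnp = "nonsynonymous",
  synonymous_variant = "synonymous", ssnp = "synonymous",
  "3_prime_utr_variant" = "utr3", "3_prime_utr" = "utr3", "3utr" = "utr3",
  "5_prime_utr_variant" = "utr5", "5_prime_utr" = "utr5", "5utr" = "utr5",
  intron_variant = "intronic", intron = "intronic",
  intergenic_variant = "intergenic",
  stop_gained_variant = "stop_gained", nonsense = "stop_gained",
  splice_region_variant = "splice_region",
  splice_acceptor_variant = "splice_acceptor",
  regulatory_region_variant = "regulatory",
  tf_binding_site_variant = "tfbs", tfbs_variant = "tfbs",
  non_coding_transcript_variant = "noncoding_transcript",
  non_coding_transcript_exon_variant = "noncoding_transcript",
  coding_sequence_variant = "coding_other")

#' Normalize consequence strings to the closed vocabulary
#'
#' Unknown inputs raise an error naming the offending value(s); they are
#' never silently mapped to a class.
#'
#' @param x character vector of consequence strings.
#' @return character vector over [consequenceClasses()].
#' @export
normalizeConsequence <- function(x) {
  key <- tolower(trimws(as.character(x)))
  out <- ifelse(key %in% consequenceClasses(), key,
                unname(.CONSEQUENCE_SYNONYMS[key]))
  bad <- is.na(out) & !is.na(x)
  if (any(bad))
    .stopf("unclassified consequence value(s): %s (row %s)",
           paste(unique(x[bad]), collapse = ", "),
           paste(which(bad), collapse = ", "))
  out
}

#' Read a GWAS-catalog-style association table
#'
#' Catalog dialects drift, so column names are mapped through
#' \code{columnMap}: a named character vector from canonical names
#' (\code{rsid}, \code{chrom}, \code{pos}, \code{trait}, \code{risk_allele},
#' \code{risk_allele_freq}, \code{gene}, \code{protein_accession},
#' \code{aa_change}, \code{consequence}) to the file's header names.
#'
#' @param path TSV file with a header line.
#' @param columnMap optional canonical-to-file column name map; by default
#'   the canonical names are expected verbatim.
#' @return a \code{data.frame} of associations with canonical columns,
#'   validated (positions \eqn{\ge} 1, risk-allele frequencies in [0,1],
#'   consequences normalized).
#' @export
readGwasCatalog <- function(path, columnMap = NULL) {
  if (!file.exists(path)) .stopf("cannot read catalog '%s'", path)
  x <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                         check.names = FALSE)
  canonical <- c("rsid", "chrom", "pos", "trait", "risk_allele",
                 "risk_allele_freq", "gene", "protein_accession",
                 "aa_change", "consequence")
  if (!is.null(columnMap))
    for (canon in names(columnMap)) {
      if (!columnMap[[canon]] %in% names(x))
        .stopf("mapped column '%s' absent from '%s'", columnMap[[canon]], path)
      names(x)[names(x) == columnMap[[canon]]] <- canon
    }
  need <- c("rsid", "trait", "consequence")
  if (!all(need %in% names(x)))
    .stopf("catalog lacks mandatory column(s): %s",
           paste(setdiff(need, names(x)), collapse = ", "))
  for (canon in setdiff(canonical, names(x))) x[[canon]] <- NA
  x$pos <- suppressWarnings(as.integer(x$pos))
  if (any(!is.na(x$pos) & x$pos < 1)) .stopf("position below 1 in catalog")
  x$risk_allele_freq <- suppressWarnings(as.numeric(x$risk_allele_freq))
  raf <- x$risk_allele_freq
  if (any(!is.na(raf) & (raf < 0 | raf > 1)))
    .stopf("risk allele frequency outside [0,1]")
  x$consequence <- normalizeConsequence(x$consequence)
  x[, c(canonical, setdiff(names(x), canonical)), drop = FALSE]
}

#' Keyword-filter a catalog to cancer-associated rows
#'
#' Retains rows whose trait contains at least one keyword
#' (case-insensitive substring by default; \code{wordBoundary = TRUE}
#' requires whole-word matches). Rows are deduplicated on (rsid, trait),
#' keeping the first occurrence; input order is preserved. A row listing
#' several phenotypes is retained if any of them matches.
#'
#' @param catalog data.frame from [readGwasCatalog()].
#' @param keywords non-empty character vector of lowercase keywords.
#' @param wordBoundary match at word boundaries instead of raw substrings.
#' @param field column to match against (catalogs carry both a reported
#'   disease/trait and a mapped trait).
#' @return the filtered, deduplicated data.frame.
#' @export
filterCatalog <- function(catalog, keywords = cancerKeywords(),
                          wordBoundary = FALSE, field = "trait") {
  if (!length(keywords)) .stopf("keyword list must be non-empty")
  if (!field %in% names(catalog)) .stopf("no '%s' column in catalog", field)
  trait <- tolower(as.character(catalog[[field]]))
  pat <- if (wordBoundary)
    paste0("\\b(", paste(tolower(keywords), collapse = "|"), ")\\b")
  else paste(tolower(keywords), collapse = "|")
  hit <- !is.na(trait) & grepl(pat, trait, perl = TRUE)
  out <- catalog[hit, , drop = FALSE]
  dup <- duplicated(paste(out$rsid, out[[field]], sep = "\r"))
  out[!dup, , drop = FALSE]
}

#' Count catalog rows per consequence class
#'
#' @param catalog data.frame with a \code{consequence} column.
#' @return named integer vector over the classes present; counts partition
#'   the input.
#' @export
consequenceCensus <- function(catalog) {
  cons <- normalizeConsequence(catalog$consequence)
  if (anyNA(cons)) .stopf("row(s) without a consequence: %s",
                          paste(which(is.na(cons)), collapse = ", "))
  tab <- table(cons)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' Select the nonsynonymous rows of a catalog
#'
#' @param catalog data.frame with a \code{consequence} column.
#' @return rows with consequence \code{nonsynonymous}, order preserved.
#' @export
selectNsSNPs <- function(catalog) {
  cons <- normalizeConsequence(catalog$consequence)
  catalog[!is.na(cons) & cons == "nonsynonymous", , drop = FALSE]
}
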