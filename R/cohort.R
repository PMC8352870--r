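# cohort_match module: which dataset variants are present in cohort VCFs
# after read-depth / quality filtering, and at what allele frequency.

#' Site quality filter
#'
#' Sites with a read depth below \code{minDepth} or a Phred-scaled quality
#' below \code{minQual} are excluded; a site exactly at either bound passes
#' (only strictly-below values are excluded).
#'
#' @param minDepth minimum read depth (reads).
#' @param minQual minimum Phred-scaled site quality.
#' @return a \code{vv_quality} specification.
#' @export
qualityFilter <- function(minDepth = 5, minQual = 30) {
  stopifnot(minDepth >= 0, minQual >= 0)
  structure(list(minDepth = minDepth, minQual = minQual),
            class = "vv_quality")
}

#' @rdname qualityFilter
#' @param depth,qual numeric vectors of per-site depth and quality.
#' @param spec a [qualityFilter()].
#' @param onMissing what to do when depth or quality is absent:
#'   \code{"fail"} (closed, the default) or \code{"pass"}.
#' @return \code{passesQuality}: logical vector.
#' @export
passesQuality <- function(depth, qual, spec = qualityFilter(),
                          onMissing = c("fail", "pass")) {
  onMissing <- match.arg(onMissing)
  ok <- depth >= spec$minDepth & qual >= spec$minQual
  ok[is.na(ok)] <- onMissing == "pass"
  ok
}

#' Alternate-allele frequency from diploid genotype strings
#'
#' Counts alternate alleles over the called (non-missing) alleles; missing
#' genotypes (\code{./.}) are excluded from the denominator. Returns
#' \code{NA} when every genotype is missing.
#'
#' @param gt character vector of GT strings (\code{"0/1"}, \code{"1|1"},
#'   \code{"./."}, ...), optionally named by sample.
#' @param alleleIndex count only this ALT allele index (1-based); default
#'   counts any non-reference allele.
#' @return frequency in [0,1], or \code{NA_real_}.
#' @examples
#' alleleFrequency(c("0/0", "0/1", "1/1"))  # 0.5
#' @export
alleleFrequency <- function(gt, alleleIndex = NULL) {
  alleles <- .parse_gt(gt)
  called <- alleles[!is.na(alleles)]
  if (!length(called)) return(NA_real_)
  hits <- if (is.null(alleleIndex)) called > 0L else called == alleleIndex
  sum(hits) / length(called)
}

# GT strings -> integer allele matrix entries (NA for '.'); errors name the
# offending sample.
.parse_gt <- function(gt) {
  parts <- strsplit(as.character(gt), "[/|]")
  bad <- !vapply(parts, function(p)
    length(p) >= 1L && all(grepl("^([0-9]+|\\.)$", p)), TRUE)
  if (any(bad)) {
    who <- if (!is.null(names(gt))) names(gt)[bad] else which(bad)
    .stopf("malformed genotype for sample(s): %s",
           paste(who, collapse = ", "))
  }
  out <- unlist(parts, use.names = FALSE)
  res <- rep(NA_integer_, length(out))
  res[out != "."] <- as.integer(out[out != "."])
  res
}

.strip_chr <- function(x) sub("^chr", "", as.character(x), ignore.case = TRUE)

#' Read a cohort VCF as a per-alternate-allele site table
#'
#' Thin wrapper around \code{VariantAnnotation::readVcf} that splits
#' multi-allelic records (one row per alternate allele), takes the per-site
#' depth from INFO/DP when present and otherwise from the sum of per-sample
#' FORMAT/DP, and records for every alternate allele whether it is observed
#' in at least one sample and at what frequency.
#'
#' @param path a VCF v4.x file (plain or bgzipped).
#' @return a \code{DataFrame} with columns \code{id}, \code{chrom},
#'   \code{pos}, \code{ref}, \code{alt}, \code{qual}, \code{depth},
#'   \code{af}, \code{altObserved}, \code{nSamples}; the depth source is
#'   recorded in \code{metadata()$depthSource}.
#' @export
readCohortVcf <- function(path) {
  if (!file.exists(path)) .stopf("cannot read VCF '%s'", path)
  vcf <- VariantAnnotation::readVcf(path, genome = "GRCh37")
  rr <- SummarizedExperiment::rowRanges(vcf)
  gt <- VariantAnnotation::geno(vcf)$GT
  info_dp <- tryCatch(VariantAnnotation::info(vcf)$DP, error = function(e) NULL)
  if (!is.null(info_dp) && !all(is.na(info_dp))) {
    depth <- as.numeric(info_dp)
    depth_source <- "INFO/DP"
  } else {
    fmt_dp <- tryCatch(VariantAnnotation::geno(vcf)$DP,
                       error = function(e) NULL)
    depth <- if (is.null(fmt_dp)) rep(NA_real_, length(rr)) else
      rowSums(fmt_dp, na.rm = TRUE)
    depth_source <- "sum(FORMAT/DP)"
  }
  alt_list <- VariantAnnotation::alt(vcf)
  n_alt <- lengths(alt_list)
  rec <- rep(seq_along(rr), n_alt)
  aidx <- unlist(lapply(n_alt, seq_len), use.names = FALSE)
  af <- obs <- numeric(length(rec))
  for (k in seq_along(rec)) {
    g <- gt[rec[k], ]
    af[k] <- alleleFrequency(g, alleleIndex = aidx[k])
    obs[k] <- isTRUE(af[k] > 0)
  }
  out <- DataFrame(
    id = rep(names(rr), n_alt),
    chrom = rep(as.character(GenomeInfoDb::seqnames(rr)), n_alt),
    pos = rep(BiocGenerics::start(rr), n_alt),
    ref = rep(as.character(VariantAnnotation::ref(vcf)), n_alt),
    alt = as.character(unlist(alt_list)),
    qual = rep(as.numeric(rr$QUAL), n_alt),
    depth = rep(depth, n_alt),
    af = af, altObserved = as.logical(obs),
    nSamples = ncol(gt))
  metadata(out)$depthSource <- depth_source
  out
}

#' Match a variant dataset against cohort VCFs
#'
#' A dataset variant matches in a cohort when a quality-passing VCF record
#' shares its chromosome and position (contig names are compared after
#' stripping any \code{chr} prefix) and the alternate allele is observed in
#' at least one sample. When the dataset row carries a risk allele, only
#' that alternate allele counts; otherwise any alternate allele does.
#' Variants without coordinates fall back to matching the VCF ID column on
#' rsid.
#'
#' @param vcfPaths character vector of VCF paths; names are used as
#'   population labels (default: file base names).
#' @param dataset data.frame with \code{rsid} and ideally \code{chrom} +
#'   \code{pos} (1-based, same assembly as the VCFs); optional
#'   \code{risk_allele}.
#' @param spec a [qualityFilter()].
#' @param onMissing forwarded to [passesQuality()].
#' @return a \code{DataFrame}, one row per dataset variant per population:
#'   \code{rsid}, \code{population}, \code{matched}, \code{reason}
#'   (matched / matched_by_id / alt_unobserved / fails_quality /
#'   no_record), \code{af}, \code{depth}, \code{qual}, \code{nSamples}.
#' @seealso [matchedRsids()] for the union across populations.
#' @export
matchDataset <- function(vcfPaths, dataset, spec = qualityFilter(),
                         onMissing = "fail") {
  stopifnot(nrow(dataset) > 0, "rsid" %in% names(dataset))
  if (is.null(names(vcfPaths)) || any(!nzchar(names(vcfPaths))))
    names(vcfPaths) <- basename(unname(vcfPaths))
  res <- lapply(names(vcfPaths), function(pop) {
    sites <- readCohortVcf(vcfPaths[[pop]])
    key <- paste(.strip_chr(sites$chrom), sites$pos)
    rows <- lapply(seq_len(nrow(dataset)), function(i) {
      d <- dataset[i, ]
      has_coord <- !is.null(d$chrom) && !is.na(d$chrom) &&
        !is.null(d$pos) && !is.na(d$pos)
      hit <- if (has_coord)
        which(key == paste(.strip_chr(d$chrom), d$pos))
      else which(sites$id == d$rsid)
      if (!is.null(d$risk_allele) && !is.na(d$risk_allele) && length(hit)) {
        hit2 <- hit[sites$alt[hit] == toupper(d$risk_allele)]
        if (length(hit2)) hit <- hit2
      }
      if (!length(hit))
        return(data.frame(rsid = d$rsid, population = pop, matched = FALSE,
                          reason = "no_record", af = NA_real_,
                          depth = NA_real_, qual = NA_real_,
                          nSamples = NA_integer_))
      passing <- hit[passesQuality(sites$depth[hit], sites$qual[hit], spec,
                                   onMissing = onMissing)]
      if (!length(passing))
        return(data.frame(rsid = d$rsid, population = pop, matched = FALSE,
                          reason = "fails_quality", af = NA_real_,
                          depth = max(sites$depth[hit]),
                          qual = max(sites$qual[hit]),
                          nSamples = sites$nSamples[hit[1]]))
      seen <- passing[sites$altObserved[passing]]
      j <- if (length(seen)) seen[which.max(sites$af[seen])] else passing[1]
      data.frame(rsid = d$rsid, population = pop,
                 matched = length(seen) > 0,
                 reason = if (length(seen)) {
                   if (has_coord) "matched" else "matched_by_id"
                 } else "alt_unobserved",
                 af = sites$af[j], depth = sites$depth[j],
                 qual = sites$qual[j], nSamples = sites$nSamples[j])
    })
    do.call(rbind, rows)
  })
  DataFrame(do.call(rbind, res))
}

#' @rdname matchDataset
#' @param matches result of \code{matchDataset}.
#' @return \code{matchedRsids}: the unique rsids matched in any population.
#' @export
matchedRsids <- function(matches) {
  sort(unique(matches$rsid[matches$matched]))
}
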