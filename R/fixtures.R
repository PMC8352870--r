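# synthetic_fixtures module, part 1: the packaged reference tables.

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "VariantVote")
  if (!nzchar(path)) .stopf("packaged table '%s' not found", file)
  path
}

.read_fixture <- function(file) {
  utils::read.delim(.extdata(file), comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Packaged reference tables
#'
#' Loads the machine-readable transcriptions of the published evaluation
#' tables, validated against the domain invariants at load time:
#' \describe{
#'   \item{confusion}{confusion counts of the eight consensus models on the
#'     100-variant clinically labeled standard set.}
#'   \item{cohortLabels}{cancer-associated nsSNPs observed in the two
#'     cohorts with the five predictors' categorical verdicts (partial
#'     transcription: 48 of the 52 published rows were recoverable) and the
#'     \code{highrisk} flag marking the eight cascade candidates.}
#'   \item{conservation}{ConSurf grades for the eight high-risk variants.}
#'   \item{stability}{I-Mutant direction/RI/\eqn{\Delta\Delta G} and
#'     TM-align TM-score/RMSD for the eight high-risk variants.}
#'   \item{annotation}{MutPred2 scores with mechanism hypotheses and
#'     ModPred PTM predictions for the three shortlisted variants.}
#' }
#'
#' @return a named list of data.frames.
#' @seealso [referenceProfiles()], [referenceCandidates()]
#' @export
referenceData <- function() {
  out <- list(confusion = .read_fixture("benchmark_confusion_8models.tsv"),
              cohortLabels = .read_fixture("cohort_nssnp_labels.tsv"),
              conservation = .read_fixture("highrisk_conservation.tsv"),
              stability = .read_fixture("highrisk_stability_structure.tsv"),
              annotation = .read_fixture("shortlist_annotation.tsv"))
  # integrity: every table must satisfy the owning type's invariants
  with(out$confusion, stopifnot(all(tp >= 0), all(fn >= 0), all(tn >= 0),
                                all(fp >= 0)))
  stopifnot(all(out$conservation$consurf_score %in% 1:9),
            all(out$stability$ri >= 0 & out$stability$ri <= 10),
            all(out$stability$tm_score >= 0 & out$stability$tm_score <= 1),
            all(out$stability$rmsd >= 0),
            all(out$annotation$mutpred_score >= 0 &
                  out$annotation$mutpred_score <= 1))
  invisible(parseAAChange(out$cohortLabels$aa_change))  # errors if malformed
  out
}

#' Cohort label table as a ProfileSet
#'
#' Converts the packaged cohort table (categorical predictor verdicts only)
#' into a [ProfileSet] with calls resolved through the label maps.
#'
#' @param thresholds a [thresholdConfig()].
#' @return a [ProfileSet]; the \code{trait} and \code{highrisk} columns are
#'   carried along.
#' @export
referenceProfiles <- function(thresholds = defaultThresholds()) {
  tab <- referenceData()$cohortLabels
  df <- data.frame(rsid = tab$rsid, gene = tab$gene,
                   aa_change = tab$aa_change,
                   sift_label = tab$sift, pp2_label = tab$polyphen2,
                   condel_label = tab$condel, provean_label = tab$provean,
                   panther_label = tab$panther,
                   trait = tab$trait, chrom = tab$chrom, pos = tab$pos,
                   highrisk = tab$highrisk, stringsAsFactors = FALSE)
  ProfileSet(df, thresholds)
}

#' The eight high-risk candidates with full cascade evidence
#'
#' Merges the cohort labels of the eight high-risk variants with their
#' conservation, stability, structure and (where available) annotation
#' evidence, ready for [runCascade()].
#'
#' @param thresholds a [thresholdConfig()].
#' @return a [ProfileSet] of 8 variants.
#' @export
referenceCandidates <- function(thresholds = defaultThresholds()) {
  ref <- referenceData()
  tab <- ref$cohortLabels[ref$cohortLabels$highrisk == 1, ]
  df <- data.frame(rsid = tab$rsid, gene = tab$gene,
                   aa_change = tab$aa_change,
                   sift_label = tab$sift, pp2_label = tab$polyphen2,
                   condel_label = tab$condel, provean_label = tab$provean,
                   panther_label = tab$panther, stringsAsFactors = FALSE)
  i <- match(df$rsid, ref$conservation$rsid)
  df$consurf_score <- ref$conservation$consurf_score[i]
  j <- match(df$rsid, ref$stability$rsid)
  df$imutant_direction <- ref$stability$direction[j]
  df$imutant_ri <- ref$stability$ri[j]
  df$imutant_ddg <- ref$stability$ddg[j]
  df$tm_score <- ref$stability$tm_score[j]
  df$rmsd <- ref$stability$rmsd[j]
  k <- match(df$rsid, ref$annotation$rsid)
  df$mutpred_score <- ref$annotation$mutpred_score[k]
  df$modpred_score <- ref$annotation$modpred_score[k]
  ProfileSet(df, thresholds)
}

#' Mechanism hypotheses of the shortlisted variants, tiered
#'
#' Expands the packaged MutPred2 feature strings into one row per
#' mechanism hypothesis with its p-value and confidence tier (see
#' [mutpredTier()]).
#'
#' @return data.frame: \code{rsid}, \code{gene}, \code{aa_change},
#'   \code{feature}, \code{p}, \code{tier}.
#' @export
shortlistHypotheses <- function() {
  ann <- referenceData()$annotation
  rows <- lapply(seq_len(nrow(ann)), function(i) {
    pairs <- strsplit(strsplit(ann$features[i], ";")[[1]], "=")
    data.frame(rsid = ann$rsid[i], gene = ann$gene[i],
               aa_change = ann$aa_change[i],
               feature = vapply(pairs, `[`, "", 1L),
               p = as.numeric(vapply(pairs, `[`, "", 2L)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$tier <- mutpredTier(ann$mutpred_score[match(out$rsid, ann$rsid)],
                          out$p)
  out
}
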