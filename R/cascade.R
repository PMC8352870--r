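# prioritization_cascade module: consensus -> conservation -> stability ->
# structure gates applied in order, with functional annotation of the
# survivors and a full per-variant trace.

#' Cascade configuration
#'
#' @param consensus a [consensusModel()] applied as the first gate, or
#'   \code{NULL} when the input profiles are an already-selected high-risk
#'   candidate set (the stage then passes every variant through and records
#'   \code{preselected}).
#' @param conservationMinGrade minimum ConSurf grade (default 7, the
#'   conserved range).
#' @param stabilityMinRI minimum I-Mutant reliability index (default 5);
#'   together with a predicted stability decrease this forms the stability
#'   gate. The reliability index, not the \eqn{\Delta\Delta G} class, is
#'   what excludes low-confidence predictions.
#' @param tmMin structural gate: TM-score must exceed this (default 0.5,
#'   the shared-fold threshold).
#' @param rmsdMax structural gate: RMSD must be below this (default 6.5
#'   Angstrom).
#' @param mutpredMin annotation threshold for the pathogenic flag
#'   (default 0.5). Annotation never eliminates a variant.
#' @return a \code{vv_cascade} configuration.
#' @export
cascadeConfig <- function(consensus = consensusModel("D"),
                          conservationMinGrade = 7, stabilityMinRI = 5,
                          tmMin = 0.5, rmsdMax = 6.5, mutpredMin = 0.5) {
  stopifnot(is.null(consensus) || is(consensus, "ConsensusModel"),
            conservationMinGrade >= 1, conservationMinGrade <= 9,
            stabilityMinRI >= 0, stabilityMinRI <= 10,
            tmMin >= 0, tmMin <= 1, rmsdMax >= 0,
            mutpredMin >= 0, mutpredMin <= 1)
  structure(list(consensus = consensus,
                 conservationMinGrade = conservationMinGrade,
                 stabilityMinRI = stabilityMinRI, tmMin = tmMin,
                 rmsdMax = rmsdMax, mutpredMin = mutpredMin),
            class = "vv_cascade")
}

#' Individual cascade stages
#'
#' Each stage returns, per variant, \code{"pass"}, \code{"fail"} or
#' \code{"not_evaluated"} (evidence absent — reported separately from a
#' failure).
#'
#' @param x a [ProfileSet].
#' @param cfg a [cascadeConfig()].
#' @return character vector of statuses.
#' @name cascade-stages
NULL

#' @rdname cascade-stages
#' @export
stageConservation <- function(x, cfg = cascadeConfig()) {
  grade <- x$consurf_score
  ifelse(is.na(grade), "not_evaluated",
         ifelse(grade >= cfg$conservationMinGrade, "pass", "fail"))
}

#' @rdname cascade-stages
#' @export
stageStability <- function(x, cfg = cascadeConfig()) {
  dir <- x$imutant_direction
  ri <- x$imutant_ri
  ifelse(is.na(dir) | is.na(ri), "not_evaluated",
         ifelse(dir == "decrease" & ri >= cfg$stabilityMinRI,
                "pass", "fail"))
}

#' @rdname cascade-stages
#' @export
stageStructure <- function(x, cfg = cascadeConfig()) {
  tm <- x$tm_score
  rmsd <- x$rmsd
  ifelse(is.na(tm) | is.na(rmsd), "not_evaluated",
         ifelse(tm > cfg$tmMin & rmsd < cfg$rmsdMax, "pass", "fail"))
}

.CASCADE_STAGES <- c("consensus", "conservation", "stability", "structure")

#' Run the staged prioritization cascade
#'
#' Applies consensus, conservation, stability and structure gates in order.
#' A variant failing (or lacking evidence for) stage k is not evaluated at
#' later stages, so survivor sets are nested. Survivors of all four gates
#' form the shortlist and are annotated with the MutPred2 pathogenicity
#' flag and the ModPred PTM confidence; annotation never eliminates.
#'
#' @param x a [ProfileSet].
#' @param cfg a [cascadeConfig()].
#' @return a list with
#'   \describe{
#'     \item{trace}{\code{DataFrame}: per variant, the status at each stage
#'       (\code{pass}/\code{fail}/\code{not_evaluated}; stages after the
#'       stopping stage are \code{not_evaluated}), the stopping stage
#'       (\code{stoppedAt}, \code{NA} for survivors) and
#'       \code{shortlisted}.}
#'     \item{survivors}{named integer vector: input size followed by the
#'       survivor count after each stage.}
#'     \item{shortlist}{\code{DataFrame} of shortlisted variants with
#'       annotation columns.}
#'   }
#' @export
runCascade <- function(x, cfg = cascadeConfig()) {
  stopifnot(is(x, "ProfileSet"), inherits(cfg, "vv_cascade"))
  n <- nrow(x)
  status <- matrix("not_evaluated", nrow = n, ncol = length(.CASCADE_STAGES),
                   dimnames = list(NULL, .CASCADE_STAGES))
  alive <- rep(TRUE, n)
  stage_status <- function(stage) {
    switch(stage,
           consensus = if (is.null(cfg$consensus)) rep("pass", n) else
             c(deleterious = "pass", benign = "fail",
               not_evaluated = "not_evaluated")[
                 applyModel(x, cfg$consensus)$decision],
           conservation = stageConservation(x, cfg),
           stability = stageStability(x, cfg),
           structure = stageStructure(x, cfg))
  }
  survivors <- c(input = n)
  for (stage in .CASCADE_STAGES) {
    st <- unname(stage_status(stage))
    status[alive, stage] <- st[alive]
    alive <- alive & st == "pass"
    survivors[stage] <- sum(alive)
  }
  stopped <- apply(status, 1L, function(row) {
    bad <- which(row != "pass")
    if (length(bad)) .CASCADE_STAGES[bad[1]] else NA_character_
  })
  trace <- DataFrame(rsid = x$rsid, gene = x$gene, aa_change = x$aa_change,
                     consensus = status[, "consensus"],
                     conservation = status[, "conservation"],
                     stability = status[, "stability"],
                     structure = status[, "structure"],
                     stoppedAt = stopped, shortlisted = alive)
  short <- x[alive, , drop = FALSE]
  shortlist <- DataFrame(
    rsid = short$rsid, gene = short$gene, aa_change = short$aa_change,
    mutpredScore = short$mutpred_score,
    mutpredPathogenic = !is.na(short$mutpred_score) &
      short$mutpred_score >= cfg$mutpredMin,
    modpredScore = short$modpred_score,
    modpredConfidence = modpredConfidence(short$modpred_score))
  list(trace = trace, survivors = survivors, shortlist = shortlist)
}
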