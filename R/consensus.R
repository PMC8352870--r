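# consensus_engine module: k-of-5 voting over the five functional
# predictors, with optional conservation and stability gates (X3 models).

#' Summarize the five functional votes per variant
#'
#' @param x a [ProfileSet] with resolved calls.
#' @param policy missing-data policy; affects only the effective vote used
#'   by the models, the raw counts reported here are policy-free except for
#'   \code{nEffective}: under \code{strict} a missing call contributes
#'   nothing, under \code{permissive} it counts as significant, under
#'   \code{fraction} the denominator shrinks to the available tools.
#' @return a \code{DataFrame} with \code{rsid}, \code{nSignificant},
#'   \code{nNotSignificant}, \code{nMissing} (summing to 5) and
#'   \code{nEffective}, the significant-vote count after applying the
#'   policy.
#' @export
countVotes <- function(x, policy = c("strict", "permissive", "fraction")) {
  policy <- match.arg(policy)
  calls <- toolCalls(x)
  n_sig <- rowSums(calls == "significant")
  n_not <- rowSums(calls == "not_significant")
  n_mis <- rowSums(calls == "missing")
  eff <- switch(policy,
                strict = n_sig,
                permissive = n_sig + n_mis,
                fraction = n_sig)
  DataFrame(rsid = x$rsid, nSignificant = unname(n_sig),
            nNotSignificant = unname(n_not), nMissing = unname(n_mis),
            nEffective = unname(eff))
}

# Vote rule per policy; integral arithmetic so there is no floating-point
# boundary. fraction compares nSig/(5 - nMissing) against minVotes/5 and
# calls an all-missing profile benign (no evidence).
.vote_deleterious <- function(n_sig, n_mis, min_votes, policy) {
  switch(policy,
         strict = n_sig >= min_votes,
         permissive = (n_sig + n_mis) >= min_votes,
         fraction = {
           avail <- 5L - n_mis
           avail > 0L & (n_sig * 5L) >= (min_votes * avail)
         })
}

#' Apply one consensus model to every variant
#'
#' A variant is called deleterious when its (policy-adjusted) significant
#' votes reach the model's minimum and, for the X3 models, the residue is
#' conserved (grade \eqn{\ge} 7) and the mutation destabilizes the protein
#' (predicted stability decrease by default, or destabilizing
#' \eqn{\Delta\Delta G} when the model's \code{stabilityGate} is
#' \code{"ddg"}); it is benign otherwise. An X3 model with conservation or
#' stability evidence absent yields \code{not_evaluated} with the reason
#' recorded — distinct from a failed gate.
#'
#' @param x a [ProfileSet].
#' @param model a [consensusModel()].
#' @return a \code{DataFrame} with the vote breakdown, gate statuses
#'   (\code{pass}/\code{fail}/\code{absent}/\code{NA} when not required)
#'   and \code{decision} in \{deleterious, benign, not_evaluated\}.
#' @examples
#' ps <- ProfileSet(data.frame(rsid = "rs1", gene = "G", aa_change = "R4Q",
#'                             sift_score = 0.01, pp2_score = 0.99,
#'                             condel_score = 0.8, provean_score = -3,
#'                             panther_score = 500))
#' applyModel(ps, consensusModel("D"))
#' @export
applyModel <- function(x, model) {
  stopifnot(is(x, "ProfileSet"), is(model, "ConsensusModel"))
  votes <- countVotes(x, model@missingPolicy)
  vote_ok <- .vote_deleterious(votes$nSignificant, votes$nMissing,
                               model@minVotes, model@missingPolicy)
  cons_gate <- stab_gate <- rep(NA_character_, nrow(x))
  not_eval <- rep(FALSE, nrow(x))
  if (model@requireConservation) {
    grade <- x$consurf_score
    cons_gate <- ifelse(is.na(grade), "absent",
                        ifelse(grade >= 7, "pass", "fail"))
    not_eval <- not_eval | cons_gate == "absent"
  }
  if (model@requireStability) {
    if (model@stabilityGate == "direction") {
      dir <- x$imutant_direction
      stab_gate <- ifelse(is.na(dir), "absent",
                          ifelse(dir == "decrease", "pass", "fail"))
    } else {
      klass <- ddgClass(x$imutant_ddg)
      stab_gate <- ifelse(is.na(klass), "absent",
                          ifelse(klass == "destabilizing", "pass", "fail"))
    }
    not_eval <- not_eval | stab_gate == "absent"
  }
  decision <- ifelse(
    not_eval, "not_evaluated",
    ifelse(vote_ok &
             (is.na(cons_gate) | cons_gate == "pass") &
             (is.na(stab_gate) | stab_gate == "pass"),
           "deleterious", "benign"))
  DataFrame(rsid = x$rsid, model = model@id,
            nSignificant = votes$nSignificant, nMissing = votes$nMissing,
            conservationGate = cons_gate, stabilityGate = stab_gate,
            decision = decision)
}

#' Confusion counts of several models against truth labels
#'
#' @param x a [ProfileSet].
#' @param truth character vector (parallel to \code{x}) with values
#'   \code{"pathogenic"} / \code{"benign"}.
#' @param models list of [consensusModel()]s (default: all eight under the
#'   strict policy).
#' @return a \code{data.frame} with one row per model: \code{model},
#'   \code{tp}, \code{fn}, \code{tn}, \code{fp}. Only a
#'   \code{deleterious} decision counts as a positive prediction, so
#'   \code{tp + fn} and \code{tn + fp} equal the class sizes for every
#'   model.
#' @export
rankModels <- function(x, truth, models = consensusModels()) {
  truth <- as.character(truth)
  if (length(truth) != nrow(x))
    .stopf("truth labels (%d) do not cover the %d profiles", length(truth),
           nrow(x))
  if (anyNA(truth) || !all(truth %in% c("pathogenic", "benign")))
    .stopf("every profile needs a truth label in {pathogenic, benign}")
  rows <- lapply(models, function(m) {
    dec <- applyModel(x, m)$decision
    pos <- dec == "deleterious"
    data.frame(model = m@id,
               tp = sum(pos & truth == "pathogenic"),
               fn = sum(!pos & truth == "pathogenic"),
               tn = sum(!pos & truth == "benign"),
               fp = sum(pos & truth == "benign"))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
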