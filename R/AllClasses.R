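#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom S4Vectors DFrame
NULL

# Column schema of the profile table dialect. Score/label pairs for the five
# functional predictors, then optional conservation / stability / structure /
# annotation evidence. Empty cell = evidence absent.
PROFILE_COLUMNS <- c(
  "rsid", "gene", "aa_change",
  "sift_score", "sift_label", "pp2_score", "pp2_label",
  "condel_score", "condel_label", "provean_score", "provean_label",
  "panther_score", "panther_label",
  "consurf_score", "imutant_direction", "imutant_ddg", "imutant_ri",
  "tm_score", "rmsd", "mutpred_score", "modpred_score")

.PROFILE_NUMERIC <- c("sift_score", "pp2_score", "condel_score",
                      "provean_score", "panther_score", "imutant_ddg",
                      "tm_score", "rmsd", "mutpred_score", "modpred_score")
.PROFILE_INTEGER <- c("consurf_score", "imutant_ri")

TOOLS <- c("sift", "pp2", "condel", "provean", "panther")
CALL_LEVELS <- c("significant", "not_significant", "missing")

#' ProfileSet: per-variant prediction evidence
#'
#' A \code{ProfileSet} holds one row per variant with the raw scores and/or
#' categorical labels of the five functional-effect predictors (SIFT,
#' PolyPhen-2, Condel, PROVEAN, PANTHER), their resolved
#' significant/not-significant/missing calls, and optional conservation
#' (ConSurf grade 1--9), stability (I-Mutant direction, \eqn{\Delta\Delta G},
#' reliability index), structure (TM-score, RMSD) and functional annotation
#' (MutPred2, ModPred) evidence. It extends \code{S4Vectors::DFrame}, so all
#' the usual table operations (\code{[}, \code{nrow}, \code{$}) apply.
#'
#' Validity enforces the domain invariants: ConSurf grades in 1--9,
#' reliability index in 0--10, TM-score in [0,1], RMSD \eqn{\ge} 0,
#' probability-scaled scores in [0,1], calls drawn from the closed
#' call vocabulary and amino-acid changes parsable.
#'
#' @seealso [readProfiles()], [validateProfiles()], [countVotes()]
#' @export
setClass("ProfileSet", contains = "DFrame")

setValidity("ProfileSet", function(object) {
  v <- validateProfiles(object)
  if (length(v)) v else TRUE
})

#' Construct a ProfileSet
#'
#' @param x a \code{data.frame} (or DataFrame) with at least \code{rsid},
#'   \code{gene} and \code{aa_change}; missing schema columns are added as
#'   \code{NA}. Extra columns (e.g. \code{trait}) are preserved.
#' @param thresholds a [thresholdConfig()] used to resolve the per-tool
#'   calls from scores/labels; \code{NULL} keeps existing \code{*_call}
#'   columns untouched.
#' @return a validated \code{ProfileSet}.
#' @examples
#' ProfileSet(data.frame(rsid = "rs1", gene = "TYR", aa_change = "R402Q",
#'                       sift_score = 0.01))
#' @export
ProfileSet <- function(x, thresholds = defaultThresholds()) {
  new("ProfileSet", .profile_frame(x, thresholds))
}

# Coerce to the schema'd DataFrame (columns filled/typed, calls resolved)
# without constructing the S4 object, so callers can validate first.
.profile_frame <- function(x, thresholds = defaultThresholds()) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  for (col in setdiff(PROFILE_COLUMNS, names(x)))
    x[[col]] <- rep(if (col %in% .PROFILE_NUMERIC) NA_real_ else
      if (col %in% .PROFILE_INTEGER) NA_integer_ else NA_character_,
      nrow(x))
  for (col in .PROFILE_NUMERIC) x[[col]] <- as.numeric(x[[col]])
  for (col in .PROFILE_INTEGER) x[[col]] <- as.integer(x[[col]])
  x$rsid <- as.character(x$rsid)
  extra <- setdiff(names(x), PROFILE_COLUMNS)
  x <- x[, c(PROFILE_COLUMNS, extra), drop = FALSE]
  df <- DataFrame(x, check.names = FALSE)
  if (!is.null(thresholds)) {
    for (tool in TOOLS)
      df[[paste0(tool, "_call")]] <- classifyTool(
        tool, df[[paste0(tool, "_score")]], df[[paste0(tool, "_label")]],
        thresholds)$call
  }
  df
}

#' Check the domain invariants of a profile table
#'
#' Returns a character vector of violation messages (empty when the table is
#' valid); each message names the row, field and rule broken. Used as the
#' class validity of [ProfileSet] but callable on any DataFrame-like input.
#'
#' @param x a \code{ProfileSet} or DataFrame with the profile schema.
#' @return character vector of violations, \code{character(0)} if valid.
#' @export
validateProfiles <- function(x) {
  v <- character()
  missing_cols <- setdiff(PROFILE_COLUMNS, colnames(x))
  if (length(missing_cols))
    return(sprintf("missing profile columns: %s",
                   paste(missing_cols, collapse = ", ")))
  chk <- function(cond, fmt, ...) {
    bad <- which(!is.na(cond) & !cond)
    if (length(bad))
      v <<- c(v, sprintf(fmt, paste(x$rsid[bad], collapse = ", "), ...))
    invisible(NULL)
  }
  cs <- x$consurf_score
  chk(cs >= 1 & cs <= 9, "%s: consurf_score outside grade range 1-9")
  ri <- x$imutant_ri
  chk(ri >= 0 & ri <= 10, "%s: imutant_ri outside 0-10")
  chk(x$tm_score >= 0 & x$tm_score <= 1, "%s: tm_score outside [0,1]")
  chk(x$rmsd >= 0, "%s: rmsd negative")
  for (col in c("sift_score", "pp2_score", "condel_score",
                "mutpred_score", "modpred_score"))
    chk(x[[col]] >= 0 & x[[col]] <= 1,
        paste0("%s: ", col, " outside [0,1]"))
  dir <- x$imutant_direction
  chk(is.na(dir) | dir %in% c("increase", "decrease"),
      "%s: imutant_direction not increase/decrease")
  for (tool in TOOLS) {
    cc <- paste0(tool, "_call")
    if (cc %in% colnames(x))
      chk(x[[cc]] %in% CALL_LEVELS,
          paste0("%s: ", cc, " outside the call vocabulary"))
  }
  aa <- parseAAChange(x$aa_change, strict = FALSE)
  bad_aa <- which(!is.na(x$aa_change) & is.na(aa$ref))
  if (length(bad_aa))
    v <- c(v, sprintf("%s: unparsable aa_change",
                      paste(x$rsid[bad_aa], collapse = ", ")))
  v
}

setMethod("show", "ProfileSet", function(object) {
  cat(sprintf("ProfileSet with %d variant(s)\n", nrow(object)))
  has <- function(col) sum(!is.na(object[[col]]))
  cat(sprintf("  evidence: conservation %d, stability %d, structure %d, annotation %d\n",
              has("consurf_score"), has("imutant_ri"), has("tm_score"),
              has("mutpred_score")))
  callNextMethod()
})

#' @describeIn ProfileSet variant identifiers
#' @param object,x a \code{ProfileSet}.
#' @export
setGeneric("rsid", function(x) standardGeneric("rsid"))

#' @rdname ProfileSet
#' @export
setMethod("rsid", "ProfileSet", function(x) x$rsid)

#' @describeIn ProfileSet the resolved per-tool call matrix (variants x
#'   five tools), values from the call vocabulary.
#' @export
setGeneric("toolCalls", function(x) standardGeneric("toolCalls"))

#' @rdname ProfileSet
#' @export
setMethod("toolCalls", "ProfileSet", function(x) {
  cols <- paste0(TOOLS, "_call")
  if (!all(cols %in% colnames(x)))
    .stopf("calls not resolved; construct via ProfileSet()/readProfiles()")
  m <- do.call(cbind, lapply(cols, function(cc) as.character(x[[cc]])))
  dimnames(m) <- list(x$rsid, TOOLS)
  m
})

#' Consensus voting model specification
#'
#' The eight consensus models combine the five functional predictors by
#' k-of-5 voting: models A--D call a variant deleterious when at least
#' 1--4 tools are significant; A3--D3 additionally require the residue to be
#' evolutionarily conserved (grade \eqn{\ge} 7) and the mutation to
#' destabilize the protein. The missing-data policy decides how an absent
#' predictor output enters the vote: \code{strict} counts it against
#' (missing is not evidence), \code{permissive} counts it in favour, and
#' \code{fraction} rescales the vote threshold to the number of available
#' tools.
#'
#' @slot id model identifier, one of A, B, C, D, A3, B3, C3, D3.
#' @slot minVotes minimum significant votes out of five (1--4).
#' @slot requireConservation,requireStability gates added by the X3 models.
#' @slot missingPolicy one of strict, permissive, fraction.
#' @slot stabilityGate \code{"direction"} (predicted stability decrease,
#'   the default) or \code{"ddg"} (destabilizing
#'   \eqn{\Delta\Delta G < -0.5} kcal/mol).
#' @export
setClass("ConsensusModel", representation(
  id = "character", minVotes = "integer",
  requireConservation = "logical", requireStability = "logical",
  missingPolicy = "character", stabilityGate = "character"))

MODEL_IDS <- c("A", "B", "C", "D", "A3", "B3", "C3", "D3")
MISSING_POLICIES <- c("strict", "permissive", "fraction")

setValidity("ConsensusModel", function(object) {
  msg <- character()
  if (!object@id %in% MODEL_IDS)
    msg <- c(msg, sprintf("unknown model id '%s'", object@id))
  k <- match(sub("3$", "", object@id), c("A", "B", "C", "D"))
  if (!is.na(k) && object@minVotes != k)
    msg <- c(msg, sprintf("model %s must use minVotes = %d", object@id, k))
  x3 <- grepl("3$", object@id)
  if (!is.na(k) && (object@requireConservation != x3 ||
                    object@requireStability != x3))
    msg <- c(msg, "conservation/stability gates must match the X3 suffix")
  if (!object@missingPolicy %in% MISSING_POLICIES)
    msg <- c(msg, sprintf("unknown missing policy '%s'", object@missingPolicy))
  if (!object@stabilityGate %in% c("direction", "ddg"))
    msg <- c(msg, "stabilityGate must be 'direction' or 'ddg'")
  if (length(msg)) msg else TRUE
})

#' @rdname ConsensusModel-class
#' @param id model identifier (A--D, A3--D3).
#' @param missingPolicy missing-data policy (see class description).
#' @param stabilityGate stability gate used by the X3 models.
#' @return a validated \code{ConsensusModel}.
#' @examples
#' consensusModel("D")
#' consensusModels()  # all eight
#' @export
consensusModel <- function(id, missingPolicy = c("strict", "permissive",
                                                 "fraction"),
                           stabilityGate = c("direction", "ddg")) {
  id <- match.arg(toupper(id), MODEL_IDS)
  missingPolicy <- match.arg(missingPolicy)
  stabilityGate <- match.arg(stabilityGate)
  x3 <- grepl("3$", id)
  new("ConsensusModel", id = id,
      minVotes = match(sub("3$", "", id), c("A", "B", "C", "D")),
      requireConservation = x3, requireStability = x3,
      missingPolicy = missingPolicy, stabilityGate = stabilityGate)
}

#' @rdname ConsensusModel-class
#' @param ... passed to [consensusModel()] for every id.
#' @export
consensusModels <- function(...) {
  models <- lapply(MODEL_IDS, consensusModel, ...)
  names(models) <- MODEL_IDS
  models
}

setMethod("show", "ConsensusModel", function(object) {
  gates <- if (object@requireConservation)
    sprintf(" + conservation + stability(%s)", object@stabilityGate) else ""
  cat(sprintf("ConsensusModel %s: >= %d of 5 tools significant%s [%s policy]\n",
              object@id, object@minVotes, gates, object@missingPolicy))
})
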