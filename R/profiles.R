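# Profile table I/O: one row per variant, empty cell = evidence absent.

#' Read a profile table
#'
#' Reads the tab-separated profile dialect (columns as in
#' \code{PROFILE_COLUMNS}; lines starting with \code{#} are comments) and
#' resolves every tool cell into a significant/not-significant/missing call
#' under \code{thresholds}. Rows violating a domain invariant are collected
#' into an error report in \code{metadata(x)$rejected} rather than silently
#' skipped.
#'
#' @param path file in the profile TSV dialect.
#' @param thresholds a [thresholdConfig()].
#' @return a [ProfileSet].
#' @seealso [writeProfiles()] for the inverse; the pair round-trips
#'   field-for-field.
#' @export
readProfiles <- function(path, thresholds = defaultThresholds()) {
  if (!file.exists(path)) .stopf("cannot read profile table '%s'", path)
  x <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  need <- c("rsid", "gene", "aa_change")
  if (!all(need %in% names(x)))
    .stopf("profile table '%s' lacks mandatory column(s): %s", path,
           paste(setdiff(need, names(x)), collapse = ", "))
  x[x == ""] <- NA
  if (nrow(x) == 0)
    return(ProfileSet(data.frame(rsid = character(), gene = character(),
                                 aa_change = character()), thresholds))
  # separate rows that break an invariant so the good rows still load
  probe <- .profile_frame(x, thresholds = NULL)
  per_row <- lapply(seq_len(nrow(x)), function(i)
    validateProfiles(probe[i, , drop = FALSE]))
  bad <- vapply(per_row, length, 1L) > 0L
  ps <- ProfileSet(x[!bad, , drop = FALSE], thresholds)
  if (any(bad))
    metadata(ps)$rejected <- data.frame(
      row = which(bad), rsid = x$rsid[bad],
      message = vapply(per_row[bad], paste, "", collapse = "; "),
      stringsAsFactors = FALSE)
  ps
}

#' Write a profile table
#'
#' @param x a [ProfileSet].
#' @param path output path; missing values become empty cells.
#' @return \code{path}, invisibly.
#' @export
writeProfiles <- function(x, path) {
  stopifnot(is(x, "ProfileSet"))
  df <- as.data.frame(x)
  df <- df[, setdiff(names(df), paste0(TOOLS, "_call")), drop = FALSE]
  num <- vapply(df, is.double, TRUE)
  df[num] <- lapply(df[num], function(col) ifelse(is.na(col), "",
                                                  format(col, digits = 15,
                                                         trim = TRUE,
                                                         scientific = FALSE)))
  df[!num] <- lapply(df[!num], function(col) ifelse(is.na(col), "",
                                                    as.character(col)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Conservation class of a ConSurf grade
#'
#' Grades 1--4 are variable, 5--6 intermediate and 7--9 conserved.
#'
#' @param score integer grade(s) in 1--9.
#' @return character vector in \{variable, intermediate, conserved\}.
#' @export
conservationClass <- function(score) {
  score <- as.integer(score)
  if (any(!is.na(score) & (score < 1 | score > 9)))
    .stopf("ConSurf grade outside 1-9")
  out <- rep(NA_character_, length(score))
  out[!is.na(score) & score <= 4] <- "variable"
  out[!is.na(score) & score >= 5 & score <= 6] <- "intermediate"
  out[!is.na(score) & score >= 7] <- "conserved"
  out
}

#' Free-energy class of a stability prediction
#'
#' \eqn{\Delta\Delta G < -0.5} kcal/mol destabilizing, \eqn{> 0.5}
#' stabilizing, neutral otherwise.
#'
#' @param ddg free-energy change(s), kcal/mol (mutant minus native).
#' @return character vector in \{destabilizing, stabilizing, neutral\}.
#' @export
ddgClass <- function(ddg) {
  ddg <- as.numeric(ddg)
  out <- rep(NA_character_, length(ddg))
  out[!is.na(ddg) & ddg < -0.5] <- "destabilizing"
  out[!is.na(ddg) & ddg > 0.5] <- "stabilizing"
  out[!is.na(ddg) & abs(ddg) <= 0.5] <- "neutral"
  out
}

#' MutPred2 hypothesis tier
#'
#' Tiers a mechanism hypothesis from the general pathogenicity score g and
#' the feature p-value: very confident (g > 0.75, p < 0.01), confident
#' (g > 0.75, p < 0.05), actionable (g > 0.5, p < 0.05), none otherwise.
#'
#' @param g MutPred2 general score(s) in [0,1].
#' @param p feature p-value(s).
#' @return character vector of tiers.
#' @export
mutpredTier <- function(g, p) {
  stopifnot(length(g) == length(p) || length(g) == 1L || length(p) == 1L)
  n <- max(length(g), length(p))
  g <- rep_len(as.numeric(g), n); p <- rep_len(as.numeric(p), n)
  out <- rep("none", n)
  out[g > 0.5 & p < 0.05] <- "actionable"
  out[g > 0.75 & p < 0.05] <- "confident"
  out[g > 0.75 & p < 0.01] <- "very_confident"
  out[is.na(g) | is.na(p)] <- NA_character_
  out
}

#' ModPred confidence tier
#'
#' Default tiering (\code{scheme = "tiered"}): score < 0.7 low, 0.7--0.9
#' medium, \eqn{\ge} 0.9 high. The coarser alternative
#' (\code{scheme = "coarse"}): > 0.5 high, exactly 0.5 medium, < 0.5 low.
#'
#' @param score ModPred score(s) in [0,1].
#' @param scheme tiering scheme.
#' @return character vector in \{low, medium, high\}.
#' @export
modpredConfidence <- function(score, scheme = c("tiered", "coarse")) {
  scheme <- match.arg(scheme)
  score <- as.numeric(score)
  out <- rep(NA_character_, length(score))
  ok <- !is.na(score)
  if (scheme == "tiered") {
    out[ok & score < 0.7] <- "low"
    out[ok & score >= 0.7 & score < 0.9] <- "medium"
    out[ok & score >= 0.9] <- "high"
  } else {
    out[ok & score < 0.5] <- "low"
    out[ok & score == 0.5] <- "medium"
    out[ok & score > 0.5] <- "high"
  }
  out
}
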