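# tool_calls module: published per-tool significance thresholds and the
# label vocabularies printed alongside them.

.LABEL_MAPS <- list(
  sift = c(del = "significant", del_low_con = "significant",
           tol = "not_significant", tol_low_con = "not_significant",
           damaging = "significant", tolerated = "not_significant"),
  # "possibly damaging" is below the 0.9 score cut, hence not significant
  pp2 = c(prob_dam = "significant", pos_dam = "not_significant",
          benign = "not_significant"),
  condel = c(del = "significant", neu = "not_significant"),
  provean = c(del = "significant", neu = "not_significant",
              deleterious = "significant", neutral = "not_significant"),
  panther = c(prob_dam = "significant", pos_dam = "not_significant",
              prob_ben = "not_significant"))

#' Per-tool significance thresholds
#'
#' Encodes the damaging-direction score cut-offs of the five functional
#' predictors: SIFT \eqn{\le} 0.05, PolyPhen-2 > 0.9, Condel > 0.5,
#' PROVEAN \eqn{\le} -2.5 and PANTHER PSEP > 450 million years, together
#' with the mapping from each tool's categorical labels to
#' significant/not-significant.
#'
#' @param sift_max SIFT cut-off (scores at or below are significant when
#'   \code{sift_inclusive}; strictly below otherwise).
#' @param sift_inclusive treat a SIFT score exactly at the cut-off as
#'   significant (default TRUE).
#' @param pp2_min PolyPhen-2 cut-off, exclusive.
#' @param condel_min Condel cut-off, exclusive.
#' @param condel_exact_one require a Condel score of exactly 1.0 instead of
#'   the \code{> condel_min} rule (off by default; a point requirement on a
#'   continuous score is unusable in practice).
#' @param provean_max PROVEAN cut-off, inclusive (published convention).
#' @param panther_min PANTHER preservation-time cut-off in millions of
#'   years, exclusive.
#' @return a \code{vv_thresholds} configuration list.
#' @examples
#' cfg <- defaultThresholds()
#' classifyCall("sift", score = 0.01, cfg = cfg)
#' @export
thresholdConfig <- function(sift_max = 0.05, sift_inclusive = TRUE,
                            pp2_min = 0.9, condel_min = 0.5,
                            condel_exact_one = FALSE,
                            provean_max = -2.5, panther_min = 450) {
  cfg <- list(sift_max = sift_max, sift_inclusive = isTRUE(sift_inclusive),
              pp2_min = pp2_min, condel_min = condel_min,
              condel_exact_one = isTRUE(condel_exact_one),
              provean_max = provean_max, panther_min = panther_min,
              label_maps = .LABEL_MAPS)
  class(cfg) <- "vv_thresholds"
  cfg
}

#' @rdname thresholdConfig
#' @export
defaultThresholds <- function() thresholdConfig()

.score_significant <- function(tool, score, cfg) {
  switch(tool,
    sift = if (cfg$sift_inclusive) score <= cfg$sift_max else
      score < cfg$sift_max,
    pp2 = score > cfg$pp2_min,
    condel = if (cfg$condel_exact_one) score == 1.0 else
      score > cfg$condel_min,
    provean = score <= cfg$provean_max,
    panther = score > cfg$panther_min,
    .stopf("unknown tool '%s'", tool))
}

#' Resolve one predictor's raw output into a call
#'
#' A numeric score, when present, takes precedence over a categorical label;
#' with neither present the call is \code{missing}. Labels suffixed
#' \code{_low_con} carry the base label's call; the low-confidence flag is
#' preserved.
#'
#' @param tool one of \code{"sift"}, \code{"pp2"}, \code{"condel"},
#'   \code{"provean"}, \code{"panther"}.
#' @param score,label the raw output(s); vectors are accepted and recycled
#'   to common length.
#' @param cfg a [thresholdConfig()].
#' @return a list with \code{call} (character, values
#'   significant/not_significant/missing) and \code{lowConfidence}
#'   (logical).
#' @export
classifyCall <- function(tool, score = NA_real_, label = NA_character_,
                         cfg = defaultThresholds()) {
  classifyTool(tool, score, label, cfg)
}

# Vectorized worker behind classifyCall / ProfileSet call resolution.
classifyTool <- function(tool, score, label, cfg = defaultThresholds()) {
  tool <- match.arg(tool, TOOLS)
  n <- max(length(score), length(label))
  score <- rep_len(as.numeric(score %||% NA_real_), n)
  label <- rep_len(as.character(label %||% NA_character_), n)
  label[!is.na(label) & !nzchar(trimws(label))] <- NA_character_
  lab_key <- tolower(trimws(label))
  low_conf <- !is.na(lab_key) & grepl("_low_con$", lab_key)
  map <- cfg$label_maps[[tool]]
  known <- is.na(lab_key) | lab_key %in% names(map)
  if (!all(known))
    .stopf("unknown %s label(s): %s (known: %s)", tool,
           paste(unique(label[!known]), collapse = ", "),
           paste(names(map), collapse = ", "))
  call <- rep("missing", n)
  has_lab <- !is.na(lab_key)
  call[has_lab] <- unname(map[lab_key[has_lab]])
  has_score <- !is.na(score)
  sig <- .score_significant(tool, score[has_score], cfg)
  call[has_score] <- ifelse(sig, "significant", "not_significant")
  list(call = call, lowConfidence = low_conf)
}
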