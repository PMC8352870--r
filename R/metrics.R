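# benchmark_harness module: sensitivity / specificity / accuracy from
# confusion counts, and model-panel evaluation on labeled records.

#' Confusion counts
#'
#' @param tp,fn,tn,fp non-negative integer counts (true positive, false
#'   negative, true negative, false positive).
#' @return a \code{vv_confusion} list.
#' @export
confusionCounts <- function(tp, fn, tn, fp) {
  for (v in list(tp, fn, tn, fp))
    if (!.is_count(v)) .stopf("confusion counts must be non-negative integers")
  structure(list(tp = as.integer(tp), fn = as.integer(fn),
                 tn = as.integer(tn), fp = as.integer(fp)),
            class = "vv_confusion")
}

.counts <- function(c) {
  if (inherits(c, "vv_confusion")) return(c)
  if (is.list(c) && all(c("tp", "fn", "tn", "fp") %in% names(c)))
    return(confusionCounts(c$tp, c$fn, c$tn, c$fp))
  .stopf("expected confusion counts (tp, fn, tn, fp)")
}

#' Sensitivity, specificity and accuracy as percentages
#'
#' Se = TP/(TP+FN) x 100, Sp = TN/(TN+FP) x 100,
#' Ac = (TP+TN)/(TP+TN+FP+FN) x 100. The numerator is scaled by 100 before
#' the division so integer counts give exact percentages. An empty
#' denominator yields \code{NA} (an explicit undefined marker, never 0 or
#' 100).
#'
#' @param c confusion counts from [confusionCounts()] (or a compatible
#'   list / one-row data.frame).
#' @return percentage in [0, 100], or \code{NA_real_} when undefined.
#' @examples
#' sensitivity(confusionCounts(tp = 42, fn = 8, tn = 47, fp = 3))  # 84
#' @export
sensitivity <- function(c) {
  c <- .counts(c)
  if (c$tp + c$fn == 0) return(NA_real_)
  (c$tp * 100) / (c$tp + c$fn)
}

#' @rdname sensitivity
#' @export
specificity <- function(c) {
  c <- .counts(c)
  if (c$tn + c$fp == 0) return(NA_real_)
  (c$tn * 100) / (c$tn + c$fp)
}

#' @rdname sensitivity
#' @export
accuracy <- function(c) {
  c <- .counts(c)
  total <- c$tp + c$fn + c$tn + c$fp
  if (total == 0) return(NA_real_)
  ((c$tp + c$tn) * 100) / total
}

#' Attach the three metrics to a confusion-count table
#'
#' @param counts data.frame with columns \code{tp}, \code{fn}, \code{tn},
#'   \code{fp} (e.g. from [rankModels()]).
#' @return the input with \code{sensitivity}, \code{specificity},
#'   \code{accuracy} columns appended (percentages, unrounded).
#' @export
metricsReport <- function(counts) {
  stopifnot(all(c("tp", "fn", "tn", "fp") %in% names(counts)))
  counts$sensitivity <- vapply(seq_len(nrow(counts)), function(i)
    sensitivity(counts[i, ]), 0)
  counts$specificity <- vapply(seq_len(nrow(counts)), function(i)
    specificity(counts[i, ]), 0)
  counts$accuracy <- vapply(seq_len(nrow(counts)), function(i)
    accuracy(counts[i, ]), 0)
  counts
}

#' Evaluate a model panel on labeled benchmark records
#'
#' Runs every model over the profiles, tallies confusion counts against the
#' truth labels and appends Se/Sp/Ac.
#'
#' @param x a [ProfileSet].
#' @param truth parallel character vector of \code{"pathogenic"} /
#'   \code{"benign"} labels.
#' @param models list of [consensusModel()]s.
#' @return data.frame: one row per model with counts and the three metrics.
#' @export
evaluateModels <- function(x, truth, models = consensusModels()) {
  if (anyDuplicated(x$rsid))
    .stopf("duplicate variant id(s) in benchmark records: %s",
           paste(unique(x$rsid[duplicated(x$rsid)]), collapse = ", "))
  metricsReport(rankModels(x, truth, models))
}
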