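# synthetic_fixtures module, part 2: generators with controlled statistical
# structure, for testing every stage without external downloads.

# Damaging-side score regions per tool (draws are uniform within a region).
.TOOL_REGIONS <- list(
  sift = list(damaging = c(0, 0.05), benign = c(0.05, 1)),
  pp2 = list(damaging = c(0.9, 1), benign = c(0, 0.9)),
  condel = list(damaging = c(0.5, 1), benign = c(0, 0.5)),
  provean = list(damaging = c(-10, -2.5), benign = c(-2.5, 5)),
  panther = list(damaging = c(450, 2000), benign = c(0, 450)))

#' Specification for a synthetic benchmark set
#'
#' Emulates a clinically labeled 50/50 standard set: per-tool scores are
#' drawn from class-conditional distributions whose overlap is controlled
#' by \code{toolAccuracy} — the probability that a tool's score lands on
#' its truth side of the threshold. The default 0.85 puts the marginal
#' per-tool accuracy in the regime where the k-of-5 models visibly trade
#' sensitivity for specificity; \code{toolAccuracy = 1} gives fully
#' separated classes.
#'
#' @param nPathogenic,nBenign class sizes (default 50/50).
#' @param toolAccuracy scalar or per-tool named vector in [0.5, 1].
#' @param missingness per-tool probability that the score is absent
#'   (scalar or named vector in [0, 1]).
#' @param evidenceAccuracy probability that the conservation and stability
#'   evidence agree with the class.
#' @param seed mandatory integer seed; one master seed fans out to
#'   per-component substreams so adding a component does not perturb the
#'   others' draws.
#' @return a \code{vv_synthetic} specification.
#' @export
syntheticSpec <- function(nPathogenic = 50, nBenign = 50,
                          toolAccuracy = 0.85, missingness = 0,
                          evidenceAccuracy = 0.9, seed) {
  stopifnot(.is_count(nPathogenic), .is_count(nBenign), .is_count(seed))
  expand <- function(x, what, lo, hi) {
    if (is.null(names(x))) x <- stats::setNames(rep_len(x, 5L), TOOLS)
    if (!all(TOOLS %in% names(x)) || any(x < lo | x > hi))
      .stopf("%s must cover all five tools with values in [%g, %g]",
             what, lo, hi)
    x[TOOLS]
  }
  structure(list(nPathogenic = nPathogenic, nBenign = nBenign,
                 toolAccuracy = expand(toolAccuracy, "toolAccuracy", 0.5, 1),
                 missingness = expand(missingness, "missingness", 0, 1),
                 evidenceAccuracy = evidenceAccuracy, seed = seed),
            class = "vv_synthetic")
}

#' Generate a labeled synthetic benchmark set
#'
#' @param spec a [syntheticSpec()].
#' @param thresholds a [thresholdConfig()] used to resolve the calls.
#' @return list with \code{profiles} (a [ProfileSet]) and \code{truth}
#'   (parallel character vector of \code{pathogenic}/\code{benign}).
#'   Reproducible given the spec's seed.
#' @export
simulateBenchmark <- function(spec, thresholds = defaultThresholds()) {
  stopifnot(inherits(spec, "vv_synthetic"))
  n <- spec$nPathogenic + spec$nBenign
  truth <- rep(c("pathogenic", "benign"), c(spec$nPathogenic, spec$nBenign))
  df <- data.frame(rsid = sprintf("sim%04d", seq_len(n)),
                   gene = sprintf("GENE%d", seq_len(n)),
                   aa_change = "A2V", stringsAsFactors = FALSE)
  runif_in <- function(k, region) stats::runif(k, region[1], region[2])
  for (tool in TOOLS) {
    set.seed(.substream(spec$seed, tool))
    on_damaging_side <- ifelse(truth == "pathogenic",
                               stats::runif(n) < spec$toolAccuracy[[tool]],
                               stats::runif(n) >= spec$toolAccuracy[[tool]])
    reg <- .TOOL_REGIONS[[tool]]
    score <- ifelse(on_damaging_side, runif_in(n, reg$damaging),
                    runif_in(n, reg$benign))
    score[stats::runif(n) < spec$missingness[[tool]]] <- NA_real_
    df[[paste0(tool, "_score")]] <- score
  }
  set.seed(.substream(spec$seed, "conservation"))
  agree <- stats::runif(n) < spec$evidenceAccuracy
  conserved <- (truth == "pathogenic") == agree
  df$consurf_score <- ifelse(conserved, sample(7:9, n, TRUE),
                             sample(1:6, n, TRUE))
  set.seed(.substream(spec$seed, "stability"))
  agree <- stats::runif(n) < spec$evidenceAccuracy
  destab <- (truth == "pathogenic") == agree
  df$imutant_direction <- ifelse(destab, "decrease", "increase")
  df$imutant_ddg <- round(ifelse(destab, stats::runif(n, -2.5, -0.6),
                                 stats::runif(n, -0.4, 1.5)), 2)
  df$imutant_ri <- sample(0:10, n, TRUE)
  set.seed(.substream(spec$seed, "structure"))
  df$tm_score <- round(stats::runif(n, 0.55, 0.99), 3)
  df$rmsd <- round(stats::runif(n, 0.5, 6), 2)
  list(profiles = ProfileSet(df, thresholds), truth = truth)
}

#' Write a synthetic cohort VCF with a matching truth table
#'
#' Genotypes are drawn per site from Hardy-Weinberg proportions at the
#' requested alternate-allele frequency; site depth and quality are drawn
#' so that a configurable fraction of sites fail the default quality
#' filter (depth < 5 or quality < 30). The truth table records which sites
#' a quality-filtered matcher should recover.
#'
#' @param sites data.frame with \code{chrom}, \code{pos}, \code{id},
#'   \code{ref}, \code{alt}, \code{af} (alternate-allele frequency in
#'   [0,1]).
#' @param nSamples number of diploid samples.
#' @param failFraction fraction of sites forced to fail the quality filter.
#' @param seed integer seed.
#' @param path output VCF path (plain text, v4.2).
#' @return list with \code{path} and \code{truth}: the sites table plus
#'   \code{depth}, \code{qual}, \code{passesFilter}, \code{altObserved},
#'   \code{empiricalAF} and \code{shouldMatch}.
#' @export
simulateVcf <- function(sites, nSamples = 20, failFraction = 0.2, seed,
                        path = tempfile(fileext = ".vcf")) {
  stopifnot(all(c("chrom", "pos", "id", "ref", "alt", "af") %in%
                  names(sites)),
            all(sites$af >= 0 & sites$af <= 1), .is_count(seed),
            failFraction >= 0, failFraction <= 1)
  set.seed(.substream(seed, "vcf"))
  n <- nrow(sites)
  fail <- stats::runif(n) < failFraction
  # a failing site is short on depth or on quality with equal odds
  fail_mode <- sample(c("depth", "qual"), n, TRUE)
  depth <- ifelse(fail & fail_mode == "depth", sample(1:4, n, TRUE),
                  5L + stats::rpois(n, 30))
  qual <- ifelse(fail & fail_mode == "qual", stats::runif(n, 5, 29.9),
                 stats::runif(n, 30, 90))
  gts <- matrix("", n, nSamples)
  emp_af <- numeric(n)
  for (i in seq_len(n)) {
    a1 <- stats::rbinom(nSamples, 1L, sites$af[i])
    a2 <- stats::rbinom(nSamples, 1L, sites$af[i])
    gts[i, ] <- paste(pmin(a1, a2), pmax(a1, a2), sep = "/")
    emp_af[i] <- (sum(a1) + sum(a2)) / (2 * nSamples)
  }
  header <- c("##fileformat=VCFv4.2",
              "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", sprintf("S%03d", seq_len(nSamples))),
                    collapse = "\t"))
  body <- vapply(seq_len(n), function(i)
    paste(c(sites$chrom[i], sites$pos[i], sites$id[i], sites$ref[i],
            sites$alt[i], sprintf("%.1f", qual[i]), "PASS",
            sprintf("DP=%d", depth[i]), "GT", gts[i, ]), collapse = "\t"),
    "")
  writeLines(c(header, body), path)
  truth <- sites
  truth$depth <- depth
  truth$qual <- qual
  truth$passesFilter <- depth >= 5 & qual >= 30
  truth$altObserved <- emp_af > 0
  truth$empiricalAF <- emp_af
  truth$shouldMatch <- truth$passesFilter & truth$altObserved
  list(path = path, truth = truth)
}
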