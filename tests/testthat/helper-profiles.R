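# Shared fixture builders. Scores that land each tool cleanly on one side
# of its published threshold, used to construct profiles with prescribed
# call states.
.SIG_SCORES <- c(sift = 0.01, pp2 = 0.95, condel = 0.8, provean = -5,
                 panther = 600)
.NOT_SCORES <- c(sift = 0.5, pp2 = 0.5, condel = 0.2, provean = 0,
                 panther = 100)

# states: character matrix (n x 5, columns sift/pp2/condel/provean/panther)
# with values significant / not_significant / missing.
profileFromStates <- function(states, ...) {
  states <- matrix(states, ncol = 5)
  n <- nrow(states)
  df <- data.frame(rsid = sprintf("v%03d", seq_len(n)),
                   gene = "G", aa_change = "A2V",
                   stringsAsFactors = FALSE)
  tools <- c("sift", "pp2", "condel", "provean", "panther")
  for (j in seq_along(tools)) {
    score <- ifelse(states[, j] == "significant", .SIG_SCORES[[tools[j]]],
                    ifelse(states[, j] == "not_significant",
                           .NOT_SCORES[[tools[j]]], NA_real_))
    df[[paste0(tools[j], "_score")]] <- score
  }
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  ProfileSet(df)
}

# All 3^5 = 243 per-tool call-state combinations, one row each.
allCallStates <- function() {
  lv <- c("significant", "not_significant", "missing")
  as.matrix(expand.grid(sift = lv, pp2 = lv, condel = lv, provean = lv,
                        panther = lv, stringsAsFactors = FALSE))
}

# Independent brute-force vote counter: literal counting over a state
# vector, kept free of the package's vote machinery.
bruteForceDecision <- function(states, min_votes, policy) {
  s <- sum(states == "significant")
  m <- sum(states == "missing")
  ok <- switch(policy,
               strict = s >= min_votes,
               permissive = (s + m) >= min_votes,
               fraction = {
                 avail <- 5 - m
                 if (avail == 0) FALSE else (s / avail) >= (min_votes / 5)
               })
  if (ok) "deleterious" else "benign"
}
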