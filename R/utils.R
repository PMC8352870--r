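`%||%` <- function(a, b) if (is.null(a)) b else a

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 0 && x == floor(x)

# One-letter amino-acid alphabet (20 canonical residues)
AA_CODES <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
              "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Parse compact amino-acid change strings
#'
#' Normalizes strings such as \code{"R402Q"} into reference residue,
#' position and alternate residue. Both residues must be canonical
#' one-letter codes and the position a positive integer.
#'
#' @param x character vector of compact changes (e.g. \code{"R402Q"}).
#' @param strict error on malformed input (default) rather than returning
#'   \code{NA} rows.
#' @return a \code{data.frame} with columns \code{ref}, \code{pos},
#'   \code{alt}, one row per input.
#' @examples
#' parseAAChange(c("R402Q", "T260N"))
#' @export
parseAAChange <- function(x, strict = TRUE) {
  x <- as.character(x)
  m <- regmatches(x, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", x))
  bad <- vapply(m, length, 1L) != 4L
  ref <- pos <- alt <- rep(NA_character_, length(x))
  ok <- which(!bad)
  ref[ok] <- toupper(vapply(m[ok], `[`, "", 2L))
  pos[ok] <- vapply(m[ok], `[`, "", 3L)
  alt[ok] <- toupper(vapply(m[ok], `[`, "", 4L))
  bad <- bad | (!is.na(ref) & !(ref %in% AA_CODES)) |
    (!is.na(alt) & !(alt %in% AA_CODES)) |
    (!is.na(pos) & as.integer(pos) < 1L)
  if (strict && any(bad & !is.na(x)))
    .stopf("malformed amino-acid change: %s",
           paste(unique(x[bad & !is.na(x)]), collapse = ", "))
  ref[bad] <- alt[bad] <- pos[bad] <- NA_character_
  data.frame(ref = ref, pos = as.integer(pos), alt = alt,
             stringsAsFactors = FALSE)
}

# Derive a reproducible sub-seed for a named component from one master seed,
# so each stochastic component consumes an independent stream.
.substream <- function(seed, component) {
  stopifnot(.is_count(seed))
  h <- sum(utf8ToInt(component) * seq_along(utf8ToInt(component)))
  as.integer((as.numeric(seed) * 2654435 + h * 97) %% 2147483647)
}
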