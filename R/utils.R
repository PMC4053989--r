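# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

# IUPAC degeneracy table; lowercase codes are accepted and mean the same
# base set (an "n" in a consensus matches any base but never an N in the
# sequence -- N bases never match any motif position).
IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of nucleotide strings
#'
#' Vectorised over its input; `N` is preserved.
#'
#' @param x character vector of sequences over `A`,`C`,`G`,`T`,`N`.
#' @return character vector of reverse-complemented sequences.
#' @export
#' @examples
#' revcomp(c("ACGTN", "AA"))
revcomp <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# Encode a sequence string as integers A=1,C=2,G=3,T=4, N/other = NA.
seq_to_int <- function(s) {
  code <- utf8ToInt(s)
  map <- rep(NA_integer_, 128L)
  map[utf8ToInt("A")] <- 1L
  map[utf8ToInt("C")] <- 2L
  map[utf8ToInt("G")] <- 3L
  map[utf8ToInt("T")] <- 4L
  map[code]
}

int_to_seq <- function(v) {
  chars <- c("A", "C", "G", "T")[v]
  chars[is.na(chars)] <- "N"
  paste(chars, collapse = "")
}

# All overlapping words of width w of a sequence string, as a character
# vector of length nchar(s) - w + 1 (empty when the sequence is shorter).
seq_words <- function(s, w) {
  n <- nchar(s)
  if (n < w) return(character(0))
  substring(s, seq_len(n - w + 1L), seq_len(n - w + 1L) + w - 1L)
}

# Vectorised reverse complement for equal-width word vectors: built
# column-wise so it stays fast on large word sets.
revcomp_words <- function(words, w) {
  if (length(words) == 0) return(character(0))
  cols <- lapply(seq_len(w), function(j) {
    chartr("ACGTN", "TGCAN", substring(words, j, j))
  })
  out <- cols[[w]]
  if (w > 1) for (j in (w - 1):1) out <- paste0(out, cols[[j]])
  out
}

# Canonical key of a word: the lexicographic minimum of the word and its
# reverse complement (collapses the two strands).
canonical_words <- function(words, w) {
  rc <- revcomp_words(words, w)
  pmin(words, rc)
}

# Per-position Hamming distance between one word and a vector of words of
# equal width (NA characters count as mismatches).
hamming_to <- function(word, words, w) {
  if (length(words) == 0) return(integer(0))
  d <- integer(length(words))
  for (j in seq_len(w)) {
    d <- d + (substring(words, j, j) != substr(word, j, j))
  }
  d
}

# Stage logging: informative counts/parameters go to stderr, never stdout.
log_stage <- function(...) {
  message("[crmscan] ", sprintf(...))
}

validate_alphabet <- function(seqs, where = "sequence") {
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop(sprintf("%s contains characters outside {A,C,G,T,N} (record %s)",
                 where, paste(names(seqs)[bad] %||% which(bad), collapse = ", ")),
         call. = FALSE)
  }
  invisible(seqs)
}
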