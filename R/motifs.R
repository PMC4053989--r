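# Motif representation: IUPAC consensus strings, position weight
# matrices, log-odds scoring, and the minimal MEME-like text dialect.

#' Construct a motif definition
#'
#' At least one of `consensus` and `pwm` must be given. When only a
#' consensus is given the PWM is synthesised with [iupac_to_pwm()] and,
#' unless a threshold is supplied, `score_threshold` is set to the
#' minimum log-odds score over all words matching the consensus -- at
#' that default, PWM scanning is exactly equivalent to IUPAC matching.
#'
#' @param name motif name.
#' @param consensus optional IUPAC consensus string.
#' @param pwm optional L x 4 probability matrix (columns A,C,G,T).
#' @param background background base probabilities (A,C,G,T), summing
#'   to 1; default uniform.
#' @param score_threshold scan threshold in bits; `NULL` picks the
#'   consensus-minimum rule (consensus motifs) or half the maximum
#'   achievable score (PWM-only motifs).
#' @param soft probability mass given to disallowed bases when expanding
#'   a consensus (see [iupac_to_pwm()]).
#' @return an object of class `motif`.
#' @export
#' @examples
#' m <- motif("svbF7", consensus = "ACHGTTAK")
#' m$score_threshold
motif <- function(name, consensus = NULL, pwm = NULL,
                  background = rep(0.25, 4), score_threshold = NULL,
                  soft = 0.04) {
  if (is.null(consensus) && is.null(pwm)) {
    stop("motif needs a consensus and/or a pwm", call. = FALSE)
  }
  stopifnot(length(background) == 4, abs(sum(background) - 1) < 1e-6,
            all(background > 0))
  if (is.null(pwm)) pwm <- iupac_to_pwm(consensus, soft = soft)
  pwm <- as.matrix(pwm)
  colnames(pwm) <- DNA_BASES
  L <- nrow(pwm)
  if (L < 4) stop("motif length must be >= 4", call. = FALSE)
  if (any(abs(rowSums(pwm) - 1) > 1e-9)) {
    stop("PWM rows must sum to 1 within 1e-9", call. = FALSE)
  }
  m <- structure(list(name = name, consensus = consensus, pwm = pwm,
                      background = background,
                      score_threshold = score_threshold),
                 class = "motif")
  if (is.null(score_threshold)) {
    m$score_threshold <- if (!is.null(consensus)) {
      min(consensus_word_scores(m))
    } else {
      0.5 * max_score(m)
    }
  }
  m
}

#' @export
print.motif <- function(x, ...) {
  cat(sprintf("motif %s: length %d%s, threshold %.3f bits\n",
              x$name, nrow(x$pwm),
              if (!is.null(x$consensus)) paste0(" (", x$consensus, ")") else "",
              x$score_threshold))
  invisible(x)
}

motif_length <- function(m) nrow(m$pwm)

max_score <- function(m) {
  sum(log2(apply(m$pwm, 1, max) / m$background[apply(m$pwm, 1, which.max)]))
}

# All literal words matching an IUPAC consensus (cartesian expansion).
consensus_words <- function(consensus) {
  letters <- strsplit(toupper(consensus), "", fixed = TRUE)[[1]]
  sets <- lapply(letters, function(ch) {
    s <- IUPAC_CODES[[ch]]
    if (is.null(s)) stop("invalid IUPAC character: ", ch, call. = FALSE)
    s
  })
  grid <- do.call(expand.grid, c(rev(sets), stringsAsFactors = FALSE))
  apply(grid[, rev(seq_along(sets)), drop = FALSE], 1, paste, collapse = "")
}

consensus_word_scores <- function(m) {
  vapply(consensus_words(m$consensus), function(w) log_odds(m, w), numeric(1))
}

#' Expand an IUPAC consensus into a position weight matrix
#'
#' At each position the bases allowed by the IUPAC code share `1 - soft`
#' equally and the disallowed bases share `soft` equally; a code allowing
#' all four bases yields the uniform column.
#'
#' @param consensus IUPAC string over `A,C,G,T,R,Y,S,W,K,M,B,D,H,V,N`
#'   (case-insensitive).
#' @param soft probability mass for disallowed bases (default 0.04).
#' @return an L x 4 probability matrix with columns A,C,G,T.
#' @export
#' @examples
#' iupac_to_pwm("H", soft = 0)  # A/C/T equally
iupac_to_pwm <- function(consensus, soft = 0.04) {
  letters <- strsplit(toupper(consensus), "", fixed = TRUE)[[1]]
  pwm <- t(vapply(letters, function(ch) {
    allowed <- IUPAC_CODES[[ch]]
    if (is.null(allowed)) stop("invalid IUPAC character: ", ch, call. = FALSE)
    k <- length(allowed)
    col <- if (k == 4) rep(0.25, 4) else {
      v <- rep(soft / (4 - k), 4)
      v[match(allowed, DNA_BASES)] <- (1 - soft) / k
      v
    }
    col
  }, numeric(4)))
  dimnames(pwm) <- list(NULL, DNA_BASES)
  pwm
}

#' Log-odds score of a word under a motif
#'
#' Sum over positions of `log2(p_base / bg_base)`. Any `N` in the word
#' yields `-Inf` (an N never matches a motif position).
#'
#' @param m a [motif()].
#' @param word string of the motif's length over `A`,`C`,`G`,`T`,`N`.
#' @return score in bits.
#' @export
log_odds <- function(m, word) {
  L <- motif_length(m)
  if (nchar(word) != L) stop("word length != motif length", call. = FALSE)
  idx <- seq_to_int(word)
  if (anyNA(idx)) return(-Inf)
  sum(log2(m$pwm[cbind(seq_len(L), idx)] / m$background[idx]))
}

# Log-odds lookup matrix (L x 4) used by the scanner.
lod_matrix <- function(m) {
  log2(sweep(m$pwm, 2, m$background, "/"))
}

#' Reverse complement of a motif
#'
#' @param m a [motif()].
#' @return the motif scored on the opposite strand (PWM reversed and
#'   complemented, consensus reverse-complemented when representable).
#' @export
reverse_complement_motif <- function(m) {
  pwm <- m$pwm[rev(seq_len(nrow(m$pwm))), c(4, 3, 2, 1), drop = FALSE]
  colnames(pwm) <- DNA_BASES
  cons <- if (!is.null(m$consensus)) {
    rc_map <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
                D = "H", H = "D", N = "N")
    paste(rev(rc_map[strsplit(toupper(m$consensus), "")[[1]]]), collapse = "")
  } else NULL
  motif(m$name, consensus = cons, pwm = pwm,
        background = m$background[c(4, 3, 2, 1)],
        score_threshold = m$score_threshold)
}

#' The trichome-enhancer motif set
#'
#' The four cis-regulatory motifs of the Svb/trichome system as IUPAC
#' consensus motifs: the in-vitro Ovo/Svb binding-site core `OvoQ6`
#' (CNGTTA), its flank-refined form `svbF7` (ACHGTTAK), and the two
#' co-occurring elements `blue` (WAGAAAGCSR) and `yellow` (TTATGCAA).
#'
#' @param background background base probabilities for scoring.
#' @return named list of [motif()] objects.
#' @export
trichome_motifs <- function(background = rep(0.25, 4)) {
  list(
    OvoQ6 = motif("OvoQ6", consensus = "CNGTTA", background = background),
    svbF7 = motif("svbF7", consensus = "ACHGTTAK", background = background),
    blue = motif("blue", consensus = "WAGAAAGCSR", background = background),
    yellow = motif("yellow", consensus = "TTATGCAA", background = background)
  )
}

#' Read motifs from the minimal MEME-like text dialect
#'
#' Each block starts with `MOTIF <name>` and may contain a
#' `CONSENSUS <iupac>` line, a `BACKGROUND <4 probs>` line, a
#' `THRESHOLD <bits>` line and a `MATRIX <L>` line followed by L rows of
#' 4 probabilities (A C G T). Rows are renormalised to sum to 1;
#' consensus-only blocks synthesise their PWM via [iupac_to_pwm()].
#'
#' @param path path to the motif text file.
#' @return list of [motif()] objects.
#' @export
read_motifs <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  starts <- which(startsWith(lines, "MOTIF"))
  if (length(starts) == 0) stop("no MOTIF blocks in ", path, call. = FALSE)
  ends <- c(starts[-1] - 1L, length(lines))
  lapply(seq_along(starts), function(i) {
    block <- lines[starts[i]:ends[i]]
    name <- sub("^MOTIF\\s+", "", block[1])
    consensus <- NULL
    background <- rep(0.25, 4)
    threshold <- NULL
    pwm <- NULL
    j <- 2L
    while (j <= length(block)) {
      ln <- block[j]
      if (startsWith(ln, "CONSENSUS")) {
        consensus <- sub("^CONSENSUS\\s+", "", ln)
      } else if (startsWith(ln, "BACKGROUND")) {
        background <- as.numeric(strsplit(sub("^BACKGROUND\\s+", "", ln),
                                          "\\s+")[[1]])
      } else if (startsWith(ln, "THRESHOLD")) {
        threshold <- as.numeric(sub("^THRESHOLD\\s+", "", ln))
      } else if (startsWith(ln, "MATRIX")) {
        L <- as.integer(sub("^MATRIX\\s+", "", ln))
        rows <- block[(j + 1L):(j + L)]
        pwm <- t(vapply(rows, function(r) {
          as.numeric(strsplit(r, "\\s+")[[1]])
        }, numeric(4)))
        rownames(pwm) <- NULL
        j <- j + L
      } else {
        stop(sprintf("unrecognised line in motif '%s': %s", name, ln),
             call. = FALSE)
      }
      j <- j + 1L
    }
    if (!is.null(pwm)) {
      if (any(pwm < 0) || any(pwm > 1)) {
        stop(sprintf("motif '%s': probabilities must lie in [0,1]", name),
             call. = FALSE)
      }
      rs <- rowSums(pwm)
      if (any(rs == 0)) {
        stop(sprintf("motif '%s': PWM row sums to 0", name), call. = FALSE)
      }
      pwm <- pwm / rs
    }
    motif(name, consensus = consensus, pwm = pwm, background = background,
          score_threshold = threshold)
  })
}

#' Write motifs in the minimal MEME-like text dialect
#'
#' Inverse of [read_motifs()].
#'
#' @param motifs list of [motif()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_motifs <- function(motifs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in motifs) {
    writeLines(paste("MOTIF", m$name), con)
    if (!is.null(m$consensus)) writeLines(paste("CONSENSUS", m$consensus), con)
    writeLines(paste("BACKGROUND",
                     paste(formatC(m$background, format = "g", digits = 10),
                           collapse = " ")), con)
    writeLines(paste("THRESHOLD",
                     formatC(m$score_threshold, format = "g", digits = 10)), con)
    writeLines(paste("MATRIX", nrow(m$pwm)), con)
    for (r in seq_len(nrow(m$pwm))) {
      writeLines(paste(formatC(m$pwm[r, ], format = "g", digits = 10),
                       collapse = " "), con)
    }
    writeLines("", con)
  }
  invisible(path)
}
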