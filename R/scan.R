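# Bidirectional PWM scanning, alignment-free cross-species conservation
# support, and the 1-kb clustering rule.

#' Scan a sequence with a motif
#'
#' Reports every offset/strand whose log-odds score reaches the
#' threshold. Minus-strand hits score the reverse complement of the
#' window and are reported at the forward offset of the window.
#'
#' @param sequence nucleotide string (`A`,`C`,`G`,`T`,`N`).
#' @param m a [motif()].
#' @param both_strands scan the minus strand too (default `TRUE`).
#' @param threshold score threshold in bits; defaults to the motif's
#'   `score_threshold`.
#' @param region_id label carried into the result.
#' @return `data.frame` with columns `region_id`, `offset` (0-based),
#'   `strand`, `score`, `word` (the forward-strand window), sorted by
#'   offset then strand. Sequences shorter than the motif give zero rows.
#' @export
#' @examples
#' m <- motif("svbF7", consensus = "ACHGTTAK")
#' scan_motif("TTTACAGTTAGTTT", m)
scan_motif <- function(sequence, m, both_strands = TRUE, threshold = NULL,
                       region_id = NA_character_) {
  threshold <- threshold %||% m$score_threshold
  L <- motif_length(m)
  n <- nchar(sequence)
  empty <- data.frame(region_id = character(0), offset = integer(0),
                      strand = character(0), score = numeric(0),
                      word = character(0), stringsAsFactors = FALSE)
  if (n < L) return(empty)
  sc <- score_seq(sequence, m, both_strands = both_strands)
  # tolerance absorbs the accumulation-order difference between the
  # vectorised scorer and per-word log_odds sums (1 ulp at ~13 bits)
  threshold <- threshold - 1e-9
  keep_f <- which(sc$fwd >= threshold)
  res <- list(data.frame(offset = keep_f - 1L,
                         strand = rep("+", length(keep_f)),
                         score = sc$fwd[keep_f]))
  if (both_strands) {
    keep_r <- which(sc$rev >= threshold)
    res <- c(res, list(data.frame(offset = keep_r - 1L,
                                  strand = rep("-", length(keep_r)),
                                  score = sc$rev[keep_r])))
  }
  hits <- do.call(rbind, res)
  if (nrow(hits) == 0) return(empty)
  hits <- hits[order(hits$offset, hits$strand), , drop = FALSE]
  data.frame(region_id = region_id, offset = hits$offset,
             strand = hits$strand, score = hits$score,
             word = substring(sequence, hits$offset + 1L, hits$offset + L),
             stringsAsFactors = FALSE, row.names = NULL)
}

# Precomputed log-odds lookup for a motif: forward and
# reverse-complement matrices with a 5th (-Inf) column for N, so an N
# anywhere in a window sinks the score to -Inf.
motif_scorer <- function(m) {
  lod <- lod_matrix(m)
  L <- nrow(lod)
  lod_rc <- lod[rev(seq_len(L)), c(4, 3, 2, 1), drop = FALSE]
  list(L = L,
       fwd = cbind(lod, rep(-Inf, L)),
       rev = cbind(lod_rc, rep(-Inf, L)))
}

# Fast scoring core: per-offset log-odds score vectors on both strands.
# Scoring the reverse complement of each window equals scoring the
# window with the reverse-complemented log-odds matrix.
score_seq <- function(sequence, m, both_strands = TRUE, scorer = NULL) {
  scorer <- scorer %||% motif_scorer(m)
  L <- scorer$L
  n <- nchar(sequence)
  if (n < L) return(list(fwd = numeric(0), rev = numeric(0)))
  si <- seq_to_int(sequence)
  si[is.na(si)] <- 5L
  n_off <- n - L + 1L
  base <- seq_len(n_off)
  score_with <- function(lod5) {
    s <- numeric(n_off)
    for (j in seq_len(L)) s <- s + lod5[j, ][si[base + j - 1L]]
    s
  }
  out <- list(fwd = score_with(scorer$fwd))
  if (both_strands) out$rev <- score_with(scorer$rev)
  out
}

#' Assess cross-species conservation of motif hits
#'
#' Motif search is performed in each species' sequence independently at
#' the same threshold (alignment-free phylogenetic footprinting). A
#' species supports a reference hit if it has a hit of the same motif,
#' on either strand, whose window centre -- rescaled by the
#' species/reference sequence-length ratio to absorb indel drift --
#' falls within `delta` bp of the reference hit's centre. Hits are kept
#' when `support >= min_species` (the reference species always counts).
#'
#' @param region an [ortho_region()].
#' @param m a [motif()].
#' @param delta offset tolerance in bp after rescaling (default 20).
#' @param min_species minimum number of supporting species, reference
#'   included; default `ceiling(0.6 * n_species)`. Lowering it relaxes
#'   the conservation requirement.
#' @param threshold scan threshold in bits (default the motif's).
#' @return `data.frame` of reference hits as from [scan_motif()] with
#'   extra columns `support` (integer) and `supporting_species`
#'   (comma-separated), filtered to `support >= min_species`.
#' @export
assess_conservation <- function(region, m, delta = 20, min_species = NULL,
                                threshold = NULL) {
  stopifnot(delta >= 0)
  species <- names(region$sequences)
  n_species <- length(species)
  min_species <- min_species %||% ceiling(0.6 * n_species)
  stopifnot(min_species >= 1)
  refname <- region$reference_species
  ref_hits <- scan_motif(ref_seq(region), m, threshold = threshold,
                         region_id = region$region_id)
  if (nrow(ref_hits) == 0) {
    ref_hits$support <- integer(0)
    ref_hits$supporting_species <- character(0)
    return(ref_hits)
  }
  L <- motif_length(m)
  len_ref <- nchar(ref_seq(region))
  ref_centers <- ref_hits$offset + L / 2
  thr <- (threshold %||% m$score_threshold) - 1e-9
  others <- setdiff(species, refname)
  scorer <- motif_scorer(m)
  support_mat <- vapply(others, function(sp) {
    sp_seq <- region$sequences[[sp]]
    sc <- score_seq(sp_seq, m, scorer = scorer)
    sp_off <- which(sc$fwd >= thr | sc$rev >= thr)
    if (length(sp_off) == 0) return(rep(FALSE, nrow(ref_hits)))
    sp_centers <- sort((sp_off - 1L + L / 2) * (len_ref / nchar(sp_seq)))
    # any species centre within [ctr - delta, ctr + delta]?
    hi <- findInterval(ref_centers + delta, sp_centers)
    lo <- findInterval(ref_centers - delta - 1e-9, sp_centers)
    hi > lo
  }, logical(nrow(ref_hits)))
  support_mat <- matrix(support_mat, nrow = nrow(ref_hits),
                        dimnames = list(NULL, others))
  ref_hits$support <- 1L + as.integer(rowSums(support_mat))
  ref_hits$supporting_species <- vapply(seq_len(nrow(ref_hits)), function(i) {
    paste(c(refname, others[support_mat[i, ]]), collapse = ",")
  }, character(1))
  ref_hits[ref_hits$support >= min_species, , drop = FALSE]
}

#' Cluster motif hits within a window
#'
#' Implements the clustering rule "at least `min_count` motifs in a
#' `window`-bp window": hits (deduplicated by offset, so overlapping
#' plus/minus hits at one position count once) are merged greedily left
#' to right; a cluster collects every hit within `window` bp of its
#' leftmost hit, clusters never share hits, and groups smaller than
#' `min_count` are dropped.
#'
#' @param hits hit `data.frame` from [scan_motif()] (one region).
#' @param window maximum span in bp (default 1000).
#' @param min_count minimum number of hits per cluster (default 2).
#' @param motif_length motif length used for the cluster span's right
#'   edge (default 0 gives offset span only).
#' @return `data.frame` with one row per cluster: `region_id`, `start`,
#'   `end`, `n_hits`, `offsets` (comma-separated).
#' @export
cluster_hits <- function(hits, window = 1000, min_count = 2,
                         motif_length = 0L) {
  empty <- data.frame(region_id = character(0), start = integer(0),
                      end = integer(0), n_hits = integer(0),
                      offsets = character(0), stringsAsFactors = FALSE)
  if (nrow(hits) == 0) return(empty)
  if (length(unique(hits$region_id)) > 1) {
    stop("cluster_hits expects hits from a single region", call. = FALSE)
  }
  offs <- sort(unique(hits$offset))
  clusters <- list()
  i <- 1L
  while (i <= length(offs)) {
    in_win <- offs >= offs[i] & offs <= offs[i] + window
    members <- offs[in_win]
    if (length(members) >= min_count) {
      clusters[[length(clusters) + 1L]] <- members
    }
    i <- i + sum(in_win)
  }
  if (length(clusters) == 0) return(empty)
  data.frame(region_id = hits$region_id[1],
             start = vapply(clusters, min, numeric(1)),
             end = vapply(clusters, max, numeric(1)) + motif_length,
             n_hits = lengths(clusters),
             offsets = vapply(clusters, paste, character(1), collapse = ","),
             stringsAsFactors = FALSE)
}

#' Export motif hits as BED6
#'
#' The BED score column is the hit score in bits times 100, rounded to
#' an integer.
#'
#' @param hits hit `data.frame` with a `chrom`/`start` context: either
#'   columns `chrom` and genomic `start`, or `region_id`s resolvable via
#'   `region_intervals` (interval `data.frame` with `id` = region id).
#' @param m the scanned [motif()] (for the hit width).
#' @param path output path.
#' @param region_intervals optional interval table mapping region ids to
#'   genomic coordinates.
#' @return `path`, invisibly.
#' @export
write_hits_bed <- function(hits, m, path, region_intervals = NULL) {
  L <- motif_length(m)
  if (!is.null(region_intervals)) {
    idx <- match(hits$region_id, region_intervals$id)
    if (anyNA(idx)) stop("unresolved region_id in hits", call. = FALSE)
    chrom <- region_intervals$chrom[idx]
    start <- region_intervals$start[idx] + hits$offset
  } else {
    chrom <- hits$chrom
    start <- hits$start
  }
  df <- data.frame(chrom = chrom, start = start, end = start + L,
                   id = paste0(m$name, "_", seq_len(nrow(hits))),
                   strand = hits$strand, stringsAsFactors = FALSE)
  df$score <- as.integer(round(hits$score * 100))
  write_bed(df, path)
}
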