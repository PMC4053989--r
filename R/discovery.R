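# Discriminative de novo discovery of fixed-length conserved motifs:
# exhaustive seeding, conserved-instance PWM refinement, binomial
# over-representation, per-region discrimination and Pareto ranking.

#' Discovery parameters
#'
#' @param word_length seed/motif length in bp (default 10, >= 6).
#' @param delta conservation offset tolerance in bp (default 20).
#' @param min_species minimum supporting species (reference included);
#'   `NULL` means `ceiling(0.6 * n_species)`. Lowering it relaxes the
#'   conservation requirement.
#' @param pseudocount per-base pseudocount when estimating PWM columns
#'   (default 0.5).
#' @param max_refine_iters refinement iteration cap (default 20).
#' @param seed_mismatch Hamming radius for collecting seed instances
#'   (default 2; 0 = exact matches only). A radius of 2 lets one seed
#'   gather all literal variants of a doubly-degenerate consensus such
#'   as ACHGTTAK.
#' @param min_seed_regions a seed must occur in at least this many
#'   positive regions (default 3).
#' @param p_threshold over-representation p-value cutoff (default 1e-3).
#' @return a `discovery_params` list.
#' @export
discovery_params <- function(word_length = 10L, delta = 20, min_species = NULL,
                             pseudocount = 0.5, max_refine_iters = 20L,
                             seed_mismatch = 2L, min_seed_regions = 3L,
                             p_threshold = 1e-3) {
  stopifnot(word_length >= 6, pseudocount > 0, max_refine_iters >= 1,
            seed_mismatch >= 0, min_seed_regions >= 1)
  structure(list(word_length = as.integer(word_length), delta = delta,
                 min_species = min_species, pseudocount = pseudocount,
                 max_refine_iters = as.integer(max_refine_iters),
                 seed_mismatch = as.integer(seed_mismatch),
                 min_seed_regions = as.integer(min_seed_regions),
                 p_threshold = p_threshold),
            class = "discovery_params")
}

#' Enumerate candidate seed words from positive regions
#'
#' All distinct w-mers over `A`,`C`,`G`,`T` occurring in the positive
#' regions' reference sequences, collapsed with their reverse
#' complements to a canonical key (the lexicographic minimum). Words
#' containing `N` contribute nothing; regions shorter than `w`
#' contribute nothing.
#'
#' @param regions list of [ortho_region()] objects (positives).
#' @param w word length.
#' @return `data.frame` with columns `seed` (canonical word) and
#'   `n_regions` (number of distinct positive regions containing it),
#'   sorted by seed.
#' @export
enumerate_seeds <- function(regions, w) {
  per_region <- lapply(regions, function(r) {
    words <- seq_words(ref_seq(r), w)
    words <- words[!grepl("N", words, fixed = TRUE)]
    if (length(words) == 0) return(character(0))
    unique(canonical_words(words, w))
  })
  all_words <- unlist(per_region, use.names = FALSE)
  if (length(all_words) == 0) {
    return(data.frame(seed = character(0), n_regions = integer(0)))
  }
  tab <- table(all_words)
  data.frame(seed = names(tab), n_regions = as.integer(tab),
             row.names = NULL, stringsAsFactors = FALSE)
}

# Word-level conserved-instance collection for one seed: offsets on
# the reference whose w-mer lies within `seed_mismatch` of the seed
# (either strand) and whose exact word is carried by >= min_species
# species (either strand) within +/- delta of the length-rescaled
# centre. Conceptually this is assess_conservation() applied to the
# seed's indicator PWM at the exact-match threshold. The conserved
# reference words are independent of the seed, so a precomputed
# `cons` table (from conserved_ref_words()) can be shared across
# seeds.
collect_seed_instances <- function(seed, regions, params, cons = NULL) {
  w <- nchar(seed)
  if (is.null(cons)) {
    n_species <- length(regions[[1]]$sequences)
    min_sp <- params$min_species %||% ceiling(0.6 * n_species)
    cons <- conserved_ref_words(regions, w, params$delta, min_sp)
  }
  if (nrow(cons) == 0) {
    return(data.frame(region_id = character(0), offset = integer(0),
                      strand = character(0), word = character(0),
                      support = integer(0)))
  }
  d_fwd <- hamming_to(seed, cons$word, w)
  d_rev <- hamming_to(revcomp(seed), cons$word, w)
  keep <- pmin(d_fwd, d_rev) <= params$seed_mismatch
  sel <- cons[keep, , drop = FALSE]
  strand <- ifelse(d_fwd[keep] <= d_rev[keep], "+", "-")
  data.frame(region_id = sel$region_id, offset = sel$offset,
             strand = strand,
             word = ifelse(strand == "+", sel$word,
                           revcomp_words(sel$word, w)),
             support = sel$support,
             stringsAsFactors = FALSE, row.names = NULL)
}

# Number of species (reference included) carrying `word` or its reverse
# complement within +/- delta of the rescaled centre of `offset`.
word_support <- function(region, offset, word, delta) {
  w <- nchar(word)
  rc <- revcomp(word)
  len_ref <- nchar(ref_seq(region))
  ctr <- offset + w / 2
  sup <- 1L
  for (sp in setdiff(names(region$sequences), region$reference_species)) {
    sseq <- region$sequences[[sp]]
    len_s <- nchar(sseq)
    ctr_s <- ctr * len_s / len_ref
    lo <- max(1L, floor(ctr_s - delta - w / 2) + 1L)
    hi <- min(len_s - w + 1L, ceiling(ctr_s + delta - w / 2) + 1L)
    if (hi < lo) next
    win_words <- substring(sseq, lo:hi, lo:hi + w - 1L)
    cand <- which(win_words == word | win_words == rc)
    if (length(cand)) {
      ctrs <- ((lo:hi)[cand] - 1L + w / 2) * (len_ref / len_s)
      if (any(abs(ctrs - ctr) <= delta)) sup <- sup + 1L
    }
  }
  sup
}

#' Refine a seed word into a PWM motif
#'
#' Conserved instances of the seed are collected on the positive
#' regions (within `seed_mismatch` of the seed on the reference, exact
#' cross-species word support at `min_species`), a PWM is estimated
#' from the instance columns with a pseudocount, and the motif is
#' refined by alternating rescans (threshold = minimum instance score
#' of the previous iteration, conservation reassessed with the PWM)
#' with PWM re-estimation, until the instance set is stable or
#' `max_refine_iters` is reached.
#'
#' @param seed seed word (length `params$word_length`).
#' @param regions list of positive [ortho_region()] objects.
#' @param params a [discovery_params()].
#' @param background background base probabilities; `NULL` estimates
#'   them from the positive reference sequences.
#' @param cons optional precomputed conserved-reference-word table
#'   shared across seeds (internal optimisation; computed when `NULL`).
#' @param instances optional precollected conserved-instance table for
#'   this seed (skips collection).
#' @return a [motif()] whose `score_threshold` is the refinement
#'   threshold, with attributes `instances` (the final instance table)
#'   and `seed`; `NULL` when fewer than 2 conserved instances exist.
#' @export
seed_to_motif <- function(seed, regions, params = discovery_params(),
                          background = NULL, cons = NULL,
                          instances = NULL) {
  w <- nchar(seed)
  n_species <- length(regions[[1]]$sequences)
  min_sp <- params$min_species %||% ceiling(0.6 * n_species)
  background <- background %||% background_freqs(regions)
  inst <- instances %||%
    collect_seed_instances(seed, regions, params, cons = cons)
  inst <- inst[inst$support >= min_sp, , drop = FALSE]
  if (nrow(inst) < 2) return(NULL)
  build <- function(words) {
    counts <- matrix(params$pseudocount, nrow = w, ncol = 4,
                     dimnames = list(NULL, DNA_BASES))
    for (j in seq_len(w)) {
      tab <- table(factor(substring(words, j, j), levels = DNA_BASES))
      counts[j, ] <- counts[j, ] + as.numeric(tab)
    }
    counts / rowSums(counts)
  }
  key <- function(df) paste(df$region_id, df$offset, df$strand,
                            sep = ":", collapse = ";")
  seen <- character(0)
  m <- NULL
  # a refinement that balloons to background-level instance counts is
  # degenerate (a diffuse PWM matching everywhere), not a motif
  max_inst <- max(30L, ceiling(0.01 * sum(vapply(regions, function(r) {
    max(nchar(ref_seq(r)) - w + 1L, 0L)
  }, numeric(1)))))
  for (iter in seq_len(params$max_refine_iters)) {
    seen <- c(seen, key(inst))
    pwm <- build(inst$word)
    m <- motif(paste0("seed_", seed), pwm = pwm, background = background,
               score_threshold = 0)
    thr <- min(vapply(inst$word, function(x) log_odds(m, x), numeric(1)))
    m$score_threshold <- thr
    new_inst <- do.call(rbind, lapply(regions, function(r) {
      h <- assess_conservation(r, m, delta = params$delta,
                               min_species = min_sp, threshold = thr)
      if (nrow(h) == 0) return(NULL)
      word <- ifelse(h$strand == "+", h$word, revcomp(h$word))
      data.frame(region_id = h$region_id, offset = h$offset,
                 strand = h$strand, word = word, support = h$support,
                 stringsAsFactors = FALSE)
    }))
    if (is.null(new_inst) || nrow(new_inst) < 2) break
    if (nrow(new_inst) > max_inst) return(NULL)
    if (key(new_inst) == key(inst)) {
      inst <- new_inst
      break
    }
    # an instance set seen before means the iteration entered a cycle
    if (key(new_inst) %in% seen) {
      inst <- new_inst
      break
    }
    inst <- new_inst
  }
  attr(m, "instances") <- inst
  attr(m, "seed") <- seed
  m
}

background_freqs <- function(regions) {
  seqs <- vapply(regions, ref_seq, character(1))
  counts <- colSums(Biostrings::alphabetFrequency(
    Biostrings::DNAStringSet(seqs))[, DNA_BASES, drop = FALSE])
  f <- counts / sum(counts)
  # guard against degenerate compositions
  f <- pmax(f, 1e-3)
  f / sum(f)
}

#' Binomial over-representation p-value
#'
#' Upper-tail probability `P[X >= k]` for `X ~ Binomial(n, bg_rate)`,
#' computed in log space via `pbinom`.
#'
#' @param k observed conserved-hit count.
#' @param n number of positions scanned.
#' @param bg_rate conserved-hit rate per scanned position in a
#'   background pool. A rate of 0 with `k > 0` yields the `p = 0`
#'   sentinel with a warning.
#' @return p-value in `[0, 1]`.
#' @export
overrepresentation <- function(k, n, bg_rate) {
  stopifnot(k >= 0, k <= n, bg_rate >= 0, bg_rate < 1)
  if (k == 0) return(1)
  if (bg_rate == 0) {
    warning("background rate 0 with k > 0: returning p = 0 sentinel")
    return(0)
  }
  exp(stats::pbinom(k - 1, n, bg_rate, lower.tail = FALSE, log.p = TRUE))
}

#' Discriminative power of a motif between two region sets
#'
#' Sensitivity is the fraction of positive regions carrying at least
#' one conserved hit; the false-positive rate is the same fraction over
#' the negative regions.
#'
#' @param m a [motif()].
#' @param positives,negatives lists of [ortho_region()] objects.
#' @param params a [discovery_params()] (uses `delta`, `min_species`).
#' @param threshold scan threshold override (default the motif's own).
#' @return one-row `data.frame`: `name`, `sensitivity`, `fpr`,
#'   `n_pos_hit`, `n_pos`, `n_neg_hit`, `n_neg`.
#' @export
discriminate <- function(m, positives, negatives,
                         params = discovery_params(), threshold = NULL) {
  if (length(positives) == 0 || length(negatives) == 0) {
    stop("positives and negatives must both be non-empty", call. = FALSE)
  }
  has_hit <- function(region) {
    nrow(assess_conservation(region, m, delta = params$delta,
                             min_species = params$min_species,
                             threshold = threshold)) > 0
  }
  np <- sum(vapply(positives, has_hit, logical(1)))
  nn <- sum(vapply(negatives, has_hit, logical(1)))
  data.frame(name = m$name,
             sensitivity = np / length(positives),
             fpr = nn / length(negatives),
             n_pos_hit = np, n_pos = length(positives),
             n_neg_hit = nn, n_neg = length(negatives),
             stringsAsFactors = FALSE)
}

#' Pareto-rank discrimination results
#'
#' Motif A dominates B iff `sensitivity_A >= sensitivity_B` and
#' `fpr_A <= fpr_B` with at least one inequality strict. Layer 1 is the
#' non-dominated front; peeling it away yields subsequent layers.
#' Within a layer, results are sorted by over-representation p-value
#' ascending, ties broken by name.
#'
#' @param results `data.frame` with columns `name`, `sensitivity`,
#'   `fpr` and (optionally) `overrep_p`.
#' @return the same `data.frame` with a `pareto_layer` column, sorted
#'   by layer, then `overrep_p`, then name.
#' @export
pareto_rank <- function(results) {
  stopifnot(nrow(results) >= 1)
  if (is.null(results$overrep_p)) results$overrep_p <- NA_real_
  n <- nrow(results)
  layer <- rep(NA_integer_, n)
  remaining <- seq_len(n)
  current <- 1L
  while (length(remaining)) {
    s <- results$sensitivity[remaining]
    f <- results$fpr[remaining]
    dominated <- vapply(seq_along(remaining), function(i) {
      any(s >= s[i] & f <= f[i] & (s > s[i] | f < f[i]))
    }, logical(1))
    layer[remaining[!dominated]] <- current
    remaining <- remaining[dominated]
    current <- current + 1L
  }
  results$pareto_layer <- layer
  p <- ifelse(is.na(results$overrep_p), Inf, results$overrep_p)
  results[order(results$pareto_layer, p, results$name), , drop = FALSE]
}

#' Discriminative de novo motif discovery
#'
#' Full chain: canonical seed enumeration on the positives, seed-region
#' support filtering, a fast conserved-word prefilter (a seed must be
#' within `seed_mismatch` of at least 2 cross-species-conserved
#' reference words), PWM refinement ([seed_to_motif()]), deduplication
#' of seeds converging to the same instance set, binomial
#' over-representation filtering against a background pool, per-region
#' discrimination, and Pareto ranking. Deterministic given inputs and
#' parameters.
#'
#' @param positives,negatives lists of [ortho_region()] objects.
#' @param background_pool list of [ortho_region()] objects used to
#'   estimate the background conserved-hit rate (default: the
#'   negatives).
#' @param params a [discovery_params()].
#' @return `data.frame` of ranked results (columns of [discriminate()]
#'   plus `seed`, `k_pos`, `overrep_p`, `pareto_layer`), with the
#'   discovered [motif()] objects in attribute `motifs` (named by
#'   motif name). Zero rows, with a warning, when no motif survives.
#' @export
discover_motifs <- function(positives, negatives, background_pool = NULL,
                            params = discovery_params()) {
  stopifnot(length(positives) > 0, length(negatives) > 0)
  background_pool <- background_pool %||% negatives
  w <- params$word_length
  n_species <- length(positives[[1]]$sequences)
  min_sp <- params$min_species %||% ceiling(0.6 * n_species)
  log_stage("discover: %d positives, %d negatives, w=%d, min_species=%d",
            length(positives), length(negatives), w, min_sp)

  seeds <- enumerate_seeds(positives, w)
  seeds <- seeds[seeds$n_regions >= params$min_seed_regions, , drop = FALSE]
  log_stage("discover: %d seeds with >= %d positive regions",
            nrow(seeds), params$min_seed_regions)
  empty <- data.frame(name = character(0), sensitivity = numeric(0),
                      fpr = numeric(0), n_pos_hit = integer(0),
                      n_pos = integer(0), n_neg_hit = integer(0),
                      n_neg = integer(0), seed = character(0),
                      k_pos = integer(0), overrep_p = numeric(0),
                      pareto_layer = integer(0))
  if (nrow(seeds) == 0) {
    warning("no seed passed the region-support filter")
    return(empty)
  }

  # Prefilter: reference w-mers conserved as exact words across
  # species. A seed worth refining must be within seed_mismatch of at
  # least max(2, min_seed_regions) of them.
  min_inst <- max(2L, params$min_seed_regions)
  cons <- conserved_ref_words(positives, w, params$delta, min_sp)
  if (nrow(cons) >= 1) {
    n_cons_inst <- vapply(seeds$seed, function(sd) {
      d <- pmin(hamming_to(sd, cons$word, w),
                hamming_to(revcomp(sd), cons$word, w))
      sum(d <= params$seed_mismatch)
    }, integer(1))
    seeds <- seeds[n_cons_inst >= min_inst, , drop = FALSE]
  } else {
    seeds <- seeds[0, , drop = FALSE]
  }
  log_stage("discover: %d seeds pass the conserved-instance prefilter",
            nrow(seeds))
  if (nrow(seeds) == 0) {
    warning("no seed has >= 2 conserved instances")
    return(empty)
  }

  bg <- background_freqs(positives)
  # Seeds lying in the same degenerate family collect identical
  # conserved-instance sets; refine each distinct set once (first seed
  # in lexicographic order wins) and deduplicate again on the
  # converged sets.
  motifs <- list()
  start_keys <- character(0)
  inst_keys <- character(0)
  for (sd in sort(seeds$seed)) {
    inst <- collect_seed_instances(sd, positives, params, cons = cons)
    if (nrow(inst) < 2) next
    k0 <- paste(inst$region_id, inst$offset, sep = ":", collapse = ";")
    if (k0 %in% start_keys) next
    start_keys <- c(start_keys, k0)
    m <- seed_to_motif(sd, positives, params, background = bg,
                       instances = inst)
    if (is.null(m)) next
    inst_c <- attr(m, "instances")
    k <- paste(inst_c$region_id, inst_c$offset, sep = ":", collapse = ";")
    if (k %in% inst_keys) next   # same converged instance set: duplicate
    inst_keys <- c(inst_keys, k)
    motifs[[m$name]] <- m
  }
  log_stage("discover: %d distinct refined motifs", length(motifs))
  if (length(motifs) == 0) {
    warning("no motif survived refinement")
    return(empty)
  }

  n_pos_positions <- sum(vapply(positives, function(r) {
    max(nchar(ref_seq(r)) - w + 1L, 0L)
  }, numeric(1)))
  n_bg_positions <- sum(vapply(background_pool, function(r) {
    max(nchar(ref_seq(r)) - w + 1L, 0L)
  }, numeric(1)))
  pool_is_negatives <- identical(background_pool, negatives)
  rows <- lapply(motifs, function(m) {
    # one conservation pass per region serves presence/absence counts
    # (discrimination) and conserved-hit totals (over-representation)
    hits_per <- function(regions) {
      vapply(regions, function(r) {
        length(unique(assess_conservation(r, m, delta = params$delta,
                                          min_species = min_sp)$offset))
      }, numeric(1))
    }
    pos_counts <- hits_per(positives)
    neg_counts <- hits_per(negatives)
    bg_counts <- if (pool_is_negatives) neg_counts else
      hits_per(background_pool)
    k_pos <- sum(pos_counts)
    p <- overrepresentation(k_pos, n_pos_positions,
                            sum(bg_counts) / n_bg_positions)
    data.frame(name = m$name,
               sensitivity = mean(pos_counts > 0),
               fpr = mean(neg_counts > 0),
               n_pos_hit = sum(pos_counts > 0), n_pos = length(positives),
               n_neg_hit = sum(neg_counts > 0), n_neg = length(negatives),
               seed = attr(m, "seed"), k_pos = k_pos, overrep_p = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res <- res[res$overrep_p <= params$p_threshold, , drop = FALSE]
  if (nrow(res) == 0) {
    warning("no motif passed the over-representation filter")
    return(empty)
  }
  res <- pareto_rank(res)
  rownames(res) <- NULL
  attr(res, "motifs") <- motifs[res$name]
  res
}

# All (region, offset) reference words of width w whose exact word is
# carried by >= min_sp species within +/- delta (both strands). The
# per-shift vectorised comparison keeps this fast enough to run on
# every offset of every region.
conserved_ref_words <- function(regions, w, delta, min_sp) {
  out <- list()
  d <- as.integer(ceiling(delta))
  for (r in regions) {
    rs <- ref_seq(r)
    words <- seq_words(rs, w)
    n_off <- length(words)
    if (n_off == 0) next
    canon_ref <- canonical_words(words, w)
    len_ref <- nchar(rs)
    support <- rep(1L, n_off)
    for (sp in setdiff(names(r$sequences), r$reference_species)) {
      sseq <- r$sequences[[sp]]
      if (nchar(sseq) != len_ref) {
        # unequal lengths: fall back to the per-offset rescaled check
        sup <- vapply(seq_len(n_off) - 1L, function(off) {
          word_support(ortho_region(r$region_id, r$reference_species,
                                    c(stats::setNames(rs, r$reference_species),
                                      stats::setNames(sseq, sp))),
                       off, words[off + 1L], delta) > 1L
        }, logical(1))
        support <- support + sup
        next
      }
      canon_sp <- canonical_words(seq_words(sseq, w), w)
      hit <- rep(FALSE, n_off)
      for (shift in -d:d) {
        i <- seq_len(n_off)
        j <- i + shift
        ok <- j >= 1L & j <= n_off
        hit[i[ok]] <- hit[i[ok]] | (canon_ref[i[ok]] == canon_sp[j[ok]])
      }
      support <- support + hit
    }
    keep <- which(support >= min_sp)
    if (length(keep)) {
      out[[length(out) + 1L]] <- data.frame(
        region_id = r$region_id, offset = keep - 1L, word = words[keep],
        support = support[keep], stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(region_id = character(0), offset = integer(0),
                      word = character(0), support = integer(0)))
  }
  do.call(rbind, out)
}
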