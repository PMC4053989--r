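# Independent oracle implementations used to cross-check the package's
# optimised code paths, plus small fixture builders. Oracles are kept
# deliberately naive (per-window loops, all-pairs scans, direct
# summation) and share no code with the implementation.

rand_seq <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

str_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

# Per-window log-odds scan, both strands, via substring + explicit
# per-position products.
oracle_scan <- function(sequence, pwm, background, threshold) {
  L <- nrow(pwm)
  n <- nchar(sequence)
  out <- list()
  if (n < L) return(data.frame(offset = integer(0), strand = character(0)))
  for (o in 0:(n - L)) {
    win <- substr(sequence, o + 1, o + L)
    for (strand in c("+", "-")) {
      word <- if (strand == "+") win else str_revcomp(win)
      chars <- strsplit(word, "")[[1]]
      if (any(!chars %in% c("A", "C", "G", "T"))) next
      idx <- match(chars, c("A", "C", "G", "T"))
      sc <- 0
      for (j in seq_len(L)) sc <- sc + log2(pwm[j, idx[j]] / background[idx[j]])
      if (sc >= threshold - 1e-9) {
        out[[length(out) + 1L]] <- data.frame(offset = o, strand = strand,
                                              score = sc)
      }
    }
  }
  if (!length(out)) return(data.frame(offset = integer(0),
                                      strand = character(0),
                                      score = numeric(0)))
  do.call(rbind, out)
}

# Greedy sliding-window clustering oracle: repeatedly anchor a window
# at the leftmost unassigned offset, take everything inside it.
oracle_cluster <- function(offsets, window, min_count) {
  offsets <- sort(unique(offsets))
  groups <- list()
  while (length(offsets)) {
    anchor <- offsets[1]
    members <- offsets[offsets - anchor <= window]
    offsets <- setdiff(offsets, members)
    if (length(members) >= min_count) groups[[length(groups) + 1]] <- members
  }
  groups
}

# All-pairs nearest-TSS oracle.
oracle_nearest <- function(centers, chroms, tss) {
  vapply(seq_along(centers), function(i) {
    cand <- tss[tss$chrom == chroms[i], ]
    if (nrow(cand) == 0) return(NA_character_)
    d <- abs(cand$pos - centers[i])
    best <- cand$gene_id[d == min(d)]
    sort(best)[1]
  }, character(1))
}

# Direct binomial upper-tail summation.
oracle_binom_upper <- function(k, n, p) {
  if (k == 0) return(1)
  sum(choose(n, k:n) * p^(k:n) * (1 - p)^(n - (k:n)))
}

# Manual Benjamini-Hochberg.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Welch two-sample test from first principles.
oracle_welch_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- var(x); vy <- var(y)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  2 * pt(-abs(t), df)
}

# All-pairs Pareto layering: count dominators, peel iteratively.
oracle_pareto_layers <- function(sens, fpr) {
  n <- length(sens)
  layer <- rep(NA_integer_, n)
  lev <- 1L
  while (anyNA(layer)) {
    open <- which(is.na(layer))
    front <- open[vapply(open, function(i) {
      !any(vapply(open, function(j) {
        j != i && sens[j] >= sens[i] && fpr[j] <= fpr[i] &&
          (sens[j] > sens[i] || fpr[j] < fpr[i])
      }, logical(1)))
    }, logical(1))]
    layer[front] <- lev
    lev <- lev + 1L
  }
  layer
}

# A small hand-built ortholog set: identical species sequences unless
# per-species overrides are given.
make_ortho <- function(ref, n_species = 10, region_id = "r1",
                       overrides = list()) {
  species <- c("dmel", paste0("sp", sprintf("%02d", seq_len(n_species - 1))))
  seqs <- setNames(rep(ref, n_species), species)
  for (nm in names(overrides)) seqs[nm] <- overrides[[nm]]
  ortho_region(region_id, "dmel", seqs)
}
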