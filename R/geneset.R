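# Motif-based gene ranking and recovery-curve analysis against
# randomized gene sets.

#' Rank genes by conserved motif content
#'
#' Each gene's score is the number of conserved hits of the motif
#' across its regulatory regions (hits deduplicated by offset within a
#' region). Ties are broken by the best hit score in bits, then by gene
#' id, so the ranking is deterministic.
#'
#' @param m a [motif()].
#' @param gene_regions named list: gene id -> list of [ortho_region()]
#'   objects (every gene has at least one region).
#' @param delta,min_species conservation parameters as in
#'   [assess_conservation()].
#' @param threshold scan threshold override.
#' @return `data.frame` with columns `gene_id`, `n_conserved`,
#'   `best_score`, ordered best to worst.
#' @export
rank_genes <- function(m, gene_regions, delta = 20, min_species = NULL,
                       threshold = NULL) {
  stopifnot(length(gene_regions) > 0)
  rows <- lapply(names(gene_regions), function(g) {
    regions <- gene_regions[[g]]
    n <- 0L
    best <- -Inf
    for (r in regions) {
      h <- assess_conservation(r, m, delta = delta,
                               min_species = min_species,
                               threshold = threshold)
      if (nrow(h)) {
        n <- n + length(unique(h$offset))
        best <- max(best, max(h$score))
      }
    }
    data.frame(gene_id = g, n_conserved = n, best_score = best,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df <- df[order(-df$n_conserved, -df$best_score, df$gene_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Recovery curve and AUC of a gene ranking against a signature
#'
#' `curve[r]` is the fraction of the signature found among the top `r`
#' ranked genes; the AUC is the trapezoid integral of the curve over
#' the normalized rank `r / N`.
#'
#' @param ranking character vector of gene ids, best first.
#' @param signature character vector of signature gene ids (non-empty,
#'   a subset of `ranking`).
#' @return list with `curve` (length `N`), `auc`.
#' @export
recovery_curve <- function(ranking, signature) {
  if (length(signature) == 0) stop("empty signature", call. = FALSE)
  if (!all(signature %in% ranking)) {
    stop("signature genes missing from the ranked universe", call. = FALSE)
  }
  hitvec <- ranking %in% signature
  curve <- cumsum(hitvec) / length(signature)
  n <- length(ranking)
  auc <- sum((curve + c(0, curve[-n])) / 2) / n
  list(curve = curve, auc = auc)
}

#' Randomized-gene-set recovery band
#'
#' Draws `n_random` uniform gene sets of size `set_size` without
#' replacement from the universe, computes each draw's recovery curve
#' against itself as signature of the *given* ranking, and returns the
#' per-rank mean and standard deviation plus a `mean +/- sigma * sd`
#' band.
#'
#' @param ranking character vector of gene ids, best first (the
#'   observed ranking whose rank positions the random sets are scored
#'   on).
#' @param set_size size of each random signature.
#' @param n_random number of random draws (default 1000, >= 2).
#' @param sigma band half-width in standard deviations (default 2).
#' @param seed RNG seed.
#' @return list with `mean`, `sd`, `upper`, `lower` (each length
#'   `length(ranking)`), `n_random`, `sigma`.
#' @export
random_band <- function(ranking, set_size, n_random = 1000, sigma = 2,
                        seed = 0) {
  n <- length(ranking)
  stopifnot(set_size <= n, n_random >= 2)
  curves <- withr::with_seed(seed, {
    vapply(seq_len(n_random), function(i) {
      idx <- sample.int(n, set_size)
      hit <- logical(n)
      hit[idx] <- TRUE
      cumsum(hit) / set_size
    }, numeric(n))
  })
  mu <- rowMeans(curves)
  sd_ <- apply(curves, 1, stats::sd)
  list(mean = mu, sd = sd_, upper = mu + sigma * sd_,
       lower = pmax(mu - sigma * sd_, 0), n_random = n_random, sigma = sigma)
}

#' Recovery analysis of a signature over a motif-based gene ranking
#'
#' Convenience wrapper combining [rank_genes()], [recovery_curve()] and
#' [random_band()].
#'
#' @inheritParams rank_genes
#' @inheritParams random_band
#' @param signature signature gene ids.
#' @return list with `ranking` (data frame), `curve`, `auc`, `band`,
#'   and `exceeds` (logical vector, observed curve strictly above the
#'   upper band).
#' @export
recovery_analysis <- function(m, gene_regions, signature, delta = 20,
                              min_species = NULL, n_random = 1000,
                              sigma = 2, seed = 0) {
  ranking <- rank_genes(m, gene_regions, delta = delta,
                        min_species = min_species)
  rc <- recovery_curve(ranking$gene_id, signature)
  band <- random_band(ranking$gene_id, length(signature),
                      n_random = n_random, sigma = sigma, seed = seed)
  list(ranking = ranking, curve = rc$curve, auc = rc$auc, band = band,
       exceeds = rc$curve > band$upper)
}
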