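# Peak integration: motif/peak cross-correlation with a chi-squared
# test, nearest-TSS peak-to-gene assignment, peak subsets per gene set.

#' Centre position of a peak
#'
#' The summit (an offset from `start`) when present, otherwise
#' `floor((start + end) / 2)`.
#'
#' @param peaks interval `data.frame`, optionally with a `summit`
#'   column (offset from `start`; `NA` = no summit).
#' @return integer vector of centre positions.
#' @export
#' @examples
#' peak_center(genomic_intervals("chr2L", 100, 600))
peak_center <- function(peaks) {
  ctr <- as.integer(floor((peaks$start + peaks$end) / 2))
  if (!is.null(peaks$summit)) {
    has <- !is.na(peaks$summit)
    ctr[has] <- as.integer(peaks$start[has] + peaks$summit[has])
    if (any(ctr[has] < peaks$start[has] | ctr[has] >= peaks$end[has])) {
      stop("summit outside its peak", call. = FALSE)
    }
  }
  ctr
}

#' Cross-correlation of motif positions with peak centres
#'
#' For every (hit, peak) pair on the same chromosome with
#' `|position - centre| < half_window`, the signed distance
#' (motif minus centre) is binned; the observed histogram is tested
#' against the uniform expectation with a chi-squared test. Counting is
#' pair-based: a hit near two peaks contributes to both windows.
#'
#' @param hit_pos `data.frame` with columns `chrom` and `pos` (genomic
#'   motif positions, e.g. conserved-hit centres).
#' @param peaks peak interval `data.frame` (optional `summit` column).
#' @param half_window half window width in bp (default 10000).
#' @param bin bin width in bp (default 500); must divide `half_window`.
#' @return list with `bin_edges` (length `n_bins + 1`), `observed`,
#'   `expected`, `chi2`, `dof`, `p`, `total_hits`. With zero pairs the
#'   test fields are `NaN` and a warning is raised.
#' @export
cross_correlate <- function(hit_pos, peaks, half_window = 10000, bin = 500) {
  if (half_window %% bin != 0) {
    stop("half_window must be divisible by bin", call. = FALSE)
  }
  n_bins <- as.integer(2 * half_window / bin)
  edges <- seq(-half_window, half_window, by = bin)
  centers <- peak_center(peaks)
  observed <- integer(n_bins)
  for (chrom in unique(peaks$chrom)) {
    hp <- hit_pos$pos[hit_pos$chrom == chrom]
    pc <- centers[peaks$chrom == chrom]
    if (length(hp) == 0 || length(pc) == 0) next
    d <- as.vector(outer(hp, pc, "-"))
    d <- d[d >= -half_window & d < half_window]
    if (length(d) == 0) next
    idx <- floor((d + half_window) / bin) + 1L
    observed <- observed + tabulate(idx, nbins = n_bins)
  }
  total <- sum(observed)
  if (total == 0) {
    warning("no (hit, peak) pair within the window: chi-squared undefined")
    return(list(bin_edges = edges, observed = observed,
                expected = rep(NaN, n_bins), chi2 = NaN, dof = n_bins - 1L,
                p = NaN, total_hits = 0L))
  }
  expected <- rep(total / n_bins, n_bins)
  chi2 <- sum((observed - expected)^2 / expected)
  dof <- n_bins - 1L
  list(bin_edges = edges, observed = observed, expected = expected,
       chi2 = chi2, dof = dof,
       p = stats::pchisq(chi2, dof, lower.tail = FALSE),
       total_hits = total)
}

#' Assign each peak to the nearest transcription start site
#'
#' Per peak, the gene whose TSS minimises the unsigned distance to the
#' peak centre, same chromosome only; equidistant genes resolve to the
#' lexicographically smallest gene id. Peaks on chromosomes without any
#' TSS are listed separately as unassigned.
#'
#' @param peaks peak interval `data.frame` (ids in the `id` column).
#' @param tss TSS table as from [read_tss_table()].
#' @return list with `assigned` (`data.frame`: `peak_id`, `gene_id`,
#'   `distance`) and `unassigned` (character vector of peak ids).
#' @export
nearest_tss <- function(peaks, tss) {
  if (nrow(tss) == 0) stop("empty TSS table", call. = FALSE)
  centers <- peak_center(peaks)
  peak_ids <- peaks$id
  if (is.null(peak_ids) || all(is.na(peak_ids))) {
    peak_ids <- paste0("peak_", seq_len(nrow(peaks)))
  }
  assigned <- list()
  unassigned <- character(0)
  for (chrom in unique(peaks$chrom)) {
    pi <- which(peaks$chrom == chrom)
    tj <- which(tss$chrom == chrom)
    if (length(tj) == 0) {
      unassigned <- c(unassigned, peak_ids[pi])
      next
    }
    ord <- order(tss$pos[tj], tss$gene_id[tj])
    tpos <- tss$pos[tj][ord]
    tgene <- tss$gene_id[tj][ord]
    for (i in pi) {
      ctr <- centers[i]
      k <- findInterval(ctr, tpos)
      cand <- unique(pmin(pmax(c(k, k + 1L), 1L), length(tpos)))
      dmin <- min(abs(tpos[cand] - ctr))
      # all TSSs at the minimal distance (duplicated positions included)
      at_min <- which(abs(tpos - ctr) == dmin)
      gene <- min(tgene[at_min])
      assigned[[length(assigned) + 1L]] <- data.frame(
        peak_id = peak_ids[i], gene_id = gene, distance = dmin,
        stringsAsFactors = FALSE)
    }
  }
  assigned <- if (length(assigned)) do.call(rbind, assigned) else
    data.frame(peak_id = character(0), gene_id = character(0),
               distance = numeric(0))
  list(assigned = assigned, unassigned = unassigned)
}

#' Peaks associated with a gene set
#'
#' @param assignment the `assigned` table from [nearest_tss()].
#' @param gene_set character vector of gene ids.
#' @return list with `peaks` (peak ids whose assigned gene is in the
#'   set), `genes` (distinct genes of the set with at least one peak),
#'   `n_peaks`, `n_genes`.
#' @export
peaks_for_geneset <- function(assignment, gene_set) {
  sel <- assignment[assignment$gene_id %in% gene_set, , drop = FALSE]
  list(peaks = sel$peak_id, genes = sort(unique(sel$gene_id)),
       n_peaks = nrow(sel), n_genes = length(unique(sel$gene_id)))
}
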