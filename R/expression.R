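# The two-mutant expression filter: differential expression between
# genotypes, the regulated-gene selection rule, and the negative
# control set.

#' Read an expression matrix with its condition map
#'
#' The matrix is a TSV of pre-normalised log2 intensities, genes in
#' rows (first column `gene_id`), samples in columns; the sidecar TSV
#' maps each sample to a condition (`wt`, `svb`, `pri`).
#'
#' @param matrix_path path to the expression TSV.
#' @param conditions_path path to the condition-map TSV (columns
#'   `sample`, `condition`).
#' @return list with `mat` (numeric matrix, genes x samples) and
#'   `conditions` (`data.frame`).
#' @export
read_expression <- function(matrix_path, conditions_path) {
  df <- utils::read.table(matrix_path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  conditions <- utils::read.table(conditions_path, sep = "\t", header = TRUE,
                                  stringsAsFactors = FALSE)
  validate_expression(mat, conditions)
  list(mat = mat, conditions = conditions)
}

#' @rdname read_expression
#' @param x list as returned by [read_expression()].
#' @export
write_expression <- function(x, matrix_path, conditions_path) {
  out <- data.frame(gene_id = rownames(x$mat), x$mat, check.names = FALSE)
  utils::write.table(out, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(x$conditions, conditions_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(matrix_path)
}

validate_expression <- function(mat, conditions) {
  if (!all(colnames(mat) %in% conditions$sample)) {
    stop("samples missing from the condition map", call. = FALSE)
  }
  cond <- conditions$condition[match(colnames(mat), conditions$sample)]
  tab <- table(cond)
  need <- c("wt", "svb", "pri")
  if (!all(need %in% names(tab))) {
    stop("conditions wt, svb and pri must all be present", call. = FALSE)
  }
  if (any(tab[need] < 2)) {
    stop("each condition needs >= 2 replicates", call. = FALSE)
  }
  invisible(TRUE)
}

#' Differential expression between two conditions
#'
#' Per gene: `log2fc = mean(cond_a) - mean(cond_b)`, a two-sided Welch
#' two-sample test, and Benjamini-Hochberg adjusted p-values. Genes
#' with zero variance in both groups get the degenerate rule (p = 0 if
#' the means differ, 1 otherwise) and are flagged.
#'
#' @param x expression list (`mat`, `conditions`) as from
#'   [read_expression()].
#' @param cond_a,cond_b condition labels; the log2 fold change is
#'   a minus b (e.g. `cond_a = "svb"`, `cond_b = "wt"` gives the
#'   mutant-versus-wild-type change).
#' @return `data.frame` with columns `gene_id`, `log2fc`, `p`, `fdr`,
#'   `degenerate`.
#' @export
differential <- function(x, cond_a, cond_b) {
  cond <- x$conditions$condition[match(colnames(x$mat), x$conditions$sample)]
  a <- which(cond == cond_a)
  b <- which(cond == cond_b)
  if (length(a) < 2 || length(b) < 2) {
    stop("both conditions need >= 2 replicates", call. = FALSE)
  }
  res <- t(apply(x$mat, 1, function(v) {
    va <- v[a]; vb <- v[b]
    lfc <- mean(va) - mean(vb)
    if (stats::var(va) == 0 && stats::var(vb) == 0) {
      c(lfc, if (lfc == 0) 1 else 0, 1)
    } else {
      c(lfc, stats::t.test(va, vb)$p.value, 0)
    }
  }))
  data.frame(gene_id = rownames(x$mat), log2fc = res[, 1], p = res[, 2],
             fdr = stats::p.adjust(res[, 2], method = "BH"),
             degenerate = res[, 3] == 1,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Select the regulated gene set from the two-mutant filter
#'
#' Keeps genes down-regulated in the first mutant that show a further
#' more-than-`fold`-fold reduction in the second, at an FDR gate on the
#' second mutant's test, ranks them by the second mutant's fold change
#' (most reduced first) and truncates to the top `top_n`.
#'
#' With `pri_vs = "svb"` (default) the further-reduction rule compares
#' the two mutant genotypes: `log2fc_pri <= log2fc_svb - log2(fold)`.
#' With `pri_vs = "wt"` it only requires `log2fc_pri <= -log2(fold)`.
#'
#' @param diff_svb,diff_pri [differential()] results over the same
#'   genes (each mutant versus wild type).
#' @param fold fold-change factor (default 2).
#' @param top_n maximum set size (default 150).
#' @param fdr_max FDR gate on the `pri` test (default 0.01).
#' @param pri_vs baseline of the further-reduction rule, `"svb"` or
#'   `"wt"`.
#' @return character vector of gene ids, ranked by `log2fc_pri`
#'   ascending (all qualifiers when fewer than `top_n`).
#' @export
select_targets <- function(diff_svb, diff_pri, fold = 2, top_n = 150,
                           fdr_max = 0.01, pri_vs = c("svb", "wt")) {
  pri_vs <- match.arg(pri_vs)
  stopifnot(fold > 1, top_n >= 1,
            identical(diff_svb$gene_id, diff_pri$gene_id))
  further <- if (pri_vs == "svb") {
    diff_pri$log2fc <= diff_svb$log2fc - log2(fold)
  } else {
    diff_pri$log2fc <= -log2(fold)
  }
  keep <- diff_svb$log2fc < 0 & further & diff_pri$fdr <= fdr_max
  sel <- diff_pri[keep, , drop = FALSE]
  sel <- sel[order(sel$log2fc, sel$gene_id), , drop = FALSE]
  utils::head(sel$gene_id, top_n)
}

#' Select a negative control gene set
#'
#' Genes showing irrelevant variation in both mutants
#' (`min(p) > p_min` and `min(fdr) > fdr_min`), down-sampled uniformly
#' to `n` with a fixed seed (all eligible genes when fewer).
#'
#' @inheritParams select_targets
#' @param p_min minimum p-value in both tests (default 0.8).
#' @param fdr_min minimum FDR in both tests (default 0.99).
#' @param n control-set size (default 100).
#' @param seed RNG seed for the down-sampling.
#' @return character vector of gene ids (sorted).
#' @export
select_controls <- function(diff_svb, diff_pri, p_min = 0.8, fdr_min = 0.99,
                            n = 100, seed = 0) {
  stopifnot(identical(diff_svb$gene_id, diff_pri$gene_id))
  eligible <- diff_svb$gene_id[
    pmin(diff_svb$p, diff_pri$p) > p_min &
      pmin(diff_svb$fdr, diff_pri$fdr) > fdr_min]
  if (length(eligible) <= n) return(sort(eligible))
  sort(withr::with_seed(seed, sample(eligible, n)))
}
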