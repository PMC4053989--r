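# Genomic intervals and the BED / TSS text formats.
#
# A single coordinate convention is used throughout the package: 0-based,
# half-open [start, end) intervals, the BED dialect. GFF-style 1-based
# closed coordinates are deliberately not supported, so no conversion can
# leak into interval arithmetic.

#' Construct a table of genomic intervals
#'
#' @param chrom character vector of chromosome/contig names.
#' @param start integer vector, 0-based inclusive starts.
#' @param end integer vector, exclusive ends (`end > start`).
#' @param id optional interval labels (recycled `NA` when absent).
#' @param strand strand tokens, each one of `"+"`, `"-"`, `"."`.
#' @return a `data.frame` with columns `chrom`, `start`, `end`, `id`,
#'   `strand`.
#' @export
#' @examples
#' genomic_intervals("chr2L", 100, 600)
genomic_intervals <- function(chrom, start, end, id = NA_character_,
                              strand = ".") {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.integer(start),
                   end = as.integer(end),
                   id = as.character(id),
                   strand = as.character(strand),
                   stringsAsFactors = FALSE)
  validate_intervals(df)
}

validate_intervals <- function(df) {
  bad <- which(!(df$start >= 0L & df$end > df$start))
  if (length(bad)) {
    stop(sprintf("invalid interval at row %d: start=%s end=%s (need 0 <= start < end)",
                 bad[1], df$start[bad[1]], df$end[bad[1]]), call. = FALSE)
  }
  badstr <- which(!df$strand %in% c("+", "-", "."))
  if (length(badstr)) {
    stop(sprintf("invalid strand at row %d: '%s'", badstr[1],
                 df$strand[badstr[1]]), call. = FALSE)
  }
  df
}

#' Read a BED3/BED6 file as genomic intervals
#'
#' Columns beyond the third are optional: column 4 becomes `id`, column 6
#' becomes `strand` (missing strand is `"."`). Coordinates are kept
#' 0-based half-open as in the file.
#'
#' @param path path to a tab-separated BED file.
#' @return interval `data.frame` as from [genomic_intervals()].
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  nf <- utils::count.fields(path, sep = "\t", quote = "", comment.char = "#")
  nf <- nf[!is.na(nf)]
  if (length(nf) == 0) stop("empty BED file: ", path, call. = FALSE)
  if (min(nf) < 3) stop("BED file needs >= 3 tab-separated columns: ", path,
                        call. = FALSE)
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "#", blank.lines.skip = TRUE,
                           fill = TRUE, col.names = paste0("V", seq_len(max(nf))))
  id <- if (ncol(raw) >= 4) raw[[4]] else NA_character_
  strand <- if (ncol(raw) >= 6) raw[[6]] else "."
  id[!is.na(id) & id == ""] <- NA_character_
  strand[is.na(strand) | strand == ""] <- "."
  df <- data.frame(chrom = raw[[1]],
                   start = suppressWarnings(as.integer(raw[[2]])),
                   end = suppressWarnings(as.integer(raw[[3]])),
                   id = id, strand = strand,
                   stringsAsFactors = FALSE)
  if (anyNA(df$start) || anyNA(df$end)) {
    stop(sprintf("non-integer coordinate at row %d of %s",
                 which(is.na(df$start) | is.na(df$end))[1], path), call. = FALSE)
  }
  validate_intervals(df)
}

#' Write genomic intervals as BED
#'
#' Emits BED6 when any `id`, `score` or `strand` information is present,
#' BED3 otherwise. A `score` column, when present, is written as-is
#' (integers expected; motif-hit exports use bits x 100).
#'
#' @param df interval `data.frame` (optionally with a `score` column).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  validate_intervals(df)
  has6 <- any(!is.na(df$id)) || any(df$strand != ".") || !is.null(df$score)
  if (has6) {
    out <- data.frame(df$chrom, df$start, df$end,
                      ifelse(is.na(df$id), ".", df$id),
                      if (!is.null(df$score)) df$score else 0L,
                      df$strand)
  } else {
    out <- df[, c("chrom", "start", "end")]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a TSS table
#'
#' Tab-separated columns `gene_id`, `chrom`, `pos`, `strand`; one
#' transcription start site per gene, `pos` a 0-based point coordinate
#' (the width-1 interval `[pos, pos + 1)`).
#'
#' @param path path to the TSV file (with header).
#' @return `data.frame` with columns `gene_id`, `chrom`, `pos`, `strand`.
#' @export
read_tss_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "")
  need <- c("gene_id", "chrom", "pos", "strand")
  if (!all(need %in% names(df))) {
    stop("TSS table must have columns gene_id, chrom, pos, strand: ", path,
         call. = FALSE)
  }
  df <- df[, need]
  df$pos <- as.integer(df$pos)
  if (anyDuplicated(df$gene_id)) {
    stop(sprintf("duplicate gene_id in TSS table: %s",
                 df$gene_id[anyDuplicated(df$gene_id)]), call. = FALSE)
  }
  if (any(df$pos < 0L)) stop("negative TSS position", call. = FALSE)
  df
}

#' @rdname read_tss_table
#' @param df a TSS `data.frame`.
#' @export
write_tss_table <- function(df, path) {
  utils::write.table(df[, c("gene_id", "chrom", "pos", "strand")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
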