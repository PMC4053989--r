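# Enhancer-candidate prediction and per-species architecture reports:
# combine the regulated gene set, peak-to-gene assignments and
# conserved motifs into ranked candidates.

#' Predict enhancer candidates
#'
#' Candidates are peak regions assigned to regulated genes that carry
#' at least one conserved hit of the primary (Svb) motif -- the primary
#' motif is a hard gate, reflecting its near-universal presence in
#' validated enhancers. Additional motifs (e.g. blue, yellow) are
#' annotated, the composition class assigned, and candidates scored as
#' the best primary-motif hit in bits plus `extra_weight` per
#' additional distinct motif class present, sorted by score (ties by
#' gene id, then peak id).
#'
#' @param assignment `assigned` table from [nearest_tss()].
#' @param target_genes character vector of regulated gene ids.
#' @param peak_regions named list: peak id -> [ortho_region()] with the
#'   peak's sequence context across species.
#' @param motifs named list of [motif()] objects; `svb_motif` names the
#'   gating motif.
#' @param svb_motif name of the gating motif in `motifs` (default
#'   `"svbF7"`).
#' @param delta,min_species conservation parameters as in
#'   [assess_conservation()].
#' @param extra_weight score bonus per additional motif class present
#'   (default 0.5).
#' @return `data.frame` with one row per candidate: `peak_id`,
#'   `gene_id`, `region_id`, `score`, `composition_class`, `n_<motif>`
#'   count columns; per-motif conserved-hit tables in attribute
#'   `hits` (named by peak id). Empty, with a warning, when nothing
#'   qualifies.
#' @export
predict_enhancers <- function(assignment, target_genes, peak_regions,
                              motifs, svb_motif = "svbF7", delta = 20,
                              min_species = NULL, extra_weight = 0.5) {
  if (!svb_motif %in% names(motifs)) {
    stop(sprintf("gating motif '%s' missing from motifs", svb_motif),
         call. = FALSE)
  }
  sel <- assignment[assignment$gene_id %in% target_genes, , drop = FALSE]
  rows <- list()
  hit_tables <- list()
  for (i in seq_len(nrow(sel))) {
    pid <- sel$peak_id[i]
    region <- peak_regions[[pid]]
    if (is.null(region)) next
    hits <- lapply(motifs, function(m) {
      assess_conservation(region, m, delta = delta,
                          min_species = min_species)
    })
    if (nrow(hits[[svb_motif]]) == 0) next
    present <- vapply(hits, function(h) nrow(h) > 0, logical(1))
    extra <- setdiff(names(motifs)[present], svb_motif)
    score <- max(hits[[svb_motif]]$score) + extra_weight * length(extra)
    counts <- vapply(hits, function(h) length(unique(h$offset)), integer(1))
    row <- data.frame(peak_id = pid, gene_id = sel$gene_id[i],
                      region_id = region$region_id, score = score,
                      composition_class = classify_architecture(
                        present[svb_motif],
                        isTRUE(present["blue"]), isTRUE(present["yellow"])),
                      stringsAsFactors = FALSE)
    for (nm in names(counts)) row[[paste0("n_", nm)]] <- counts[[nm]]
    rows[[length(rows) + 1L]] <- row
    hit_tables[[pid]] <- hits
  }
  if (length(rows) == 0) {
    warning("no enhancer candidate qualifies")
    out <- data.frame(peak_id = character(0), gene_id = character(0),
                      region_id = character(0), score = numeric(0),
                      composition_class = character(0))
    attr(out, "hits") <- list()
    return(out)
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$score, out$gene_id, out$peak_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "hits") <- hit_tables[out$peak_id]
  out
}

#' Composition class of a candidate
#'
#' Classes by presence/absence of conserved blue and yellow motifs
#' given the Svb motif: `svb_only`, `svb_blue`, `svb_yellow`,
#' `all_three`, or `none` (no Svb motif).
#'
#' @param has_svb,has_blue,has_yellow logical presence flags.
#' @return class label.
#' @export
classify_architecture <- function(has_svb, has_blue = FALSE,
                                  has_yellow = FALSE) {
  if (!has_svb) return("none")
  if (has_blue && has_yellow) return("all_three")
  if (has_blue) return("svb_blue")
  if (has_yellow) return("svb_yellow")
  "svb_only"
}

#' Per-species motif architecture of a region
#'
#' Motif search is performed in each species' sequence independently,
#' at the same threshold for each motif in all species. Reference hits
#' carry a conservation flag from [assess_conservation()]: `filled`
#' (evolutionarily conserved) or `open` (present in the reference but
#' not traceable across species).
#'
#' @param region an [ortho_region()].
#' @param motifs named list of [motif()] objects.
#' @param delta,min_species conservation parameters.
#' @return list with `reference` (`data.frame`: `motif`, `offset`,
#'   `strand`, `score`, `conserved`) and `species` (named list of
#'   per-species `data.frame`s: `motif`, `offset`, `strand`, `score`,
#'   offset-ordered).
#' @export
architecture_report <- function(region, motifs, delta = 20,
                                min_species = NULL) {
  per_species <- lapply(names(region$sequences), function(sp) {
    hits <- do.call(rbind, lapply(names(motifs), function(nm) {
      h <- scan_motif(region$sequences[[sp]], motifs[[nm]])
      if (nrow(h) == 0) return(NULL)
      data.frame(motif = nm, offset = h$offset, strand = h$strand,
                 score = h$score, stringsAsFactors = FALSE)
    }))
    if (is.null(hits)) {
      hits <- data.frame(motif = character(0), offset = integer(0),
                         strand = character(0), score = numeric(0))
    }
    hits[order(hits$offset, hits$motif, hits$strand), , drop = FALSE]
  })
  names(per_species) <- names(region$sequences)
  reference <- per_species[[region$reference_species]]
  if (nrow(reference)) {
    conserved <- logical(nrow(reference))
    for (nm in unique(reference$motif)) {
      kept <- assess_conservation(region, motifs[[nm]], delta = delta,
                                  min_species = min_species)
      sel <- reference$motif == nm
      conserved[sel] <- paste(reference$offset[sel], reference$strand[sel]) %in%
        paste(kept$offset, kept$strand)
    }
    reference$conserved <- conserved
  } else {
    reference$conserved <- logical(0)
  }
  rownames(reference) <- NULL
  list(reference = reference, species = per_species)
}

#' Text schematic of per-species motif architectures
#'
#' One line per species, motifs ordered by offset, conserved reference
#' hits upper-case and unconserved ones bracketed.
#'
#' @param report result of [architecture_report()].
#' @return character vector (one line per species), invisibly; also
#'   printed.
#' @export
format_architecture <- function(report) {
  ref <- report$reference
  lines <- vapply(names(report$species), function(sp) {
    h <- report$species[[sp]]
    if (nrow(h) == 0) return(sprintf("%-14s (no motifs)", sp))
    glyphs <- vapply(seq_len(nrow(h)), function(i) {
      g <- sprintf("%s@%d%s", h$motif[i], h$offset[i], h$strand[i])
      if (!is.null(ref$conserved)) {
        j <- which(ref$motif == h$motif[i] & ref$offset == h$offset[i] &
                     ref$strand == h$strand[i])
        if (length(j) && !ref$conserved[j[1]]) g <- paste0("(", g, ")")
      }
      g
    }, character(1))
    sprintf("%-14s %s", sp, paste(glyphs, collapse = " "))
  }, character(1))
  cat(lines, sep = "\n")
  invisible(lines)
}
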