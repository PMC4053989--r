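# FASTA IO and orthologous region sets.

#' Read a FASTA file
#'
#' Sequences are uppercased; any character outside `A`,`C`,`G`,`T`,`N`
#' is rejected.
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop(sprintf("FASTA parse error in %s: %s",
                                     path, conditionMessage(e)), call. = FALSE))
  if (length(set) == 0) stop("empty FASTA file: ", path, call. = FALSE)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  if (any(names(seqs) == "")) {
    stop(sprintf("malformed FASTA header (record %d) in %s",
                 which(names(seqs) == "")[1], path), call. = FALSE)
  }
  if (any(nchar(seqs) == 0)) {
    stop(sprintf("empty FASTA record '%s' in %s",
                 names(seqs)[nchar(seqs) == 0][1], path), call. = FALSE)
  }
  validate_alphabet(seqs, where = paste0("FASTA file ", path))
  seqs
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Construct an orthologous region set
#'
#' One genomic region on a reference species plus its orthologous
#' sequences across species. Conservation assessment is alignment-free,
#' so the sequences are stored unaligned.
#'
#' @param region_id region label.
#' @param reference_species name of the reference species; must be a name
#'   of `sequences`.
#' @param sequences named character vector, species -> sequence
#'   (`A`,`C`,`G`,`T`,`N`).
#' @param interval optional single-row interval `data.frame` locating the
#'   region on the reference genome.
#' @return an object of class `ortho_region`.
#' @export
ortho_region <- function(region_id, reference_species, sequences,
                         interval = NULL) {
  if (!reference_species %in% names(sequences)) {
    stop(sprintf("region %s: reference species '%s' missing from sequences",
                 region_id, reference_species), call. = FALSE)
  }
  if (any(nchar(sequences) == 0)) {
    stop(sprintf("region %s: empty sequence", region_id), call. = FALSE)
  }
  sequences <- toupper(sequences)
  validate_alphabet(sequences, where = paste0("region ", region_id))
  structure(list(region_id = region_id,
                 reference_species = reference_species,
                 sequences = sequences,
                 interval = interval),
            class = "ortho_region")
}

#' @export
print.ortho_region <- function(x, ...) {
  cat(sprintf("ortho_region %s: %d species (ref %s), ref length %d bp\n",
              x$region_id, length(x$sequences), x$reference_species,
              nchar(x$sequences[[x$reference_species]])))
  invisible(x)
}

ref_seq <- function(region) region$sequences[[region$reference_species]]

#' Read a directory of orthologous region sets
#'
#' One multi-FASTA per region (`<region_id>.fa`), record ids being
#' species names. A JSON manifest (`manifest.json`) names the reference
#' species and, optionally, the expected species list.
#'
#' @param path directory containing the multi-FASTA files.
#' @param reference_species reference species; when `NULL`, taken from
#'   the manifest.
#' @return list of [ortho_region()] objects (empty for an empty
#'   directory).
#' @export
read_ortho_dir <- function(path, reference_species = NULL) {
  if (!dir.exists(path)) stop("no such directory: ", path, call. = FALSE)
  if (is.null(reference_species)) {
    mpath <- file.path(path, "manifest.json")
    if (!file.exists(mpath)) {
      stop("no reference_species given and no manifest.json in ", path,
           call. = FALSE)
    }
    manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE)
    reference_species <- manifest$reference_species
  }
  files <- sort(list.files(path, pattern = "\\.(fa|fasta)$", full.names = TRUE))
  lapply(files, function(f) {
    seqs <- read_fasta(f)
    rid <- tools::file_path_sans_ext(basename(f))
    if (!reference_species %in% names(seqs)) {
      stop(sprintf("file %s lacks the reference species record '%s'",
                   f, reference_species), call. = FALSE)
    }
    ortho_region(rid, reference_species, seqs)
  })
}

#' Write orthologous region sets to a directory
#'
#' Inverse of [read_ortho_dir()]: one multi-FASTA per region plus a JSON
#' manifest naming the reference species and species list.
#'
#' @param regions list of [ortho_region()] objects.
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_ortho_dir <- function(regions, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (r in regions) {
    write_fasta(r$sequences, file.path(path, paste0(r$region_id, ".fa")))
  }
  refs <- unique(vapply(regions, function(r) r$reference_species, character(1)))
  if (length(refs) > 1) stop("regions disagree on reference species", call. = FALSE)
  species <- if (length(regions)) names(regions[[1]]$sequences) else character(0)
  jsonlite::write_json(
    list(reference_species = refs %||% character(0), species = species),
    file.path(path, "manifest.json"), auto_unbox = TRUE)
  invisible(path)
}
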