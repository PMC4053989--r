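# Synthetic benchmark generator: multi-species ortholog sets with
# planted motif instances and core-only decoys, peaks, a TSS table and
# a replicated expression matrix, plus a ground-truth manifest. Every
# random draw flows from a single seed, so a config + seed pair yields
# a byte-identical bundle.

#' Benchmark configuration
#'
#' Defaults emulate the study conditions: 14 validated enhancers
#' (positives) versus 25 inactive regions (negatives), ~10 Drosophilid
#' species, five replicates per genotype, and a 150-gene regulated set
#' selected from the two-mutant filter.
#'
#' @param n_species number of species per ortholog set (reference
#'   included; default 10).
#' @param divergence per-species background substitution probability
#'   per base (star phylogeny; default 0.25).
#' @param conservation_factor multiplier (<= 1) on the substitution
#'   probability inside planted motif instances (default 0.1).
#' @param n_positive,n_negative training-region counts (defaults 14
#'   and 25).
#' @param region_length region length in bp (default 1500).
#' @param gc background GC content (default 0.42).
#' @param pos_motif_rate probability a positive region carries the
#'   primary (svbF7) motif (default 0.9).
#' @param copies_dist probability of 1, 2 or 3 planted copies given
#'   presence (single-copy-biased; default `c(0.6, 0.3, 0.1)`).
#' @param blue_rate,yellow_rate probability a positive region also
#'   carries one blue / yellow instance (defaults 0.6 and 0.5).
#' @param decoy_rate probability a negative region carries core-only
#'   decoys: CNGTTA cores whose flanks are resampled until the 8-mer no
#'   longer matches ACHGTTAK (default 0.8).
#' @param decoy_copies_dist probability of 1 or 2 decoys given presence
#'   (default `c(0.7, 0.3)`).
#' @param ortho_jitter per-species uniform shift (bp) of planted
#'   instances, exercising the conservation offset window (default 5;
#'   0 disables).
#' @param n_genes genes in the expression/ranking universe (default
#'   1000; 0 disables the gene layer).
#' @param n_target_genes regulated genes among them (default 150).
#' @param target_enhancer_rate probability a target gene's region
#'   carries a planted primary-motif enhancer (default 1).
#' @param effect_svb mean and sd of the target log2 fold change in the
#'   svb mutant (default `c(-0.8, 0.3)`).
#' @param effect_pri_extra mean and sd of the *additional* log2 drop in
#'   the pri mutant (default `c(-1.5, 0.4)`).
#' @param noise_sd replicate noise sd in log2 units (default 0.2).
#' @param replicates replicates per condition (default 5).
#' @param baseline mean and sd of per-gene baseline log2 intensity
#'   (default `c(8, 1)`).
#' @param peak_jitter_sd sd (bp) of the peak centre around the planted
#'   motif (default 150).
#' @param peak_width peak width in bp (default 500).
#' @param n_decoy_peaks peaks centred in random null-gene regions
#'   (default 100).
#' @param seed RNG seed for the whole bundle (default 0).
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_species = 10, divergence = 0.25,
                       conservation_factor = 0.1, n_positive = 14,
                       n_negative = 25, region_length = 1500, gc = 0.42,
                       pos_motif_rate = 0.9,
                       copies_dist = c(0.6, 0.3, 0.1),
                       blue_rate = 0.6, yellow_rate = 0.5,
                       decoy_rate = 0.8, decoy_copies_dist = c(0.7, 0.3),
                       ortho_jitter = 5, n_genes = 1000,
                       n_target_genes = 150, target_enhancer_rate = 1,
                       effect_svb = c(-0.8, 0.3),
                       effect_pri_extra = c(-1.5, 0.4), noise_sd = 0.2,
                       replicates = 5, baseline = c(8, 1),
                       peak_jitter_sd = 150, peak_width = 500,
                       n_decoy_peaks = 100, seed = 0) {
  cfg <- list(n_species = n_species, divergence = divergence,
              conservation_factor = conservation_factor,
              n_positive = n_positive, n_negative = n_negative,
              region_length = region_length, gc = gc,
              pos_motif_rate = pos_motif_rate, copies_dist = copies_dist,
              blue_rate = blue_rate, yellow_rate = yellow_rate,
              decoy_rate = decoy_rate, decoy_copies_dist = decoy_copies_dist,
              ortho_jitter = ortho_jitter, n_genes = n_genes,
              n_target_genes = n_target_genes,
              target_enhancer_rate = target_enhancer_rate,
              effect_svb = effect_svb, effect_pri_extra = effect_pri_extra,
              noise_sd = noise_sd, replicates = replicates,
              baseline = baseline, peak_jitter_sd = peak_jitter_sd,
              peak_width = peak_width, n_decoy_peaks = n_decoy_peaks,
              seed = seed)
  stopifnot(divergence >= 0, divergence <= 1,
            conservation_factor >= 0, conservation_factor <= 1,
            gc >= 0, gc <= 1, abs(sum(copies_dist) - 1) < 1e-9,
            n_genes == 0 || n_target_genes <= n_genes, replicates >= 2)
  structure(cfg, class = "sim_config")
}

# Species names: a star of 10 Drosophilids, dmel as reference.
SIM_SPECIES <- c("dmel", "dsim", "dsec", "dyak", "dere",
                 "dana", "dpse", "dper", "dwil", "dvir")

sim_species <- function(n) {
  if (n <= length(SIM_SPECIES)) return(SIM_SPECIES[seq_len(n)])
  c(SIM_SPECIES, sprintf("dsp%02d", seq_len(n - length(SIM_SPECIES))))
}

#' Random background sequence
#'
#' Independent base draws with `P(G) = P(C) = gc / 2`.
#'
#' @param length sequence length (> 0).
#' @param gc GC content.
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @return a nucleotide string.
#' @export
background_sequence <- function(length, gc = 0.42, seed = NULL) {
  stopifnot(length > 0)
  draw <- function() {
    p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    int_to_seq(sample.int(4L, length, replace = TRUE, prob = p))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Plant a motif word into a sequence
#'
#' Replaces the substring at `offset` (0-based) with the word, or its
#' reverse complement on the minus strand. When plants overlap, the
#' later plant wins (callers record this in the truth manifest).
#'
#' @param sequence nucleotide string.
#' @param word word to plant.
#' @param offset 0-based offset; `offset + nchar(word)` must not exceed
#'   the sequence length.
#' @param strand `"+"` or `"-"`.
#' @return the modified sequence.
#' @export
plant_word <- function(sequence, word, offset, strand = "+") {
  L <- nchar(word)
  if (offset < 0 || offset + L > nchar(sequence)) {
    stop("plant offset out of range", call. = FALSE)
  }
  if (strand == "-") word <- revcomp(word)
  paste0(substr(sequence, 1, offset),
         word,
         substr(sequence, offset + L + 1, nchar(sequence)))
}

#' Evolve an orthologous sequence from a reference
#'
#' Star-phylogeny substitution model: each base is substituted (to a
#' uniformly random different base) with probability `divergence`
#' outside planted sites and `divergence * conservation_factor` inside
#' them. Indels are not modelled.
#'
#' @param ref_sequence reference nucleotide string (sites already
#'   planted).
#' @param planted_sites `data.frame` with columns `offset` (0-based)
#'   and `length`; may have zero rows.
#' @param divergence background substitution probability.
#' @param conservation_factor multiplier inside planted sites.
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @return the evolved nucleotide string.
#' @export
evolve_ortholog <- function(ref_sequence, planted_sites, divergence,
                            conservation_factor, seed = NULL) {
  run <- function() {
    v <- seq_to_int(ref_sequence)
    rate <- rep(divergence, length(v))
    for (i in seq_len(nrow(planted_sites))) {
      o <- planted_sites$offset[i]
      idx <- (o + 1L):(o + planted_sites$length[i])
      rate[idx] <- divergence * conservation_factor
    }
    sub <- stats::runif(length(v)) < rate & !is.na(v)
    if (any(sub)) {
      v[sub] <- ((v[sub] - 1L + sample.int(3L, sum(sub), replace = TRUE)) %% 4L) + 1L
    }
    int_to_seq(v)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# Sample k non-overlapping 0-based offsets for sites of width L in a
# sequence of length n, keeping a margin from the edges and away from
# already-occupied sites. Gives up on a site after 200 tries.
sample_offsets <- function(k, n, L, occupied = integer(0), margin = 10L) {
  out <- integer(0)
  occ <- occupied
  for (i in seq_len(k)) {
    for (try in seq_len(200L)) {
      o <- sample(seq.int(margin, n - L - margin), 1L)
      if (all(abs(o - occ) >= L)) {
        out <- c(out, o)
        occ <- c(occ, o)
        break
      }
    }
  }
  out
}

# One decoy 8-mer: CNGTTA core, flanks resampled until the word no
# longer matches ACHGTTAK.
decoy_word <- function() {
  repeat {
    x1 <- sample(DNA_BASES, 1)
    nmid <- sample(DNA_BASES, 1)
    x8 <- sample(DNA_BASES, 1)
    w <- paste0(x1, "C", nmid, "GTTA", x8)
    if (!(x1 == "A" && nmid %in% c("A", "C", "T") && x8 %in% c("G", "T"))) {
      return(w)
    }
  }
}

# Build one ortholog set: plant `sites` (df: motif, word, offset,
# strand) into a background sequence, evolve each non-reference
# species, then shift each planted instance by a per-species jitter.
# Returns the ortho_region plus the manifest site table.
build_region <- function(region_id, cfg, sites, interval = NULL) {
  len <- cfg$region_length
  species <- sim_species(cfg$n_species)
  refname <- species[1]
  ref <- background_sequence(len, cfg$gc)
  nsite <- nrow(sites)
  if (nsite) {
    for (i in seq_len(nsite)) {
      ref <- plant_word(ref, sites$word[i], sites$offset[i], sites$strand[i])
    }
  }
  site_df <- if (nsite) data.frame(offset = sites$offset,
                                   length = nchar(sites$word)) else
    data.frame(offset = integer(0), length = integer(0))
  seqs <- stats::setNames(character(cfg$n_species), species)
  seqs[refname] <- ref
  mutated <- matrix(FALSE, nrow = nsite, ncol = cfg$n_species - 1)
  shifts <- matrix(0L, nrow = nsite, ncol = cfg$n_species - 1)
  for (s in seq_len(cfg$n_species - 1)) {
    sp <- evolve_ortholog(ref, site_df, cfg$divergence,
                          cfg$conservation_factor)
    if (nsite && cfg$ortho_jitter > 0) {
      for (i in seq_len(nsite)) {
        L <- nchar(sites$word[i])
        shift <- sample.int(2L * cfg$ortho_jitter + 1L, 1L) -
          cfg$ortho_jitter - 1L
        o <- sites$offset[i]
        new_o <- min(max(o + shift, 0L), len - L)
        if (new_o != o) {
          wsp <- substr(sp, o + 1L, o + L)
          sp <- paste0(substr(sp, 1, new_o), wsp,
                       substr(sp, new_o + L + 1L, len))
          shifts[i, s] <- new_o - o
        }
      }
    }
    if (nsite) {
      planted_oriented <- ifelse(sites$strand == "-",
                                 revcomp(sites$word), sites$word)
      for (i in seq_len(nsite)) {
        o <- sites$offset[i] + shifts[i, s]
        L <- nchar(sites$word[i])
        mutated[i, s] <- substr(sp, o + 1L, o + L) != planted_oriented[i]
      }
    }
    seqs[species[s + 1]] <- sp
  }
  manifest_sites <- if (nsite) {
    data.frame(motif = sites$motif, word = sites$word,
               offset = sites$offset, strand = sites$strand,
               species_mutated = apply(mutated, 1, function(x) {
                 paste(species[-1][x], collapse = ",")
               }),
               species_shift = apply(shifts, 1, paste, collapse = ","),
               stringsAsFactors = FALSE)
  } else {
    data.frame(motif = character(0), word = character(0),
               offset = integer(0), strand = character(0),
               species_mutated = character(0), species_shift = character(0))
  }
  list(region = ortho_region(region_id, refname, seqs, interval = interval),
       sites = manifest_sites)
}

# Site table for one positive training region.
positive_sites <- function(cfg, svb_words, blue_words, yellow_words) {
  sites <- data.frame(motif = character(0), word = character(0),
                      offset = integer(0), strand = character(0),
                      stringsAsFactors = FALSE)
  add <- function(sites, motif, words, k) {
    if (k == 0) return(sites)
    offs <- sample_offsets(k, cfg$region_length, 10L,
                           occupied = sites$offset)
    if (length(offs) == 0) return(sites)
    rbind(sites, data.frame(
      motif = motif, word = sample(words, length(offs), replace = TRUE),
      offset = offs, strand = sample(c("+", "-"), length(offs),
                                     replace = TRUE),
      stringsAsFactors = FALSE))
  }
  if (stats::runif(1) < cfg$pos_motif_rate) {
    k <- sample.int(length(cfg$copies_dist), 1, prob = cfg$copies_dist)
    sites <- add(sites, "svbF7", svb_words, k)
  }
  if (stats::runif(1) < cfg$blue_rate) sites <- add(sites, "blue", blue_words, 1L)
  if (stats::runif(1) < cfg$yellow_rate) {
    sites <- add(sites, "yellow", yellow_words, 1L)
  }
  sites
}

negative_sites <- function(cfg) {
  if (stats::runif(1) >= cfg$decoy_rate) {
    return(data.frame(motif = character(0), word = character(0),
                      offset = integer(0), strand = character(0),
                      stringsAsFactors = FALSE))
  }
  k <- sample.int(length(cfg$decoy_copies_dist), 1,
                  prob = cfg$decoy_copies_dist)
  offs <- sample_offsets(k, cfg$region_length, 10L)
  data.frame(motif = "decoy",
             word = vapply(seq_along(offs), function(i) decoy_word(),
                           character(1)),
             offset = offs,
             strand = sample(c("+", "-"), length(offs), replace = TRUE),
             stringsAsFactors = FALSE)
}

# Remove chance full-consensus matches of the primary motif from a
# negative reference sequence by point-mutating one base per match,
# so that no negative ever carries the full svbF7 word.
scrub_consensus <- function(seq, words) {
  w <- nchar(words[1])
  rc <- revcomp_words(words, w)
  bad_set <- c(words, rc)
  for (round in seq_len(50L)) {
    wins <- seq_words(seq, w)
    hit <- which(wins %in% bad_set)
    if (length(hit) == 0) return(seq)
    for (h in hit) {
      j <- h + sample.int(w, 1L) - 1L
      old <- substr(seq, j, j)
      substr(seq, j, j) <- sample(setdiff(DNA_BASES, old), 1L)
    }
  }
  seq
}

#' Generate the full synthetic benchmark
#'
#' Emits (in memory, and optionally to a directory) the complete
#' benchmark: positive/negative training ortholog sets, per-gene
#' regulatory regions across species, a TSS table, peaks centred near
#' planted primary-motif instances (plus decoy peaks in null-gene
#' regions), a replicated wt/svb/pri expression matrix, and the
#' ground-truth manifest. Deterministic per config seed.
#'
#' @param cfg a [sim_config()].
#' @param dir optional output directory; when given, the bundle is
#'   written as `positives/`, `negatives/`, `gene_regions/` (ortholog
#'   multi-FASTA directories), `peaks.bed`, `tss.tsv`,
#'   `expression.tsv`, `conditions.tsv` and `manifest.json`.
#' @return a list with elements `positives`, `negatives` (lists of
#'   [ortho_region()]), `gene_regions` (named list gene id -> list of
#'   regions), `peak_regions` (named list peak id -> region), `tss`,
#'   `peaks`, `expression` (`mat` + `conditions`), `manifest`.
#' @export
generate_benchmark <- function(cfg = sim_config(), dir = NULL) {
  withr::with_seed(cfg$seed, generate_benchmark_impl(cfg, dir))
}

generate_benchmark_impl <- function(cfg, dir) {
  svb_words <- consensus_words("ACHGTTAK")
  blue_words <- consensus_words("WAGAAAGCSR")
  yellow_words <- consensus_words("TTATGCAA")
  log_stage("simulate: seed=%d, %d+%d training regions, %d genes",
            cfg$seed, cfg$n_positive, cfg$n_negative, cfg$n_genes)

  region_manifest <- list()
  positives <- vector("list", cfg$n_positive)
  for (i in seq_len(cfg$n_positive)) {
    rid <- sprintf("pos_%02d", i)
    built <- build_region(rid, cfg,
                          positive_sites(cfg, svb_words, blue_words,
                                         yellow_words))
    positives[[i]] <- built$region
    region_manifest[[rid]] <- list(label = "positive", sites = built$sites)
  }
  negatives <- vector("list", cfg$n_negative)
  for (i in seq_len(cfg$n_negative)) {
    rid <- sprintf("neg_%02d", i)
    sites <- negative_sites(cfg)
    built <- build_region(rid, cfg, sites)
    # construction guarantee: no full primary-motif consensus word in
    # any negative reference sequence
    refname <- built$region$reference_species
    built$region$sequences[refname] <-
      scrub_consensus(built$region$sequences[[refname]], svb_words)
    negatives[[i]] <- built$region
    region_manifest[[rid]] <- list(label = "negative", sites = built$sites)
  }

  bundle <- list(positives = positives, negatives = negatives,
                 gene_regions = NULL, peak_regions = NULL, tss = NULL,
                 peaks = NULL, expression = NULL)

  genes_df <- NULL
  peaks_df <- NULL
  if (cfg$n_genes > 0) {
    gene_ids <- sprintf("gene_%04d", seq_len(cfg$n_genes))
    target_ids <- sort(sample(gene_ids, cfg$n_target_genes))
    spacing <- cfg$region_length + 2000L
    tss_pos <- (seq_len(cfg$n_genes) - 1L) * spacing +
      as.integer(floor(cfg$region_length / 2))
    gene_regions <- vector("list", cfg$n_genes)
    names(gene_regions) <- gene_ids
    peak_rows <- list()
    peak_regions <- list()
    site_tables <- vector("list", cfg$n_genes)
    for (i in seq_len(cfg$n_genes)) {
      gid <- gene_ids[i]
      rid <- paste0("reg_", gid)
      is_target <- gid %in% target_ids
      sites <- data.frame(motif = character(0), word = character(0),
                          offset = integer(0), strand = character(0),
                          stringsAsFactors = FALSE)
      if (is_target && stats::runif(1) < cfg$target_enhancer_rate) {
        k <- sample.int(length(cfg$copies_dist), 1, prob = cfg$copies_dist)
        offs <- sample_offsets(k, cfg$region_length, 10L)
        sites <- data.frame(
          motif = "svbF7",
          word = sample(svb_words, length(offs), replace = TRUE),
          offset = offs,
          strand = sample(c("+", "-"), length(offs), replace = TRUE),
          stringsAsFactors = FALSE)
        if (stats::runif(1) < cfg$blue_rate) {
          bo <- sample_offsets(1L, cfg$region_length, 10L, sites$offset)
          if (length(bo)) sites <- rbind(sites, data.frame(
            motif = "blue", word = sample(blue_words, 1), offset = bo,
            strand = sample(c("+", "-"), 1), stringsAsFactors = FALSE))
        }
        if (stats::runif(1) < cfg$yellow_rate) {
          yo <- sample_offsets(1L, cfg$region_length, 10L, sites$offset)
          if (length(yo)) sites <- rbind(sites, data.frame(
            motif = "yellow", word = sample(yellow_words, 1), offset = yo,
            strand = sample(c("+", "-"), 1), stringsAsFactors = FALSE))
        }
      }
      start <- (i - 1L) * spacing
      interval <- genomic_intervals("chrS", start, start + cfg$region_length,
                                    id = rid)
      built <- build_region(rid, cfg, sites, interval = interval)
      gene_regions[[gid]] <- list(built$region)
      site_tables[[i]] <- built$sites
      svb_sites <- built$sites[built$sites$motif == "svbF7", , drop = FALSE]
      if (nrow(svb_sites)) {
        planted_center <- start + svb_sites$offset[1] + 4L
        center <- planted_center +
          as.integer(round(stats::rnorm(1, 0, cfg$peak_jitter_sd)))
        center <- max(center, as.integer(cfg$peak_width / 2))
        pid <- sprintf("peak_%04d", length(peak_rows) + 1L)
        peak_rows[[length(peak_rows) + 1L]] <- data.frame(
          peak_id = pid, gene_id = gid, region_id = rid, enhancer = TRUE,
          center = center, planted_center = planted_center,
          stringsAsFactors = FALSE)
        peak_regions[[pid]] <- built$region
      }
    }
    # decoy peaks in random null-gene regions
    null_ids <- setdiff(gene_ids, target_ids)
    if (cfg$n_decoy_peaks > 0 && length(null_ids) > 0) {
      picks <- sample(null_ids, cfg$n_decoy_peaks, replace = TRUE)
      for (gid in picks) {
        i <- match(gid, gene_ids)
        start <- (i - 1L) * spacing
        center <- start + sample.int(cfg$region_length, 1L) - 1L +
          as.integer(round(stats::rnorm(1, 0, cfg$peak_jitter_sd)))
        center <- max(center, as.integer(cfg$peak_width / 2))
        pid <- sprintf("peak_%04d", length(peak_rows) + 1L)
        peak_rows[[length(peak_rows) + 1L]] <- data.frame(
          peak_id = pid, gene_id = gid, region_id = paste0("reg_", gid),
          enhancer = FALSE, center = center, planted_center = NA_integer_,
          stringsAsFactors = FALSE)
        peak_regions[[pid]] <- gene_regions[[gid]][[1]]
      }
    }
    peaks_df <- do.call(rbind, peak_rows)
    half <- as.integer(cfg$peak_width / 2)
    peaks <- if (is.null(peaks_df)) NULL else
      genomic_intervals("chrS",
                        pmax(peaks_df$center - half, 0L),
                        peaks_df$center + half,
                        id = peaks_df$peak_id)
    tss <- data.frame(gene_id = gene_ids, chrom = "chrS", pos = tss_pos,
                      strand = "+", stringsAsFactors = FALSE)

    # expression matrix: baseline + genotype effects + replicate noise
    eff_svb <- stats::setNames(rep(0, cfg$n_genes), gene_ids)
    eff_extra <- eff_svb
    eff_svb[target_ids] <- stats::rnorm(cfg$n_target_genes,
                                        cfg$effect_svb[1], cfg$effect_svb[2])
    eff_extra[target_ids] <- stats::rnorm(cfg$n_target_genes,
                                          cfg$effect_pri_extra[1],
                                          cfg$effect_pri_extra[2])
    baseline <- stats::rnorm(cfg$n_genes, cfg$baseline[1], cfg$baseline[2])
    conds <- rep(c("wt", "svb", "pri"), each = cfg$replicates)
    samples <- paste0(conds, "_", rep(seq_len(cfg$replicates), times = 3))
    shift <- rbind(wt = 0, svb = eff_svb, pri = eff_svb + eff_extra)
    mat <- matrix(0, nrow = cfg$n_genes, ncol = length(samples),
                  dimnames = list(gene_ids, samples))
    for (j in seq_along(samples)) {
      mat[, j] <- baseline + shift[conds[j], ] +
        stats::rnorm(cfg$n_genes, 0, cfg$noise_sd)
    }
    genes_df <- data.frame(gene_id = gene_ids,
                           status = ifelse(gene_ids %in% target_ids,
                                           "target", "null"),
                           effect_svb = eff_svb,
                           effect_pri_extra = eff_extra,
                           region_id = paste0("reg_", gene_ids),
                           tss_pos = tss_pos,
                           n_svb_sites = vapply(site_tables, function(s) {
                             sum(s$motif == "svbF7")
                           }, integer(1)),
                           stringsAsFactors = FALSE, row.names = NULL)
    for (i in seq_len(cfg$n_genes)) {
      region_manifest[[paste0("reg_", gene_ids[i])]] <-
        list(label = ifelse(gene_ids[i] %in% target_ids,
                            "gene_target", "gene_null"),
             sites = site_tables[[i]])
    }
    bundle$gene_regions <- gene_regions
    bundle$peak_regions <- peak_regions
    bundle$tss <- tss
    bundle$peaks <- peaks
    bundle$expression <- list(
      mat = mat,
      conditions = data.frame(sample = samples, condition = conds,
                              stringsAsFactors = FALSE))
  }

  bundle$manifest <- list(
    config = unclass(cfg),
    species = sim_species(cfg$n_species),
    reference_species = sim_species(cfg$n_species)[1],
    regions = region_manifest,
    genes = genes_df,
    peaks = peaks_df,
    provenance = c(peak_calling = "consumed as BED (MACS P < 0.00001, IDR = 0.02 upstream)",
                   expression = "pre-normalized log2 intensities"))

  if (!is.null(dir)) write_benchmark(bundle, dir)
  bundle
}

write_benchmark <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_ortho_dir(bundle$positives, file.path(dir, "positives"))
  write_ortho_dir(bundle$negatives, file.path(dir, "negatives"))
  if (!is.null(bundle$gene_regions)) {
    write_ortho_dir(unlist(bundle$gene_regions, recursive = FALSE,
                           use.names = FALSE),
                    file.path(dir, "gene_regions"))
    write_bed(bundle$peaks, file.path(dir, "peaks.bed"))
    write_tss_table(bundle$tss, file.path(dir, "tss.tsv"))
    write_expression(bundle$expression, file.path(dir, "expression.tsv"),
                     file.path(dir, "conditions.tsv"))
  }
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
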