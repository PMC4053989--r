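# The synthetic benchmark generator and its ground-truth manifest.

test_that("background sequences honour GC content and seeding", {
  s <- background_sequence(500, gc = 1, seed = 1)
  expect_true(grepl("^[GC]+$", s))
  expect_identical(background_sequence(200, 0.42, seed = 3),
                   background_sequence(200, 0.42, seed = 3))

  big <- background_sequence(1e6, gc = 0.42, seed = 5)
  gc_obs <- mean(strsplit(big, "")[[1]] %in% c("G", "C"))
  se <- sqrt(0.42 * 0.58 / 1e6)
  expect_lt(abs(gc_obs - 0.42), 3 * se)
})

test_that("planting is recoverable by scanning, on either strand", {
  m <- motif("svbF7", consensus = "ACHGTTAK")
  s <- background_sequence(200, 0.42, seed = 2)
  s1 <- plant_word(s, "ACAGTTAG", 60, "+")
  h <- scan_motif(s1, m)
  expect_true(any(h$offset == 60 & h$strand == "+"))
  s2 <- plant_word(s, "ACAGTTAG", 60, "-")
  h2 <- scan_motif(s2, m)
  expect_true(any(h2$offset == 60 & h2$strand == "-"))
  expect_error(plant_word(s, "ACAGTTAG", 195, "+"), "out of range")
  # overlapping plants: the later call wins
  s3 <- plant_word(plant_word(s, "AAAAAAAA", 10, "+"), "CCCCCCCC", 14, "+")
  expect_equal(substr(s3, 15, 22), "CCCCCCCC")
})

test_that("ortholog evolution respects rates and conservation factors", {
  ref <- background_sequence(2000, 0.42, seed = 7)
  expect_identical(evolve_ortholog(ref, data.frame(offset = integer(0),
                                                   length = integer(0)),
                                   0, 0.1, seed = 1), ref)
  # conservation factor 0 keeps planted words intact in every species
  planted <- plant_word(ref, "ACAGTTAG", 500, "+")
  sites <- data.frame(offset = 500, length = 8)
  for (i in 1:5) {
    sp <- evolve_ortholog(planted, sites, 0.4, 0, seed = i)
    expect_equal(substr(sp, 501, 508), "ACAGTTAG")
  }
  # observed substitution rates inside vs outside planted sites
  long <- background_sequence(1e5, 0.42, seed = 9)
  sites2 <- data.frame(offset = seq(0, 99000, by = 1000), length = 500)
  sp <- evolve_ortholog(long, sites2, 0.3, 0.1, seed = 11)
  a <- strsplit(long, "")[[1]]
  b <- strsplit(sp, "")[[1]]
  inside <- unlist(lapply(seq_len(nrow(sites2)), function(i) {
    sites2$offset[i] + seq_len(sites2$length[i])
  }))
  diff_in <- mean(a[inside] != b[inside])
  diff_out <- mean(a[-inside] != b[-inside])
  expect_lt(abs(diff_in - 0.03), 3 * sqrt(0.03 * 0.97 / length(inside)))
  expect_lt(abs(diff_out - 0.3), 3 * sqrt(0.3 * 0.7 / (1e5 - length(inside))))
})

test_that("default benchmarks emit the study-shaped bundle deterministically", {
  cfg <- sim_config(n_genes = 0, seed = 4)
  b <- generate_benchmark(cfg)
  expect_length(b$positives, 14)
  expect_length(b$negatives, 25)
  expect_length(b$positives[[1]]$sequences, 10)
  b2 <- generate_benchmark(cfg)
  expect_identical(b$positives[[3]]$sequences, b2$positives[[3]]$sequences)
  expect_identical(b$manifest$regions, b2$manifest$regions)
})

test_that("every planted primary-motif instance is found by the scanner", {
  m <- motif("svbF7", consensus = "ACHGTTAK")
  for (seed in 0:2) {
    b <- generate_benchmark(sim_config(n_genes = 0, seed = seed))
    for (r in b$positives) {
      sites <- b$manifest$regions[[r$region_id]]$sites
      svb <- sites[sites$motif == "svbF7", , drop = FALSE]
      if (nrow(svb) == 0) next
      h <- scan_motif(ref_seq <- r$sequences[[r$reference_species]], m)
      for (i in seq_len(nrow(svb))) {
        expect_true(any(h$offset == svb$offset[i] &
                          h$strand == svb$strand[i]),
                    info = paste(r$region_id, svb$offset[i]))
      }
    }
  }
})

test_that("negatives never contain a full consensus word", {
  m <- motif("svbF7", consensus = "ACHGTTAK")
  for (seed in 0:2) {
    b <- generate_benchmark(sim_config(n_genes = 0, seed = seed))
    for (r in b$negatives) {
      hits <- scan_motif(r$sequences[[r$reference_species]], m)
      expect_equal(nrow(hits), 0, info = r$region_id)
    }
  }
})

test_that("benchmark bundles survive a disk round trip", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_genes = 40, n_target_genes = 10, n_decoy_peaks = 5,
                    seed = 6)
  b <- generate_benchmark(cfg, dir = dir)
  pos <- read_ortho_dir(file.path(dir, "positives"))
  expect_length(pos, 14)
  expect_identical(pos[[1]]$sequences, b$positives[[1]]$sequences)
  peaks <- read_bed(file.path(dir, "peaks.bed"))
  expect_equal(nrow(peaks), nrow(b$peaks))
  expect_equal(peaks$start, b$peaks$start)
  tss <- read_tss_table(file.path(dir, "tss.tsv"))
  expect_equal(tss$pos, b$tss$pos)
  ex <- read_expression(file.path(dir, "expression.tsv"),
                        file.path(dir, "conditions.tsv"))
  expect_equal(ex$mat, b$expression$mat, tolerance = 1e-12)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  expect_equal(manifest$reference_species, "dmel")
})

test_that("realized expression effects track the configured sizes", {
  lfc_svb <- c(); lfc_extra <- c()
  for (seed in 0:2) {
    cfg <- sim_config(n_genes = 300, n_target_genes = 60, seed = seed)
    b <- generate_benchmark(cfg)
    truth <- b$manifest$genes
    t_ids <- truth$gene_id[truth$status == "target"]
    cond <- b$expression$conditions$condition
    mw <- rowMeans(b$expression$mat[t_ids, cond == "wt"])
    ms <- rowMeans(b$expression$mat[t_ids, cond == "svb"])
    mp <- rowMeans(b$expression$mat[t_ids, cond == "pri"])
    lfc_svb <- c(lfc_svb, ms - mw)
    lfc_extra <- c(lfc_extra, mp - ms)
  }
  n <- length(lfc_svb)
  se_svb <- sqrt(0.3^2 + 2 * 0.2^2 / 5) / sqrt(n)
  se_extra <- sqrt(0.4^2 + 2 * 0.2^2 / 5) / sqrt(n)
  expect_lt(abs(mean(lfc_svb) - (-0.8)), 3 * se_svb)
  expect_lt(abs(mean(lfc_extra) - (-1.5)), 3 * se_extra)
})
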