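# De novo discriminative motif discovery: seeding, refinement,
# over-representation, discrimination and Pareto ranking.

test_that("seed enumeration collapses strands and matches brute force", {
  r1 <- make_ortho("ACGTACGT", n_species = 2, region_id = "r1")
  s <- enumerate_seeds(list(r1), 8)
  expect_equal(nrow(s), 1)   # a single word of exactly w

  # a word and its reverse complement in different regions: one seed
  r2 <- make_ortho("AAACGTTT", n_species = 2, region_id = "r2")
  r3 <- make_ortho(str_revcomp("AAACGTTT"), n_species = 2, region_id = "r3")
  s2 <- enumerate_seeds(list(r2, r3), 8)
  expect_equal(nrow(s2), 1)
  expect_equal(s2$n_regions, 2)

  # toy 3-region set vs a hash-set oracle
  withr::with_seed(4, {
    regions <- lapply(1:3, function(i) {
      make_ortho(rand_seq(60), n_species = 2, region_id = paste0("t", i))
    })
    w <- 6
    got <- enumerate_seeds(regions, w)
    canon <- function(x) {
      rc <- str_revcomp(x)
      if (rc < x) rc else x
    }
    per_region <- lapply(regions, function(r) {
      s <- r$sequences[["dmel"]]
      unique(vapply(1:(nchar(s) - w + 1),
                    function(o) canon(substr(s, o, o + w - 1)), character(1)))
    })
    want <- table(unlist(per_region))
    expect_setequal(got$seed, names(want))
    expect_equal(got$n_regions, as.integer(want[got$seed]))
  })

  # region shorter than w contributes nothing
  short <- make_ortho("ACGT", n_species = 2, region_id = "s")
  expect_equal(nrow(enumerate_seeds(list(short), 8)), 0)
})

test_that("seed refinement builds PWMs from conserved instances", {
  # identical conserved instances, pseudocount -> 0: indicator columns
  word <- "ACGTTAGC"
  base <- withr::with_seed(1, rand_seq(300, 0.42))
  regions <- lapply(1:4, function(i) {
    s <- plant_word(withr::with_seed(i, rand_seq(300, 0.42)), word, 40 * i, "+")
    make_ortho(s, n_species = 4, region_id = paste0("p", i),
               overrides = setNames(
                 rep(list(s), 3), paste0("sp", sprintf("%02d", 1:3))))
  })
  params <- discovery_params(word_length = 8, pseudocount = 1e-9,
                             min_species = 4, seed_mismatch = 0)
  m <- seed_to_motif(word, regions, params)
  expect_false(is.null(m))
  idx <- match(strsplit(word, "")[[1]], c("A", "C", "G", "T"))
  for (j in 1:8) expect_gt(m$pwm[j, idx[j]], 0.999)

  # column frequencies equal counting plus pseudocount normalisation
  inst <- attr(m, "instances")
  expect_gte(nrow(inst), 4)
  params2 <- discovery_params(word_length = 8, pseudocount = 0.5,
                              min_species = 4, seed_mismatch = 0)
  m2 <- seed_to_motif(word, regions, params2)
  counts <- sapply(1:8, function(j) {
    tab <- table(factor(substring(attr(m2, "instances")$word, j, j),
                        levels = c("A", "C", "G", "T")))
    (as.numeric(tab) + 0.5) / (sum(tab) + 2)
  })
  expect_equal(unname(m2$pwm), unname(t(counts)), tolerance = 1e-12)

  # fewer than 2 conserved instances: discarded
  lone <- list(make_ortho(plant_word(base, word, 100, "+"), n_species = 4,
                          region_id = "lone"))
  expect_null(seed_to_motif(word, lone, params))
})

test_that("refinement always terminates within the iteration cap", {
  withr::with_seed(77, {
    regions <- lapply(1:6, function(i) {
      s <- rand_seq(400, 0.42)
      make_ortho(s, n_species = 4, region_id = paste0("r", i),
                 overrides = setNames(rep(list(s), 3),
                                      paste0("sp", sprintf("%02d", 1:3))))
    })
    params <- discovery_params(word_length = 8, max_refine_iters = 5,
                               min_species = 2)
    seeds <- enumerate_seeds(regions, 8)
    for (sd in sample(seeds$seed, 50)) {
      expect_error(seed_to_motif(sd, regions, params), NA)
    }
  })
})

test_that("binomial over-representation matches direct summation", {
  expect_equal(overrepresentation(0, 10, 0.3), 1)
  expect_equal(overrepresentation(5, 5, 0.1), 1e-5, tolerance = 1e-12)
  expect_warning(p0 <- overrepresentation(3, 10, 0), "sentinel")
  expect_equal(p0, 0)
  withr::with_seed(11, {
    for (i in 1:30) {
      n <- sample(5:60, 1)
      k <- sample(0:n, 1)
      rate <- runif(1, 0.01, 0.6)
      expect_equal(overrepresentation(k, n, rate),
                   oracle_binom_upper(k, n, rate), tolerance = 1e-9)
    }
  })
})

test_that("discrimination separates planted from clean regions", {
  m <- motif("svbF7", consensus = "ACHGTTAK")
  withr::with_seed(21, {
    mk <- function(id, plant) {
      s <- rand_seq(400, 0.42)
      if (plant) s <- plant_word(s, "ACAGTTAG", sample(20:370, 1), "+")
      s <- scrub <- s
      make_ortho(s, n_species = 4, region_id = id,
                 overrides = setNames(rep(list(s), 3),
                                      paste0("sp", sprintf("%02d", 1:3))))
    }
    pos <- lapply(paste0("p", 1:6), mk, plant = TRUE)
    neg <- lapply(paste0("n", 1:6), mk, plant = FALSE)
    # remove chance consensus matches from the negatives
    neg <- lapply(neg, function(r) {
      while (nrow(scan_motif(r$sequences[[1]], m)) > 0) {
        s2 <- rand_seq(400, 0.42)
        r <- make_ortho(s2, n_species = 4, region_id = r$region_id,
                        overrides = setNames(rep(list(s2), 3),
                                             paste0("sp", sprintf("%02d", 1:3))))
      }
      r
    })
    d <- discriminate(m, pos, neg, discovery_params(word_length = 8,
                                                    min_species = 4))
    expect_equal(d$sensitivity, 1)
    expect_equal(d$fpr, 0)
    expect_equal(d$n_pos_hit, 6)

    # raising the threshold never increases either rate
    d_hi <- discriminate(m, pos, neg,
                         discovery_params(word_length = 8, min_species = 4),
                         threshold = m$score_threshold + 2)
    expect_lte(d_hi$sensitivity, d$sensitivity)
    expect_lte(d_hi$fpr, d$fpr)
  })
  expect_error(discriminate(m, list(), list()), "non-empty")
})

test_that("Pareto ranking matches the all-pairs dominance oracle", {
  one <- data.frame(name = "a", sensitivity = 0.5, fpr = 0.5)
  expect_equal(pareto_rank(one)$pareto_layer, 1)

  two <- data.frame(name = c("a", "b"), sensitivity = c(0.9, 0.5),
                    fpr = c(0.1, 0.3))
  expect_equal(pareto_rank(two)$pareto_layer, c(1, 2))

  withr::with_seed(13, {
    for (i in 1:100) {
      n <- sample(2:12, 1)
      df <- data.frame(name = paste0("m", 1:n),
                       sensitivity = round(runif(n), 2),
                       fpr = round(runif(n), 2),
                       overrep_p = runif(n))
      got <- pareto_rank(df)
      want <- oracle_pareto_layers(df$sensitivity, df$fpr)
      expect_equal(got$pareto_layer[match(df$name, got$name)], want)
      # within-layer ordering: p ascending, ties by name
      for (l in unique(got$pareto_layer)) {
        sub <- got[got$pareto_layer == l, ]
        expect_equal(sub$overrep_p, sort(sub$overrep_p))
      }
    }
  })
})

test_that("discovery is deterministic and invariant to reverse complement", {
  cfg <- sim_config(n_genes = 0, n_positive = 8, n_negative = 10, seed = 5)
  b <- generate_benchmark(cfg)
  params <- discovery_params(word_length = 8)
  res1 <- suppressWarnings(discover_motifs(b$positives, b$negatives,
                                           params = params))
  res2 <- suppressWarnings(discover_motifs(b$positives, b$negatives,
                                           params = params))
  expect_identical(res1, res2)

  flip <- function(r) {
    ortho_region(r$region_id, r$reference_species,
                 vapply(r$sequences, str_revcomp, character(1)))
  }
  res_rc <- suppressWarnings(discover_motifs(lapply(b$positives, flip),
                                             lapply(b$negatives, flip),
                                             params = params))
  # same seeds survive with identical discrimination statistics
  expect_equal(res_rc$seed, res1$seed)
  expect_equal(res_rc$sensitivity, res1$sensitivity)
  expect_equal(res_rc$fpr, res1$fpr)
  expect_equal(res_rc$k_pos, res1$k_pos)
  expect_equal(res_rc$pareto_layer, res1$pareto_layer)
  # and each PWM equals the original up to reverse complement
  m1 <- attr(res1, "motifs")[[res1$name[1]]]
  mrc <- attr(res_rc, "motifs")[[res_rc$name[1]]]
  same <- max(abs(m1$pwm - mrc$pwm))
  flipped <- max(abs(reverse_complement_motif(m1)$pwm - mrc$pwm))
  expect_lt(min(same, flipped), 1e-12)
})

test_that("identical positive and negative sets cannot discriminate", {
  cfg <- sim_config(n_genes = 0, n_positive = 8, n_negative = 10, seed = 6)
  b <- generate_benchmark(cfg)
  res <- suppressWarnings(discover_motifs(b$positives, b$positives,
                                          params = discovery_params(
                                            word_length = 8)))
  if (nrow(res) > 0) {
    top <- res[res$pareto_layer == 1, ]
    expect_true(all(abs(top$sensitivity - top$fpr) < 1e-12))
  } else {
    succeed()
  }
})

test_that("relaxing the conservation requirement never loses sensitivity", {
  cfg <- sim_config(n_genes = 0, seed = 8)
  b <- generate_benchmark(cfg)
  m <- motif("svbF7", consensus = "ACHGTTAK")
  sens <- vapply(c(8, 6, 4, 2, 1), function(cc) {
    discriminate(m, b$positives, b$negatives,
                 discovery_params(word_length = 8,
                                  min_species = cc))$sensitivity
  }, numeric(1))
  expect_true(all(diff(sens) >= 0))
})
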