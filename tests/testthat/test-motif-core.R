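# Motif representation, log-odds scoring, bidirectional scanning,
# conservation assessment, and the 1-kb clustering rule.

test_that("IUPAC expansion puts soft mass on disallowed bases", {
  expect_equal(iupac_to_pwm("A", soft = 0)[1, ], c(A = 1, C = 0, G = 0, T = 0))
  expect_equal(iupac_to_pwm("H", soft = 0)[1, ],
               c(A = 1 / 3, C = 1 / 3, G = 0, T = 1 / 3))
  p <- iupac_to_pwm("K", soft = 0.04)[1, ]
  expect_equal(unname(p), c(0.02, 0.02, 0.48, 0.48))
  expect_equal(iupac_to_pwm("N")[1, ], c(A = .25, C = .25, G = .25, T = .25))
  expect_error(iupac_to_pwm("AXG"), "invalid IUPAC")
  full <- iupac_to_pwm("ACHGTTAK")
  for (j in 1:8) {
    expect_equal(full[j, ], iupac_to_pwm(substr("ACHGTTAK", j, j))[1, ])
  }
})

test_that("consensus-matching words and only they reach the default threshold", {
  # brute force over all 4^8 words: the 6 literal matches of ACHGTTAK
  # score above every non-matching word, and the default threshold
  # separates them exactly
  m <- motif("svbF7", consensus = "ACHGTTAK")
  grid <- expand.grid(rep(list(c("A", "C", "G", "T")), 8),
                      stringsAsFactors = FALSE)
  words <- do.call(paste0, grid)
  scores <- vapply(words, function(w) log_odds(m, w), numeric(1))
  matches <- grepl("^AC[ACT]GTTA[GT]$", words)
  expect_equal(sum(matches), 6)
  expect_true(min(scores[matches]) > max(scores[!matches]))
  expect_true(all(scores[matches] >= m$score_threshold - 1e-9))
  expect_true(all(scores[!matches] < m$score_threshold - 1e-9))
})

test_that("log-odds scoring matches a brute-force oracle and handles N", {
  m0 <- motif("flat", pwm = matrix(0.25, 5, 4), score_threshold = -100)
  for (w in c("ACGTA", "TTTTT", "GCGCG")) expect_equal(log_odds(m0, w), 0)

  # one fixed position over uniform background adds exactly 2 bits
  m1 <- motif("onefix", pwm = rbind(c(1, 0, 0, 0), matrix(0.25, 3, 4)),
              score_threshold = 0)
  expect_equal(log_odds(m1, "ACGT"), 2)
  expect_identical(log_odds(m1, "TCGT"), -Inf)  # zero-probability base

  expect_identical(log_odds(motif("c", consensus = "ACGT"), "ACNT"), -Inf)

  withr::with_seed(42, {
    for (i in 1:25) {
      L <- sample(4:10, 1)
      pwm <- matrix(rgamma(L * 4, 1), L, 4)
      pwm <- pwm / rowSums(pwm)
      bg <- c(0.3, 0.2, 0.2, 0.3)
      m <- motif(paste0("r", i), pwm = pwm, background = bg,
                 score_threshold = 0)
      word <- rand_seq(L)
      idx <- match(strsplit(word, "")[[1]], c("A", "C", "G", "T"))
      manual <- sum(vapply(seq_len(L),
                           function(j) log2(pwm[j, idx[j]] / bg[idx[j]]),
                           numeric(1)))
      expect_equal(log_odds(m, word), manual, tolerance = 1e-12)
    }
  })
})

test_that("scanning finds planted words at their offsets on both strands", {
  m <- motif("svbF7", consensus = "ACHGTTAK")
  s <- strrep("T", 30)
  s <- plant_word(s, "ACCGTTAG", 5, "+")
  s <- plant_word(s, "ACAGTTAT", 20, "-")
  h <- scan_motif(s, m)
  expect_equal(h$offset, c(5, 20))
  expect_equal(h$strand, c("+", "-"))
  expect_equal(h$word[1], "ACCGTTAG")

  expect_equal(nrow(scan_motif(strrep("N", 50), m)), 0)
  expect_equal(nrow(scan_motif("ACGT", m)), 0)  # shorter than the motif
})

test_that("scan equals the per-window oracle on random sequences", {
  withr::with_seed(202, {
    for (i in 1:20) {
      L <- sample(5:8, 1)
      pwm <- matrix(rgamma(L * 4, 1), L, 4)
      pwm <- pwm / rowSums(pwm)
      m <- motif("r", pwm = pwm, score_threshold = 1.5)
      s <- rand_seq(300, gc = runif(1, 0.3, 0.7))
      got <- scan_motif(s, m)
      want <- oracle_scan(s, pwm, m$background, 1.5)
      expect_equal(paste(got$offset, got$strand),
                   paste(want$offset, want$strand))
      expect_equal(got$score, want$score, tolerance = 1e-9)
    }
  })
})

test_that("scan hits mirror exactly under reverse complement", {
  m <- motif("svbF7", consensus = "ACHGTTAK")
  withr::with_seed(7, {
    for (i in 1:100) {
      s <- rand_seq(200, gc = 0.42)
      s <- plant_word(s, sample(c("ACAGTTAG", "ACTGTTAT"), 1),
                      sample(0:192, 1), sample(c("+", "-"), 1))
      h_fwd <- scan_motif(s, m)
      h_rev <- scan_motif(str_revcomp(s), m)
      mirrored <- sort(nchar(s) - 8 - h_fwd$offset)
      expect_equal(sort(h_rev$offset), mirrored)
      flip <- c(`+` = "-", `-` = "+")
      expect_setequal(paste(nchar(s) - 8 - h_fwd$offset, flip[h_fwd$strand]),
                      paste(h_rev$offset, h_rev$strand))
    }
  })
})

test_that("raising the threshold never adds hits", {
  m <- motif("ovo", consensus = "CNGTTA")
  withr::with_seed(5, {
    s <- rand_seq(2000, gc = 0.42)
    base <- scan_motif(s, m, threshold = m$score_threshold - 3)
    for (dt in c(-1, 0, 1, 2)) {
      h <- scan_motif(s, m, threshold = m$score_threshold + dt)
      expect_true(all(paste(h$offset, h$strand) %in%
                        paste(base$offset, base$strand)))
      expect_lte(nrow(h), nrow(base))
    }
  })
})

test_that("conservation support counts species carrying the hit nearby", {
  m <- motif("svbF7", consensus = "ACHGTTAK")
  base <- withr::with_seed(10, rand_seq(400, 0.42))
  planted <- plant_word(base, "ACAGTTAG", 100, "+")

  # same offset in all 10 species: support 10, kept at any c <= 10
  r_all <- make_ortho(planted, overrides = setNames(
    rep(list(planted), 9), paste0("sp", sprintf("%02d", 1:9))))
  h <- assess_conservation(r_all, m, min_species = 10)
  expect_equal(h$support, 10)
  expect_equal(h$offset, 100)

  # reference only: dropped at c = 6, support 1 at c = 1
  r_ref <- make_ortho(planted, overrides = setNames(
    rep(list(base), 9), paste0("sp", sprintf("%02d", 1:9))))
  expect_equal(nrow(assess_conservation(r_ref, m, min_species = 6)), 0)
  h1 <- assess_conservation(r_ref, m, min_species = 1)
  expect_equal(h1$support, 1)

  # shifted beyond delta in every other species: support stays 1
  shifted <- plant_word(base, "ACAGTTAG", 100 + 21, "+")
  r_shift <- make_ortho(planted, overrides = setNames(
    rep(list(shifted), 9), paste0("sp", sprintf("%02d", 1:9))))
  expect_equal(assess_conservation(r_shift, m, delta = 20,
                                   min_species = 1)$support, 1)
  # within delta it counts
  near <- plant_word(base, "ACAGTTAG", 100 + 15, "+")
  r_near <- make_ortho(planted, overrides = setNames(
    rep(list(near), 9), paste0("sp", sprintf("%02d", 1:9))))
  expect_equal(assess_conservation(r_near, m, delta = 20,
                                   min_species = 1)$support, 10)
})

test_that("conservation at c = 1 returns exactly the reference scan", {
  m <- motif("ovo", consensus = "CNGTTA")
  withr::with_seed(31, {
    for (i in 1:5) {
      ref <- rand_seq(500, 0.42)
      ovr <- setNames(lapply(1:9, function(j) rand_seq(500, 0.42)),
                      paste0("sp", sprintf("%02d", 1:9)))
      r <- make_ortho(ref, overrides = ovr)
      ref_hits <- scan_motif(ref, m, region_id = "r1")
      cons <- assess_conservation(r, m, min_species = 1)
      expect_equal(cons$offset, ref_hits$offset)
      expect_equal(cons$strand, ref_hits$strand)
      expect_equal(cons$score, ref_hits$score)
    }
  })
})

test_that("a single-species set gives every hit support 1", {
  m <- motif("ovo", consensus = "CNGTTA")
  s <- plant_word(strrep("A", 60), "CAGTTA", 20, "+")
  r <- ortho_region("solo", "dmel", c(dmel = s))
  h <- assess_conservation(r, m, min_species = 1)
  expect_true(all(h$support == 1))
})

test_that("the 1-kb cluster rule matches its examples and the oracle", {
  mk <- function(offs) data.frame(region_id = "r", offset = offs,
                                  strand = "+", score = 1,
                                  word = "X", stringsAsFactors = FALSE)
  cl <- cluster_hits(mk(c(100, 900)))
  expect_equal(nrow(cl), 1)
  expect_equal(cl$n_hits, 2)
  expect_equal(nrow(cluster_hits(mk(c(100, 1200)))), 0)

  withr::with_seed(99, {
    for (i in 1:200) {
      offs <- sort(sample(0:3000, sample(2:12, 1)))
      window <- sample(c(250, 500, 1000), 1)
      min_count <- sample(2:3, 1)
      got <- cluster_hits(mk(offs), window = window, min_count = min_count)
      want <- oracle_cluster(offs, window, min_count)
      expect_equal(nrow(got), length(want))
      if (length(want)) {
        expect_equal(got$offsets,
                     vapply(want, paste, character(1), collapse = ","))
      }
    }
  })
})

test_that("hits on both strands at one offset count once for clustering", {
  hits <- data.frame(region_id = "r", offset = c(50, 50, 900),
                     strand = c("+", "-", "+"), score = 1, word = "X",
                     stringsAsFactors = FALSE)
  cl <- cluster_hits(hits)
  expect_equal(cl$n_hits, 2)  # 50 deduplicated
})
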