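# crmscan

Conserved-motif scanning and enhancer prediction for mapping a
transcription factor's direct targets.

## What it does, and for whom

`crmscan` is for regulatory genomicists who want to go from "this
factor binds thousands of sites" to "these are the enhancers through
which it regulates its targets". The motivating system is the
Drosophila factor Svb (Shavenbaby), whose trichome enhancers carry the
binding-site core CNGTTA (OvoQ6), refined by discriminative analysis
to the flank-extended svbF7 motif ACHGTTAK, together with two further
cis-regulatory elements, blue (WAGAAAGCSR) and yellow (TTATGCAA). The
package implements the full computational chain:

* **Phylogenetic footprinting** — PWM scanning of orthologous
  sequence sets, species by species (alignment-free), with a hit
  called conserved when enough species carry it within an offset
  window: per-position log-odds
  `S(w) = sum_j log2(p_j(w_j) / q(w_j))` in bits, both strands.
* **Binding-site clustering** — the "at least two motifs in a 1 kb
  window" rule.
* **Discriminative de novo discovery** — canonical w-mer seeding on
  validated enhancers, conserved-instance PWM refinement, binomial
  over-representation against a background pool, and Pareto ranking
  of (sensitivity, false-positive rate) against inactive regions.
* **Peak integration** — motif/ChIP-peak cross-correlation (signed
  distances to peak centres, 10 kb half-window, 500 bp bins,
  chi-squared against uniform) and nearest-TSS peak-to-gene
  assignment.
* **Two-mutant expression filter** — genes down-regulated in *svb*
  and more than two-fold further down in *pri* (Welch tests,
  Benjamini–Hochberg, FDR 0.01 gate, top 150), plus a matched
  negative-control set.
* **Enhancer prediction** — peaks of regulated genes carrying a
  conserved svbF7 site, annotated with blue/yellow composition
  classes and per-species architecture maps.
* **A synthetic benchmark generator** — seeded multi-species ortholog
  sets with planted motifs, core-only decoys, peaks, TSSs and a
  replicated wt/svb/pri expression matrix, with a ground-truth
  manifest, so every stage is verifiable without genome downloads.

## Worked example

Scan a sequence for svbF7 on both strands:

```r
library(crmscan)
m <- trichome_motifs()$svbF7
m
#> motif svbF7: length 8 (ACHGTTAK), threshold 12.944 bits
scan_motif("TTTACAGTTAGTTTCTAACTGTTT", m)
#>   region_id offset strand    score     word
#> 1      <NA>      3      + 12.94389 ACAGTTAG
#> 2      <NA>     14      - 12.94389 CTAACTGT
```

The hit at offset 3 is a literal ACHGTTAK match on the plus strand;
the hit at offset 14 is the same motif on the minus strand (the
reported `word` is always the forward-strand window). The 12.94-bit
score is the minimum over the 6 words matching the consensus — the
default threshold at which PWM scanning equals IUPAC matching.

Discover discriminative motifs on a synthetic benchmark shaped like
the study (14 enhancers vs 25 inactive regions, 10 species, svbF7
planted in 90% of positives, core-only decoys in negatives):

```r
b <- generate_benchmark(sim_config(n_genes = 0, seed = 0))
res <- discover_motifs(b$positives, b$negatives,
                       params = discovery_params(word_length = 8))
head(res[, c("seed", "sensitivity", "fpr", "n_pos_hit", "n_neg_hit",
             "overrep_p", "pareto_layer")], 5)
#>       seed sensitivity fpr n_pos_hit n_neg_hit overrep_p pareto_layer
#> 1 ACAGTTAT       0.929   0        13         0  0.00e+00            1
#> 2 ACAGTAAG       1.000   1        14        25  4.11e-07            1
#> 3 AAAAAGCG       0.857   0        12         0  0.00e+00            2
#> 4 AAGAAAGC       0.857   0        12         0  0.00e+00            2
#> 5 CCGCTTTC       0.857   0        12         0  0.00e+00            2
```

The top-ranked motif detects 13/14 positives and 0/25 negatives; its
refined PWM is the planted svbF7 profile (fixed A-C-.-G-T-T-A-.
columns, degenerate H and K columns):

```r
round(attr(res, "motifs")[[res$name[1]]]$pwm, 2)
#>         A    C    G    T
#> [1,] 0.92 0.03 0.03 0.03
#> [2,] 0.03 0.92 0.03 0.03
#> [3,] 0.24 0.55 0.03 0.18
#> [4,] 0.03 0.03 0.92 0.03
#> [5,] 0.03 0.03 0.03 0.92
#> [6,] 0.03 0.03 0.03 0.92
#> [7,] 0.92 0.03 0.03 0.03
#> [8,] 0.03 0.03 0.55 0.39
```

Layer-2 seeds such as `AAGAAAGC` are fragments of the planted blue
motif (WAGAAAGCSR): enriched and conserved, but dominated by svbF7 in
the sensitivity/FPR plane. The full pipeline — expression filter,
peak assignment, enhancer prediction with architecture reports — is
walked through in `vignettes/trichome-enhancer-mapping.Rmd`.

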