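# mitocomp

Comparative mitogenomics for insect mitochondrial genomes: who changed, how,
and under what selective pressure.

Insect mitogenomes are compact, AT-biased, 37-gene circular genomes whose
comparative analysis follows a well-worn statistical path: base composition
and strand skews, codon-usage bias, population diversity, synonymous vs
nonsynonymous divergence, lineage-specific tests of positive selection, and
the architecture of the repeat-bearing control region. `mitocomp` implements
that path as a single tested R package, together with a synthetic-mitogenome
simulator so every stage can be exercised end-to-end without downloading
anything.

## What it computes

* **Composition** — AT%/GC%, AT-skew `(A−T)/(A+T)` and GC-skew `(G−C)/(G+C)`
  for whole genomes, genes, the control region and pooled codon positions;
  Welch t-test group contrasts with significance stars; Pearson correlations
  with fitted lines.
* **Codon usage** — RSCU, Wright's effective number of codons (ENC)
  generalized to the invertebrate mitochondrial code (62 sense codons, max
  ENC 62), the codon bias index (CBI), and the null curve
  `ENC = 2 + s + 29/(s² + (1−s)²)` against GC3.
* **Diversity** — segregating sites, nucleotide diversity Pi (pairwise or
  complete deletion), 100 bp/25 bp sliding windows, haplotype diversity with
  the n/(n−1) correction, and pairwise identity at nucleotide or amino-acid
  level.
* **Ka/Ks** — Nei–Gojobori (1986) counting with pathway averaging over
  multi-hit codons and Jukes–Cantor correction.
* **Branch-site selection test** — the GY94 codon model with the Model A
  site-class mixture (classes 0/1/2a/2b, foreground ω2 ≥ 1 on designated
  branches), likelihood-ratio test of ω2 = 1 against χ²₁, and Bayes
  empirical Bayes per-site posteriors with `*`/`**` flags at 0.95/0.99. The
  pruning engine is compiled (RcppArmadillo) and the class proportions are
  profiled out by EM, so calibration and power studies run at desk scale.
* **Topology tests** — Kishino–Hasegawa, Shimodaira–Hasegawa and expected
  likelihood weights by RELL resampling of per-site log-likelihoods.
* **Control region** — tandem-repeat detection (k-mer seeded, match/mismatch
  scored, consensus + copy number), conserved-block segmentation of aligned
  CRs, poly-A/T and (TA)n annotation.
* **I/O & pipeline** — GenBank flat-file read/write (lossless coordinate
  round-trip including origin-wrapping features), FASTA, gene-name synonym
  mapping, supermatrix concatenation with partition tables, and a
  `run_pipeline()` orchestrator writing per-stage TSVs plus a JSON summary.

## Worked example: detecting planted positive selection

Simulate a codon alignment on a random 8-taxon tree in which 10% of sites
evolve with ω2 = 5 on one (foreground) branch, then test that branch:

```r
library(mitocomp)

cfg <- simulation_config(seed = 42, n_taxa = 8, n_codons = 500, omega2 = 5)
sim <- simulate_codon_alignment(cfg)
fit <- fit_branch_site(sim$alignment, sim$tree, sim$foreground)
fit
#> <branch_site_fit> 500 sites, kappa = 2.002
#>   null: lnL = -6088.2737 (omega0 = 0.0848)
#>   alt:  lnL = -6078.2399 (omega0 = 0.0893, omega2 = 3.8753)
#>   2*deltaL = 20.0676, p = 7.475e-06
```

The alternative model improves the log-likelihood by 2ΔL ≈ 20.1 — far beyond
the χ²₁ 5% critical value of 3.84 — and recovers ω2 ≈ 3.9 against a true
value of 5. The BEB site ranking puts truly selected sites on top:

```r
bt <- beb(fit)
head(bt[order(-bt$pp), ], 5)
#>    site ref_aa    pp stars
#>   1 339 M      0.998 **
#>   2 221 N      0.997 **
#>   3  33 I      0.994 **
#>   4 195 N      0.993 **
#>   5 283 P      0.973 *
```

All five top-ranked sites are among the planted ω2 = 5 sites
(`sim$classes >= 3`). A full synthetic genome behaves like the real thing:

```r
g <- simulate_mitogenome(simulation_config(seed = 42))
g
#> <mitogenome> SYN0001 (Syntheticus exemplum), 15504 bp, 38 features
#>   [PCG 13 | tRNA 22 | rRNA 2], habitat: unknown
base_composition(setNames(g$sequence, g$id))$AT_pct
#> [1] 77.9
annotate_cr(g)$repeats  # the planted TATTA x 8 array is the top scorer
#>    start  end period copy_number consensus percent_matches score
#> ..   379  419      5           8 TATTA                 100    70
```

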