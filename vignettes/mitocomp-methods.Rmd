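---
title: "Methods: comparative mitogenomics with mitocomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative mitogenomics with mitocomp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

mitocomp implements the statistical toolkit used in comparative analyses of
insect mitochondrial genomes: composition and strand-skew profiling,
codon-usage bias indices, population diversity summaries, pairwise Ka/Ks, a
branch-site codon-model engine for detecting positive selection on designated
lineages, RELL-based topology tests, and control-region repeat annotation.
This vignette documents the models, the tunable parameters, the numerical
choices, and what the synthetic-data generator does and does not emulate.

```{r setup, eval = FALSE}
library(mitocomp)
```

## Sequence conventions

Mitogenomes are circular; features are stored with 0-based half-open
coordinates on the forward (majority, "J") strand, with an explicit
`wraps_origin` flag for features spanning the origin. All user-facing reports
and GenBank output use the 1-based inclusive convention, so I/O round-trips
are lossless. Minus-strand genes are extracted reverse-complemented.

The genetic code defaults to the invertebrate mitochondrial table (NCBI
table 5), the code used by beetle mitochondrial genes: `ATA` = Met, `TGA` =
Trp, `AGA`/`AGG` = Ser, and only `TAA`/`TAG` as stops, leaving 62 sense
codons. Every code-dependent statistic (RSCU families, ENC size classes,
Ka/Ks site counting, the codon models) derives its structure from the
`genetic_code()` object rather than hard-coding it, so other tables work
unchanged. Truncated terminal stops — a `T` or `TA` completed by
polyadenylation, common in insect mitogenomes — are treated as complete stops
and excluded from peptides.

Ambiguity codes other than `N` are rejected at parse time; `N` and gap
characters are excluded from both numerators and denominators of every
composition statistic, and codons containing them are treated as missing data
in the likelihood engine (not deleted column-wise), which keeps site indices
aligned with the per-site selection output.

## Composition and group comparisons

AT-skew is (A − T)/(A + T) and GC-skew (G − C)/(G + C), computed on the
strand as given. Profiles are produced for whole genomes, single genes, the
control region and pooled codon positions. Whole-genome values include the
control region (the whole forward strand), since that is the natural scope of
"total" composition; per-feature scopes are available when the control region
should be excluded.

Group contrasts (habitat classes, families, subfamilies) use Welch's
unequal-variance two-sample t-test for every pair of groups. Welch's form was
chosen over the pooled-variance t-test because taxon panels are small and
unbalanced and group variances have no reason to be equal; with equal
variances the two tests agree closely. Raw p-values are starred (`*` < 0.05,
`**` < 0.01, `***` < 0.001); a Benjamini–Hochberg option exists but is off by
default because raw stars are what comparative tables conventionally report.

## Codon-usage bias

RSCU divides a codon's count by its synonymous-family mean; families with
zero usage are reported as missing rather than zero. The effective number of
codons (ENC) is Wright's estimator generalized to the active code's
family-size classes: per family, codon homozygosity F = (nΣp² − 1)/(n − 1);
ENC sums (number of families of size k)/mean(F of size k) over classes, plus
the single-codon families. Under the invertebrate mitochondrial code the
classes are thirteen 2-fold, five 4-fold, one 6-fold (Leu) and one 8-fold
(Ser) family, so ENC ranges up to 62. A size class with no informative family
(fewer than two counted codons) is imputed from the neighbouring classes'
mean F and flagged; the estimate is capped at the number of sense codons,
which also makes the finite-sample "uniform usage" case hit the cap exactly.
Stop codons are excluded from all usage counts (the choice is stated here
because population-genetics GUIs are not explicit about it).

The null ENC expectation against GC3 is `2 + s + 29/(s² + (1 − s)²)`,
evaluated literally with no boundary special-casing. CBI is
(N_opt − N_ran)/(N_tot − N_ran) over degenerate families; the default
"optimal" set is the most frequent synonym per family over the pooled
dataset (alphabetical tie-break), user-overridable, since the conventional
tooling does not document its set.

## Diversity and Ka/Ks

Nucleotide diversity Pi is the mean pairwise proportion of differing sites;
gap handling is per pair ("pairwise deletion") by default with a
complete-deletion option, because the two conventions differ in gapped
alignments and some reference implementations default to the latter for some
statistics. Sliding windows (default 100 bp window, 25 bp step) are in
alignment coordinates and the final partial window is dropped, which makes
window counts and midpoints deterministic. Haplotype diversity uses the
n/(n − 1) small-sample correction; sequences are grouped into one haplotype
when they agree at every mutually included position.

Ka/Ks uses Nei–Gojobori (1986) counting: fractional synonymous site counts
per codon (each position contributes the fraction of its three possible
changes that are synonymous), averaged between the two sequences; multi-hit
codons average their synonymous/nonsynonymous difference counts over all
orderings of the changed positions, excluding pathways that pass through a
stop codon whenever a stop-free pathway exists. Changes that would create a
stop codon count as nonsynonymous, which preserves the identity
S_sites + N_sites = 3 × codons. Both proportions receive the Jukes–Cantor
correction −(3/4)·log(1 − 4p/3); p ≥ 3/4 is reported as a saturation error
rather than silently truncated, and Ks = 0 leaves the ratio undefined
(missing) rather than infinite. Clade-level values are exposed per pair so
any aggregation (mean, median, per-family) can be recomputed; the bundled
pipeline reports all within-set pairs.

## Branch-site positive selection

The selection engine implements the GY94 codon substitution model and the
branch-site "Model A" mixture. Sites fall into four classes: 0 (ω0 < 1
everywhere), 1 (ω = 1 everywhere), 2a and 2b (background ω0 or 1, foreground
ω2 ≥ 1 on the designated branch(es)). Class proportions obey
p2a = (1 − p0 − p1)·p0/(p0 + p1) and correspondingly for p2b, i.e. the
mixture factorizes into two independent binary factors — a structure the
optimizer exploits (below). The null model fixes ω2 = 1; the test statistic
is 2ΔL, referred by default to χ² with one degree of freedom (conservative
for this boundary problem; the 50:50 mixture reference is available).

Codon equilibrium frequencies are F3x4 (products of position-specific
nucleotide frequencies, renormalized over sense codons, with a small floor
against zero frequencies). The generator assigns rate π_target × {1, κ, ω,
κω} to synonymous/nonsynonymous transversions/transitions and zero to
multi-nucleotide changes; transition probabilities come from a symmetric
eigendecomposition of the reversible generator, shared between the simulator
and the pruning engine. Rate matrices are scaled by a common factor so that
the class-mixture mean rate on background branches is one, making branch
lengths expected substitutions per codon under the mixture; the scaling
weights are refreshed between optimization rounds and the final
log-likelihoods are evaluated self-consistently.

Numerical strategy, chosen for a desk-scale reimplementation of a workflow
normally run in a dedicated ML package:

* **Branch lengths** are estimated once under a single-ratio (M0) fit as one
  proportional scale factor on the input tree's relative lengths, then held
  fixed for both branch-site fits. Relative lengths are taken from the input
  tree (the paper-style workflow supplies a previously estimated tree);
  per-branch re-optimization adds many parameters for little effect on the
  LRT and is omitted.
* **κ** is taken from the M0 fit and held fixed in the branch-site fits.
* **Class proportions are profiled out by EM.** Because the Model A mixture
  factorizes, the expected-complete-data updates for (p0 + p1) and
  p0/(p0 + p1) are one-line means of responsibilities; given the four
  per-site class likelihoods this inner EM costs almost nothing, so the outer
  numeric optimization is only over ω0 (null) or (ω0, ω2) (alternative) with
  box constraints ω0 ∈ (10⁻⁴, 0.999), ω2 ∈ [1, 999]. The 999 cap mirrors the
  convention of reporting a hit cap rather than an unbounded estimate.
* **Starts.** The alternative surface is multimodal in ω2, so four
  deterministic starts (ω2 ∈ {1.5, 5, 50, 499.5}) are screened by one profile
  evaluation each; full optimization runs from the best screen and from the
  null optimum (ω2 → 1), and the better result is kept. Warm-starting from
  the null guarantees lnL_alt ≥ lnL_null up to optimizer tolerance; 2ΔL is
  clamped at zero.
* **Pruning engine.** Felsenstein pruning over the 62 sense-codon states is
  compiled code with per-pattern compression; subtrees that contain no
  foreground branch are cached across site classes (classes 0/2a and 1/2b
  share their background passes), roughly halving the work per likelihood
  evaluation.

Bayes empirical Bayes (BEB) site identification averages the per-site
posterior probability of classes 2a + 2b over a uniform 10-point-per-
dimension grid on (p0, p1/(1 − p0), ω0, ω2 ∈ (1, 11)), weighting grid points
by the whole-alignment likelihood with κ, branch lengths and the rate-matrix
scaling fixed at their estimates. Sites with posterior > 0.95 are starred
`*`, > 0.99 `**`, matching the conventional reporting. The foreground
default when a clade is named is its stem (ancestral) branch only — the
reading consistent with "the ancestral branch of the subfamily" — with
arbitrary edge sets accepted for other designs.

Topology tests take a trees × sites matrix of per-site log-likelihoods and
perform RELL resampling (default 1000 resamples): the one-sided
Kishino–Hasegawa test against the best tree, the Shimodaira–Hasegawa test
with simultaneous max-comparison over centered resampled totals, and
expected likelihood weights (mean normalized likelihood across replicates).
The approximately-unbiased test requires multiscale bootstrap machinery and
is intentionally not provided.

## Control-region architecture

The tandem-repeat detector seeds candidate periods from exact 3-mer
recurrence distances (both consecutive-occurrence gaps and distances to the
first occurrence, so homopolymer runs and motifs with internally repeated
3-mers still propose their true period), then verifies each period by scoring the sequence
against itself at that lag (+2 per match, −7 per mismatch, the conventional
default weights) and taking maximal positive-scoring segments. Overlapping
reports from different periods keep the best score, with smaller periods
winning ties so a period-p array is not re-reported at 2p. The consensus is
the column majority over copies. The default minimum score of 8 is set so
that the smallest biologically reported arrays (three perfect copies of a
2 bp motif) remain detectable; raising it suppresses chance hits in long
random sequence. The detector handles substitutional divergence between
copies but does not align around indels inside an array (the indel weight is
accepted for interface compatibility); arrays diverged by indels will be
reported as split segments.

Conserved blocks of aligned control regions are maximal runs of gap-free,
100%-identical columns of length ≥ 3 ("longer than 2 bp"); the threshold is
exposed because the criterion is conventional rather than principled.
`annotate_cr()` composes repeat detection with poly-A/poly-T runs, (TA)n
microsatellites and a windowed AT% track into an ordered segmentation.

## The synthetic-data generator

`simulate_mitogenome()` builds a complete 37-gene mitogenome in the
ancestral insect gene order (no rearrangement), with stop-free
position-biased protein-coding genes, a conserved short spacer between trnS2
and nad1, and a control region between rrnS and trnI containing a planted
tandem array flanked by poly-A/poly-T stretches. The default whole-genome AT
target of 0.78 sits in the middle of the published hydrophiloid range
(roughly 0.76–0.81); third codon positions are biased +0.08 and second
positions −0.08 around the target, reproducing the position gradient of real
mitogenomes. The planted array is followed and preceded by four bases chosen
to break its periodicity, so the planted period and copy number are exactly
recoverable — a property the tests rely on.

`simulate_codon_alignment()` draws each site's class from the Model A
mixture and evolves codons down the tree using the same generator matrices
and scaling as the fitting engine, so parameter-recovery experiments are
internally consistent; true site classes are returned for recovery checks.
Defaults: 8 taxa, uniform(0.05, 0.3) branch lengths, κ = 2, ω0 = 0.1,
p0 = 0.75, p1 = 0.15 (hence 10% foreground-selected sites), ω2 = 5 — a
regime where the test should reject in more than half of replicates at
500 codons while remaining calibrated under ω2 = 1.
`simulate_population()` mutates haplotypes independently from a common
reference at a low per-site probability (default 10⁻³), emulating
near-monomorphic high-altitude population samples.

One integer seed drives each generator call; identical configuration and
seed give byte-identical output. The generator does **not** emulate
sequencing error, indel evolution, alignment uncertainty, gene
rearrangement, recombination (absent in mitochondria), or selection on
background branches; passing tests therefore demonstrate correctness of the
statistical machinery under the stated generative model, not robustness to
real-data artefacts such as misalignment or annotation error.

## Problem sizes and runtime choices

The bundled statistical checks use 3-taxon × 2-codon instances for the
exhaustive-enumeration oracle (20 replicates), 200 null simulations and 50
power simulations at 8 taxa × 300–500 codons for LRT calibration and power,
and 100 random constructions for repeat recovery — sizes chosen so the whole
suite completes on a single desktop core in well under half an hour while
keeping Monte-Carlo error small relative to the asserted margins (the null
rejection band is the binomial 2σ interval). The acceptance script uses 150
null and 40 power replicates for the same reason. Larger studies only
tighten the same comparisons.

## Known limitations

* The branch-site fit fixes κ and the branch-length scale at their M0
  estimates; joint re-estimation would change log-likelihoods slightly
  (not the test's calibration, which the null simulations verify).
* BEB fixes the rate-matrix scaling at the MLE across the grid.
* The repeat detector is a deliberately simple scorer, not a probabilistic
  reimplementation of a full tandem-repeat finder; very diverged or
  indel-rich arrays will be under-merged.
* Real-data workflows (GenBank panels, codon-aware alignment) are supported
  at the I/O level, but alignment itself is out of scope — aligned input is
  expected.
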