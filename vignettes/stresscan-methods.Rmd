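---
title: "stresscan: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{stresscan: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of what it computes, which
choices were genuinely open, and what its tests do and do not establish.

## The analysis model

The package takes, for a control and a perturbed condition, per-base
coverage of five assays: γH2AX (a chromatin mark of DNA damage), the
unphosphorylated H2AX variant and histone H3 (controls for nucleosome
occupancy), RNAPII ChIP (chromatin-bound polymerase) and GRO (nascent
transcription, strand-resolved). Coverage is modelled as piecewise-constant
non-negative signal; positions absent from a bedGraph read as zero, which
matches that format's semantics.

**Per-gene quantification.** Every gene is scored by its mean signal per bp
over the gene body extended by a 500 bp flank on each side, clamped to the
chromosome (`gene_window()`, `gene_density()`). GRO is quantified on the
gene's sense strand only, because nuclear run-on is strand-resolved while
ChIP is not. Cross-condition ratios are formed per gene; for the
histone-mark assays the density is first divided by the H3 density *within
the same condition*, so nucleosome-occupancy differences cancel:

    r_g = (γH2AX_g / H3_g)_case / (γH2AX_g / H3_g)_control

H3 normalisation is deliberately per gene, not per bin; per-bin
normalisation is used only inside metagene profiles, where a ratio of
aggregated bin means is exposed as an option.

**Damage ranking.** Active genes are ranked by `r_g` descending; the top
`round-half-up(0.10 n)` genes form the high-damage set. Round-half-up is
not incidental: it is the only simple rounding rule that gives a 414-gene
set from 4140 eligible genes and a 216-gene set from 2158. Damage Z-scores
are computed on `log2 r_g` (sample sd), the log making gains and losses
symmetric. Whether ranking uses the raw ratio or its Z is a free choice
that does not change the ordering; both are exposed
(`damage_rank(statistic=)`).

**Stress calls.** A gene is under transcription stress when its RNAPII
ratio exceeds 1 while its GRO ratio is below 1 — strict inequalities on
both, so boundary values (1.0, 0.9) and (1.2, 1.0) are negative. The field
describes this as RNAPII accumulation uncoupled from nascent-RNA output.
No single "stress intensity" statistic is canonical; the package ranks
stress genes by `rnapii_ratio / gro_ratio`, which is monotone in both
defining criteria and directly measures the uncoupling. This is a design
choice, documented rather than hidden, and the ranking function accepts the
two ratios so alternatives are easy to add.

**Active genes.** There is no canonical operational definition of "actively
transcribed". The package uses: control-condition sense-strand GRO density
strictly above a threshold (default 0) *and* window total signal of at
least `activity_min_total` (default 10 units), both exposed in
`pipeline_config()` and logged in the summary. All decile selections are
made within the active set.

**Enrichment statistics.** Set overlap uses the hypergeometric upper tail
`P(X ≥ k)` (the standard over-representation convention; the ≥ vs >
distinction is easy to get wrong silently, hence it is stated in the
function contract and tested). The default universe is the active-gene
set, since every set being compared is drawn from it; `universe = "all"`
is available because the choice is not forced by the data. Rank enrichment
uses the two-sample Kolmogorov–Smirnov statistic comparing subset vs
complement score distributions, with the asymptotic p-value by default:
exact two-sample KS is infeasible at thousands of genes, and the
asymptotics are accurate there (`exact = TRUE` exists for small sets and
is verified against full permutation enumeration in the tests). Location
comparisons (gene length, expression) report both Mann–Whitney and Welch
t, the two tests conventionally used for such panels.

**Mutation burden.** For a targeted panel of `L` bp (computed after
merging overlapping intervals, so overlapping amplicons are not
double-counted), the de novo count between a baseline and an endpoint call
set — matched on chrom/pos/ref/alt, presence/absence only, since events
rather than allele fractions are the quantity of interest — is tested
against `Binomial(L, 1 − (1 − μ)^g)`, upper tail, in log space.
μ defaults to 6×10⁻⁸ per site per generation (a standard estimate for
cultured mouse cells) and `g` to 45 doublings. The binomial is primary and
the Poisson limit serves as an independent oracle in the tests (they agree
within 1% relative at `L = 5×10⁴`). `p_site` is computed as
`-expm1(g * log1p(-mu))` to avoid cancellation at realistic μ.

## The synthetic generator

`generate_dataset()` emulates the study the analysis is designed for:

* **Genes.** 4140 genes (the default matches the size of a typical active
  set in a fibroblast line) placed without overlap on 8 × 12 Mb
  chromosomes, intergenic gaps ≥ 2 kb so neighbouring ±500 bp windows
  stay disjoint. Lengths are log-normal: the planted damaged subset
  (10%) with median ≈ 4.1 kb, the rest tuned so the overall median is
  ≈ 10.6 kb — damaged genes are short. Their expression (gamma-distributed
  density) is drawn with twice the mean of the background — damaged genes
  are highly expressed.
* **Effects.** Damaged genes carry a 1.5× γH2AX/H3 case:control ratio
  (damage raises the mark by about half); stressed genes carry RNAPII ×1.3 and GRO ×0.95.
  The stressed set equals the damaged set by default and can be decoupled
  (`fraction_stressed`) because partial overlap regimes need testing too.
* **Tracks.** Control: flat H3/H2AX, constant γH2AX inside genes (zero
  intergenic — the mark is depleted outside transcribed regions), RNAPII
  and sense-strand GRO proportional to expression, with a promoter-
  proximal RNAPII peak. Noise is per-bin Poisson: counts with expectation
  density × bin width (50 bp), density = counts/width. This is the
  simplest generative model consistent with read-derived coverage; the
  real data's noise model is unknown, so Poisson is the package's choice,
  not a claim about the study. Gene coordinates are aligned to the bin
  grid, which keeps noiseless per-gene ratios *exactly* equal to the
  planted effects — the anchor for the exact-recovery tests.
* **Classes and fragile sites.** 1.47% of genes are histone-like, drawn
  with elevated odds from the damaged subset (weight 6.8, putting ≈ 40% of
  them in the damaged set). Fragile-site intervals cover undamaged genes
  with probability 0.12 and damaged genes with 2.5× the odds (≈ 25%
  coverage), ± 1 kb flanks, merged.
* **Mutations.** A panel of 8 histone-like + 1 other gene (of order
  50 kb) accumulates per-site mutations with probability
  `1 − (1 − μ)^g`; the perturbed condition multiplies μ by 50
  (a hypermutator), the control leaves it at the null rate. Substitutions,
  insertions and deletions are drawn 70/15/15 in minimal representation.
  Panel composition and baseline variants sit on their own RNG stream so
  both conditions share them, as two populations split from one ancestor
  would.

All stages draw from per-stage RNG streams derived from one master seed:
adding a stage cannot perturb earlier draws, and identical configs are
bit-identical.

**What the generator does not emulate** — and what passing tests therefore
do not show about real data: mappability and GC bias, replicate-to-
replicate variability, overlapping genes, overdispersion beyond Poisson,
non-uniform fragment-level autocorrelation of coverage, replication
timing, and sequencing error in the variant calls. Recovery and
calibration results on synthetic data bound the pipeline's correctness,
not real-data performance.

## Numerical choices

* **Pseudocount.** Ratios are `(case + ε)/(control + ε)`. The default ε is
  1% of the median per-gene density of the assay (conditions pooled) — a
  scale-free guard against near-silent genes. A genome-wide per-base
  median was rejected because the sparse assays (γH2AX, GRO) are zero over
  most of the genome, which would make the guard vanish exactly where it
  is needed. With ε = 0 a 0/0 ratio yields `NaN` with a warning — flagged,
  never silently dropped.
* **Tie-breaking.** All rankings break ties lexicographically by gene
  identifier, so results are permutation-invariant and reproducible.
* **Degenerate inputs.** Zero library totals, zero-variance Z-scores,
  empty gene sets, empty subset or complement in KS, constant samples in
  the t-test, `k > min(n, K)` overlaps: all raise immediate errors naming
  the problem rather than propagating NaN.
* **Library scaling.** `library_scale()` provides signal-per-million
  factors, but the pipeline default is `library_norm = "none"`: the
  generator (like most deposited tracks) emits depth-calibrated densities,
  and unconditional rescaling would break the exact noiseless identity
  between measured and planted ratios. Count-scale inputs should enable
  `"spm"`.
* **Extreme tails.** Hypergeometric and binomial tails are available in
  log space (`log.p`, `log_p`), stable far beyond the smallest positive
  double.

## Test and simulation sizes

The suite runs synthetic studies of 40–300 genes on 2–4 Mb chromosomes
(seconds each), 200–300-seed Monte-Carlo checks of generator marginals,
and 1000-replicate null calibrations at 2000 genes; the acceptance script
runs the full 4140-gene default once. These sizes were chosen so the whole
suite stays desk-scale while keeping Monte-Carlo error well below the
asserted margins.

One calibration subtlety is worth recording. Under a global null with
*heterogeneous* per-gene depth, the per-gene ratio noise is larger for
low-coverage genes in every assay at once, so the top-damage and
top-stress selections are both enriched for the same noisy genes and
their overlap is genuinely non-uniform — that is a property of ranking
noisy estimates, not a miscalibration of the hypergeometric test. The
null-calibration tests therefore use uniform depth (iid ratios), which is
the regime the calibration claim is about; on real data, damage ranking by
raw ratio inherits this depth coupling, and a variance-stabilised or
count-aware ranking would be the remedy if it matters.

## Known limitations

* Overlapping genes are quantified independently; no signal apportioning
  is attempted because no deconvolution rule is forced by the data.
* Single tracks per condition: no replicate-aware variance modelling, so
  per-gene ratios carry no confidence intervals.
* The stress score and the activity threshold are reasonable but not
  unique choices; both are parameters, not facts.
* The burden test's `L` must come from the panel definition; p-values are
  meaningless without an honest panel size.
* The KS p-value is asymptotic at genome scale and underflows to zero for
  extreme separations; the log-space hypergeometric is the better tool
  there.
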