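---
title: "splicemap: models, corrections and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{splicemap: models, corrections and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

splicemap maps cis splicing QTLs from three sample-aligned tables —
genotype dosages, percent-spliced-in (PSI) values of alternative-splicing
(AS) events with per-sample quality flags, and covariates — and then
characterises the called sQTL SNPs against functional annotations,
regulatory tracks and GWAS loci. This vignette is the package's own
account of the statistics it implements, the knobs that matter, and the
choices made where the design was genuinely open.

## The association model

For each SNP–event pair within the cis window we fit, by ordinary least
squares,

$$\mathrm{PSI}_{e,i} = \beta_0 + \beta\, g_i + \gamma^\top C_i + \varepsilon_i,
\qquad \varepsilon_i \sim N(0, \sigma^2),$$

with $g_i \in \{0,1,2\}$ the alt-allele dosage and $C_i$ the covariate row
(numeric covariates centred; categorical covariates expanded into
indicator columns for all non-reference levels). The two-sided p-value for
$\beta$ uses the t distribution with $n - k - 2$ residual degrees of
freedom ($k$ retained covariate columns, plus intercept and genotype);
at cohort sizes of a few hundred the exact t reference costs nothing and
avoids the slight anticonservativeness of a normal approximation.

Assumptions worth keeping in mind: effects are additive in dosage (no
dominance or interaction terms), residuals are treated as Gaussian even
though PSI is bounded in [0, 100], and each pair is fitted independently.
Bounded-response distortion matters mainly for events whose baseline sits
near 0 or 100 — exactly the events the degenerate-PSI filter tends to
remove first.

Missing-data policy: missing dosages are mean-imputed per SNP before
regression (the convention of matrix-based eQTL engines, which keeps the
design matrix complete and shrinks $\beta$ slightly rather than dropping
samples); missing PSI drops the sample for that pair only. A pair is
skipped, with a reason code in the `skipped` attribute, when fewer than 10
usable samples remain or the dosage has zero variance after imputation; a
constant PSI vector returns $\beta = 0$, $p = 1$. Rank-deficient covariate
columns are pruned with a warning; if the genotype column itself is
aliased the pair is skipped rather than silently refitted.

## The double correction

Raw pair p-values are Benjamini–Hochberg adjusted **once, jointly over all
tested cis pairs** — adjusting per chromosome or per chunk changes the
result, and a counter-example test enforces that this is not done. Then,
per SNP,

$$p_{\text{double}} = \min\bigl(1,\; \min_{e \in \text{window}} p^{BH}_{g,e}
\times n_{\text{local events}}\bigr),$$

and the SNP is called an sQTL when $p_{\text{double}} < \alpha$ (default
0.05). The local multiplier counts **all filtered AS events** whose gap
distance to the SNP is strictly below the window, not just the pairs that
were actually testable — the penalty reflects splicing opportunity, not
test bookkeeping, so an event skipped for missingness still counts.
The rationale for the second layer: a SNP with many local events gets many
chances at a small minimum, and the per-SNP Bonferroni makes the minimum
honest.

Best-SNP-per-event extraction takes, among called sQTL SNPs paired with an
event, the smallest raw p; ties break by smaller distance, then
lexicographic SNP ID — fully deterministic.

## Windows, boundaries and coordinates

Every threshold in the package is strict, and each strictness is pinned by
a boundary test:

* cis window: gap distance `< 100000` bp (a SNP exactly 100 kb away is
  out; `inclusive = TRUE` on `filter_snps()` flips this, since the
  convention at exactly 100 kb is ambiguous in common usage);
* event QC: drop when quality fails in `> 20%` of samples, then when PSI
  is exactly 0 or 100 in `> 90%` of the samples with non-missing PSI
  (fractions over non-missing values, because real PSI tables have
  per-sample coverage gaps); the order — quality first, degeneracy second
  — is fixed, and an audit attribute partitions the input events;
* MAF: keep `maf >= 0.01`, with MAF recomputed on the analysis sample set
  after the three tables are intersected;
* non-sQTL universe: minimum uncorrected p `> 0.05`;
* locus expansion: r² `> 0.6`; triage LD: r² `> 0.8`; GWAS significance:
  p `< 5e-8`; MHC mask: chr6:28,477,797–33,448,354, **inclusive** at both
  ends.

Coordinates are 1-based inclusive everywhere except at the BED boundary,
where intervals are 0-based half-open and a SNP at 1-based position $p$ is
a member iff $p - 1 \in [\text{start}, \text{end})$.

Gap distance to an event span is 0 inside the span, else the distance to
the nearer span end.

## LD, pruning and matched controls

LD is the squared Pearson correlation of unphased dosage vectors over
pairwise-complete samples — close to PLINK's composite measure and
phasing-free. Pruning mirrors `--indep-pairwise 50 5 0.5`: a 50-SNP window
advancing by 5; within a window, while any surviving pair exceeds
r² = 0.5, the pair with the largest r² is resolved by removing its
lower-MAF member (MAF tie: the later position). Removing the lower-MAF
SNP keeps the more informative variant, which is what pruning is for; the
published parameters fix only 50/5/0.5, so the removal rule is our
documented choice. The survivors provably contain no within-window pair
above the threshold, and a test verifies this exhaustively on block-LD
panels.

MAF matching stratifies both sets into 2% bins ([0, 0.02), …,
[0.48, 0.50]) and scales: with $s = \min_b \text{controls}_b /
\text{sQTLs}_b$ over occupied bins, each bin contributes
$\lfloor s \cdot \text{sQTLs}_b \rfloor$ controls, topped up by largest
remainder to hit $\lfloor s \cdot \text{sQTL total} \rfloor$ exactly;
sampling within bins is without replacement and seed-deterministic.
Proportional scaling is one consistent reading of "matched by 2% bins";
capping at the sQTL histogram would be another, and would produce smaller
control sets. The per-bin proportion error is bounded by one over the
smallest occupied bin's sQTL count.

## Enrichment machinery

`fisher_2x2()` computes the exact p by hypergeometric enumeration
(two-tailed: all tables with probability ≤ the observed, with the
customary $1 + 10^{-7}$ relative slack for floating-point ties;
one-tailed: the upper tail). The reported OR is the sample cross-product
ratio, with Haldane–Anscombe +0.5 on all cells only when a zero cell
occurs, and a Woolf logit 95% CI; the conditional-MLE OR (what
`stats::fisher.test()` estimates) is available via `or_method = "cmle"`.
The cross-product default is the simplest convention that a reader can
recompute from the printed 2×2 counts. Degenerate tables — a feature row
empty or full in both sets — carry no conditional information and are
reported as p = 1 with the corrected OR rather than as errors.

Functional classification resolves multi-label annotations to the
highest-impact label in the fixed 13-class order (nonsense → … →
intergenic); unlabelled SNPs are intergenic. The class family tests ten
types (nonsense/readthrough/start-loss/frameshift pooled as "other
loss-of-function"), each Bonferroni-corrected by 10, plus a pooled
exonic-vs-rest test on its own. Track families are corrected by the
number of retained tracks after the record-count floor; genome-scale TF
compendia conventionally use a 50,000-record floor, which is exposed as
`min_records` (the synthetic tracks are far smaller, so the pipeline
default is 0). The GWAS-locus test is one-tailed in the enrichment
direction, with a 15-trait family correction by default and optional
exonic / non-exonic / no-IR subsets and MHC masking for sensitivity
analyses.

## Triage

A called sQTL SNP is nominated for a locus when all three criteria hold —
r² to the resolved index SNP strictly above 0.8, its own GWAS p strictly
below 5×10⁻⁸, and credible-set membership. Each criterion is individually
necessary (relaxing any one can only enlarge the set; tested). When a
declared index SNP is absent from the LD reference, the most significant
genotyped SNP in the locus substitutes (ties: position, then ID); a locus
with no genotyped SNP is skipped with a warning. All qualifying SNPs per
locus are reported, ranked by double-corrected p, since suppressing
secondary credible-set sQTLs would hide exactly the records a reviewer
would want to see.

## What the generator emulates — and what it does not

`simulate_study()` produces one chromosome with:

* **Genotypes**: SNP positions uniform without replacement; consecutive
  blocks of `ld_block_size` SNPs share a per-haplotype latent Gaussian
  with weight `within_block_rho`, thresholded at each SNP's target MAF
  quantile; dosage is the sum of two haplotypes. This gives tunable
  within-block r² and exact between-block independence. The latent-
  threshold construction was chosen over copying real LD because every
  downstream check needs a controllable, seed-reproducible r² structure.
* **PSI**: latent Gaussian around a uniform 20–70 baseline, plus
  `effect_size_psi` per alt allele for the planted causal pairs, plus
  covariate terms (age, RIN-like score, 3-level site), clipped to
  [0, 100]. Gaussian-then-clip matches the additive linear model actually
  fitted; a logit-normal generator would be more realistic at the
  boundaries but would make the planted β not the estimand. Events whose
  latent values leave [0, 100] in more than half the samples trigger a
  warning. Quality flags fail independently at `quality_fail_rate`.
* **Annotations/GWAS**: multi-label functional classes with
  intron/intergenic dominating; random element and TF interval tracks;
  risk loci spanning the LD block of each selected causal SNP. The locus
  index SNP is the planted causal SNP itself — as at real loci where the
  top GWAS variant is the splicing variant — and the credible set holds
  the causal SNP plus decoy IDs absent from the genotype panel. This
  construction keeps LD block mates of the causal SNP (which are
  correctly called sQTLs, but are not the planted variant) out of
  credible sets, so triage precision measures the criteria rather than
  the generator's leakage. Decoy "null" loci are placed in SNP-free gaps.

All randomness derives from a single seed through fixed per-stage offsets,
so identical configurations are byte-identical.

Not emulated: read-level noise and PSI quantification error, sequence
determinants of splicing, population structure and relatedness, multiple
chromosomes, trans effects, and realistic annotation geometry (tracks are
uniform, not promoter-biased). Passing tests therefore demonstrate that
the *statistical machinery* behaves as specified under its own model —
type-I control, power at the planted effect size, boundary exactness —
not that the pipeline is robust to quantification artefacts or stratified
cohorts.

## Reference scales and defaults

The default `sim_config()` — 200 samples, 2,000 SNPs, 200 events, 20 Mb,
blocks of 10 at latent correlation 0.8, MAF in [0.05, 0.5], 50 causal
pairs at 8 PSI units per allele against noise SD 5, causal MAF ≥ 0.2 —
keeps SNP and event densities of the same order as a genome-wide cohort
(one SNP per 5–10 kb) while the full pipeline runs in seconds. At these
settings a planted effect has a t-statistic around 15, so recovery is
essentially complete and the interesting margins are the corrections, the
matched sets and the triage criteria. The multi-seed operating
characteristics in the test suite use a 1,000-SNP / 100-event variant of
the same configuration.

## Known limitations

* The Gaussian-clipped noise model understates uncertainty for events
  pinned near 0/100; a sensitivity re-run with a logit-normal generator
  would quantify this.
* Mean imputation of missing dosages biases $\beta$ toward zero at high
  missingness; the package inherits this deliberately for comparability
  with matrix-eQTL-style engines.
* The pruning result depends on window phase for pairs 46–49 SNPs apart
  (a consequence of the 5-SNP stride, shared with the reference
  implementation of `--indep-pairwise`).
* Fisher enrichment treats SNPs as exchangeable; residual LD within the
  pruned sets still induces mild dependence that the test ignores.
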