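---
title: "Calling variable and stable methylation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling variable and stable methylation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(methvar)
```

# The problem

Whole blood is the workhorse tissue of epigenome-wide association studies,
yet most CpG sites on a methylation array barely vary between people.
Separating the probes that genuinely differ across individuals (variably
methylated positions, VMPs) from those that are essentially fixed (stably
methylated positions, SMPs) gives a reference catalogue: a VMP hit in an
association study is plausible biology, an "association" at an SMP is a red
flag, and the variable fraction itself is the substrate for studies of
genetic control, cell composition and epialleles.

`methvar` implements such a cataloguing pipeline end to end on beta-value
matrices (methylated / total signal, in $[0,1]$), together with the
downstream characterisation stages, and a synthetic-data generator that
plants known structure so that every stage can be validated against ground
truth.

# The variability caller

For a probe-by-sample matrix the caller:

1. removes `floor(drop_fraction * n)` samples uniformly at random
   (default 10%), to protect the call against outlier individuals;
2. computes each probe's sample standard deviation (SD, $n-1$ denominator)
   over the retained samples, on the beta scale;
3. labels the `floor(q * P)` probes of highest SD as VMPs and of lowest SD
   as SMPs (default deciles, `q = 0.10`);
4. repeats 1-3 `n_repeats` times (default 10) and keeps only probes
   selected in *every* repeat;
5. runs the whole procedure independently on a discovery and a validation
   cohort and intersects the two, yielding the final catalogue.

Choices the procedure leaves open, fixed here as follows:

* **Seeds.** Repeat $i$ of the discovery cohort uses `rng_seed + i`;
  validation repeats continue the sequence at `rng_seed + n_repeats + i`.
  Downsampling draws are keyed to *sorted sample ids*, so column order is
  irrelevant and two runs with the same seed are identical.
* **Ties and truncation.** Both the drop count and the decile size use
  `floor()`; SD ties at the cut go to the lexicographically smaller probe
  id. Ties are astronomically unlikely on real data but make the contract
  deterministic.
* **Per-run thresholds.** The SD decile is recomputed within every
  downsampled replicate rather than fixed globally; the per-replicate
  selection is what makes the repeat-intersection meaningful.
* **Strictness.** A probe must appear in all `n_repeats` replicates of
  *both* cohorts. Partial membership (9/10) is "neither".
* **Missing values.** Probes with more than `max_missing_fraction`
  (default 5%) missing betas in either cohort are dropped up front and
  reported with `NA` calls; otherwise SDs use the available samples.
  Array preprocessing usually delivers complete matrices, so this path is
  a guard rail rather than a modelling choice.

# Cell-composition correction

Blood methylation mixes six major cell types (CD8T, CD4T, NK, B, Mono,
Gran); compositional drift between individuals masquerades as methylation
variability. The correction regresses each probe on an intercept and
*five* of the six Houseman proportions — the six sum to ~1, so one is the
complement of the others and must be excluded; NK is the default exclusion
(highest variance relative to abundance). The corrected value is
**intercept + residual**, per probe and sample, deliberately *not* clipped
to $[0,1]$ (the out-of-range rate is recorded instead) and *not*
re-centred: a probe that is exactly `0.2 + 0.6*CD4T` corrects to the
constant 0.2. Consequently the corrected mean equals the model intercept,
not the raw mean, whenever covariates have non-zero means — the two
coincide only under centred covariates, which this parameterisation does
not use.

The corrected catalogue is rebuilt with the *same* seeds as the raw one,
so differences between the two reflect the correction and not resampling
noise. OLS guarantees the corrected variance can never exceed the raw
variance; residual orthogonality to each included proportion is exact to
numerical precision.

# Genomic-context enrichment

Each probe carries one island relation (island / shore / shelf / open
sea), any number of features (exon, intron, 5'UTR, 3'UTR, promoter,
enhancer, intergenic, TE — multi-feature probes count once in every
feature they carry), and flags (imprinted, non-CpG, 450K). Enrichment of a
probe set against the array background reports
$\log_2\!\big((k/m)\,/\,(K/M)\big)$ — observed over expected fraction —
marked *undefined* (never $\pm\infty$) when either fraction is zero, and a
two-sided Fisher exact p-value. The 2×2 contrast excludes the test set
from the background column so the two columns are disjoint. The
imprinted-region test is a permutation test: `n_reps` (default 1000)
random sets of the observed size drawn from the background without
replacement, with the add-one estimate
$p = (1 + \#\{\text{overlap} \ge \text{observed}\})/(n_{\text{reps}}+1)$,
so $p \in [1/(n_{\text{reps}}+1),\,1]$ by construction. Draws are
unconstrained (chromosome composition is not preserved).

Housekeeping labelling follows the top-40% rule: a gene is housekeeping
iff its within-tissue percentile rank (average ranks for ties) is at least
0.6 in every tissue; a constant tissue column leaves all genes tied and
passes them for that tissue.

# mQTL annotation and 3D co-occupancy

"cis" is used at nucleosome scale: a SNP-CpG pair is cis iff the two lie
on the same chromosome at most `cis_window_bp` apart (default 500 bp,
about three nucleosomes; a pair at exactly 500 bp is cis). Everything
else — greater separation or different chromosomes — is trans, and a CpG
with both kinds of partners is "cis_and_trans". This window is a
deliberate departure from the conventional megabase-scale definition: it
isolates effects of sequence variation in or immediately flanking the
probe.

TADs arrive as BED (0-based half-open; a 1-based position $p$ is inside
$[s,e)$ iff $s < p \le e$ — a position exactly at the interval end is
outside), loops as BEDPE anchor pairs. A pair is *same-TAD* iff one TAD
contains both positions (TADs must be non-overlapping within a
chromosome; overlap is an error, not a silent choice), and
*loop-connected* iff some loop holds the SNP in one anchor and the CpG in
the other — both positions in the same single anchor do not count.
Co-occupancy enrichment contrasts a pair set against the all-mQTL-pair
background with the same Fisher machinery as above.

# The dip test and epiallele screening

A putative epiallele is a VMP whose pooled-cohort mean beta lies in the
inclusive window $[0.40, 0.60]$ and whose cross-individual distribution
is bimodal. Bimodality is assessed with Hartigan's dip statistic — the
smallest sup-norm distance between the empirical CDF and any unimodal CDF
(convex below its single mode, concave above, a jump allowed only at the
mode). The dip is bounded by $1/(2n)$ below and $0.25$ above, the maximum
being attained by two equal point masses.

The statistic is implemented from scratch in C++ by iterative narrowing
of the modal interval over greatest-convex-minorant / least-concave-
majorant hulls of the empirical CDF. It is validated in the test suite
against an independent brute-force minimiser that solves, for every
candidate mode placement, an exact linear program over piecewise-linear
unimodal CDFs; the two agree to $10^{-10}$ and better across hundreds of
samples including ties and adversarial spacings.

Two properties worth stating precisely:

* The dip is invariant under permutation of the input and under affine
  maps $x \mapsto ax+b$ ($a \neq 0$). It is **not** invariant under
  general monotone transforms: a nonlinear stretch changes which CDFs are
  convex-then-concave, hence the distance to the unimodal class.
  Concretely, `dip(1,2,3,4) = 0.125` while `dip(0, 0.01, 0.99, 1)` is
  near the 0.25 maximum — the same ranks, very different geometry. (This
  non-invariance is also what makes the uniform the *least favourable*
  unimodal null; under rank invariance every continuous null would give
  the same dip distribution and that phrase would be vacuous.)
* Degenerate all-equal samples return the minimal dip $1/(2n)$ with a
  `degenerate` attribute, never an error: a constant candidate in the
  screen is reported, not fatal.

P-values are Monte Carlo against the standard uniform (`B = 2000` draws
of the candidate's sample size by default), with the add-one estimate, so
$p \in [1/(B+1), 1]$. Within one screen all complete candidates share a
single null sample — they share a sample size, marginal p-values are
unchanged, and the screen runs in seconds; a candidate with missing
values gets its own null at its own $n$. The flag applies the unadjusted
threshold `dip_alpha = 0.05`; a Benjamini-Hochberg column over the
tested candidates is emitted alongside for users who want it, but takes
no part in the flag. Uniform order statistics for the null are generated
pre-sorted by the exponential-spacings construction, so no sort is
needed.

# Expression integration

Two modes, mirroring the two data situations:

* **Variation vs variation** (unmatched cohorts): Pearson correlation,
  per genomic feature group, between per-probe methylation SD and
  target-gene expression CV (SD/mean; genes with non-positive mean are
  excluded and counted). Probes map to their manifest gene (first listed
  when several; empty-gene probes dropped and counted). Groups with fewer
  than 3 pairs report `NA`.
* **Level vs level** (matched samples): per probe-gene pair, Pearson
  correlation across the samples shared by the two matrices (at least 3),
  summarised per feature group by the mean r.

# What the synthetic generator emulates

Each probe belongs to one of six classes, all sampled from beta
distributions in the mean/concentration parameterisation
($\alpha = \mu k$, $\beta = (1-\mu)k$), which respects the $[0,1]$ support
and matches array practice:

| class | default share | mechanism | typical SD |
|---|---|---|---|
| stable_low / stable_high | 0.20 + 0.20 | $\mu \approx 0.05 / 0.95$, $k = 200$ | 0.015 |
| variable_unimodal | 0.35 | $\mu \in [0.4, 0.6]$, per-probe $k \in [6, 40]$ | 0.08-0.19 |
| epiallele_bimodal | 0.05 | equal-weight mixture at modes 0.25 / 0.75, per-sample component | 0.26 |
| cell_driven | 0.10 | $\mu = b + \text{effect} \cdot \text{Gran}$, per-probe effect in $[0.8, 2.0]$ | 0.09-0.17 |
| mqtl_driven | 0.10 | $\mu = b + \text{effect} \cdot g$, $g \sim$ Hardy-Weinberg(MAF 0.3), effect in $[0.10, 0.25]$ | 0.07-0.16 |

Defaults are one fixed choice of "realistic at desk scale": 2000 probes,
400 + 400 samples, six-cell Dirichlet proportions around typical blood
composition (Gran 0.55, CD4T 0.17, ...) at concentration 30, 21% cis mQTL
pairs, 90% of trans pairs placed within a shared TAD, 10% connected by a
planted loop, 5% of trans pairs on another chromosome. Per-probe
heterogeneity of effect sizes (slope and concentration ranges) gives the
SD spectrum a continuous right tail, so the decile boundary falls inside
a mixture of mechanisms rather than between well-separated blocks — as
on a real array. Cell-driven baselines are chosen so the population-mean
methylation sits mid-range, preventing saturation of the beta scale at
large slopes. Out-of-range means are clipped into $(0,1)$; the clip rate
is recorded on the bundle and stays well below 1% at the defaults.

Expression is Gamma-distributed per gene with the per-gene CV tied to the
gene's probe methylation SD through a Gaussian copula on ranks at
$\rho = 0.6$; epiallele probes carrying the 5'UTR feature instead receive
an expression profile that decreases linearly in the probe's betas — the
planted signal for the matched-sample mode. Genomic context is planted
with a shore/enhancer bias in the variable classes and a non-CpG bias in
the stable classes, so enrichment recovery is testable.

What the generator does *not* emulate, and what passing tests therefore
do not show: probe-sequence artefacts and cross-hybridisation, chip and
batch effects, linkage disequilibrium between SNPs, age/sex/smoking
structure in the betas (covariates are decorative), spatial correlation
of neighbouring CpGs, and realistic TAD nesting. Results on synthetic
bundles validate the *machinery*, not biological effect sizes.

# Problem sizes and runtimes

The test suite simulates bundles of 600-2000 probes and 120-800 samples;
the parameter-recovery check runs the full caller on 2000 probes x 400 +
400 samples, and dip calibration uses 2000 uniform trials at $n = 500$
with $B = 2000$ null draws each (the C++ dip computes a sample of that
size in microseconds). The analysis scripts and the acceptance script use
the 2000-probe default design. Everything is seeded; reruns are
byte-identical.

# Known limitations

* The dip's Monte-Carlo null is exchangeable within a screen but the
  per-probe p-values are then correlated across probes; the BH column
  inherits that correlation (standard for pooled-null permutation
  schemes).
* The catalogue treats cohorts symmetrically; there is no support for
  more than two cohorts or for weighting them by size.
* `cis_and_trans` CpGs are reported as their own class; collapsing them
  into cis or trans percentages (to make the two sum to 100%) is left to
  the caller, since any collapse rule is arbitrary.
* Corrected betas can leave $[0,1]$; downstream stages accept this, but
  plotting code that assumes the unit interval should use the recorded
  out-of-range rate as a sanity check.
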