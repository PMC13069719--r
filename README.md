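# methvar

Cataloguing interindividually **variable** (VMP) and **stable** (SMP) DNA
methylation in whole blood, and characterising what drives the variable
fraction.

Most CpG sites on a methylation array barely differ between people; the
minority that do are where genetics, cell composition and epigenetic
polymorphism show up. `methvar` is an R package plus analysis workflow
that builds a robust VMP/SMP catalogue from EPIC-style beta-value
matrices and then runs the downstream characterisation stages:

* **Variability calling** — per-probe SD on the beta scale; ten runs per
  cohort, each on a random 90% of samples; the top and bottom SD deciles
  per run; a probe is called only if selected in *every* run of *both* a
  discovery and a validation cohort.
* **Cell-composition correction** — per-probe OLS on five of the six
  Houseman cell proportions (NK excluded as the dependent remainder);
  corrected value = intercept + residual; the catalogue is rebuilt on
  corrected values with the same seeds to see which calls were
  cell-driven.
* **Genomic-context enrichment** — log2(observed/expected) per island
  relation, feature and flag against the array background, with
  two-sided Fisher exact tests and a permutation test for
  imprinted-region overlap.
* **mQTL annotation** — SNP-CpG pairs are *cis* iff within 500 bp
  (nucleosome scale; boundary inclusive), else *trans*; per-CpG
  cis/trans/cis-and-trans classes; same-TAD and chromatin-loop
  co-occupancy of trans pairs (BED/BEDPE inputs, half-open conventions)
  with enrichment against the all-pair background.
* **Epiallele screening** — VMPs with pooled mean beta in [0.40, 0.60]
  whose cross-individual distribution is bimodal by **Hartigan's dip
  test**, implemented from scratch in C++ (dip = minimal sup-norm
  distance between the empirical CDF and any unimodal CDF; Monte-Carlo
  uniform null, add-one p-values).
* **Expression integration** — Pearson correlation of methylation SD
  with target-gene expression CV (unmatched cohorts), and of methylation
  level with expression level across matched samples, stratified by
  genomic feature.
* **Synthetic data** — a generator that plants all of the above
  (stable/unimodal/bimodal probe classes, granulocyte-driven and
  Hardy-Weinberg-genotype-driven probes, TAD/loop structure,
  copula-coupled expression dispersion) so every stage is testable
  against ground truth.

The methods vignette (`vignettes/methylation-variability.Rmd`) documents
the models, parameters, numerical conventions and design decisions.

## Worked example

The numbered scripts under `analysis/` run the whole study on a
simulated 2000-probe, 400+400-sample bundle (`Rscript
analysis/01_simulate.R`, then `02`...`07`; outputs land in `results/`).
Script 02 prints, for seed 1:

```
Final catalogue: 172 VMPs, 124 SMPs of 2000 probes
True classes among VMPs:
      cell_driven epiallele_bimodal       mqtl_driven variable_unimodal
               23               100                 3                46
```

All 100 planted bimodal-epiallele probes and the strongest unimodal,
cell-driven and genotype-driven probes are called VMP; SMPs are drawn
exclusively from the planted stable classes. Script 03 then reports

```
VMPs lost after correction: 23 (13.4%); SMPs lost: 2 (1.6%)
True classes among lost VMPs:
cell_driven
         23
```

— exactly the cell-driven calls disappear once composition is regressed
out. Script 06 screens the VMPs for epialleles:

```
Candidates (VMP, mean in [0.40, 0.60]): 165; flagged: 102
Detection among planted bimodal candidates: 100.0% (n = 100)
Flag rate among planted unimodal candidates: 0.0% (n = 44)
```

and script 07 isolates the planted expression signal: the matched-sample
mean correlation is -0.98 in the 5'UTR feature group and below 0.02 in
magnitude everywhere else.

Equivalent programmatic use:

```r
library(methvar)
bundle <- simulate_bundle(simulation_design(rng_seed = 1))
cfg <- methvar_config(rng_seed = 1)
catalog <- call_catalog(bundle$betas_discovery, bundle$betas_validation, cfg)
epi <- screen_epialleles(cbind(bundle$betas_discovery,
                               bundle$betas_validation), catalog, cfg)
sum(epi$is_epiallele)
```

`run_pipeline(cfg, inputs, out_dir)` runs every stage on files and
writes the result tables plus the configuration snapshot; reruns with
the same seed are byte-identical.

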