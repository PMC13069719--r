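#!/usr/bin/env Rscript
# Annotate VMPs/SMPs to mQTLs: cis (<= 500 bp) vs trans pairs, per-CpG
# classes, and same-TAD / loop-connected co-occupancy of trans pairs
# against the all-mQTL-pair background.

library(methvar)

betasD <- read_beta_matrix("results/bundle/betas_discovery.tsv")
betasV <- read_beta_matrix("results/bundle/betas_validation.tsv")
manifest <- read_probe_manifest("results/bundle/manifest.csv")
mqtl <- read_mqtl_table("results/bundle/mqtl.tsv")
tads <- read_intervals("results/bundle/tads.bed", "bed")
loops <- read_intervals("results/bundle/loops.bedpe", "bedpe")

cfg <- methvar_config(rng_seed = 1L)
catal <- call_catalog(betasD, betasV, cfg)
vmps <- vmp_ids(catal); smps <- smp_ids(catal)

pairs <- annotate_pairs(classify_pairs(mqtl, manifest, cfg$cis_window_bp),
                        tads, loops)
write.table(pairs, "results/mqtl_pairs.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(summarize_cpg_mqtl(pairs), "results/mqtl_cpg_summary.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("VMPs with >= 1 mQTL: %.1f%%; SMPs: %.1f%%\n",
            100 * mean(vmps %in% pairs$cpg_id),
            100 * mean(smps %in% pairs$cpg_id)))
pv <- pairs[pairs$cpg_id %in% vmps, ]
cat(sprintf("mQTL-VMP pairs: %d (%.1f%% cis, %.1f%% trans)\n", nrow(pv),
            100 * mean(pv$pair_class == "cis"),
            100 * mean(pv$pair_class == "trans")))

trans_all <- pairs[pairs$pair_class == "trans", ]
trans_vmp <- pv[pv$pair_class == "trans", ]
cat(sprintf("Trans mQTL-VMP pairs in the same TAD: %.1f%% (background %.1f%%)\n",
            100 * mean(trans_vmp$same_tad), 100 * mean(trans_all$same_tad)))
co <- co_occupancy_enrichment(trans_vmp, trans_all)
print(co)
write.table(co, "results/co_occupancy_vmp.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
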