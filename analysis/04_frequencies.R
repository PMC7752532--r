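#!/usr/bin/env Rscript
# Step 4: the frequency analysis proper, as one pipeline run — post counts
# per concept with superclass rollup, per-cancer-type stratification with
# per-stratum denominators, top-10 ranking, and comparison against the
# (synthetic stand-in) registry incidence ranking.

suppressPackageStartupMessages(library(oncolex))

save_ontology(skeleton_ontology(), "results/ontology_skeleton.tsv")
cfg <- pipeline_config(ontology = "results/ontology_skeleton.tsv",
                       corpus = "results/synthetic_corpus.jsonl",
                       out_dir = "results/frequency")
rep <- run_pipeline(cfg)

cat("Superclass frequencies (ALL strata):\n")
print(as.data.frame(rep$freq_superclass))
cat("\nTop cancer types by post count:\n")
print(as.data.frame(rep$freq_types))
cat("\nRanking vs registry:\n")
print(rep$rank_comparison)
cat("\nAll tables under results/frequency/\n")
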