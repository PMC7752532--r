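#!/usr/bin/env Rscript
# Step 2: simulate a social-media post corpus with known ground truth. The
# generator plants cancer-type mentions (colon 6.4%, breast 6.3%, stomach
# 5.0%, ... at the head), per-superclass concept mentions conditional on
# each cancer type, a 5% advertising contamination, and stop-phrase
# confusables ("agseong virus", "an-am", ...) in 5% of non-cancer posts,
# over the window 2014-01-01..2017-06-30 with a 58.7% blog share.
#
# Usage: Rscript analysis/02_simulate_corpus.R [n_posts] [seed]

suppressPackageStartupMessages(library(oncolex))
args <- commandArgs(trailingOnly = TRUE)
n_posts <- if (length(args) >= 1) as.integer(args[1]) else 20000L
seed <- if (length(args) >= 2) as.integer(args[2]) else 1L
dir.create("results", showWarnings = FALSE)

ont <- skeleton_ontology()
spec <- corpus_spec(n_posts = n_posts, seed = seed)
g <- generate_corpus(spec, ont)

write_corpus(g$corpus, "results/synthetic_corpus.jsonl")
write_ground_truth(g$truth, "results/synthetic_truth.jsonl")

s <- summarize_corpus(g$corpus)
print(s)
write_corpus_summary(s, "results/corpus_summary.csv")
cat(sprintf("\n%d posts (%d ads, %d confusables) -> results/synthetic_corpus.jsonl\n",
            nrow(g$corpus), sum(g$truth$is_ad), sum(g$truth$is_confusable)))
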