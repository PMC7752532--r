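#!/usr/bin/env Rscript
# Step 1: load the packaged consumer cancer ontology skeleton, validate it,
# and write its structure tables. The skeleton has the 9 superclasses
# (cancer type, prevention, diagnosis, treatment, prognosis, risk factor,
# symptom, dealing with cancer, emotion), the publicly documented
# subclasses, and consumer terms (synonyms, abbreviations, heteronyms).

suppressPackageStartupMessages(library(oncolex))
dir.create("results", showWarnings = FALSE)

ont <- skeleton_ontology()
rep <- validate_ontology(ont)
print(rep)
stopifnot(nrow(rep$errors) == 0)

save_ontology(ont, "results/ontology_skeleton.tsv")
save_ontology(ont, "results/ontology_skeleton.obo", format = "obo")

cat("\nSuperclasses and subtree sizes:\n")
for (r in ont$roots) {
  cat(sprintf("  %-20s %2d descendant classes\n", r, length(descendants(ont, r))))
}
cat("\nWrote results/ontology_skeleton.{tsv,obo}\n")
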