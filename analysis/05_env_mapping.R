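#!/usr/bin/env Rscript

# Stage 5: environmental mapping and the synchrony test.
#
# OTUs map to a GFC only when every retained alignment hit (identity above
# the threshold, top 20 by rank) falls in a single GFC (specificity index
# = 1). OTU pairs with at least one mapped member are split into same-GFC
# and different-GFC groups and their frequency interaction scores compared
# with a one-sided Welch t-test (Wilcoxon alongside), plus two seeded
# randomization controls.

library(traitatlas)

in_dir <- "results/inputs"
out_dir <- "results/atlas"
cfg <- read_config(file.path(in_dir, "config.json"))
gfc_tab <- read.delim(file.path(out_dir, "clusters_gfc.tsv"))
gfc <- setNames(gfc_tab$gfc_id, gfc_tab$genome_id)
hits <- read_hits(file.path(in_dir, "hits.tsv"))
pairs <- read.delim(file.path(in_dir, "pair_scores.tsv"))
abund <- read.delim(file.path(in_dir, "otu_abundances.tsv"))
w <- function(df, p) write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)

for (thr in cfg$identity_thresholds) {
  mapping <- map_otus(hits, gfc, thr, cfg$max_hits)
  w(mapping, file.path(out_dir, sprintf("otu_mapping_%s.tsv", thr)))
  cf <- community_fraction(abund, mapping)
  cat(sprintf("identity >= %5.1f%%: %d/%d OTUs mapped, mean read fraction %.3f\n",
              thr, sum(mapping$mapped), nrow(mapping), cf$mean))
  lab <- label_pairs(pairs, mapping)
  if (length(unique(lab$group)) == 2L) {
    rep_ <- synchrony_test(lab, n_randomizations = cfg$n_permutations,
                           seed = cfg$seed)
    print(rep_)
  } else {
    cat("  (one pair group empty; synchrony test skipped)\n")
  }
}
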