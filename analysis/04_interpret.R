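#!/usr/bin/env Rscript

# Stage 4: interpret the clusterings.
#
# Coherence: a GFC is monophyletic when it holds all and only the genomes
# of one genus. LTC semantics: present in a genome when > 50% of its
# traits are present, present in a GFC when present in > 50% of its
# genomes; core / common / ancillary at > 90% / 30-90% / <= 30% genome
# presence; LTCs present in no GFC mark their traits unclustered.
# Vitamin strategies (consumer / independent / flexible), interaction
# trait counts vs genome size, permutation enrichment per GFC, and the
# q / taxon-down-sampling sensitivity scan.

library(traitatlas)

in_dir <- "results/inputs"
out_dir <- "results/atlas"
cfg <- read_config(file.path(in_dir, "config.json"))
genomes <- read_genomes(file.path(in_dir, "genomes.tsv"))
tm <- read_trait_matrix(file.path(out_dir, "trait_matrix.tsv"))
gfc_tab <- read.delim(file.path(out_dir, "clusters_gfc.tsv"))
ltc_tab <- read.delim(file.path(out_dir, "clusters_ltc.tsv"))
gfc <- setNames(gfc_tab$gfc_id, gfc_tab$genome_id)
ltc <- setNames(ltc_tab$ltc_id, ltc_tab$trait_id)
w <- function(df, p) write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)

coh <- classify_coherence(gfc, genomes, rank = "genus")
w(coh, file.path(out_dir, "coherence.tsv"))
cat("coherence at genus level:\n")
print(table(coh$label))

pf <- prevalence_filter(tm, cfg$prevalence_min)
sim_t <- suppressWarnings(build_similarity(pf$matrix, "trait", cfg$fdr_alpha))
ltcs <- ltc_presence(pf$matrix, ltc, gfc, cfg, phi_raw = sim_t$phi_raw)
w(ltcs$summary, file.path(out_dir, "ltc_summary.tsv"))
cat(sprintf("LTC categories: %s; background mean r = %.3f\n",
            paste(sprintf("%s=%d", names(table(ltcs$summary$category)),
                          table(ltcs$summary$category)), collapse = ", "),
            ltcs$background_mean_r))
cat(sprintf("mean within-LTC r (LTCs with >= 10 traits): %.3f\n",
            mean(ltcs$summary$mean_within_r[ltcs$summary$n_traits >= 10])))

vit <- classify_vitamins(tm)
w(vit, file.path(out_dir, "vitamin_profiles.tsv"))
cfgs <- enumerate_configurations(vit)
w(cfgs, file.path(out_dir, "configurations.tsv"))
cat(sprintf("vitamin strategy configurations: %d of %d cells occupied\n",
            attr(cfgs, "n_observed"), nrow(cfgs)))

ic <- count_interaction_traits(tm, genomes)
w(ic, file.path(out_dir, "interaction_counts.tsv"))
sz <- size_expectation(ic, genomes, n_permutations = cfg$n_permutations,
                       seed = cfg$seed)
w(sz$per_taxon, file.path(out_dir, "size_residuals_taxon.tsv"))
cat(sprintf("interaction-trait load vs genome size: slope %.2e per bp\n",
            sz$model["genome_size"]))

enr <- enrichment_test(tm, gfc, n_permutations = cfg$n_permutations,
                       seed = cfg$seed)
w(enr, file.path(out_dir, "enrichment.tsv"))
cat(sprintf("GFCs enriched in interaction traits (BH p < 0.05): %s\n",
            paste(enr$gfc_id[enr$p_adj < 0.05], collapse = ", ")))

sens <- sensitivity_analysis(tm, genomes, cfg)
jsonlite::write_json(sens, file.path(out_dir, "sensitivity.json"),
                     auto_unbox = TRUE, digits = NA)
cat("sensitivity: cluster count by q:\n")
print(sens$q_scan)
cat(sprintf("down-sampling ARIs vs full clustering: %s\n",
            paste(sprintf("%.2f", sens$downsampling$ari), collapse = ", ")))
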