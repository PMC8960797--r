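#!/usr/bin/env Rscript

# Stage 2: reconstruct module completeness from the KO tables and
# assemble the genome x trait presence/absence matrix.
#
# Modules are complete when every reaction has an annotated KO
# alternative, tolerating one missing reaction in modules of >= 3
# reactions. The matrix unions module traits with the curated call tables
# (secondary metabolites, transporters, phytohormone pathways, sulfur
# catabolism), flags the curated interaction traits, and carries the
# B-vitamin synthesis/transport tags.

library(traitatlas)

in_dir <- "results/inputs"
out_dir <- "results/atlas"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

genomes <- read_genomes(file.path(in_dir, "genomes.tsv"))
ko <- read_ko_table(file.path(in_dir, "ko_annotations.tsv"))
defs <- read_module_defs(file.path(in_dir, "module_definitions.json"))
modules <- call_all(defs, ko, genome_ids = genomes$genome_id)
write_tsv <- function(df, p) write.table(df, p, sep = "\t", quote = FALSE,
                                         row.names = FALSE)
write_tsv(modules$calls, file.path(out_dir, "module_calls.tsv"))

cat(sprintf("module reconstruction: %d genomes x %d modules, %.1f%% complete calls\n",
            nrow(modules$matrix), ncol(modules$matrix),
            100 * mean(modules$matrix)))

calls <- lapply(c("secondary_metabolite", "transporter",
                  "phytohormone_pathway", "sulfur_catabolism"),
                function(cat) read_trait_calls(
                  file.path(in_dir, sprintf("trait_calls_%s.tsv", cat)), cat))
interaction <- readLines(file.path(in_dir, "interaction_traits.txt"))
tags <- read.delim(file.path(in_dir, "trait_tags.tsv"))

tm <- assemble_trait_matrix(modules$matrix, calls, interaction, tags)
write_trait_matrix(tm, file.path(out_dir, "trait_matrix.tsv"))
print(tm)
cat(sprintf("interaction traits flagged: %d\n", sum(tm$meta$interaction)))
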