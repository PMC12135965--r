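#!/usr/bin/env Rscript

# Stage 1 -- build the synthetic study corpus with known ground truth:
# a protein database planting a 200-member effector family (bipartite
# domain, WHxxxH motif, subclass I/II architectures, toxin-family
# extensions) among 2,000 background decoys; one genome per effector with
# an immunity-like neighbor and T6SS core-component genes; and a 3-vs-3
# LFQ secretome table with a 13-protein planted secreted set.

suppressPackageStartupMessages(library(whixscan))

out <- "results/synthetic"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- synthetic_config()          # rng_seed 101; the study conditions
db <- generate_effector_db(cfg)
genomes <- generate_genomes(db$truth, cfg)
lfq <- generate_lfq(cfg)

write_protein_fasta(db$proteins, file.path(out, "proteins.fasta"))
writeLines(db$seed_region, file.path(out, "seed_region.txt"))
write_tsv(db$truth, file.path(out, "truth_manifest.tsv"))
write_tsv(db$extension_truth, file.path(out, "extension_truth.tsv"))
write_features_tsv(genomes$features, file.path(out, "features.tsv"))
write_features_gff3(genomes$features, file.path(out, "features.gff3"))
write_tsv(genomes$sp_calls, file.path(out, "sp_calls.tsv"))
write_tsv(genomes$genome_truth, file.path(out, "genome_truth.tsv"))
write_tsv(genomes$immunity_truth, file.path(out, "immunity_truth.tsv"))
write_tsv(genomes$locus_truth, file.path(out, "locus_truth.tsv"))
write_lfq_tsv(lfq$table, file.path(out, "lfq_table.tsv"))
write_tsv(lfq$truth, file.path(out, "lfq_truth.tsv"))

fam <- db$truth[db$truth$is_family, ]
cat(sprintf(
  "corpus: %d proteins (%d family, %d decoys); seed region %d aa\n",
  length(db$proteins), nrow(fam), sum(!db$truth$is_family),
  nchar(db$seed_region)))
cat(sprintf("  subclass II: %.1f%%; C-extension: %.1f%%\n",
            100 * mean(fam$subclass == "II"),
            100 * mean(fam$has_c_extension)))
cat(sprintf("genomes: %d; features: %d genes; T6SS-positive (truth): %.1f%%\n",
            length(unique(genomes$features$genome_acc)),
            nrow(genomes$features),
            100 * mean(genomes$genome_truth$t6ss_positive)))
cat(sprintf("LFQ: %d proteins, %d planted secreted\n",
            nrow(lfq$table), sum(lfq$truth$planted_secreted)))
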