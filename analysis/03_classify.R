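#!/usr/bin/env Rscript

# Stage 3 -- effector classification. Turns domain calls into annotations
# (subclass I/II by the >99 aa N-extension rule, extension lengths, WHxxxH
# motif position), builds a profile-anchored alignment of the recovered
# domains trimmed to the seed columns, exports it for external tree
# building, and computes the per-column conservation logo.

suppressPackageStartupMessages(library(whixscan))

src <- "results/synthetic"
prof_dir <- "results/profile"
out <- "results/classify"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

proteins <- read_protein_fasta(file.path(src, "proteins.fasta"))
seed_region <- readLines(file.path(src, "seed_region.txt"))
profile <- read_profile(file.path(prof_dir, "whix_profile.txt"))
calls <- read.delim(file.path(prof_dir, "domain_calls.tsv"))

ann <- annotate_all(calls, proteins)
write_tsv(ann, file.path(out, "annotations.tsv"))

# profile-anchored alignment: each hit's residues placed at their profile
# columns, gaps elsewhere; the seed row makes every column reference-backed
params <- search_params()
hits <- scan_database(profile, proteins, params)
width <- profile$width
rows <- c(SEED = seed_region)
for (acc in unique(hits$subject_acc)) {
  sub <- hits[hits$subject_acc == acc, ]
  row <- rep("-", width)
  res <- strsplit(proteins[[acc]], "")[[1]]
  for (r in seq_len(nrow(sub)))
    row[sub$prof_cols[[r]]] <- res[sub$sub_pos[[r]]]
  rows[acc] <- paste(row, collapse = "")
}
msa <- trim_to_reference(rows, "SEED")
write_protein_fasta(msa, file.path(out, "domain_alignment.fasta"))

logo <- compute_logo(msa)
write_logo_tsv(logo, file.path(out, "conservation_logo.tsv"))

cat(sprintf("annotated %d effectors: %d subclass I, %d subclass II\n",
            nrow(ann), sum(ann$subclass == "I"), sum(ann$subclass == "II")))
cat(sprintf("  motif found in %.1f%%; C-extension in %.1f%%\n",
            100 * mean(!is.na(ann$motif_position)),
            100 * mean(ann$has_c_extension)))
cat(sprintf("alignment: %d rows x %d columns; mean information %.2f bits\n",
            length(msa), nchar(msa[[1]]), mean(logo$information)))
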