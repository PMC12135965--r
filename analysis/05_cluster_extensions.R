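#!/usr/bin/env Rscript

# Stage 5 -- toxin-family clustering. Extracts N-terminal extensions
# (subclass II) and the last 100 aa of C-extension-bearing effectors,
# scores all-vs-all local similarity against a shuffled-pair null, and
# partitions each set into connected components; components with fewer
# than 4 members are labeled "others" and left unanalyzed.

suppressPackageStartupMessages(library(whixscan))

src <- "results/synthetic"
cls <- "results/classify"
out <- "results/clusters"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

proteins <- read_protein_fasta(file.path(src, "proteins.fasta"))
ann <- read.delim(file.path(cls, "annotations.tsv"))
ext_truth <- read.delim(file.path(src, "extension_truth.tsv"))

termini <- extract_termini(ann, proteins)

report <- function(seqs, side, truth_col) {
  if (length(seqs) < 2L) {
    cat(sprintf("%s: fewer than 2 sequences, skipped\n", side))
    return(invisible(NULL))
  }
  edges <- pairwise_similarity(seqs, rng_seed = 101L)
  cl <- cluster_extensions(edges, names(seqs))
  write_tsv(cl, file.path(out, paste0(side, "_clusters.tsv")))
  write_clans_matrix(edges, sort(names(seqs)),
                     file.path(out, paste0(side, "_edges.clans")))
  named <- setdiff(unique(cl$label), "others")
  truth <- ext_truth[[truth_col]][match(cl$acc, ext_truth$acc)]
  purity <- mean(tapply(truth, cl$label, function(x)
    length(unique(x[!is.na(x)])) <= 1L))
  cat(sprintf("%s: %d sequences -> %d named families (+%d in 'others'); ",
              side, length(seqs), length(named),
              sum(cl$label == "others")))
  cat(sprintf("cluster purity vs planted families: %.2f\n", purity))
}

report(termini$n_term, "n_term", "n_family")
report(termini$c_term, "c_term", "c_family")
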