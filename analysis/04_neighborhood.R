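#!/usr/bin/env Rscript

# Stage 4 -- genomic context. Extracts the neighborhoods of every effector
# locus, removes contig-end loci, collapses duplicate loci (same genome,
# same downstream protein at the same distance in another genomic
# accession), flags immunity candidates from signal-peptide calls, and
# censuses T6SS core components per genome (positive at >= 9 of 11).

suppressPackageStartupMessages(library(whixscan))

src <- "results/synthetic"
out <- "results/neighborhood"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

features <- read_features_tsv(file.path(src, "features.tsv"))
sp_calls <- read.delim(file.path(src, "sp_calls.tsv"))
truth <- read.delim(file.path(src, "truth_manifest.tsv"))
genome_truth <- read.delim(file.path(src, "genome_truth.tsv"))
fam <- truth$acc[truth$is_family]

records <- extract_neighborhoods(features, fam, k = 3L)
filtered <- deduplicate(filter_contig_ends(records))
flagged <- lapply(filtered, flag_immunity_candidates, sp_calls = sp_calls)

write_tsv(neighborhoods_to_df(flagged), file.path(out, "neighborhoods.tsv"))
census <- census_t6ss(features)
write_tsv(census, file.path(out, "census.tsv"))

cat(sprintf("loci: %d raw -> %d after contig-end and duplicate filters\n",
            length(records), length(filtered)))
down <- mean(vapply(flagged, function(r) isTRUE(r$downstream_candidate),
                    logical(1)))
cat(sprintf("  downstream immunity candidate at %.1f%% of loci\n",
            100 * down))
agree <- merge(census, genome_truth, by = "genome_acc")
cat(sprintf("census: %.1f%% T6SS-positive; agreement with truth: %.3f\n",
            100 * mean(census$t6ss_positive),
            mean(agree$t6ss_positive.x == agree$t6ss_positive.y)))
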