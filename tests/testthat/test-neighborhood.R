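# Hand-laid contig: 5 genes, ordinals 1..5, alternating strands.
demo_features <- function() {
  data.frame(
    genome_acc = "G1", genomic_acc = "C1", ordinal = 1:5,
    start = c(100L, 700L, 1500L, 2500L, 3600L),
    end = c(600L, 1400L, 2400L, 3500L, 4200L),
    strand = c("+", "+", "-", "+", "+"),
    protein_acc = paste0("P", 1:5),
    annotation = "hypothetical", stringsAsFactors = FALSE)
}

test_that("neighborhood extraction is strand-aware with intergenic distances", {
  f <- demo_features()
  rec <- extract_neighborhoods(f, "P2", k = 2L)
  expect_length(rec, 1L)
  r <- rec[[1]]
  # plus-strand focal: downstream is the higher-coordinate side
  expect_identical(r$downstream$protein_acc, c("P3", "P4"))
  expect_identical(r$upstream$protein_acc, "P1")
  expect_identical(r$downstream$distance[1], 100)   # 1500 - 1400
  expect_identical(r$upstream$distance[1], 100)     # 700 - 600

  # minus-strand focal: orientation flips
  rec3 <- extract_neighborhoods(f, "P3", k = 1L)[[1]]
  expect_identical(rec3$downstream$protein_acc, "P2")
  expect_identical(rec3$upstream$protein_acc, "P4")

  # missing accessions are recorded, not raised
  rec_m <- extract_neighborhoods(f, c("P2", "ABSENT"), k = 1L)
  expect_identical(attr(rec_m, "missing"), "ABSENT")
})

test_that("single-gene contigs yield empty neighbor lists", {
  f <- data.frame(genome_acc = "G", genomic_acc = "C", ordinal = 1L,
                  start = 10L, end = 400L, strand = "+",
                  protein_acc = "LONER", annotation = "x",
                  stringsAsFactors = FALSE)
  r <- extract_neighborhoods(f, "LONER", k = 3L)[[1]]
  expect_identical(nrow(r$upstream), 0L)
  expect_identical(nrow(r$downstream), 0L)
})

test_that("extraction agrees with a brute-force contig scan on random layouts", {
  set.seed(17)
  for (rep in 1:100) {
    n <- sample(1:8, 1)
    starts <- cumsum(sample(50:500, n, replace = TRUE))
    f <- data.frame(genome_acc = "G", genomic_acc = "C", ordinal = seq_len(n),
                    start = starts, end = starts + sample(100:400, n, TRUE),
                    strand = sample(c("+", "-"), n, TRUE),
                    protein_acc = paste0("P", seq_len(n)),
                    annotation = "x", stringsAsFactors = FALSE)
    focal_i <- sample(n, 1)
    k <- sample(1:3, 1)
    r <- extract_neighborhoods(f, f$protein_acc[focal_i], k)[[1]]
    # oracle: ordinal-sorted scan on each side of the focal gene
    higher <- f[f$ordinal > focal_i, , drop = FALSE]
    lower <- f[f$ordinal < focal_i, , drop = FALSE]
    lower <- lower[order(-lower$ordinal), , drop = FALSE]
    if (f$strand[focal_i] == "-") {
      exp_down <- head(lower$protein_acc, k)
      exp_up <- head(higher$protein_acc, k)
    } else {
      exp_down <- head(higher$protein_acc, k)
      exp_up <- head(lower$protein_acc, k)
    }
    expect_identical(r$downstream$protein_acc, exp_down)
    expect_identical(r$upstream$protein_acc, exp_up)
  }
})

test_that("contig-end filtering removes terminal foci and is idempotent", {
  f <- demo_features()
  recs <- extract_neighborhoods(f, paste0("P", 1:5), k = 1L)
  once <- filter_contig_ends(recs)
  kept <- vapply(once, function(r) r$focal$protein_acc, character(1))
  expect_identical(sort(kept), c("P2", "P3", "P4"))
  twice <- filter_contig_ends(once)
  expect_identical(vapply(twice, function(r) r$focal$protein_acc,
                          character(1)), kept)
})

test_that("duplicate loci collapse only on identical downstream gene and distance", {
  same <- as_neighborhoods(list(
    make_record("G1", "C_B", "WHX1", "IMM1", 50),
    make_record("G1", "C_A", "WHX1", "IMM1", 50)))
  out <- deduplicate(same)
  expect_length(out, 1L)
  expect_identical(out[[1]]$focal$genomic_acc, "C_A")  # lexical representative

  diff_dist <- as_neighborhoods(list(
    make_record("G1", "C_B", "WHX1", "IMM1", 50),
    make_record("G1", "C_A", "WHX1", "IMM1", 60)))
  expect_length(deduplicate(diff_dist), 2L)

  diff_gene <- as_neighborhoods(list(
    make_record("G1", "C_B", "WHX1", "IMM1", 50),
    make_record("G1", "C_A", "WHX1", "IMM2", 50)))
  expect_length(deduplicate(diff_gene), 2L)

  # different genomes never interact
  cross <- as_neighborhoods(list(
    make_record("G1", "C_A", "WHX1", "IMM1", 50),
    make_record("G2", "C_B", "WHX1", "IMM1", 50)))
  expect_length(deduplicate(cross), 2L)

  # sole occurrences are never removed
  sole <- as_neighborhoods(list(make_record("G1", "C_A", "WHX1", "IMM1", 50)))
  expect_length(deduplicate(sole), 1L)
})

test_that("dedup equals the exhaustive pairwise oracle on random cases", {
  set.seed(23)
  for (rep in 1:500) {
    n <- sample(2:6, 1)
    recs <- lapply(seq_len(n), function(i)
      make_record(genome = sample(c("G1", "G2"), 1),
                  contig = sample(paste0("C", 1:3), 1),
                  focal_acc = sample(c("WHX1", "WHX2"), 1),
                  down_acc = sample(c("IMM1", "IMM2", NA), 1),
                  down_dist = sample(c(50, 60), 1)))
    recs <- as_neighborhoods(recs)
    got <- deduplicate(recs)
    want <- recs[dedup_oracle(recs)]
    expect_identical(length(got), length(want))
    expect_identical(lapply(got, function(r) r$focal),
                     lapply(want, function(r) r$focal))
  }
})

test_that("contig-end and dedup filters commute on the synthetic corpus", {
  cfg <- tiny_config(frac_contig_end = 0.2, frac_duplicated = 0.4)
  db <- generate_effector_db(cfg)
  g <- generate_genomes(db$truth, cfg)
  recs <- extract_neighborhoods(g$features, db$truth$acc[db$truth$is_family],
                                k = 2L)
  ab <- deduplicate(filter_contig_ends(recs))
  ba <- filter_contig_ends(deduplicate(recs))
  sig <- function(rs) vapply(rs, function(r)
    paste(r$focal$genomic_acc, r$focal$ordinal), character(1))
  expect_identical(sort(sig(ab)), sort(sig(ba)))
})

test_that("census counts distinct components against the >=9 threshold", {
  comp <- t6ss_core_components()
  mk <- function(anns) data.frame(
    genome_acc = "G", genomic_acc = "C", ordinal = seq_along(anns),
    start = seq_along(anns) * 1000L, end = seq_along(anns) * 1000L + 500L,
    strand = "+", protein_acc = paste0("P", seq_along(anns)),
    annotation = anns, stringsAsFactors = FALSE)
  expect_true(census_t6ss(mk(comp))$t6ss_positive)            # 11 distinct
  expect_true(census_t6ss(mk(comp[1:9]))$t6ss_positive)       # 9 distinct
  expect_false(census_t6ss(mk(comp[1:8]))$t6ss_positive)      # 8 distinct
  # copies of one component count once: 3x Hcp + 8 others = 9 distinct
  expect_true(census_t6ss(mk(c(rep(comp[1], 3), comp[2:9])))$t6ss_positive)
  # 3x Hcp + 7 others = 10 genes but 8 distinct
  expect_false(census_t6ss(mk(c(rep(comp[1], 3), comp[2:8])))$t6ss_positive)
  expect_warning(census_t6ss(mk(comp), core_component_names = comp[1:10]),
                 "11")
})

test_that("census status is monotone under added annotations", {
  comp <- t6ss_core_components()
  set.seed(3)
  for (rep in 1:50) {
    present <- sample(comp, sample(0:11, 1))
    anns <- c(present, rep("hypothetical", 3))
    f <- data.frame(genome_acc = "G", genomic_acc = "C",
                    ordinal = seq_along(anns), start = seq_along(anns) * 10L,
                    end = seq_along(anns) * 10L + 5L, strand = "+",
                    protein_acc = paste0("P", seq_along(anns)),
                    annotation = anns, stringsAsFactors = FALSE)
    before <- census_t6ss(f)$t6ss_positive
    extra <- f[1, ]
    extra$ordinal <- nrow(f) + 1L
    extra$protein_acc <- "PX"
    extra$annotation <- sample(comp, 1)
    after <- census_t6ss(rbind(f, extra))$t6ss_positive
    expect_true(!before || after)
  }
})

test_that("immunity candidates follow signal-peptide calls on immediate neighbors", {
  f <- demo_features()
  rec <- extract_neighborhoods(f, "P2", k = 1L)[[1]]
  sp <- data.frame(protein_acc = c("P1", "P3"),
                   signal_peptide = c(FALSE, TRUE),
                   stringsAsFactors = FALSE)
  flagged <- flag_immunity_candidates(rec, sp)
  expect_true(flagged$downstream_candidate)
  expect_false(flagged$upstream_candidate)
  expect_identical(flagged$candidate_accs, "P3")
  # missing call -> unknown
  flagged2 <- flag_immunity_candidates(rec,
    data.frame(protein_acc = "P3", signal_peptide = TRUE))
  expect_true(is.na(flagged2$upstream_candidate))
})

test_that("planted immunity genes are recovered from synthetic genomes", {
  cfg <- tiny_config(frac_contig_end = 0, frac_duplicated = 0)
  db <- generate_effector_db(cfg)
  g <- generate_genomes(db$truth, cfg)
  recs <- extract_neighborhoods(g$features, db$truth$acc[db$truth$is_family],
                                k = 1L)
  flagged <- lapply(recs, flag_immunity_candidates, sp_calls = g$sp_calls)
  got <- sort(unique(unlist(lapply(flagged, function(r) r$candidate_accs))))
  want <- sort(unique(g$immunity_truth$immunity_acc))
  expect_identical(got, want)
})

test_that("feature tables round-trip through TSV and GFF3", {
  f <- demo_features()
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_features_tsv(f, tsv)
  expect_identical(read_features_tsv(tsv), f)

  skip_if_not_installed("rtracklayer")
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_features_gff3(f, gff)
  back <- read_features_gff3(gff)
  expect_identical(back[order(back$protein_acc), whixscan:::FEATURE_COLS],
                   f[order(f$protein_acc), whixscan:::FEATURE_COLS])
})
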