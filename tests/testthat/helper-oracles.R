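# Independent oracles used across the suite. Each re-derives the expected
# result by the most transparent method available (plain dynamic
# programming, exhaustive scanning, union-find) without touching the code
# path it checks.

# Quadratic-time affine-gap local alignment, plain R matrices.
sw_oracle <- function(prof, subj_codes, gap_open, gap_extend) {
  L <- nrow(prof)
  n <- length(subj_codes)
  NEG <- -1e30
  H <- matrix(0, L + 1L, n + 1L)
  E <- matrix(NEG, L + 1L, n + 1L)
  F <- matrix(NEG, L + 1L, n + 1L)
  best <- 0
  for (i in 2L:(L + 1L)) {
    for (j in 2L:(n + 1L)) {
      E[i, j] <- max(H[i, j - 1L] - gap_open - gap_extend,
                     E[i, j - 1L] - gap_extend)
      F[i, j] <- max(H[i - 1L, j] - gap_open - gap_extend,
                     F[i - 1L, j] - gap_extend)
      code <- subj_codes[j - 1L]
      s <- if (code < 0L) 0 else prof[i - 1L, code + 1L]
      H[i, j] <- max(0, H[i - 1L, j - 1L] + s, E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# Naive sliding-window motif scan: leftmost W,H,any,any,any,H.
motif_oracle <- function(sequence) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  if (n < 6L) return(NA_integer_)
  for (i in seq_len(n - 5L)) {
    if (chars[i] == "W" && chars[i + 1L] == "H" && chars[i + 5L] == "H")
      return(i)
  }
  NA_integer_
}

# Connected components by union-find over an edge list.
union_find_components <- function(nodes, edges_a, edges_b) {
  parent <- setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  for (k in seq_along(edges_a)) {
    ra <- find(edges_a[k]); rb <- find(edges_b[k])
    if (ra != rb) parent[[ra]] <- rb
  }
  vapply(nodes, find, character(1))
}

# Build a minimal neighborhood record by hand (for dedup oracles).
make_record <- function(genome, contig, focal_acc, down_acc = NA,
                        down_dist = NA, ordinal = 2L, contig_size = 5L,
                        strand = "+") {
  list(focal = data.frame(genome_acc = genome, genomic_acc = contig,
                          ordinal = ordinal, start = 100L, end = 400L,
                          strand = strand, protein_acc = focal_acc,
                          annotation = "x", stringsAsFactors = FALSE),
       upstream = data.frame(protein_acc = character(0),
                             distance = numeric(0)),
       downstream = if (is.na(down_acc))
         data.frame(protein_acc = character(0), distance = numeric(0))
       else data.frame(protein_acc = down_acc, distance = down_dist,
                       stringsAsFactors = FALSE),
       contig_size = contig_size)
}

as_neighborhoods <- function(records) {
  class(records) <- "whix_neighborhoods"
  records
}

# Exhaustive pairwise dedup oracle: a record is dropped iff another record
# of the same genome and focal accession, in a lexically smaller genomic
# accession, has the identical immediate downstream protein and distance.
dedup_oracle <- function(records) {
  n <- length(records)
  keep <- rep(TRUE, n)
  key <- function(r) {
    if (nrow(r$downstream) == 0L) return(NA_character_)
    paste(r$focal$genome_acc, r$focal$protein_acc,
          r$downstream$protein_acc[1], r$downstream$distance[1], sep = "|")
  }
  keys <- vapply(records, key, character(1))
  gacc <- vapply(records, function(r) r$focal$genomic_acc, character(1))
  for (i in seq_len(n)) {
    if (is.na(keys[i])) next
    for (j in seq_len(n)) {
      if (j == i || is.na(keys[j])) next
      if (keys[j] == keys[i] && gacc[j] < gacc[i]) keep[i] <- FALSE
    }
  }
  keep
}

# Small, fast generator configuration shared by several tests.
tiny_config <- function(...) {
  defaults <- list(n_family = 20L, n_decoy = 60L, lead_len = 8L,
                   region1_len = 30L, linker_len = 30L, region2_len = 50L,
                   decoy_len_range = c(80L, 250L), genes_per_contig = 8L,
                   lfq_n_proteins = 60L, lfq_n_secreted = 13L)
  do.call(synthetic_config, utils::modifyList(defaults, list(...)))
}

# Fast search parameters matched to the tiny corpus.
tiny_params <- function(...) {
  search_params(calib_null_n = 150L, ...)
}
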