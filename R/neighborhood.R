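FEATURE_COLS <- c("genome_acc", "genomic_acc", "ordinal", "start", "end",
                  "strand", "protein_acc", "annotation")

validate_features <- function(features) {
  missing <- setdiff(FEATURE_COLS, names(features))
  if (length(missing))
    stop("feature table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (any(features$start > features$end))
    stop("feature table has start > end", call. = FALSE)
  by_contig <- split(features$ordinal, features$genomic_acc)
  ok <- vapply(by_contig, function(o) identical(sort(o), seq_along(o)),
               logical(1))
  if (!all(ok))
    stop("ordinals are not consecutive on contig(s): ",
         paste(names(by_contig)[!ok], collapse = ", "), call. = FALSE)
  invisible(features)
}

# Intergenic gap between the focal gene and a neighbor on the same contig:
# positive when separated, negative when overlapping.
intergenic_gap <- function(focal, neighbor) {
  if (neighbor$start > focal$end) neighbor$start - focal$end
  else focal$start - neighbor$end
}

#' Extract the genomic neighborhood of each focal gene occurrence
#'
#' For every occurrence of a focal protein accession, collects up to `k`
#' genes on each side from the same contig, oriented relative to the focal
#' gene's strand (downstream = increasing coordinates on `+`, decreasing on
#' `-`), each with its intergenic nucleotide gap to the focal gene.
#'
#' @param features validated feature table (one row per gene; columns
#'   `genome_acc`, `genomic_acc`, `ordinal`, `start`, `end`, `strand`,
#'   `protein_acc`, `annotation`).
#' @param focal_accs protein accessions of interest.
#' @param k maximum neighbors per side (>= 1).
#' @return List of neighborhood records (class `whix_neighborhoods`), each
#'   with `focal` (one feature row), `upstream` and `downstream` (feature
#'   rows nearest-first with a `distance` column) and `contig_size`. Focal
#'   accessions with no occurrence are recorded in the `missing` attribute,
#'   not raised as errors.
#' @export
extract_neighborhoods <- function(features, focal_accs, k = 1L) {
  validate_features(features)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  found <- character(0)
  records <- list()
  occ <- which(features$protein_acc %in% focal_accs)
  for (i in occ) {
    focal <- features[i, , drop = FALSE]
    contig <- features[features$genomic_acc == focal$genomic_acc, ,
                       drop = FALSE]
    contig <- contig[order(contig$ordinal), , drop = FALSE]
    pos <- match(focal$ordinal, contig$ordinal)
    after <- contig[contig$ordinal > focal$ordinal, , drop = FALSE]
    before <- contig[contig$ordinal < focal$ordinal, , drop = FALSE]
    # nearest-first on each physical side
    before <- before[order(-before$ordinal), , drop = FALSE]
    if (focal$strand == "-") {
      down <- before; up <- after
    } else {
      down <- after; up <- before
    }
    down <- head(down, k); up <- head(up, k)
    add_dist <- function(df) {
      if (nrow(df) == 0L) { df$distance <- numeric(0); return(df) }
      df$distance <- vapply(seq_len(nrow(df)), function(r)
        intergenic_gap(focal, df[r, ]), numeric(1))
      df
    }
    records[[length(records) + 1L]] <- list(
      focal = focal, upstream = add_dist(up), downstream = add_dist(down),
      contig_size = nrow(contig))
    found <- c(found, focal$protein_acc)
  }
  attr(records, "missing") <- setdiff(focal_accs, found)
  class(records) <- "whix_neighborhoods"
  records
}

keep_records <- function(records, keep) {
  out <- records[keep]
  attributes(out) <- attributes(records)[setdiff(names(attributes(records)),
                                                 "names")]
  out
}

#' Remove neighborhood records whose focal gene sits at a contig end
#'
#' A focal gene that is first or last on its contig has a truncated
#' neighborhood and is discarded. The filter is idempotent.
#'
#' @param records neighborhoods from [extract_neighborhoods()].
#' @return Filtered records.
#' @export
filter_contig_ends <- function(records) {
  keep <- vapply(records, function(r)
    r$focal$ordinal != 1L && r$focal$ordinal != r$contig_size, logical(1))
  keep_records(records, keep)
}

#' Remove duplicate loci of a focal protein within a genome
#'
#' Within one genome, occurrences of the same focal protein accession in
#' different genomic accessions are considered duplicates when their
#' immediate downstream protein accession and downstream intergenic distance
#' both match; one representative (the lexically smallest genomic accession)
#' is kept. Occurrences lacking a downstream neighbor, or differing in
#' downstream gene or distance, are never removed.
#'
#' @param records neighborhoods from [extract_neighborhoods()].
#' @return Deduplicated records.
#' @export
deduplicate <- function(records) {
  if (length(records) == 0L) return(records)
  key <- vapply(records, function(r) {
    if (nrow(r$downstream) == 0L) return(NA_character_)
    paste(r$focal$genome_acc, r$focal$protein_acc,
          r$downstream$protein_acc[1], r$downstream$distance[1], sep = "\r")
  }, character(1))
  keep <- rep(TRUE, length(records))
  for (kk in unique(key[!is.na(key)])) {
    idx <- which(!is.na(key) & key == kk)
    if (length(idx) < 2L) next
    gaccs <- vapply(records[idx], function(r) r$focal$genomic_acc,
                    character(1))
    if (length(unique(gaccs)) < 2L) next
    keep[idx[gaccs != min(gaccs)]] <- FALSE
  }
  keep_records(records, keep)
}

#' Census of T6SS core components per genome
#'
#' Counts the distinct core components annotated in each genome (multiple
#' copies of one component count once). A genome is called T6SS-positive
#' when at least `threshold` of the components are present.
#'
#' @param features feature table; `annotation` holds component labels.
#' @param core_component_names component label set (11 by convention; a
#'   different length raises a configuration warning but the threshold
#'   stands unless overridden).
#' @param threshold minimum distinct components for positive status.
#' @return Data frame: `genome_acc`, `components_present`, `count`,
#'   `t6ss_positive`.
#' @export
census_t6ss <- function(features,
                        core_component_names = t6ss_core_components(),
                        threshold = 9L) {
  validate_features(features)
  if (length(core_component_names) != 11L)
    warning("core component list has ", length(core_component_names),
            " entries, not the conventional 11; threshold remains ",
            threshold)
  by_genome <- split(features$annotation, features$genome_acc)
  res <- lapply(names(by_genome), function(g) {
    present <- sort(unique(intersect(by_genome[[g]], core_component_names)))
    data.frame(genome_acc = g,
               components_present = paste(present, collapse = ","),
               count = length(present),
               t6ss_positive = length(present) >= threshold,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Flag immunity candidates next to an effector
#'
#' The immediate upstream and downstream neighbors are candidate immunity
#' genes when their protein carries a predicted signal peptide (periplasmic
#' localization). Neighbors without a signal-peptide call are flagged
#' unknown (`NA`).
#'
#' @param record a single neighborhood record.
#' @param sp_calls data frame `protein_acc`, `signal_peptide` (logical).
#' @return The record with `upstream_candidate` / `downstream_candidate`
#'   fields (logical or `NA`) and candidate accessions.
#' @export
flag_immunity_candidates <- function(record, sp_calls) {
  lookup <- function(acc) {
    i <- match(acc, sp_calls$protein_acc)
    if (is.na(i)) NA else isTRUE(sp_calls$signal_peptide[i])
  }
  side <- function(df) {
    if (nrow(df) == 0L) return(list(flag = FALSE, acc = NA_character_))
    fl <- lookup(df$protein_acc[1])
    list(flag = fl, acc = if (isTRUE(fl)) df$protein_acc[1] else NA_character_)
  }
  up <- side(record$upstream)
  down <- side(record$downstream)
  record$upstream_candidate <- up$flag
  record$downstream_candidate <- down$flag
  record$candidate_accs <- c(up$acc, down$acc)[!is.na(c(up$acc, down$acc))]
  record
}

#' Flatten neighborhood records to a table
#'
#' One row per record: focal gene metadata, immediate up/downstream
#' neighbor accession and distance, and (when flagged) immunity-candidate
#' flags.
#'
#' @param records neighborhoods list.
#' @return Data frame.
#' @export
neighborhoods_to_df <- function(records) {
  if (length(records) == 0L)
    return(data.frame(genome_acc = character(0), genomic_acc = character(0),
                      ordinal = integer(0), protein_acc = character(0),
                      strand = character(0), upstream_acc = character(0),
                      upstream_distance = numeric(0),
                      downstream_acc = character(0),
                      downstream_distance = numeric(0)))
  rows <- lapply(records, function(r) {
    data.frame(
      genome_acc = r$focal$genome_acc, genomic_acc = r$focal$genomic_acc,
      ordinal = r$focal$ordinal, protein_acc = r$focal$protein_acc,
      strand = r$focal$strand,
      upstream_acc = if (nrow(r$upstream)) r$upstream$protein_acc[1]
        else NA_character_,
      upstream_distance = if (nrow(r$upstream)) r$upstream$distance[1]
        else NA_real_,
      downstream_acc = if (nrow(r$downstream)) r$downstream$protein_acc[1]
        else NA_character_,
      downstream_distance = if (nrow(r$downstream)) r$downstream$distance[1]
        else NA_real_,
      upstream_candidate = r$upstream_candidate %||% NA,
      downstream_candidate = r$downstream_candidate %||% NA,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a flat feature table (TSV)
#' @param path TSV with the feature columns.
#' @return Validated feature data frame.
#' @export
read_features_tsv <- function(path) {
  f <- read.delim(path, stringsAsFactors = FALSE)
  validate_features(f)
  f
}

#' Write a feature table as TSV
#' @param features feature data frame.
#' @param path output path.
#' @export
write_features_tsv <- function(features, path) {
  write.table(features, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a feature table as GFF3
#'
#' Writes one CDS feature per gene with `ID`/`protein_id`/`genome`/
#' `annotation` attributes; round-trippable through standard GFF3 readers.
#'
#' @param features feature data frame.
#' @param path output path.
#' @export
write_features_gff3 <- function(features, path) {
  validate_features(features)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  attrs <- sprintf("ID=%s;protein_id=%s;genome=%s;annotation=%s",
                   features$protein_acc, features$protein_acc,
                   features$genome_acc, features$annotation)
  lines <- paste(features$genomic_acc, "whixscan", "CDS", features$start,
                 features$end, ".", features$strand, "0", attrs, sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Import genome features from GFF3
#'
#' Uses `rtracklayer` to parse the file, then reconstructs contig ordinals
#' from coordinate order.
#'
#' @param path GFF3 file with `protein_id`, `genome` and `annotation`
#'   attributes (as written by [write_features_gff3()]).
#' @return Validated feature data frame.
#' @export
read_features_gff3 <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("reading GFF3 requires the rtracklayer package", call. = FALSE)
  gr <- as.data.frame(rtracklayer::import(path, format = "gff3"))
  df <- data.frame(
    genome_acc = as.character(gr$genome),
    genomic_acc = as.character(gr$seqnames),
    start = gr$start, end = gr$end,
    strand = as.character(gr$strand),
    protein_acc = as.character(gr$protein_id),
    annotation = as.character(gr$annotation), stringsAsFactors = FALSE)
  df <- df[order(df$genomic_acc, df$start), , drop = FALSE]
  df$ordinal <- ave(seq_len(nrow(df)), df$genomic_acc,
                    FUN = seq_along)
  df <- df[, FEATURE_COLS]
  validate_features(df)
  df
}
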