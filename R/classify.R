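#' Annotate an effector from its domain call
#'
#' Splits the protein into an N-terminal extension, the domain interval and
#' a C-terminal extension, assigns the subclass (II when the N-terminal
#' extension exceeds 99 amino acids, I otherwise), and searches the domain
#' interval for the leftmost WHxxxH motif.
#'
#' @param call one-row domain call (from [merge_hits()]): `subject_acc`,
#'   `domain_start`, `domain_end`.
#' @param protein the subject sequence (single string).
#' @param min_c_ext minimum C-terminal extension length (aa) for
#'   `has_c_extension`; shorter tails are treated as truncated/absent.
#' @return One-row data frame: accession, domain interval, subclass,
#'   extension lengths, `has_c_extension`, and `motif_position` (start of
#'   WHxxxH within the protein, `NA` when absent).
#' @export
annotate <- function(call, protein, min_c_ext = 10L) {
  len <- nchar(protein)
  ds <- call$domain_start
  de <- call$domain_end
  if (is.na(ds) || is.na(de) || ds < 1L || de > len || ds > de)
    stop("domain call out of protein bounds", call. = FALSE)
  n_ext <- ds - 1L
  c_ext <- len - de
  motif <- find_motif(protein, c(ds, de))
  data.frame(protein_acc = call$subject_acc,
             whix_start = ds, whix_end = de,
             subclass = if (n_ext > 99L) "II" else "I",
             n_ext_len = n_ext, c_ext_len = c_ext,
             has_c_extension = c_ext >= min_c_ext,
             motif_position = if (is.na(motif)) NA_integer_ else motif,
             stringsAsFactors = FALSE)
}

#' Annotate every domain call against its protein
#'
#' @param calls domain-call table from [merge_all_hits()].
#' @param proteins named character vector of sequences.
#' @param min_c_ext see [annotate()].
#' @return Data frame of annotations, one row per call.
#' @export
annotate_all <- function(calls, proteins, min_c_ext = 10L) {
  proteins <- as_protein_set(proteins)
  if (nrow(calls) == 0L)
    return(data.frame(protein_acc = character(0), whix_start = integer(0),
                      whix_end = integer(0), subclass = character(0),
                      n_ext_len = integer(0), c_ext_len = integer(0),
                      has_c_extension = logical(0),
                      motif_position = integer(0)))
  res <- do.call(rbind, lapply(seq_len(nrow(calls)), function(i)
    annotate(calls[i, ], proteins[[calls$subject_acc[i]]], min_c_ext)))
  rownames(res) <- NULL
  res
}

#' Find the leftmost WHxxxH motif within an interval
#'
#' The motif is the literal pattern W, H, any, any, any, H.
#'
#' @param sequence protein sequence.
#' @param interval 1-based inclusive `c(start, end)` to search within;
#'   defaults to the whole sequence.
#' @return 1-based start position of the leftmost match within the full
#'   sequence, or `NA_integer_` when absent.
#' @export
find_motif <- function(sequence, interval = c(1L, nchar(sequence))) {
  start <- interval[1]; end <- interval[2]
  if (start < 1L || end > nchar(sequence) || start > end)
    stop("interval out of sequence bounds", call. = FALSE)
  window <- substr(sequence, start, end)
  m <- regexpr("WH...H", window, perl = TRUE)
  if (m == -1L) NA_integer_ else as.integer(m) + start - 1L
}

#' Trim an alignment to the columns of a reference row
#'
#' Keeps exactly the columns at which the reference carries a residue, so
#' the output width equals the ungapped reference length; row order is
#' preserved. This is the column set on which the conservation logo and the
#' exported alignment are defined.
#'
#' @param msa named character vector of equal-length gapped sequences (or an
#'   `AAStringSet`).
#' @param reference_id name of the reference row.
#' @return Named character vector of trimmed rows.
#' @export
trim_to_reference <- function(msa, reference_id) {
  msa <- as_gapped_character(msa)
  if (!reference_id %in% names(msa))
    stop("reference `", reference_id, "` not found in alignment",
         call. = FALSE)
  if (length(unique(nchar(msa))) != 1L)
    stop("alignment rows differ in length", call. = FALSE)
  ref <- strsplit(msa[[reference_id]], "")[[1]]
  keep <- which(ref != "-")
  vapply(msa, function(row)
    paste(strsplit(row, "")[[1]][keep], collapse = ""), "",
    USE.NAMES = TRUE)
}

#' Per-column conservation logo of a trimmed alignment
#'
#' Information content per column is `log2(20)` minus the Shannon entropy of
#' the observed residue frequencies (gaps excluded; no small-sample
#' correction). Letter heights are frequency times information content, so
#' heights per column sum to the column's information content. Columns that
#' are entirely gaps get zero content and are flagged.
#'
#' @param msa rectangular gapped alignment (named character vector).
#' @return List with `information` (numeric per column),
#'   `heights` (20 x width matrix, rows named by residue), and `all_gap`
#'   (logical per column).
#' @export
compute_logo <- function(msa) {
  msa <- as_gapped_character(msa)
  if (length(msa) < 1L) stop("alignment is empty", call. = FALSE)
  if (length(unique(nchar(msa))) != 1L)
    stop("alignment rows differ in length", call. = FALSE)
  mat <- do.call(rbind, strsplit(toupper(msa), ""))
  width <- ncol(mat)
  info <- numeric(width)
  heights <- matrix(0, 20L, width, dimnames = list(AA20, NULL))
  all_gap <- logical(width)
  for (j in seq_len(width)) {
    counts <- tabulate(match(mat[, j], AA20), nbins = 20L)
    n <- sum(counts)
    if (n == 0L) {
      all_gap[j] <- TRUE
      next
    }
    p <- counts / n
    nz <- p > 0
    ent <- -sum(p[nz] * log2(p[nz]))
    info[j] <- log2(20) - ent
    heights[, j] <- p * info[j]
  }
  list(information = info, heights = heights, all_gap = all_gap)
}

#' Write per-column logo heights as TSV
#'
#' @param logo result of [compute_logo()].
#' @param path output file.
#' @export
write_logo_tsv <- function(logo, path) {
  df <- data.frame(column = seq_along(logo$information),
                   information = logo$information,
                   all_gap = logo$all_gap,
                   t(logo$heights), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
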