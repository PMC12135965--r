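#' Construct a two-group LFQ table
#'
#' Wraps a protein-group data frame (MaxQuant proteinGroups-like export)
#' with an explicit column mapping: a protein id, an identification score,
#' and log-scale LFQ intensity columns for the two groups (e.g. wild type
#' vs secretion-deficient mutant).
#'
#' @param df data frame holding at least `protein_id`, `score` and the
#'   intensity columns.
#' @param group_a,group_b intensity column names (equal replicate counts;
#'   at least 2 each).
#' @return `df` with class `lfq_table` and the grouping in attributes.
#' @export
lfq_table <- function(df, group_a, group_b) {
  stopifnot(is.data.frame(df))
  missing <- setdiff(c("protein_id", "score", group_a, group_b), names(df))
  if (length(missing))
    stop("LFQ table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (length(group_a) != length(group_b))
    stop("groups must have equal replicate counts", call. = FALSE)
  if (length(group_a) < 2L)
    stop("need at least 2 replicates per group", call. = FALSE)
  structure(df, class = c("lfq_table", "data.frame"),
            group_a = group_a, group_b = group_b)
}

#' Two-group secretome enrichment with difference, p-value and score gates
#'
#' For each protein with at least two valid intensities per group, computes
#' the group-mean difference `mean(A) - mean(B)`, a two-sample Student
#' t-test p-value (pooled variance by default, matching the Perseus
#' "Student's t-test"; Welch via `var_equal = FALSE`), and the volcano
#' coordinate `-log10(p)`. A protein passes when all three gates hold:
#' difference greater than `diff_min`, p-value below `p_max`, and
#' identification score above `score_min`. The difference gate assumes
#' log-scale intensities (a MaxQuant LFQ convention); on raw-scale inputs
#' the threshold means something else entirely.
#'
#' Degenerate inputs follow fixed conventions: zero variance in both groups
#' with equal means gives p = 1; with unequal means p = 0 and the protein
#' is flagged `degenerate`. Proteins failing the replicate minimum are
#' reported with `tested = FALSE` and never pass.
#'
#' @param table an [lfq_table()].
#' @param diff_min minimum group-mean difference (log units).
#' @param p_max maximum raw p-value (no multiple-testing correction, by
#'   design).
#' @param score_min minimum identification score.
#' @param var_equal pooled-variance Student t-test when `TRUE` (default);
#'   Welch otherwise.
#' @return Data frame per protein: `protein_id`, `score`, `mean_a`,
#'   `mean_b`, `difference`, `t_stat`, `df`, `p_value`, `neg_log10_p`,
#'   `tested`, `degenerate`, `passes`.
#' @export
enrich <- function(table, diff_min = 3, p_max = 0.02, score_min = 40,
                   var_equal = TRUE) {
  stopifnot(inherits(table, "lfq_table"))
  a_cols <- attr(table, "group_a")
  b_cols <- attr(table, "group_b")
  df <- as.data.frame(table)
  n <- nrow(df)
  res <- data.frame(protein_id = df$protein_id, score = df$score,
                    mean_a = NA_real_, mean_b = NA_real_,
                    difference = NA_real_, t_stat = NA_real_, df = NA_real_,
                    p_value = NA_real_, neg_log10_p = NA_real_,
                    tested = FALSE, degenerate = FALSE, passes = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    a <- as.numeric(df[i, a_cols])
    b <- as.numeric(df[i, b_cols])
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2L || length(b) < 2L) next
    res$tested[i] <- TRUE
    res$mean_a[i] <- mean(a)
    res$mean_b[i] <- mean(b)
    res$difference[i] <- mean(a) - mean(b)
    if (sd(a) == 0 && sd(b) == 0) {
      if (mean(a) == mean(b)) {
        res$p_value[i] <- 1
      } else {
        res$p_value[i] <- 0
        res$degenerate[i] <- TRUE
      }
      res$neg_log10_p[i] <- -log10(res$p_value[i])
      next
    }
    tt <- t.test(a, b, var.equal = var_equal)
    res$t_stat[i] <- unname(tt$statistic)
    res$df[i] <- unname(tt$parameter)
    res$p_value[i] <- tt$p.value
    res$neg_log10_p[i] <- -log10(tt$p.value)
  }
  res$passes <- res$tested & !is.na(res$difference) &
    res$difference > diff_min & res$p_value < p_max & res$score > score_min
  res
}

#' Read an LFQ table from TSV
#'
#' @param path TSV with `protein_id`, `score` and intensity columns.
#' @param group_a,group_b intensity column names.
#' @return An [lfq_table()].
#' @export
read_lfq_tsv <- function(path, group_a, group_b) {
  lfq_table(read.delim(path, stringsAsFactors = FALSE, check.names = FALSE),
            group_a, group_b)
}

#' Write an LFQ table (or enrichment result) as TSV
#' @param x data frame.
#' @param path output path.
#' @export
write_lfq_tsv <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
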