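#' Scan a protein database with a calibrated profile
#'
#' Aligns the profile locally (position-specific scores, affine gaps)
#' against every subject. Multiple non-overlapping hits per subject are
#' extracted by masking previously aligned subject residues and re-aligning,
#' mirroring how a bipartite domain yields two profile hits. A hit is kept
#' when its E-value is at most `e_max`; a subject is reported only when the
#' distinct profile columns covered by all of its kept hits reach
#' `min_coverage` of the profile width (overall-domain coverage).
#'
#' @param profile a calibrated `whix_profile` (see [calibrate()]).
#' @param db named character vector of protein sequences (or `AAStringSet`).
#' @param params a [search_params()].
#' @return A data frame of domain hits, sorted by subject accession and
#'   subject start, with list-columns `prof_cols`/`sub_pos` carrying the
#'   aligned column map (used by profile iteration), and per-subject
#'   `subject_coverage`.
#' @export
scan_database <- function(profile, db, params = search_params()) {
  stopifnot(inherits(profile, "whix_profile"))
  if (is.null(profile$calibration))
    stop("profile is not calibrated; run calibrate() first", call. = FALSE)
  db <- as_protein_set(db)
  empty <- data.frame(subject_acc = character(0), sub_start = integer(0),
                      sub_end = integer(0), prof_start = integer(0),
                      prof_end = integer(0), raw_score = numeric(0),
                      bit_score = numeric(0), e_value = numeric(0),
                      coverage = numeric(0), subject_coverage = numeric(0))
  if (length(db) == 0L) return(empty)
  db_residues <- sum(nchar(db))
  W <- profile$width

  out <- vector("list", length(db))
  for (k in seq_along(db)) {
    enc <- encode_protein(db[[k]])
    mask <- rep(FALSE, length(enc))
    hits <- list()
    cols_union <- integer(0)
    for (h in seq_len(params$max_hits_per_subject)) {
      aln <- .sw_align_profile(profile$scores, enc, params$gap_open,
                               params$gap_extend, mask)
      if (aln$score <= 0) break
      ev <- profile_evalue(profile, aln$score, db_residues)
      if (ev > params$e_max) break
      cols <- unique(aln$prof_cols)
      hits[[length(hits) + 1L]] <- data.frame(
        subject_acc = names(db)[k], sub_start = aln$sub_start,
        sub_end = aln$sub_end, prof_start = aln$prof_start,
        prof_end = aln$prof_end, raw_score = aln$score,
        bit_score = aln$score / 2, e_value = ev,
        coverage = length(cols) / W, stringsAsFactors = FALSE)
      hits[[length(hits)]]$prof_cols <- I(list(aln$prof_cols))
      hits[[length(hits)]]$sub_pos <- I(list(aln$sub_pos))
      cols_union <- union(cols_union, cols)
      mask[aln$sub_start:aln$sub_end] <- TRUE
    }
    if (!length(hits)) next
    subj <- do.call(rbind, hits)
    subj$subject_coverage <- length(cols_union) / W
    if (subj$subject_coverage[1] >= params$min_coverage)
      out[[k]] <- subj
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) return(empty)
  res <- res[order(res$subject_acc, res$sub_start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

as_protein_set <- function(db) {
  if (methods::is(db, "XStringSet"))
    db <- setNames(as.character(db), names(db))
  if (length(db) && is.null(names(db)))
    stop("protein set must be named by accession", call. = FALSE)
  db
}

#' Merge the hits of one subject into a single domain call
#'
#' The domain interval spans from the starting position of the first hit to
#' the ending position of the last hit (hits ordered along the subject).
#'
#' @param hits data frame of hits for a single subject (from
#'   [scan_database()]).
#' @return One-row data frame: `subject_acc`, `domain_start`, `domain_end`,
#'   `n_hits`.
#' @export
merge_hits <- function(hits) {
  if (nrow(hits) < 1L) stop("no hits to merge", call. = FALSE)
  if (length(unique(hits$subject_acc)) != 1L)
    stop("merge_hits() expects hits of a single subject", call. = FALSE)
  data.frame(subject_acc = hits$subject_acc[1],
             domain_start = min(hits$sub_start),
             domain_end = max(hits$sub_end),
             n_hits = nrow(hits), stringsAsFactors = FALSE)
}

#' Merge hits subject-by-subject into domain calls
#'
#' @param hits hit table from [scan_database()].
#' @return Data frame with one domain call per subject accession.
#' @export
merge_all_hits <- function(hits) {
  if (nrow(hits) == 0L)
    return(data.frame(subject_acc = character(0), domain_start = integer(0),
                      domain_end = integer(0), n_hits = integer(0)))
  res <- do.call(rbind, lapply(split(hits, hits$subject_acc), merge_hits))
  rownames(res) <- NULL
  res[order(res$subject_acc), , drop = FALSE]
}

#' Iterative profile enrichment from a seed region
#'
#' Iteration 0 scores the database with a single-sequence profile built from
#' the plain substitution matrix over the seed region. Each subsequent
#' iteration keeps at most `max_hits_per_iteration` subjects passing the
#' E-value and coverage filters (best E-value first), aligns their residues
#' back to seed columns via the hits' profile-column maps, and rebuilds the
#' pseudocount-smoothed log-odds profile (the seed itself is always
#' included, so columns never covered by hits retain their seed-based
#' estimate). Iteration stops after `params$iterations` rounds or as soon as
#' the included-subject set repeats (convergence).
#'
#' @param seed_region seed amino-acid sequence (profile width = its length).
#' @param db named character vector of protein sequences.
#' @param params a [search_params()].
#' @param pseudocount_weight pseudocount mass for rebuilt profiles.
#' @param rng_seed base seed for per-iteration calibration.
#' @return Calibrated `whix_profile` with attributes `iterations_run` and
#'   `included_per_iteration` (list of subject-accession sets).
#' @export
iterate_profile <- function(seed_region, db, params = search_params(),
                            pseudocount_weight = 1, rng_seed = 1L) {
  if (nchar(seed_region) < 1L) stop("seed region is empty", call. = FALSE)
  db <- as_protein_set(db)
  bg <- background_frequencies()
  profile <- single_sequence_profile(seed_region, params$substitution_matrix,
                                     bg)
  profile <- calibrate(profile, params, rng_seed = rng_seed)
  seed_codes <- match(strsplit(toupper(seed_region), "")[[1]], AA20)
  W <- profile$width

  included <- list()
  prev_set <- NULL
  it_run <- 0L
  for (it in seq_len(params$iterations)) {
    hits <- scan_database(profile, db, params)
    if (nrow(hits) == 0L) {
      if (it == 1L) {
        warning("no hits in iteration 0; returning the single-sequence ",
                "profile")
        break
      }
      break
    }
    best_e <- vapply(split(hits$e_value, hits$subject_acc), min, numeric(1))
    keep_accs <- names(sort(best_e))[
      seq_len(min(length(best_e), params$max_hits_per_iteration))]
    included[[it]] <- sort(keep_accs)
    it_run <- it
    if (!is.null(prev_set) && identical(prev_set, sort(keep_accs))) break
    prev_set <- sort(keep_accs)

    counts <- matrix(0, W, 20L)
    sel <- hits[hits$subject_acc %in% keep_accs, , drop = FALSE]
    for (r in seq_len(nrow(sel))) {
      subj_res <- strsplit(db[[sel$subject_acc[r]]], "")[[1]]
      codes <- match(subj_res[sel$sub_pos[[r]]], AA20)
      cols <- sel$prof_cols[[r]]
      ok <- !is.na(codes)
      if (any(ok)) {
        idx <- cbind(cols[ok], codes[ok])
        for (q in seq_len(nrow(idx)))
          counts[idx[q, 1], idx[q, 2]] <- counts[idx[q, 1], idx[q, 2]] + 1
      }
    }
    uncovered <- rowSums(counts) == 0
    ok <- uncovered & !is.na(seed_codes)
    counts[cbind(which(ok), seed_codes[ok])] <- 1
    profile <- new_profile(scores_from_counts(counts, bg[AA20],
                                              pseudocount_weight),
                           bg[AA20], pseudocount_weight)
    profile <- calibrate(profile, params, rng_seed = rng_seed + it)
  }
  attr(profile, "iterations_run") <- it_run
  attr(profile, "included_per_iteration") <- included
  profile
}
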