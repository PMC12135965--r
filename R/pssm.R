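#' Search parameters for profile construction and scanning
#'
#' Defaults follow the published search protocol: at most 500 hits per
#' iteration, an expect-value threshold of 1e-6, 70 percent overall coverage
#' of the domain profile, and five profile iterations. Gap penalties are the
#' BLAST-like affine defaults (open 11, extend 1, in half-bit units).
#'
#' @param e_max reporting and inclusion E-value threshold (> 0).
#' @param min_coverage minimum fraction of profile columns covered per
#'   subject, in (0, 1].
#' @param iterations number of profile iterations (>= 1).
#' @param max_hits_per_iteration cap on subjects used to rebuild the profile.
#' @param gap_open,gap_extend affine gap penalties; opening a gap costs
#'   `gap_open + gap_extend`.
#' @param substitution_matrix matrix used for the iteration-0 single-sequence
#'   profile (a matrix name resolvable by [Biostrings]).
#' @param max_hits_per_subject cap on distinct local hits extracted per
#'   subject by iterative masking.
#' @param calib_method `"empirical"` (Gumbel fit to null maxima) or
#'   `"analytic"` (Karlin-Altschul lambda/K derived from the same fit).
#' @param calib_null_n number of background-sampled null sequences used for
#'   calibration.
#' @param calib_null_len null sequence length; defaults to the profile width.
#' @return A validated list of class `whix_search_params`.
#' @export
search_params <- function(e_max = 1e-6, min_coverage = 0.70, iterations = 5L,
                          max_hits_per_iteration = 500L,
                          gap_open = 11, gap_extend = 1,
                          substitution_matrix = "BLOSUM62",
                          max_hits_per_subject = 4L,
                          calib_method = c("empirical", "analytic"),
                          calib_null_n = 300L, calib_null_len = NULL) {
  p <- list(e_max = e_max, min_coverage = min_coverage,
            iterations = as.integer(iterations),
            max_hits_per_iteration = as.integer(max_hits_per_iteration),
            gap_open = gap_open, gap_extend = gap_extend,
            substitution_matrix = substitution_matrix,
            max_hits_per_subject = as.integer(max_hits_per_subject),
            calib_method = match.arg(calib_method),
            calib_null_n = as.integer(calib_null_n),
            calib_null_len = calib_null_len)
  if (!is.numeric(p$e_max) || p$e_max <= 0)
    stop("e_max must be > 0", call. = FALSE)
  if (p$min_coverage <= 0 || p$min_coverage > 1)
    stop("min_coverage must lie in (0, 1]", call. = FALSE)
  if (p$iterations < 1L) stop("iterations must be >= 1", call. = FALSE)
  if (p$gap_open < 0 || p$gap_extend < 0)
    stop("gap penalties must be >= 0", call. = FALSE)
  class(p) <- "whix_search_params"
  p
}

new_profile <- function(scores, background, pseudocount) {
  stopifnot(is.matrix(scores), ncol(scores) == 20L)
  colnames(scores) <- AA20
  structure(list(width = nrow(scores), scores = scores,
                 background = background, pseudocount = pseudocount,
                 calibration = NULL),
            class = "whix_profile")
}

#' @export
print.whix_profile <- function(x, ...) {
  cat("Position-specific scoring matrix:", x$width, "columns\n")
  cat("  score units: half-bits; pseudocount weight:", x$pseudocount, "\n")
  if (is.null(x$calibration)) cat("  calibration: none\n")
  else cat("  calibration:", x$calibration$method, "(null n =",
           x$calibration$null_n, ", null len =", x$calibration$null_len, ")\n")
  invisible(x)
}

# Shared log-odds construction from per-column residue counts.
# counts: width x 20; weights row sums may differ per column.
scores_from_counts <- function(counts, background, pseudocount) {
  n_col <- rowSums(counts)
  alpha <- pseudocount
  p <- (counts + alpha * matrix(background, nrow(counts), 20L, byrow = TRUE)) /
    (n_col + alpha)
  2 * log2(p / matrix(background, nrow(counts), 20L, byrow = TRUE))
}

#' Build a position-specific scoring matrix from an alignment
#'
#' Columns at which the reference sequence carries a gap are dropped, so the
#' profile width equals the ungapped reference length over the seed region.
#' Per-column residue frequencies (gaps excluded) are smoothed towards the
#' background with a fixed pseudocount mass and converted to half-bit
#' log-odds scores.
#'
#' @param alignment named character vector of equal-length gapped sequences
#'   (or a `Biostrings::AAStringSet`/`AAMultipleAlignment`).
#' @param reference_id name of the reference row.
#' @param pseudocount_weight total pseudocount mass added per column (> 0
#'   keeps every score finite).
#' @param background residue background frequencies.
#' @return A `whix_profile` (uncalibrated).
#' @export
build_pssm <- function(alignment, reference_id, pseudocount_weight = 1,
                       background = background_frequencies()) {
  alignment <- as_gapped_character(alignment)
  if (length(alignment) == 0L)
    stop("alignment is empty", call. = FALSE)
  if (!reference_id %in% names(alignment))
    stop("reference `", reference_id, "` not found in alignment",
         call. = FALSE)
  mat <- do.call(rbind, strsplit(toupper(alignment), ""))
  if (length(unique(nchar(alignment))) != 1L)
    stop("alignment rows differ in length", call. = FALSE)
  keep <- mat[match(reference_id, names(alignment)), ] != "-"
  if (!any(keep))
    stop("degenerate alignment: zero columns remain after trimming to the ",
         "reference", call. = FALSE)
  mat <- mat[, keep, drop = FALSE]
  bg <- background[AA20]
  counts <- t(apply(mat, 2L, function(col)
    tabulate(match(col, AA20), nbins = 20L)))
  new_profile(scores_from_counts(counts, bg, pseudocount_weight),
              bg, pseudocount_weight)
}

# Iteration-0 profile: one row of the plain substitution matrix per seed
# residue, in the matrix's native (half-bit) units.
single_sequence_profile <- function(seq, matrix_name = "BLOSUM62",
                                    background = background_frequencies()) {
  mat <- get_substitution_matrix(matrix_name)
  res <- strsplit(toupper(seq), "")[[1]]
  scores <- mat[res, AA20, drop = FALSE]
  rownames(scores) <- NULL
  new_profile(unname(scores) + 0, background[AA20], pseudocount = 0)
}

get_substitution_matrix <- function(name) {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  m <- get(name, envir = e)
  storage.mode(m) <- "double"
  m
}

as_gapped_character <- function(x) {
  if (methods::is(x, "AAMultipleAlignment"))
    x <- methods::as(x, "AAStringSet")
  if (methods::is(x, "XStringSet"))
    x <- setNames(as.character(x), names(x))
  x
}

gumbel_neg_loglik <- function(par, x) {
  mu <- par[1]; beta <- par[2]
  if (beta <= 0) return(1e12)
  z <- (x - mu) / beta
  sum(log(beta) + z + exp(-z))
}

gumbel_tail <- function(s, mu, beta) {
  # P(max >= s) under Gumbel(mu, beta); stable in the far tail
  z <- (s - mu) / beta
  -expm1(-exp(-z))
}

#' Calibrate a profile's score-to-E-value mapping
#'
#' Scans `null_n` background-sampled sequences of length `null_len` with the
#' profile, collects per-sequence maximal local scores, and fits an
#' extreme-value (Gumbel) distribution by maximum likelihood. The
#' `"analytic"` method re-expresses the same fit as Karlin-Altschul
#' parameters (lambda = 1/scale, K from the location); if that conversion
#' degenerates it falls back to the empirical fit with a warning. E-values
#' scale linearly with database search space and are nonincreasing in score.
#'
#' @param profile a `whix_profile`.
#' @param params a [search_params()] (gap penalties and calibration sizes).
#' @param rng_seed seed for the null sample (calibration is deterministic
#'   given profile, params and seed).
#' @return The profile with a `calibration` record attached.
#' @export
calibrate <- function(profile, params = search_params(), rng_seed = 1L) {
  stopifnot(inherits(profile, "whix_profile"))
  set.seed(rng_seed)
  null_len <- params$calib_null_len %||% profile$width
  nulls <- replicate(params$calib_null_n,
                     sample_background(null_len, profile$background))
  enc <- lapply(nulls, encode_protein)
  maxima <- .sw_score_batch(profile$scores, enc,
                            params$gap_open, params$gap_extend)
  init <- c(mean(maxima) - 0.5772 * sd(maxima) * sqrt(6) / pi,
            sd(maxima) * sqrt(6) / pi)
  fit <- optim(init, gumbel_neg_loglik, x = maxima, method = "Nelder-Mead")
  mu <- fit$par[1]; beta <- fit$par[2]

  calib <- list(method = "empirical", mu = mu, beta = beta,
                null_n = params$calib_null_n, null_len = null_len,
                gap_open = params$gap_open, gap_extend = params$gap_extend,
                maxima = maxima)
  if (params$calib_method == "analytic") {
    lambda <- 1 / beta
    K <- exp(mu * lambda) / (profile$width * null_len)
    if (!is.finite(lambda) || lambda <= 0 || !is.finite(K) || K <= 0 ||
        fit$convergence != 0) {
      warning("analytic Karlin-Altschul fit diverged; ",
              "falling back to empirical calibration")
    } else {
      calib$method <- "analytic"
      calib$lambda <- lambda
      calib$K <- K
    }
  }
  profile$calibration <- calib
  profile
}

#' E-value of a raw score against a calibrated profile
#'
#' @param profile calibrated `whix_profile`.
#' @param score raw local alignment score(s), half-bit units.
#' @param db_residues total residue count of the searched database.
#' @return Expected number of equal-or-better chance hits.
#' @export
profile_evalue <- function(profile, score, db_residues) {
  cal <- profile$calibration
  if (is.null(cal))
    stop("profile is not calibrated; run calibrate() first", call. = FALSE)
  if (identical(cal$method, "analytic"))
    cal$K * profile$width * db_residues * exp(-cal$lambda * score)
  else
    (db_residues / cal$null_len) * gumbel_tail(score, cal$mu, cal$beta)
}

#' Serialize a profile to a versioned text format
#'
#' @param profile a `whix_profile`.
#' @param path output file.
#' @export
write_profile <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#whixscan-profile v1",
               paste0("#width\t", profile$width),
               paste0("#pseudocount\t", profile$pseudocount),
               paste0("#background\t",
                      paste(formatC(profile$background, format = "g",
                                    digits = 10), collapse = ",")),
               if (!is.null(profile$calibration))
                 paste0("#calibration\t", profile$calibration$method, "\t",
                        formatC(profile$calibration$mu, format = "g",
                                digits = 12), "\t",
                        formatC(profile$calibration$beta, format = "g",
                                digits = 12), "\t",
                        profile$calibration$null_n, "\t",
                        profile$calibration$null_len, "\t",
                        profile$calibration$gap_open, "\t",
                        profile$calibration$gap_extend),
               paste(c("col", AA20), collapse = "\t")), con)
  for (i in seq_len(profile$width))
    writeLines(paste(c(i, formatC(profile$scores[i, ], format = "g",
                                  digits = 12)), collapse = "\t"), con)
  invisible(path)
}

#' Read a profile written by [write_profile()]
#' @param path file path.
#' @return A `whix_profile`.
#' @export
read_profile <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "#whixscan-profile"))
    stop("not a whixscan profile file", call. = FALSE)
  hdr <- lines[startsWith(lines, "#")]
  field <- function(key) {
    ln <- hdr[startsWith(hdr, paste0("#", key))]
    if (!length(ln)) return(NULL)
    strsplit(sub(paste0("^#", key, "\t"), "", ln[1]), "\t")[[1]]
  }
  bg <- as.numeric(strsplit(field("background"), ",")[[1]])
  names(bg) <- AA20
  body <- lines[!startsWith(lines, "#")]
  body <- body[-1]  # column header
  rows <- do.call(rbind, lapply(strsplit(body, "\t"), as.numeric))
  prof <- new_profile(rows[, -1, drop = FALSE], bg,
                      as.numeric(field("pseudocount")))
  cal <- field("calibration")
  if (!is.null(cal)) {
    prof$calibration <- list(method = cal[1], mu = as.numeric(cal[2]),
                             beta = as.numeric(cal[3]),
                             null_n = as.integer(cal[4]),
                             null_len = as.integer(cal[5]),
                             gap_open = as.numeric(cal[6]),
                             gap_extend = as.numeric(cal[7]))
    if (cal[1] == "analytic") {
      prof$calibration$lambda <- 1 / prof$calibration$beta
      prof$calibration$K <- exp(prof$calibration$mu / prof$calibration$beta) /
        (prof$width * prof$calibration$null_len)
    }
  }
  prof
}
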