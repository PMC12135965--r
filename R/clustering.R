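#' Extract N- and C-terminal extension sequences from annotations
#'
#' N-terminal extensions are taken from subclass II effectors only
#' (residues 1 to `whix_start - 1`). C-terminal material is the last
#' `c_tail` residues of every protein with a C-terminal extension (the
#' whole tail when the protein is shorter), mirroring the "last 100 amino
#' acids" convention for toxin-domain clustering.
#'
#' @param annotations annotation table from [annotate_all()].
#' @param proteins named character vector of sequences.
#' @param c_tail tail window length (default 100).
#' @return List with `n_term` and `c_term` named character vectors.
#' @export
extract_termini <- function(annotations, proteins, c_tail = 100L) {
  proteins <- as_protein_set(proteins)
  n_term <- character(0)
  c_term <- character(0)
  for (i in seq_len(nrow(annotations))) {
    a <- annotations[i, ]
    seq <- proteins[[a$protein_acc]]
    if (identical(a$subclass, "II") && a$n_ext_len > 0L)
      n_term[a$protein_acc] <- substr(seq, 1L, a$whix_start - 1L)
    if (isTRUE(a$has_c_extension)) {
      len <- nchar(seq)
      c_term[a$protein_acc] <- substr(seq, max(1L, len - c_tail + 1L), len)
    }
  }
  list(n_term = n_term, c_term = c_term)
}

#' Local alignment similarity score between two sequences
#'
#' BLOSUM62 Smith-Waterman score via [Biostrings::pairwiseAlignment()];
#' the primitive behind [pairwise_similarity()].
#'
#' @param x protein sequence(s); vectorized against a single `y`.
#' @param y a single protein sequence.
#' @param gap_open,gap_extend affine gap penalties.
#' @return Numeric score vector, one per element of `x`.
#' @export
local_similarity_score <- function(x, y, gap_open = 11, gap_extend = 1) {
  as.numeric(Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(x), y, type = "local",
    substitutionMatrix = "BLOSUM62",
    gapOpening = gap_open, gapExtension = gap_extend, scoreOnly = TRUE))
}

#' All-vs-all similarity edges over a sequence set
#'
#' Scores every unordered pair by local BLOSUM62 alignment and attaches an
#' attenuation value `p_like`: the Gumbel tail probability of the score
#' under a null of residue-shuffled pairs drawn from the same set. Edges
#' with `p_like` above `p_max` are dropped.
#'
#' @param seqs named character vector (>= 2 sequences).
#' @param p_max significance threshold for keeping an edge.
#' @param n_null number of shuffled pairs for the null fit.
#' @param rng_seed seed for shuffling.
#' @param gap_open,gap_extend affine gap penalties.
#' @return Data frame `acc_a`, `acc_b`, `score`, `p_like` (kept edges only),
#'   with the null fit in the `null_fit` attribute.
#' @export
pairwise_similarity <- function(seqs, p_max = 1e-4, n_null = 200L,
                                rng_seed = 1L, gap_open = 11,
                                gap_extend = 1) {
  if (length(seqs) < 2L)
    stop("need at least two sequences", call. = FALSE)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must have unique names", call. = FALSE)
  set.seed(rng_seed)
  shuffle <- function(s) paste(sample(strsplit(s, "")[[1]]), collapse = "")
  idx <- cbind(sample.int(length(seqs), n_null, replace = TRUE),
               sample.int(length(seqs), n_null, replace = TRUE))
  null_scores <- vapply(seq_len(n_null), function(r)
    local_similarity_score(shuffle(seqs[[idx[r, 1]]]),
                           shuffle(seqs[[idx[r, 2]]]),
                           gap_open, gap_extend)[1], numeric(1))
  init <- c(mean(null_scores) - 0.5772 * sd(null_scores) * sqrt(6) / pi,
            sd(null_scores) * sqrt(6) / pi)
  fit <- optim(init, gumbel_neg_loglik, x = null_scores,
               method = "Nelder-Mead")
  mu <- fit$par[1]; beta <- fit$par[2]

  n <- length(seqs)
  rows <- list()
  for (i in seq_len(n - 1L)) {
    sc <- local_similarity_score(seqs[(i + 1L):n], seqs[[i]],
                                 gap_open, gap_extend)
    p <- gumbel_tail(sc, mu, beta)
    keep <- p <= p_max
    if (any(keep))
      rows[[length(rows) + 1L]] <- data.frame(
        acc_a = names(seqs)[i], acc_b = names(seqs)[(i + 1L):n][keep],
        score = sc[keep], p_like = p[keep], stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(acc_a = character(0), acc_b = character(0),
               score = numeric(0), p_like = numeric(0))
  rownames(out) <- NULL
  attr(out, "null_fit") <- list(mu = mu, beta = beta, n_null = n_null)
  out
}

#' Cluster extension sequences into putative toxin families
#'
#' Connected components of the thresholded similarity graph partition the
#' input set. Components smaller than `min_size` are labeled `"others"`
#' (left unanalyzed); larger components are labeled `family_1`,
#' `family_2`, ... in decreasing size order (ties broken by smallest member
#' accession, so the labeling is input-order invariant).
#'
#' @param edges edge table from [pairwise_similarity()].
#' @param nodes all accessions to partition (isolated nodes become
#'   singletons).
#' @param min_size minimum members for a named family (default 4).
#' @return Data frame `acc`, `cluster_id`, `label`, `size`.
#' @export
cluster_extensions <- function(edges, nodes, min_size = 4L) {
  nodes <- sort(unique(nodes))
  g <- igraph::graph_from_data_frame(
    edges[edges$acc_a %in% nodes & edges$acc_b %in% nodes,
          c("acc_a", "acc_b"), drop = FALSE],
    directed = FALSE, vertices = nodes)
  comp <- igraph::components(g)
  membership <- comp$membership[nodes]
  comps <- split(nodes, membership)
  ord <- order(-vapply(comps, length, integer(1)),
               vapply(comps, min, character(1)))
  comps <- comps[ord]
  rows <- lapply(seq_along(comps), function(ci) {
    members <- comps[[ci]]
    data.frame(acc = members, cluster_id = ci,
               label = if (length(members) < min_size) "others"
                 else sprintf("family_%d", ci),
               size = length(members), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$acc), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export similarity edges in a CLANS-compatible matrix text layout
#'
#' @param edges edge table from [pairwise_similarity()].
#' @param nodes accession set (declares isolated nodes too).
#' @param path output file.
#' @export
write_clans_matrix <- function(edges, nodes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("sequences=", length(nodes)), "<seq>"), con)
  writeLines(paste0(">", nodes), con)
  writeLines(c("</seq>", "<hsp>"), con)
  ia <- match(edges$acc_a, nodes) - 1L
  ib <- match(edges$acc_b, nodes) - 1L
  writeLines(sprintf("%d %d:%.3e", ia, ib, edges$p_like), con)
  writeLines("</hsp>", con)
  invisible(path)
}
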