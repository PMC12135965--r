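mutants <- function(consensus, n, rate, prefix) {
  out <- vapply(seq_len(n), function(i)
    whixscan:::mutate_sequence(consensus, rate), "")
  setNames(out, sprintf("%s_%02d", prefix, seq_len(n)))
}

test_that("terminus extraction follows the domain geometry", {
  # double-blade architecture: 862 aa, domain 148..699
  set.seed(2)
  protein <- whixscan:::sample_background(862)
  ann <- data.frame(protein_acc = "AWE1", whix_start = 148L,
                    whix_end = 699L, subclass = "II", n_ext_len = 147L,
                    c_ext_len = 163L, has_c_extension = TRUE,
                    stringsAsFactors = FALSE)
  t <- extract_termini(ann, c(AWE1 = protein))
  expect_identical(unname(t$n_term["AWE1"]), substr(protein, 1, 147))
  expect_identical(unname(t$c_term["AWE1"]), substr(protein, 763, 862))
  expect_identical(nchar(t$c_term[["AWE1"]]), 100L)

  # subclass I contributes no N-terminal entry
  ann1 <- ann
  ann1$subclass <- "I"; ann1$n_ext_len <- 0L; ann1$whix_start <- 1L
  t1 <- extract_termini(ann1, c(AWE1 = protein))
  expect_length(t1$n_term, 0L)

  # short proteins clamp to the full tail
  short <- whixscan:::sample_background(80)
  ann2 <- data.frame(protein_acc = "S", whix_start = 1L, whix_end = 60L,
                     subclass = "I", n_ext_len = 0L, c_ext_len = 20L,
                     has_c_extension = TRUE, stringsAsFactors = FALSE)
  t2 <- extract_termini(ann2, c(S = short))
  expect_identical(unname(t2$c_term["S"]), short)
  expect_lte(nchar(t2$c_term[["S"]]), 100L)
})

test_that("similarity scores are symmetric and identical pairs always connect", {
  set.seed(4)
  a <- whixscan:::sample_background(120)
  b <- whixscan:::sample_background(120)
  expect_identical(local_similarity_score(a, b),
                   local_similarity_score(b, a))
  edges <- pairwise_similarity(c(x = a, y = a, z = b), rng_seed = 1L)
  xy <- edges[(edges$acc_a == "x" & edges$acc_b == "y") |
                (edges$acc_a == "y" & edges$acc_b == "x"), ]
  expect_identical(nrow(xy), 1L)
  expect_lt(xy$p_like, 1e-10)
})

test_that("random unrelated pairs rarely pass a strict threshold", {
  set.seed(6)
  seqs <- setNames(replicate(25, whixscan:::sample_background(100)),
                   sprintf("R%02d", 1:25))
  edges <- pairwise_similarity(seqs, p_max = 1e-4, rng_seed = 2L)
  # 300 unordered background pairs at p <= 1e-4: expect about 0 edges
  expect_lte(nrow(edges), 2L)
})

test_that("planted extension families are recovered as named clusters", {
  set.seed(8)
  fams <- lapply(1:3, function(k) whixscan:::sample_background(120))
  seqs <- c(mutants(fams[[1]], 10, 0.05, "A"),
            mutants(fams[[2]], 10, 0.05, "B"),
            mutants(fams[[3]], 10, 0.05, "C"))
  edges <- pairwise_similarity(seqs, rng_seed = 3L)
  cl <- cluster_extensions(edges, names(seqs))
  named <- cl[cl$label != "others", ]
  expect_identical(sort(unique(named$label)),
                   c("family_1", "family_2", "family_3"))
  # members of one planted family share one cluster label
  planted <- substr(cl$acc, 1, 1)
  expect_identical(length(unique(paste(planted, cl$label))), 3L)
})

test_that("the <4-member rule labels small components as others", {
  nodes <- paste0("n", 1:7)
  edges3 <- data.frame(acc_a = c("n1", "n2"), acc_b = c("n2", "n3"),
                       score = 100, p_like = 1e-9)
  cl <- cluster_extensions(edges3, nodes)
  expect_identical(unique(cl$label[cl$acc %in% c("n1", "n2", "n3")]),
                   "others")
  edges4 <- rbind(edges3, data.frame(acc_a = "n3", acc_b = "n4",
                                     score = 100, p_like = 1e-9))
  cl4 <- cluster_extensions(edges4, nodes)
  expect_identical(unique(cl4$label[cl4$acc %in% paste0("n", 1:4)]),
                   "family_1")
  # no edges: every node a singleton labeled others
  cl0 <- cluster_extensions(edges3[0, ], nodes)
  expect_identical(nrow(cl0), 7L)
  expect_true(all(cl0$label == "others"))
  expect_true(all(cl0$size == 1L))
})

test_that("clustering is invariant to input order", {
  set.seed(12)
  nodes <- sprintf("m%02d", 1:30)
  edges <- data.frame(acc_a = sample(nodes, 40, TRUE),
                      acc_b = sample(nodes, 40, TRUE),
                      score = 50, p_like = 1e-9)
  edges <- edges[edges$acc_a != edges$acc_b, ]
  cl1 <- cluster_extensions(edges, nodes)
  perm <- sample(nrow(edges))
  cl2 <- cluster_extensions(edges[perm, ], rev(nodes))
  expect_identical(cl1, cl2)
})

test_that("components match a union-find oracle on random graphs", {
  set.seed(14)
  for (rep in 1:50) {
    n <- sample(5:60, 1)
    nodes <- sprintf("v%03d", seq_len(n))
    m <- sample(0:(2 * n), 1)
    ea <- sample(nodes, m, TRUE)
    eb <- sample(nodes, m, TRUE)
    keep <- ea != eb
    edges <- data.frame(acc_a = ea, acc_b = eb, score = rep(1, m),
                        p_like = rep(1e-9, m))[keep, , drop = FALSE]
    cl <- cluster_extensions(edges, nodes, min_size = 4L)
    roots <- union_find_components(nodes, edges$acc_a, edges$acc_b)
    # identical partitions: same co-membership for every pair sample
    got <- cl$cluster_id[match(nodes, cl$acc)]
    expect_identical(length(unique(got)), length(unique(roots)))
    expect_true(all(tapply(roots, got, function(x)
      length(unique(x)) == 1L)))
  }
})

test_that("CLANS matrix export writes all nodes and thresholded edges", {
  nodes <- c("a", "b", "c")
  edges <- data.frame(acc_a = "a", acc_b = "b", score = 99, p_like = 1e-8)
  path <- withr::local_tempfile(fileext = ".clans")
  write_clans_matrix(edges, nodes, path)
  lines <- readLines(path)
  expect_identical(sum(startsWith(lines, ">")), 3L)
  expect_true(any(grepl("^0 1:", lines)))
})
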