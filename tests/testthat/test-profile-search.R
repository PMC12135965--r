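test_that("PSSM columns matching the background score zero; reference gaps define width", {
  # uniform background + one of each residue per column => smoothed
  # frequencies equal the background exactly, so all scores are 0
  aas <- paste(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
               collapse = "")
  aln <- setNames(strsplit(aas, "")[[1]], paste0("s", 1:20))
  uni <- setNames(rep(1 / 20, 20), strsplit(aas, "")[[1]])
  prof <- build_pssm(aln, "s1", pseudocount_weight = 1, background = uni)
  expect_equal(unname(prof$scores[1, ]), rep(0, 20), tolerance = 1e-12)

  # columns gapped in the reference are dropped
  aln2 <- c(ref = "A-C-G", other = "ABCDE")
  prof2 <- build_pssm(aln2, "ref")
  expect_identical(prof2$width, 3L)
  expect_error(build_pssm(aln2, "missing"), "missing")
  expect_error(build_pssm(c(ref = "---", x = "ACD"), "ref"), "degenerate")
})

test_that("single-sequence profile peaks at the reference residue", {
  seq <- "MKWHACDHLV"
  prof <- build_pssm(setNames(seq, "ref"), "ref", pseudocount_weight = 1e-9)
  res <- strsplit(seq, "")[[1]]
  for (i in seq_len(nchar(seq)))
    expect_identical(names(which.max(prof$scores[i, ])), res[i])
})

test_that("the synthetic seed region yields a 477-column profile", {
  db <- generate_effector_db(synthetic_config(n_family = 1L, n_decoy = 0L))
  expect_identical(nchar(db$seed_region), 477L)
  prof <- build_pssm(setNames(db$seed_region, "seed"), "seed")
  expect_identical(prof$width, 477L)
})

test_that("E-values scale linearly with database size and fall with score", {
  db <- generate_effector_db(tiny_config())
  for (method in c("empirical", "analytic")) {
    p <- tiny_params(calib_method = method)
    prof <- calibrate(single_seq <- build_pssm(
      setNames(db$seed_region, "seed"), "seed"), p, rng_seed = 7L)
    s <- seq(20, 400, by = 5)
    e1 <- profile_evalue(prof, s, 1e5)
    e2 <- profile_evalue(prof, s, 2e5)
    expect_equal(e2, 2 * e1, tolerance = 1e-9)
    expect_true(all(diff(e1) <= 0))
  }
})

test_that("calibration is deterministic given the seed", {
  db <- generate_effector_db(tiny_config())
  prof <- build_pssm(setNames(db$seed_region, "seed"), "seed")
  a <- calibrate(prof, tiny_params(), rng_seed = 3L)
  b <- calibrate(prof, tiny_params(), rng_seed = 3L)
  expect_identical(a$calibration, b$calibration)
})

test_that("scanning the seed against itself gives a full-coverage top hit", {
  cfg <- tiny_config()
  db <- generate_effector_db(cfg)
  seedset <- c(SEED_0001.1 = db$seed_region, db$proteins)
  p <- tiny_params()
  prof <- calibrate(build_pssm(setNames(db$seed_region, "seed"), "seed"), p,
                    rng_seed = 1L)
  hits <- scan_database(prof, seedset, p)
  self <- hits[hits$subject_acc == "SEED_0001.1", ]
  expect_identical(nrow(self), 1L)
  expect_identical(c(self$prof_start, self$prof_end), c(1L, prof$width))
  expect_equal(self$coverage, 1.0)
  expect_identical(max(hits$raw_score), self$raw_score)
  # filter soundness on everything returned
  expect_true(all(hits$e_value <= p$e_max))
  expect_true(all(hits$subject_coverage >= p$min_coverage))
})

test_that("uncalibrated profiles and empty databases are handled", {
  prof <- build_pssm(c(ref = "ACDEFGHIKL"), "ref")
  expect_error(scan_database(prof, c(x = "ACDEFGHIKL")), "calibrat")
  prof <- calibrate(prof, tiny_params(), rng_seed = 1L)
  expect_identical(nrow(scan_database(prof, character(0), tiny_params())),
                   0L)
})

test_that("background-shuffled decoys yield no hits at the default E threshold", {
  set.seed(42)
  seed <- sample_background(150)
  p <- tiny_params()
  prof <- calibrate(build_pssm(setNames(seed, "s"), "s"), p, rng_seed = 11L)
  decoys <- setNames(replicate(1000, sample_background(300)),
                     sprintf("N%04d", 1:1000))
  hits <- scan_database(prof, decoys, p)
  # expected false positives <= e_max * database size ~ 1e-3
  expect_identical(nrow(hits), 0L)
})

test_that("merged domain calls equal the min/max span of their hits", {
  h <- data.frame(subject_acc = "X", sub_start = c(10L, 120L),
                  sub_end = c(50L, 200L))
  call <- merge_hits(h)
  expect_identical(c(call$domain_start, call$domain_end), c(10L, 200L))
  single <- merge_hits(data.frame(subject_acc = "X", sub_start = 31L,
                                  sub_end = 476L))
  expect_identical(c(single$domain_start, single$domain_end), c(31L, 476L))
  expect_error(merge_hits(data.frame(subject_acc = c("X", "Y"),
                                     sub_start = 1L, sub_end = 2L)),
               "single subject")
})

test_that("profile iteration is a fixed point on a seed-only database", {
  cfg <- tiny_config()
  db <- generate_effector_db(cfg)
  seed_only <- c(SEED.1 = db$seed_region)
  p <- tiny_params(iterations = 5L)
  prof <- iterate_profile(db$seed_region, seed_only, p,
                          pseudocount_weight = 1, rng_seed = 5L)
  inc <- attr(prof, "included_per_iteration")
  expect_true(all(vapply(inc, identical, logical(1), y = "SEED.1")))
  ref <- build_pssm(setNames(db$seed_region, "SEED.1"), "SEED.1",
                    pseudocount_weight = 1)
  expect_equal(prof$scores, ref$scores, tolerance = 1e-12)
})

test_that("iteration improves or preserves recall on a divergent family", {
  cfg <- tiny_config(n_family = 40L, n_decoy = 150L,
                     substitution_rate = 0.25)
  db <- generate_effector_db(cfg)
  fam <- db$truth$acc[db$truth$is_family]
  recall_at <- function(iters) {
    p <- tiny_params(iterations = iters)
    prof <- iterate_profile(db$seed_region, db$proteins, p, rng_seed = 2L)
    hits <- scan_database(prof, db$proteins, p)
    mean(fam %in% hits$subject_acc)
  }
  r1 <- recall_at(1L)
  r5 <- recall_at(5L)
  expect_gte(r5, r1)
  expect_gte(r5, 0.9)
})

test_that("included hit sets never exceed the per-iteration cap", {
  cfg <- tiny_config()
  db <- generate_effector_db(cfg)
  p <- tiny_params(max_hits_per_iteration = 10L)
  prof <- iterate_profile(db$seed_region, db$proteins, p, rng_seed = 2L)
  inc <- attr(prof, "included_per_iteration")
  expect_true(all(lengths(inc) <= 10L))
  # defaults carry the conventional cap of 500
  expect_identical(search_params()$max_hits_per_iteration, 500L)
})

test_that("a sequence scores highest against its own profile", {
  set.seed(9)
  seqs <- setNames(replicate(20, sample_background(80)),
                   sprintf("Q%02d", 1:20))
  own <- seqs[[1]]
  p <- tiny_params(e_max = 1e3, min_coverage = 0.01)
  prof <- calibrate(build_pssm(setNames(own, "own"), "own"), p, rng_seed = 1L)
  enc <- lapply(seqs, whixscan:::encode_protein)
  scores <- whixscan:::.sw_score_batch(prof$scores, enc, p$gap_open,
                                       p$gap_extend)
  expect_identical(which.max(scores), 1L)
})

test_that("profile serialization round-trips scores and calibration", {
  db <- generate_effector_db(tiny_config())
  prof <- calibrate(build_pssm(setNames(db$seed_region, "s"), "s"),
                    tiny_params(), rng_seed = 4L)
  path <- withr::local_tempfile(fileext = ".txt")
  write_profile(prof, path)
  back <- read_profile(path)
  expect_equal(back$scores, prof$scores, tolerance = 1e-9)
  expect_equal(back$calibration$mu, prof$calibration$mu, tolerance = 1e-9)
  expect_equal(back$calibration$beta, prof$calibration$beta,
               tolerance = 1e-9)
  s <- c(50, 150, 250)
  expect_equal(profile_evalue(back, s, 1e5), profile_evalue(prof, s, 1e5),
               tolerance = 1e-6)
})
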