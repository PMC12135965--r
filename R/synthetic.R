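#' Configuration for the synthetic ground-truth corpus
#'
#' Bundles every tunable of the synthetic-data generators: the planted
#' effector family (a bipartite conserved domain carrying a WHxxxH motif,
#' with optional N- and C-terminal toxin extensions), decoy proteins, genome
#' layouts with immunity-like neighbors and T6SS core-component genes, and
#' two-group LFQ tables with a planted secreted set.
#'
#' The default domain geometry mirrors the reference effector used to seed
#' the profile: a 477-residue seed region whose conserved bipartite domain
#' spans a 96-residue first region (carrying the motif), a 144-residue
#' linker, and a 206-residue second region, preceded by a 31-residue lead.
#'
#' @param rng_seed integer seed; every generator derives its stream from it.
#' @param n_family number of planted domain-bearing proteins.
#' @param n_decoy number of unrelated background proteins.
#' @param lead_len,region1_len,linker_len,region2_len consensus geometry (aa).
#' @param substitution_rate per-site substitution probability in `[0,1)`
#'   applied to each family member's copy of the consensus.
#' @param frac_subclass2 fraction of family members receiving an N-terminal
#'   extension (length >= 100), i.e. planted subclass II.
#' @param next_len_range,cext_len_range integer length ranges for N- and
#'   C-terminal extensions.
#' @param frac_c_extension fraction of family members with a C-terminal
#'   extension.
#' @param n_toxin_families number of distinct extension families.
#' @param ext_substitution_rate per-site substitution rate within an
#'   extension family (kept low so families stay recoverable by clustering).
#' @param decoy_len_range decoy protein length range.
#' @param genes_per_contig,contigs_per_genome genome layout.
#' @param n_core_components_range inclusive range (within 0..11) for the
#'   number of distinct T6SS core components planted per genome.
#' @param frac_contig_end fraction of effector genes deliberately placed at a
#'   contig end (to exercise the contig-end filter).
#' @param frac_duplicated fraction of effector genes duplicated in a second
#'   genomic accession of the same genome with the identical downstream gene
#'   at the identical distance (to exercise deduplication).
#' @param core_component_names character vector of core-component labels;
#'   the default lists the 11 conserved T6SS components used by the census.
#' @param lfq_n_proteins,lfq_n_secreted LFQ table size and planted secreted
#'   set size.
#' @param lfq_effect planted log2-intensity shift of secreted proteins.
#' @param lfq_noise_sd replicate noise standard deviation (log2 scale).
#' @param n_replicates replicates per group (>= 2).
#' @return A validated list of class `whix_config`.
#' @export
synthetic_config <- function(rng_seed = 101L,
                             n_family = 200L,
                             n_decoy = 2000L,
                             lead_len = 31L,
                             region1_len = 96L,
                             linker_len = 144L,
                             region2_len = 206L,
                             substitution_rate = 0.2,
                             frac_subclass2 = 0.16,
                             next_len_range = c(100L, 160L),
                             cext_len_range = c(100L, 200L),
                             frac_c_extension = 0.965,
                             n_toxin_families = 3L,
                             ext_substitution_rate = 0.08,
                             decoy_len_range = c(200L, 800L),
                             genes_per_contig = 12L,
                             contigs_per_genome = 2L,
                             n_core_components_range = c(8L, 11L),
                             frac_contig_end = 0.05,
                             frac_duplicated = 0.1,
                             core_component_names = t6ss_core_components(),
                             lfq_n_proteins = 400L,
                             lfq_n_secreted = 13L,
                             lfq_effect = 6,
                             lfq_noise_sd = 0.5,
                             n_replicates = 3L) {
  cfg <- list(rng_seed = as.integer(rng_seed), n_family = as.integer(n_family),
              n_decoy = as.integer(n_decoy), lead_len = as.integer(lead_len),
              region1_len = as.integer(region1_len),
              linker_len = as.integer(linker_len),
              region2_len = as.integer(region2_len),
              substitution_rate = substitution_rate,
              frac_subclass2 = frac_subclass2,
              next_len_range = as.integer(next_len_range),
              cext_len_range = as.integer(cext_len_range),
              frac_c_extension = frac_c_extension,
              n_toxin_families = as.integer(n_toxin_families),
              ext_substitution_rate = ext_substitution_rate,
              decoy_len_range = as.integer(decoy_len_range),
              genes_per_contig = as.integer(genes_per_contig),
              contigs_per_genome = as.integer(contigs_per_genome),
              n_core_components_range = as.integer(n_core_components_range),
              frac_contig_end = frac_contig_end,
              frac_duplicated = frac_duplicated,
              core_component_names = core_component_names,
              lfq_n_proteins = as.integer(lfq_n_proteins),
              lfq_n_secreted = as.integer(lfq_n_secreted),
              lfq_effect = lfq_effect, lfq_noise_sd = lfq_noise_sd,
              n_replicates = as.integer(n_replicates))
  class(cfg) <- "whix_config"
  validate_config(cfg)
  cfg
}

#' Default names of the 11 conserved T6SS core components
#'
#' The census counts distinct members of this set per genome; genomes with at
#' least 9 are called T6SS-positive. The list is configurable wherever it is
#' consumed.
#' @return Character vector of length 11.
#' @export
t6ss_core_components <- function() {
  c("Hcp", "VgrG", "TssB", "TssC", "TssE", "TssF",
    "TssG", "TssJ", "TssK", "TssL", "TssM")
}

validate_config <- function(cfg) {
  bad <- function(field, msg)
    stop("invalid configuration field `", field, "`: ", msg, call. = FALSE)
  counts <- c("n_family", "n_decoy", "lead_len", "region1_len", "linker_len",
              "region2_len", "n_toxin_families", "genes_per_contig",
              "contigs_per_genome", "lfq_n_proteins", "lfq_n_secreted")
  for (f in counts)
    if (length(cfg[[f]]) != 1L || is.na(cfg[[f]]) || cfg[[f]] < 0L)
      bad(f, "must be a single count >= 0")
  if (!is.numeric(cfg$substitution_rate) || cfg$substitution_rate < 0 ||
      cfg$substitution_rate >= 1)
    bad("substitution_rate", "must lie in [0, 1)")
  if (cfg$frac_subclass2 < 0 || cfg$frac_subclass2 > 1)
    bad("frac_subclass2", "must lie in [0, 1]")
  if (cfg$n_replicates < 2L)
    bad("n_replicates", "must be >= 2")
  for (f in c("next_len_range", "cext_len_range", "decoy_len_range",
              "n_core_components_range"))
    if (length(cfg[[f]]) != 2L || any(is.na(cfg[[f]])) ||
        cfg[[f]][1] > cfg[[f]][2])
      bad(f, "must be an ordered integer pair")
  if (cfg$next_len_range[1] < 100L)
    bad("next_len_range", "subclass II N-extensions must be >= 100 aa")
  if (cfg$n_core_components_range[1] < 0L ||
      cfg$n_core_components_range[2] > length(cfg$core_component_names))
    bad("n_core_components_range", "must lie within 0..#core components")
  if (cfg$lfq_n_secreted > cfg$lfq_n_proteins)
    bad("lfq_n_secreted", "cannot exceed lfq_n_proteins")
  invisible(cfg)
}

consensus_length <- function(cfg)
  cfg$lead_len + cfg$region1_len + cfg$linker_len + cfg$region2_len

# Per-site substitution: with probability `rate`, replace by a residue drawn
# from the background conditioned on differing from the original.
mutate_sequence <- function(seq, rate, freqs = background_frequencies()) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  hit <- runif(length(chars)) < rate
  for (i in which(hit)) {
    p <- freqs
    p[chars[i]] <- 0
    chars[i] <- sample(names(p), 1L, prob = p)
  }
  paste(chars, collapse = "")
}

#' Generate a synthetic effector protein database with ground truth
#'
#' Plants `n_family` proteins each containing a mutated copy of a shared
#' bipartite consensus whose first region embeds the literal WHxxxH motif,
#' among `n_decoy` proteins drawn iid from the background model. A fraction
#' of family members receive an N-terminal extension (>= 100 aa, subclass
#' II) and most receive a C-terminal extension; extensions are drawn from a
#' small number of distinct toxin families so that similarity clustering can
#' recover them.
#'
#' @param config a [synthetic_config()].
#' @return A list with `proteins` (named character vector, accession ->
#'   sequence), `seed_region` (the unmutated consensus used to seed profile
#'   searches), `truth` (the per-protein manifest data frame), and
#'   `extension_truth` giving the planted extension family per member.
#' @export
generate_effector_db <- function(config) {
  validate_config(config)
  set.seed(config$rng_seed)
  freqs <- background_frequencies()
  L <- consensus_length(config)

  consensus <- strsplit(sample_background(L, freqs), "")[[1]]
  motif_at <- config$lead_len + 10L  # inside region 1
  consensus[motif_at] <- "W"
  consensus[motif_at + 1L] <- "H"
  consensus[motif_at + 5L] <- "H"
  consensus <- paste(consensus, collapse = "")

  n_fam <- config$n_family
  ext_cons_n <- replicate(max(config$n_toxin_families, 1L),
                          sample_background(max(config$next_len_range), freqs))
  ext_cons_c <- replicate(max(config$n_toxin_families, 1L),
                          sample_background(max(config$cext_len_range), freqs))

  acc_fam <- sprintf("WHX_%04d.1", seq_len(n_fam))
  is2 <- if (n_fam) runif(n_fam) < config$frac_subclass2 else logical(0)
  hasc <- if (n_fam) runif(n_fam) < config$frac_c_extension else logical(0)

  seqs <- character(n_fam)
  truth <- vector("list", n_fam)
  ext_truth <- vector("list", n_fam)
  for (i in seq_len(n_fam)) {
    core <- mutate_sequence(consensus, config$substitution_rate, freqs)
    # the motif anchors define the family and stay invariant under mutation
    substr(core, motif_at, motif_at) <- "W"
    substr(core, motif_at + 1L, motif_at + 1L) <- "H"
    substr(core, motif_at + 5L, motif_at + 5L) <- "H"
    n_ext <- ""
    n_fam_lab <- NA_character_
    if (is2[i]) {
      k <- sample.int(config$n_toxin_families, 1L)
      len <- sample(seq(config$next_len_range[1], config$next_len_range[2]), 1L)
      n_ext <- substr(mutate_sequence(ext_cons_n[k],
                                      config$ext_substitution_rate, freqs),
                      1L, len)
      n_fam_lab <- paste0("ntox_", k)
    }
    c_ext <- ""
    c_fam_lab <- NA_character_
    if (hasc[i]) {
      k <- sample.int(config$n_toxin_families, 1L)
      len <- sample(seq(config$cext_len_range[1], config$cext_len_range[2]), 1L)
      c_ext <- substr(mutate_sequence(ext_cons_c[k],
                                      config$ext_substitution_rate, freqs),
                      1L, len)
      c_fam_lab <- paste0("ctox_", k)
    }
    seqs[i] <- paste0(n_ext, core, c_ext)
    truth[[i]] <- data.frame(
      acc = acc_fam[i], is_family = TRUE,
      domain_start = nchar(n_ext) + 1L,
      domain_end = nchar(n_ext) + L,
      subclass = if (is2[i]) "II" else "I",
      n_ext_len = nchar(n_ext), c_ext_len = nchar(c_ext),
      has_c_extension = hasc[i], length = nchar(n_ext) + L + nchar(c_ext),
      stringsAsFactors = FALSE)
    ext_truth[[i]] <- data.frame(acc = acc_fam[i], n_family = n_fam_lab,
                                 c_family = c_fam_lab,
                                 stringsAsFactors = FALSE)
  }

  n_dec <- config$n_decoy
  acc_dec <- sprintf("DCY_%04d.1", seq_len(n_dec))
  dec_len <- if (n_dec) sample(seq(config$decoy_len_range[1],
                                   config$decoy_len_range[2]),
                               n_dec, replace = TRUE) else integer(0)
  dec_seqs <- vapply(dec_len, sample_background, "", freqs = freqs)
  dec_truth <- if (n_dec) data.frame(
    acc = acc_dec, is_family = FALSE, domain_start = NA_integer_,
    domain_end = NA_integer_, subclass = NA_character_, n_ext_len = NA_integer_,
    c_ext_len = NA_integer_, has_c_extension = NA, length = dec_len,
    stringsAsFactors = FALSE) else NULL

  proteins <- c(setNames(seqs, acc_fam), setNames(dec_seqs, acc_dec))
  truth_df <- do.call(rbind, c(truth, list(dec_truth)))
  if (is.null(truth_df))
    truth_df <- data.frame(acc = character(0), is_family = logical(0))
  list(proteins = proteins,
       seed_region = consensus,
       motif_position = motif_at,
       truth = truth_df,
       extension_truth = do.call(rbind, ext_truth))
}

# 20-residue synthetic signal-peptide tag: M + 15 hydrophobic + polar tail.
SP_HYDROPHOBIC <- c("A", "L", "I", "V", "F")

synthetic_sp_tag <- function() {
  paste0("M", paste(sample(SP_HYDROPHOBIC, 15L, replace = TRUE),
                    collapse = ""), "SAQA")
}

#' Toy signal-peptide predictor for synthetic sequences
#'
#' Recognises the fixed-composition 20-residue N-terminal tag written by the
#' genome generator: an initial methionine followed by a strongly hydrophobic
#' stretch. It is a deliberately simple stand-in so that the immunity-gene
#' flagging logic is exercisable end to end on synthetic data; real
#' signal-peptide calls enter the pipeline as an external table.
#'
#' @param seqs character vector of protein sequences.
#' @return Logical vector.
#' @export
predict_signal_peptide <- function(seqs) {
  vapply(seqs, function(s) {
    if (is.na(s) || nchar(s) < 20L) return(FALSE)
    if (substr(s, 1L, 1L) != "M") return(FALSE)
    win <- strsplit(substr(s, 2L, 16L), "")[[1]]
    sum(win %in% c(SP_HYDROPHOBIC, "M", "W", "C")) >= 12L
  }, logical(1), USE.NAMES = FALSE)
}

#' Generate synthetic genomes around planted effector genes
#'
#' Lays each family protein from [generate_effector_db()] into its own
#' genome: contigs of `genes_per_contig` genes with realistic intergenic
#' gaps, an immunity-like signal-peptide-positive gene immediately downstream
#' of the effector, a configurable number of distinct T6SS core-component
#' genes scattered over the genome, a configurable fraction of effectors at
#' contig ends, and a configurable fraction duplicated in a second genomic
#' accession with the identical downstream gene at the identical distance.
#'
#' @param truth manifest from [generate_effector_db()].
#' @param config a [synthetic_config()].
#' @return A list with `features` (flat feature table; one row per gene),
#'   `neighbor_proteins` (sequences of generated non-effector proteins),
#'   `sp_calls` (toy signal-peptide calls for all proteins in the features),
#'   `genome_truth` (per-genome core-component count and T6SS status),
#'   `immunity_truth` (planted immunity gene per effector locus) and
#'   `locus_truth` (per effector occurrence: contig-end and duplicate flags).
#' @export
generate_genomes <- function(truth, config) {
  validate_config(config)
  if (config$genes_per_contig < 3L)
    stop("layout error: genes_per_contig must be >= 3 to place an effector ",
         "with a downstream neighbor", call. = FALSE)
  set.seed(config$rng_seed + 1L)
  freqs <- background_frequencies()
  fam <- truth[truth$is_family, , drop = FALSE]
  g <- config$genes_per_contig

  features <- list()
  neighbor_proteins <- character(0)
  genome_truth <- list()
  immunity_truth <- list()
  locus_truth <- list()
  fil_counter <- 0L

  for (i in seq_len(nrow(fam))) {
    genome_acc <- sprintf("GNM_%04d", i)
    at_end <- runif(1) < config$frac_contig_end
    dup <- !at_end && config$contigs_per_genome >= 2L &&
      runif(1) < config$frac_duplicated

    imm_acc <- sprintf("IMM_%04d.1", i)
    imm_seq <- paste0(synthetic_sp_tag(), sample_background(110L, freqs))
    neighbor_proteins[imm_acc] <- imm_seq

    n_core <- sample(seq(config$n_core_components_range[1],
                         config$n_core_components_range[2]), 1L)
    comps <- sample(config$core_component_names, n_core)
    # occasionally plant an extra copy of one component: the census must
    # count distinct components, not genes
    extra_copy <- n_core > 0L && runif(1) < 0.3
    comp_genes <- c(comps, if (extra_copy) comps[1])
    n_filler <- config$contigs_per_genome * g - 2L * (1L + dup)
    if (length(comps) > n_filler)
      stop("layout error: genome ", genome_acc, " cannot host ",
           length(comps), " core-component genes in ", n_filler,
           " filler slots", call. = FALSE)
    comp_genes <- comp_genes[seq_len(min(length(comp_genes), n_filler))]
    # scatter component genes over the genome's filler slots
    ann_pool <- sample(c(comp_genes,
                         rep("hypothetical", n_filler - length(comp_genes))))
    pool_i <- 0L

    # gene-by-gene layout per contig
    eff_gap <- sample(20:200, 1L)
    for (ct in seq_len(config$contigs_per_genome)) {
      contig_acc <- sprintf("CTG_%04d.%d", i, ct)
      place_eff <- (ct == 1L) || (ct == 2L && dup)
      eff_ord <- if (!place_eff) NA_integer_
        else if (at_end) 1L else sample(2:(g - 1L), 1L)
      pos <- 0L
      for (j in seq_len(g)) {
        gap <- sample(20:200, 1L)
        if (place_eff && j == eff_ord + 1L) gap <- eff_gap
        strand <- sample(c("+", "-"), 1L)
        if (place_eff && j == eff_ord) {
          acc <- fam$acc[i]
          plen <- fam$length[i]
          ann <- "whix_candidate"
          strand <- "+"   # immunity gene sits at the next ordinal
        } else if (place_eff && j == eff_ord + 1L) {
          acc <- imm_acc
          plen <- nchar(imm_seq)
          ann <- "hypothetical"
          strand <- "+"
        } else {
          fil_counter <- fil_counter + 1L
          acc <- sprintf("FIL_%05d.1", fil_counter)
          plen <- sample(150:400, 1L)
          neighbor_proteins[acc] <- sample_background(plen, freqs)
          pool_i <- pool_i + 1L
          ann <- ann_pool[pool_i]
        }
        start <- pos + gap
        end <- start + 3L * plen + 2L
        pos <- end
        features[[length(features) + 1L]] <- data.frame(
          genome_acc = genome_acc, genomic_acc = contig_acc, ordinal = j,
          start = start, end = end, strand = strand, protein_acc = acc,
          annotation = ann, stringsAsFactors = FALSE)
      }
      if (place_eff)
        locus_truth[[length(locus_truth) + 1L]] <- data.frame(
          genome_acc = genome_acc, genomic_acc = contig_acc,
          effector_acc = fam$acc[i], ordinal = eff_ord,
          at_contig_end = at_end || eff_ord == g,
          duplicated = dup, stringsAsFactors = FALSE)
    }
    genome_truth[[i]] <- data.frame(
      genome_acc = genome_acc, n_core = n_core,
      components = paste(sort(comps), collapse = ","),
      t6ss_positive = n_core >= 9L, stringsAsFactors = FALSE)
    immunity_truth[[i]] <- data.frame(
      genome_acc = genome_acc, effector_acc = fam$acc[i],
      immunity_acc = imm_acc, side = "downstream", stringsAsFactors = FALSE)
  }

  features <- if (length(features)) do.call(rbind, features) else
    data.frame(genome_acc = character(0), genomic_acc = character(0),
               ordinal = integer(0), start = integer(0), end = integer(0),
               strand = character(0), protein_acc = character(0),
               annotation = character(0), stringsAsFactors = FALSE)
  sp_calls <- data.frame(
    protein_acc = names(neighbor_proteins),
    signal_peptide = predict_signal_peptide(unname(neighbor_proteins)),
    stringsAsFactors = FALSE)
  list(features = features,
       neighbor_proteins = neighbor_proteins,
       sp_calls = sp_calls,
       genome_truth = do.call(rbind, genome_truth),
       immunity_truth = do.call(rbind, immunity_truth),
       locus_truth = do.call(rbind, locus_truth))
}

#' Generate a synthetic two-group LFQ table with a planted secreted set
#'
#' Emulates a MaxQuant-style protein-group table comparing the secretome of
#' a wild-type (T6SS-positive) strain against a secretion-deficient mutant,
#' with `n_replicates` replicates per group on a log2 intensity scale.
#' Planted secreted proteins receive a `lfq_effect` group-mean shift and
#' identification scores above the score gate. When `lfq_n_secreted` is 13,
#' the planted set is named after the canonical synthetic secretome (VgrG
#' and Hcp protein groups, the effectors TseI/Tle1/Awe1/DUF3289, and the
#' three flagellar proteins FlaB, FlgM, FliD); this table is a synthetic
#' stand-in for a real comparative-secretome export.
#'
#' @param config a [synthetic_config()].
#' @return List with `table` (an [lfq_table()]) and `truth` (per-protein
#'   planted-secreted and flagellar flags).
#' @export
generate_lfq <- function(config) {
  validate_config(config)
  set.seed(config$rng_seed + 2L)
  n <- config$lfq_n_proteins
  ns <- config$lfq_n_secreted
  nr <- config$n_replicates

  canonical <- c("VgrG1", "VgrG2a", "VgrG2b", "VgrG3", "Hcp1/Hcp3", "Hcp2",
                 "TseI", "Tle1", "Awe1", "DUF3289", "FlaB", "FlgM", "FliD")
  sec_ids <- if (ns == 13L) canonical else sprintf("SEC_%03d", seq_len(ns))
  bkg_ids <- sprintf("BKG_%04d", seq_len(n - ns))
  ids <- c(sec_ids, bkg_ids)
  secreted <- c(rep(TRUE, ns), rep(FALSE, n - ns))
  flagellar <- ids %in% c("FlaB", "FlgM", "FliD") & secreted

  base <- runif(n, 24, 34)
  a <- matrix(base, n, nr) + matrix(rnorm(n * nr, 0, config$lfq_noise_sd), n, nr)
  b <- matrix(base, n, nr) + matrix(rnorm(n * nr, 0, config$lfq_noise_sd), n, nr)
  a[secreted, ] <- a[secreted, ] + config$lfq_effect

  score <- numeric(n)
  score[secreted] <- runif(ns, 60, 320)
  score[!secreted] <- runif(n - ns, 2, 200)

  df <- data.frame(protein_id = ids, score = score, stringsAsFactors = FALSE)
  a_cols <- sprintf("wt_%d", seq_len(nr))
  b_cols <- sprintf("mut_%d", seq_len(nr))
  df[a_cols] <- as.data.frame(a)
  df[b_cols] <- as.data.frame(b)

  list(table = lfq_table(df, group_a = a_cols, group_b = b_cols),
       truth = data.frame(protein_id = ids, planted_secreted = secreted,
                          flagellar = flagellar, stringsAsFactors = FALSE))
}
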