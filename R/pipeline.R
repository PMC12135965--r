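#' Run the discovery pipeline end to end on a synthetic corpus
#'
#' Executes the stages in dependency order: simulate (protein database,
#' genomes, LFQ table, all with ground truth), iterative profile search,
#' database scan with E-value/coverage filters, domain-call merging and
#' effector annotation, genomic-neighborhood extraction with contig-end and
#' duplicate-locus filtering plus immunity-candidate flagging, T6SS census,
#' extension clustering, and secretome enrichment. Stage outputs are written
#' as TSVs under `out_dir` (when given) together with a JSON run report
#' echoing every parameter and the seed; identical config and seed produce
#' byte-identical bundles.
#'
#' @param config a [synthetic_config()]; its `rng_seed` drives every
#'   stochastic step.
#' @param params a [search_params()].
#' @param out_dir output directory (created if needed); `NULL` skips
#'   writing.
#' @param stages character subset of
#'   `c("profile", "neighborhood", "cluster", "enrich")`; the simulation
#'   always runs (it defines the inputs), and stages depending on a
#'   disabled stage are skipped.
#' @param k neighbors per side for neighborhood extraction.
#' @param min_cluster_size minimum members for a named extension family.
#' @param diff_min,p_max,score_min enrichment gates.
#' @return List with the stage outputs and a `summary` of headline counts.
#' @export
run_whix_pipeline <- function(config = synthetic_config(),
                              params = search_params(),
                              out_dir = NULL,
                              stages = c("profile", "neighborhood",
                                         "cluster", "enrich"),
                              k = 3L, min_cluster_size = 4L,
                              diff_min = 3, p_max = 0.02, score_min = 40) {
  res <- list(config = config, params = params)
  db <- generate_effector_db(config)
  genomes <- generate_genomes(db$truth, config)
  lfq <- generate_lfq(config)
  res$db <- db
  res$genomes <- genomes
  res$lfq <- lfq
  fam_accs <- db$truth$acc[db$truth$is_family]
  summary <- list(
    rng_seed = config$rng_seed,
    n_family = length(fam_accs),
    n_decoy = sum(!db$truth$is_family))

  if ("profile" %in% stages) {
    profile <- iterate_profile(db$seed_region, db$proteins, params,
                               rng_seed = config$rng_seed)
    hits <- scan_database(profile, db$proteins, params)
    calls <- merge_all_hits(hits)
    ann <- annotate_all(calls, db$proteins)
    res$profile <- profile
    res$hits <- hits
    res$calls <- calls
    res$annotations <- ann
    hit_accs <- unique(calls$subject_acc)
    summary$n_hit_subjects <- length(hit_accs)
    summary$sensitivity <- if (length(fam_accs))
      mean(fam_accs %in% hit_accs) else NA_real_
    summary$decoy_hits <- sum(!hit_accs %in% fam_accs)
    summary$subclass2_fraction <- if (nrow(ann))
      mean(ann$subclass == "II") else NA_real_
    summary$c_extension_fraction <- if (nrow(ann))
      mean(ann$has_c_extension) else NA_real_
    summary$motif_detected_fraction <- if (nrow(ann))
      mean(!is.na(ann$motif_position)) else NA_real_
  }

  if ("neighborhood" %in% stages) {
    records <- extract_neighborhoods(genomes$features, fam_accs, k = k)
    filtered <- deduplicate(filter_contig_ends(records))
    flagged <- lapply(filtered, flag_immunity_candidates,
                      sp_calls = genomes$sp_calls)
    attributes(flagged) <- attributes(filtered)
    census <- census_t6ss(genomes$features, config$core_component_names)
    res$neighborhoods <- flagged
    res$census <- census
    summary$n_loci_raw <- length(records)
    summary$n_loci_filtered <- length(filtered)
    summary$t6ss_positive_fraction <- mean(census$t6ss_positive)
    summary$immunity_candidate_fraction <- if (length(flagged))
      mean(vapply(flagged, function(r)
        isTRUE(r$upstream_candidate) || isTRUE(r$downstream_candidate),
        logical(1))) else NA_real_
  }

  if ("cluster" %in% stages && "profile" %in% stages) {
    termini <- extract_termini(res$annotations, db$proteins)
    cluster_one <- function(seqs) {
      if (length(seqs) < 2L) return(NULL)
      edges <- pairwise_similarity(seqs, rng_seed = config$rng_seed)
      cluster_extensions(edges, names(seqs), min_size = min_cluster_size)
    }
    res$termini <- termini
    res$n_term_clusters <- cluster_one(termini$n_term)
    res$c_term_clusters <- cluster_one(termini$c_term)
    named_families <- function(cl)
      if (is.null(cl)) 0L else length(setdiff(unique(cl$label), "others"))
    summary$n_term_families <- named_families(res$n_term_clusters)
    summary$c_term_families <- named_families(res$c_term_clusters)
  }

  if ("enrich" %in% stages) {
    enr <- enrich(lfq$table, diff_min = diff_min, p_max = p_max,
                  score_min = score_min)
    res$enrichment <- enr
    summary$n_enriched <- sum(enr$passes)
    summary$n_enriched_flagellar <- sum(
      enr$passes & enr$protein_id %in% c("FlaB", "FlgM", "FliD"))
  }

  res$summary <- summary

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_protein_fasta(db$proteins, file.path(out_dir, "proteins.fasta"))
    write_tsv(db$truth, file.path(out_dir, "truth_manifest.tsv"))
    write_features_tsv(genomes$features, file.path(out_dir, "features.tsv"))
    write_tsv(genomes$sp_calls, file.path(out_dir, "sp_calls.tsv"))
    write_lfq_tsv(lfq$table, file.path(out_dir, "lfq_table.tsv"))
    if (!is.null(res$profile))
      write_profile(res$profile, file.path(out_dir, "profile.txt"))
    if (!is.null(res$hits))
      write_hits_tsv(res$hits, file.path(out_dir, "hits.tsv"))
    if (!is.null(res$calls))
      write_tsv(res$calls, file.path(out_dir, "domain_calls.tsv"))
    if (!is.null(res$annotations))
      write_tsv(res$annotations, file.path(out_dir, "annotations.tsv"))
    if (!is.null(res$neighborhoods))
      write_tsv(neighborhoods_to_df(res$neighborhoods),
                file.path(out_dir, "neighborhoods.tsv"))
    if (!is.null(res$census))
      write_tsv(res$census, file.path(out_dir, "census.tsv"))
    if (!is.null(res$n_term_clusters))
      write_tsv(res$n_term_clusters,
                file.path(out_dir, "n_term_clusters.tsv"))
    if (!is.null(res$c_term_clusters))
      write_tsv(res$c_term_clusters,
                file.path(out_dir, "c_term_clusters.tsv"))
    if (!is.null(res$enrichment))
      write_tsv(res$enrichment, file.path(out_dir, "enrichment.tsv"))
    report <- list(
      package_version = as.character(utils::packageVersion("whixscan")),
      rng_seed = config$rng_seed,
      config = config[setdiff(names(config), "core_component_names")],
      core_component_names = config$core_component_names,
      search_params = unclass(params),
      stages = stages,
      summary = summary)
    jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(res)
}
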