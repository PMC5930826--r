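#' Core / pan / strain-specific analysis of a proteome set
#'
#' Runs the all-vs-all search once, then clusters the similarity graph twice:
#' under the strict core thresholds (PI >= 90, PC >= 90, E <= 1e-4) and under
#' the permissive pan thresholds (PI >= 30, PC >= 70). The core-gene
#' concatenates (one representative per universal cluster, identical order in
#' every genome) are built from whichever run has universal clusters — the
#' strict run when possible, otherwise the permissive one.
#'
#' @param proteomes List of [genome_proteome()] (>= 2).
#' @param scheme A [scoring_scheme()].
#' @param core,pan [threshold_set()]s for the two runs.
#' @param out_dir Optional directory; when given, cluster tables, summaries,
#'   the presence/absence matrix, concatenates and a JSON run report are
#'   written there.
#' @param prefilter,word_size All-vs-all prefilter controls; the family-scale
#'   default word size is 5 (methods vignette).
#' @param both_directions Require both directions of a hit to pass (default
#'   FALSE: either direction qualifies an edge).
#' @return List with `hits`, `core`, `pan` (cluster sets), `summary_core`,
#'   `summary_pan`, `concatenates`, `presence_absence` (from the pan run) and
#'   `params`.
#' @export
run_pancore <- function(proteomes, scheme = scoring_scheme(),
                        core = core_thresholds(), pan = pan_thresholds(),
                        out_dir = NULL, prefilter = TRUE, word_size = 5,
                        both_directions = FALSE) {
  if (length(proteomes) < 2) stopf("need >= 2 genomes")
  hits <- search_all_vs_all(proteomes, scheme, prefilter = prefilter,
                            k = word_size)
  universe <- flatten_proteomes(proteomes)[, c("genome_id", "gene_id")]
  cs_core <- cluster_orthologs(
    build_similarity_graph(hits, core, both_directions), universe, core)
  cs_pan <- cluster_orthologs(
    build_similarity_graph(hits, pan, both_directions), universe, pan)
  sum_core <- summarize_pancore(cs_core)
  sum_pan <- summarize_pancore(cs_pan)
  concat_from <- if (sum_core$core_count > 0) cs_core else cs_pan
  concatenates <- if (summarize_pancore(concat_from)$core_count > 0)
    concatenate_core(concat_from, proteomes) else NULL
  res <- list(hits = hits, core = cs_core, pan = cs_pan,
              summary_core = sum_core, summary_pan = sum_pan,
              concatenates = concatenates,
              presence_absence = presence_absence_matrix(cs_pan),
              params = list(core = unclass(core), pan = unclass(pan),
                            prefilter = prefilter, word_size = word_size,
                            both_directions = both_directions))
  if (!is.null(out_dir)) write_pancore_artifacts(res, out_dir)
  res
}

write_pancore_artifacts <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_cluster_table(res$core, file.path(out_dir, "clusters_core.tsv"))
  write_cluster_table(res$pan, file.path(out_dir, "clusters_pan.tsv"))
  utils::write.table(res$presence_absence,
                     file.path(out_dir, "presence_absence.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  if (!is.null(res$concatenates))
    write_fasta(res$concatenates, file.path(out_dir, "core_concatenates.faa"))
  jsonlite::write_json(
    list(params = res$params,
         core_count = res$summary_core$core_count,
         pan_count = res$summary_pan$pan_count,
         strain_specific = as.list(res$summary_pan$strain_specific)),
    file.path(out_dir, "pancore_report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Species delimitation and tree concordance analysis
#'
#' Computes the AAI matrix, delimits clades at the AAI cutoff, and builds
#' three neighbor-joining trees: from core-gene distances (shared gene
#' families of the permissive run), from Jaccard distances over the strict
#' run's presence/absence profiles (gene-content/accessory signal at variant
#' resolution), and from `100 - AAI`. Each tree is then cut into as many
#' groups as the AAI partition has clades, and the report states whether all
#' three tree partitions and the AAI partition agree — the concordance claim
#' that core-gene, gene-content and identity analyses delimit the same
#' candidate species.
#'
#' @param proteomes List of [genome_proteome()] (>= 3).
#' @param scheme A [scoring_scheme()].
#' @param cutoff AAI species cutoff in percent (default 95).
#' @param out_dir Optional output directory (matrices, Newick trees,
#'   partition files, JSON report).
#' @param rbh_pi_min,rbh_pc_min AAI reciprocal-best-hit filters.
#' @param prefilter,word_size All-vs-all prefilter controls.
#' @return List with `aai` ([identity_matrix()]), `partition`
#'   (`clade_partition`), `trees` (named list of `phylo`: `core`, `accessory`,
#'   `aai`), `tree_partitions` (named memberships), `concordant` (logical),
#'   `pancore` (the underlying [run_pancore()] result) and `params`.
#' @export
run_species <- function(proteomes, scheme = scoring_scheme(), cutoff = 95,
                        out_dir = NULL, rbh_pi_min = 30, rbh_pc_min = 70,
                        prefilter = TRUE, word_size = 5) {
  if (length(proteomes) < 3) stopf("need >= 3 genomes")
  pc <- run_pancore(proteomes, scheme, prefilter = prefilter,
                    word_size = word_size)
  aai <- aai_matrix(proteomes, scheme, hits = pc$hits,
                    rbh_pi_min = rbh_pi_min, rbh_pc_min = rbh_pc_min)
  partition <- delimit_clades(aai, cutoff)
  k <- length(partition$clades)

  shared_cs <- if (pc$summary_core$core_count > 0) pc$core else pc$pan
  d_core <- core_distance_matrix(shared_cs, proteomes, scheme)
  pa_strict <- presence_absence_matrix(pc$core)
  d_acc <- jaccard_distance_matrix(pa_strict)
  d_aai <- 100 - aai$values
  if (anyNA(d_aai)) {
    warning("missing AAI for some pairs; treated as maximal distance",
            call. = FALSE)
    d_aai[is.na(d_aai)] <- max(d_aai, 100, na.rm = TRUE)
  }
  diag(d_aai) <- 0
  trees <- list(core = nj_tree(d_core), accessory = nj_tree(d_acc),
                aai = nj_tree(d_aai))
  tree_partitions <- lapply(trees, tree_clades, k = k)
  concordant <- all(vapply(tree_partitions, function(tp)
    compare_partitions(tp, partition) == 1, logical(1)))
  res <- list(aai = aai, partition = partition, trees = trees,
              tree_partitions = tree_partitions, concordant = concordant,
              pancore = pc,
              params = list(cutoff = cutoff, rbh_pi_min = rbh_pi_min,
                            rbh_pc_min = rbh_pc_min, prefilter = prefilter,
                            word_size = word_size))
  if (!is.null(out_dir)) write_species_artifacts(res, out_dir)
  res
}

write_species_artifacts <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix(res$aai$values, file.path(out_dir, "aai_matrix.tsv"))
  write_clade_partition(res$partition, file.path(out_dir, "clades.tsv"))
  for (nm in names(res$trees))
    write_newick(res$trees[[nm]], file.path(out_dir,
                                            paste0("tree_", nm, ".nwk")))
  jsonlite::write_json(
    list(params = res$params, n_clades = length(res$partition$clades),
         is_clean = res$partition$is_clean, concordant = res$concordant),
    file.path(out_dir, "species_report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
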