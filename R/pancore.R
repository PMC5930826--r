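#' Similarity thresholds for ortholog-graph edges
#'
#' @param pi_min Minimum percent identity (0-100).
#' @param pc_min Minimum percent query coverage (0-100).
#' @param evalue_max Maximum E-value, or `NULL` for no E-value filter.
#' @return A `threshold_set`.
#' @export
threshold_set <- function(pi_min, pc_min, evalue_max = NULL) {
  stopifnot(pi_min >= 0, pi_min <= 100, pc_min >= 0, pc_min <= 100,
            is.null(evalue_max) || evalue_max >= 0)
  structure(list(pi_min = pi_min, pc_min = pc_min, evalue_max = evalue_max),
            class = "threshold_set")
}

#' Published core-genome thresholds: PI >= 90, PC >= 90, E <= 1e-4
#' @export
core_thresholds <- function() threshold_set(90, 90, 1e-4)

#' Published pan-genome thresholds: PI >= 30 across >= 70 percent of the gene
#' @export
pan_thresholds <- function() threshold_set(30, 70, NULL)

#' Build the ortholog similarity graph
#'
#' An undirected edge joins two genes when at least one direction's hit passes
#' all thresholds (boundaries inclusive); with `both_directions = TRUE`, both
#' directional hits must pass. Self-genome pairs never appear because the hit
#' table is cross-genome only.
#'
#' @param hits Hit table from [search_all_vs_all()].
#' @param thresholds A [threshold_set()].
#' @param both_directions Require both directions to qualify (default FALSE).
#' @return A `data.table` of edges with columns `genome1`, `gene1`, `genome2`,
#'   `gene2` (unordered pairs, deduplicated).
#' @export
build_similarity_graph <- function(hits, thresholds,
                                   both_directions = FALSE) {
  h <- data.table::as.data.table(hits)
  pass <- h$percent_identity >= thresholds$pi_min &
    h$percent_query_coverage >= thresholds$pc_min
  if (!is.null(thresholds$evalue_max))
    pass <- pass & h$evalue <= thresholds$evalue_max
  h <- h[pass]
  if (nrow(h) == 0)
    return(data.table::data.table(genome1 = character(), gene1 = character(),
                                  genome2 = character(), gene2 = character()))
  a <- paste(h$query_genome, h$query_id, sep = "\r")
  b <- paste(h$subject_genome, h$subject_id, sep = "\r")
  lo <- pmin(a, b); hi <- pmax(a, b)
  keykeep <- if (both_directions) {
    key <- paste(lo, hi, sep = "\n")
    names(which(table(key) >= 2))
  } else unique(paste(lo, hi, sep = "\n"))
  if (length(keykeep) == 0)
    return(data.table::data.table(genome1 = character(), gene1 = character(),
                                  genome2 = character(), gene2 = character()))
  parts <- data.table::tstrsplit(keykeep, "\n", fixed = TRUE)
  p1 <- data.table::tstrsplit(parts[[1]], "\r", fixed = TRUE)
  p2 <- data.table::tstrsplit(parts[[2]], "\r", fixed = TRUE)
  out <- data.table::data.table(genome1 = p1[[1]], gene1 = p1[[2]],
                                genome2 = p2[[1]], gene2 = p2[[2]])
  data.table::setorder(out, genome1, gene1, genome2, gene2)
  out[]
}

#' Cluster genes into ortholog groups by single linkage
#'
#' Clusters are the connected components of the similarity graph; genes with
#' no qualifying edge become singleton clusters, so the clusters always
#' partition the full gene universe. Cluster ids are assigned in order of each
#' component's smallest global gene id.
#'
#' @param edges Edge table from [build_similarity_graph()].
#' @param all_genes Gene universe: a `data.frame` with columns `genome_id` and
#'   `gene_id`, or a list of [genome_proteome()] to enumerate it from.
#' @param thresholds Optional [threshold_set()] recorded on the result.
#' @return A `cluster_set`: list with `clusters` (data.table `cluster_id`,
#'   `genome_id`, `gene_id`), `n_genomes_total`, `thresholds`.
#' @export
cluster_orthologs <- function(edges, all_genes, thresholds = NULL) {
  if (is.list(all_genes) && !is.data.frame(all_genes))
    all_genes <- flatten_proteomes(all_genes)[, c("genome_id", "gene_id")]
  stopifnot(all(c("genome_id", "gene_id") %in% names(all_genes)))
  universe <- paste(all_genes$genome_id, all_genes$gene_id, sep = "\r")
  if (anyDuplicated(universe)) stopf("duplicate gene in universe")

  if (nrow(edges) > 0) {
    ek1 <- paste(edges$genome1, edges$gene1, sep = "\r")
    ek2 <- paste(edges$genome2, edges$gene2, sep = "\r")
    unknown <- setdiff(c(ek1, ek2), universe)
    if (length(unknown))
      stopf("edge references unknown gene '%s'",
            gsub("\r", ":", unknown[1]))
    g <- igraph::graph_from_data_frame(
      data.frame(from = ek1, to = ek2), directed = FALSE,
      vertices = data.frame(name = universe))
    comp <- igraph::components(g)$membership[universe]
  } else {
    comp <- seq_along(universe)
  }
  # deterministic ids: order components by their smallest member gene key
  smallest <- tapply(universe, comp, min)
  newid <- setNames(rank(smallest, ties.method = "first"), names(smallest))
  clusters <- data.table::data.table(
    cluster_id = as.integer(newid[as.character(comp)]),
    genome_id = all_genes$genome_id,
    gene_id = all_genes$gene_id)
  data.table::setorder(clusters, cluster_id, genome_id, gene_id)
  structure(list(clusters = clusters,
                 n_genomes_total = length(unique(all_genes$genome_id)),
                 thresholds = thresholds),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  s <- summarize_pancore(x)
  cat(sprintf("<cluster_set> %d clusters over %d genomes (%d core)\n",
              s$pan_count, x$n_genomes_total, s$core_count))
  invisible(x)
}

cluster_genome_counts <- function(cs) {
  cs$clusters[, list(n_genomes = data.table::uniqueN(genome_id)),
              by = cluster_id]
}

#' Core / pan / strain-specific summary of a cluster set
#'
#' Core clusters have at least one member in every genome; the pan-genome
#' count is the total number of clusters including singletons; a
#' strain-specific cluster draws all its members from a single genome.
#'
#' @param cs A [cluster_orthologs()] result.
#' @return A `pancore_summary`: list with `core_count`, `pan_count`,
#'   `strain_specific` (named integer vector over all genomes, zeros kept),
#'   `n_genomes_total`.
#' @export
summarize_pancore <- function(cs) {
  stopifnot(inherits(cs, "cluster_set"))
  cnt <- cluster_genome_counts(cs)
  core <- sum(cnt$n_genomes == cs$n_genomes_total)
  specific_tab <- cs$clusters[
    cluster_id %in% cnt[n_genomes == 1L, cluster_id],
    list(n = data.table::uniqueN(cluster_id)), by = genome_id]
  genomes <- sort(unique(cs$clusters$genome_id))
  specific <- setNames(integer(length(genomes)), genomes)
  specific[specific_tab$genome_id] <- specific_tab$n
  structure(list(core_count = core, pan_count = nrow(cnt),
                 strain_specific = specific,
                 n_genomes_total = cs$n_genomes_total),
            class = "pancore_summary")
}

#' @export
print.pancore_summary <- function(x, ...) {
  cat(sprintf(paste0("<pancore_summary> core %d / pan %d clusters; ",
                     "strain-specific mean %.1f (max %d)\n"),
              x$core_count, x$pan_count, mean(x$strain_specific),
              max(x$strain_specific)))
  invisible(x)
}

# Representative of a cluster within one genome: longest member, ties broken
# by lexicographically smallest gene id.
cluster_representatives <- function(cs, proteomes, cluster_ids = NULL) {
  idx <- flatten_proteomes(proteomes)
  cl <- cs$clusters
  if (!is.null(cluster_ids)) cl <- cl[cluster_id %in% cluster_ids]
  m <- merge(cl, idx, by = c("genome_id", "gene_id"), sort = FALSE)
  if (nrow(m) < nrow(cl)) stopf("proteomes are missing clustered genes")
  data.table::setorder(m, cluster_id, genome_id, -len, gene_id)
  m[, .SD[1], by = list(cluster_id, genome_id)]
}

#' Ordered concatenation of core genes per genome
#'
#' For every genome, the representative of each core cluster (longest member;
#' ties by gene id) is concatenated in ascending cluster-id order — the same
#' order for every genome — yielding alignable per-strain supermatrix
#' sequences.
#'
#' @param cs A `cluster_set` with at least one core cluster.
#' @param proteomes The proteome list the clusters were built from.
#' @return Named character vector: genome id -> concatenated sequence.
#' @export
concatenate_core <- function(cs, proteomes) {
  cnt <- cluster_genome_counts(cs)
  core_ids <- cnt[n_genomes == cs$n_genomes_total, cluster_id]
  if (length(core_ids) == 0) stopf("no core genome: no cluster spans all genomes")
  reps <- cluster_representatives(cs, proteomes, core_ids)
  data.table::setorder(reps, genome_id, cluster_id)
  out <- reps[, list(seq = paste(sequence, collapse = "")), by = genome_id]
  setNames(out$seq, out$genome_id)
}

#' Gene presence/absence matrix
#'
#' @param cs A `cluster_set`.
#' @return Binary integer matrix, genomes x clusters (columns in cluster-id
#'   order); entry 1 iff the genome has at least one member in the cluster.
#' @export
presence_absence_matrix <- function(cs) {
  genomes <- sort(unique(cs$clusters$genome_id))
  ids <- sort(unique(cs$clusters$cluster_id))
  m <- matrix(0L, length(genomes), length(ids),
              dimnames = list(genomes, as.character(ids)))
  m[cbind(match(cs$clusters$genome_id, genomes),
          match(cs$clusters$cluster_id, ids))] <- 1L
  m
}

#' Screen a proteome for a set of reference genes
#'
#' Aligns every reference protein against a proteome and reports whether a
#' similar sequence exists, in the spirit of screening genomes for the
#' *B. subtilis* sporulation gene set: a reference gene is "present" when its
#' best hit reaches at least `identity_min` percent identity.
#'
#' @param reference Reference proteins: record `data.frame` or named character
#'   vector.
#' @param proteome A [genome_proteome()].
#' @param scheme A [scoring_scheme()].
#' @param identity_min Presence cutoff on best-hit percent identity
#'   (default 20).
#' @param prefilter,k Optionally skip alignment of pairs sharing no k-mer.
#'   Off by default: at a 20 percent identity cutoff even short chance
#'   alignments can establish presence, and such pairs need not share a
#'   word — the screen is exhaustive unless asked otherwise.
#' @return `data.frame` sorted by reference gene id: `ref_id`, `best_pi`,
#'   `best_pc`, `best_subject`, `present`.
#' @export
gene_presence_screen <- function(reference, proteome,
                                 scheme = scoring_scheme(),
                                 identity_min = 20, prefilter = FALSE,
                                 k = 4) {
  if (is.character(reference))
    reference <- data.frame(id = names(reference), sequence = unname(reference),
                            stringsAsFactors = FALSE)
  stopifnot(nrow(reference) >= 1)
  empty_report <- data.frame(ref_id = sort(reference$id),
                             best_pi = NA_real_, best_pc = NA_real_,
                             best_subject = NA_character_, present = FALSE,
                             stringsAsFactors = FALSE)
  if (length(proteome$sequences) == 0) {
    warning("empty proteome: all reference genes reported absent",
            call. = FALSE)
    return(empty_report)
  }
  ref_p <- genome_proteome(".ref", setNames(reference$sequence, reference$id))
  hits <- search_all_vs_all(list(ref_p, proteome), scheme,
                            prefilter = prefilter, k = k)
  hits <- hits[query_genome == ".ref"]
  best <- hits[order(-score, subject_id), .SD[1], by = query_id]
  out <- empty_report
  i <- match(best$query_id, out$ref_id)
  out$best_pi[i] <- best$percent_identity
  out$best_pc[i] <- best$percent_query_coverage
  out$best_subject[i] <- best$subject_id
  out$present <- !is.na(out$best_pi) & out$best_pi >= identity_min
  out
}

#' Write a cluster table as tab-separated text
#' @param cs A `cluster_set`.
#' @param path Output path; columns `cluster_id`, `genome_id`, `gene_id`.
#' @export
write_cluster_table <- function(cs, path) {
  data.table::fwrite(cs$clusters, path, sep = "\t")
  invisible(path)
}
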