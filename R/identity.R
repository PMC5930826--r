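#' Strain-by-strain identity matrix
#'
#' Container for AAI or ANI values: symmetric, diagonal fixed at 100, entries
#' in \[0, 100\] or `NA` where a pair produced no usable signal (no reciprocal
#' best hits / no retained fragments).
#'
#' @param values Square numeric matrix with strain dimnames.
#' @param kind `"AAI"` or `"ANI"`.
#' @param n_pairs Matrix of supporting pair counts (RBH pairs or fragments).
#' @return An `identity_matrix`.
#' @export
identity_matrix <- function(values, kind = c("AAI", "ANI"), n_pairs = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(values), nrow(values) == ncol(values),
            identical(rownames(values), colnames(values)))
  diag(values) <- 100
  offd <- values[row(values) != col(values)]
  if (any(!is.na(offd) & (offd < 0 | offd > 100)))
    stopf("identity values must lie in [0, 100]")
  if (max(abs(values - t(values)), na.rm = TRUE) > 1e-9)
    stopf("identity matrix must be symmetric")
  structure(list(labels = rownames(values), values = values, kind = kind,
                 n_pairs = n_pairs), class = "identity_matrix")
}

#' @export
print.identity_matrix <- function(x, ...) {
  offd <- x$values[row(x$values) != col(x$values)]
  cat(sprintf("<identity_matrix> %s over %d strains; off-diagonal %s\n",
              x$kind, length(x$labels),
              if (all(is.na(offd))) "all missing" else
                sprintf("range %.1f-%.1f", min(offd, na.rm = TRUE),
                        max(offd, na.rm = TRUE))))
  invisible(x)
}

#' @export
as.matrix.identity_matrix <- function(x, ...) x$values

# Best directed hits per query gene for one ordered genome pair.
best_directed <- function(hits, qg, sg) {
  h <- hits[query_genome == qg & subject_genome == sg]
  if (nrow(h) == 0) return(h)
  h[order(-score, subject_id), .SD[1], by = query_id]
}

aai_from_hits <- function(hits, ga, gb, rbh_pi_min, rbh_pc_min) {
  ab <- best_directed(hits, ga, gb)
  ba <- best_directed(hits, gb, ga)
  if (nrow(ab) == 0 || nrow(ba) == 0)
    return(list(aai = NA_real_, n_rbh = 0L))
  ab <- ab[percent_identity >= rbh_pi_min &
             percent_query_coverage >= rbh_pc_min]
  ba <- ba[percent_identity >= rbh_pi_min &
             percent_query_coverage >= rbh_pc_min]
  rec <- merge(ab[, list(query_id, subject_id, percent_identity)],
               ba[, list(subject_id = query_id, query_id = subject_id)],
               by = c("query_id", "subject_id"))
  if (nrow(rec) == 0) return(list(aai = NA_real_, n_rbh = 0L))
  list(aai = mean(rec$percent_identity), n_rbh = nrow(rec))
}

#' Average amino-acid identity between two proteomes
#'
#' Computes best hits in both directions, keeps reciprocal best-hit (RBH)
#' pairs whose hits pass the identity/coverage filters in both directions, and
#' averages the percent identity over the retained pairs (unweighted). When no
#' RBH pair qualifies the AAI is undefined and `NA` is returned — never 0.
#'
#' @param a,b [genome_proteome()] objects.
#' @param scheme A [scoring_scheme()].
#' @param rbh_pi_min,rbh_pc_min RBH retention filters (defaults 30 / 70).
#' @param prefilter,k Alignment prefilter controls (see
#'   [search_all_vs_all()]).
#' @return List with `aai` (percent or `NA`) and `n_rbh`.
#' @export
compute_aai <- function(a, b, scheme = scoring_scheme(),
                        rbh_pi_min = 30, rbh_pc_min = 70,
                        prefilter = TRUE, k = 4) {
  stopifnot(length(a$sequences) > 0, length(b$sequences) > 0)
  hits <- search_all_vs_all(list(a, b), scheme, prefilter = prefilter, k = k)
  aai_from_hits(hits, a$genome_id, b$genome_id, rbh_pi_min, rbh_pc_min)
}

#' AAI matrix over a set of proteomes
#'
#' @param proteomes List of [genome_proteome()].
#' @param scheme A [scoring_scheme()].
#' @param hits Optional precomputed hit table from [search_all_vs_all()] over
#'   the same proteomes (avoids re-aligning).
#' @param rbh_pi_min,rbh_pc_min RBH retention filters.
#' @param prefilter,k Prefilter controls when `hits` is not supplied.
#' @return An [identity_matrix()] of kind `"AAI"`.
#' @export
aai_matrix <- function(proteomes, scheme = scoring_scheme(), hits = NULL,
                       rbh_pi_min = 30, rbh_pc_min = 70,
                       prefilter = TRUE, k = 4) {
  labels <- vapply(proteomes, function(p) p$genome_id, character(1))
  if (is.null(hits))
    hits <- search_all_vs_all(proteomes, scheme, prefilter = prefilter, k = k)
  n <- length(labels)
  vals <- matrix(NA_real_, n, n, dimnames = list(labels, labels))
  cnt <- matrix(0L, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    r <- aai_from_hits(hits, labels[i], labels[j], rbh_pi_min, rbh_pc_min)
    vals[i, j] <- vals[j, i] <- r$aai
    cnt[i, j] <- cnt[j, i] <- r$n_rbh
  }
  identity_matrix(vals, "AAI", cnt)
}

#' Fragment-based average nucleotide identity between two genomes
#'
#' Each genome is chopped into consecutive windows (default 1020 bp, the
#' classic fragment length); every fragment is locally aligned against the
#' other genome on both strands and the better strand kept. Fragments whose
#' best hit passes the identity and coverage filters contribute their percent
#' identity; the ANI is the mean over retained fragments, computed in both
#' directions and averaged so the result is symmetric.
#'
#' @param a,b Nucleotide genomes: character vectors of contig sequences
#'   (upper-case A/C/G/T/N) or record data frames from
#'   `read_fasta(..., "dna")`.
#' @param fragment_len Window size in bases (default 1020).
#' @param pi_min,pc_min Fragment retention filters (defaults 30 / 70).
#' @param scheme Nucleotide [scoring_scheme()]; default [dna_scheme()].
#' @return List with `ani` (percent or `NA` when no fragment is retained) and
#'   `n_fragments_used`.
#' @export
compute_ani <- function(a, b, fragment_len = 1020, pi_min = 30, pc_min = 70,
                        scheme = dna_scheme()) {
  ca <- as_contigs(a); cb <- as_contigs(b)
  d1 <- ani_one_direction(ca, cb, fragment_len, pi_min, pc_min, scheme)
  d2 <- ani_one_direction(cb, ca, fragment_len, pi_min, pc_min, scheme)
  n <- d1$n + d2$n
  if (n == 0) return(list(ani = NA_real_, n_fragments_used = 0L))
  vals <- c(d1$mean_pi, d2$mean_pi)
  list(ani = mean(vals[!is.na(vals)]), n_fragments_used = n)
}

as_contigs <- function(x) {
  if (is.data.frame(x)) x <- x$sequence
  stopifnot(is.character(x), length(x) >= 1, all(nchar(x) >= 1))
  toupper(x)
}

chop_fragments <- function(contigs, fragment_len) {
  unlist(lapply(contigs, function(s) {
    n <- nchar(s)
    starts <- seq(1, n, by = fragment_len)
    substring(s, starts, pmin(starts + fragment_len - 1, n))
  }), use.names = FALSE)
}

revcomp <- function(s) {
  chartr("ACGTN", "TGCAN",
         vapply(s, function(x) paste(rev(strsplit(x, "")[[1]]),
                                     collapse = ""), character(1),
                USE.NAMES = FALSE))
}

ani_one_direction <- function(query_contigs, subject_contigs, fragment_len,
                              pi_min, pc_min, scheme) {
  frags <- chop_fragments(query_contigs, fragment_len)
  seqs <- c(frags, revcomp(frags), subject_contigs)
  nf <- length(frags)
  subj_idx <- 2L * nf + seq_along(subject_contigs)
  pairs <- as.matrix(expand.grid(qi = seq_len(2L * nf), si = subj_idx))
  stats <- sw_batch(seqs, pairs, scheme)
  pi_ <- ifelse(stats[, "aln_len"] > 0,
                100 * stats[, "identities"] / stats[, "aln_len"], -Inf)
  frag_of <- ((pairs[, 1] - 1L) %% nf) + 1L
  pc <- 100 * (stats[, "qend"] - stats[, "qstart"]) / nchar(frags)[frag_of]
  # best hit per fragment over strands and subject contigs (by raw score)
  best <- tapply(seq_len(nrow(pairs)), frag_of, function(rows)
    rows[order(-stats[rows, "score"], rows)][1])
  keep <- pi_[best] >= pi_min & pc[best] >= pc_min & is.finite(pi_[best])
  list(mean_pi = if (any(keep)) mean(pi_[best][keep]) else NA_real_,
       n = sum(keep))
}

#' Delimit clades (candidate species) from an identity matrix
#'
#' Strains are joined whenever their pairwise identity reaches the cutoff and
#' clades are the connected components (single linkage). Missing identities
#' count as below the cutoff. `is_clean` audits the partition: `TRUE` iff
#' every within-clade pair is at or above the cutoff and every between-clade
#' pair below it, i.e. the partition does not depend on the linkage rule.
#'
#' @param m An [identity_matrix()] (or plain symmetric matrix with dimnames).
#' @param cutoff Percent identity cutoff, default 95 (the conspecificity
#'   threshold for AAI).
#' @return A `clade_partition`: list with `cutoff`, `clades` (list of strain
#'   vectors, ordered by smallest member), `membership` (named integer),
#'   `is_clean`.
#' @export
delimit_clades <- function(m, cutoff = 95) {
  vals <- if (inherits(m, "identity_matrix")) m$values else m
  stopifnot(is.matrix(vals), nrow(vals) == ncol(vals))
  labels <- rownames(vals)
  adj <- 1L * (!is.na(vals) & vals >= cutoff)
  diag(adj) <- 1L
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "max")
  comp <- igraph::components(g)$membership
  smallest <- tapply(labels, comp, min)
  ord <- order(smallest)
  clades <- lapply(as.integer(names(smallest)[ord]),
                   function(k) sort(labels[comp == k]))
  membership <- setNames(integer(length(labels)), labels)
  for (i in seq_along(clades)) membership[clades[[i]]] <- i
  within_ok <- TRUE; between_ok <- TRUE
  for (i in seq_len(nrow(vals) - 1)) for (j in (i + 1):ncol(vals)) {
    same <- membership[labels[i]] == membership[labels[j]]
    v <- vals[i, j]
    ok <- !is.na(v) && v >= cutoff
    if (same && !ok) within_ok <- FALSE
    if (!same && ok) between_ok <- FALSE
  }
  structure(list(cutoff = cutoff, clades = clades, membership = membership,
                 is_clean = within_ok && between_ok),
            class = "clade_partition")
}

#' @export
print.clade_partition <- function(x, ...) {
  cat(sprintf("<clade_partition> %d clades at cutoff %.1f%% (%s)\n",
              length(x$clades), x$cutoff,
              if (x$is_clean) "clean" else "linkage-dependent"))
  for (i in seq_along(x$clades))
    cat(sprintf("  clade %d: %s\n", i, paste(x$clades[[i]], collapse = ", ")))
  invisible(x)
}

#' Write a clade partition with its audit block
#'
#' Emits a two-column tab-separated file (strain, clade id) and, alongside it,
#' a `.json` audit with the cutoff, the `is_clean` flag and clade rosters.
#' @param partition A `clade_partition`.
#' @param path Output TSV path; the audit goes to `paste0(path, ".json")`.
#' @export
write_clade_partition <- function(partition, path) {
  df <- data.frame(strain = names(partition$membership),
                   clade_id = unname(partition$membership))
  data.table::fwrite(df, path, sep = "\t")
  jsonlite::write_json(
    list(cutoff = partition$cutoff, is_clean = partition$is_clean,
         n_clades = length(partition$clades), clades = partition$clades),
    paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
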