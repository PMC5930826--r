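#' Core-gene distance matrix between strains
#'
#' For every pair of strains, the per-cluster representatives (longest member,
#' ties by gene id) of each cluster present in all genomes are aligned and the
#' distance is `100 -` the length-weighted mean percent identity, with weights
#' equal to the mean of the two representative lengths.
#'
#' @param cs A `cluster_set` with at least one cluster spanning all genomes.
#' @param proteomes The proteome list the clusters were built from.
#' @param scheme A [scoring_scheme()].
#' @return Symmetric numeric distance matrix with zero diagonal.
#' @export
core_distance_matrix <- function(cs, proteomes, scheme = scoring_scheme()) {
  cnt <- cluster_genome_counts(cs)
  core_ids <- cnt[n_genomes == cs$n_genomes_total, cluster_id]
  if (length(core_ids) == 0) stopf("no core genome: no cluster spans all genomes")
  reps <- cluster_representatives(cs, proteomes, core_ids)
  genomes <- sort(unique(reps$genome_id))
  n <- length(genomes)
  if (n < 2) stopf("need >= 2 genomes")
  # one representative sequence per (cluster, genome); align all genome pairs
  # within each cluster in a single batch
  data.table::setorder(reps, cluster_id, genome_id)
  reps[, qi := .I]
  tasks <- reps[, {
    cmb <- utils::combn(qi, 2)
    list(a = cmb[1, ], b = cmb[2, ])
  }, by = cluster_id]
  stats <- sw_batch(reps$sequence, cbind(tasks$a, tasks$b), scheme)
  pi_ <- ifelse(stats[, "aln_len"] > 0,
                100 * stats[, "identities"] / stats[, "aln_len"], 0)
  w <- (reps$len[tasks$a] + reps$len[tasks$b]) / 2
  gi <- match(reps$genome_id[tasks$a], genomes)
  gj <- match(reps$genome_id[tasks$b], genomes)
  num <- matrix(0, n, n); den <- matrix(0, n, n)
  for (t in seq_along(pi_)) {
    num[gi[t], gj[t]] <- num[gi[t], gj[t]] + w[t] * pi_[t]
    den[gi[t], gj[t]] <- den[gi[t], gj[t]] + w[t]
  }
  d <- matrix(0, n, n, dimnames = list(genomes, genomes))
  upper <- den > 0
  d[upper] <- 100 - num[upper] / den[upper]
  d <- d + t(d)
  diag(d) <- 0
  d
}

#' Jaccard distance between gene-content profiles
#'
#' `d(i, j) = 1 - |intersection| / |union|` over cluster columns of a
#' presence/absence matrix.
#'
#' @param pa Binary matrix from [presence_absence_matrix()] (rows = genomes).
#' @return Symmetric distance matrix in \[0, 1\] with zero diagonal.
#' @export
jaccard_distance_matrix <- function(pa) {
  stopifnot(is.matrix(pa), all(pa %in% c(0, 1)))
  rs <- rowSums(pa)
  if (any(rs == 0))
    stopf("genome '%s' has an all-zero profile", rownames(pa)[rs == 0][1])
  inter <- pa %*% t(pa)
  uni <- outer(rs, rs, "+") - inter
  d <- 1 - inter / uni
  diag(d) <- 0
  dimnames(d) <- list(rownames(pa), rownames(pa))
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining via `ape::nj()`; any negative branch length is
#' clamped to zero with a message. NJ is exact on additive matrices: the
#' tree's path distances reproduce the input.
#'
#' @param d Symmetric distance matrix with labels (>= 3 taxa), or `dist`.
#' @return An unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (nrow(d) < 3) stopf("neighbor joining needs >= 3 labels")
  tree <- ape::nj(as.dist(d))
  neg <- tree$edge.length < 0
  if (any(neg)) {
    message(sprintf("nj_tree: clamped %d negative branch length(s) to 0",
                    sum(neg)))
    tree$edge.length[neg] <- 0
  }
  tree
}

#' Cut a tree into k leaf groups
#'
#' Induces a partition from a tree by single-linkage clustering of its
#' cophenetic (path) distances, cut at `k` groups — the partition a reader
#' would draw by slicing the k-1 deepest splits.
#'
#' @param tree An `ape::phylo`.
#' @param k Number of groups.
#' @return Named integer membership vector over the tree's tips.
#' @export
tree_clades <- function(tree, k) {
  stopifnot(inherits(tree, "phylo"), is_count(k), k >= 1,
            k <= length(tree$tip.label))
  coph <- cophenetic(tree)
  cutree(hclust(as.dist(coph), method = "single"), k = k)
}

#' Rand index between two partitions
#'
#' Fraction of label pairs on which the two partitions agree (same block in
#' both, or different blocks in both); 1 means identical partitions.
#'
#' @param p1,p2 Partitions over the same labels: named membership vectors,
#'   `clade_partition` objects, or lists of label vectors.
#' @return Rand index in \[0, 1\].
#' @export
compare_partitions <- function(p1, p2) {
  m1 <- as_membership(p1); m2 <- as_membership(p2)
  if (!setequal(names(m1), names(m2)))
    stopf("partitions are over different label sets")
  m2 <- m2[names(m1)]
  n <- length(m1)
  if (n < 2) return(1)
  tab <- table(m1, m2)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  total <- choose(n, 2)
  (total + 2 * sum_ij - sum_a - sum_b) / total
}

as_membership <- function(p) {
  if (inherits(p, "clade_partition")) return(p$membership)
  if (is.list(p) && !is.data.frame(p)) {
    labs <- unlist(p)
    if (anyDuplicated(labs)) stopf("partition blocks overlap")
    return(setNames(rep(seq_along(p), lengths(p)), labs))
  }
  if (!is.null(names(p))) return(p)
  stopf("cannot interpret partition")
}

#' Write / read Newick trees
#' @param tree An `ape::phylo`.
#' @param path File path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) ape::read.tree(path)
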