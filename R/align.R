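#' Scoring scheme for local alignment
#'
#' Bundles a symmetric substitution matrix, affine gap penalties and the
#' Karlin-Altschul parameters used to turn raw Smith-Waterman scores into bit
#' scores and E-values. The protein default is BLOSUM62 with gap open -11 /
#' extend -1 and the canonical gapped-BLOSUM62 statistics (lambda = 0.267,
#' K = 0.041).
#'
#' @param substitution_matrix Symmetric integer matrix with single-character
#'   dimnames covering the sequence alphabet.
#' @param gap_open,gap_extend Negative integers; a gap of length L costs
#'   `-(gap_open) + L * -(gap_extend)`.
#' @param lambda,k_param Positive Karlin-Altschul parameters.
#' @param alphabet `"protein"` or `"dna"`.
#' @return An object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(substitution_matrix = blosum62(),
                           gap_open = -11L, gap_extend = -1L,
                           lambda = 0.267, k_param = 0.041,
                           alphabet = "protein") {
  m <- substitution_matrix
  if (!is.matrix(m) || nrow(m) != ncol(m) ||
      !identical(rownames(m), colnames(m)))
    stopf("substitution matrix must be square with matching dimnames")
  if (!isTRUE(all.equal(m, t(m)))) stopf("substitution matrix must be symmetric")
  if (!(gap_open <= gap_extend && gap_extend < 0))
    stopf("need gap_open <= gap_extend < 0")
  if (lambda <= 0 || k_param <= 0) stopf("lambda and k_param must be positive")
  storage.mode(m) <- "integer"
  structure(list(substitution_matrix = m,
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 lambda = lambda, k_param = k_param,
                 alphabet = alphabet),
            class = "scoring_scheme")
}

#' BLOSUM62 substitution matrix restricted to the package alphabet
#' @return 21 x 21 integer matrix (20 standard amino acids plus X).
#' @export
blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  aa <- valid_letters("protein")
  m <- e$BLOSUM62[aa, aa]
  storage.mode(m) <- "integer"
  m
}

#' Nucleotide scoring scheme for ANI fragments
#'
#' Megablast-like defaults: match +1, mismatch -2, gap open -5, gap extend -2;
#' `N` scores 0 against everything. Karlin-Altschul parameters are those of
#' the +1/-2 scoring system.
#' @export
dna_scheme <- function() {
  nt <- valid_letters("dna")
  m <- matrix(-2L, 5, 5, dimnames = list(nt, nt))
  diag(m) <- 1L
  m["N", ] <- 0L
  m[, "N"] <- 0L
  scoring_scheme(m, gap_open = -5L, gap_extend = -2L,
                 lambda = 1.28, k_param = 0.46, alphabet = "dna")
}

# Internal: one-shot batch SW over an index-pair matrix. Each pair is
# aligned in a canonical orientation (lexicographically smaller sequence as
# query, spans swapped back afterwards) so that among co-optimal alignments
# the same one is reported regardless of argument order — identity and
# coverage statistics are then orientation-invariant, not just the score.
sw_batch <- function(seqs, pairs, scheme) {
  if (nrow(pairs) == 0)
    return(matrix(numeric(0), 0, 7,
                  dimnames = list(NULL, c("score", "qstart", "qend", "sstart",
                                          "send", "aln_len", "identities"))))
  swap <- seqs[pairs[, 1]] > seqs[pairs[, 2]]
  canon <- pairs
  canon[swap, ] <- pairs[swap, c(2, 1), drop = FALSE]
  st <- sw_batch_cpp(seqs, canon, scheme$substitution_matrix,
                     rownames(scheme$substitution_matrix),
                     open_first = -(scheme$gap_open + scheme$gap_extend),
                     extend = -scheme$gap_extend)
  st[swap, c("qstart", "qend", "sstart", "send")] <-
    st[swap, c("sstart", "send", "qstart", "qend"), drop = FALSE]
  st
}

#' Optimal local alignment of two sequences
#'
#' Smith-Waterman with affine gaps under the given scheme. Traceback prefers
#' diagonal over up over left and, among equal-scoring end points, the first
#' reached in row-major order, so results are deterministic. If no pair of
#' residues can produce a positive score, the empty-alignment sentinel
#' (score 0, zero-length spans) is returned.
#'
#' @param query,subject Sequences: single character strings, or named
#'   length-1 character vectors (the name becomes the id), or single-row
#'   record data frames from [read_fasta()].
#' @param scheme A [scoring_scheme()] matching the sequence alphabet.
#' @return A `local_alignment`: list with `query_id`, `subject_id`, `score`,
#'   `query_span` and `subject_span` (0-based half-open), `alignment_length`,
#'   `identities`.
#' @export
#' @examples
#' local_align("MKVLA", "MKVLA", scoring_scheme())$identities  # 5
local_align <- function(query, subject, scheme = scoring_scheme()) {
  q <- as_single_seq(query, "query")
  s <- as_single_seq(subject, "subject")
  for (x in list(q, s)) {
    if (nchar(x$sequence) < 1) stopf("empty sequence")
    bad <- setdiff(strsplit(x$sequence, "")[[1]],
                   rownames(scheme$substitution_matrix))
    if (length(bad))
      stopf("sequence alphabet mismatch with scheme: residue '%s'", bad[1])
  }
  r <- sw_batch(c(q$sequence, s$sequence), cbind(1L, 2L), scheme)[1, ]
  structure(list(query_id = q$id, subject_id = s$id,
                 score = unname(r["score"]),
                 query_span = unname(c(r["qstart"], r["qend"])),
                 subject_span = unname(c(r["sstart"], r["send"])),
                 alignment_length = unname(r["aln_len"]),
                 identities = unname(r["identities"])),
            class = "local_alignment")
}

as_single_seq <- function(x, what) {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1)
    list(id = x$id, sequence = x$sequence)
  } else if (is.character(x) && length(x) == 1) {
    list(id = names(x) %||% what, sequence = unname(x))
  } else stopf("%s must be a single sequence", what)
}

#' Similarity statistics of a local alignment
#'
#' Converts a [local_align()] result into the statistics the clustering
#' cutoffs are expressed in: percent identity
#' `PI = 100 * identities / alignment_length`, percent query coverage
#' `PC = 100 * query span length / query length`, bit score
#' `(lambda * score - ln K) / ln 2`, and E-value
#' `query_len * db_residues * 2^(-bit_score)`.
#'
#' @param aln A `local_alignment`.
#' @param query_len Length of the full query sequence.
#' @param db_residues Total residues in the search database.
#' @param scheme The [scoring_scheme()] providing lambda and K.
#' @param query_genome,subject_genome Optional strain labels carried through.
#' @return A one-row `data.frame` (a pairwise hit).
#' @export
hit_from_alignment <- function(aln, query_len, db_residues,
                               scheme = scoring_scheme(),
                               query_genome = NA_character_,
                               subject_genome = NA_character_) {
  if (aln$alignment_length == 0)
    stopf("empty alignment has no identity")
  span <- aln$query_span[2] - aln$query_span[1]
  if (query_len < span) stopf("query_len shorter than aligned span")
  if (db_residues <= 0) stopf("db_residues must be positive")
  bit <- (scheme$lambda * aln$score - log(scheme$k_param)) / log(2)
  data.frame(query_id = aln$query_id, subject_id = aln$subject_id,
             query_genome = query_genome, subject_genome = subject_genome,
             percent_identity = 100 * aln$identities / aln$alignment_length,
             percent_query_coverage = 100 * span / query_len,
             bit_score = bit,
             evalue = query_len * db_residues * 2^(-bit),
             score = aln$score,
             alignment_length = aln$alignment_length,
             identities = aln$identities,
             query_start = aln$query_span[1], query_end = aln$query_span[2],
             subject_start = aln$subject_span[1],
             subject_end = aln$subject_span[2],
             stringsAsFactors = FALSE)
}

#' Do two sequences share an exact k-mer?
#'
#' Cheap screen run before alignment: when it returns `FALSE` the pair is
#' skipped by the all-vs-all search.
#'
#' @param a,b Sequences (strings or single records).
#' @param k Word length, default 4.
#' @return Logical scalar.
#' @export
kmer_prefilter <- function(a, b, k = 4) {
  if (!is_count(k) || k < 2) stopf("k must be an integer >= 2")
  sa <- as_single_seq(a, "a")$sequence
  sb <- as_single_seq(b, "b")$sequence
  if (nchar(sa) < k || nchar(sb) < k) return(FALSE)
  any(kmers(sa, k) %in% kmers(sb, k))
}

kmers <- function(s, k) {
  n <- nchar(s)
  unique(substring(s, 1:(n - k + 1), k:n))
}

#' All-vs-all cross-genome protein search
#'
#' For every ordered pair of genes from different genomes that shares at least
#' one exact k-mer (or every pair when `prefilter = FALSE`), computes the best
#' local alignment and reports its similarity statistics. Both directions of a
#' gene pair are reported (the optimal local alignment is direction-symmetric
#' under a symmetric matrix; coverage and E-value are per-query). The database
#' size behind E-values is the total residue count over all proteomes, as for
#' a single combined search database.
#'
#' @param proteomes List of [genome_proteome()] objects (at least two).
#' @param scheme A [scoring_scheme()].
#' @param prefilter Skip pairs sharing no k-mer (default `TRUE`).
#' @param k Prefilter word length (default 4; the family-scale pipeline
#'   drivers use 5, see the methods vignette).
#' @return A `data.table` of hits ordered by query genome, query id, subject
#'   genome, subject id; columns as in [hit_from_alignment()].
#' @export
search_all_vs_all <- function(proteomes, scheme = scoring_scheme(),
                              prefilter = TRUE, k = 4) {
  idx <- flatten_proteomes(proteomes)
  if (length(unique(idx$genome_id)) < 2) stopf("need >= 2 genomes")
  db_residues <- sum(idx$len)

  pairs <- if (prefilter) {
    kmer_candidate_pairs_cpp(idx$sequence, match(idx$genome_id,
                                                 unique(idx$genome_id)),
                             as.integer(k))
  } else {
    g <- match(idx$genome_id, unique(idx$genome_id))
    all <- which(outer(g, g, "!="), arr.ind = TRUE)
    unname(as.matrix(all[all[, 1] < all[, 2], , drop = FALSE]))
  }
  stats <- sw_batch(idx$sequence, pairs, scheme)
  keep <- stats[, "aln_len"] > 0
  pairs <- pairs[keep, , drop = FALSE]
  stats <- stats[keep, , drop = FALSE]
  hits_from_batch(idx, pairs, stats, scheme, db_residues)
}

# Shared hit-table assembly: emits both directions of each aligned pair.
hits_from_batch <- function(idx, pairs, stats, scheme, db_residues) {
  empty <- data.table::data.table(
    query_id = character(), subject_id = character(),
    query_genome = character(), subject_genome = character(),
    percent_identity = numeric(), percent_query_coverage = numeric(),
    bit_score = numeric(), evalue = numeric(), score = numeric(),
    alignment_length = numeric(), identities = numeric(),
    query_start = numeric(), query_end = numeric(),
    subject_start = numeric(), subject_end = numeric())
  if (nrow(pairs) == 0) return(empty)
  bit <- (scheme$lambda * stats[, "score"] - log(scheme$k_param)) / log(2)
  pi_ <- 100 * stats[, "identities"] / stats[, "aln_len"]
  one_dir <- function(qi, si, qs, qe, ss, se) {
    qlen <- idx$len[qi]
    data.table::data.table(
      query_id = idx$gene_id[qi], subject_id = idx$gene_id[si],
      query_genome = idx$genome_id[qi], subject_genome = idx$genome_id[si],
      percent_identity = pi_,
      percent_query_coverage = 100 * (stats[, qe] - stats[, qs]) / qlen,
      bit_score = bit, evalue = qlen * db_residues * 2^(-bit),
      score = stats[, "score"], alignment_length = stats[, "aln_len"],
      identities = stats[, "identities"],
      query_start = stats[, qs], query_end = stats[, qe],
      subject_start = stats[, ss], subject_end = stats[, se])
  }
  hits <- data.table::rbindlist(list(
    one_dir(pairs[, 1], pairs[, 2], "qstart", "qend", "sstart", "send"),
    one_dir(pairs[, 2], pairs[, 1], "sstart", "send", "qstart", "qend")))
  data.table::setorder(hits, query_genome, query_id, subject_genome,
                       subject_id)
  hits[]
}

flatten_proteomes <- function(proteomes) {
  if (inherits(proteomes, "genome_proteome")) proteomes <- list(proteomes)
  stopifnot(length(proteomes) >= 1,
            all(vapply(proteomes, inherits, TRUE, "genome_proteome")))
  idx <- data.table::rbindlist(lapply(proteomes, function(p)
    data.table::data.table(genome_id = p$genome_id,
                           gene_id = names(p$sequences),
                           sequence = unname(p$sequences))))
  key <- paste(idx$genome_id, idx$gene_id)
  if (anyDuplicated(key))
    stopf("duplicate global gene id '%s'", key[duplicated(key)][1])
  idx$len <- nchar(idx$sequence)
  idx
}

#' Export a hit table as tabular text
#'
#' Tab-separated, one line per directional hit, a superset of the 12-column
#' tabular-BLAST convention: query id, subject id, percent identity, alignment
#' length, identities, query start, query end, subject start, subject end,
#' E-value, bit score, percent query coverage. Coordinates are 0-based
#' half-open.
#'
#' @param hits Hit table from [search_all_vs_all()].
#' @param path Output path.
#' @export
export_hits <- function(hits, path) {
  out <- hits[, list(query_id, subject_id,
                     percent_identity = sprintf("%.2f", percent_identity),
                     alignment_length, identities, query_start, query_end,
                     subject_start, subject_end,
                     evalue = sprintf("%.3g", evalue),
                     bit_score = sprintf("%.1f", bit_score),
                     percent_query_coverage =
                       sprintf("%.2f", percent_query_coverage))]
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}
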