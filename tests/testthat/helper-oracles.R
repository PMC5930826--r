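# Independent oracles and small fixture builders used across the suite.

# Reference local-alignment score from Biostrings (independent dynamic
# programming implementation; same affine convention: gap of length L costs
# opening + L * extension). Local scores are floored at 0.
oracle_sw_score <- function(q, s, matrix = "BLOSUM62",
                            gap_open = 11, gap_extend = 1) {
  sc <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(q), Biostrings::AAString(s), type = "local",
    substitutionMatrix = matrix, gapOpening = gap_open,
    gapExtension = gap_extend, scoreOnly = TRUE)
  max(sc, 0)
}

# Brute-force connected components by repeated transitive closure over an
# adjacency matrix; returns a canonical membership vector.
oracle_components <- function(nodes, edges) {
  n <- length(nodes)
  adj <- diag(n) > 0
  if (nrow(edges) > 0) {
    i <- match(edges[[1]], nodes)
    j <- match(edges[[2]], nodes)
    adj[cbind(i, j)] <- TRUE
    adj[cbind(j, i)] <- TRUE
  }
  repeat {
    nxt <- (adj %*% adj) > 0 | adj
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  memb <- apply(adj, 1, function(r) min(which(r)))
  stats::setNames(match(memb, unique(memb)), nodes)
}

# Rand index by explicit enumeration of all label pairs.
oracle_rand <- function(m1, m2) {
  m2 <- m2[names(m1)]
  n <- length(m1)
  agree <- 0; total <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    total <- total + 1
    same1 <- m1[i] == m1[j]
    same2 <- m2[i] == m2[j]
    if (same1 == same2) agree <- agree + 1
  }
  agree / total
}

random_aa_string <- function(len) {
  bg <- aa_background()
  paste(sample(names(bg), len, replace = TRUE, prob = bg), collapse = "")
}

random_dna_string <- function(len)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")

# Tiny proteome builders for hand-checked cases.
toy_proteome <- function(id, ...) {
  genome_proteome(id, unlist(list(...)))
}

# A small simulated family shared by several tests.
small_family <- function(seed = 11, q_within = 0.01, q_between = 0.12,
                         core = 12, specific = 3) {
  simulate_family(family_spec(
    n_clades = 3, strains_per_clade = c(2, 1, 2), core_size = core,
    strain_specific_per_strain = specific, gene_length_mean = 90,
    gene_length_min = 60, q_within = q_within, q_between = q_between,
    seed = seed))
}
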