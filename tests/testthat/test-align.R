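test_that("self-alignment of identical sequences is perfect", {
  a <- local_align(c(g1 = "MKVLA"), c(g2 = "MKVLA"))
  expect_equal(a$identities, 5)
  expect_equal(a$alignment_length, 5)
  expect_equal(a$query_span, c(0, 5))
  h <- hit_from_alignment(a, query_len = 5, db_residues = 100)
  expect_equal(h$percent_identity, 100)
  expect_equal(h$percent_query_coverage, 100)
})

test_that("sequences with no positive-scoring pair give the empty sentinel", {
  a <- local_align("MKV", "AAAA")
  expect_equal(a$score, 0)
  expect_equal(a$alignment_length, 0)
  expect_error(hit_from_alignment(a, 3, 100), "empty alignment")
})

test_that("scores match the independent local-alignment oracle", {
  set.seed(101)
  scheme <- scoring_scheme()
  for (i in 1:60) {
    q <- random_aa_string(sample(10:40, 1))
    s <- random_aa_string(sample(10:40, 1))
    mine <- local_align(q, s, scheme)$score
    expect_equal(mine, oracle_sw_score(q, s), info = paste("pair", i))
  }
})

test_that("score is symmetric under a symmetric matrix and equal penalties", {
  set.seed(102)
  for (i in 1:25) {
    q <- random_aa_string(sample(15:50, 1))
    s <- random_aa_string(sample(15:50, 1))
    expect_equal(local_align(q, s)$score, local_align(s, q)$score)
  }
})

test_that("traceback statistics are internally consistent", {
  set.seed(103)
  for (i in 1:25) {
    q <- random_aa_string(sample(20:60, 1))
    s <- random_aa_string(sample(20:60, 1))
    a <- local_align(q, s)
    if (a$alignment_length == 0) next
    expect_lte(a$identities, a$alignment_length)
    expect_lte(diff(a$query_span), a$alignment_length)
    expect_lte(diff(a$subject_span), a$alignment_length)
    expect_gte(a$query_span[1], 0)
    expect_lte(a$query_span[2], nchar(q))
    expect_lte(a$subject_span[2], nchar(s))
  }
})

test_that("bit score and E-value follow the Karlin-Altschul formulas", {
  scheme <- scoring_scheme()  # lambda 0.267, K 0.041
  aln <- structure(list(query_id = "q", subject_id = "s", score = 100,
                        query_span = c(0, 10), subject_span = c(0, 10),
                        alignment_length = 10, identities = 9),
                   class = "local_alignment")
  h <- hit_from_alignment(aln, query_len = 100, db_residues = 10000, scheme)
  bit_expected <- (0.267 * 100 - log(0.041)) / log(2)
  expect_equal(h$bit_score, bit_expected)
  expect_equal(h$evalue, 100 * 10000 * 2^(-bit_expected))
  expect_equal(h$percent_identity, 90)
  expect_equal(h$percent_query_coverage, 10)

  # coverage examples: 10/10 vs 7/10 of the query
  aln$query_span <- c(0, 7)
  expect_equal(hit_from_alignment(aln, 10, 1e4,
                                  scheme)$percent_query_coverage, 70)
})

test_that("E-value decreases strictly as score increases", {
  scheme <- scoring_scheme()
  ev <- vapply(seq(20, 200, by = 20), function(sc) {
    aln <- structure(list(query_id = "q", subject_id = "s", score = sc,
                          query_span = c(0, 10), subject_span = c(0, 10),
                          alignment_length = 10, identities = 10),
                     class = "local_alignment")
    hit_from_alignment(aln, 100, 1e4, scheme)$evalue
  }, numeric(1))
  expect_true(all(diff(ev) < 0))
})

test_that("k-mer prefilter detects shared words and respects its contract", {
  expect_true(kmer_prefilter("MKVLA", "KVLAM", k = 4))   # shared KVLA
  expect_false(kmer_prefilter("MMMM", "KKKK", k = 4))
  expect_error(kmer_prefilter("MKVLA", "KVLAM", k = 1), "k must be")

  # prefilter = FALSE implies no hit at the permissive clustering
  # thresholds, checked at the gene lengths the pipeline operates on
  # (covering 70% of a >= 60-residue gene without sharing a single word
  # is what the filter bets against; very short sequences are excluded)
  set.seed(104)
  checked <- 0
  for (i in 1:200) {
    a <- random_aa_string(sample(60:180, 1))
    b <- random_aa_string(sample(60:180, 1))
    if (kmer_prefilter(a, b, 4)) next
    checked <- checked + 1
    aln <- local_align(a, b)
    if (aln$alignment_length == 0) next
    pi_ <- 100 * aln$identities / aln$alignment_length
    pc <- 100 * diff(aln$query_span) / nchar(a)
    expect_false(pi_ >= 30 && pc >= 70)
  }
  expect_gt(checked, 20)
})

test_that("all-vs-all search finds reciprocal perfect hits and orders output", {
  p1 <- toy_proteome("A", c(x = "MKVLAWDERT"))
  p2 <- toy_proteome("B", c(y = "MKVLAWDERT"))
  hits <- search_all_vs_all(list(p1, p2))
  expect_equal(nrow(hits), 2)
  expect_equal(hits$percent_identity, c(100, 100))
  expect_equal(hits$percent_query_coverage, c(100, 100))
  expect_equal(hits$query_genome, c("A", "B"))

  # no shared k-mers with prefilter on: no hits
  p3 <- toy_proteome("C", c(z = strrep("W", 30)))
  p4 <- toy_proteome("D", c(w = strrep("K", 30)))
  expect_equal(nrow(search_all_vs_all(list(p3, p4))), 0)

  expect_error(search_all_vs_all(list(p1)), ">= 2 genomes")
  expect_error(
    search_all_vs_all(list(p1, genome_proteome("A", c(x = "MKVLAWDERT")))),
    "duplicate global gene id")
})

test_that("prefiltered search equals exhaustive search at core thresholds", {
  set.seed(105)
  ps <- lapply(c("g1", "g2", "g3"), function(g) {
    base <- random_aa_string(80)
    genome_proteome(g, stats::setNames(
      c(mutate_sequence(base, 0.05),
        vapply(1:4, function(i) random_aa_string(sample(50:90, 1)),
               character(1))),
      sprintf("%s_gene%d", g, 1:5)))
  })
  h_on <- search_all_vs_all(ps, prefilter = TRUE, k = 4)
  h_off <- search_all_vs_all(ps, prefilter = FALSE)
  e_on <- build_similarity_graph(h_on, core_thresholds())
  e_off <- build_similarity_graph(h_off, core_thresholds())
  expect_equal(e_on, e_off)
})
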