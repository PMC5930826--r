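make_hit <- function(qg, q, sg, s, pi, pc, ev = 1e-10) {
  data.table::data.table(
    query_id = q, subject_id = s, query_genome = qg, subject_genome = sg,
    percent_identity = pi, percent_query_coverage = pc,
    bit_score = 50, evalue = ev, score = 100, alignment_length = 50,
    identities = round(pi / 2), query_start = 0, query_end = 50,
    subject_start = 0, subject_end = 50)
}

test_that("edge qualification honors inclusive thresholds per direction", {
  th <- core_thresholds()
  keep <- make_hit("A", "a1", "B", "b1", pi = 95, pc = 95)
  drop_pi <- make_hit("A", "a2", "B", "b2", pi = 89.9, pc = 95)
  at_boundary <- make_hit("A", "a3", "B", "b3", pi = 90, pc = 90, ev = 1e-4)
  bad_ev <- make_hit("A", "a4", "B", "b4", pi = 95, pc = 95, ev = 1e-3)
  e <- build_similarity_graph(
    data.table::rbindlist(list(keep, drop_pi, at_boundary, bad_ev)), th)
  expect_equal(e$gene1, c("a1", "a3"))

  # either direction suffices by default; both_directions demands two
  one_dir <- make_hit("A", "a1", "B", "b1", pi = 95, pc = 95)
  rev_fail <- make_hit("B", "b1", "A", "a1", pi = 95, pc = 50)
  h <- data.table::rbindlist(list(one_dir, rev_fail))
  expect_equal(nrow(build_similarity_graph(h, th)), 1)
  expect_equal(nrow(build_similarity_graph(h, th, both_directions = TRUE)), 0)
})

test_that("random hit tables filter identically to a direct re-filter", {
  set.seed(201)
  for (rep in 1:5) {
    n <- 40
    h <- data.table::rbindlist(lapply(1:n, function(i)
      make_hit(sample(LETTERS[1:4], 1), sprintf("q%d", i),
               sample(LETTERS[5:8], 1), sprintf("s%d", i),
               pi = runif(1, 0, 100), pc = runif(1, 0, 100),
               ev = 10^runif(1, -20, 0))))
    th <- threshold_set(runif(1, 0, 100), runif(1, 0, 100), 1e-4)
    e <- build_similarity_graph(h, th)
    manual <- h[percent_identity >= th$pi_min &
                  percent_query_coverage >= th$pc_min & evalue <= 1e-4]
    expect_equal(nrow(e), nrow(unique(manual[, .(query_id, subject_id)])))
  }
})

test_that("ortholog clusters equal brute-force transitive closure", {
  set.seed(202)
  for (rep in 1:10) {
    n <- sample(10:50, 1)
    genes <- data.frame(genome_id = sample(LETTERS[1:5], n, TRUE),
                        gene_id = sprintf("g%02d", 1:n))
    n_edges <- sample(0:40, 1)
    edges <- data.table::data.table(
      genome1 = character(0), gene1 = character(0),
      genome2 = character(0), gene2 = character(0))
    if (n_edges > 0) {
      i <- sample(n, n_edges, TRUE); j <- sample(n, n_edges, TRUE)
      ok <- i != j
      edges <- data.table::data.table(
        genome1 = genes$genome_id[i[ok]], gene1 = genes$gene_id[i[ok]],
        genome2 = genes$genome_id[j[ok]], gene2 = genes$gene_id[j[ok]])
    }
    cs <- cluster_orthologs(edges, genes)
    keys <- paste(genes$genome_id, genes$gene_id, sep = "\r")
    ref <- oracle_components(
      keys, data.frame(a = paste(edges$genome1, edges$gene1, sep = "\r"),
                       b = paste(edges$genome2, edges$gene2, sep = "\r")))
    got <- stats::setNames(
      cs$clusters$cluster_id[match(keys,
        paste(cs$clusters$genome_id, cs$clusters$gene_id, sep = "\r"))],
      keys)
    expect_equal(oracle_rand(got, ref), 1)
    # partition property: every gene in exactly one cluster
    expect_equal(nrow(cs$clusters), n)
  }
})

test_that("pan/core/strain-specific counts follow their definitions", {
  genes <- data.frame(genome_id = c("A", "B", "C", "A", "B"),
                      gene_id = c("a1", "b1", "c1", "a2", "b2"))
  edges <- data.table::data.table(genome1 = c("A", "B"),
                                  gene1 = c("a1", "b1"),
                                  genome2 = c("B", "C"),
                                  gene2 = c("b1", "c1"))
  s <- summarize_pancore(cluster_orthologs(edges, genes))
  expect_equal(s$core_count, 1)
  expect_equal(s$pan_count, 3)
  expect_equal(s$strain_specific, c(A = 1L, B = 1L, C = 0L))

  # all singletons from one genome: no core unless single-genome set
  genes1 <- data.frame(genome_id = "A", gene_id = c("a1", "a2"))
  s1 <- summarize_pancore(cluster_orthologs(
    data.table::data.table(genome1 = character(0), gene1 = character(0),
                           genome2 = character(0), gene2 = character(0)),
    genes1))
  expect_equal(s1$pan_count, 2)
})

test_that("threshold and genome monotonicity hold on simulated families", {
  sim <- small_family(seed = 21)
  hits <- search_all_vs_all(sim$proteomes, k = 4)
  universe <- do.call(rbind, lapply(sim$proteomes, function(p)
    data.frame(genome_id = p$genome_id, gene_id = names(p$sequences))))
  counts <- lapply(c(90, 60, 30), function(pi_min) {
    cs <- cluster_orthologs(
      build_similarity_graph(hits, threshold_set(pi_min, 70)), universe)
    summarize_pancore(cs)
  })
  cores <- vapply(counts, `[[`, numeric(1), "core_count")
  pans <- vapply(counts, `[[`, numeric(1), "pan_count")
  expect_true(all(diff(cores) >= 0))  # lowering pi_min never loses core
  expect_true(all(diff(pans) <= 0))   # ... and never gains clusters

  # dropping a genome never decreases core or increases pan
  sub <- sim$proteomes[-1]
  hits_sub <- hits[query_genome != "s01" & subject_genome != "s01"]
  uni_sub <- universe[universe$genome_id != "s01", ]
  full <- summarize_pancore(cluster_orthologs(
    build_similarity_graph(hits, pan_thresholds()), universe))
  less <- summarize_pancore(cluster_orthologs(
    build_similarity_graph(hits_sub, pan_thresholds()), uni_sub))
  expect_gte(less$core_count, full$core_count)
  expect_lte(less$pan_count, full$pan_count)

  # strain-specific clusters have exactly one genome
  cs <- cluster_orthologs(build_similarity_graph(hits, pan_thresholds()),
                          universe)
  cnt <- cs$clusters[, .(ng = data.table::uniqueN(genome_id)),
                     by = cluster_id]
  specific_ids <- cs$clusters[
    , .(one = data.table::uniqueN(genome_id) == 1), by = cluster_id]
  expect_equal(sum(specific_ids$one),
               sum(summarize_pancore(cs)$strain_specific))
  expect_true(all(cnt$ng[specific_ids$one] == 1))
})

test_that("core concatenation uses one order and the longest representative", {
  pA <- toy_proteome("A", c(g1 = "MKVLAWDERT", g2 = strrep("HEWLK", 4)))
  pB <- toy_proteome("B", c(h1 = "MKVLAWDERT", h2 = strrep("HEWLK", 4),
                            h3 = "MKVLAWDERTAA"))  # paralog, longer
  hits <- search_all_vs_all(list(pA, pB), k = 4)
  cs <- cluster_orthologs(build_similarity_graph(hits, pan_thresholds()),
                          list(pA, pB))
  cc <- concatenate_core(cs, list(pA, pB))
  expect_equal(sort(names(cc)), c("A", "B"))
  expect_equal(nchar(cc[["A"]]), 30)
  # paralog cluster picks the longest member for B
  expect_equal(nchar(cc[["B"]]), 32)
  expect_true(startsWith(cc[["B"]], "MKVLAWDERTAA") ||
                endsWith(cc[["B"]], strrep("HEWLK", 4)))

  # zero divergence: concatenates identical across strains
  sim0 <- simulate_family(family_spec(n_clades = 2,
                                      strains_per_clade = c(2, 2),
                                      core_size = 5,
                                      strain_specific_per_strain = 0,
                                      q_within = 0, q_between = 0,
                                      seed = 3))
  h0 <- search_all_vs_all(sim0$proteomes, k = 4)
  cs0 <- cluster_orthologs(build_similarity_graph(h0, core_thresholds()),
                           sim0$proteomes)
  cc0 <- concatenate_core(cs0, sim0$proteomes)
  expect_length(unique(unname(cc0)), 1)

  # single cluster: concatenate equals the representative itself
  p1 <- toy_proteome("X", c(x = "MKVLAWDERT"))
  p2 <- toy_proteome("Y", c(y = "MKVLAWDERT"))
  h1 <- search_all_vs_all(list(p1, p2))
  cs1 <- cluster_orthologs(build_similarity_graph(h1, core_thresholds()),
                           list(p1, p2))
  expect_equal(unname(concatenate_core(cs1, list(p1, p2))["X"]),
               "MKVLAWDERT")
})

test_that("presence/absence matrix reflects cluster membership", {
  genes <- data.frame(genome_id = c("A", "B", "C", "A"),
                      gene_id = c("a1", "b1", "c1", "a2"))
  edges <- data.table::data.table(genome1 = c("A", "B"),
                                  gene1 = c("a1", "b1"),
                                  genome2 = c("B", "C"),
                                  gene2 = c("b1", "c1"))
  cs <- cluster_orthologs(edges, genes)
  pa <- presence_absence_matrix(cs)
  expect_equal(dim(pa), c(3, 2))
  expect_equal(ncol(pa), summarize_pancore(cs)$pan_count)
  core_col <- which(colSums(pa) == 3)
  expect_length(core_col, 1)
  expect_true(all(pa[, core_col] == 1))
  expect_equal(sum(pa[, -core_col]), 1)  # strain-specific column: one 1
})

test_that("gene presence screen flags matches above the identity cutoff", {
  prot <- toy_proteome("A", c(target = "MKVLAWDERTMKVLAWDERT",
                              other = strrep("HEWLK", 6)))
  ref <- c(hitme = "MKVLAWDERTMKVLAWDERT", nohit = strrep("C", 25))
  rep <- gene_presence_screen(ref, prot)
  expect_equal(rep$ref_id, c("hitme", "nohit"))
  expect_equal(rep$best_pi[1], 100)
  expect_true(rep$present[1])
  expect_false(rep$present[2])

  expect_warning(
    empty <- gene_presence_screen(ref, genome_proteome("E", character(0) |>
                                                         stats::setNames(character(0)))),
    "empty proteome")
  expect_false(any(empty$present))

  # flags equal a direct per-reference best-hit recomputation
  set.seed(203)
  prot2 <- toy_proteome("B", stats::setNames(
    vapply(sample(40:80, 6, TRUE), random_aa_string, character(1)),
    sprintf("p%d", 1:6)))
  ref2 <- stats::setNames(
    c(mutate_sequence(prot2$sequences[["p1"]], 0.3),
      vapply(1:3, function(i) random_aa_string(50), character(1))),
    sprintf("r%d", 1:4))
  rep2 <- gene_presence_screen(ref2, prot2)
  for (rid in names(ref2)) {
    scores <- vapply(prot2$sequences, function(s)
      local_align(ref2[[rid]], s)$score, numeric(1))
    if (max(scores) == 0) {
      expect_false(rep2$present[rep2$ref_id == rid])
      next
    }
    best <- sort(names(scores)[scores == max(scores)])[1]
    al <- local_align(ref2[[rid]], prot2$sequences[[best]])
    expect_equal(rep2$present[rep2$ref_id == rid],
                 100 * al$identities / al$alignment_length >= 20, info = rid)
  }
})
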