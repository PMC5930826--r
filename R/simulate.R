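#' Background amino-acid frequencies
#'
#' Robinson-Robinson average composition of globular proteins, normalized to
#' sum to one; the sampling distribution for [random_protein()] and the
#' replacement distribution in [mutate_sequence()].
#' @return Named numeric vector over the 20 standard amino acids.
#' @export
aa_background <- function() {
  f <- c(A = 0.078, R = 0.051, N = 0.045, D = 0.054, C = 0.019, Q = 0.043,
         E = 0.063, G = 0.074, H = 0.022, I = 0.051, L = 0.091, K = 0.057,
         M = 0.022, F = 0.039, P = 0.052, S = 0.071, T = 0.058, W = 0.013,
         Y = 0.032, V = 0.064)
  f / sum(f)
}

#' Random protein sequence from the background composition
#'
#' Deterministic under the caller's RNG seed.
#' @param length Sequence length (>= 1).
#' @return A single protein sequence string.
#' @export
random_protein <- function(length) {
  if (!is_count(length) || length < 1)
    stopf("length must be a positive integer")
  bg <- aa_background()
  paste(sample(names(bg), length, replace = TRUE, prob = bg), collapse = "")
}

random_dna <- function(length) {
  paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
}

#' Substitute sites of a sequence independently
#'
#' Each site is substituted with probability `q`; the replacement residue is
#' drawn from the background composition conditioned on differing from the
#' original, so expected identity to the parent is exactly `100 * (1 - q)`.
#'
#' @param s A sequence string.
#' @param q Per-site substitution probability in \[0, 1\].
#' @param alphabet `"protein"` (background replacement) or `"dna"` (uniform
#'   over the other three bases).
#' @return Mutated sequence string of the same length.
#' @export
mutate_sequence <- function(s, q, alphabet = c("protein", "dna")) {
  alphabet <- match.arg(alphabet)
  stopifnot(q >= 0, q <= 1)
  if (q == 0) return(s)
  chars <- strsplit(s, "")[[1]]
  hit <- which(stats::runif(length(chars)) < q)
  if (length(hit) == 0) return(s)
  if (alphabet == "protein") {
    bg <- aa_background()
    repl <- sample(names(bg), length(hit), replace = TRUE, prob = bg)
    while (any(bad <- repl == chars[hit]))
      repl[bad] <- sample(names(bg), sum(bad), replace = TRUE, prob = bg)
  } else {
    nt <- c("A", "C", "G", "T")
    repl <- vapply(chars[hit],
                   function(x) sample(setdiff(nt, x), 1), character(1),
                   USE.NAMES = FALSE)
  }
  chars[hit] <- repl
  paste(chars, collapse = "")
}

#' Specification of a simulated proteome family
#'
#' Defaults mirror the cocci-shaped *Sporosarcina* study system: 29 strains in
#' 8 clades (clade sizes follow the published clade rosters), a planted core
#' of 200 genes, 50 strain-specific genes per strain, mild within-clade
#' divergence (q = 0.01 per site) and strong between-clade divergence
#' (q = 0.12 per site), substitution-only, mean gene length 120 residues.
#'
#' @param n_clades Number of clades.
#' @param strains_per_clade Integer vector of clade sizes (length `n_clades`).
#' @param core_size Number of planted core genes.
#' @param strain_specific_per_strain Freshly generated genes per strain.
#' @param gene_length_mean,gene_length_min Gene lengths are drawn uniformly on
#'   `[min, 2 * mean - min]` (bounded, mean-preserving).
#' @param q_within Per-site substitution probability clade-root -> strain.
#' @param q_between Per-site substitution probability ancestor -> clade root.
#' @param indels If `TRUE`, also apply rare indels (geometric lengths); off by
#'   default so analytic identity expectations hold exactly.
#' @param seed RNG seed; the whole family is reproducible from it.
#' @return A `family_spec`.
#' @export
family_spec <- function(n_clades = 8,
                        strains_per_clade = c(3, 1, 3, 5, 2, 5, 5, 5),
                        core_size = 200, strain_specific_per_strain = 50,
                        gene_length_mean = 120, gene_length_min = 60,
                        q_within = 0.01, q_between = 0.12,
                        indels = FALSE, seed = 1) {
  stopifnot(is_count(n_clades), n_clades >= 1,
            length(strains_per_clade) == n_clades,
            all(strains_per_clade >= 1),
            is_count(core_size), core_size >= 0,
            is_count(strain_specific_per_strain),
            strain_specific_per_strain >= 0,
            gene_length_min >= 7, gene_length_mean >= gene_length_min,
            q_within >= 0, q_between >= q_within, q_between <= 1)
  structure(list(n_clades = n_clades,
                 strains_per_clade = as.integer(strains_per_clade),
                 core_size = as.integer(core_size),
                 strain_specific_per_strain =
                   as.integer(strain_specific_per_strain),
                 gene_length_mean = gene_length_mean,
                 gene_length_min = gene_length_min,
                 q_within = q_within, q_between = q_between,
                 indels = indels, seed = as.integer(seed)),
            class = "family_spec")
}

apply_indels <- function(s, rate = 0.002, ext = 0.5) {
  chars <- strsplit(s, "")[[1]]
  out <- character(0)
  i <- 1
  bg <- aa_background()
  while (i <= length(chars)) {
    u <- stats::runif(1)
    if (u < rate / 2) {                       # deletion
      i <- i + stats::rgeom(1, 1 - ext) + 1
    } else if (u < rate) {                    # insertion
      len <- stats::rgeom(1, 1 - ext) + 1
      out <- c(out, sample(names(bg), len, replace = TRUE, prob = bg),
               chars[i]); i <- i + 1
    } else {
      out <- c(out, chars[i]); i <- i + 1
    }
  }
  if (length(out) == 0) s else paste(out, collapse = "")
}

# Planted-gene similarity screen. A candidate ancestor gene is rejected when
# its best local alignment against an already-planted gene reaches the
# class-specific identity/coverage margin (coverage of either sequence):
#   core vs core      PI >= 25, cov >= 60  (both lineages mutate; the merge
#                                           test is a max over ~29x29 copy
#                                           pairs, so leave the widest margin
#                                           below the 30/70 cluster cutoffs)
#   core vs specific  PI >= 27, cov >= 65  (one lineage mutates)
#   specific pairs    PI >= 30, cov >= 70  (never mutate: the exact cutoffs)
# Only pool members sharing at least one 4-mer with the candidate are
# aligned; the clustering stage itself only ever aligns pairs sharing a
# 5-mer, so the screen sees a superset of the pairs the pipeline can link.
screen_margins <- function(class_a, class_b) {
  if (class_a == "core" && class_b == "core") c(25, 60)
  else if (class_a == "specific" && class_b == "specific") c(30, 70)
  else c(27, 65)
}

new_gene_screen <- function(scheme) {
  pool <- character(0)
  pool_class <- character(0)
  kmer_index <- new.env(parent = emptyenv())
  list(
    ok = function(s, class) {
      idx <- sort(unlist(mget(kmers(s, 4), envir = kmer_index,
                              ifnotfound = list(NULL)), use.names = FALSE))
      idx <- unique(idx)
      if (length(idx) == 0) return(TRUE)
      stats <- sw_batch(c(pool[idx], s),
                        cbind(length(idx) + 1L, seq_along(idx)), scheme)
      aln <- stats[, "aln_len"]
      has <- which(aln > 0)
      if (length(has) == 0) return(TRUE)
      pi_ <- 100 * stats[has, "identities"] / aln[has]
      cov <- pmax(
        100 * (stats[has, "qend"] - stats[has, "qstart"]) / nchar(s),
        100 * (stats[has, "send"] - stats[has, "sstart"]) /
          nchar(pool[idx[has]]))
      lim <- vapply(pool_class[idx[has]], screen_margins, numeric(2),
                    class_b = class)
      !any(pi_ >= lim[1, ] & cov >= lim[2, ])
    },
    add = function(s, class) {
      pool <<- c(pool, s)
      pool_class <<- c(pool_class, class)
      i <- length(pool)
      for (k in kmers(s, 4))
        assign(k, c(kmer_index[[k]], i), envir = kmer_index)
      invisible(i)
    })
}

#' Simulate a proteome family with planted clades
#'
#' Generates an ancestral core proteome, derives one root per clade by
#' background substitution at `q_between`, then each strain's core genes from
#' its clade root at `q_within`, and finally adds freshly generated
#' strain-specific genes.
#'
#' Planted families are guaranteed unmergeable, so planted core and pan
#' counts are exact: candidate genes are rejection-sampled at draw time
#' (no chance local similarity approaching the clustering cutoffs to any
#' already-planted gene, and no 6-mer shared between a strain-specific gene
#' and any ancestral core gene), and after the strains are derived the
#' realized gene copies are scanned for cross-family pairs that would qualify
#' at the permissive clustering cutoffs (PI >= 30 covering >= 70 percent of
#' either copy) — substitution occasionally creates such chance similarity
#' between unrelated short proteins — and any affected family is redrawn
#' until none remain. Everything is drawn under `spec$seed`, so the family is
#' byte-reproducible.
#'
#' Under the two-layer substitution model the expected identity between two
#' strains of the same clade is `100 * (1 - q_within)^2` and between clades
#' `100 * ((1 - q_within) * (1 - q_between))^2`.
#'
#' @param spec A [family_spec()].
#' @return List with `proteomes` (list of [genome_proteome()], strain labels
#'   `s01`, `s02`, ...) and `truth` (planted partition, core size, per-strain
#'   specific counts, expected within/between identities).
#' @export
simulate_family <- function(spec) {
  stopifnot(inherits(spec, "family_spec"))
  with_seed(spec$seed, {
    lmin <- spec$gene_length_min
    lmax <- 2 * spec$gene_length_mean - lmin
    scheme <- scoring_scheme()
    screen <- new_gene_screen(scheme)
    draw_planted <- function(class, extra_ok = function(s) TRUE) {
      repeat {
        s <- random_protein(sample(seq(lmin, lmax), 1))
        if (extra_ok(s) && screen$ok(s, class)) {
          screen$add(s, class)
          return(s)
        }
      }
    }

    n_strains <- sum(spec$strains_per_clade)
    strain_ids <- sprintf("s%02d", seq_len(n_strains))
    partition <- setNames(rep(seq_len(spec$n_clades),
                              spec$strains_per_clade), strain_ids)

    # ancestor -> clade roots -> strain copies, for one core family
    derive_core_family <- function(anc) {
      out <- character(n_strains)
      si <- 0
      for (cl in seq_len(spec$n_clades)) {
        root <- mutate_sequence(anc, spec$q_between)
        for (k in seq_len(spec$strains_per_clade[cl])) {
          si <- si + 1
          s <- mutate_sequence(root, spec$q_within)
          if (spec$indels) s <- apply_indels(s)
          out[si] <- s
        }
      }
      out
    }

    core_kmer_env <- new.env(parent = emptyenv())
    note_core_kmers <- function(s)
      for (k in kmers(s, 6)) assign(k, TRUE, envir = core_kmer_env)
    no_core_kmer <- function(s)
      !any(vapply(kmers(s, 6), exists, logical(1), envir = core_kmer_env))

    draw_core_family <- function() {
      anc <- draw_planted("core")
      note_core_kmers(anc)
      derive_core_family(anc)
    }
    fresh_specific <- function() draw_planted("specific", no_core_kmer)

    core_members <- lapply(seq_len(spec$core_size),
                           function(f) draw_core_family())
    n_uniq <- spec$strain_specific_per_strain
    uniq_genes <- lapply(seq_len(n_strains), function(si)
      vapply(seq_len(n_uniq), function(j) fresh_specific(), character(1)))

    # member-level repair: redraw any family whose realized copies show
    # chance cross-family similarity at the clustering cutoffs; candidate
    # pairs are those sharing a 5-mer, matching the search prefilter
    for (round in seq_len(25)) {
      seqs <- c(unlist(core_members), unlist(uniq_genes))
      fam <- c(rep(seq_len(spec$core_size), each = n_strains),
               rep(spec$core_size + seq_len(n_strains * n_uniq),
                   each = if (n_uniq > 0) 1 else 0))
      if (length(seqs) < 2) break
      pairs <- kmer_candidate_pairs_cpp(seqs, as.integer(fam), 5L)
      bad_fams <- integer(0)
      if (nrow(pairs) > 0) {
        st <- sw_batch(seqs, pairs, scheme)
        has <- st[, "aln_len"] > 0
        pi_ <- ifelse(has, 100 * st[, "identities"] /
                        pmax(st[, "aln_len"], 1), 0)
        cov <- pmax(
          100 * (st[, "qend"] - st[, "qstart"]) / nchar(seqs[pairs[, 1]]),
          100 * (st[, "send"] - st[, "sstart"]) / nchar(seqs[pairs[, 2]]))
        conflict <- which(pi_ >= 30 & cov >= 70)
        if (length(conflict) > 0) {
          fa <- fam[pairs[conflict, 1]]
          fb <- fam[pairs[conflict, 2]]
          # redraw the strain-specific member when one is involved (cheap),
          # otherwise the younger core family; deterministic choice
          pick <- ifelse(fa > spec$core_size & fb <= spec$core_size, fa,
                         ifelse(fb > spec$core_size & fa <= spec$core_size,
                                fb, pmax(fa, fb)))
          bad_fams <- sort(unique(pick))
        }
      }
      if (length(bad_fams) == 0) break
      if (round == 25)
        stopf("family simulation did not converge to unmergeable families")
      for (f in bad_fams) {
        if (f <= spec$core_size) {
          core_members[[f]] <- draw_core_family()
        } else {
          u <- f - spec$core_size
          si <- (u - 1) %/% n_uniq + 1
          j <- (u - 1) %% n_uniq + 1
          uniq_genes[[si]][j] <- fresh_specific()
        }
      }
    }

    proteomes <- lapply(seq_len(n_strains), function(si) {
      core <- vapply(core_members, `[`, character(1), si)
      names(core) <- sprintf("core%04d", seq_len(spec$core_size))
      uniq <- uniq_genes[[si]]
      names(uniq) <- sprintf("uniq%04d", seq_len(n_uniq))[seq_along(uniq)]
      genome_proteome(strain_ids[si], c(core, uniq))
    })
    truth <- list(
      partition = partition,
      planted_core = spec$core_size,
      planted_strain_specific = setNames(rep(n_uniq, n_strains), strain_ids),
      expected_within_identity = 100 * (1 - spec$q_within)^2,
      expected_between_identity =
        100 * ((1 - spec$q_within) * (1 - spec$q_between))^2)
    list(proteomes = proteomes, truth = truth)
  })
}

#' Write a simulated family to disk
#'
#' One protein FASTA per strain plus `truth.json` with the planted partition
#' and counts.
#' @param sim Result of [simulate_family()].
#' @param dir Output directory (created if needed).
#' @export
write_family <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (p in sim$proteomes)
    write_fasta(p$sequences, file.path(dir, paste0(p$genome_id, ".faa")))
  jsonlite::write_json(
    list(partition = as.list(sim$truth$partition),
         planted_core = sim$truth$planted_core,
         planted_strain_specific =
           as.list(sim$truth$planted_strain_specific),
         expected_within_identity = sim$truth$expected_within_identity,
         expected_between_identity = sim$truth$expected_between_identity),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}
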