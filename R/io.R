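#' Read a FASTA file into a sequence-record table
#'
#' Parses a (possibly line-wrapped) multi-record FASTA file. Headers are split
#' at the first whitespace into a record id and a free-text description.
#' Sequences are upper-cased; `*` stop characters in protein sequences are
#' stripped with a warning, matching common annotation-pipeline output.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"protein"` (20 standard amino acids plus `X`) or `"dna"`
#'   (`A`, `C`, `G`, `T`, `N`). Any other residue is an error naming the
#'   offending record and position.
#' @return A `data.frame` with columns `id`, `description`, `sequence` (one row
#'   per record, input order preserved) and attribute `alphabet`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".faa")
#' writeLines(c(">g1 a demo", "MKV", "LA"), f)
#' read_fasta(f)
read_fasta <- function(path, alphabet = c("protein", "dna")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stopf("file not found: %s", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stopf("no records in %s", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(ids == "")) stopf("record %d has an empty id", which(ids == "")[1])
  if (anyDuplicated(ids))
    stopf("duplicate record id '%s'", ids[duplicated(ids)][1])
  seqs <- toupper(as.character(set))
  if (alphabet == "protein" && any(grepl("*", seqs, fixed = TRUE))) {
    warning("stripped '*' stop characters from protein sequences",
            call. = FALSE)
    seqs <- gsub("*", "", seqs, fixed = TRUE)
  }
  validate_residues(seqs, ids, alphabet)
  out <- data.frame(id = ids, description = desc, sequence = unname(seqs),
                    stringsAsFactors = FALSE)
  attr(out, "alphabet") <- alphabet
  out
}

valid_letters <- function(alphabet) {
  if (alphabet == "protein") c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")
  else c("A", "C", "G", "T", "N")
}

validate_residues <- function(seqs, ids, alphabet) {
  ok <- valid_letters(alphabet)
  pat <- paste0("[^", paste(ok, collapse = ""), "]")
  for (i in seq_along(seqs)) {
    if (nchar(seqs[i]) < 1) stopf("record '%s' has an empty sequence", ids[i])
    m <- regexpr(pat, seqs[i])
    if (m > 0)
      stopf("illegal %s residue '%s' in record '%s' at position %d",
            alphabet, substr(seqs[i], m, m), ids[i], m)
  }
  invisible(TRUE)
}

#' Write sequence records as FASTA
#'
#' Round-trip property: `read_fasta(write_fasta(x))` reproduces ids,
#' descriptions and sequences exactly.
#'
#' @param records A `data.frame` as returned by [read_fasta()], or a named
#'   character vector of sequences (names become ids, descriptions empty).
#' @param path Output file path.
#' @param width Line-wrap width for sequences (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70) {
  if (is.character(records) && !is.null(names(records)))
    records <- data.frame(id = names(records), description = "",
                          sequence = unname(records), stringsAsFactors = FALSE)
  stopifnot(is.data.frame(records),
            all(c("id", "sequence") %in% names(records)))
  if (!is_count(width) || width < 1) stopf("width must be a positive integer")
  desc <- records$description %||% rep("", nrow(records))
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- ifelse(desc == "", records$id,
                       paste(records$id, desc))
  Biostrings::writeXStringSet(set, path, width = as.integer(width))
  invisible(path)
}

#' A strain's proteome
#'
#' Bundles one genome's protein sequences under a strain label; the unit of
#' every comparison in the pipeline.
#'
#' @param genome_id Non-empty strain label, e.g. `"P33"`.
#' @param sequences Named character vector of protein sequences (names are
#'   gene ids, unique within the proteome) or a record `data.frame` from
#'   [read_fasta()].
#' @return An object of class `genome_proteome` with elements `genome_id`,
#'   `sequences` (named character) and `total_residues`.
#' @export
genome_proteome <- function(genome_id, sequences) {
  if (!is.character(genome_id) || length(genome_id) != 1 || genome_id == "")
    stopf("genome_id must be a non-empty string")
  if (is.data.frame(sequences))
    sequences <- setNames(sequences$sequence, sequences$id)
  if (is.null(names(sequences)) || any(names(sequences) == ""))
    stopf("all sequences must be named by gene id")
  if (anyDuplicated(names(sequences)))
    stopf("duplicate gene id '%s' in proteome '%s'",
          names(sequences)[duplicated(names(sequences))][1], genome_id)
  if (any(nchar(sequences) < 1)) stopf("empty sequence in proteome")
  structure(list(genome_id = genome_id,
                 sequences = sequences,
                 total_residues = sum(nchar(sequences))),
            class = "genome_proteome")
}

#' @export
print.genome_proteome <- function(x, ...) {
  cat(sprintf("<genome_proteome> %s: %d genes, %d residues\n",
              x$genome_id, length(x$sequences), x$total_residues))
  invisible(x)
}

#' Read one strain's proteome from a protein FASTA file
#'
#' @param path Protein FASTA file.
#' @param genome_id Strain label; defaults to the file name without extension.
#' @return A [genome_proteome()].
#' @export
read_proteome <- function(path, genome_id = NULL) {
  genome_id <- genome_id %||% sub("\\.[^.]*$", "", basename(path))
  genome_proteome(genome_id, read_fasta(path, "protein"))
}

#' Load a genome-characteristics table
#'
#' Reads a tab-separated table of per-genome characteristics (the packaged
#' fixture transcribes the published table for the 29 cocci-shaped
#' *Sporosarcina* strains). Numeric columns may contain thousands separators;
#' the prophage column is kept as raw text because the published counts are
#' internally ambiguous.
#'
#' @param path Tab-separated file; defaults to the packaged fixture.
#' @return A `data.frame` with columns `accession`, `strain`, `genome_bp`,
#'   `gc_percent`, `cds`, `trnas`, `plasmids`, `prophages` (character),
#'   `is_elements`.
#' @export
#' @examples
#' tab <- load_genome_table()
#' nrow(tab)  # 29 strains
load_genome_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "sporosarcina_genome_table.tsv",
                                package = "pancocci", mustWork = TRUE)
  raw <- tryCatch(
    read.delim(path, colClasses = "character", check.names = FALSE),
    error = function(e) stopf("cannot read genome table: %s",
                              conditionMessage(e)))
  if (nrow(raw) == 0) stopf("no records in %s", path)
  required <- c("accession", "strain", "genome_bp", "gc_percent", "cds",
                "trnas", "plasmids", "prophages", "is_elements")
  missing <- setdiff(required, names(raw))
  if (length(missing))
    stopf("genome table is missing column(s): %s",
          paste(missing, collapse = ", "))
  num <- function(col, integer = FALSE) {
    v <- suppressWarnings(as.numeric(gsub(",", "", raw[[col]], fixed = TRUE)))
    if (anyNA(v))
      stopf("non-numeric value in column '%s', row %d ('%s')",
            col, which(is.na(v))[1], raw$strain[which(is.na(v))[1]])
    if (integer) as.integer(v) else v
  }
  out <- data.frame(accession = raw$accession, strain = raw$strain,
                    genome_bp = num("genome_bp", TRUE),
                    gc_percent = num("gc_percent"),
                    cds = num("cds", TRUE), trnas = num("trnas", TRUE),
                    plasmids = num("plasmids", TRUE),
                    prophages = raw$prophages,
                    is_elements = num("is_elements", TRUE),
                    stringsAsFactors = FALSE)
  if (any(out$genome_bp <= 0)) stopf("genome_bp must be positive")
  if (any(out$gc_percent < 0 | out$gc_percent > 100))
    stopf("gc_percent out of [0, 100]")
  if (any(out$cds < 0 | out$trnas < 0 | out$plasmids < 0 |
          out$is_elements < 0)) stopf("counts must be non-negative")
  out
}

#' Write a labelled square matrix as tab-separated text
#'
#' First row and first column hold the labels; values are rendered with four
#' decimal places, so a round trip through [read_matrix()] reproduces values
#' to 1e-4.
#'
#' @param m Square numeric matrix with identical row and column names.
#' @param path Output path.
#' @export
write_matrix <- function(m, path) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stopf("matrix must be square (got %d x %d)", NROW(m), NCOL(m))
  labels <- rownames(m) %||% as.character(seq_len(nrow(m)))
  lines <- c(paste(c("", labels), collapse = "\t"),
             vapply(seq_len(nrow(m)), function(i)
               paste(c(labels[i], sprintf("%.4f", m[i, ])), collapse = "\t"),
               character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a matrix written by [write_matrix()]
#' @param path Tab-separated labelled matrix file.
#' @return Numeric matrix with dimnames.
#' @export
read_matrix <- function(path) {
  raw <- read.delim(path, check.names = FALSE, row.names = 1)
  m <- as.matrix(raw)
  storage.mode(m) <- "double"
  m
}
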