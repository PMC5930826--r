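#' Summary statistics of a genome-characteristics table
#'
#' Reproduces the headline per-genome averages from a table such as the
#' packaged 29-strain fixture: mean genome size (Mb, 2 decimals), mean CDS and
#' tRNA counts (nearest integer), mean IS-element count (1 decimal) with its
#' range, and the GC range. Rounding follows the precision these quantities
#' are conventionally reported at and is not configurable. The prophage column
#' is excluded (kept as raw text by [load_genome_table()]).
#'
#' @param rows `data.frame` from [load_genome_table()] (>= 1 row).
#' @return A `genome_table_summary`: list with `n_genomes`, `mean_bp`,
#'   `mean_mb`, `mean_cds`, `mean_trnas`, `mean_is`, `min_is`, `max_is`,
#'   `gc_min`, `gc_max`.
#' @export
#' @examples
#' summarize_genome_table(load_genome_table())
summarize_genome_table <- function(rows) {
  if (!is.data.frame(rows) || nrow(rows) < 1)
    stopf("need at least one genome row")
  structure(list(
    n_genomes = nrow(rows),
    mean_bp = mean(rows$genome_bp),
    mean_mb = round(mean(rows$genome_bp) / 1e6, 2),
    mean_cds = round(mean(rows$cds)),
    mean_trnas = round(mean(rows$trnas)),
    mean_is = round(mean(rows$is_elements), 1),
    min_is = min(rows$is_elements),
    max_is = max(rows$is_elements),
    gc_min = min(rows$gc_percent),
    gc_max = max(rows$gc_percent)), class = "genome_table_summary")
}

#' @export
print.genome_table_summary <- function(x, ...) {
  cat(sprintf(paste0("<genome_table_summary> %d genomes: mean %.2f Mb, ",
                     "%d CDS, %d tRNAs; IS %.1f (range %d-%d); ",
                     "GC %.1f-%.1f%%\n"),
              x$n_genomes, x$mean_mb, x$mean_cds, x$mean_trnas, x$mean_is,
              x$min_is, x$max_is, x$gc_min, x$gc_max))
  invisible(x)
}

#' Write a genome-table summary as key-value text and JSON
#' @param s A `genome_table_summary`.
#' @param path Output stem: writes `<path>.txt` and `<path>.json`.
#' @export
write_summary <- function(s, path) {
  kv <- unlist(unclass(s))
  writeLines(paste(names(kv), kv, sep = "\t"), paste0(path, ".txt"))
  jsonlite::write_json(unclass(s), paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
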