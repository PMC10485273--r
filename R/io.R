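# Shared I/O: the genotype-table TSV dialect, deterministic report
# serialization, and FASTA convenience wrappers.

#' Read a population genotype table (TSV)
#'
#' Tab-separated with header `plant_id`, `locus`, `allele_a`, `allele_b`;
#' one row per plant x locus. Rows with a wrong field count are rejected
#' with their line number; duplicate (plant, locus) rows are an error.
#' Allele columns may be `NA` (missing/deleted), otherwise integer labels.
#'
#' @param path File path.
#' @return Validated data frame (empty, with the right columns, for a
#'   header-only file).
#' @export
read_genotype_table <- function(path) {
  if (!file.exists(path)) .stop_ctx("no such file: ", path)
  nf <- utils::count.fields(path, sep = "\t", blank.lines.skip = FALSE)
  nf <- nf[!is.na(nf)]
  bad <- which(nf != 4L)
  if (length(bad))
    .stop_ctx("malformed genotype table: line ", bad[1L], " has ", nf[bad[1L]],
              " fields (expected 4: plant_id, locus, allele_a, allele_b)")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c("character", "character",
                                          "integer", "integer"))
  need <- c("plant_id", "locus", "allele_a", "allele_b")
  if (!identical(names(tab), need))
    .stop_ctx("genotype table header must be exactly: ",
              paste(need, collapse = ", "))
  dup <- duplicated(tab[, c("plant_id", "locus")])
  if (any(dup))
    .stop_ctx("duplicate (plant_id, locus) row at line ",
              which(dup)[1L] + 1L)
  tab
}

#' Write a population genotype table (TSV)
#'
#' @param genotypes Data frame in the [read_genotype_table()] dialect.
#' @param path File path.
#' @export
write_genotype_table <- function(genotypes, path) {
  utils::write.table(genotypes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write an analysis report deterministically
#'
#' Serializes results to JSON (keys sorted recursively, numbers at fixed
#' 6-digit precision), TSV (data frames) or Newick (trees), so repeat runs
#' of a seeded pipeline produce byte-identical files.
#'
#' @param results A list (JSON), data frame (TSV) or `phylo` (Newick).
#' @param path Output path.
#' @param format `"json"`, `"tsv"` or `"newick"`.
#' @return The path, invisibly.
#' @export
write_report <- function(results, path, format = c("json", "tsv", "newick")) {
  format <- match.arg(format)
  dir <- dirname(path)
  if (!dir.exists(dir)) .stop_ctx("output directory does not exist: ", dir)
  switch(format,
    json = jsonlite::write_json(.sort_names(results), path,
                                auto_unbox = TRUE, digits = 6L,
                                pretty = TRUE, null = "null"),
    tsv = {
      if (!is.data.frame(results))
        .stop_ctx("tsv format requires a data frame")
      utils::write.table(results, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    },
    newick = {
      if (!inherits(results, "phylo"))
        .stop_ctx("newick format requires a phylo tree")
      ape::write.tree(results, file = path)
    })
  invisible(path)
}

#' Read / write sequences as FASTA
#'
#' Thin wrappers over Biostrings returning and accepting plain named
#' character vectors, the sequence currency of this package.
#'
#' @param path File path.
#' @return `read_fasta` returns a named character vector (upper case).
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(x)), names(x))
}

#' @rdname read_fasta
#' @param seqs Named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Marker-by-marker recombination profile of a mapped interval
#'
#' Flattens an [map_locus_interval()] result into the tabular profile of
#' the locus figure: one row per marker with its physical coordinate, loss
#' count among recombinants and conditional genetic distance.
#'
#' @param interval An `interval_estimate`.
#' @param map The `marker_map` used for mapping.
#' @return Data frame with columns `marker`, `phys_kb`, `losses`, `cM`.
#' @export
recombination_profile <- function(interval, map) {
  stopifnot(inherits(interval, "interval_estimate"))
  m <- names(interval$per_marker_losses)
  data.frame(marker = m,
             phys_kb = map$phys_kb[match(m, map$name)],
             losses = unname(interval$per_marker_losses),
             cM = unname(interval$cM_per_marker),
             stringsAsFactors = FALSE)
}
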