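#' Marker map for a focal chromosome
#'
#' A marker map is an ordered table of markers on the chromosome carrying the
#' selected locus. Physical coordinates are signed kilobases relative to the
#' start codon of the focal gene (the A of the ATG sits at the origin;
#' upstream of the gene is negative, following the SCAR-marker convention in
#' which the marker 68 kb upstream is written -68). Genetic positions are in
#' centimorgans and must be non-decreasing in map order; physical positions
#' may tie (two markers can sit on the same assembly coordinate).
#'
#' @param name Character vector of unique marker names.
#' @param phys_kb Numeric vector, signed kb relative to the locus start codon.
#' @param gen_cM Numeric vector, non-decreasing map positions in cM.
#' @param dominant_linked_allele Allele label (integer) linked to the dominant
#'   determinant at each marker; defaults to 1 throughout.
#' @return A `marker_map` (data frame with columns `name`, `phys_kb`,
#'   `gen_cM`, `dominant_linked_allele`).
#' @export
#' @examples
#' marker_map(c("L", "PAR", "R"), phys_kb = c(500, 0, -70), gen_cM = c(0, 0.3, 0.6))
marker_map <- function(name, phys_kb, gen_cM,
                       dominant_linked_allele = 1L) {
  map <- data.frame(
    name = as.character(name),
    phys_kb = as.numeric(phys_kb),
    gen_cM = as.numeric(gen_cM),
    dominant_linked_allele = as.integer(dominant_linked_allele),
    stringsAsFactors = FALSE
  )
  class(map) <- c("marker_map", "data.frame")
  validate_marker_map(map)
  map
}

#' Validate a marker map
#'
#' Checks the `marker_map` invariants: non-empty, unique names, numeric
#' coordinates, non-decreasing `gen_cM`.
#'
#' @param map A `marker_map`.
#' @return The map, invisibly, if valid; otherwise an error.
#' @export
validate_marker_map <- function(map) {
  if (!is.data.frame(map) || nrow(map) == 0L)
    .stop_ctx("marker map must be a non-empty data frame")
  need <- c("name", "phys_kb", "gen_cM", "dominant_linked_allele")
  missing <- setdiff(need, names(map))
  if (length(missing))
    .stop_ctx("marker map lacks column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(map$name))
    .stop_ctx("marker names must be unique")
  if (any(!is.finite(map$gen_cM)) || any(!is.finite(map$phys_kb)))
    .stop_ctx("marker coordinates must be finite")
  if (is.unsorted(map$gen_cM))
    .stop_ctx("gen_cM must be non-decreasing in map order")
  invisible(map)
}

#' Read / write a marker map as TSV
#'
#' Tab-separated dialect with header columns `name`, `phys_kb`, `gen_cM`,
#' `dominant_linked_allele`.
#'
#' @param path File path.
#' @return `read_marker_map` returns a validated `marker_map`.
#' @export
read_marker_map <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  marker_map(tab$name, tab$phys_kb, tab$gen_cM,
             tab$dominant_linked_allele %||% 1L)
}

#' @rdname read_marker_map
#' @param map A `marker_map` to serialize.
#' @export
write_marker_map <- function(map, path) {
  validate_marker_map(map)
  utils::write.table(as.data.frame(map), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.marker_map <- function(x, ...) {
  cat(sprintf("Marker map: %d markers, %.0f kb physical span, %.3g cM\n",
              nrow(x), diff(range(x$phys_kb)),
              max(x$gen_cM) - min(x$gen_cM)))
  print.data.frame(x, ...)
  invisible(x)
}
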