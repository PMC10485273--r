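# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Reverse complement of a DNA string
#'
#' Plain-character convenience used throughout the transposon and
#' sequence-synthesis code. Case-insensitive input; returns upper case.
#' Non-ACGT characters are left unchanged (after complement lookup they map
#' to themselves), which keeps alignment gap characters intact.
#'
#' @param x Single character string of DNA.
#' @return Reverse-complemented string.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  chars <- rev(strsplit(toupper(x), "", fixed = TRUE)[[1L]])
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N", "-" = "-")
  out <- comp[chars]
  out[is.na(out)] <- chars[is.na(out)]
  paste0(out, collapse = "")
}

# split a string into a character vector of single bases
.chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

.stop_ctx <- function(...) stop(..., call. = FALSE)

# recursively sort list names for deterministic JSON serialization
.sort_names <- function(x) {
  if (is.list(x) && !is.null(names(x))) {
    x <- x[order(names(x))]
    lapply(x, .sort_names)
  } else if (is.list(x)) {
    lapply(x, .sort_names)
  } else {
    x
  }
}
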