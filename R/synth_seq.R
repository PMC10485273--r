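# Synthetic sequence fixtures: promoter pairs differing by one TE insertion,
# and codon alignments with a prescribed synonymous divergence.

.BASES <- c("A", "C", "G", "T")

#' Random DNA sequence
#'
#' @param n Length in bases.
#' @param seed Optional seed.
#' @return Character string.
#' @export
random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste0(sample(.BASES, n, replace = TRUE), collapse = "")
}

#' Synthesize a dominant/recessive promoter pair differing by one TE
#'
#' Inserts a class II transposable element into `recessive_seq` upstream of
#' the start codon, producing the architecture of a dominant allele: the
#' element carries terminal inverted repeats (`tir_seq` at its left end and,
#' unless `tir_right` overrides it, the reverse complement of `tir_seq` at
#' its right end) and is flanked by a target-site duplication of the
#' `tsd_len` host bases immediately 5' of the insertion point.
#'
#' Coordinates follow the start-codon convention: the A of the ATG is +1,
#' the base immediately upstream is -1, there is no position 0. `site_bp`
#' is the (negative) position of the first inserted element base.
#'
#' @param recessive_seq Host sequence containing the annotated ATG.
#' @param length_bp Total element length (>= 2 x TIR length, or 0 for no
#'   insertion).
#' @param tir_seq Left terminal repeat sequence.
#' @param tsd_len Target-site duplication length (>= 0).
#' @param site_bp Negative insertion site relative to the start codon.
#' @param atg 1-based index of the A of the ATG within `recessive_seq`.
#' @param tir_right Optional explicit right terminus (element orientation);
#'   default `revcomp(tir_seq)` gives a perfect inverted repeat.
#' @param seed Optional seed for the element's internal sequence.
#' @return List with `dominant_seq`, `recessive_seq`, `te_seq`, `tsd_seq`,
#'   `site_bp`, `length_bp`, `atg_dominant` (index of the A in the dominant
#'   sequence).
#' @export
synth_promoter_pair <- function(recessive_seq, length_bp, tir_seq,
                                tsd_len, site_bp, atg,
                                tir_right = NULL, seed = NULL) {
  stopifnot(is.character(recessive_seq), length(recessive_seq) == 1L)
  recessive_seq <- toupper(recessive_seq)
  if (length_bp == 0L)
    return(list(dominant_seq = recessive_seq, recessive_seq = recessive_seq,
                te_seq = "", tsd_seq = "", site_bp = NA_integer_,
                length_bp = 0L, atg_dominant = atg))
  if (site_bp >= 0) .stop_ctx("site_bp must be negative (upstream of ATG)")
  if (tsd_len < 0) .stop_ctx("tsd_len must be >= 0")
  i <- atg + site_bp  # host index where the first element base will sit
  if (i < tsd_len + 1L)
    .stop_ctx("insertion site lies beyond the start of the sequence")
  if (atg > nchar(recessive_seq))
    .stop_ctx("atg index beyond sequence end")
  tir_seq <- toupper(tir_seq)
  right <- toupper(tir_right %||% revcomp(tir_seq))
  mid_len <- length_bp - nchar(tir_seq) - nchar(right)
  if (mid_len < 0)
    .stop_ctx("length_bp shorter than the two terminal repeats")
  if (!is.null(seed)) set.seed(seed)
  te <- paste0(tir_seq, random_dna(mid_len), right)
  tsd <- if (tsd_len > 0) substr(recessive_seq, i - tsd_len, i - 1L) else ""
  # Identifiability guard: if the host base at the insertion point equals
  # the element's first base and the host base preceding the duplication
  # equals its last base, a strictly inward-shifted (site+1, length-2,
  # TSD+2) decomposition generates the *identical* dominant sequence, and
  # no locator can recover the intended parameters. Such junctions are
  # refused; pick a different host or terminal repeat.
  for (j in seq_len(min(4L, tsd_len + 4L))) {
    fwd <- substr(recessive_seq, i, i + j - 1L)
    back_lo <- i - tsd_len - j
    if (back_lo < 1L) break
    back <- substr(recessive_seq, back_lo, i - tsd_len - 1L)
    if (identical(substr(te, 1L, j), fwd) &&
        identical(substr(te, nchar(te) - j + 1L, nchar(te)), back)) {
      .stop_ctx("ambiguous junction: host bases at the insertion site ",
                "mirror the element's termini, making the (site, length, ",
                "TSD) decomposition non-identifiable; use a different host ",
                "or terminal repeat")
    }
  }
  dominant <- paste0(substr(recessive_seq, 1L, i - 1L), te, tsd,
                     substr(recessive_seq, i, nchar(recessive_seq)))
  list(dominant_seq = dominant, recessive_seq = recessive_seq,
       te_seq = te, tsd_seq = tsd, site_bp = as.integer(site_bp),
       length_bp = as.integer(length_bp),
       atg_dominant = atg + nchar(te) + nchar(tsd))
}

# codon tables derived from the standard genetic code (Biostrings)
.codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)
  list(codons = codons, aa = unname(gc))
}

# number of synonymous single-nucleotide neighbours of a codon, by position;
# mutations creating stop codons count as nonsynonymous, stop codons have no
# sites
.syn_profile <- function() {
  ct <- .codon_table()
  aa <- stats::setNames(ct$aa, ct$codons)
  prof <- lapply(ct$codons, function(cod) {
    if (aa[[cod]] == "*") return(list(s = 0, syn_neighbours = character(0)))
    ch <- .chars(cod)
    syn <- character(0)
    s <- 0
    for (pos in 1:3) {
      for (b in setdiff(.BASES, ch[pos])) {
        alt <- ch; alt[pos] <- b
        alt <- paste0(alt, collapse = "")
        if (aa[[alt]] == aa[[cod]]) {
          s <- s + 1 / 3
          syn <- c(syn, alt)
        }
      }
    }
    list(s = s, syn_neighbours = syn)
  })
  names(prof) <- ct$codons
  prof
}

.SYN_PROFILE <- NULL
.get_syn_profile <- function() {
  if (is.null(.SYN_PROFILE)) {
    p <- .syn_profile()
    utils::assignInMyNamespace(".SYN_PROFILE", p)
  }
  .SYN_PROFILE
}

#' Synthesize an aligned codon pair with a target synonymous divergence
#'
#' Generates a random stop-free coding sequence and derives a partner by
#' planting synonymous single-nucleotide differences so that the
#' Nei-Gojobori estimate of Ks is centred on `target_Ks`: each codon is
#' switched to one of its synonymous neighbours with probability
#' `pS * s_c`, where `s_c` is the codon's synonymous site count and
#' `pS = 3/4 (1 - exp(-4/3 target_Ks))` inverts the Jukes-Cantor correction.
#' At most one difference is planted per codon, which keeps the construction
#' exact for the sub-saturation targets it supports.
#'
#' @param n_codons Number of codons (>= 10).
#' @param target_Ks Target synonymous substitutions per synonymous site
#'   (0 <= target_Ks <= 1; larger values approach saturation and error out).
#' @param seed Optional seed.
#' @return List with `seq_a`, `seq_b` (gap-free aligned CDS strings) and
#'   `target_Ks`.
#' @export
synth_cds_pair <- function(n_codons, target_Ks, seed = NULL) {
  if (n_codons < 10) .stop_ctx("n_codons must be >= 10")
  if (target_Ks < 0) .stop_ctx("target_Ks must be >= 0")
  if (target_Ks > 1)
    .stop_ctx("target_Ks > 1 approaches synonymous saturation; ",
              "the planted-difference construction does not support it")
  if (!is.null(seed)) set.seed(seed)
  prof <- .get_syn_profile()
  usable <- names(prof)[vapply(prof, function(p) p$s > 0, logical(1L))]
  cod_a <- sample(usable, n_codons, replace = TRUE)
  pS <- 3 / 4 * (1 - exp(-4 / 3 * target_Ks))
  cod_b <- vapply(cod_a, function(cod) {
    p <- prof[[cod]]
    if (stats::runif(1L) < pS * p$s && length(p$syn_neighbours))
      sample(p$syn_neighbours, 1L)
    else cod
  }, character(1L))
  list(seq_a = paste0(cod_a, collapse = ""),
       seq_b = paste0(cod_b, collapse = ""),
       target_Ks = target_Ks)
}
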