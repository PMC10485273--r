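# In-study worked-example fixtures: the published marker coordinates, the
# 287-polyhaploid allele-linkage table, and the dominant-allele transposon
# characteristics, transcribed as printed (unit notes below).

.fixture_marker_map <- function() {
  name <- c("289K02", "Lsat10", "445AG", "606_CT", "754_AT", "907_CT",
            "1110_AG", "1123", "1267", "Lsat46", "1405_CT", "comp14899",
            "135_T7", "cds23", "135_SP6", "335_N12", "Pp.PAR", "620_T7",
            "comp6390", "AnnxD3", "398_O14", "501", "EIF3e", "56_L17")
  phys_kb <- c(2594, 1607, 1401, 1239, 1092, 940, 735, 667, 667, 506, 488,
               457, 398, 203, 198, 156, 0, -68, -506, -1112, -1175, -1417,
               -5000, -6000)
  approx <- name %in% c("EIF3e", "56_L17")
  # The source prints no per-marker cM; the genetic coordinate is an
  # augmentation at the study-scale gradient of 0.2 cM/Mb (0.6 cM over the
  # ~3 Mb core region), increasing in map order and anchored at 0.
  gen_cM <- (max(phys_kb) - phys_kb) * 0.2e-3
  map <- marker_map(name, phys_kb, gen_cM, dominant_linked_allele = 1L)
  map$approx_kb <- approx
  map
}

.fixture_linkage <- function() {
  counts <- matrix(c(280, 0, 4, 3,
                     0, 120, 0, 1,
                     0, 1, 127, 0,
                     0, 1, 1, 36),
                   nrow = 4, byrow = TRUE,
                   dimnames = list(paste0("PpAnnD3-", 1:4),
                                   paste0("PpEIF3e-", 1:4)))
  allele_linkage_table(counts, anchor_allele = 1L)
}

.fixture_te <- function() {
  tir_pilosella <- "ATGAAAAACTATCGGACCGGCCCTGACGAAAAACTAATGGACCGGCCCTG"
  tir_taraxacum <- "CAGGGCCGGCCACAGAGCCGGCCC"
  tir_hieracium <- paste0(
    "GAGTAAATTACAAAAATGGTCCCTGTGGTTATATATAGTTTTTGAATCAAGTCCAGTTTTTTCAATTGT",
    "GAGTAAATTACAGAAATGGTCCCTATGGTTATATG^A^TTTTTTGAATCAAGTCCAGATTTTTTAATTGT")
  data.frame(
    genus = c("Hieracium", "Pilosella", "Taraxacum"),
    mechanism = c("Mitotic diplospory", "Apospory", "Meiotic diplospory"),
    ks = c(0.017, 0.014, 0.084),
    ks_sem = c(0.008, 0.004, 0.012),
    age_mya = c(1.06, 0.87, 5.23),
    site_bp = c(-154L, -137L, -110L),
    tir_printed = c(tir_hieracium, tir_pilosella, tir_taraxacum),
    family = c("Mutator", "hAT", "hAT"),
    length_bp = c(1233L, 1282L, 1335L),
    calibration = c(FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
}

#' Load an in-study worked-example fixture
#'
#' Ships the three small published tables the pipeline's worked examples are
#' anchored on:
#' \describe{
#'   \item{`marker_map_t2`}{The 24 SCAR/SSR markers with their signed
#'     physical coordinates (kb from the PAR start codon; the focal gene at
#'     0, 620_T7 at -68). Two distal markers whose coordinates are printed
#'     only approximately carry `approx_kb = TRUE` and are stored at -5000
#'     and -6000 kb. A synthetic `gen_cM` column (see source) completes the
#'     `marker_map` contract.}
#'   \item{`linkage_t4`}{The 4x4 chromatid-count table between the two
#'     anchor genes in 287 polyhaploids (anchor-row total 287, grand total
#'     574), as an [allele_linkage_table()].}
#'   \item{`te_t5`}{Characteristics of the three dominant-allele promoter
#'     transposons: insertion site, printed terminal-repeat alignment
#'     string, superfamily, length, Ks with bootstrap s.e.m., and the
#'     published divergence age used for calibration.}
#' }
#'
#' @param name One of `"marker_map_t2"`, `"linkage_t4"`, `"te_t5"`.
#' @return The typed fixture object.
#' @export
#' @examples
#' load_paper_fixtures("linkage_t4")
load_paper_fixtures <- function(name = c("marker_map_t2", "linkage_t4",
                                         "te_t5")) {
  name <- match.arg(name)
  switch(name,
         marker_map_t2 = .fixture_marker_map(),
         linkage_t4 = .fixture_linkage(),
         te_t5 = .fixture_te())
}

#' Split a printed terminal-repeat alignment string into its two halves
#'
#' The published terminal-repeat strings concatenate the element's left end
#' with the reverse complement of its right end; `^` marks a base missing
#' from one side in the printed alignment. This helper removes the markers
#' and splits the string into the two aligned halves.
#'
#' @param s Printed string.
#' @param split 1-based length of the left half after marker removal; by
#'   default half of the cleaned string.
#' @return List with `lhs` and `rhs_rc` (right half as printed, i.e. already
#'   reverse-complemented).
#' @export
split_tir_string <- function(s, split = NULL) {
  clean <- gsub("^", "", s, fixed = TRUE)
  if (is.null(split)) split <- nchar(clean) %/% 2L
  list(lhs = substr(clean, 1L, split),
       rhs_rc = substr(clean, split + 1L, nchar(clean)))
}
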