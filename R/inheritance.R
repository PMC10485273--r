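# Inference of inheritance mode and transmission bias from diploid
# polyhaploid genotypes at two linked loci.

#' Parsimony phasing of a two-locus diploid genotype into chromatids
#'
#' A diploid polyhaploid observed at two linked loci has two possible
#' phasings of its unordered allele pairs into two chromatids. Alleles are
#' homologue labels, so a chromatid whose labels differ between the loci
#' implies one crossover; the phasing minimizing the implied crossover count
#' is returned, and equal-cost phasings are flagged ambiguous (the first
#' enumeration order is returned for inspection but anchored tables exclude
#' ambiguous plants).
#'
#' @param g1,g2 Length-2 vectors: the unordered allele pairs at locus 1 and
#'   locus 2.
#' @param anchor_allele Allele label anchored by gametophytic selection at
#'   locus 1 (default 1). A genotype lacking it is flagged `no_anchor`.
#' @return A `phased_pair`: list with `chromatid_a`, `chromatid_b` (each
#'   `c(locus1, locus2)`), `implied_crossovers`, `ambiguous`, `no_anchor`.
#' @export
#' @examples
#' phase_chromatids(c(1, 2), c(1, 4))  # (1,1) + (2,4), one crossover
phase_chromatids <- function(g1, g2, anchor_allele = 1L) {
  if (length(g1) != 2L || length(g2) != 2L)
    .stop_ctx("each locus genotype must hold exactly 2 allele labels")
  if (anyNA(g1) || anyNA(g2))
    .stop_ctx("missing allele labels cannot be phased")
  ph1 <- list(c(g1[1L], g2[1L]), c(g1[2L], g2[2L]))
  ph2 <- list(c(g1[1L], g2[2L]), c(g1[2L], g2[1L]))
  cost <- function(ph) sum(ph[[1L]][1L] != ph[[1L]][2L],
                           ph[[2L]][1L] != ph[[2L]][2L])
  c1 <- cost(ph1); c2 <- cost(ph2)
  same <- identical(ph1, ph2) ||
    (identical(ph1[[1L]], ph2[[2L]]) && identical(ph1[[2L]], ph2[[1L]]))
  best <- if (c1 <= c2) ph1 else ph2
  out <- list(chromatid_a = best[[1L]], chromatid_b = best[[2L]],
              implied_crossovers = min(c1, c2),
              ambiguous = (c1 == c2) && !same,
              no_anchor = !anchor_allele %in% g1)
  class(out) <- "phased_pair"
  out
}

#' Allele-linkage (chromatid count) table
#'
#' 4x4 table of chromatid counts between two loci: rows are the allele at
#' locus 1, columns the allele at locus 2. Anchored on the dominant-linked
#' allele: every plant contributes one chromatid carrying the anchor at
#' locus 1, so the anchor row sums to the population size N, the remaining
#' rows (each plant's second chromatid) also sum to N, and the grand total
#' is 2N.
#'
#' @param counts 4x4 numeric matrix of chromatid counts.
#' @param anchor_allele Row index/label of the anchored allele.
#' @return An `allele_linkage_table`.
#' @export
allele_linkage_table <- function(counts, anchor_allele = 1L) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(4L, 4L)) || any(counts < 0))
    .stop_ctx("counts must be a non-negative 4x4 matrix")
  N <- sum(counts[anchor_allele, ])
  if (sum(counts) != 2 * N)
    warning("table invariant violated: grand total != 2 x anchor-row total",
            call. = FALSE)
  structure(list(counts = counts, anchor_allele = as.integer(anchor_allele),
                 N = as.integer(N)),
            class = "allele_linkage_table")
}

#' @export
print.allele_linkage_table <- function(x, ...) {
  cat(sprintf("Allele-linkage table: N = %d plants (anchor allele %d)\n",
              x$N, x$anchor_allele))
  tot <- rowSums(x$counts)
  disp <- cbind(x$counts, `Total (%)` = tot)
  print(disp)
  cat("Second-allele shares (%):",
      paste(sprintf("%s %.0f", rownames(x$counts)[-x$anchor_allele],
                    100 * tot[-x$anchor_allele] / x$N), collapse = ", "),
      "\n")
  invisible(x)
}

#' Build an allele-linkage table from a population genotype table
#'
#' Phases every plant by parsimony ([phase_chromatids()]) and accumulates
#' the two chromatids per unambiguous plant into the 4x4 count table.
#' Ambiguous phasings are excluded (their count is reported), as are plants
#' missing the anchor allele at locus 1 (with a warning) and plants with
#' missing genotypes.
#'
#' @param genotypes Long-format genotype data frame with columns `plant_id`,
#'   `locus`, `allele_a`, `allele_b` (see [as_genotype_table()] /
#'   [read_genotype_table()]).
#' @param locus1,locus2 Names of the two loci (locus 1 carries the anchor).
#' @param anchor_allele Dominant-linked allele label at locus 1.
#' @return An `allele_linkage_table` with attribute `n_ambiguous`.
#' @export
build_allele_linkage_table <- function(genotypes, locus1, locus2,
                                       anchor_allele = 1L) {
  need <- c("plant_id", "locus", "allele_a", "allele_b")
  if (!all(need %in% names(genotypes)))
    .stop_ctx("genotype table needs columns ", paste(need, collapse = ", "))
  counts <- matrix(0L, 4L, 4L,
                   dimnames = list(paste0(locus1, "-", 1:4),
                                   paste0(locus2, "-", 1:4)))
  n_amb <- 0L; n_noanchor <- 0L; n_missing <- 0L
  for (pid in unique(genotypes$plant_id)) {
    rows <- genotypes[genotypes$plant_id == pid, ]
    r1 <- rows[rows$locus == locus1, ]; r2 <- rows[rows$locus == locus2, ]
    if (nrow(r1) != 1L || nrow(r2) != 1L ||
        anyNA(c(r1$allele_a, r1$allele_b, r2$allele_a, r2$allele_b))) {
      n_missing <- n_missing + 1L
      next
    }
    ph <- phase_chromatids(c(r1$allele_a, r1$allele_b),
                           c(r2$allele_a, r2$allele_b), anchor_allele)
    if (ph$no_anchor) { n_noanchor <- n_noanchor + 1L; next }
    if (ph$ambiguous) { n_amb <- n_amb + 1L; next }
    for (ch in list(ph$chromatid_a, ph$chromatid_b))
      counts[ch[1L], ch[2L]] <- counts[ch[1L], ch[2L]] + 1L
  }
  if (n_noanchor > 0L)
    warning(sprintf("%d plant(s) lacked anchor allele %d and were excluded",
                    n_noanchor, anchor_allele), call. = FALSE)
  out <- allele_linkage_table(counts, anchor_allele)
  attr(out, "n_ambiguous") <- n_amb
  attr(out, "n_missing") <- n_missing
  out
}

#' Chi-square test of allele transmission bias
#'
#' Pearson goodness-of-fit (no continuity correction, df = k - 1) of the
#' second-allele totals for a subset of non-anchor alleles against expected
#' proportions. The anchor allele is conditioned to frequency 1 by
#' gametophytic selection and is uninformative, so it is never included.
#'
#' @param table An `allele_linkage_table`.
#' @param alleles Integer subset of allele labels to test (>= 2, excluding
#'   the anchor); default: all three non-anchor alleles.
#' @param expected `"uniform"` or a numeric vector of expected weights.
#' @return List (`test_result`) with `statistic`, `df`, `p_value`,
#'   `observed`, `expected_counts`.
#' @export
transmission_bias_test <- function(table, alleles = NULL,
                                   expected = "uniform") {
  stopifnot(inherits(table, "allele_linkage_table"))
  alleles <- alleles %||% setdiff(1:4, table$anchor_allele)
  if (length(alleles) < 2L) .stop_ctx("need at least 2 alleles to test")
  if (table$anchor_allele %in% alleles)
    .stop_ctx("the anchor allele is conditioned to frequency 1; test only non-anchor alleles")
  obs <- rowSums(table$counts)[alleles]
  p <- if (identical(expected, "uniform")) {
    rep(1 / length(alleles), length(alleles))
  } else {
    if (length(expected) != length(alleles) || any(expected <= 0))
      .stop_ctx("expected weights must be positive, one per tested allele")
    expected / sum(expected)
  }
  ht <- stats::chisq.test(obs, p = p)
  structure(list(statistic = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = unname(ht$p.value), observed = obs,
                 expected_counts = unname(ht$expected)),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("Chi-square GOF: X2 = %.4g, df = %d, p = %.3g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Classify tetrasomic versus disomic inheritance from an anchored table
#'
#' Under disomic inheritance with partition `{(anchor, p), (q, r)}`, the
#' anchor's pairing partner `p` can appear as a plant's second allele only
#' via a crossover between the scored locus and the selected locus, at most
#' at a small leak rate. For each of the three perfect pairings of the four
#' labels, the partner's second-allele total is tested against that leak by
#' an exact one-sided binomial test. All three partitions rejected at
#' `alpha` means tetrasomic exchange; exactly one surviving partition means
#' disomic inheritance with that partition; anything else (or a population
#' below the power guard) is inconclusive.
#'
#' @param table An `allele_linkage_table`.
#' @param alpha Rejection level per partition (default 0.01).
#' @param leak_rate Crossover leak rate under the disomic null (default
#'   0.02, i.e. 2 cM between the scored and selected loci; pass
#'   `d_cM / 100` when the map distance is known).
#' @param min_n Power guard: populations smaller than this are inconclusive.
#' @return List (`inheritance_call`) with `mode` (`"tetrasomic"`,
#'   `"disomic"`, `"inconclusive"`), `partition` (for disomic), and the
#'   per-partition binomial p-values.
#' @export
classify_inheritance_mode <- function(table, alpha = 0.01, leak_rate = 0.02,
                                      min_n = 30L) {
  stopifnot(inherits(table, "allele_linkage_table"))
  anchor <- table$anchor_allele
  N <- table$N
  if (N < min_n)
    return(structure(list(mode = "inconclusive", partition = NULL,
                          p_values = NULL, reason = "population too small"),
                     class = "inheritance_call"))
  partners <- setdiff(1:4, anchor)
  tot <- rowSums(table$counts)
  pvals <- vapply(partners, function(p) {
    x <- tot[p]  # times the partner shows up as the second allele
    stats::binom.test(x, N, p = leak_rate, alternative = "greater")$p.value
  }, numeric(1L))
  names(pvals) <- paste0("partner_", partners)
  rejected <- pvals < alpha
  if (all(rejected)) {
    mode <- "tetrasomic"; part <- NULL
  } else if (sum(!rejected) == 1L) {
    p <- partners[!rejected]
    mode <- "disomic"
    part <- list(sort(c(anchor, p)), setdiff(1:4, c(anchor, p)))
  } else {
    mode <- "inconclusive"; part <- NULL
  }
  structure(list(mode = mode, partition = part, p_values = pvals,
                 alpha = alpha, leak_rate = leak_rate),
            class = "inheritance_call")
}

#' @export
print.inheritance_call <- function(x, ...) {
  cat("Inheritance mode:", x$mode)
  if (!is.null(x$partition))
    cat(" with partition {(", paste(x$partition[[1L]], collapse = ","),
        "), (", paste(x$partition[[2L]], collapse = ","), ")}", sep = "")
  cat("\n")
  if (!is.null(x$p_values)) print(signif(x$p_values, 3))
  invisible(x)
}

#' Crossover summary of an anchored allele-linkage table
#'
#' Off-diagonal chromatids carry different homologue labels at the two loci
#' and are therefore crossover products. An unordered allele pair `{i, j}`
#' counts as observed in exchange when either off-diagonal cell `(i, j)` or
#' `(j, i)` is non-zero.
#'
#' @param table An `allele_linkage_table`.
#' @return List with `crossover_chromatids`, `observed_pairs`,
#'   `missing_pairs` (each pair a sorted integer vector).
#' @export
crossover_summary <- function(table) {
  stopifnot(inherits(table, "allele_linkage_table"))
  cnt <- table$counts
  xo <- sum(cnt) - sum(diag(cnt))
  pairs <- utils::combn(4L, 2L, simplify = FALSE)
  seen <- vapply(pairs, function(pr)
    cnt[pr[1L], pr[2L]] + cnt[pr[2L], pr[1L]] > 0, logical(1L))
  list(crossover_chromatids = xo,
       observed_pairs = pairs[seen],
       missing_pairs = pairs[!seen])
}

#' Deterministic population reconstruction from a linkage table
#'
#' Expands an anchored chromatid-count table into a synthetic long-format
#' genotype table whose parsimony re-phasing reproduces the input counts
#' exactly. Chromatid pairing within plants is chosen so that no plant's
#' phasing is ambiguous or mis-phased: off-diagonal (crossover) second
#' chromatids are paired with non-recombinant anchor chromatids, and
#' recombinant anchor chromatids `(anchor, j)` are paired with diagonal
#' second chromatids `(j, j)`.
#'
#' @param table An `allele_linkage_table`.
#' @param locus1,locus2 Locus names for the output table.
#' @return Long-format genotype data frame (one plant per chromatid pair).
#' @export
population_from_linkage_table <- function(table, locus1 = "locus1",
                                          locus2 = "locus2") {
  stopifnot(inherits(table, "allele_linkage_table"))
  cnt <- table$counts
  anchor <- table$anchor_allele
  expand <- function(m, rows) {
    out <- list()
    for (i in rows) for (j in 1:4) {
      k <- m[i, j]
      if (k > 0) out <- c(out, rep(list(c(i, j)), k))
    }
    out
  }
  anchors <- expand(cnt, anchor)
  others <- expand(cnt, setdiff(1:4, anchor))
  if (length(anchors) != length(others))
    .stop_ctx("table is not anchored: row totals do not balance")
  # order anchor chromatids: non-recombinant (anchor, anchor) first
  a_rec <- vapply(anchors, function(ch) ch[1L] != ch[2L], logical(1L))
  # order second chromatids: off-diagonal (crossover) first, to meet the
  # plain (anchor, anchor) chromatids; diagonal ones later
  o_rec <- vapply(others, function(ch) ch[1L] != ch[2L], logical(1L))
  anchors <- c(anchors[!a_rec], anchors[a_rec])
  # recombinant anchor (anchor, j) must meet a (j, j) diagonal chromatid
  diag_pool <- others[!o_rec]
  xo_pool <- others[o_rec]
  tail_anchors <- anchors[seq(length(anchors) - sum(a_rec) + 1L,
                              length.out = sum(a_rec))]
  paired_tail <- lapply(tail_anchors, function(ch) {
    j <- ch[2L]
    hit <- which(vapply(diag_pool, function(o) o[1L] == j, logical(1L)))[1L]
    if (is.na(hit))
      .stop_ctx("cannot pair recombinant anchor chromatid unambiguously")
    out <- diag_pool[[hit]]
    diag_pool[[hit]] <<- NULL
    out
  })
  others_ordered <- c(xo_pool, diag_pool, paired_tail)
  n_head <- length(anchors) - length(tail_anchors)
  if (length(xo_pool) + length(diag_pool) != n_head)
    .stop_ctx("internal pairing mismatch")
  seconds <- others_ordered
  plants <- lapply(seq_along(anchors), function(i)
    list(a = anchors[[i]], b = seconds[[i]]))
  rows <- lapply(seq_along(plants), function(i) {
    p <- plants[[i]]
    g1 <- sort(c(p$a[1L], p$b[1L])); g2 <- sort(c(p$a[2L], p$b[2L]))
    data.frame(plant_id = rep(sprintf("plant_%04d", i), 2L),
               locus = c(locus1, locus2),
               allele_a = c(g1[1L], g2[1L]),
               allele_b = c(g1[2L], g2[2L]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
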