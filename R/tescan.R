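# Annotation of dominant promoter alleles: locate the transposon insertion
# against the recessive allele, characterize terminal inverted repeats,
# extract the target-site duplication, classify the superfamily, and call
# dominance by the conserved-window rule.
#
# Coordinate convention: the A of the start codon is +1, the base
# immediately upstream is -1, there is no position 0. Promoter insertions
# therefore have negative sites; the reported site is the position of the
# first inserted element base.

# signed position of dominant-sequence index `idx` relative to the ATG at
# dominant-sequence index `atg`
.signed_pos <- function(idx, atg) {
  d <- idx - atg
  as.integer(ifelse(d >= 0, d + 1L, d))
}

# ungapped terminal-inverted-repeat score of a putative element: anchored
# best-prefix score of the first w bases against the reverse complement of
# the last w bases (match +1 / mismatch -1). Taking the running maximum
# instead of a fixed-width sum avoids penalizing elements whose repeats are
# shorter than the window, so in-register boundaries score near the repeat
# length while out-of-register ones score near zero.
.tir_score <- function(te, w = 40L) {
  n <- nchar(te)
  w <- min(w, n %/% 2L)
  if (w < 4L) return(-Inf)
  a <- .chars(substr(te, 1L, w))
  b <- .chars(substr(revcomp(te), 1L, w))
  max(cumsum(ifelse(a == b, 1L, -1L)))
}

# exact-path insertion finder: dominant differs from recessive by one pure
# insertion (no substitutions). Returns all consistent block placements.
.exact_placements <- function(dom, rec) {
  nd <- nchar(dom); nr <- nchar(rec)
  if (nd <= nr) return(NULL)
  dch <- .chars(dom); rch <- .chars(rec)
  ins <- nd - nr
  pre <- 0L
  while (pre < nr && dch[pre + 1L] == rch[pre + 1L]) pre <- pre + 1L
  suf <- 0L
  while (suf < nr && dch[nd - suf] == rch[nr - suf]) suf <- suf + 1L
  if (pre + suf < nr) return(NULL)  # substitutions present: not a pure insertion
  # block start b valid for b in [nr - suf + 1, pre + 1]
  starts <- seq.int(max(1L, nr - suf + 1L), pre + 1L)
  lapply(starts, function(b) list(start = b, block = substr(dom, b, b + ins - 1L)))
}

# alignment-path insertion finder for inputs with substitutions: global
# alignment, insertion blocks = gap runs in the recessive (subject); block
# start positions are reported in pattern (= dominant) coordinates, which
# for a single insertion equal recessive coordinates upstream of the block
.aligned_placements <- function(dom, rec, min_len) {
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(dom), Biostrings::DNAString(rec),
    type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -2, baseOnly = TRUE),
    gapOpening = 10, gapExtension = 0.2)
  pat <- .chars(as.character(Biostrings::alignedPattern(al)))
  sub <- .chars(as.character(Biostrings::alignedSubject(al)))
  ppos <- cumsum(pat != "-")
  in_gap <- sub == "-"
  if (!any(in_gap)) return(list())
  r <- rle(in_gap)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  blocks <- list()
  for (k in which(r$values)) {
    pstart <- ppos[starts[k]]
    plen <- ends[k] - starts[k] + 1L
    blocks <- c(blocks, list(list(start = pstart,
                                  block = substr(dom, pstart, pstart + plen - 1L))))
  }
  blocks[order(-vapply(blocks, function(b) nchar(b$block), numeric(1L)))]
}

#' Locate a promoter transposon insertion against the recessive allele
#'
#' Identifies the largest contiguous dominant-only block by comparing the
#' dominant and recessive promoter sequences (an exact prefix/suffix scan
#' when the pair differs by a pure insertion; a global alignment otherwise).
#' When a target-site duplication is present, the block placement and the
#' TE/TSD split are ambiguous by up to the duplication length; candidates
#' are resolved by scoring each putative element boundary for
#' terminal-inverted-repeat quality, which makes recovery of the generating
#' (site, length) exact for TIR elements.
#'
#' @param dominant_seq,recessive_seq Promoter (+ CDS) sequences.
#' @param atg 1-based index of the A of the ATG in `recessive_seq`.
#' @param min_len Minimum insertion length to annotate (default 50 bp);
#'   shorter or absent insertions return a length-0 annotation.
#' @param max_tsd Maximum target-site-duplication length considered (12 bp).
#' @return A `te_annotation`: list with `site_bp`, `length_bp`, `te_seq`,
#'   `tsd_seq`, `tsd_len`, `flank_left`, `flank_right` (15 bp host flanks),
#'   plus empty TIR fields to be filled by [find_tirs()] /
#'   [classify_te()] (see [annotate_te()]).
#' @export
locate_insertion <- function(dominant_seq, recessive_seq, atg,
                             min_len = 50L, max_tsd = 12L) {
  dom <- toupper(dominant_seq); rec <- toupper(recessive_seq)
  if (atg < 1L || atg > nchar(rec)) .stop_ctx("atg index outside recessive_seq")
  empty <- structure(list(site_bp = NA_integer_, length_bp = 0L,
                          te_seq = "", tsd_seq = "", tsd_len = 0L,
                          flank_left = "", flank_right = "",
                          tir_left = "", tir_right = "",
                          tir_mismatch_positions = integer(0),
                          tir_gap_count = 0L,
                          superfamily = "unclassified",
                          in_conserved_window = FALSE),
                     class = "te_annotation")
  if (identical(dom, rec)) return(empty)

  placements <- .exact_placements(dom, rec)
  if (is.null(placements)) {
    blocks <- .aligned_placements(dom, rec, min_len)
    if (!length(blocks)) return(empty)
    big <- vapply(blocks, function(b) nchar(b$block), numeric(1L))
    if (big[1L] < min_len) return(empty)
    if (length(blocks) > 1L && big[2L] >= min_len)
      .stop_ctx("multiple comparable insertion blocks: ",
                paste(sprintf("%d bp at pattern position %d",
                              big[big >= min_len],
                              vapply(blocks[big >= min_len],
                                     function(b) b$start, numeric(1L))),
                      collapse = "; "))
    placements <- blocks[1L]
  }
  ins_len <- nchar(placements[[1L]]$block)
  if (ins_len < min_len) return(empty)

  # enumerate (placement, tsd length) candidates: the block's trailing k
  # bases must equal the k host bases immediately upstream of the block
  cands <- list()
  for (pl in placements) {
    b <- pl$start; block <- pl$block
    for (k in 0:min(max_tsd, ins_len - 1L)) {
      if (k > 0L) {
        if (b - k < 1L) break
        up <- substr(dom, b - k, b - 1L)
        tail <- substr(block, ins_len - k + 1L, ins_len)
        if (!identical(up, tail)) next
      }
      te <- substr(block, 1L, ins_len - k)
      cands <- c(cands, list(list(start = b, te = te, k = k)))
    }
  }
  # Boundary candidates shifted through the duplication keep the terminal
  # repeats in register and score like the true boundary, while off-register
  # candidates score near zero: filter to near-best repeat scores, then take
  # the maximal duplication (the canonical reading; see the vignette for the
  # residual non-identifiable junction class, which synth_promoter_pair
  # refuses to generate).
  score <- vapply(cands, function(cd) .tir_score(cd$te), numeric(1L))
  ks <- vapply(cands, function(cd) cd$k, integer(1L))
  bs <- vapply(cands, function(cd) cd$start, integer(1L))
  keep <- score >= max(score) - 4
  ord <- order(-ks[keep], -score[keep], -bs[keep])
  best <- cands[keep][[ord[1L]]]

  te <- best$te
  te_len <- nchar(te)
  b <- best$start
  k <- best$k
  # host flanks around the element in the dominant sequence
  fl_l <- substr(dom, max(1L, b - 15L), b - 1L)
  fl_r <- substr(dom, b + te_len, min(nchar(dom), b + te_len + 14L))
  ann <- empty
  # the block start's host (recessive) coordinate equals its dominant
  # coordinate because the upstream prefix is shared, so the insertion site
  # in the start-codon convention is measured against the recessive ATG
  ann$site_bp <- .signed_pos(b, atg)
  ann$length_bp <- te_len
  ann$te_seq <- te
  ann$tsd_seq <- if (k > 0L) substr(dom, b - k, b - 1L) else ""
  ann$tsd_len <- k
  ann$flank_left <- fl_l
  ann$flank_right <- fl_r
  ann
}

#' @export
print.te_annotation <- function(x, ...) {
  if (x$length_bp == 0L) {
    cat("TE annotation: no insertion\n")
    return(invisible(x))
  }
  cat(sprintf("TE annotation: %d bp element at site %+d (TSD %s, %d bp) -> %s\n",
              x$length_bp, x$site_bp,
              if (nzchar(x$tsd_seq)) x$tsd_seq else "none", x$tsd_len,
              x$superfamily))
  if (nzchar(x$tir_left))
    cat(sprintf("  TIR %d/%d bp, %d mismatch(es), %d gap(s)\n",
                nchar(x$tir_left), nchar(x$tir_right),
                length(x$tir_mismatch_positions), x$tir_gap_count))
  cat(sprintf("  in conserved promoter window: %s\n", x$in_conserved_window))
  invisible(x)
}

#' Align a terminal-repeat pair (left end vs reverse-complemented right end)
#'
#' Global alignment of the element's left terminus against the reverse
#' complement of its right terminus, reporting mismatch columns and gap
#' count, in the style of published terminal-repeat alignments where
#' mis-aligned bases are highlighted and `^` marks a missing base.
#' Ungapped when the halves have equal length and `allow_gaps = FALSE`;
#' otherwise a small Needleman-Wunsch (match +1, mismatch -1, gap -2).
#'
#' @param lhs Left terminal repeat.
#' @param rhs_rc Reverse complement of the right terminal repeat (i.e. both
#'   halves in the same reading orientation).
#' @param allow_gaps Permit indels in the alignment.
#' @return List with `mismatch_positions` (alignment columns), `gap_count`,
#'   `score`, `aligned_lhs`, `aligned_rhs`.
#' @export
#' @examples
#' align_tir_pair("ACGTACGT", "ACGAACGT")
align_tir_pair <- function(lhs, rhs_rc, allow_gaps = TRUE) {
  a <- .chars(toupper(lhs)); b <- .chars(toupper(rhs_rc))
  if (!allow_gaps && length(a) == length(b)) {
    mism <- which(a != b)
    return(list(mismatch_positions = mism, gap_count = 0L,
                score = sum(a == b) - length(mism),
                aligned_lhs = lhs, aligned_rhs = rhs_rc))
  }
  nw <- .nw_align(a, b, match = 1, mismatch = -1, gap = -2)
  cols_a <- nw$aligned_a; cols_b <- nw$aligned_b
  mism <- which(cols_a != cols_b & cols_a != "-" & cols_b != "-")
  gaps <- sum(cols_a == "-") + sum(cols_b == "-")
  list(mismatch_positions = mism, gap_count = gaps, score = nw$score,
       aligned_lhs = paste0(cols_a, collapse = ""),
       aligned_rhs = paste0(cols_b, collapse = ""))
}

# plain global Needleman-Wunsch on character vectors; small inputs only
.nw_align <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  n <- length(a); m <- length(b)
  S <- matrix(0, n + 1L, m + 1L)
  S[, 1L] <- gap * (0:n)
  S[1L, ] <- gap * (0:m)
  for (i in seq_len(n)) {
    sub <- ifelse(a[i] == b, match, mismatch)
    for (j in seq_len(m)) {
      S[i + 1L, j + 1L] <- max(S[i, j] + sub[j],
                               S[i, j + 1L] + gap,
                               S[i + 1L, j] + gap)
    }
  }
  # traceback
  i <- n; j <- m
  ca <- character(0); cb <- character(0)
  while (i > 0L || j > 0L) {
    if (i > 0L && j > 0L &&
        S[i + 1L, j + 1L] == S[i, j] + ifelse(a[i] == b[j], match, mismatch)) {
      ca <- c(a[i], ca); cb <- c(b[j], cb); i <- i - 1L; j <- j - 1L
    } else if (i > 0L && S[i + 1L, j + 1L] == S[i, j + 1L] + gap) {
      ca <- c(a[i], ca); cb <- c("-", cb); i <- i - 1L
    } else {
      ca <- c("-", ca); cb <- c(b[j], cb); j <- j - 1L
    }
  }
  list(aligned_a = ca, aligned_b = cb, score = S[n + 1L, m + 1L])
}

#' Find the terminal inverted repeats of a transposable element
#'
#' Compares the element's 5' end against the reverse complement of its 3'
#' end, anchored at the termini (terminal repeats are terminal: column 1 is
#' the outermost base of each end). The repeat extent is chosen to maximize
#' the anchored alignment score (match +1, mismatch -1, gap -2; gapped by
#' default because published repeats can differ by a missing base), subject
#' to a minimum length and score; elements with no scoring repeat return
#' empty TIRs.
#'
#' @param te_seq Element sequence.
#' @param max_tir_len Longest repeat considered (default 80 bp).
#' @param allow_gaps Permit indels between the two repeats.
#' @param min_tir_len Minimum repeat length (default 8 bp).
#' @param min_score Minimum anchored alignment score (default 6).
#' @return List with `tir_left`, `tir_right` (element orientation),
#'   `mismatch_positions` (alignment columns of the left-vs-revcomp(right)
#'   comparison), `gap_count`, `score`.
#' @export
find_tirs <- function(te_seq, max_tir_len = 80L, allow_gaps = TRUE,
                      min_tir_len = 8L, min_score = 6) {
  te <- toupper(te_seq)
  n <- nchar(te)
  if (n < 2L * min_tir_len)
    .stop_ctx("element shorter than twice the minimum repeat length")
  W <- min(max_tir_len, n %/% 2L)
  a <- .chars(substr(te, 1L, W))
  b <- .chars(substr(revcomp(te), 1L, W))
  empty <- list(tir_left = "", tir_right = "",
                mismatch_positions = integer(0), gap_count = 0L,
                score = -Inf)

  if (!allow_gaps) {
    sc <- cumsum(ifelse(a == b, 1L, -1L))
    ok <- seq_len(W) >= min_tir_len
    if (!any(ok & sc >= min_score)) return(empty)
    k <- which.max(replace(sc, !ok, -Inf))
    al <- align_tir_pair(paste0(a[1:k], collapse = ""),
                         paste0(b[1:k], collapse = ""), allow_gaps = FALSE)
    return(list(tir_left = substr(te, 1L, k),
                tir_right = substr(te, n - k + 1L, n),
                mismatch_positions = al$mismatch_positions,
                gap_count = 0L, score = al$score))
  }

  # anchored gapped extension: global-score DP from (0,0); best (i, j)
  # endpoint over i, j >= min_tir_len maximizes the anchored score
  match <- 1; mismatch <- -1; gap <- -2
  S <- matrix(0, W + 1L, W + 1L)
  S[, 1L] <- gap * (0:W)
  S[1L, ] <- gap * (0:W)
  for (i in seq_len(W)) {
    sub <- ifelse(a[i] == b, match, mismatch)
    for (j in seq_len(W)) {
      S[i + 1L, j + 1L] <- max(S[i, j] + sub[j],
                               S[i, j + 1L] + gap,
                               S[i + 1L, j] + gap)
    }
  }
  sub_grid <- S[(min_tir_len + 1L):(W + 1L), (min_tir_len + 1L):(W + 1L),
                drop = FALSE]
  best <- max(sub_grid)
  if (best < min_score) return(empty)
  hits <- which(sub_grid == best, arr.ind = TRUE)
  # deterministic, left/right-symmetric tie-break: smallest i + j, then
  # smallest |i - j|, then smallest i
  ii <- hits[, 1L] + min_tir_len - 1L
  jj <- hits[, 2L] + min_tir_len - 1L
  ord <- order(ii + jj, abs(ii - jj), ii)
  i_star <- ii[ord[1L]]; j_star <- jj[ord[1L]]
  al <- align_tir_pair(paste0(a[seq_len(i_star)], collapse = ""),
                       paste0(b[seq_len(j_star)], collapse = ""),
                       allow_gaps = TRUE)
  list(tir_left = substr(te, 1L, i_star),
       tir_right = substr(te, n - j_star + 1L, n),
       mismatch_positions = al$mismatch_positions,
       gap_count = al$gap_count, score = best)
}

#' Classify a transposon superfamily from its target-site duplication
#'
#' The duplication is the longest identical direct repeat (up to 12 bp)
#' formed by the host sequence immediately flanking the element: a suffix of
#' the left flank equal to a prefix of the right flank. Superfamily follows
#' the duplication-length diagnostic: 8 bp -> hAT; 9-11 bp -> Mutator;
#' the 2 bp motif TA -> Tc1/Mariner-like (reported as `other`); anything
#' else (including no duplication) -> unclassified.
#'
#' @param flank_left Host sequence immediately 5' of the element (>= 15 bp
#'   recommended).
#' @param flank_right Host sequence immediately 3' of the element.
#' @param max_tsd Longest duplication considered (12 bp).
#' @return List with `tsd_seq`, `tsd_len`, `superfamily`.
#' @export
classify_te <- function(flank_left, flank_right, max_tsd = 12L) {
  l <- toupper(flank_left); r <- toupper(flank_right)
  kmax <- min(max_tsd, nchar(l), nchar(r))
  tsd <- ""
  for (k in seq_len(kmax)) {
    if (identical(substr(l, nchar(l) - k + 1L, nchar(l)), substr(r, 1L, k)))
      tsd <- substr(r, 1L, k)
  }
  len <- nchar(tsd)
  fam <- if (len == 8L) "hAT"
         else if (len >= 9L && len <= 11L) "Mutator"
         else if (len == 2L && tsd == "TA") "other"
         else "unclassified"
  list(tsd_seq = tsd, tsd_len = len, superfamily = fam)
}

#' Dominance call by the conserved-window rule
#'
#' A promoter allele is called dominant when it carries a transposon whose
#' insertion site falls inside the conserved window immediately upstream of
#' the start codon (default 200 bp): `length_bp > 0` and
#' `site_bp` in `[-window_bp, -1]`. Elements outside the window are flagged.
#'
#' @param annotation A `te_annotation`.
#' @param window_bp Window size upstream of the ATG (default 200).
#' @return Logical; attribute `note` explains a FALSE with an element
#'   present.
#' @export
is_dominant_allele <- function(annotation, window_bp = 200L) {
  stopifnot(inherits(annotation, "te_annotation"))
  if (annotation$length_bp <= 0L) return(FALSE)
  ok <- !is.na(annotation$site_bp) &&
    annotation$site_bp >= -window_bp && annotation$site_bp <= -1L
  if (!ok) attr(ok, "note") <- "TE outside conserved window"
  ok
}

#' Full annotation of a dominant/recessive promoter pair
#'
#' Convenience wrapper running [locate_insertion()], [find_tirs()],
#' [classify_te()] and [is_dominant_allele()] and returning the completed
#' `te_annotation` (the row shape of the published allele-characteristics
#' table).
#'
#' @inheritParams locate_insertion
#' @param window_bp Conserved-window size for the dominance call.
#' @param ... Passed to [find_tirs()].
#' @return A `te_annotation` with all fields populated.
#' @export
annotate_te <- function(dominant_seq, recessive_seq, atg, min_len = 50L,
                        window_bp = 200L, ...) {
  ann <- locate_insertion(dominant_seq, recessive_seq, atg,
                          min_len = min_len)
  if (ann$length_bp > 0L) {
    tir <- find_tirs(ann$te_seq, ...)
    ann$tir_left <- tir$tir_left
    ann$tir_right <- tir$tir_right
    ann$tir_mismatch_positions <- tir$mismatch_positions
    ann$tir_gap_count <- tir$gap_count
    cls <- classify_te(ann$flank_left, ann$flank_right)
    ann$tsd_seq <- cls$tsd_seq
    ann$tsd_len <- cls$tsd_len
    ann$superfamily <- cls$superfamily
    ann$in_conserved_window <- isTRUE(is_dominant_allele(ann, window_bp))
  }
  ann
}
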