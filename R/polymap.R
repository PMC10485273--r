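# Recombination mapping of a gametophytically selected locus from
# polyhaploid genotypes.

# does the plant carry the dominant-linked allele at a marker?
# (presence/absence scoring, matching allele-specific SCAR markers)
.carries <- function(genotypes, plant, marker, allele) {
  rows <- genotypes[genotypes$plant_id == plant & genotypes$locus == marker, ]
  if (nrow(rows) != 1L) return(NA)
  if (anyNA(c(rows$allele_a, rows$allele_b))) return(NA)
  allele %in% c(rows$allele_a, rows$allele_b)
}

#' Call recombinants between two flanking markers
#'
#' Every polyhaploid carries the dominant determinant at the selected locus,
#' so its dominant-linked flanking alleles are discordant exactly when a
#' crossover occurred between the flanks. A plant is recombinant iff it
#' carries the dominant-linked allele at exactly one flank. Plants with a
#' missing genotype at either flank are excluded and reported.
#'
#' @param genotypes Long-format genotype table (`plant_id`, `locus`,
#'   `allele_a`, `allele_b`).
#' @param map A `marker_map` containing both flanks (supplies each flank's
#'   dominant-linked allele label).
#' @param flank_left,flank_right Names of the flanking markers.
#' @return Data frame of calls: `plant_id`, `left_has`, `right_has`,
#'   `is_recombinant`; excluded plants are listed in attribute `excluded`.
#' @export
call_recombinants <- function(genotypes, map, flank_left, flank_right) {
  validate_marker_map(map)
  for (fl in c(flank_left, flank_right))
    if (!fl %in% map$name) .stop_ctx("flank marker '", fl, "' not in map")
  al <- map$dominant_linked_allele[match(flank_left, map$name)]
  ar <- map$dominant_linked_allele[match(flank_right, map$name)]
  plants <- unique(genotypes$plant_id)
  left <- vapply(plants, .carries, NA, genotypes = genotypes,
                 marker = flank_left, allele = al)
  right <- vapply(plants, .carries, NA, genotypes = genotypes,
                  marker = flank_right, allele = ar)
  keep <- !is.na(left) & !is.na(right)
  calls <- data.frame(plant_id = plants[keep],
                      left_has = left[keep], right_has = right[keep],
                      is_recombinant = xor(left[keep], right[keep]),
                      stringsAsFactors = FALSE)
  attr(calls, "excluded") <- plants[!keep]
  calls
}

#' Delimit the selected-locus interval from recombinant marker losses
#'
#' For each marker between the flanks, counts the recombinants lacking that
#' marker's dominant-linked allele ("losses"). Because every recombinant
#' retains the dominant determinant itself, markers inside the locus show
#' zero losses; the locus interval is the maximal zero-loss run of internal
#' markers, bounded by the innermost loss-bearing marker on each side (or by
#' the flank when no loss occurs on that side, flagged unbounded). With no
#' recombinants at all the interval degenerates to the full flank-to-flank
#' region and is flagged unresolved.
#'
#' Conditional genetic distances are reported per marker as `100 * k / N`
#' (see [conditional_map_distance()]).
#'
#' @param calls Output of [call_recombinants()].
#' @param genotypes Long-format genotype table.
#' @param map A `marker_map`; markers are taken in map order between the
#'   flanks (inclusive).
#' @param flank_left,flank_right Flanking marker names.
#' @param N Population size for conditional distances; defaults to the
#'   number of plants in `calls`.
#' @return An `interval_estimate`: list with `left_marker`, `right_marker`,
#'   `span_kb`, `per_marker_losses`, `cM_per_marker`, `N`,
#'   `n_recombinants`, `resolved`, `bounded`.
#' @export
map_locus_interval <- function(calls, genotypes, map, flank_left,
                               flank_right, N = NULL) {
  validate_marker_map(map)
  idx <- match(c(flank_left, flank_right), map$name)
  if (anyNA(idx)) .stop_ctx("flank markers must be on the map")
  idx <- sort(idx)
  markers <- map$name[idx[1L]:idx[2L]]
  alleles <- map$dominant_linked_allele[idx[1L]:idx[2L]]
  N <- N %||% nrow(calls)
  recs <- calls$plant_id[calls$is_recombinant]
  losses <- vapply(seq_along(markers), function(j) {
    has <- vapply(recs, .carries, NA, genotypes = genotypes,
                  marker = markers[j], allele = alleles[j])
    sum(!has, na.rm = TRUE)
  }, integer(1L))
  names(losses) <- markers
  cMs <- 100 * losses / N
  phys <- map$phys_kb[match(markers, map$name)]

  if (length(recs) == 0L) {
    out <- list(left_marker = markers[1L],
                right_marker = markers[length(markers)],
                span_kb = abs(phys[1L] - phys[length(phys)]),
                per_marker_losses = losses, cM_per_marker = cMs,
                N = N, n_recombinants = 0L,
                resolved = FALSE, bounded = c(FALSE, FALSE))
    class(out) <- "interval_estimate"
    return(out)
  }

  zero <- losses == 0L
  # maximal zero-loss run (ties broken towards the first)
  r <- rle(zero)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  zi <- which(r$values)
  if (!length(zi)) .stop_ctx(
    "no zero-loss marker between the flanks; the selected locus does not lie in this interval")
  best <- zi[which.max(r$lengths[zi])]
  run <- c(starts[best], ends[best])
  lb <- if (run[1L] > 1L) run[1L] - 1L else 1L
  rb <- if (run[2L] < length(markers)) run[2L] + 1L else length(markers)
  out <- list(left_marker = markers[lb], right_marker = markers[rb],
              span_kb = abs(phys[lb] - phys[rb]),
              per_marker_losses = losses, cM_per_marker = cMs, N = N,
              n_recombinants = length(recs), resolved = TRUE,
              bounded = c(run[1L] > 1L, run[2L] < length(markers)))
  class(out) <- "interval_estimate"
  out
}

#' @export
print.interval_estimate <- function(x, ...) {
  cat(sprintf(
    "Locus interval: [%s, %s], %.0f kb (%d recombinants of N = %d)\n",
    x$left_marker, x$right_marker, x$span_kb, x$n_recombinants, x$N))
  if (!x$resolved) cat("  unresolved: no recombinants; full flank-to-flank region\n")
  if (!all(x$bounded))
    cat("  unbounded on the", paste(c("left", "right")[!x$bounded],
                                    collapse = " and "), "side\n")
  invisible(x)
}

#' Conditional map distance from a single recombinant class
#'
#' Polyhaploid populations condition on inheritance of the dominant
#' determinant, so only one recombinant class is observable and the genetic
#' distance is the raw class fraction, `100 * k / N` cM, with no
#' mapping-function correction (negligible at the sub-centimorgan distances
#' this design resolves).
#'
#' @param losses_k Recombinant count for the class.
#' @param N Population size (plants carrying the dominant determinant).
#' @return Distance in cM.
#' @export
#' @examples
#' conditional_map_distance(13, 2169)  # ~0.6 cM
conditional_map_distance <- function(losses_k, N) {
  if (N <= 0) .stop_ctx("N must be positive")
  if (losses_k < 0 || losses_k > N) .stop_ctx("need 0 <= k <= N")
  100 * losses_k / N
}

#' Deletion evidence record
#'
#' @param mutant_id Identifier of the deletion mutant.
#' @param breakpoint_kb Breakpoint position, signed kb.
#' @param phenotype `"lost"` (locus function lost) or `"retained"`.
#' @param deleted_side Which side of the breakpoint is deleted: `"lower"`
#'   or `"upper"` in phys_kb order.
#' @return A `deletion_evidence` data-frame row.
#' @export
deletion_evidence <- function(mutant_id, breakpoint_kb,
                              phenotype = c("lost", "retained"),
                              deleted_side = c("lower", "upper")) {
  phenotype <- match.arg(phenotype)
  deleted_side <- match.arg(deleted_side)
  structure(data.frame(mutant_id = mutant_id,
                       breakpoint_kb = as.numeric(breakpoint_kb),
                       phenotype = phenotype, deleted_side = deleted_side,
                       stringsAsFactors = FALSE),
            class = c("deletion_evidence", "data.frame"))
}

#' Refine a locus interval with deletion-mutant breakpoints
#'
#' A function-lost mutant whose breakpoint falls inside the interval places
#' the locus on its deleted side: the bound on the retained side moves to
#' the breakpoint. A function-retained mutant places the locus on the
#' retained side and moves the opposite bound. Breakpoints outside the
#' current interval are uninformative and logged. Contradictory evidence
#' (an emptied interval) raises a diagnostic listing the conflict.
#'
#' @param interval An `interval_estimate`.
#' @param evidence One or more [deletion_evidence()] rows (rbind-able).
#' @param map A `marker_map` locating the interval bounds.
#' @return The refined `interval_estimate`; refined bounds are reported in
#'   kb (`left_kb`, `right_kb`) with the contributing mutants in
#'   `refined_by`.
#' @export
refine_with_deletions <- function(interval, evidence, map) {
  stopifnot(inherits(interval, "interval_estimate"))
  validate_marker_map(map)
  kb <- function(m) map$phys_kb[match(m, map$name)]
  bounds <- sort(c(kb(interval$left_marker), kb(interval$right_marker)))
  if (anyNA(bounds)) .stop_ctx("interval bounds must be on the map")
  lo <- bounds[1L]; hi <- bounds[2L]
  used <- character(0)
  if (!is.null(evidence) && nrow(evidence)) {
    span <- range(map$phys_kb)
    for (i in seq_len(nrow(evidence))) {
      ev <- evidence[i, ]
      if (ev$breakpoint_kb < span[1L] || ev$breakpoint_kb > span[2L])
        .stop_ctx("breakpoint of '", ev$mutant_id, "' lies off the map")
      b <- ev$breakpoint_kb
      # each mutant constrains the locus to one side of its breakpoint;
      # the interval is the intersection of all constraints, so an
      # already-satisfied constraint is uninformative and an emptied
      # intersection is contradictory evidence
      locus_low <- (ev$phenotype == "lost") == (ev$deleted_side == "lower")
      if (locus_low) {
        if (b >= hi) next
        hi <- b
      } else {
        if (b <= lo) next
        lo <- b
      }
      used <- c(used, ev$mutant_id)
      if (lo >= hi)
        .stop_ctx("contradictory deletion evidence: interval emptied after '",
                  ev$mutant_id, "' (", paste(used, collapse = ", "), ")")
    }
  }
  interval$left_kb <- lo
  interval$right_kb <- hi
  interval$span_kb <- hi - lo
  interval$refined_by <- used
  interval
}
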