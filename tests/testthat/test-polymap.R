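# Recombinant calling, interval delimitation, conditional distances,
# deletion refinement.

sim_mapping_pop <- function(N = 400, seed = 1, n_markers = 8,
                            locus_at = 5) {
  m <- toy_map(n_markers, locus_at = locus_at)
  p <- make_parent(m, selection_locus = "LOCUS")
  pop <- simulate_population(p, selection_model(), N, seed = seed)
  list(map = m, parent = p, pop = pop, g = as_genotype_table(pop))
}

test_that("recombinant calls agree with chromatid-provenance truth", {
  s <- sim_mapping_pop(N = 300, seed = 11)
  flanks <- c("M1", "M8")
  calls <- call_recombinants(s$g, s$map, flanks[1], flanks[2])
  expect_equal(nrow(calls), 300L)
  # truth from the simulator: the dominant-linked allele (1) present at a
  # flank iff some chromatid carries homologue 1 there
  truth <- vapply(seq_along(s$pop$records), function(i) {
    g <- s$pop$records[[i]]$genotype
    xor(1L %in% g["M1", ], 1L %in% g["M8", ])
  }, logical(1))
  expect_identical(unname(calls$is_recombinant), truth)
  # concordant-at-both-flanks plants are never called recombinant
  both <- calls$left_has & calls$right_has
  expect_false(any(calls$is_recombinant[both]))
})

test_that("plants with missing flank genotypes are excluded from calls", {
  s <- sim_mapping_pop(N = 50, seed = 12)
  g <- s$g
  g$allele_a[g$plant_id == "plant_0001" & g$locus == "M1"] <- NA
  calls <- call_recombinants(g, s$map, "M1", "M8")
  expect_equal(nrow(calls), 49L)
  expect_identical(attr(calls, "excluded"), "plant_0001")
})

test_that("the mapped interval contains the true locus and reports zero internal losses", {
  s <- sim_mapping_pop(N = 500, seed = 13)
  calls <- call_recombinants(s$g, s$map, "M1", "M8")
  iv <- map_locus_interval(calls, s$g, s$map, "M1", "M8")
  markers <- names(iv$per_marker_losses)
  li <- match(iv$left_marker, markers); ri <- match(iv$right_marker, markers)
  expect_true(li <= match("LOCUS", markers) &&
              match("LOCUS", markers) <= ri)
  inner <- markers[seq(li + as.integer(iv$bounded[1L]),
                       ri - as.integer(iv$bounded[2L]))]
  expect_true(all(iv$per_marker_losses[inner] == 0L))
  expect_equal(iv$cM_per_marker,
               100 * iv$per_marker_losses / iv$N)
  expect_equal(iv$span_kb,
               abs(s$map$phys_kb[s$map$name == iv$left_marker] -
                   s$map$phys_kb[s$map$name == iv$right_marker]))
})

test_that("zero recombinants degrade to the flagged flank-to-flank interval", {
  m <- toy_map(6, total_cM = 0)  # no recombination possible
  p <- make_parent(m, selection_locus = "LOCUS")
  pop <- simulate_population(p, selection_model(), 40, seed = 14)
  g <- as_genotype_table(pop)
  calls <- call_recombinants(g, m, "M1", "M6")
  expect_equal(sum(calls$is_recombinant), 0L)
  iv <- map_locus_interval(calls, g, m, "M1", "M6")
  expect_false(iv$resolved)
  expect_identical(c(iv$left_marker, iv$right_marker), c("M1", "M6"))
})

test_that("interval width is non-increasing in the number of recombinants", {
  s <- sim_mapping_pop(N = 600, seed = 15)
  calls <- call_recombinants(s$g, s$map, "M1", "M8")
  rec_ids <- calls$plant_id[calls$is_recombinant]
  widths <- vapply(c(5L, 15L, length(rec_ids)), function(k) {
    sub <- calls
    drop <- setdiff(rec_ids, rec_ids[seq_len(k)])
    sub$is_recombinant[sub$plant_id %in% drop] <- FALSE
    map_locus_interval(sub, s$g, s$map, "M1", "M8")$span_kb
  }, numeric(1))
  expect_true(all(diff(widths) <= 0))
})

test_that("conditional map distances are the raw single-class fractions", {
  expect_equal(conditional_map_distance(0, 100), 0)
  expect_equal(conditional_map_distance(13, 2169), 0.5994, tolerance = 1e-4)
  expect_equal(conditional_map_distance(52, 2169), 2.3974, tolerance = 1e-4)
  # additivity over disjoint adjacent classes
  expect_equal(conditional_map_distance(5, 500) + conditional_map_distance(7, 500),
               conditional_map_distance(12, 500))
  expect_error(conditional_map_distance(5, 0), "positive")
  expect_error(conditional_map_distance(10, 5), "<=")
})

test_that("deletion evidence refines the interval arithmetically", {
  # synthetic frame shaped like the worked example: a 654 kb interval with
  # a function-lost breakpoint 127 kb inside one end leaves 527 kb
  m <- marker_map(c("W", "L", "LOCUS", "R"), phys_kb = c(800, 654, 300, 0),
                  gen_cM = c(0, 0.1, 0.3, 0.6))
  iv <- structure(list(left_marker = "L", right_marker = "R",
                       span_kb = 654,
                       per_marker_losses = c(L = 2, LOCUS = 0, R = 3),
                       cM_per_marker = c(L = 0.2, LOCUS = 0, R = 0.3),
                       N = 1000, n_recombinants = 5L, resolved = TRUE,
                       bounded = c(TRUE, TRUE)),
                  class = "interval_estimate")
  # breakpoint 127 kb into the interval, upper side deleted, function lost
  # -> locus above the breakpoint: 654 - 127 = 527 kb remain
  ev <- deletion_evidence("mut_lost", 127, "lost", "upper")
  iv2 <- refine_with_deletions(iv, ev, m)
  expect_equal(iv2$span_kb, 527)
  expect_equal(c(iv2$left_kb, iv2$right_kb), c(127, 654))

  # no evidence: unchanged span
  iv3 <- refine_with_deletions(iv, NULL, m)
  expect_equal(iv3$span_kb, 654)

  # breakpoint outside the interval: uninformative
  iv4 <- refine_with_deletions(
    iv, deletion_evidence("mut_out", 700, "lost", "lower"), m)
  expect_equal(iv4$span_kb, 654)
  expect_length(iv4$refined_by, 0L)

  # retained phenotype places the locus on the undeleted side
  iv5 <- refine_with_deletions(
    iv, deletion_evidence("mut_ret", 127, "retained", "upper"), m)
  expect_equal(c(iv5$left_kb, iv5$right_kb), c(0, 127))

  # contradiction: two lost mutants pointing at disjoint sides
  expect_error(refine_with_deletions(
    iv, rbind(deletion_evidence("a", 127, "lost", "lower"),
              deletion_evidence("b", 500, "lost", "upper")), m),
    "contradictory")
})

test_that("interval bounds match brute-force enumeration on tiny instances", {
  # brute force: the locus must lie where every recombinant retains the
  # dominant-linked allele; enumerate all markers consistent with that and
  # compare with the returned zero-loss run
  for (seed in c(21, 22, 23)) {
    s <- sim_mapping_pop(N = 40, seed = seed, n_markers = 6, locus_at = 4)
    calls <- call_recombinants(s$g, s$map, "M1", "M6")
    if (sum(calls$is_recombinant) == 0) next
    iv <- map_locus_interval(calls, s$g, s$map, "M1", "M6")
    rec_ids <- calls$plant_id[calls$is_recombinant]
    consistent <- vapply(s$map$name, function(mk) {
      all(vapply(rec_ids, function(pid) {
        row <- s$g[s$g$plant_id == pid & s$g$locus == mk, ]
        1L %in% c(row$allele_a, row$allele_b)
      }, logical(1)))
    }, logical(1))
    # the enumeration's crossover-consistent marker set equals the
    # pipeline's zero-loss set
    zero <- names(which(iv$per_marker_losses == 0))
    expect_identical(sort(names(which(consistent))), sort(zero))
    # and the returned bounds delimit a zero-loss run containing the locus
    markers <- names(iv$per_marker_losses)
    li <- match(iv$left_marker, markers)
    ri <- match(iv$right_marker, markers)
    lo <- li + as.integer(iv$bounded[1L])
    hi <- ri - as.integer(iv$bounded[2L])
    expect_true(all(iv$per_marker_losses[seq(lo, hi)] == 0))
    expect_true(match("LOCUS", markers) >= lo &&
                match("LOCUS", markers) <= hi)
  }
})
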