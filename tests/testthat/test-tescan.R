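# Transposon annotation: insertion location, terminal repeats, target-site
# duplication, dominance call.

test_that("identical promoter pair yields a length-0 annotation", {
  host <- random_dna(800, seed = 31)
  ann <- locate_insertion(host, host, atg = 600)
  expect_equal(ann$length_bp, 0L)
  expect_true(is.na(ann$site_bp))
  expect_false(is_dominant_allele(ann))
})

test_that("construction/recovery round-trip is exact across random parameters", {
  set.seed(32)
  done <- 0L; trial <- 0L
  while (done < 60L && trial < 400L) {
    trial <- trial + 1L
    atg <- 900
    host <- random_dna(1200)
    len <- sample(60:400, 1)
    tir <- random_dna(sample(10:25, 1))
    tsd <- sample(0:10, 1)
    site <- -sample(30:700, 1)
    # the generator refuses non-identifiable junctions; redraw those
    sp <- tryCatch(synth_promoter_pair(host, len, tir, tsd, site, atg = atg),
                   error = function(e) NULL)
    if (is.null(sp)) next
    ann <- locate_insertion(sp$dominant_seq, sp$recessive_seq, atg = atg)
    expect_identical(c(ann$site_bp, ann$length_bp), c(site, len))
    expect_identical(ann$tsd_len, tsd)
    done <- done + 1L
  }
  expect_identical(done, 60L)
})

test_that("the three published architectures round-trip from fixture parameters", {
  t5 <- load_paper_fixtures("te_t5")
  tsd_for <- c(Mutator = 9L, hAT = 8L)
  host_seed <- c(221, 322, 223)
  for (i in seq_len(nrow(t5))) {
    host <- random_dna(2500, seed = host_seed[i])
    lhs <- split_tir_string(t5$tir_printed[i])$lhs
    sp <- synth_promoter_pair(host, t5$length_bp[i], lhs,
                              tsd_for[[t5$family[i]]], t5$site_bp[i],
                              atg = 2000, seed = 230 + i)
    ann <- annotate_te(sp$dominant_seq, sp$recessive_seq, atg = 2000)
    expect_identical(ann$site_bp, t5$site_bp[i])
    expect_identical(ann$length_bp, t5$length_bp[i])
    expect_identical(ann$superfamily, t5$family[i])
    expect_true(ann$in_conserved_window)
  }
})

test_that("ambiguous host/element junctions are refused by the generator", {
  # host engineered so that the insertion-point base equals the element's
  # first base and the base before the duplication equals its last base
  tir <- "GGATCCGTTA"
  te_first <- "G"; te_last <- revcomp(tir) |> substr(10, 10)
  host <- paste0(random_dna(80, seed = 44), te_last,
                 "ACGTACGT",  # the 8 bp that will be duplicated
                 te_first, random_dna(100, seed = 45))
  atg <- nchar(host) - 10L
  site <- -(atg - 90L)
  expect_error(
    synth_promoter_pair(host, 120, tir, 8, site, atg = atg),
    "non-identifiable")
})

test_that("printed terminal-repeat strings align with the published defects", {
  t5 <- load_paper_fixtures("te_t5")
  pil <- split_tir_string(t5$tir_printed[t5$genus == "Pilosella"])
  expect_identical(nchar(pil$lhs), 25L)
  al <- align_tir_pair(pil$lhs, pil$rhs_rc)
  expect_identical(al$mismatch_positions, c(2L, 12L, 13L))
  expect_identical(al$gap_count, 0L)

  tar <- split_tir_string(t5$tir_printed[t5$genus == "Taraxacum"])
  expect_identical(nchar(tar$lhs), 12L)
  al <- align_tir_pair(tar$lhs, tar$rhs_rc)
  expect_identical(al$mismatch_positions, c(4L, 12L))
  expect_identical(al$gap_count, 0L)
})

test_that("find_tirs recovers terminal repeats and their defects", {
  # perfect inverted repeat
  tir <- "GGATCCGTTACGGAT"
  te <- paste0(tir, random_dna(180, seed = 33), revcomp(tir))
  res <- find_tirs(te)
  expect_length(res$mismatch_positions, 0L)
  expect_identical(res$gap_count, 0L)
  expect_gte(nchar(res$tir_left), nchar(tir))

  # imperfect repeat built from the printed left/right halves
  t5 <- load_paper_fixtures("te_t5")
  pil <- split_tir_string(t5$tir_printed[t5$genus == "Pilosella"])
  te2 <- paste0(pil$lhs, random_dna(300, seed = 34), revcomp(pil$rhs_rc))
  res2 <- find_tirs(te2)
  expect_true(all(c(2L, 12L, 13L) %in% res2$mismatch_positions))
  expect_identical(res2$gap_count, 0L)

  # no repeat at all
  res3 <- find_tirs(paste0(random_dna(100, seed = 35)))
  expect_identical(res3$tir_left, "")

  expect_error(find_tirs("ACGT"), "shorter")
})

test_that("find_tirs is symmetric under reverse complement of the element", {
  tir <- "CAGGGCCGGTTACA"
  te <- paste0(tir, random_dna(150, seed = 36), revcomp(tir))
  a <- find_tirs(te)
  b <- find_tirs(revcomp(te))
  expect_identical(a$tir_left, revcomp(b$tir_right))
  expect_identical(a$tir_right, revcomp(b$tir_left))
  expect_identical(a$score, b$score)
})

test_that("TSD length classifies the superfamily", {
  mk <- function(tsd) {
    left <- paste0(random_dna(10, seed = 37), tsd)
    right <- paste0(tsd, random_dna(10, seed = 38))
    classify_te(left, right)
  }
  expect_identical(mk("ACGTACGT")$superfamily, "hAT")          # 8 bp
  expect_identical(mk("ACGTACGTA")$superfamily, "Mutator")     # 9 bp
  expect_identical(mk("ACGTACGTACG")$superfamily, "Mutator")   # 11 bp
  res_ta <- classify_te("GGCCGGCCGGTA", "TAGGCCGGCCGG")
  expect_identical(res_ta$superfamily, "other")                # TA motif
  no_dup <- classify_te("AAAAAAAAAACCC", "GGGTTTTTTTTTT")
  expect_identical(no_dup$superfamily, "unclassified")
  expect_identical(no_dup$tsd_len, 0L)
})

test_that("dominance follows the conserved-window rule", {
  host <- random_dna(1500, seed = 39)
  in_win <- synth_promoter_pair(host, 200, "CAGTTCCGGA", 8, -137,
                                atg = 1200, seed = 1)
  ann <- locate_insertion(in_win$dominant_seq, in_win$recessive_seq, 1200)
  expect_true(is_dominant_allele(ann))

  out_win <- synth_promoter_pair(host, 200, "CAGTTCCGGA", 8, -250,
                                 atg = 1200, seed = 2)
  ann2 <- locate_insertion(out_win$dominant_seq, out_win$recessive_seq, 1200)
  flag <- is_dominant_allele(ann2)
  expect_false(flag)
  expect_match(attr(flag, "note"), "outside")
})

test_that("substitution-bearing pairs still locate the insertion; short ones do not", {
  host <- random_dna(1000, seed = 41)
  sp <- synth_promoter_pair(host, 150, "GGATCCGTTA", 6, -200, atg = 800,
                            seed = 42)
  # sprinkle substitutions into the recessive copy away from the junction
  rec <- .subst <- strsplit(sp$recessive_seq, "")[[1]]
  for (i in c(50, 300, 950)) rec[i] <- setdiff(c("A", "C", "G", "T"), rec[i])[1]
  ann <- locate_insertion(sp$dominant_seq, paste0(rec, collapse = ""),
                          atg = 800)
  expect_identical(ann$length_bp + ann$tsd_len, 156L)
  expect_lt(abs(ann$site_bp - (-200)), 8L)

  # insertions under min_len are ignored
  small <- synth_promoter_pair(host, 30, "GGATC", 4, -100, atg = 800,
                               seed = 43)
  ann2 <- locate_insertion(small$dominant_seq, small$recessive_seq, 800)
  expect_identical(ann2$length_bp, 0L)
})
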