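# Nei-Gojobori Ks, calibrated ages, HKY distances, NJ trees, bootstrap,
# allele-divergence summaries.

test_that("Nei-Gojobori matches hand-counted arithmetic", {
  # identical pair
  ks0 <- ks_nei_gojobori("TTTGGGAAA", "TTTGGGAAA", bootstrap_reps = 10,
                         seed = 1)
  expect_equal(ks0$ks, 0)
  expect_equal(ks0$sem, 0)

  # one synonymous third-position change, hand-countable sites:
  # TTT (1/3 syn sites), GGG (1), AAA (1/3) -> S = 5/3; GGA also 1 -> S = 5/3
  # Sd = 1, pS = 3/5, Ks = -3/4 log(1 - 4/5)
  ks1 <- ks_nei_gojobori("TTTGGGAAA", "TTTGGAAAA", bootstrap_reps = 0)
  expect_equal(ks1$syn_sites, 5 / 3)
  expect_equal(ks1$syn_diffs, 1)
  expect_equal(ks1$ks, -3 / 4 * log(1 - 4 / 3 * 3 / 5))
  expect_equal(ks1$nonsyn_diffs, 0)

  # two-difference codon, both pathways synonymous (TTG -> CTG -> CTA and
  # TTG -> TTA -> CTA are all leucine): Sd = 2; sites: TTG 2/3, CTA 4/3,
  # pair average 1, plus ten identical GGG codons (1 each) -> S = 11
  a <- paste0(strrep("GGG", 10), "TTG")
  b <- paste0(strrep("GGG", 10), "CTA")
  ks2 <- ks_nei_gojobori(a, b, bootstrap_reps = 0)
  expect_equal(ks2$syn_sites, 11)
  expect_equal(ks2$syn_diffs, 2)
  expect_equal(ks2$ks, -3 / 4 * log(1 - 4 / 3 * 2 / 11))

  expect_error(ks_nei_gojobori("TTTG", "TTTG"), "divisible")
  expect_error(ks_nei_gojobori("TTTTAA", "TTTTAA"), "stop")
  expect_error(ks_nei_gojobori("TT-GGG", "TTTGGG"), "gap-free")
})

test_that("codon bootstrap s.e.m. is reproducible and positive for diverged pairs", {
  p <- synth_cds_pair(200, 0.08, seed = 51)
  e1 <- ks_nei_gojobori(p$seq_a, p$seq_b, bootstrap_reps = 100, seed = 7)
  e2 <- ks_nei_gojobori(p$seq_a, p$seq_b, bootstrap_reps = 100, seed = 7)
  expect_identical(e1$sem, e2$sem)
  expect_gt(e1$sem, 0)
})

test_that("age/rate calibration algebra is exact and matches the published table", {
  r <- rate_from_calibration(0.084, 5.23)
  expect_equal(r, 0.084 / (2 * 5.23e6))
  expect_equal(r, 8.03e-9, tolerance = 1e-3)

  # round-trip identity: age(ks, rate(ks, a)) = a
  for (ks in c(0.01, 0.08, 0.3)) for (a in c(0.5, 2, 7)) {
    expect_equal(estimate_age(ks, rate_from_calibration(ks, a))$age_mya_unrounded,
                 a)
  }

  t5 <- load_paper_fixtures("te_t5")
  cal <- t5[t5$calibration, ]
  rate <- rate_from_calibration(cal$ks, cal$age_mya)
  expect_equal(estimate_age(0.014, rate)$age_mya, 0.87)
  expect_equal(estimate_age(0.017, rate)$age_mya, 1.06)
  # internal consistency: the 0.017/1.06 pair implies (nearly) the same rate
  expect_equal(rate_from_calibration(0.017, 1.06), rate, tolerance = 0.01)

  expect_error(rate_from_calibration(0, 5), "positive")
  expect_error(estimate_age(0.1, -1), "positive")
})

test_that("HKY distance reduces to Jukes-Cantor in the symmetric limit", {
  bases <- c("A", "C", "G", "T")
  for (mism_per_pair in c(3L, 10L, 25L, 45L)) {
    a <- character(0); b <- character(0)
    for (x in bases) for (y in bases) {
      k <- if (x == y) 200L else mism_per_pair
      a <- c(a, rep(x, k)); b <- c(b, rep(y, k))
    }
    d <- hky_distance(paste0(a, collapse = ""), paste0(b, collapse = ""))
    p <- mean(a != b)
    jc <- -3 / 4 * log(1 - 4 / 3 * p)
    expect_lt(abs(as.numeric(d) - jc), 1e-6)
  }
})

test_that("HKY distance recovers simulated divergence; degenerate input falls back", {
  sim <- simulate_hky_pair(10000, 0.05, kappa = 3, pi = c(.3, .2, .3, .2),
                           seed = 52)
  d <- hky_distance(sim$seq_a, sim$seq_b)
  se <- sqrt(0.05 / 10000)  # rough Poisson scale
  expect_lt(abs(as.numeric(d) - 0.05), 3 * se)
  expect_identical(attr(d, "model"), "HKY85")

  expect_equal(as.numeric(hky_distance("ACGTACGT", "ACGTACGT")), 0)

  # no G anywhere: frequencies degenerate -> K80 fallback
  d2 <- hky_distance("ACATACATACATACAT", "ACATACTTACATACAT")
  expect_identical(attr(d2, "model"), "K80")
  expect_error(hky_distance("----", "----"), "comparable")
})

test_that("NJ recovers 3- and 4-taxon additive metrics exactly", {
  # 3 taxa: closed-form star branch lengths
  D3 <- matrix(c(0, 5, 9, 5, 0, 8, 9, 8, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr3 <- nj_tree(D3)
  expect_equal(sort(unname(tr3$edge.length)), sort(c(3, 2, 6)))

  # 4 taxa: additive tree ((a:1,b:2):1.5,(c:1,d:3))
  D4 <- matrix(c(0, 3, 3.5, 5.5,
                 3, 0, 4.5, 6.5,
                 3.5, 4.5, 0, 4,
                 5.5, 6.5, 4, 0), 4, 4,
               dimnames = list(letters[1:4], letters[1:4]))
  tr4 <- nj_tree(D4)
  # topology: a-b form a cherry separated from c-d
  expect_true(ape::is.monophyletic(ape::unroot(tr4), c("a", "b")))
  # branch lengths reproduce the generating metric
  expect_equal(as.matrix(ape::cophenetic.phylo(tr4))[letters[1:4], letters[1:4]],
               D4)

  # duplicate taxa join in a zero-length cherry
  D5 <- D4
  D5["b", ] <- D5["a", ]; D5[, "b"] <- D5[, "a"]; D5["a", "b"] <- D5["b", "a"] <- 0
  tr5 <- nj_tree(D5)
  cp <- as.matrix(ape::cophenetic.phylo(tr5))
  expect_equal(cp["a", "b"], 0)

  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("NJ matches exhaustive least-squares search on 5-taxon additive matrices", {
  skip_if_not_installed("phangorn")
  set.seed(53)
  for (rep in 1:5) {
    true <- ape::rtree(5, br = function(n) runif(n, 0.5, 2))
    D <- as.matrix(ape::cophenetic.phylo(true))
    D <- D[sort(rownames(D)), sort(rownames(D))]
    nj_fit <- nj_tree(D)
    # brute force: least-squares fit on every unrooted 5-taxon topology;
    # the generating topology is the unique zero-residual fit
    cands <- phangorn::allTrees(5, tip.label = rownames(D))
    rss <- vapply(cands, function(tr) {
      tr$edge.length <- rep(1, nrow(tr$edge))
      # design matrix: which edges lie on each tip-pair path
      X <- sapply(seq_len(nrow(tr$edge)), function(e) {
        tr2 <- tr; tr2$edge.length <- replace(rep(0, nrow(tr$edge)), e, 1)
        as.vector(as.dist(as.matrix(ape::cophenetic.phylo(tr2))[rownames(D), rownames(D)]))
      })
      y <- as.vector(as.dist(D))
      fit <- stats::lm.fit(X, y)
      sum(fit$residuals^2)
    }, numeric(1))
    best <- cands[[which.min(rss)]]
    expect_equal(min(rss), 0, tolerance = 1e-10)
    expect_equal(ape::dist.topo(ape::unroot(nj_fit), ape::unroot(best)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("bootstrap supports separate clean clades and are deterministic", {
  set.seed(54)
  base1 <- random_dna(600)
  base2 <- .mutate <- strsplit(base1, "")[[1]]
  flip <- sample(600, 120)
  comp <- c(A = "G", C = "T", G = "A", T = "C")
  base2[flip] <- comp[base2[flip]]
  base2 <- paste0(base2, collapse = "")
  jitter_seq <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    i <- sample(length(ch), k)
    ch[i] <- comp[ch[i]]
    paste0(ch, collapse = "")
  }
  aln <- c(a1 = jitter_seq(base1, 2), a2 = jitter_seq(base1, 2),
           a3 = jitter_seq(base1, 2),
           b1 = jitter_seq(base2, 2), b2 = jitter_seq(base2, 2),
           b3 = jitter_seq(base2, 2))
  tr <- bootstrap_support(aln, reps = 100, seed = 9)
  # the single internal edge separating the clades has near-full support
  expect_gte(max(tr$node.label, na.rm = TRUE), 95)
  tr2 <- bootstrap_support(aln, reps = 100, seed = 9)
  expect_identical(tr$node.label, tr2$node.label)

  tr1 <- bootstrap_support(aln, reps = 1, seed = 9)
  expect_true(all(tr1$node.label %in% c(0, 100)))

  rooted <- bootstrap_support(aln, reps = 20, seed = 9, outgroup = "b1")
  expect_true(ape::is.rooted(rooted))
  expect_error(bootstrap_support(aln, reps = 20, outgroup = "zz"), "outgroup")
})

test_that("allele-divergence summary separates clonal dominant from recombining recessive", {
  set.seed(55)
  comp <- c(A = "G", C = "T", G = "A", T = "C")
  anc <- random_dna(500)
  mut <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    i <- sample(length(ch), k)
    ch[i] <- comp[ch[i]]
    paste0(ch, collapse = "")
  }
  dom <- anc  # invariate dominant clade
  aln <- c(d1 = dom, d2 = dom, d3 = dom,
           r1 = mut(anc, 40), r2 = mut(anc, 40), r3 = mut(anc, 40))
  res <- asd_summary(aln, c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(res$within_dominant, 0)
  expect_gt(res$within_recessive, res$within_dominant)
  expect_true(res$dominant_monophyletic)

  same <- c(s1 = anc, s2 = anc, s3 = anc, s4 = anc)
  res2 <- asd_summary(same, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(res2$within_dominant, 0)
  expect_equal(res2$within_recessive, 0)
  expect_equal(res2$between, 0)

  expect_error(asd_summary(aln, c(TRUE, rep(FALSE, 5))), ">= 2")
})
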