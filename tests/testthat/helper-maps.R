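# Shared builders for the test suite.

# small uniform map with a central selection locus
toy_map <- function(n = 8L, span_kb = 700, total_cM = 7,
                    locus_at = ceiling(n / 2)) {
  name <- paste0("M", seq_len(n))
  name[locus_at] <- "LOCUS"
  marker_map(name,
             phys_kb = seq(span_kb, 0, length.out = n),
             gen_cM = seq(0, total_cM, length.out = n))
}

# three-marker map mimicking the scored-gene design: selected locus plus
# two linked genes at the given distances (cM)
linked_loci_map <- function(d1 = 0.25, d2 = 1.25) {
  marker_map(c("PAR", "AnnD3", "EIF3e"),
             phys_kb = c(0, -1100, -5000),
             gen_cM = c(0, d1, d2))
}

# canonical form of an unordered chromatid pair, for comparisons
pair_set <- function(a, b) {
  l <- list(as.integer(a), as.integer(b))
  l[order(vapply(l, paste, "", collapse = ","))]
}

# true phased chromatid labels of a simulated record at two loci
true_phase <- function(record, parent, locus1, locus2) {
  map <- parent$map
  i1 <- match(locus1, map$name); i2 <- match(locus2, map$name)
  lapply(record$chromatids, function(ch) {
    c(parent$homologues[ch$origin[i1], i1],
      parent$homologues[ch$origin[i2], i2])
  })
}
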