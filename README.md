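# apomap

Simulation and inference tools for fine-mapping a dominant gametophytic
locus in an autotetraploid plant, modelled on the *LOSS OF PARTHENOGENESIS*
(*LOP*) / *PARTHENOGENESIS* (*PAR*) system of *Pilosella piloselloides*.

## The problem

In gametophytic apomicts of the *Pilosella* type, a dominant determinant at
*LOP* acts in the gamete itself: a meiotically reduced egg cell develops
into a (poly)haploid seedling only if it inherited the dominant allele.
This makes polyhaploid populations a one-sided mapping resource — every
plant carries the dominant allele, only one recombinant class is
observable, and the dominant allele never transmits through haploid
gametes. `apomap` packages the machinery needed to work in this setting:

- **`simpop`-style simulation** — autotetraploid meiosis as two bivalents
  (pairing resampled uniformly over the three perfect pairings per meiosis
  under tetrasomic inheritance, fixed under disomic), Poisson crossovers
  with positions placed on the genetic map (Haldane model: recombinant
  chromatid fraction `(1 − e^(−2d))/2` at distance `d` Morgans),
  gametophytic selection (dominant-allele requirement, haploid lethality,
  negative-selection transgenes, per-allele viability weights), and
  generators for sequence fixtures (promoter pairs differing by one
  transposon insertion; codon alignments with a target Ks).
- **Polyhaploid mapping** — recombinant calling between flanking markers,
  locus-interval delimitation from per-marker losses of the
  dominant-linked allele, conditional map distances `100·k/N` cM, and
  interval refinement from deletion-mutant breakpoints.
- **Inheritance inference** — parsimony phasing of two-locus diploid
  genotypes into chromatids, 4×4 allele-linkage tables anchored on the
  dominant-linked allele, χ² transmission-bias tests, and
  tetrasomic-versus-disomic classification by exact binomial tests of each
  candidate pairing partner.
- **Transposon annotation** — locating the promoter insertion against the
  recessive allele, terminal-inverted-repeat characterization (anchored,
  gapped alignment of the 5′ end against the reverse complement of the 3′
  end), target-site-duplication extraction and superfamily classification
  (8 bp → hAT, 9–11 bp → Mutator, TA → Tc1/Mariner-like), and the
  conserved-200-bp-window dominance call.
- **Molecular evolution** — Nei–Gojobori synonymous divergence with
  Jukes–Cantor correction and codon-bootstrap s.e.m., divergence ages
  `T = Ks/(2r)` with the rate calibrated from a published Ks/age pair,
  HKY85 maximum-likelihood pairwise distances, neighbor-joining trees with
  site-bootstrap support, and dominant-versus-recessive allele sequence
  divergence summaries.

## Worked example

The package ships the published two-locus allele-linkage counts of 287
polyhaploids as a fixture:

```r
library(apomap)
lt <- load_paper_fixtures("linkage_t4")
lt
#> Allele-linkage table: N = 287 plants (anchor allele 1)
#>           PpEIF3e-1 PpEIF3e-2 PpEIF3e-3 PpEIF3e-4 Total (%)
#> PpAnnD3-1       280         0         4         3       287
#> PpAnnD3-2         0       120         0         1       121
#> PpAnnD3-3         0         1       127         0       128
#> PpAnnD3-4         0         1         1        36        38
#> Second-allele shares (%): PpAnnD3-2 42, PpAnnD3-3 45, PpAnnD3-4 13
```

Every plant carries the anchor allele (gametophytic selection conditions it
to frequency 1); the second allele varies. Testing the three non-anchor
totals for transmission bias:

```r
transmission_bias_test(lt)                  # alleles 2, 3, 4 vs uniform
#> Chi-square GOF: X2 = 52.4, df = 2, p = 4.19e-12
transmission_bias_test(lt, alleles = c(2, 3))
#> Chi-square GOF: X2 = 0.1968, df = 1, p = 0.657
```

Alleles 2 and 3 transmit equally (p = 0.66) while allele 4 is strongly
under-transmitted (p < 0.001). The pairing structure rejects every disomic
partition — the signature of an autopolyploid:

```r
classify_inheritance_mode(lt)
#> Inheritance mode: tetrasomic
#> partner_2 partner_3 partner_4
#> 3.28e-124 3.09e-135  7.63e-20
crossover_summary(lt)$crossover_chromatids  # 11 off-diagonal chromatids
#> [1] 11
```

Dating the dominant/recessive allele split from synonymous divergence,
with the substitution rate calibrated on the published *Taraxacum* pair
(Ks 0.084, 5.23 MYA):

```r
t5 <- load_paper_fixtures("te_t5")
cal <- t5[t5$calibration, ]
r <- rate_from_calibration(cal$ks, cal$age_mya)
estimate_age(t5$ks[t5$genus == "Pilosella"], r, "Taraxacum pair")
#> Estimated divergence age: 0.87 MYA (rate 8.03e-09 /site/yr, calibrated on Taraxacum pair)
```

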