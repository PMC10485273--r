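---
title: "Models and methods behind apomap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind apomap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apomap)
```

`apomap` implements the inference machinery for fine-mapping a dominant
gametophytic locus in an autotetraploid apomict — the *LOP*/*PAR*
configuration of *Pilosella*-type systems — together with the simulator
that stands in for living mapping populations. This vignette records the
models, their assumptions, the tunable parameters, and the design choices
made where the design was genuinely open.

## The meiosis and selection model

A tetraploid parent is represented as four homologue allele vectors over a
marker map (`make_parent()`); by construction homologue *h* carries allele
label *h*, so labels track homologue identity and the allele linked to the
dominant determinant is label 1 — the same convention used when scoring
real polyhaploids, where the dominant-linked allele is designated allele 1.

Meiosis is modelled at the bivalent level:

- **Pairing.** The four homologues form two bivalents. Under tetrasomic
  inheritance the partition is drawn uniformly from the three perfect
  pairings at *every* meiosis; under disomic inheritance one fixed
  partition is used. Quadrivalent formation is not modelled.
- **Crossovers.** Per bivalent, the crossover count is Poisson in the
  bivalent's genetic length (Morgans); positions are uniform on the
  genetic (cM) scale. The single transmitted chromatid switches homologue
  at every crossover, so the probability that two markers at distance *d*
  Morgans recombine on a chromatid is `P(odd count) = (1 − e^(−2d))/2`,
  the Haldane mapping function. There is no interference and no obligate
  chiasma — the simplest model consistent with the sub-centimorgan
  distances this design resolves, and a documented limitation at larger
  scales.
- **Double reduction** is off by default (`dr_rate = 0`): nothing in the
  data this package targets invokes it, and at the locus itself it would
  only perturb the exact 1/2 transmission of a simplex allele. A rate
  parameter is exposed for sensitivity work (when triggered, both
  transmitted chromatids are drawn from one bivalent).
- **Selection** (`selection_model()`): `require_dominant` keeps only
  gametes carrying the dominant allele at the selection locus (the
  defining property of a gametophytic locus); `haploid_lethal` kills
  haploid carriers (no haploid transmission of the dominant allele,
  through eggs or pollen); `exclude_dominant` inverts the requirement and
  models a negative-selectable transgene; `viability_weights` multiplies
  per-allele survival probabilities at a chosen locus. Weights act at
  acceptance and deliberately do not distinguish gametic from zygotic
  bias — the polyhaploid design cannot distinguish them either.

Two closed-form consequences anchor the test suite: a simplex dominant
allele is carried by exactly half of all diploid gametes under either
pairing mode (without double reduction), and, conditional on the anchor
allele at a fully linked marker, the second allele is uniform over the
other three labels (each 1/3) under tetrasomic pairing.

The generator emulates: simplex dominance, Poisson/Haldane crossovers on a
marker map, gametophytic selection, per-allele viability, spontaneous
polyhaploidy combined with transgene segregation (`simulate_seed_recovery`),
promoter pairs differing by one transposon insertion, and codon alignments
with a target synonymous divergence. It does **not** emulate: genotyping
error, missing data patterns, segregation distortion of non-focal origin,
quadrivalents, chromatid interference, or whole-genome context (one focal
chromosome only). Passing tests therefore validate the inference machinery
under clean Mendelian noise, not robustness to the failure modes of real
marker assays.

## Polyhaploid mapping

Because polyhaploids form only through gametes carrying the dominant
determinant, scoring is presence/absence of the *dominant-linked* allele
(hemizygous-style, matching allele-specific SCAR markers), not biallelic
dosage. A plant is recombinant iff it carries that allele at exactly one
flanking marker; plants with missing flank genotypes are excluded, not
imputed. For each marker between the flanks, the number of recombinants
*lacking* the dominant-linked allele ("losses") is counted; the locus
interval is the maximal zero-loss run, bounded by the innermost
loss-bearing markers (flagged when a side is unbounded or when there are
no recombinants at all).

Genetic distances are the raw conditional class fractions `100·k/N` cM:
only one recombinant class is observable and the whole population carries
the dominant allele, so `N` is the dominant-carrying count. No
mapping-function correction is applied — at the ≪ 1 cM distances involved
the Haldane correction is far below the counting noise. The per-population
resolution is reported as `100/N` cM per single recombinant.

Physical spans are always computed from the marker coordinates as
supplied; the package does not force any externally stated span.
Deletion-mutant refinement treats each breakpoint as a half-space
constraint (a function-lost mutant places the locus on its deleted side;
a function-retained one on the retained side); the interval is the
intersection of all constraints, already-satisfied constraints are
uninformative, and an emptied intersection raises a diagnostic naming the
conflicting mutants. The evidence record therefore carries an explicit
`deleted_side` field — a breakpoint alone does not orient the constraint.

## Inheritance inference

Two-locus diploid genotypes are phased by parsimony: of the two possible
chromatid assignments, the one implying fewer crossovers (label mismatches
within a chromatid) wins; equal-cost phasings are flagged ambiguous and
excluded from anchored tables rather than split fractionally, with the
exclusion count reported. On simulated data, parsimony phasing equals true
phase whenever the plant's true crossover count is ≤ 1 (a tested
property).

The anchored 4×4 chromatid-count table satisfies `anchor row = N`,
`non-anchor rows = N`, `grand total = 2N`. Transmission bias is tested by
Pearson χ² goodness-of-fit without continuity correction, `df = k − 1`,
on the *non-anchor* row totals only — the anchor allele is conditioned to
frequency 1 by selection and carries no information.

Mode classification tests, for each of the three perfect pairings, the
disomic prediction that the anchor's partner never appears as a second
allele except through crossover leak: an exact one-sided binomial test
against `leak_rate` (default 0.02, i.e. 2 cM between the scored and the
selected locus; pass `d_cM/100` when the map distance is known). All three
partitions rejected at `alpha` (default 0.01) → tetrasomic; exactly one
surviving → disomic with that partition; otherwise, or below the power
guard (`min_n = 30`), inconclusive.

## Transposon annotation

Coordinates follow the start-codon convention: the A of the ATG is +1, the
base immediately upstream is −1, there is no position 0, and the reported
insertion site is the position of the *first inserted element base* (the
alternative — measuring to the duplication — is recoverable from the
reported TSD length). A single insertion is assumed; multiple comparable
blocks are an error listing the candidates, not silently merged.

`locate_insertion()` finds the inserted block by an exact prefix/suffix
scan when the pair differs by a pure insertion, falling back to a global
Biostrings alignment (affine gaps) when substitutions are present. A
target-site duplication makes the block placement ambiguous by up to its
own length, so candidate (boundary, TSD) splits are scored for
terminal-inverted-repeat quality — an anchored best-prefix score of the
element's 5′ end against the reverse complement of its 3′ end (match +1,
mismatch −1, running maximum over a 40 bp window). Candidates within 4
points of the best score are kept (in-register boundaries score near the
repeat length; out-of-register ones near zero) and the maximal duplication
among them is the canonical reading.

One residual class is genuinely non-identifiable: if the host base at the
insertion point equals the element's first base *and* the host base
preceding the duplication equals its last base, an inward-shifted
decomposition (site+1, length−2, TSD+2) generates the byte-identical
dominant sequence. No locator can split that tie, so
`synth_promoter_pair()` refuses to generate such junctions (with a
diagnostic), keeping the construction/recovery round-trip exact for every
pair it emits.

`find_tirs()` aligns the element's termini anchored at column 1 (terminal
repeats are terminal), gapped by default — published repeat pairs can
differ by a missing base — with linear gap penalty −2, choosing the
endpoint pair maximizing the anchored score subject to a minimum length
(8 bp) and score (6), with a left/right-symmetric deterministic
tie-break. The TSD is the longest identical direct repeat (≤ 12 bp)
flanking the element; superfamily follows the duplication-length
diagnostic (8 → hAT; 9–11 → Mutator; the TA dinucleotide →
Tc1/Mariner-like, reported as "other"; anything else unclassified). The
dominance call is `length > 0` and site within the conserved 200 bp window
upstream of the ATG (`window_bp` tunable).

## Molecular evolution

**Ks.** Nei–Gojobori (1986) counting — fractional synonymous site counts
per codon position, minimal-pathway averaging for multi-difference codons
with stop-passing pathways excluded, mutations to stops counted as
nonsynonymous — with the Jukes–Cantor correction
`Ks = −3/4 · log(1 − 4/3 · pS)`. The method had to be chosen here (the
estimator behind the published values is unnamed); Nei–Gojobori is the
standard transparent choice and a hand-countable toy codon pair is frozen
in the tests as its oracle. The s.e.m. is a codon-resampling bootstrap
(default 200 replicates). Saturation (`pS ≥ 3/4`) is a diagnostic error.
The companion generator `synth_cds_pair()` plants synonymous differences
at per-site probability `pS = 3/4(1 − e^(−4/3·Ks_target))`, at most one
per codon, which keeps the estimate centred on the target for the
sub-saturation values it supports (targets above 1 are refused).

**Ages.** `T = Ks/(2r)`: the factor 2 reads the published ages as
divergence between two lineages each accumulating at rate *r* — the only
reading internally consistent with the published Ks/age ratios. The rate
is never hard-coded: it is a required calibration input, defaulting in
examples to the value implied by the published *Taraxacum* pair
(`rate_from_calibration(0.084, 5.23)` ≈ 8.03 × 10⁻⁹ /site/yr). Ages are
reported to 2 decimals alongside the unrounded value.

**Distances and trees.** HKY85 pairwise distances are maximized
numerically (Nelder–Mead over log-distance and log-κ with a 1-D polish)
from the symmetrized 4×4 site-pattern counts with empirical base
frequencies; gap/ambiguity sites are excluded pairwise; degenerate
frequencies fall back to K80. In the symmetric limit the estimate agrees
with Jukes–Cantor to < 10⁻⁶ (tested). Trees are standard neighbor-joining
(via ape) — a deliberate, documented substitute for the unnamed
commercial tree builder, aiming at topology-level agreement — with
negative branch lengths clamped to zero with a message. Bootstrap support
resamples alignment columns (default 200 replicates here; a
5,000-replicate run is a parameter, not a different method), counts clades
on the full-data tree, and uses the outgroup for display rooting only.
The allele-divergence summary reports mean pairwise distance within
dominant, within recessive and between groups, plus monophyly of the
dominant group judged against a recessive outgroup; dominants at exact
pairwise distance zero — the "invariate clade" pattern, which ties NJ
arbitrarily — count as monophyletic when separated from every recessive.

## Fixtures and conventions

Three published tables ship as code-built fixtures
(`load_paper_fixtures()`): the 24-marker coordinate table (signed kb from
the PAR start codon; upstream negative, e.g. the marker 68 kb upstream at
−68; two distal markers with only approximate printed coordinates are
flagged `approx_kb`), the 287-polyhaploid allele-linkage table, and the
three dominant-allele transposon architectures with their printed
terminal-repeat strings, Ks values and ages. The marker table prints no
per-marker genetic positions, so the fixture's `gen_cM` column is a
synthetic augmentation at the study-scale gradient of 0.2 cM/Mb,
anchored at the most distal marker — adequate for simulation, not a
published map. Physical ties between markers are kept and ordered by map
order.

`population_from_linkage_table()` deterministically expands a count table
into a synthetic genotype population whose parsimony re-phasing reproduces
the counts exactly; chromatid pairing within plants is chosen so no plant
is ambiguous or mis-phased (crossover chromatids are paired with
non-recombinant anchor chromatids, recombinant anchor chromatids with
matching diagonal partners).

## Seeds, problem sizes, and what the tests show

All stochastic stages consume explicit integer seeds; populations are
byte-identical under a fixed seed. The shipped test suite uses
desk-scale problem sizes chosen as the package's own defaults: 6,000 to
10,000 gametes for rate checks (binomial 3-s.e. bands), populations of
300–600 plants over 6–8 markers for mapping properties (20 seeds for the
locus-coverage sweep), 50–120 random draws for construction/recovery
sweeps, 100–200 bootstrap replicates, and 50-seed grids for Ks recovery.
These sizes put Monte-Carlo error well inside the asserted bands while
keeping the full suite around two minutes on one core.

## Known limitations

- No interference, obligate chiasma, or quadrivalent pairing in meiosis;
  double reduction only as a crude optional rate.
- Viability weights conflate gametic and zygotic selection by design.
- `synth_cds_pair()` plants at most one synonymous change per codon, so it
  is not a saturation simulator.
- The NJ/bootstrap layer is a distance-based stand-in; no ML/Bayesian
  inference, no codon-model (GY94) Ks, no multiple-sequence alignment
  (inputs must be pre-aligned).
- The hypothesis-test framework for inheritance mode is not a full
  likelihood model of polysomic segregation (no double-reduction ML).
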