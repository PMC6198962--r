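---
title: "In silico PCR-RFLP chlorotyping: models, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In silico PCR-RFLP chlorotyping: models, conventions and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chlorotypr)
```

## The chlorotyping model

A *chlorotype* is a chloroplast-DNA haplotype read out through a CAPS
(cleaved amplified polymorphic sequence) panel: three non-coding cpDNA
regions — the *trnQ-rps16* spacer (cpDNA01), the *ndhF-rpl32* spacer
(cpDNA02) and the *rps16* intron (cpDNA03) — are PCR-amplified and each
product is digested with a small set of restriction enzymes. Every
(region, enzyme) pair in the panel is a *diagnostic site*: a point
substitution at that site either creates or abolishes the enzyme's
recognition motif, so the digest outcome is binary. A sample's chlorotype
is the ordered string of those outcomes, `1` for digested, `0` for
undigested, with `?` for inconclusive calls and lowercase letters for
complex digestion patterns that match no known fragment profile.

The shipped panels mirror the dogwood (*Cornus*) system. The original
four-site panel is, in order, cpDNA01/AcuI, cpDNA02/TaqI, cpDNA02/Tsp45I,
cpDNA03/SwaI, with the classical named types H1 = `0101`, H2 = `0011`,
H3 = `1110`, H4 = `0111`. The extended twelve-site panel appends
cpDNA01/Hpy188I, cpDNA01/MseI, cpDNA01/MspI, cpDNA01/TaqI,
cpDNA02/Hpy188I, cpDNA03/AluI, cpDNA03/ApoI and cpDNA03/MmeI — the eight
additional informative substitutions found by sequencing the three
regions across cultivars of both species.

Everything downstream is plain population genetics on those strings:
per-group frequency tables, Pearson chi-square tests on chlorotype-by-group
contingency tables, analysis of molecular variance (AMOVA) with a
Monte-Carlo permutation test, and minimum spanning networks (MSNs) with
eigenvector centrality to nominate the most ancestral type.

## Sequence-level conventions

**Coordinates** are 0-based and half-open on the top strand of the
amplicon, everywhere: motif hits, cut coordinates, diagnostic columns.

**IUPAC matching.** Enzyme motifs may be degenerate (ApoI `RAATTY`,
Tsp45I `GTSAC`, MmeI `TCCRAC`, Hpy188I `TCNGA`); a template base matches a
motif character when it belongs to the code's expansion. An undetermined
template base `N` matches *nothing* under the default conservative policy:
a miscalled base must never invent a restriction site. A permissive policy
is available per call.

**Strands.** Palindromic motifs are scanned once; non-palindromic enzymes
(AcuI, MmeI) are additionally scanned with the reverse-complement motif
and minus-strand hits count as sites, since the physical enzyme binds
either orientation.

**Cuts.** Cut coordinates are `site position + cut_offset`, clamped to the
sequence bounds. The two Type IIS downstream cutters carry their REBASE
offsets (AcuI CTGAAG(16/14), MmeI TCCRAC(20/18)); because their distal cut
can fall off a short amplicon, chlorotype calls are driven by motif
presence, never by the cut position. Fragment lengths are the gaps between
consecutive distinct cut coordinates plus the ends, and always sum to the
sequence length.

**Amplicon extraction** slides each primer over the template exhaustively
and takes the mismatch-minimising position (ties resolve towards the outer
ends), allowing one substitution per primer by default — routine
amplification does not need more, and indels in a primer footprint are a
failed PCR, not a variant call. A product outside the region's expected
size range is flagged, not rejected. Primer sequences are user-supplied
configuration: the package deliberately hard-codes none.

**Digest calls** are made against a reference alignment. State `1`
requires the motif to start exactly at the diagnostic column; `0` requires
its absence there *and* an off-site hit pattern matching some reference
sequence; any other pattern gets a novel lowercase symbol, assigned
alphabetically in order of first appearance (stable across runs given the
same input order); a gap or `N` inside the motif footprint yields `?`.
Scanning happens on the ungapped molecule and hits are projected back to
alignment columns by the motif's first base — digestion happens on real
DNA, not on alignments.

## Site discovery and panel selection

`discover_informative_digests()` screens every catalog enzyme over every
aligned region and reports each alignment column where site presence
differs between at least one pair of samples. This operationalises an
"informative substitution" as a *restriction-pattern change*, not a raw
SNP: one SNP can touch several overlapping motifs, and only analytically
usable changes count. Indel columns are reported by
`find_polymorphic_columns()` but are not used as diagnostic sites.

`select_minimal_panel()` is a greedy set cover over sample pairs: add the
site splitting the most still-unsplit pairs until everything separable by
the full site set is separated, with deterministic ties by (region,
enzyme, column). Greedy set cover is within a log factor of optimal and is
exact on the panel sizes involved here; the tests verify it against
exhaustive subset search. On synthetic sequences realising the sixteen
published twelve-site chlorotypes, 8 of the 12 digests suffice to keep all
sixteen types distinct.

## AMOVA

With squared inter-individual distances `d²` the decomposition is the
classical one:

* `SSD_total = (1/N) Σ_{i<j} d²(i,j)`,
  `SSD_within = Σ_g (1/n_g) Σ_{i<j∈g} d²`, `SSD_among` the difference;
* `df_among = G−1`, `df_within = N−G`, mean squares `SSD/df`;
* `σ²_within = MS_within`,
  `σ²_among = (MS_among − MS_within)/n₀` with
  `n₀ = (N − Σ n_g²/N)/(G−1)`;
* percentages over `σ²_among + σ²_within`, negative components floored at
  zero with a flag.

The default distance is the Hamming count of differing panel positions,
which equals the squared Euclidean distance on 0/1 site vectors — the
natural "genotype agreement" metric for binary digest data; `nei` is
available as an alternative and is then used directly as the squared
distance. Novel symbols count as different from both `0` and `1`.
Samples containing `?` are excluded from chi-square, AMOVA and networks
(they remain in frequency reports' exclusion lists).

Significance uses a Monte-Carlo test permuting individuals across groups
with group sizes fixed (999 permutations by default, seeded):
`p = (1 + #{σ²_among,perm ≥ observed}) / (n_perm + 1)`.

Per-group *within-group contributions* are
`100 · [(1/n_g) Σ_{i<j∈g} d²] / SSD_within`; they sum to 100 and show
which collection carries the diversity.

Numerical notes worth knowing:

* `SSD_among + SSD_within = SSD_total` holds to 1e-9 relative tolerance
  and is asserted in the tests (the implementation is cross-checked
  against `ade4::amova` and a direct-summation oracle).
* The *SSD shares* are exactly invariant under duplicating every
  individual; the σ²-based percentages are not (the degrees of freedom
  rescale by `2(N−G)/(2N−G)`), and for near-null data at small N they can
  move by several points. They stabilise quickly with N; the tests assert
  exact SSD-share invariance and σ²-percentage stability at N = 60.
* With discrete data the permutation p is conservative when many
  permutations tie the observed statistic; the uniformity test therefore
  uses 12-position strings, where ties are rare.

## Networks and centrality

Distances between chlorotypes are Hamming or the per-site haploid Nei
distance `−ln(m/L)` (`m` matching positions of `L`); a pair with no
matching position has infinite Nei distance and is excluded from network
construction rather than given an invented weight.

The MSN is built by Kruskal's algorithm processing whole weight levels at
once: within a level, every edge joining two components *as they stood
before the level* is retained, so all equally short alternative
connections survive (tie tolerance 1e-9 absolute — integer Hamming weights
tie exactly, Nei weights need the tolerance). The retained set always
contains a minimum spanning tree, verified against exhaustive
spanning-tree enumeration for small graphs.

Eigenvector centrality is the principal eigenvector of an affinity matrix
with edge affinity `1/weight` (option: `max − weight`), by power iteration
with a positive diagonal shift (bipartite adjacency otherwise oscillates
between `±λ₁`). With `frequency_weighted = TRUE` each node is treated as
the collapsed clique of its `f` identical individuals — the diagonal gets
`(f−1)` couplings at the zero-distance affinity. This is the reading under
which the network behaves like the individual-level MSN whose nodes are
samples; it was chosen over a simple `sqrt(f_i f_j)` edge scaling because
the clique model is what collapsing an individual-level network actually
produces. Applied to the published four-site survey, the central type is
decided by a near-tie between the two most abundant chlorotypes, H4
(`0111`) and H3 (`1110`): with the unique-entry group sizes of the
frequency table (225/91/109/32) H4 wins by three reconstructed counts
(131 vs 128, inside the rounding error of percentage reconstruction),
while with the full study collection — all 168 *C. kousa* samples fixed
for H3 — H3 is the unambiguous centre, matching the published genealogical
reading. `analysis/04_networks.R` prints both.

## The synthetic generator

`generate_haplotype_sequences()` is the validation backbone: it emits, per
region, sequences whose digest states are controlled exactly. One random
background per region (uniform over A/C/G/T) is shared by all haplotypes;
each diagnostic site gets a dedicated locus carrying a concrete
instantiation of the motif (state `1`) or a single-substitution broken
motif (state `0`). A candidate substitution is accepted only if, in its
local context, it changes no other catalog enzyme's hit set; otherwise the
flanks are resampled with bounded retries, and a final global audit
verifies that for every enzyme the haplotypes differ only at that enzyme's
own diagnostic columns. Synthetic primers flank the interior so the
sequences behave as complete amplicons for `extract_amplicon()`.

Default region lengths are 1667, 986 and 907 bp — the alignment sizes of
the three dogwood regions — so synthetic data have realistic scale.
Collections are drawn per group either with exact counts
(largest-remainder rounding; the default for reproduction work) or
multinomially (for property tests), with `?` injected independently per
call at a configurable missing rate. Everything is a deterministic
function of the spec, seed included.

What the generator does *not* emulate: indels, alignment uncertainty,
mutation-process realism (no coalescent), partial digestion artefacts, or
primer-region variation. Passing round-trip tests therefore demonstrates
that the scoring machinery is exact on clean molecules with isolated
substitutions — not that real chromatograms would be called as cleanly.

## Reconstructing the published survey

The printed survey reports per-group chlorotype *percentages* with group
sizes n = 225 / 91 / 109 / 32 (four-site) and n = 91 / 109 (twelve-site).
`reconstruct_survey_dataset()` converts a column back to counts by
`round(pct·n/100)`, topping up or trimming by largest remainder when the
printed column does not round back to the group size (the wild *C.
florida* column sums to 96%, so nine counts are redistributed there; both
twelve-site columns round back exactly). Reconstructed counts inherit the
±0.5-percentage-point quantisation of the printed table; that is the
resolution limit of every downstream number.

On the reconstructed twelve-site collections the package computes: 7
distinct chlorotypes among the *C. florida* cultivars and 9 among the *C.
kousa* cultivars, none shared; Pearson χ² = 200 (df = 15, p ≈ 2·10⁻³⁴);
and an AMOVA partition of **91.4% among / 8.6% within** groups
(permutation p = 0.001 at 999 permutations), with the within-group sum of
squares split 28.9% / 71.1% between the *florida* and *kousa* collections.
`ade4::amova` reproduces the partition to machine precision. The
percentages 91.4/8.6 match the published AMOVA table with the
between/within labels transposed; the same transposition explains the
published four-site comparisons (the wild-vs-cultivar row prints 84.9/15.1
where this implementation and `ade4` obtain 15.5% among, and the
four-group row prints 36.1/63.9 against 63.8% among), while the published
four-group within-contributions (82/11/0/7) match this implementation's
definition directly (82.0/11.0/0/5.8 on reconstructed counts). A ΦST
near 0.91 is also the only coherent reading for two species that share no
chlorotype. The package reports the components under their standard
definitions.

## Problem sizes and determinism

The test suite and the acceptance script run on the reconstructed
collections (N ≤ 457), synthetic collections up to N = 400 for
parameter-recovery checks (five designed variance partitions × 10
multinomial seeds), 999 permutations for reported p-values and 199 for
the uniformity study, and exhaustive oracles on instances small enough to
enumerate (≤ 8 individuals for AMOVA, ≤ 6 nodes for spanning trees).
Every stochastic step takes an explicit integer seed; identical inputs
and seeds reproduce reports byte for byte, and the pipeline embeds a hash
of the analytic configuration in every report it writes.

## Known limitations

* Typing from sequences requires the sample to share the reference
  alignment's column space; the package consumes alignments, it does not
  build them.
* Novel-pattern symbols are stable only given identical input order.
* The digest-table format identifies panel positions by (region, enzyme),
  so a custom panel with two diagnostic columns for the same enzyme in
  the same region cannot round-trip through that format (sequence-based
  typing handles it).
* Nei distances between length-L strings take at most L distinct finite
  values; MSNs on Nei distances therefore tie heavily, and the retained
  tie edges — not the arbitrary MST choice — are the meaningful object.
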