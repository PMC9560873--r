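---
title: "Comparing plastomes that lost an inverted repeat: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing plastomes that lost an inverted repeat: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastcomp)
```

# The scientific problem

Most autotrophic seed-plant plastomes keep a quadripartite architecture: a
large and a small single-copy region (LSC, SSC) separated by two large
inverted-repeat copies (IR_A, IR_B) that are exact reverse complements of
each other. A handful of lineages have lost one IR copy, and those plastomes
are often — but not always — heavily rearranged and faster-evolving. Whether
IR loss *causes* the instability, or merely accompanies it, is tested by
comparing IR-lacking plastomes with their closest canonical-IR relatives
(CRCIRs) and, where available, with rearranged IR-present relatives, on a
common set of variables: dispersed-repeat number, tandem-repeat number,
rearrangement distance, indel frequency, SNV frequency, whole-plastome GC,
protein-coding GC, GC3, and the synonymous rate dS — all compared in a
phylogenetic framework so shared ancestry does not masquerade as signal.

`plastcomp` implements that comparison end to end, plus a synthetic-data
module that generates every input with known ground truth, so each stage is
testable without any downloads.

# Genome handling

Internal coordinates are 0-based half-open on a linearized circle; GenBank
I/O converts to and from 1-based inclusive spans (`join()` locations become
multi-interval features). The quadripartite partition is found as the
longest pair of exact reverse-complement duplications of at least
`min_ir_len` bp; the longer gap is labelled LSC, the shorter SSC. The
default `min_ir_len = 1000` operationalizes "canonical IR": genuine plastid
IRs are tens of kilobases, while dispersed repeats are rarely over a few
hundred bp, so any threshold in that wide gap behaves identically; 1 kb is
comfortably inside it. When rRNA annotations exist, the chosen IR must
contain them (the rRNA operon is the invariant IR core); equally long
competing candidates are resolved toward the rRNA-containing one with a
warning.

`collapse_ir()` removes IR_B — the copy after the SSC in
LSC–IR_A–SSC–IR_B order. Which copy is dropped is arbitrary: every
downstream statistic (repeat counts, gene order, GC) is invariant to the
choice, so the package fixes one and records it in the partition.
Comparative gene orders use loci present exactly once in every record
(after collapsing), matched case-insensitively through a small synonym
table; multi-copy loci are excluded with a warning because their homology
assignment is ambiguous.

# Rearrangement distance

Shared single-copy gene orders are converted to signed permutations
(reference order = identity; sign = strand agreement with the reference)
and the exact minimum number of signed reversals is computed from the
breakpoint graph by the Hannenhalli–Pevzner formula
*d* = (*n* + 1) − *c* + *h* + *f*, with *c* the alternating cycles, *h* the
hurdles (minimal unoriented components plus the greatest one), and *f* the
fortress correction. A sorting scenario attaining *d* is built greedily:
because the formula is exact, from any non-identity permutation some
reversal lowers it by one, so trying reversals in order always finds a step.
Scenarios are generally not unique; the package reports one optimal scenario
and the replayed breakpoint intervals, which is the right granularity for
endpoint/repeat association but should not be over-interpreted as *the*
historical event series.

Correctness is not taken on faith: an independent oracle computes distances
by breadth-first search over the complete reversal graph (all 2^n·n!
signed permutations, feasible to n = 8; a single BFS from the identity
suffices because each reversal is an involution, making the distance
symmetric). The test suite checks the formula against the oracle
exhaustively for n ≤ 5 and on 5,000 random permutations at n = 6–8.

Two conventions matter when comparing published coordinates:

* Inversion sites are flanking breakpoints *a–b* with length exactly
  *b* − *a*; the bundled 22-row coordinate table satisfies this identity
  row for row, which pins the convention.
* The SSC orientation of an IR-present plastome is a free isomer (the two
  flip-flop forms coexist in vivo). Distances are therefore computed under
  both SSC isomers of the reference and the minimum is reported, which
  removes the isomer artifact without any manual editing step.

# Repeats

Dispersed repeats are maximal exact repeated substrings (direct or
reverse-complement) of ≥ 30 bp occurring ≥ 2 times — the standard
plastome census setting (30 bp minimum, 0% mismatch). Detection seeds
shared k-mers and collapses them along diagonals; a run of matching k-mers
that cannot be extended at either end *is* a maximal match, so the method is
exact, and the suite verifies it against a brute-force all-offset scan on
planted fixtures. Copies of a pair may overlap only by less than half the
repeat length; larger overlaps are tandem structure and belong to the SSR
module. Ambiguous bases split candidates, and repeats are counted after IR
collapsing so the giant IR duplication does not flood the census.

The redundancy filter resolves nested families with two rules applied in
this order: (1) a containing family at most 10 bp longer than its contained
family is dropped (keep the shorter representative); (2) among survivors, a
contained family is dropped when its container occurs at least three times.
Stated informally, such filters are ambiguous about rule order; this
reading minimizes double counting while letting genuinely high-copy long
families absorb their fragments, and the filter is idempotent. Both a
family count and a per-copy count are derivable from the returned object,
since census tools differ on which they report.

SSRs are maximal perfect tandem runs with the unit-size minima
1-10 2-6 3-5 4-5 5-5 6-5 and a 100 bp compound-interruption distance.
Motifs must be primitive (an AA dimer inside a mononucleotide run is not
reported twice), spans cover complete units only, and compound loci count
as the number of their component SSRs for the tandem-repeat-number trait.

Repeat/inversion association: a family hits an inversion when any copy
overlaps or lies within 500 bp of either endpoint breakpoint (inclusive);
per inversion the longest associated repeat length is reported. The
generator plants inverted repeat pairs exactly at the breakpoints of a
configurable fraction of events, so association sensitivity is measurable
— and is 100% on the planted suite.

# Sequence statistics

GC content excludes N from numerator and denominator. RSCU is the observed
codon count scaled by family size over the family total, so each family
sums to its degeneracy; GC3 is the G+C fraction at third positions of sense
codons, excluding stop codons and N-containing codons (the CodonW
convention). Indel frequency is base-wise — gap bases in columns where
exactly one of target/reference is gapped, divided by total plastome length
— with an event-wise count emitted for diagnostics; SNV frequency counts
differing unambiguous base pairs. Both the whole-plastome and the
class-length denominators are returned, since published per-class rates can
be read either way. Alignments are inputs (the synthetic module emits true
alignments); the package does not infer them.

# Codon models

Rates come from an MG94-style codon model: single-nucleotide codon changes
only, rate = transition/transversion factor κ × F3×4 target-nucleotide
frequency × ω for nonsynonymous changes. The package uses HKY
exchangeabilities (one κ) rather than a full GTR vector: at desk-scale
alignment sizes the additional exchangeability parameters are weakly
identified and slow the optimizer, while ω — the quantity under test — is
insensitive to the difference; the rate-matrix builder takes the
exchangeability structure as data, so extending to GTR is mechanical.
Codon frequencies are F3×4 from the data with a 10⁻⁴ floor (keeps the chain
irreducible); the genetic code is the standard table, which coincides with
the plastid code for these genes; gapped or ambiguous codons are missing
data (partial likelihood 1).

Likelihoods are computed by Felsenstein pruning over the 61 sense codons
(compiled, with per-column rescaling); the chain is reversible, so trees
are unrooted for fitting. Branch lengths are expected substitutions per
codon under each branch's own ω. Branch models: one ω, two ω
(foreground/background), or free (one ω per branch). Optimization is
bounded quasi-Newton on log parameters (ω ∈ [10⁻⁴, 20], branch lengths
∈ [10⁻⁶, 30], κ ∈ [0.05, 100]), with optional extra starts; the two-ratio
fit warm-starts from the one-ratio optimum, which guarantees the likelihood
nesting that the LRT (χ²₁) requires. Per-branch dS and dN use the standard
decomposition: synonymous site proportion from the ω = 1 opportunity,
synonymous flux under the fitted ω. Per-taxon dS for group comparisons is
the terminal-branch dS under the free-ratio model (root-to-tip sums are
derivable from the edge table; the terminal branch is the quantity that
varies between sister groups and is the less confounded choice).

Selection labels follow the movement-toward-one rule: with estimates below
1 the regime is purifying ("Negative"); a foreground ω closer to 1 than the
background is "relaxation", farther is "intensification"; significance
comes from the LRT. Direction labels are printed even for non-significant
tests (matching how such tables are conventionally presented), so the
significance column must always be read alongside them. dS ratio tables
flag genes with dS(IR)/dS(SC) below 0.5 as "IR-like" and above 3.7 as
"SC-like" — the empirical bands separating IR-resident from single-copy
substitution regimes.

# Phylogenetic comparisons

All tests share the Brownian covariance C (shared root-to-MRCA path
lengths). The "phylogenetic t-test" is a GLS fit of the trait on a 0/1
group dummy with error covariance σ²C (homoscedastic across groups — with
the small group sizes typical here, freeing the variances buys little and
costs degrees of freedom), t = β̂₁/SE
with n − 2 df; PGLS is the same machinery with a continuous regressor. On a
star tree with equal depths both collapse to ordinary least squares, which
the suite asserts to 10⁻¹⁰. Zero-length-branch singularities are ridged by
10⁻⁸ × depth with a message.

The phylogenetic ANOVA compares the ordinary one-way F statistic against a
null distribution from Brownian simulation on the tree (rate = the ML
residual variance under a GLS grand mean), p = (1 + #{F* ≥ F}) / (n_sim+1);
post-hoc pairwise t statistics use the pooled mean square with the same
simulated null and Holm correction (Bonferroni/BH selectable). This is the
phytools-style construction, and the suite cross-checks the observed F
exactly and the simulation p within Monte-Carlo error against
`phytools::phylANOVA`. Defaults n_sim = 1000 and Holm follow that tool's
conventions.

# What the generator emulates — and what it does not

`simulate_plastome()` builds LSC + IR_A + SSC + IR_B with real plastid gene
names (including the rRNA/tRNA IR core), exact reverse-complement IRs,
geometric intergenic spacers, and optional deletion of either IR copy. The
four bases flanking the planted IRs are set to break chance extension, so
the planted boundaries are exactly the maximal-match boundaries and
partition recovery can be asserted bit-exactly. `apply_inversions()`
plants non-overlapping, gene-boundary-respecting inversions (optionally
repeat-mediated, with the inverted pair at the breakpoints) and assembles
the final genome in one left-to-right pass, recording events in the
flanking-breakpoint convention. `synthetic_study()` layers taxon-specific
intergenic substitutions, synonymous third-position recoding toward a
group GC3 target, group-dependent inversion counts, per-class alignments
with group substitution/indel rates (deletions only — alignment columns
stay fixed to the reference), and a codon alignment whose IR-lacking
terminal branches are elongated (the dS shift). Indel lengths are geometric
with mean 3 bp, the typical plastome microstructural scale.

Deliberately *not* emulated: IR expansion/contraction and gene conversion
between IRs, overlapping inversion histories, transposition/translocation,
alignment error, annotation error, and insertion columns in the class
alignments. Passing tests therefore demonstrate algorithmic correctness
and calibration under the model's assumptions — not robustness to the
messiness of real GenBank records, which is why real analyses should
inspect the parameter echo and warnings that every stage emits.

# Numerical choices and problem sizes

Tolerances: optimizer convergence ~10⁻⁸ relative (L-BFGS-B `factr = 1e8`);
LRT guard allows a 10⁻³ lnL dip before declaring an optimizer fault;
likelihood underflow is prevented by per-column rescaling. Ties in the IR
partition resolve toward the rRNA-containing candidate. Degenerate GLS fits
(constant traits) return a zero effect with p = 1 rather than NaN.

The validation suite runs at sizes chosen to exercise every code path while
keeping a laptop run comfortable: exhaustive oracle comparison to n = 5
plus 5,000 samples at n = 6–8; 200 inversion histories over four base
genomes; 100 brute-force repeat fixtures at 2.5 kb; ω recovery at 2,000
codons on 8 taxa; 500 null LRT replicates at 250 codons on 5 taxa; 1,000
Brownian null replicates for the GLS tests; and a 22-taxon three-group
specificity suite for the ANOVA. The acceptance script
(`scripts/acceptance.R`) re-runs scaled-down versions of the same
computations from scratch and writes the resulting numbers as JSON.

# Known limitations

* Blocks are annotation-based shared single-copy loci, not
  alignment-derived collinear blocks; records with very divergent gene
  content can lose resolution (each excluded locus coarsens the
  permutation).
* Only exact repeat matching is implemented; mismatch-tolerant
  (REPuter-style) detection is out of scope, so diverged repeat copies are
  invisible.
* The codon model is a branch model; site-model heterogeneity (M-series)
  and covariate tests are out of scope.
* The reversal distance is for a single linear chromosome; translocation,
  transposition and DCJ distances are not implemented.
* Free-ratio ω on terminal branches of small alignments is noisy; treat
  per-taxon ω as a comparative variable, not as a per-branch point
  estimate.
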