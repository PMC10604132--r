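---
title: "Methods and design of mitochar"
author: "mitochar authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of mitochar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitochar)
```

# Scope

`mitochar` characterizes circular vertebrate mitochondrial genomes the
way comparative mitogenomics studies of fish clades do: base
composition and strand skews, codon usage and RSCU under the vertebrate
mitochondrial code, gene architecture (order, overlaps, spacers,
control region), conserved blocks and the light-strand
replication-origin stem-loop in the non-coding regions, a
distance-based phylogeny with bootstrap support, and per-site selection
tests on the protein-coding genes. A synthetic-genome and
sequence-evolution simulator provides data with known truth, so every
stage is testable without downloads. The bundled feature table of the
*Myripristis kuntee* (shoulderbar soldierfish) mitogenome — 37 genes on
a 16,529 bp circle — serves as the reference annotation and as the
template for the generator.

Out of scope by design: read processing and assembly, de novo
annotation (MITOS/tRNAscan-SE territory), thermodynamic RNA folding,
model-selected maximum-likelihood or Bayesian tree inference, and
HYPHY's exact estimators; see "Design choices" below for what stands in
for the last two.

# Composition and skews

AT-skew is (A − T)/(A + T) and GC-skew is (G − C)/(G + C), computed on
whatever strand the input string represents. N bases are excluded from
every denominator, and a skew whose denominator is zero is reported as
`NA`, never as 0. `composition_report()` emits rows for the whole
genome, the concatenated PCGs, each PCG, the concatenated tRNAs and
rRNAs, and the control region.

Per-gene rows are computed on the gene's **sense strand** by default.
No convention is universal in the literature; the sense-strand choice
makes nad6's signature (an excess of T over A and G over C on its
coding sequence, mirroring the genome-wide skews because it is the one
L-strand PCG) a property of the gene itself rather than of the
reporting frame. `sense_strand = FALSE` switches every row to the
H-strand frame for cross-checking. Percentages are printed to two
decimals, rounding half away from zero, matching how such tables are
typically typeset.

# Codon usage

Reading frames start at position 1 of each CDS. A trailing 1–2 nt that
cannot form a codon is an *incomplete stop* (completed to TAA by
polyadenylation); it is annotated but never counted as a codon. In the
reference annotation three genes (cox2, nad4, cob) end this way, giving
CDS lengths ≡ 1 (mod 3).

Two codon totals are reported, because the field's customary headline
number and the strict count differ. `n_triplets` is the summed PCG
length divided by 3 — 11,439/3 = 3813 for the reference plan — while
`n_codons_no_stop` counts complete codons minus terminating stops
(3802 here). The first reproduces published totals; the second is the
count a strict "excluding stop codons" reading implies.

RSCU for codon *j* of a synonymous family of size *n* is its count
divided by the family mean, so each nonzero family averages to exactly 1.
Families are the amino-acid synonym sets of the genetic code in force
(default NCBI table 2: AGA/AGG are stops, ATA is Met, TGA is Trp, so
there are 60 sense codons and Leu and Ser are both 6-codon families).
Zero-count families get RSCU 0 with an explicit `rscu_undefined` flag.

# Gene architecture

Coordinates are 1-based inclusive throughout; `end < start` marks an
origin-spanning feature on the circle and all interval arithmetic is
circular. Overlap motifs are reported in the **H-strand frame**
regardless of member strands: the 5 bp nad5/nad6 overlap joins genes on
opposite strands, so no single sense frame exists and the H frame makes
the report well-defined.

The control region is not an annotated feature in typical published
feature tables — it is the conspicuous gap between trnP and trnF. The
reader therefore never invents a CR feature; `locate_control_region()`
returns an explicit CR annotation when one exists and otherwise the
longest intergenic spacer (at least 200 bp), warning when its flanks
are not trnP/trnF. Likewise the 33 bp trnN–trnC gap inside the WANCY
tRNA cluster is reported as the *candidate* replication origin; the
package flags it rather than asserting it.

Arrangement comparison is signed and circular: two genomes are
`identical` when one signed gene order is a rotation of the other, and
`breakpoints` counts adjacencies of one absent from the other (the
standard breakpoint-distance convention). Identity, not distance, is
the primary output, since the clades this package targets show no
rearrangements.

# Non-coding analytics

**Conserved sequence blocks.** Published CSB figures mark conserved
columns with asterisks but state no scoring scheme, so the package
defines one and exposes every knob: a column's identity is its
majority-base frequency with a gap-inclusive denominator; a window
(default 15 columns) qualifies when its mean identity reaches
`min_identity` (default 0.85) and no column exceeds `max_gap_frac`
(default 0.2) gaps; overlapping qualifying windows merge, and merged
runs shorter than `min_block` (default 12) are dropped. Blocks are
numbered CSB-I, CSB-II, ... positionally — no homology to the
canonical vertebrate CSB-1/2/3 nomenclature is claimed. The defaults
were chosen once so that the five seeded blocks of the synthetic
control region emerge cleanly over a highly divergent background; they
are not tuned per data set.

**Stem-loops.** `find_stem_loops()` enumerates inverted repeats
exhaustively: a 5' arm, a loop of 3–20 nt, and a 3' arm reverse
complementary up to `max_mismatch` violations (default 0). Only
*maximal* hairpins — extensible neither outward nor into the loop —
are reported, ranked by (G−C pairs, stem length). Only exact G−C pairs
count toward `gc_pairs`; G·U wobble is not a pair here. The search is
quadratic and intended for short regions such as the WANCY gap.

# Phylogeny

The package's tree machinery is deliberately distance-based. The
biological claims it must support are topological — two reciprocally
monophyletic subfamilies, two genera per clade, near-maximal support —
and neighbor joining with bootstrap reproduces exactly those claims at
desk scale with no external inference engines. Likelihood and Bayesian
machinery (with model selection) are not re-implemented; on the
simulated study conditions the NJ topology is identical to the truth,
which is the property the acceptance checks exercise.

Details that matter for reproducibility:

* Distances: p, JC69 (−3/4·log(1 − 4p/3)) or K2P, with pairwise
  deletion of gap/N sites by default (complete deletion by flag).
  Saturated pairs raise an error naming the pair.
* NJ ties on the Q criterion break to the lowest index pair, so the
  tree is deterministic; negative branch lengths clamp to 0 with a
  warning.
* Bootstrap resamples columns with replacement; support for each
  internal bipartition of the point tree is the percentage of
  replicate trees containing it. Supports on zero-length internal
  edges are reported as empty (an all-identical alignment has no
  informative bipartition). The default is 100 replicates — enough to
  express "≥ 95%" claims — and is configurable.
* Monophyly is the unrooted-edge sense: a subset is monophyletic when
  it forms one side of some edge bipartition. Robinson–Foulds distance
  is the symmetric difference of internal bipartitions.
* Alignment: a Gotoh affine-gap pairwise/profile aligner (gap of
  length k scores `gap_open + (k−1)·gap_extend`, diagonal-first
  tie-break) drives a progressive aligner over a UPGMA guide tree;
  sequences are processed in sorted-label order so the result is
  input-order invariant. The conserved-block trimmer classifies
  columns by identity thresholds and drops long nonconserved runs,
  with the retained-column map preserved.

Trees are inferred unrooted; outgroup rooting is a display concern.

# Per-site selection

**Counting test (SLAC-style).** Per codon site:

1. Ancestral codons come from 60-state codon Fitch parsimony (rooted
   arbitrarily; the change count is root-invariant). Final-pass
   ambiguities resolve deterministically — root takes the
   lexicographically smallest option, children keep the parent state
   when possible — and the number of ambiguous nodes is recorded.
   Known ancestral states (e.g. simulator truth) can be supplied
   instead.
2. Along each branch, a codon change of Hamming distance k is split
   into synonymous/nonsynonymous steps by averaging over all k!
   orderings that avoid stop-codon intermediates, with equal weights;
   pathways through stops are discarded (if every ordering is blocked,
   the average falls back to all orderings). OS + ON always equals the
   summed Hamming distance.
3. Expected sites ES/EN are branch-length-weighted averages of the
   per-codon site counts over both ends of every branch. Site counts
   follow the convention that changes to stops are excluded from both
   numerator and denominator at each codon position (a position whose
   three changes are all stops contributes nothing); the
   "stops-as-nonsynonymous" alternative is available by flag.
4. The p-value is a two-tailed binomial test of ON against the neutral
   expectation EN/(ES+EN) in ON+OS trials. Fractional counts are
   rounded to the nearest integer for the test — a documented
   approximation of the extended counting procedure. Classification at
   level α follows the sign of dN − dS.

**Likelihood test (`fel_lite`).** A deliberately simplified two-rate
per-site test: an MG94-style codon generator with equal nucleotide
exchangeabilities and uniform codon frequencies, α scaling synonymous
and β nonsynonymous changes, branch lengths fixed from the data-wide
NJ tree. Because the generator is α·(Qs + ωQn), its eigendecomposition
depends only on ω = β/α and is cached across the optimization. The
null constrains β = α; the LRT p-value uses χ²₁ halved. This is not a
replacement for a full FEL implementation (no estimated nucleotide
biases, no codon-frequency model); it is calibrated — neutral
simulations yield about the nominal false-positive rate — and
directionally correct under purifying selection.

# The synthetic generator

`make_genome()` emulates the statistical structure the analyses
assume, on the bundled 37-gene plan:

* **Composition targets are met by construction.** PCG codons are
  sampled from per-base probability products restricted to sense
  codons; afterwards the unconstrained positions (tRNAs, rRNAs,
  spacers, control-region background) are filled with exact
  target-count sampling, so whole-genome A+T and both skews land
  within ±0.5 percentage points (in practice, within rounding) of the
  requested values. nad6 samples its sense codons from mirrored skews,
  reproducing the one-gene sign reversal.
* **ORFs are valid.** Every PCG begins with its annotated start codon,
  contains no internal stop under code 2, and ends with its annotated
  stop class — including the three incomplete-stop genes. The
  generator verifies this and fails loudly rather than emit a broken
  ORF.
* **Overlap motifs are reconciled with reading frames.** The 7 bp
  nad4l/nad4 motif ATGCTAA and the 5 bp nad5/nad6 motif CCTAA are
  exactly consistent with the flanking start/stop codons and are
  realized verbatim. The canonical 10 bp atp8/atp6 motif AGCTTCTTCG is
  *not* jointly satisfiable with atp6 starting ATG and atp8 ending TAA
  at the annotated coordinates; annotated codons take precedence, so
  the realized overlap keeps the motif's interior but reads
  ATG····TAA at the edges. This precedence rule is the package's
  resolution of a genuine inconsistency in published annotation
  summaries.
* **Non-coding structure.** The control region (length configurable in
  the observed 838–960 bp band; total genome length varies through it
  alone) carries the five CSB motifs at randomized offsets with enough
  margin that detected blocks never merge; the trnN–trnC gap carries a
  stem-loop with 7 or 8 exact G−C stem pairs and a T-poor loop.

`evolve_codons()` is a continuous-time codon simulator: single-
nucleotide changes at rate κ for transitions (1 for transversions),
×ω when nonsynonymous, 0 into stops, normalized so one unit of branch
length is one expected substitution per codon site at ω = 1 under
uniform codon usage. Every substitution is logged with branch, site
and synonymy, which lets the counting machinery be cross-validated
*exactly*: when the true tree and true ancestral states are supplied
and no branch carries two hits at one site, SLAC's OS/ON must equal
the log totals (the test fixes a seed verified to satisfy the
single-hit condition).

`make_study_set()` evolves an ancestral genome along a known tree with
a two-clade ingroup (two "genera" per clade, mirroring a
squirrelfish/soldierfish-type subfamily split) plus outgroups. Default
conditions: 14 ingroup + 3 outgroup taxa; per-gene ω = 0.1 (strong
purifying selection, as expected for mitochondrial oxidative-
phosphorylation genes); κ = 2; clade stem branches 0.15, within-clade
internals 0.04, terminals 0.05, outgroup stem 0.25 (codon
substitutions/site); control-region background positions resampled
per taxon with probability 0.3. These were chosen once as realistic
study conditions — deep, well-supported clades over ~11 kb of coding
sequence — and are not revisited per test.

What the generator does **not** emulate, hence what passing tests do
not show about real data: no indels (alignments of simulated genes are
gap-free, so the aligner and trimmer are exercised separately on
constructed cases); genome length varies only through the control
region; tRNA/rRNA sequences are conserved across taxa rather than
evolving; control-region background divergence is independent per
taxon rather than tree-correlated; structurally constrained codons
(starts, stops, overlap joints) are frozen during evolution; and codon
usage comes from a base-composition product rather than an empirical
codon table.

# Problem sizes and determinism

The shipped tests and the acceptance script run, by choice, at sizes
where the statistical claims are comfortably identifiable on one CPU:
the full 17-taxon study set with 100 bootstrap replicates for the
topology claims; 500 codon sites × 8 taxa for dN/dS recovery (±0.15);
200 sites for type-I calibration (≤ 7% at α = 0.05); 150 sites for the
exact truth-log reconciliation; strings ≤ 50 nt and trees ≤ 12 taxa
for the brute-force oracle equivalences. Every stochastic operation
accepts one integer seed, and equal seeds give byte-identical genomes,
alignments, logs and reports.

# Known limitations

* The binomial SLAC p-value and the halved-χ² `fel_lite` p-value are
  stated approximations, calibrated but not exact small-sample
  procedures.
* Fitch reconstruction reports one deterministic resolution of
  equally parsimonious assignments; counts on ambiguous sites depend
  on that rule (the ambiguity count is reported per site).
* The progressive aligner is a correct but basic stand-in; for real
  divergent data a dedicated aligner will do better, and the package
  reads externally aligned FASTA for exactly that reason.
* Published headline site counts from real 14-genome alignments
  (thousands of sites, specific purifying/positive tallies) depend on
  the deposited accessions and the original tool chain; they are
  reproduction goals for downloaded data, not packaged tests. The
  package documents the published envelopes (genome length
  16,507–16,639 bp, A+T 53.12–56.85%) and its generator covers them.
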