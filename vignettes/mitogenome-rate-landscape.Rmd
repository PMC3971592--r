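---
title: "Comparative rate landscapes of whole mitogenomes: models, thresholds and design choices"
author: "mitorate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative rate landscapes of whole mitogenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

mitorate compares whole mitochondrial genomes of very closely related taxa:
samples of the same species, and species of the same genus. At these
distances, third codon positions and noncoding regions still accumulate
substitutions roughly linearly, synonymous sites saturate somewhere between
the intraspecies and congeneric levels, and nonsynonymous rates span the two
orders of magnitude that separate "population" from "species". This
vignette records the models the package implements, the defaults and
thresholds it exposes, and the reasoning behind the design decisions that
were genuinely open.

## Region partitioning

A `mito_genome` holds a circular sequence plus typed features (PCG, tRNA,
rRNA, NCR); coordinates are 0-based half-open internally, converted to
1-based only at the GenBank boundary, and an origin-wrapping feature is
stored as `start > end`. `extract_regions()` builds per-genome concatenates:
in-frame protein-coding codons with reading offsets applied and terminal
complete or incomplete (`T`/`TA`) stop codons removed, and tRNA, rRNA and
NCR concatenates. Protein-coding genes are concatenated **alphabetically by
gene name**: pairwise statistics are order-invariant, so any fixed order
works, and a canonical one makes outputs diffable across genomes and runs.
NCR features are synthesized for every positive inter-gene gap, so the NCR
total is exactly genome length minus annotated gene length. Overlapping
genes are possible in these genomes; each nucleotide is assigned to the
first feature in canonical order and overlaps surface as negative adjacency
lengths in the NCR table, never as silent double counting.

## Distances and codon-position classes

Uncorrected *p*-distances use pairwise deletion: a site is dropped only for
the pair in which it carries a gap or ambiguity. Complete deletion would
discard sites globally and, with many pairs, waste most of the alignment;
pairwise deletion maximizes the sites available to each comparison. Codon
columns carry P1/P2/P3 site-class labels, so the first-plus-second (P12) and
third (P3) position classes are exact complements of the all-positions PCG
record — their site and difference counts are additive, which the tests
assert. Distances are fractions internally and percentages only at
presentation.

## The pairwise codon model

`fit_pairwise()` maximizes the likelihood of a two-sequence alignment under
a Goldman–Yang codon model over the 62 sense codons of the ascidian
mitochondrial code (NCBI table 13; AGA/AGG → Gly, ATA → Met, TGA → Trp —
fixed by default, overridable):

$$q_{ij} = \pi_j \,\kappa^{\mathbb{1}[\text{transition}]}\,
\omega^{\mathbb{1}[\text{nonsynonymous}]}, \qquad i \ne j
\text{ differing at one position,}$$

normalized to one expected substitution per codon per unit of *t*, with
F3×4 frequencies (products of position-specific nucleotide frequencies
pooled over both sequences, floored at 1e-10 and renormalized). The matrix
is reversible by construction, so *P(t) = e^{Qt}* is computed through the
symmetrized eigendecomposition — stable out to the *t* ≈ 10–200 needed for
synonymously saturated congeneric pairs.

Numerical choices:

* Optimization is bounded quasi-Newton (L-BFGS-B) on log-transformed
  (*t*, κ, ω), bounds *t* ∈ [1e-6, 200], κ ∈ [0.01, 100], ω ∈ [1e-4, 10];
  the very high *t* ceiling exists because congeneric synonymous divergence
  can run into the hundreds of substitutions per site and the fit must be
  allowed to say so (such dS values are reported but flagged saturated by
  the landscape stage, not trusted as rates).
* Starting points (0.3, 2, 0.2), (1, 2, 0.2), (5, 2, 0.2). The likelihood
  is evaluated at all three; full optimization launches from the best start
  and continues through the others only if it fails to converge or ends
  below a start. This preserves the invariant lnL(MLE) ≥ lnL(every start)
  at a fraction of the cost of three full optimizations — relevant because
  the validation suite fits several hundred pairs.
* The eigendecomposition is cached on (κ, ω), so line searches and
  *t*-derivatives reuse it.
* Codon columns containing a stop codon in either sequence are masked with
  a warning; annotated genes should not contain them, and a handful of
  masked columns must not abort a cohort run.
* Non-convergence after all starts returns a fit with `converged = FALSE`,
  never an exception — one refractory pair must not kill a pipeline run.

Site counts follow the mutational-opportunity convention: S and N are the
synonymous and nonsynonymous shares of substitution flux with ω forced
to 1 (at the fitted κ and frequencies). With dS = t·ρS/(3S/(S+N)) and
dN = t·ρN/(3N/(S+N)) this makes dN/dS ≡ ω exactly, which the tests assert.
Counting conventions differ across programs precisely at this point, and dS
is the quantity most sensitive to them; dN is robust, which is why the
cross-check below is phrased on dN.

`ng86_estimate()` is the independent oracle: Nei–Gojobori-style site and
difference counting with equal-path averaging (paths through stop codons
are excluded when an alternative path exists) and Jukes–Cantor correction,
returning NaN when a corrected proportion saturates (p ≥ 3/4). On simulated
pairs with *t* ≤ 0.3 and ω ≤ 0.3 at 3,000 codons, the ML and counting dN
agree within 15% on every pair (median ~6%); dS disagrees by construction
(the counting method ignores the transition bias when weighting sites), and
no attempt is made to reconcile the conventions.

Parameter recovery is validated over regimes {t = 0.05, 0.3, 1.0} ×
{ω = 0.05, 0.3} at 3,000 codons. The acceptance suite measures median
relative bias with 150 replicates per regime rather than 50: at t = 0.05
an individual ω estimate rests on ~20 nonsynonymous events and carries
>20% sampling error, so the *median of 50* such estimates still has ~4%
measurement noise — of the same order as the 5% bias bound being tested.
150 replicates measure the same quantity with the precision the bound
requires (the underlying bias, measured at 200 replicates during
development, is below 2% in every regime).

## The rate landscape: saturation, gap, flags

`saturation_table()` pairs each region's observed (uncorrected) distance
with a model-inferred expectation: for P12 and P3 the fitted expected
substitutions per site of that class (from the positional decomposition of
the flux of the fitted Q), for the synonymous/nonsynonymous views the
dS/dN estimates against the raw counting proportions. Synonymous saturation
is flagged at dS > 1 substitution/site (exposed as a threshold). The
inferred quantity is emitted **per site**; per-codon normalizations differ
by a constant factor and would not change the saturation call.

`dn_gap_report()` is exact bookkeeping: highest intraspecies dN, lowest
congeneric dN, their difference, with deterministic tie-breaking by pair id
and explicit exclusion lists. A negative delta is reported as "no gap" —
absence of a gap is informative and is never clamped.

`flag_intermediate_pairs()` flags an intraspecies pair when its dN is at
least 5× the intraspecies baseline **and** at least 5× below the congeneric
minimum (both ratios configurable; the defaults sit at the low ends of the
ranges such intermediate pairs actually occupy). The baseline is the
maximum intraspecies dN among pairs of *other* species — a leave-species-out
rule rather than leave-pair-out. The reason is structural: when one species
harbours a genuine internal split, *every* pair of that species spanning
the split is elevated, so a leave-one-pair-out baseline would contain the
other elevated pairs and the ratio would collapse to ~1 for exactly the
pairs that must be flagged. Cross-species intraspecies pairs are the only
contamination-free reference. A corollary worth knowing: at realistic
intraspecies divergence the baseline dN rests on a handful of substitution
events, so the flag ratios carry Poisson noise; with the default synthetic
study conditions the flag set is stable for the large majority of seeds,
but a baseline fluctuation can occasionally move a borderline pair across
the 5× line.

`grouped_distance_gap()` is the same min-between minus max-within logic for
any clade-labelled distance matrix (the barcode-gap setting); singleton
groups contribute no within-group distances and a single group is an error.

## tRNA cloverleaf analysis

Structures are **input**, not predicted — structure prediction
(tRNAscan-SE/ARWEN-style) is out of scope, and packaged structures are
synthetic fixtures labelled as such. The fixture format is three lines per
record (id, sequence, per-position annotation); stems are bracket-matched by
construction (k-th 5' position pairs the k-th-from-last 3' position), and
parsing validates balance, non-overlap and anticodon placement.

`classify_trna_substitutions()` attributes every differing column to
exactly one structural element (insertions relative to the reference
inherit the element of the nearest preceding reference position — the
alternative, a dedicated insertion bucket, would fragment already-small
counts). Stem changes are classified per pair-event: compensatory when both
partners differ and pairing — Watson–Crick **or** G·U, which is a valid
wobble pairing thermodynamically — holds in both sequences; everything else
is noncompensatory. Event-level accounting makes
compensatory + noncompensatory = stem events an assertable identity.
Arm-level percentages aggregate stem + loop (T-arm = T-stem ∪ T-loop);
spacer substitutions go to a separate "other" bucket rather than an
adjacent arm, and the reported shares state this. At study-scale divergence
(tRNAs 0–7% diverged) the aggregate rests on one-to-two hundred
substitutions, several of them shared across pairs through common branches,
so arm shares fluctuate by several percentage points between seeds.

The structure-aware simulator mutates loop positions independently and stem
pairs as events: with probability *c* an event is a joint move to a valid
pair differing at both partners; otherwise a single partner takes a random
different base. Compensated events are therefore always classifiable as
compensatory and uncompensated ones never are, so the classifier recovers
*c* without bias — the acceptance suite demands ±5 points at 1,000 events.
Two independent events hitting the same pair on the two lineages can
masquerade as a single event of the other class; at the event densities
used this is a sub-point effect.

The anomaly screen tests, in order: T-arm presence; the single-nucleotide
spacer between D- and AC-arms; pyrimidine at the semi-invariant position 5'
of the anticodon; pairing at the AA-stem base (the outermost pair); and the
AA-stem mispair count against a threshold (default > 2). Each check reads
only the annotation and sequence, so a screen never depends on a
comparison partner.

## NCR architecture

`ncr_adjacency_table()` emits one row per inter-gene adjacency per genome
(negative length = overlap) and refuses cohorts with discordant gene order,
naming the first discordant adjacency. `find_homopolymers()` reports
maximal runs; the default threshold of 9 reflects the length at which
polymerase slippage visibly destabilizes these genomes' T-runs, with 6
catching the shorter runs seen in other taxa.

`classify_ncr_difference()` distinguishes three causes. The decisive test
for a **boundary shift** is sequence-anchored: a window of fixed length
(margins plus the largest NCR) starting a fixed distance before the end of
the upstream gene is extracted from each genome; if the windows match
(identity ≥ 0.9 — allowing for point substitutions between conspecific
genomes) while the annotated NCR lengths differ, only the annotation moved,
which is exactly the start/stop-codon shift case. Otherwise the NCR
sequences themselves are aligned (affine global alignment: match 1,
mismatch −1, open 4, extend 1 — Biostrings defaults for short, conserved
noncoding stretches) and a **true indel** is called when the matched
columns are ≥ 85% identical, i.e. the alignment is clean gapped blocks over
a conserved spacer. Anything else stays **unclassified**: ambiguous
evidence is never guessed at. "Sizeable" differences default to > 5 bp —
the value that separates slippage-scale length wobble from the
indel/boundary-shift events worth individual attention — and NCRs > 20 bp
are additionally marked as boxes for display purposes.

## The simulator and what passing tests mean

`simulate_genome_pair()`/`simulate_cohort()` evolve a stationary ancestor
down a tree: protein-coding genes by exact transition-probability sampling
under the fitted-form GY94 matrix (two branches of *t*/2 from a stationary
ancestor match the reversible pairwise model exactly — one branch of *t*
would too, but the two-branch form is what a cohort tree generalizes);
tRNAs by the structure-aware process; rRNAs by a 2:1 transition-biased
nucleotide process; NCRs likewise, plus slippage length changes on
homopolymer runs and optional injected indels and annotation-level
start-codon shifts (a conserved 12-bp T-homopolymer pad at the start of two
genes is held invariant so the shifts remain classifiable). Defaults —
3,500 protein-coding codons, 24 tRNAs of 72 nt, 2,000 bp of rRNA, ~650 bp
of NCR across ten adjacencies, AT-rich position-specific composition —
reproduce the scale and structure of the ascidian mitogenomes the package
targets. Divergence regimes sit at *t* = 0.02 (intraspecies), 0.3
(intermediate) and 3.0 (congeneric) substitutions per codon, with ω ≪ 1.

`study_cohort()` is the calibrated emulation of a full comparative study:
five genera; conspecific pairs at dS ≈ 0.010–0.017; one four-sample species
containing a near-identical pair (dS ≈ 0.06) and two deeply diverged
specimens whose five pairwise comparisons sit at dS ≈ 0.30 with dN chosen
inside the intermediate band (≈ 7× the other-species intraspecies maximum,
≈ 6-8× below the congeneric dN floor); cryptic-species pairs at dS ≈
3.3–3.4 anchoring gap deltas of ≈ 0.05 (full cohort) and ≈ 0.13 (cryptic
pairs removed); further congeneric pairs at dS 5–8; and the NCR program
(true indels of 11 and 13 bp, boundary shifts of 11 and 7 bp, five small
slippage differences — nine differing adjacencies, four sizeable). Branch
lengths are derived **analytically** from the target dS values by inverting
dS = t·ρS/(3·fS) under the generator's own model — calibration happens
before any data are drawn, not by adjusting to estimates.

What the generator does *not* emulate bounds what green tests show:
sequences evolve without coding indels or gene rearrangements, alignments
are therefore exact by construction, and there is no sequencing error or
annotation noise. Passing tests demonstrate that the estimators and
classifiers recover what the models put in at realistic sizes; they say
nothing about alignment curation or annotation quality on real data, which
remain the user's responsibility (region extraction accepts externally
curated alignments for exactly this reason).

Randomness policy: every simulation entry point takes a seed, seeds R's
generator for the duration of the call and restores the caller's RNG state
afterwards; identical seeds give byte-identical cohorts.

## Problem sizes used by the validation suite

Engine identities run at full precision in milliseconds. The oracle
cross-check uses 50 pairs × 3,000 codons; parameter recovery 150 replicates
× 6 regimes × 3,000 codons; landscape recovery 20 seeded cohorts of 7
genomes at 1,000 codons (regime separation is 15×, so 1,000 codons place
every ratio far from the flag thresholds); the stem classifier 1,000 stem
events; the study emulation one 17-genome cohort at the full 3,500 codons.
The complete suite runs in a few minutes on one CPU.

## Known limitations

* Pairwise fits only — no site-class (M-series) or branch models, no trees.
* dS above saturation is reported but meaningless as a rate; downstream
  logic treats it only through the saturation flag.
* The NG86 oracle and the ML fit disagree on dS by convention; only dN is
  cross-checked.
* The boundary-shift classifier assumes locally colinear genomes; a
  rearrangement spanning the adjacency defeats the window comparison (the
  gene-order check upstream refuses such cohorts outright).
* The heuristic that attributes insertion columns to the preceding element
  slightly favours elements that precede loops in the cloverleaf when
  indels are common; at the indel densities of conspecific tRNAs this is
  negligible.
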