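---
title: "Detecting selection on amino acid physicochemical properties: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting selection on amino acid physicochemical properties: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(propsel)
```

## The question and the model

Protein-coding genes evolve by nucleotide substitution, but selection acts
on the *physicochemical consequences* of the amino acid replacements those
substitutions cause.  propsel implements the magnitude-category framework
used for mitochondrial protein-coding genes in sarcopterygian phylogenetics
(amphibians, lungfishes, coelacanths): each observed amino acid replacement
is scored by how much it changes a given physicochemical property (its
*magnitude*), magnitudes are binned into eight categories from conservative
(1) to radical (8), and the observed category counts are compared with what
random mutation would produce.  An excess of radical change — *positive
destabilizing selection* — is read as the signature of adaptive shifts in
protein structure or function; an excess of conservative change is
*positive stabilizing selection*.

The method has three ingredients.

**The null model.**  Under neutrality every single-nucleotide mutation that
turns one sense codon into another is taken as equally likely.  For a
genetic code the package enumerates all ordered pairs of sense codons one
nucleotide apart (526 for the standard code, 508 for the vertebrate
mitochondrial code, which is the default because the motivating data are
mtDNA-encoded), keeps the nonsynonymous pairs, and computes, for each
property, the distribution of change magnitudes over those pairs.  Bins are
eight equal-width intervals spanning `[0, max |Δ|]`, where the maximum is
taken over the nonsynonymous neighbourhood; the expected probability
`p_k` of category `k` is the fraction of neighbourhood pairs falling in
bin `k`.  Because bins scale with the property's own range, the expected
distribution is invariant under affine rescaling of the property values.
No codon-frequency or transition/transversion weighting is applied: the
null is deliberately the "completely random replacement" model the
statistic was designed against.

**Observed replacements.**  Replacement events are inferred by parsimony
ancestral reconstruction on *codon* states (not amino acids, so synonymous
changes remain identifiable and are excluded from the property statistics).
The implementation is Fitch parsimony generalized to arbitrary node degree
(Hartigan's vote-counting form), with deterministic tie-breaks: on the
top-down pass a node inherits its parent's state whenever that state is in
its optimal set, and otherwise takes the lexicographically smallest member;
the root takes the lexicographically smallest member of its set.  Codons
containing `-` or `N` are treated as missing data (wildcards) and never
generate events.  A codon differing at several positions across one branch
counts as a single source→target replacement; sites with fewer than two
unmasked taxa are skipped.  Tests verify the reconstruction against
exhaustive minimization over all ancestral assignments on hundreds of
random 4–6 leaf trees.

**The test.**  For each site (or sliding window of `window` codon sites
centred on it), property, and category, with `n` nonsynonymous events in
the window and `observed` of them in the category,

> z = (observed − n·p) / sqrt(n·p·(1 − p)),

the normal approximation to the binomial; `z > 3.09` (one-tailed p ≈ 0.001)
flags positive selection.  Categories 6–8 flag destabilizing, 1–3
stabilizing selection.  An exact binomial tail probability is emitted
alongside every z for audit.  The *whole-protein* statistic sums the signed
per-site z-scores of one property across the protein and compares the sum
with the same threshold; by default each site contributes its
destabilizing-category z-scores (`sum_mode = "focus"`), with
`sum_mode = "all"` as the labelled alternative, since which per-site value
enters the sum is not pinned down by the original description.

## Site-level calls: why the default pools categories 6–8

The per-category z at threshold 3.09 is strongly anticonservative for rare
categories at realistic event counts: with `p = 0.01` and a handful of
events, a single radical event already exceeds 3.09, and the true size of
the test is 0.5–7% rather than the nominal 0.1% across a wide range of
`n`.  This is a property of the normal approximation plus count
discreteness, not of any particular data set; it is also why per-category
false-positive fractions in our neutral simulations sit near 1.5–2% rather
than 0.1–0.5%.  The package therefore bases its default site-level
selection calls on the *pooled destabilizing band*: one test per (site,
property) with `observed` the event count anywhere in categories 6–8 and
`p` the band's total null mass (typically 0.1–0.3, where the normal
approximation behaves).  Pooled-band false-positive rates in neutral
simulation are 0.2–0.5% per property.  The per-category tests are always
computed and reported; `call_mode = "category"` switches the calls to
them.

## Cross-clade shared-site comparison

Clade groups (e.g. amphibians, lungfishes, coelacanths) are analyzed
*separately*, each with its own subtree, against the same master alignment
per gene, so codon site coordinates are comparable across groups — this
master-alignment convention is the package's answer to the otherwise
under-determined question of how sites from separate group analyses
correspond.  For each property and group tuple the report counts sites
flagged positive-destabilizing in every group of the tuple (columns A-L,
A-C, L-C, A-L-C), and per tuple a *deduplicated* total: distinct sites
shared under at least one property, each counted once however many
properties flag it.  Per-property cells overlap and must not be summed;
the object enforces `deduplicated total ≤ column sum` as a checked
invariant, and the print method repeats the caveat.

## The property table

Property values are configuration, not code.  The bundled table
(`default_property_table()`, `inst/extdata/aa_properties.tsv`) carries 20
properties including the nine headline abbreviations used in the
comparison tables — pK′ (COOH ionization constant), Ra (solvent accessible
reduction ratio), an (power to be at the N-terminal), Hp (surrounding
hydrophobicity), H (hydropathy), K° (compressibility), F (mean r.m.s.
fluctuation displacement), Ht (thermodynamic transfer hydrophobicity), P
(polarity) — with representative values compiled from the standard
literature scales.  Analyses tied to a specific published instrument
should substitute their own TSV via `read_property_table()`; every
downstream number flows from whatever table is supplied.

## The synthetic-data generator

`simulate_codon_evolution()` exists so that every pipeline stage is
testable with known ground truth.  Its neutral law is constructed to match
the analysis null *exactly*: every ordered sense→sense single-nucleotide
move carries the same rate, so the stationary distribution over sense
codons is uniform, the flux over ordered pairs is uniform, and the
realized nonsynonymous category frequencies converge to
`expected_distribution()` — the keystone internal-consistency test tying
the simulator to the null model.  Rates are normalized so one unit of
branch length is one expected substitution per codon site at the neutral
baseline.  Branch lengths are in expected substitutions per codon site;
roots are drawn uniformly over sense codons unless supplied.
Destabilizing bias multiplies the rate of moves whose property change
falls in categories 6–8 by β (≥ 1; β = 1 is neutral) at chosen (clade,
site) pairs, where a branch belongs to a clade when all its descendant
leaves do.  One master seed drives everything; per-branch substreams are
derived from the branch's descendant-leaf set, so adding taxa does not
perturb unrelated branches, and identical seeds give byte-identical FASTA.

What the generator deliberately does *not* emulate: indels and alignment
error, transition/transversion bias, unequal codon frequencies,
among-site rate variation beyond a per-site multiplier, and CpG-like
context effects.  Passing tests on these simulations therefore show that
the chain of inference is internally correct under the method's own
assumptions — not that the null model is adequate for any particular real
data set.

## Calibration and power: what the tests show

Three empirical facts about the method, established by the package's own
simulations and worth knowing before interpreting output:

1. **Per-category tests are anticonservative** (above).  Neutral
   per-category false-positive fractions are ~1.5–2% at the 3.09 cutoff
   across window sizes 5–21 and branch lengths 0.1–0.3 — an order of
   magnitude above nominal.  This persists even when the tests are fed the
   simulator's exact event log, because successive substitutions at one
   site are Markov-dependent bursts as well.  Use the pooled band (the
   default) for site calls.

2. **Saturation erodes the radical signal.**  At 0.3 expected
   substitutions per codon site per branch — and ~3× that at sites under
   strong bias (β = 10 raises the substitution rate through the radical
   channel) — parsimony recovers fewer than half of the realized events,
   and multi-step paths collapse into single net changes whose magnitudes
   are no longer radical: in our simulations the realized radical fraction
   0.78 at biased sites drops to 0.47 among reconstructed events.  A
   closed-form calculation shows that even with *perfect* event recovery
   the per-site power of the z > 3.09 test under those conditions peaks
   near 0.74 (property `an`); with parsimony reconstruction the measured
   per-site sensitivity is ~0.1 at specificity ~0.97.  Per-site detection
   under strong saturation is information-limited; whole-region and
   cross-clade aggregates remain informative.

3. **The whole-protein sum is weakly calibrated for long genes.**  The
   statistic compares a sum over all sites with the same fixed threshold
   3.09, so its null standard deviation grows with sqrt(sites) and
   neutral genes of a few hundred codons cross the threshold ~40–60% of
   the time (reconstruction artifacts also skew it positive).  It is
   reported because it is part of the method; treat it as descriptive.

The planted-bias studies in the test suite use the target property `Hp`
(surrounding hydrophobicity): a design power analysis favors properties
with mid-sized radical band mass (~0.16) — large-mass properties need
near-unanimous radical counts before z can clear 3.09 at small `n`, while
rare-band properties starve the test of events.  The cross-clade study
uses groups of 12, 12 and 4 taxa at 0.1 substitutions/site/branch with 30
shared biased sites among 300 — group A sized like the twelve amphibians
of the motivating study — and under that design the A-L column strictly
dominates A-C and L-C in ~90% of replicates.

## Numerical and degenerate-input policy

* Codon sites are 1-based in all reports.
* Bin edges are half-open `[lo, hi)`, final bin closed; magnitudes equal to
  an interior edge (within a 1e-9 relative tolerance) belong to the higher
  bin; magnitudes beyond the neighbourhood maximum (possible for amino
  acid pairs not reachable in one nucleotide step) clamp to category 8.
* A property constant over the neighbourhood has no magnitude range and
  raises a degenerate-range error.
* `z = 0` when a window holds no events; a category with `p = 0` scores 0
  when empty and `NA` (unscorable, excluded from sums and calls) if an
  event lands in it.
* Windows larger than the gene clamp to the gene with a warning; even
  window sizes centre on the lower-index side.
* Two-taxon trees degenerate to pairwise comparison on the single branch
  pair, matching how a two-species clade must be handled.

## Problem sizes used by the test suite

The suite's simulation studies are sized to be decisive yet desk-scale:
the simulator/null consistency check uses two taxa × 14,000 sites (~10,500
nonsynonymous events); false-positive calibration uses 8 taxa × 700 sites
× 20 properties × 8 categories = 112,000 tests at window 5; the planted
recovery and cross-clade studies use 20 replicate seeds of 300-site genes.
These sizes keep every study's Monte Carlo error well below the margins
being asserted.

## Limitations

Trees and alignments are inputs: the package neither aligns nor infers
topologies, and reconstruction uncertainty is not propagated — parsimony
gives one deterministic history.  No multiple-testing correction is
applied by default (matching the method's tradition); with 20 properties ×
8 categories per site, genome-scale scans should expect the per-category
anticonservatism discussed above.  The null conditions on the full code
neighbourhood rather than on the codons actually present in a data set; a
data-conditioned null is a natural extension hook.  dN/dS-style and
likelihood branch-site models are out of scope by design.
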