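---
title: "Methods: motif-based discovery and molecular evolution of CEP genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: motif-based discovery and molecular evolution of CEP genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, algorithms and design decisions behind
`cepkit`, in the order the pipeline runs them. It is the reference for *why*
each default is what it is; the function reference documents the *what*.

## The gene family and the discovery problem

CEP genes are single-exon genes encoding a prepropeptide with four
segments: an N-terminal secretion signal (NSS), a variable region, one or
more 15-residue CEP domains, and a usually short C-terminal extension
(sometimes absent: the stop codon can immediately follow the final domain).
The mature signaling peptide is the excised 15-mer. Because the coding
sequences are short — down to roughly 48 residues — they are systematically
missed by standard gene predictors, so the survey strategy is to scan *all*
open reading frames of a genome for the two essential features: a secretion
signal at a plausible start codon, and at least one high-scoring CEP domain.

## The motif model

**PSPM.** The CEP domain is modelled as a width-15 position-specific
probability matrix: `probs[i, a]` is the probability of amino acid `a` at
motif position `i`, estimated by weighted column counting over a set of
identified domain instances with Dirichlet smoothing:

```
probs[i, a] = (sum of weights of domains with a at i + pc * bg[a]) / (W + pc)
```

where `W` is the total weight. The default pseudocount `pc` is 1% of `W`:
on unweighted counts this is the conventional `0.01 * n_sites` smoothing,
and defining it relative to total weight keeps the same smoothing fraction
after the weighting stage normalizes `W` to 1.

**Two-stage weighting.** Surveys spanning many genomes are distorted by
two imbalances: assemblies contribute very different gene counts, and some
lineages are sequenced far more densely than others. Stage one equalizes at
three levels — all domains within an ORF share the ORF's mass, all ORFs
within an assembly share the assembly's mass, and all assemblies receive
equal mass. Stage two multiplies each domain's weight by `decay^depth`,
where `depth` counts the internal nodes on the species-tree path from the
root to the organism's leaf, the root included, and `decay = 0.8` (a 20%
reduction per internal node). Counting the root means a two-leaf tree
applies one decay factor to both leaves; since a factor common to all
domains cancels when the weights are renormalized to sum to one, the
convention is observationally neutral on balanced trees and only the
*relative* depths matter.

**Scoring and exact P-values.** A window `w` scores
`S(w) = Σ_i log2(probs[i, w_i] / bg[w_i])` bits. The P-value of a score is
the exact tail probability of `S` for a random window drawn from the
background model, computed by dynamic programming: per-position score
contributions are discretized onto a common grid (2^17 bins across the full
score range) and convolved across positions. Two numerical details matter:

* Window P-values in `scanOrf()` are looked up by the window's own *binned*
  score (the sum of its per-position integer offsets), so the reported tail
  probability is exact for the discretized model — this is what makes the
  brute-force-enumeration checks in the test suite exact, and the null
  P-value distribution super-uniform rather than merely approximate.
* For an arbitrary real threshold (`scorePvalue()`), the threshold is
  mapped to the grid with a slack of half a bin per motif position, the
  worst-case displacement of a binned window sum. At the default
  resolution this slack is far below the spacing of distinct scores, and
  halving the granularity moves P-values by well under 1%.

P-values of a discretized score distribution are super-uniform (the
cumulative probability of `p ≤ x` never exceeds `x`), with a visible atom
at `p = 1` because many letters share the pseudocount floor in well
conserved columns.

The survey cutoff is `P ≤ 6e-11`, deliberately conservative: scanning a
genome's six frames tests on the order of 10^8–10^9 windows, and the cutoff
keeps the expected number of false windows far below one (the test suite
checks that a 10^4-residue background sequence yields zero hits).
Overlapping hits are resolved greedily by descending bit score, ties to the
leftmost offset — deterministic, and consistent with one peptide per
window of sequence.

## Gene discovery

`extractOrfs()` translates all six frames and emits maximal stop-free runs
of at least 50 residues (inclusive; runs abutting contig ends are kept, and
`N`-containing codons translate to `X` without terminating a run). Genes
shorter than 50 residues remain discoverable whenever their surrounding
stop-free genomic context reaches 50.

`findStart()` implements non-AUG-aware start selection: every ATG and every
leucine codon (all six, configurable) upstream of the first domain is a
candidate; each candidate's downstream prefix is scored by the signal
scorer, and the maximum wins if it *strictly* exceeds 0.400, ties breaking
to the 5'-most candidate (the longest signal). ORFs with no passing
candidate are rejected with a reason code.

The **signal scorer** is a pluggable contract (`SignalScorer`): any
deterministic function from an amino-acid prefix to `[0, 1]` plus a
cleavage-site call. The built-in `heuristicSignalScorer()` combines the
three classical signal-peptide features — positive charge among residues
2–5, the maximal 8-residue mean Kyte–Doolittle hydropathy within residues
6–20, and small residues at the −3/−1 positions of the best cleavage site
searched over signal lengths 15–30 — through a fixed logistic:
`plogis(1.2*min(charge, 2) + 0.9*(hyd − 1.5) + 1.4*small − 3.2)`. The
weights were set once so that canonical tripartite signals score > 0.8,
acidic or unstructured prefixes score < 0.1, and 0.400 sits in the sparse
middle of the scale. It is a deliberately simple stand-in with the same
interface as a dedicated predictor; `tableSignalScorer()` wires in
externally computed scores where fidelity to a specific predictor matters.

`parseArchitecture()` tiles the prepropeptide exactly: the NSS length is
the scorer's cleavage call, the variable region runs to the first domain,
and the C-terminal extension runs from the last domain to the stop codon —
length zero is flagged. A bounding stop codon is required (an ORF truncated
by a contig edge has no defined C-terminal border and is rejected as
`no_stop`). Genes reachable from overlapping ORFs are deduplicated on their
CDS span. All coordinates are 0-based, half-open, forward-strand.

## Distances, diversity and group comparisons

Pairwise distances use the JTT empirical amino-acid model, embedded as the
published exchangeability triangle and frequencies with the generator
normalized to one expected substitution per site per unit time.
`mlDistance()` maximizes `Σ_sites log(π_a P(t)_{ab})` over `t ∈ [1e-6, 10]`
by bracketed scalar search (tolerance 1e-6), excluding gapped columns;
boundary optima carry a saturation flag. `alignPair()` is a classical
Needleman–Wunsch with affine gaps (Gotoh's three-state recursion, gap cost
`11 + 1·L` in the half-bit units of the JTT log-odds matrix evaluated at
`t = 1`), with a fixed tie-breaking preference in the traceback; the test
suite cross-checks both the alignment scores (against an independent
alignment engine) and the distances (against an independent likelihood
implementation). Gamma rate variation is not modelled.

IOPDs — intra-organism pairwise distances — are the distances between all
gene (or domain) pairs within one assembly, pooled by plant family. Pooled
distance distributions are multimodal and skewed, so family contrasts use
Tukey's HSD on rank-transformed values (average ranks on ties); GC-content
contrasts logit-transform the proportions first, with the standard
small-sample smoothing `p ← (p(n−1)+0.5)/n` to keep 0 and 1 finite. Both
run through base R's `aov`/`TukeyHSD` (studentized-range distribution).
One caution, quantified in the test suite: pooled IOPD values within a
family are statistically dependent (pairs share genes), so the nominal
Tukey error level is reliable only when a family contributes many
effectively independent units (e.g. many assemblies); the null-calibration
test uses two genes per assembly — one IOPD each — precisely so the values
are independent.

`trimColumns()` approximates gap-based column trimming: per-column gap
fractions are sorted and the cut placed at the largest jump of the
distribution; gapless alignments pass through unchanged.

## Sitewise dN/dS

The Bayesian renaissance-counting profiler that inspired this module is out
of scope; `sitewiseDnds()` is a declared counting substitute. Per codon
site, expected synonymous/non-synonymous site counts (per-position fraction
of non-stop single-base changes that are synonymous) and observed
differences (averaged over stop-free substitution pathways between the two
codons) are pooled over all sequence pairs; proportions are Jukes–Cantor
corrected and the ratio formed. Sites with no synonymous changes but
non-synonymous ones return `Inf` with an undefined upper bound; sites with
no changes return `NA`.

Uncertainty is the delicate part. A bootstrap over the `C(n,2)` pairs
treats them as independent, although every sequence participates in `n−1`
pairs; in simulation that yields intervals narrow enough to flag a large
fraction of genuinely neutral sites as constrained. The package therefore
bootstraps at the *sequence* level — resample sequences with replacement,
recompute the pooled counts over pairs of distinct resampled sequences —
and forms a normal interval on the log scale (ratios are log-symmetric, and
the raw percentile upper tail is inflated by low-information replicates),
falling back to percentile bounds where the point estimate or log spread is
undefined. A site is flagged *constrained* when the upper limit is below 1.

This calibration is honest about its power. In the recovery simulations (20
sequences, per-site acceptance probabilities 0.2 vs 1.0 for non-synonymous
changes, about three mutation events per codon site — the divergence at
which a power scan of the final estimator peaks; beyond it the Jukes–Cantor
correction saturates), false flags at neutral sites stay within the
one-site resolution of the fixtures, while sensitivity at constrained sites
is a clear majority of sites rather than near-complete. Detecting
per-site constraint from ~20 short sequences is simply a low-information
problem for a counting estimator; a model-based profiler that pools
information across sites and along a tree is the appropriate upgrade when
stronger sensitivity is needed.

## Orthology

`similarityScores()` computes Smith–Waterman local-alignment scores with
the same JTT-derived matrix and gap penalties for all cross-organism pairs
(the internal scorer is symmetric; both directions are recorded, and
external tabular scores can be substituted). `buildRbhGraph()` keeps an
edge only for reciprocal *unique* best hits — ties produce no edge, keeping
the construction deterministic — weighted by the smaller directional score.
`pruneToCliques()` scans current edges in ascending weight (ties
lexicographic on the gene-id pair), deletes the first edge whose endpoints
disagree on their neighbor sets, and restarts; at termination every
component is a clique whose members share identical ortholog sets.
Restarting after each deletion is the stricter of the two possible readings
of the iterative procedure and is verified in the tests against an
independent re-sorting reference implementation on random graphs.
Components of at least `min_group_size = 4` members are emitted (the
threshold is configurable because "more than four" and "minimum of four"
are both defensible readings; ≥ 4 is the default).

## The synthetic-data generator

`simulateDataset()` builds the study conditions the tests assume: one
contig per species; canonical loci planted as
`stop codon · ATG · NSS · variable region · domain(s) · extension · stop`
on either strand (probability 0.5 each) in random intergenic background
(default GC 0.4, mean spacer 300 nt). Defaults: 4 species on a caterpillar
tree, 5 one-to-one ortholog sets, one decoy per class per species, domain
count 1 plus a Bernoulli(0.2) second domain, no C-terminal extension with
probability 0.1, variable regions of 25–60 residues (prepropeptides of
roughly 60–120 residues, comfortably above the 50-residue ORF threshold, as
in the real family where genes this short are the extreme), ortholog
divergence 0.05 substitutions/site per tree edge under JTT.

Three contracts make planted truth exactly recoverable, all enforced by
rejection sampling at construction: every canonical domain beats the scan
threshold under the generating PSPM; signal templates (M + two basic
residues + a 10–12 residue hydrophobic core + A-x-A) score > 0.8 with the
template length as the cleavage call, and start selection on the
back-translated CDS picks the true start; and an in-frame stop immediately
precedes each planted start so the containing ORF begins exactly at the
gene. Decoy classes mirror the survey's rejection modes: "group II"-like
loci carry a domain sampled from a rotated, uniform-mixed PSPM and
rejection-sampled so that *no window of the locus* reaches the scan
threshold while the domain itself stays motif-like (background P-value
above 1e-8); signal-less loci use variable regions from residues that carry
neither charge, hydrophobic bulk, start codons nor cleavage-like smallness;
domain-less loci carry a valid signal only.

`simulateFamilyContrast()` emulates diversification by duplication for the
statistical contrasts: per assembly, a base gene is generated and each
paralog evolved from it at the configured within-genome divergence, so two
families differing only in that dial (or in codon GC bias, via
`exp(gc3_bias · GC-count)` codon weighting in back-translation) differ in
their true IOPD (or GC) distributions by a known shift.

What the generator does *not* emulate: introns and multi-exon models,
indel evolution (segment lengths are conserved within an ortholog set, so
within-set codon alignments are trivial), repeats and isochore structure in
the background, assembly gaps and sequencing error, and biased gene
conversion beyond the codon-choice dial. Passing recovery tests therefore
demonstrate the correctness of the scanning/selection machinery under the
family's canonical architecture, not robustness to annotation-grade messy
real genomes.

## Pipeline and provenance

`runPipeline()` validates the configuration before any stage runs, executes
the requested stages in order (discover → weighted PSPM → IOPD → orthology
→ dN/dS → GC), writes one TSV per stage with a header carrying the package
version, an MD5 hash of the serialized configuration and the seed, and
records per-file checksums in a manifest; reruns with identical
configuration are byte-identical. A stage failure halts the run naming the
stage and what had completed. The exported R functions are the pipeline's
interface; every stage is equally callable on its own.

## Problem sizes in the validation suites

The shipped tests run at desk scale by design: discovery recovery uses five
simulated datasets of 4 species × 5 ortholog sets plus 12 decoys each; the
clique-pruning oracle comparison uses 200 random graphs of 5–9 vertices;
distance calibration uses 50 replicates of 500-site pairs at true
divergence 0.3; the Tukey null calibrations use 1000 (rank) and 200 (logit)
replicates of direct draws plus 200 full pipeline replicates for the IOPD
null; dN/dS recovery uses 20 sequences × 30 codon sites with 300–1000
bootstrap replicates. These sizes were chosen so each property is measured
with useful resolution by an ordinary laptop R session.
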