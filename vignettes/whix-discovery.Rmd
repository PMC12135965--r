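---
title: "Discovering a bipartite T6SS secretion domain: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering a bipartite T6SS secretion domain: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(whixscan)
```

# The problem

Type VI secretion systems (T6SS) deliver toxic effectors into neighboring
bacteria. Cargo effectors are modular: a secretion domain mediates loading
onto the secreted spike, and one or two flanking toxic domains act in the
target cell. Defining a new effector class from sequence means (i) turning
one founding example into a sensitive sequence profile, (ii) finding and
delimiting the domain in a protein database, (iii) classifying the domain
architectures around it, (iv) checking the genomic context expected of
effectors (adjacent immunity-like genes, T6SS-encoding genomes), (v)
grouping the fused toxic domains into families, and (vi) confirming
secretion with comparative proteomics. `whixscan` implements each of these
steps and a synthetic-data module that plants all the structure the
analysis assumes, so the whole chain is testable against known truth.

# Profile model

## Scores

A profile of width $w$ holds, per column, half-bit log-odds scores
$s_j(a) = 2\log_2(p_j(a)/q(a))$, where $p_j$ are pseudocount-smoothed
column frequencies and $q$ the Robinson–Robinson background frequencies
(the BLAST null model; we adopt it because profile search methods in this
field inherit it and it is published and fixed). Smoothing blends observed
counts $c_j(a)$ with the background at a fixed total pseudocount mass
$\alpha$ (default 1):
$p_j(a) = (c_j(a) + \alpha q(a)) / (n_j + \alpha)$. With $\alpha > 0$
every score is finite; a column whose smoothed frequencies equal the
background scores exactly zero everywhere, so uninformative columns are
neutral in alignment.

Iteration 0 has no column counts: the profile is the seed sequence's rows
of a plain substitution matrix (BLOSUM62, which is already in half-bit
units).

## Alignment

Scanning uses local alignment with affine gaps (Gotoh recurrence),
position-specific match scores, gap open 11 and extend 1 in the same
half-bit units (the BLAST-like defaults). Opening a gap costs
open + extend; each further position costs extend. Unknown residues score
0 against every column. Multiple hits per subject are extracted by masking
the aligned subject interval and re-aligning (at most 4 rounds) — a
bipartite domain whose halves diverge at different rates can legitimately
produce two local hits, which the call-merging step reunites.

Numerical notes: the implementation is compiled (Rcpp) and follows the
identical recurrence as the quadratic-time R oracle used in the tests, so
scores agree to floating-point round-off; equal-scoring alignments
resolve deterministically because strict improvement is required to move
the best cell, which prefers the smallest subject start and then the
shortest alignment.

## E-values

Calibration scans $n$ background-sampled null sequences of length $L_0$
(defaults: $n = 300$, $L_0 = w$) and fits a Gumbel distribution to the
per-sequence maxima by maximum likelihood (moment-based start, Nelder–Mead
refinement). For a database of $N$ residues,
$E(S) = (N/L_0)\,P(\mathrm{max} \ge S)$, which is monotone nonincreasing
in $S$ and linear in search-space size. The analytic mode re-expresses the
fit as Karlin–Altschul $\lambda = 1/\beta$ and
$K = e^{\mu\lambda}/(wL_0)$; if the conversion degenerates (non-positive
parameters or failed convergence) the empirical fit is kept with a
warning. The tests hold the fit to a factor of two against a held-out
null of 10,000 maxima at the 99.9th percentile — about the accuracy one
can expect from a 2,000-sample Gumbel fit that far into the tail.

The search's inclusion threshold and the reporting threshold are the same
`e_max` (default $10^{-6}$); the underlying tools distinguish them but
the protocol we follow states only one value.

## Coverage and iteration

A subject is reported when the *distinct profile columns covered by all
of its hits* reach `min_coverage` (default 0.70) of the width — i.e.
coverage is interpreted per merged subject ("overall coverage of the
domain"), matching how a bipartite domain should be measured; per-hit
coverage is also recorded. Profile iteration keeps at most 500 subjects
per round (best E-value first), stacks their aligned residues onto seed
columns via the alignment maps, and rebuilds the smoothed profile;
columns no hit covers keep the seed-based estimate. Iteration stops at 5
rounds or when the included set repeats.

# Classification rules

* Subclass II iff the N-terminal extension exceeds 99 aa; otherwise
  subclass I. The boundary is exact (99 → I, 100 → II).
* `has_c_extension` uses a minimum tail of `min_c_ext = 10` aa: published
  counts of "no domain / truncated" proteins imply some cutoff but state
  none, so the parameter is explicit and documented.
* The WHxxxH motif is the leftmost literal match of W, H, any, any, any,
  H inside the domain interval; one motif per domain is reported.
* The conservation logo excludes gaps from frequency estimates (the
  WebLogo default) and applies no small-sample correction; per column,
  information is $\log_2 20 - H$ (Shannon entropy, bits) and letter
  heights are frequency × information. All-gap columns get zero content
  and a flag.
* Tree inference is out of scope by design: the reference-trimmed
  alignment is exported as FASTA for external tree builders.

# Genomic-context rules

* Upstream/downstream are strand-relative (operon logic: immunity genes
  sit downstream of their effector in transcription order).
* "Distance" in the duplicate-locus rule is the intergenic nucleotide gap
  between the focal gene and its immediate downstream neighbor (negative
  when genes overlap); gene-rank distance is an alternative but the gap
  matches how locus tables report context. Only the immediate downstream
  gene is compared — the rule says "the same downstream protein ... at
  the same distance", not the whole downstream context.
* The representative kept among duplicates is the lexically smallest
  genomic accession: deterministic and input-order independent.
* The census counts *distinct* core components (copies count once);
  positive at ≥ 9 of the 11 configured components. The component list is
  configurable (the canonical 11 are Hcp, VgrG, TssB, TssC, TssE, TssF,
  TssG, TssJ, TssK, TssL, TssM); supplying a different number raises a
  configuration warning but keeps the threshold unless overridden.

# Extension clustering

CLANS-style 2-D embedding is replaced by connected components on the
thresholded similarity graph: downstream consumers need cluster
membership, not coordinates. Edges are BLOSUM62 local-alignment scores
with an attenuation value `p_like` — the Gumbel tail probability of the
score under a null of residue-shuffled pairs from the same input set —
kept at `p_like` ≤ 10⁻⁴. The published analysis used an unstated cutoff;
ours is a documented default, not a reproduction. Components with < 4
members are labeled "others" and left unanalyzed; larger components are
named `family_k` in decreasing size order with ties broken by smallest
member accession, so labels are input-order invariant.

# Secretome enrichment

Per protein with at least two valid intensities per group:
difference = mean(WT) − mean(mutant) on the log2 scale, pooled-variance
Student *t*-test (the Perseus "Student's t-test" default; Welch via
`var_equal = FALSE`), and the three-gate pass rule difference > 3,
p < 0.02, score > 40. Choices worth flagging:

* The difference gate assumes **log-scale** intensities (MaxQuant LFQ
  convention). On raw-scale inputs "difference > 3" means something
  entirely different; the reader must map columns accordingly.
* No multiple-testing correction — the protocol filters on the raw
  p-value.
* No imputation: proteins failing the replicate minimum are reported
  untested rather than filled in, because the original imputation
  parameters are unstated. On real exports the enriched set should be
  checked with and without this rule.
* Degenerate inputs: zero variance in both groups gives p = 1 at equal
  means and p = 0 (flagged) otherwise.

# What the synthetic generator emulates — and what it does not

`synthetic_config()` defaults are the study conditions: 200 family
members among 2,000 decoys; a 477-aa seed region whose bipartite domain
comprises a 96-aa first region (motif-bearing), 144-aa linker and 206-aa
second region behind a 31-aa lead; 20 % per-site substitution; 16 %
subclass II with N-extensions of 100–160 aa; 96.5 % C-extension
frequency; 3 toxin families per terminus; genomes of 2 contigs × 12
genes with 8–11 distinct core components; LFQ tables of 400 proteins with
13 planted secreted at a 6-unit log2 shift, 0.5 noise SD, 3 replicates
per group. Within-family divergence is calibrated only to make recovery
tests meaningful — the real family's divergence distribution is not
published, so no claim is made of matching it.

Deliberate idealisations, hence limits on what passing tests show about
real data:

* Family members are iid mutants of one consensus — no phylogenetic
  correlation structure, no indels inside the domain. Real homologs at
  similar divergence with indels would stress the aligner more.
* The three motif anchor residues are held invariant under mutation: the
  motif is the family's defining conserved feature and the generator
  treats it as such. At `substitution_rate = 0` the whole consensus is
  exact.
* C-extensions default to ≥ 100 aa so that the 100-aa clustering window
  samples pure extension sequence. Shorter extensions make the window
  include shared-domain residues, which links families through the domain
  rather than the toxin — a real phenomenon the clustering stage cannot
  distinguish, and worth remembering when interpreting real "families"
  built from tail windows.
* The toy signal peptide is a fixed-composition 20-residue tag recognised
  by an equally toy predictor; real predictors are pluggable inputs, and
  nothing about their accuracy is tested here.
* LFQ noise is iid Gaussian with no missing-value mechanism; real
  label-free data are missing-not-at-random near the detection limit.
* Decoys are iid background residues; real non-homologs have composition
  biases that inflate local-alignment nulls. The E-value calibration
  samples the same background, so the zero-false-positive result is a
  statement about the calibration's self-consistency, not about
  low-complexity real sequences (composition-based score adjustment is a
  non-goal).

# Problem sizes and runtime choices

The default corpus (2,200 proteins, 477-column profile, 5 iterations)
runs the full profile stage in well under a minute on one core; tests use
a reduced geometry (118-aa consensus, 80 proteins) where the full corpus
adds nothing to the property being checked. Calibration uses 300 null
sequences in the pipeline and 2,000 + 10,000 (fit + held-out) in the
statistical tests. Oracle-equivalence tests run 1,000 random instances
up to 50×50 against a plain-R dynamic program.

# A note on the founding pair

The two founding effectors' N-terminal regions are reported as about 65 %
identical. Recomputing that number requires downloading the two accessions
and depends on the alignment method and identity denominator (alignment
columns vs shorter sequence), so the package documents the expectation —
a BLOSUM62 local alignment of the N-terminal/domain regions should land
near 65 %, with a few points' spread across methods — without asserting
it in the test suite.
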