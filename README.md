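# whixscan

Profile-based discovery and classification of a family of type VI
secretion system (T6SS) effectors that share a bipartite secretion domain
marked by a conserved WHxxxH motif.

Gram-negative bacteria use the T6SS to inject toxic effector proteins into
neighboring cells. Many "cargo" effectors are modular: a secretion domain
loads the protein onto the secreted spike, and one or two toxic domains do
the damage. `whixscan` implements the in-silico pipeline that defines such
an effector class from sequence alone, end to end:

1. **Profile search** — build a position-specific scoring matrix (PSSM)
   from a seed domain region, iteratively enrich it against a protein
   database (up to 500 included hits per iteration at E ≤ 10⁻⁶ and ≥ 70 %
   domain coverage), and scan databases with a native position-specific
   Smith–Waterman aligner (affine gaps) whose E-values come from an
   extreme-value fit to background-sampled null maxima.
2. **Classification** — merge per-protein hits into a single domain call
   (first-hit start to last-hit end), split effectors into subclass I
   (domain at the N-terminus) and subclass II (an N-terminal extension
   > 99 aa precedes the domain, the "double-blade" architecture), detect
   the WHxxxH motif, and compute a conservation logo on a
   reference-trimmed alignment.
3. **Genomic context** — extract gene neighborhoods, drop contig-end loci,
   collapse duplicate loci (same genome, same downstream protein at the
   same distance in another genomic accession), flag candidate immunity
   genes by signal-peptide calls, and census the 11 T6SS core components
   per genome (T6SS⁺ at ≥ 9 distinct components).
4. **Toxin-family clustering** — all-vs-all local similarity of N-terminal
   extensions and of the last 100 aa of C-extension-bearing effectors,
   thresholded against a shuffled-pair null; connected components with
   < 4 members are labeled "others".
5. **Secretome enrichment** — per-protein two-group comparison of
   label-free quantification (LFQ) intensities: a protein is enriched when
   mean difference > 3 (log scale), pooled-variance Student *t*-test
   p < 0.02, and identification score > 40.

A first-class synthetic-data module generates protein databases, genome
feature tables and LFQ tables with a ground-truth manifest, so every stage
is testable without downloads.

## The statistics at the core

For a profile of width *w* with column scores *s₁…s_w* (half-bit
log-odds of pseudocount-smoothed column frequencies over background
frequencies *q*), a subject is scored by local affine-gap alignment
(Gotoh). Per-sequence maximal null scores are fitted with a Gumbel
distribution (μ, β); the E-value of score *S* against a database of *N*
residues is

    E(S) = (N / L₀) · P(max ≥ S),   P(max ≥ S) = 1 − exp(−e^{−(S−μ)/β})

with *L₀* the null sequence length. The analytic mode re-expresses the
same fit as Karlin–Altschul parameters λ = 1/β, K = e^{μλ}/(w·L₀), giving
E = K·w·N·e^{−λS}. Enrichment p-values use the pooled two-sample *t*
statistic with n₁+n₂−2 degrees of freedom.

## Worked example

The numbered drivers under `analysis/` run the whole study on the default
synthetic corpus (200 planted effectors among 2,000 decoys, 20 % per-site
divergence, seed 101) and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_profile_search.R
# ... through 06
```

Printed output of the run:

```
corpus: 2200 proteins (200 family, 2000 decoys); seed region 477 aa
  subclass II: 14.5%; C-extension: 95.0%
profile converged after 2 iteration(s)
scan: 200 hits over 200 proteins
  sensitivity vs truth: 1.000; decoy hits: 0
annotated 200 effectors: 171 subclass I, 29 subclass II
  motif found in 100.0%; C-extension in 95.0%
loci: 221 raw -> 192 after contig-end and duplicate filters
  downstream immunity candidate at 100.0% of loci
census: 71.5% T6SS-positive; agreement with truth: 1.000
n_term: 29 sequences -> 3 named families (+0 in 'others'); cluster purity vs planted families: 1.00
c_term: 190 sequences -> 3 named families (+0 in 'others'); cluster purity vs planted families: 1.00
enriched: 13 of 400 proteins pass all three gates
  planted secreted recovered: 13/13; false positives: 0
  flagellar proteins among enriched: 3 (FlaB, FlgM, FliD)
```

Reading the numbers: the iterative profile recovers every planted family
member with zero false positives among 2,000 decoys; the subclass split
and motif calls match the manifest; the neighborhood filters remove the
planted contig-end and duplicate loci; clustering recovers the three
planted toxin families on each terminus; and the three-gate LFQ filter
recovers exactly the 13 planted secreted proteins, three of them
flagellar.

Equivalently, `run_whix_pipeline(synthetic_config())` runs all stages in
one call and returns the stage outputs plus a summary.

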