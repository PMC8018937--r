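---
title: "Quantifying cassette-exon usage from junction reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cassette-exon usage from junction reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceq)
```

## The problem

Tau, the product of *MAPT*, is expressed as isoforms with three or four
microtubule-binding repeats (3R, 4R) depending on whether the cassette
exon conventionally numbered exon 10 is skipped or included. Foetal human
brain expresses only 3R tau; the adult brain expresses 3R and 4R at
roughly equal levels, and the 3R/4R balance is central to tauopathies.
The same question — how much of a gene's output includes a cassette exon —
arises for *APP* exons 7/8 and for cassette exons generally.

Bulk RNA-seq answers it without assembling full transcripts: a read whose
spliced alignment skips an intron is direct evidence for one specific
exon–exon junction. Inclusion of a cassette produces two junctions
(upstream–cassette and cassette–downstream), skipping produces one
(upstream–downstream), so counting reads over three junctions suffices.

## The statistic

Let $X_{9,10}$ and $X_{10,11}$ be the read counts over the two inclusion
junctions and $X_{9,11}$ the count over the skipping junction (MAPT
numbering; the package generalises to any cassette event). The usage
percentage is

$$U = 100 \cdot \frac{\tfrac{1}{2}(X_{9,10} + X_{10,11})}{X_{9,11}},$$

with the mean taken over $k$ inclusion junctions in general. Under uniform
read coverage each junction is crossed with the same per-molecule
probability, so $E[X_\text{incl}] \propto f$ and
$E[X_\text{excl}] \propto 1-f$ for molar inclusion fraction $f$, giving
$U \approx 100 f/(1-f)$ — a 4R/3R odds on a percentage scale. The package
therefore also reports the inverse transform
$\hat f = U / (100 + U) \in [0, 1)$ as an inclusion-fraction estimate.
$U$ is undefined when $X_{9,11} = 0$ (a pure-inclusion sample, e.g. adult
rodent cortex for *Mapt*); `compute_usage()` flags this rather than
dividing by zero. $U$ is a within-sample ratio and is invariant to any
global rescaling of counts, so depth normalization (`normalize_depth()`,
reads per million) never changes it; it matters only when individual
junction counts are compared across samples.

## Gene models and conventions

A `gene_model` stores, per gene: isoform exon structures, strand, and
named cassette events given by their junctions. Conventions, chosen once:

* **Coordinates** are 1-based inclusive, as genome browsers and Ensembl
  print them. Half-open or intron-boundary formats are converted at the
  I/O boundary (`read_junction_table(dialect = "star_sj")` shifts the
  intron first/last base by ∓1; `read_gene_model(dialect_shift = TRUE)`
  does the same for model files).
* **Junctions** are keyed by their flanking exonic bases — the last base
  of the upstream exon and the first base of the downstream exon — in
  ascending genomic order with an explicit strand field, regardless of
  transcriptional orientation. Minus-strand genes such as porcine MAPT
  are therefore stored low-to-high even where the literature prints the
  spans high-to-low; alignment-derived junction evidence is
  strand-agnostic, and matching ignores strand.
* **Exon numbering** is carried as labels in the model file, so numbering
  conventions never affect computation.

The packaged fixtures (`gene_model_fixture()`) provide the porcine
(ENSSSCG00000017311, chr12) and human (ENSG00000186868, chr17) MAPT
exon 9/10/11 cassette models, and a toy cassette gene used by the
simulator: two 300-base constitutive exons flanking a 93-base cassette —
93 bases being the length the MAPT exon-10 cassette region spans between
its annotated junction flanks. In the MAPT fixtures the junction-flank
coordinates are the annotated values; the outer exon edges do not enter
any computation and are nominal.

`flatten_exon_bins()` cuts the union of all isoform exons at every exon
boundary, yielding disjoint bins with a constant set of contributing
isoforms — the DEXSeq-count style counting units used by
`count_exon_bins()` for exon-usage profiling. Models are validated to
keep at least one intronic base between exons of an isoform (adjacent
pieces should be merged), which makes this flattening identical to
labelling every exonic base with its isoform set and merging maximal runs.

## Junction extraction

`extract_junctions()` reads SAM-dialect records directly: for every skip
(`N`) operation it increments the junction between the last aligned base
before the skip and the first aligned base after it, provided both
flanking aligned blocks are at least `min_anchor` bases. Defaults, and
why:

* `min_anchor = 1` — any overhang counts. Junction-level counters in
  common use impose no long anchor by default, and the simulator applies
  the same setting on both the generating and counting side, so the
  ledger comparison is exact. Raising it trades sensitivity against
  misalignment artefacts on real data.
* Unmapped, secondary and supplementary records are skipped; duplicates
  are not removed. Library size is the number of primary mapped records
  processed — the choice is irrelevant to $U$ (scale invariance) and is
  recorded in the table attributes.
* A junction of an event that never appears in a sample is counted as
  zero with a warning, not an error: pure-isoform samples legitimately
  produce zero-count junctions.

## The simulator and what it does (not) emulate

`sim_config()`/`simulate_reads()` implement the minimal generative model
under which the usage statistic is an unbiased transform of $f$: fixed
read length, no positional bias, no sequencing error. `proportions` are
molar isoform fractions; a read's isoform is drawn with probability
proportional to `proportion × (transcript_length − read_length + 1)` and
its start uniformly over the valid starts of that transcript — i.e. every
valid read start in the pool of transcript molecules is equally likely.
This length weighting is what "uniform coverage" means for a mixture of
transcripts of unequal length; drawing isoforms by their molar fractions
directly would bias $U$ downward by the ratio of valid-start counts
(about 15% for the toy gene) and make the estimator inconsistent.

`simulate_reads()` emits a seeded toy reference (FASTA), spliced
SAM-dialect alignments, and a truth ledger listing every junction each
read spans with both anchors ≥ `min_anchor`, computed from the aligned
block widths exactly as the extractor sees them. Equality between
`extract_junctions()` output and the ledger is asserted over randomized
configurations in the test suite. `simulate_junction_table()` is the fast
path for statistical work: it draws per-isoform read totals
multinomially over the pool weights and each junction's count binomially
with its exact crossing probability
`(read_length − 2·min_anchor + 1) / (transcript_length − read_length + 1)`
(window clipped at transcript ends), skipping read generation.

Default conditions: $f = 0.148$ — the inclusion fraction whose
closed-form ratio $100 f / (1-f) = 17.37\%$ matches the adult-scale
porcine induced-neuron 4R/3R value — at $10^5$ reads of 75 bases.
The 75-base default is shorter than the 93-base cassette, so the two
inclusion junctions are spanned by distinct reads at default length;
longer reads produce double-skip alignments, which both the simulator
and extractor handle (each skip counts independently).

What passing these tests does **not** show about real data: no coverage
bias (fragmentation, GC, 3′ bias), no sequencing error or misalignment,
no multimapping ambiguity, no paired-end structure, single-gene models
only. The simulation validates the estimator arithmetic and the counting
machinery, not an aligner.

## Expression profiling

`compute_tpm()` uses the union-exonic length of the gene model as the
effective length: rate = count/length, TPM = rate rescaled to sum to
$10^6$ per sample, with `log2(TPM + 1)` alongside. All-zero samples
return zero with a warning rather than NaN. `count_exon_bins()` counts a
record into every bin one of its aligned blocks overlaps by ≥ 1 base, at
most once per bin per record (no fractional assignment). Relative usage
divides by the gene's summed bin counts, making it a within-gene
composition that sums to one and is invariant to expression level.
`compare_exon_usage()` adds a pseudocount of 0.5 to each raw bin count
before forming compared usages, so log ratios stay finite on unobserved
bins; genes silent in one condition are flagged rather than dropped.
A read-to-gene assignment subtlety: a record counts toward a gene if it
overlaps at least one of that gene's bins.

## qPCR standard-curve quantification

`fit_standard_curve()` regresses Cq on $\log_{10}$(relative template
amount) over a pooled-cDNA dilution series (≥ 3 distinct dilutions);
efficiency is $10^{-1/\text{slope}} - 1$, exactly 1 at slope
$-1/\log_{10} 2 = -3.321928$. Technical triplicates are summarized by
mean Cq before interpolation (the replicate s.d. is carried into
reports); quantities are $10^{(Cq - \text{intercept})/\text{slope}}$,
normalized per sample to the geometric mean of the reference genes
(GAPDH and HPRT1 by default), and the 4R/3R percentage is the ratio of
normalized quantities × 100. Wells above a Cq cutoff (default 38,
covering no-RT and water controls) are excluded and reported, not used
numerically. Degenerate fits (zero or positive slope) are flagged and
refuse interpolation. No inter-plate calibration is attempted: the
workflow models single-run relative quantification against one pooled
curve. `simulate_qpcr()` forward-simulates Cq from known quantities under
the same curve model, so the pipeline is testable end-to-end: noise-free
input is inverted to machine precision, and Gaussian-noise input is
recovered within Monte-Carlo tolerance.

## Numerical and design notes

* Summaries report the sample standard deviation ($n-1$) with $n$, the
  convention of "mean ± s.d., n = …" figure captions; $n = 1$ yields an
  `NA` s.d. rather than 0.
* Report TSVs use 6-decimal fixed formatting for reproducible diffs;
  rerunning a deterministic pipeline byte-reproduces its reports.
* All randomness flows through explicit integer seeds; the simulators
  save and restore the caller's RNG state.
* Problem sizes used by the validation suite — 200 replicates of $10^5$
  reads for estimator recovery, 50 randomized configurations of up to
  5,000 reads for extractor–ledger equivalence, 50 random models for the
  flattening oracle — were chosen to bound the Monte-Carlo error of each
  check well below its assertion tolerance.

## Limitations

Only junctions named in a gene model enter usage statistics (novel
junctions are retained in raw tables but unused); no differential-usage
or differential-expression testing is performed (use DEXSeq/DESeq2
downstream); alignment itself is out of scope — inputs are spliced
alignments or junction tables. Published 4R/3R ratios from real tissue
can only be reproduced from the corresponding raw sequencing runs; the
package's simulations validate the estimator, not any specific dataset.

## A worked session

```{r example}
# three simulated replicates at the adult-scale inclusion fraction
toy <- gene_model_fixture("toy")
res <- lapply(1:3, function(s) {
  jt <- simulate_junction_table(sim_config(n_reads = 1e5, seed = s))
  compute_usage(jt$table, toy$events$TOY_4R)
})
summarize_samples(res)
```
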