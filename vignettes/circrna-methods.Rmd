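---
title: "Methods: simulation-validated circRNA detection and characterization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation-validated circRNA detection and characterization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`backsplice` re-implements a circRNA identification and characterization
workflow for bulk RNA-seq as a closed loop: a read simulator that plants
circRNAs with known coordinates, fractions and genomic context, and an
analysis chain whose every stage can be checked against that truth. This
vignette explains the models, the parameters that matter, and the design
choices made where the methodology was genuinely open.

## The detection model

Exonic circRNAs are detected through junction-spanning reads. For every
gene we enumerate candidate junctions from the annotation: one *linear*
junction per adjacent exon pair, and one *back-splice* junction for every
ordered exon pair (a, b) with a ≤ b (transcript order) whose genomic span
is at least `min_span` (default 200 nt, mirroring the minimum fusion
distance commonly used by spliced aligners for circRNA work). A probe is
the concatenation of the last `anchor` nt of the donor exon and the first
`anchor` nt of the acceptor exon (default 50 + 50), built from
reverse-complemented exon sequence for minus-strand genes. A read supports
a junction when it contains the probe's central 2×`anchor_min` nt (found by
exact k-mer seeds, split into `max_mismatch + 1` segments so a within-budget
match always contains an exact seed), matches the probe with at most
`max_mismatch` substitutions over the read–probe overlap, and overhangs the
junction by at least `anchor_min` (default 25 nt, the common minimum mapped
length) on both sides. Each read counts for at most one junction; ties
between junctions are discarded rather than double-counted, so neither circ
nor linear evidence is inflated.

Detection is annotation-guided by design: no attempt is made to discover
junctions outside the annotated exon set, which buys an exact truth oracle
and determinism at desk scale. Annotation-free discovery, fusion detection
and non-canonical splice motifs are out of scope.

A circRNA is called when at least `min_reads` (4) back-spliced reads are
observed in each of at least `min_samples` (2) samples. The support rule
"at least four back-spliced reads in at least two different samples" admits
a second reading — at least 4 reads pooled, present in 2 samples — which is
exposed as `mode = "pooled"`; the stricter per-sample reading is the
default.

## What the simulator emulates

Each simulated gene is one linear isoform: uniform-random exons
(150–300 nt) separated by log-uniform introns (300–1500 nt, long right
tail). A fixed fraction of genes with ≥ 3 exons (default 0.3) is selected
to circularize; a circle is an internal exon run with genomic span
≥ 200 nt, so both flanking introns exist. Host-gene introns are multiplied
by `circ_intron_mult` (default 3), reproducing the observation that introns
flanking circularized exons are longer than average. With probability
`rcs_plant_prob` (0.8) a copy of the Alu-like consensus (~300 nt) is
written into the downstream intron and its reverse complement into the
upstream intron (transcript orientation, strand-aware on the genome) — the
inverted-repeat pairing geometry believed to promote circularization.

Per sample, each gene receives a negative-binomial molecule count
(mean `depth / n_genes`, dispersion `nb_dispersion` = 0.1). At circ genes a
binomial split sends a fraction `circ_fraction` of molecules to the
circular form; the default 0.1 reflects the low circ:linear molarity seen
in immune cells. Every non-reference group multiplies the circular odds by
`2^effect_log2fc` (default 2-fold, patients higher), emulating elevated
circRNA output under disease. The default group layout is 4 healthy vs 6
patient samples, matching a small discovery cohort. Fragments
(N(300, 30) nt) are placed uniformly on the linear transcript, or uniformly
on the circle with wrap-around (circular permutation), so reads crossing
the back-splice carry last-exon→first-exon sequence; 126-nt mates are read
from both fragment ends. Substitution errors are off by default — detector
mismatch tolerance is tested explicitly, not implicitly.

The truth table annotates each read with the single junction it spans at
≥ `anchor_min` overhang. Because the minimum exon length (150 nt) exceeds
`read_len − 2·anchor_min` (76 nt), a read can satisfy the overhang rule for
at most one junction, which is what makes detector counts equal truth
counts *exactly* at zero error rate — an equality asserted in the tests
across seeds. Features of real data deliberately not emulated: empirical
error and quality profiles, GC and positional bias, isoform diversity,
intronic/intergenic circles, and expression heterogeneity across genes.
Passing tests therefore validate the logic of the pipeline, not its
robustness to alignment artifacts in real libraries.

## Quantification

The back-splice-to-linear ratio of a called circle is
`mean(c) / max(mean(l1), mean(l2))` with means taken over all samples
(subset via `samples =` for per-group summaries): `c` is the back-splice
junction count and `l1`, `l2` are the linear junctions flanking the circled
exons. A zero denominator yields an *undefined* ratio, excluded from
summaries and counted, rather than an infinity that would wreck medians.
Summaries report median and quartiles by linear interpolation.

The circ-vs-host comparison is a classical paired t test on per-pair mean
log2(x+1) of median-of-ratios-normalized counts; the transform is a
package choice (variance stabilization), as the underlying methodology
does not state one. The degenerate all-zero-difference case is defined as
t = 0, p = 1.

## RCS screening and significance

The screen aligns revcomp(upstream intron) against the downstream intron
with local (Smith–Waterman) alignment, scoring match +1, mismatch −1, gap
open 5, gap extend 2 (a gap of length L costs 5 + 2L). These values favor
long, high-identity inverted repeats; the original tooling's scoring is not
public, so the scores are validated against a brute-force DP oracle rather
than against published values. Introns longer than `max_len` (5000 nt) are
truncated to the window nearest the circle — the side where pairing must
occur — and flagged.

Significance is empirical: `n_shuffles` dinucleotide-preserving shuffles of
the upstream intron (random Eulerian-path / Altschul–Erickson shuffle, which
exactly preserves dinucleotide counts and the terminal bases), realigned to
the downstream intron, give `p = (1 + #{shuffled ≥ observed}) / (n + 1)`.
The shuffle preserves local composition, so composition alone (e.g. an
AT-rich intron pair) cannot create significance. Because alignment scores
are integers, ties with the observed score make this p conservative on
short sequences; the null-calibration simulations therefore use 400-nt
introns, where the score distribution is spread enough for the rejection
rate at α = 0.05 to stay within the tested 0.05 ± 0.02 band, while shorter
null loci under-reject. A planted perfect 300-nt inverted repeat is
unreachable by any shuffle, so such loci attain the lower bound
p = 1/(n+1).

Repeat annotation is an in-house gapless identity matcher against the
simulator's consensus library (classes: Alu-like, simple, none): every
alignment offset of each consensus (both orientations) is scanned for
`min_len` (50 nt) windows at ≥ `min_identity` (80 %) identity; hits are
merged per class and reported as covered fraction plus intervals. It is a
deliberate simplification — no indels, no divergence model, no genome-wide
masking — sufficient for consensus-planted simulations, and it is not a
replacement for a full repeat annotator on real genomes.

## miRNA seed sites

Target prediction is reduced to exact 7-mer seed complementarity: the DNA
reverse complement of miRNA nucleotides 2–8, counted with overlaps in exon
sequence (transcript orientation). This is deterministic and
oracle-checkable, unlike minimum-free-energy hybridization, and is
documented as a deviation, not an equivalence. Densities (sites per kb) are
compared between exons inside called circles and all other exons with a
two-sample Kolmogorov–Smirnov test on the empirical CDFs; density rather
than raw counts is the default so exon-length differences cannot confound
the comparison (raw counts can be passed directly when wanted).

## Differential abundance

Counts are normalized by median-of-ratios size factors (geometric-mean
centered; total-count fallback when no feature is positive everywhere).
The two-group test is an in-house negative-binomial Wald test: per-feature
moment dispersion pooled across groups (floored at 1e-8), delta-method
standard error of the log2 fold change from Var(K) = μ + φμ², and a t
reference with n1 + n2 − 2 degrees of freedom — the normal reference is
anti-conservative at n = 6 per group, while the t reference keeps the
type-I error inside the [0.03, 0.07] band asserted by the test suite's
null simulation. No numerical equivalence to shrinkage-based DE tools is
claimed; dispersion shrinkage and covariates are non-goals. Significance
follows padj ≤ 0.05 (Benjamini–Hochberg) with point-estimate linear fold
change ≥ 1.5; a nominal-p flag is also emitted because circRNA studies at
small n often report nominal sets.

One practical caveat surfaced by simulation: when most circRNAs carry the
group effect, size factors estimated from the circ count matrix absorb the
effect completely. The pipeline therefore estimates library scaling from
the linear junction counts and passes it to `nb_test`.

## Numerical and engineering choices

- 1-based inclusive coordinates throughout; `circ_id` is
  `contig:min-max` regardless of strand, matching the usual printed form.
- Determinism: every stochastic operation draws from a seed supplied in
  the configuration (stage seeds are fixed offsets of the master seed);
  RNG state is saved and restored around seeded internals. Identical
  configurations produce byte-identical FASTA/GTF/FASTQ/TSV outputs, and
  the run manifest records MD5 hashes to prove it.
- Alignment ties in `pairwiseAlignment` are resolved deterministically by
  the library; reported spans are one optimal alignment.
- Degenerate inputs are defined, not crashed on: empty FASTQ files parse;
  empty intron sides flag the RCS result undefined; zero-mean DE features
  are skipped with a flag; undefined ratios are excluded and counted.
- Problem sizes in the tests (e.g. 100-gene cohorts at depth 50 000 for
  recovery, 1000 loci for null calibrations, 2000 features for DE
  operating characteristics) were chosen as the smallest sizes at which
  the binomial/NB noise of the measured property is well inside its
  assertion band.

## Known limitations

Single isoform per gene; exon-only circles; no sequencing-error model
beyond uniform substitutions; annotation-guided detection only; gapless
repeat matching; seed-only miRNA site model; two-group DE without
covariates. These bounds are inherited from the goal — a fully
truth-validated desk-scale pipeline — rather than from the biology.
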