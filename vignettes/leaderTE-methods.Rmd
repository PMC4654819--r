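---
title: "Methods: translational efficiency, transcript-leader features and TSS fingerprints"
author: "leaderTE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: translational efficiency, transcript-leader features and TSS fingerprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leaderTE)
```

## The problem

Polysome profiling compares two RNA populations per cell state: *total*
cytoplasmic mRNA (the transcriptome) and mRNA engaged by two or more
ribosomes (the polysomal fraction, an operational translatome). A gene's
**translational efficiency (TE)** is the ratio of its polysomal to total
abundance; genes whose TE *changes* between two cell states (here labelled
generically `case` and `control`) are candidates for translational
regulation. Because genes with multiple transcription start sites (TSS)
produce mRNAs differing only in their 5′ transcript leader (TL), the same
data also ask a finer question: are specific TSS variants of a gene
recruited onto polysomes preferentially in one cell state? leaderTE
implements the count-level statistics for both questions, the sequence-level
annotation of TL features that explain differential recruitment (uORFs,
Kozak context, cap-proximal starts), and a simulator that plants known
effects so every stage can be validated end-to-end.

## Depth-equalising down-sampling

Libraries differ in sequencing depth, so raw fragment counts are rescaled
before any ratio is formed. For sample $n$ with depth $x_n$ (the column sum
of its counts) the rescale factor is

$$\mathrm{factor}_n = \frac{x_n}{\min_i(x_i)},$$

with the minimum taken within the sample's group, and every count is
divided by its sample's factor. Total and polysomal libraries are
normalised independently by default (`grouping = "by-fraction"`): the two
fractions sample different molecular populations, so each is equalised to
its own shallowest library, which passes through unchanged.

Two deliberate numerical choices:

* **Deterministic division, not stochastic sub-sampling.** The factor is a
  scalar rescale; dividing is exact, reproducible, and makes the
  conservation property (equal within-group column sums after
  normalisation, to ~1e-16 relative) testable to machine precision. No
  stochastic mode is provided.
* **No re-rounding.** Normalised counts are kept as reals; rounding would
  break conservation and add noise with no benefit downstream.

Depth is taken from the supplied count table itself (the total alignment
count of the original libraries is not recoverable from a gene-level
table); this is self-contained and monotone in the library's true depth.

## The binned Z-score TE statistic

Per gene, normalised counts are averaged over the replicates of each of the
four condition × fraction cells, giving expressions
$E_{c,f}$. The differential-TE statistic is

$$\Delta = \log_2\!\left(
  \frac{E_{\mathrm{case,poly}} / E_{\mathrm{case,total}}}
       {E_{\mathrm{ctrl,poly}} / E_{\mathrm{ctrl,total}}}\right).$$

The sampling noise of $\Delta$ depends strongly on expression level, so
$\Delta$ is standardised against genes expressed at a similar level: genes
are sorted ascending by their **minimum expression** (the lowest of the four
$E$ values), cut into consecutive bins of 300, and each gene's Z-score is
$(\Delta - \mu_b)/\sigma_b$ with $\mu_b, \sigma_b$ the mean and
standard deviation (denominator $n-1$) of its bin. Genes with $z > 2$ are
called up-regulated, $z < -2$ down-regulated (strict inequalities).

Open choices, resolved as follows:

* **Log2 before Z-scoring.** Only "fold change" is prescribed by the
  approach; the log scale makes up- and down-regulation symmetric, and the
  label-swap antisymmetry (swapping `case`/`control` negates every $\Delta$
  and $z$ exactly) becomes an exact invariant that the tests assert. A raw
  `scale = "ratio"` mode is retained for sensitivity analysis.
* **Two-sided calling on $|z|$** with the sign giving direction, since both
  up- and down-regulated sets are of interest.
* **Remainder merge.** A trailing bin of fewer than 300 genes would have an
  unstable standard deviation; it is merged into the preceding bin, so 650
  genes form bins of 300 and 350.
* **Ascending sort, ties broken by gene id** — bit-reproducible bin
  membership.
* **Zero handling.** The TE ratio is undefined at zero expression. The
  default is hard filtering (any gene with a zero cell mean is reported as
  `filtered`, never called); an optional global pseudocount is available.
  Filtering never fabricates a direction, which is why it is the default.

Under the null (no planted effects) roughly
$2(1-\Phi(2)) \approx 4.6\,\%$ of genes should exceed $|z| = 2$ if
$\Delta$ is approximately normal within bins; the acceptance checks verify
the observed rate lies in $[3.5, 5.5]\,\%$ on 6000 simulated genes. This
is a calibration of the *ranking*, not a false-discovery control: the Z-cut
is a candidate-selection rule, and no multiple-testing correction is
applied or claimed.

## Transcript-leader annotation

All coordinates are 0-based half-open internally; written reports are
1-based inclusive. Sequences are canonicalised to uppercase DNA (U → T).
The TL of a transcript is `sequence[0, cds_start)`.

For every ATG in the TL (overlapping occurrences included) the scanner
translates forward in that frame through the *full* transcript to the first
stop codon and classifies:

* `upstream` — the stop ends at or before the principal start; a classical
  uORF. `n_codons` counts sense codons *including* the initiator ATG and
  *excluding* the stop; `gap_to_main` is the nucleotides strictly between
  stop and principal ATG. This convention reproduces the published worked
  examples (a 1-codon uORF is an AUG followed immediately by a stop; a
  5-codon uORF spans 18 nt), so it was frozen after that validation.
* `in_frame_extension` — frame 0 and no in-frame stop before the principal
  start: initiation here yields an N-terminally extended protein.
* `overlapping` — out of frame, first stop (if any) at or beyond the
  principal start; `n_codons` is defined only when a stop exists.

Kozak strength uses the two dominant context positions: strong = purine at
−3 *and* G at +4, moderate = exactly one, weak = neither; positions beyond
the sequence are padded with N, which satisfies neither. (Published usage
sometimes calls a purine-only context like ACCAUGC "relatively strong";
under this three-class scheme it is `moderate` — a vocabulary difference
only.) Upstream AUGs closer than `cap_threshold` (default 15 nt,
configurable) to the 5′ end are flagged cap-proximal: a 43S subunit loaded
at the cap is unlikely to recognise a start that close, the documented
example being a uAUG 12 nt from the cap. The exact cutoff is a tool
parameter, not a biological claim.

## TSS fingerprints and gradient summaries

For each gene with more than one TSS, transcript abundances are pooled by
`tss_id`, averaged over replicates per condition × fraction, and converted
to proportions — the gene's TSS fingerprint in that RNA population.
Fingerprints are compared with the Jensen–Shannon divergence with base-2
logarithms (symmetric, 0 iff equal, bounded by 1), both between fractions
within a condition (differential recruitment onto polysomes) and between
conditions within a fraction (promoter shifts). Cells whose gene total is
zero propagate as missing, never as zeros. The JSD is a transparent
descriptive score, not a calibrated test; for uncertainty a permutation
test over replicate labels is provided (statistic: JSD of group-mean
fingerprints; add-one rule $p = (1 + k)/(n_{\mathrm{perm}} + 1)$). With
3 + 3 replicates the permutation resolution is coarse (20 distinct splits,
so $p \gtrsim 0.1$); the p-values are honest but weak at triplicate scale,
which is why the JSD itself is the primary ranking.

Gradient summaries normalise per-fraction signal intensities (e.g.
quantitated RT-PCR bands) to a distribution and report the mass over
user-supplied masks (`polysome_share` over fractions at ≥ disomes,
`heavy_share` over heavy fractions). The light/heavy boundary is an
experimental labelling choice, so masks are inputs, never inferred.

## The synthetic-data generator

The generator emulates the target study design and is itself first-class,
tested code:

* **Counts.** 2 conditions × 2 fractions × 3 replicates. Per-gene baselines
  are log-normal (log2 mean 6, sd 2 — counts centred near 64, spanning the
  few-counts to few-thousand range typical of bulk RNA-seq); counts are
  negative-binomial with variance $\mu(1+\phi\mu)$, $\phi = 0.1$, a
  standard bulk overdispersion; per-sample library factors are uniform on
  [0.7, 1.3]. TE effects are planted multiplicatively on the **polysomal
  mean only**, so transcriptional and translational effects are separable
  in the truth table. A floor (`regulated_min_mean`) restricts planting to
  well-expressed genes when requested.
* **Transcripts.** TL backgrounds are generated by a character-level
  sampler that can never emit an ATG (when the running 2-mer is "AT" the
  next base excludes G), so planted uAUGs are provably the only ones; uORF
  bodies reject in-frame stops and stop codons are chosen so they cannot
  complete a spurious ATG at a junction. The emitted truth table is exactly
  what the scanner must recover, which turns annotation testing into exact
  field-for-field comparison.
* **Usage.** Multi-TSS genes draw Dirichlet fingerprints (concentration 5);
  a planted subset redraws the polysomal fingerprint independently,
  rejecting redraws with JSD < 0.05 bits from the total fingerprint so that
  every planted shift is genuinely distinct — without the floor, an
  independent redraw occasionally lands next to the original and the
  "planted" shift has no magnitude to recover.

One master seed drives everything; each component derives its own stream
(seed × small multiplier + component index), so adding draws to one
component never shifts another, and identical spec + seed reproduces the
dataset bit-for-bit.

What the simulator does *not* model: read-level artefacts (alignment,
multi-mapping, GC bias), batch effects, correlated replicates, or
transcript-abundance estimation error. Passing tests therefore demonstrate
that the statistics are implemented correctly and behave as designed under
idealised NB sampling — not that the pipeline is robust to the full error
structure of real libraries.

## Problem sizes and runtime choices

The bundled analyses and checks use 6000 genes × 12 samples for the count
pipeline (19 bins of 300 after filtering), 500 planted transcripts plus
1000 fully random transcripts (length ≤ 500, GC 0.25–0.75) for the scanner
oracle comparison, 200 multi-TSS genes for usage, and 1000 null genes × 200
permutations for the p-value calibration. These sizes give stable estimates
(binomial sampling error on the null call rate at 6000 genes is ≈ 0.27
percentage points) while keeping a full run in seconds to a couple of
minutes.

## Known limitations

* The Z-cut ranks candidates; it is not an error-controlled test, and no
  replicate-level variance model (NB GLM) is fitted.
* Only ATG starts are scanned; near-cognate initiation is out of scope, as
  is RNA secondary structure.
* The TSS permutation test is underpowered at triplicate scale by
  construction (see above).
* Reproducing the specific gene lists of any published cell-line comparison
  requires that study's raw reads and alignment; the package validates the
  statistics on synthetic data and on constructed reference architectures
  instead.
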