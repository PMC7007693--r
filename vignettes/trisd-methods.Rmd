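---
title: "Inferring transcriptional regulators by chromatin landscape modeling and in silico deletion"
author: "trisd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring transcriptional regulators by chromatin landscape modeling and in silico deletion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trisd)
```

## The problem

Differential-expression and co-expression experiments produce gene sets,
and the recurring question is *which transcriptional regulators (TRs)
drive them*. Direct evidence — a TR ChIP-seq experiment in the matching
cell type — is usually unavailable, and even when a cistrome (the
genome-wide binding-site set of a TR) is at hand, linking binding sites to
the genes they regulate is not trivial: enhancer–gene maps are incomplete,
several enhancers can serve one gene, and not every binding site is
functional. `trisd` addresses this with two ingredients: per-gene
**regulatory potentials** that integrate genomic signal around each TSS,
and **in silico deletion (ISD)** of candidate cistromes from a
gene-set-specific chromatin model.

## Regulatory potentials

For gene $k$ with TSS $t_k$ and a chromatin profile $j$ binned into 1-kb
windows with mean signal $s_{jm}$, the chromatin regulatory potential
(chrom-RP) is

$$R_{jk} = \sum_{m :\, |mid_m - t_k| \le L} w(|mid_m - t_k|)\, s_{jm},
\qquad
w(d) = \frac{2e^{-\mu d / L}}{1 + e^{-\mu d / L}},$$

with $L = 100$ kb and $\mu = \ln(3)\,L/\Delta$ chosen so that
$w(\Delta) = 1/2$ at the decay distance $\Delta = 10$ kb. The weight is 1
at the TSS, falls to one half 10 kb away, and is
$2\cdot 3^{-10}/(1+3^{-10}) \approx 3.4\times 10^{-5}$ at 100 kb.
The **peak-RP** is the same sum with binary occupancy (1 for each 1-kb
window containing a peak summit) in place of signal; it scores a cistrome
directly against a gene without any chromatin data.

Two conventions deserve a note, because several published descriptions of
this kernel family are ambiguous:

* **The decay-rate parameterization.** A literal reading of the commonly
  printed expression for $\mu$ yields a negative rate. We fix
  $\mu = \ln(3)\,L/\Delta$, the only parameterization under which the
  weight decays and $\Delta$ is a meaningful half-decay distance
  ($e^{-\mu\Delta/L} = 1/3$ reproduces the conventional factor 3).
* **Binned evaluation.** The chrom-RP is evaluated on the 1-kb grid
  (window-midpoint distances), not per-nucleotide. This makes the ISD
  subtraction *exactly* self-consistent — deleting every window in range
  drives the RP to zero, and the per-window deletion term $w_m s_{jm}$
  matches the per-window accumulation term. Any sub-1-kb discrepancy with
  a per-nucleotide evaluation is accepted in exchange.

A window contributes if and only if its midpoint lies within
$[t_k - L,\, t_k + L]$; the interval is truncated at chromosome ends; the
last, possibly partial window of each chromosome keeps its actual span so
binning conserves signal mass. Strand places the TSS but does not flip the
(symmetric) kernel. Raw RPs are normalized per profile as
$R'_{jk} = \log(R_{jk}+1) - c_j$ with $c_j$ the mean of $\log(R+1)$ over
all genes (natural log throughout; the mean is over the full annotation,
written $K$ here — sources that print the denominator once as $k$ and once
as $K$ are read as the latter).

## The chromatin landscape model

Given a query gene set, the package samples a background of 3000 genes
(default) from the non-query universe, stratified into promoter-activity
deciles so the background matches the universe's activity distribution —
an activity-matched control rather than a uniform draw, with no
gene-ontology filtering. The covariate is a single per-gene
promoter-activity value stored in the compendium; in the synthetic data it
is derived from mean accessibility around the TSS. We match the
*universe's* stratum proportions (not the query's): the contract is
representative sampling across the activity range, and matching the query
instead would build the query's activity bias into the null. Sampling is
without replacement and deterministic given the seed.

An L1-penalized logistic regression of query membership on the normalized
chrom-RP columns selects the few profiles (cap 10) that discriminate query
from background. The penalty is found by binary search on the
log-penalty scale — bounds auto-expanded, at most 50 bisections — and the
search returns the *weakest* penalty whose nonzero-coefficient count is
within $[1, 10]$, i.e. the largest admissible model under the cap.
Features are standardized internally so the penalty treats profiles
comparably regardless of dynamic range. The final model is refit on the
selected profiles with an essentially unpenalized logistic regression
(ridge $10^{-6}$, for stability under perfect separation — a refit, not a
re-application of the L1 penalty); coefficients $\alpha_j$ are reported on
the normalized-RP scale, so the **model-RP** is simply
$\alpha_0 + \sum_j \alpha_j R'_{jk}$. Discrimination is summarized by the
rank-based (Mann–Whitney) ROC AUC.

One known behavior of the L1 step: if two candidate profiles are exact
duplicates, coordinate descent may keep both with split weights rather
than zeroing one. This cannot inflate a duplicate's influence — the summed
coefficients equal the single-column coefficient and predictions are
unchanged — but callers should not read "both selected" as independent
evidence.

## In silico deletion

Deleting cistrome $i$ zeroes the signal in its occupied 1-kb windows. On
the binned convention the deleted RP needs no re-scan:

$$\tilde R_{ijk} = R_{jk} - \sum_{m \in M_{ik}} w_m s_{jm},$$

summing over the cistrome's windows inside the gene's $\pm L$ interval
($\tilde R$ is clamped at 0 against rounding). Deleted RPs are
renormalized **with the original offsets** $c_j$ — recomputing the offset
after deletion would let a large cistrome shift every gene's baseline.
The per-gene effect of the deletion is

$$\Delta R'_{ik} = \sum_j \alpha_j\,(R'_{jk} - \tilde R'_{ijk}),$$

with the model coefficients frozen (no refitting). Genes with no occupied
window within $\pm L$ get an exact zero and are skipped; $\Delta R'$ is
computed only for query and background genes, the only ones entering the
test. When all $\alpha_j \ge 0$, $\Delta R' \ge 0$ and is monotone in the
deleted support.

## Evidence channels and ranking

Each candidate cistrome yields up to three one-sided Wilcoxon rank-sum
p-values comparing query against background genes: the peak-RP channel
and one ISD channel per assay (DNase-seq and H3K27ac). The test is
one-sided because deleting a *true* regulator should lower the model's
score for query genes specifically. A cistrome whose $\Delta R'$ is zero
on every tested gene gets $p = 1$ for that channel — in a one-sided test,
no effect is evidence of no effect — rather than being dropped. The
channels are combined with the Cauchy combination test,

$$t = \frac{1}{d}\sum_{i=1}^{d} \tan\{(0.5 - p_i)\pi\}, \qquad
p_{comb} = \tfrac12 - \arctan(t)/\pi,$$

with $d = 3$ for ChIP-seq cistromes and $d = 2$ (the two ISD channels)
for motif-imputed cistromes. The Cauchy combination is robust to
dependence between channels, which matters because the two ISD channels
share the background genes and often the underlying biology. Component
p-values are clamped to $[10^{-15}, 1-10^{-15}]$ before the tangent
transform, which diverges at 0 and 1; combined p-values are therefore
floored near $10^{-15}$. Cistromes are ranked by combined p; ties break by
the smaller mean ISD p, then lexicographically by cistrome id, so rankings
are deterministic. The per-TR summary takes the minimum combined p across
that TR's cistromes; no multiple-testing correction is applied across
cistromes — the output is a ranked list, not a thresholded call set.
Up- and downregulated gene sets should be analyzed as two separate runs.

The Wilcoxon test uses the exact rank-sum distribution when the smaller
sample has at most 8 observations and there are no ties, otherwise the
normal approximation with tie and continuity corrections
(`stats::wilcox.test` underneath).

## Motif-imputed cistromes

Where TR ChIP-seq is unavailable, PWM scanning imputes binding: the
genome is tiled into non-overlapping 100-bp windows, each scored by the
best log-odds placement over both strands and all offsets that fit
entirely inside the window (pseudocount $0.001\times$background mixed in
before the log, so zero entries stay finite; placements covering an `N`
are excluded). Per motif, hits are windows whose score *strictly* exceeds
the genome-wide 99th percentile (linear interpolation) — strictness keeps
the hit fraction at or below 1% under ties — and hits are mapped to the
1-kb window containing the tile midpoint. Tiling (rather than overlapping
100-bp windows) is a documented choice; with stride-1 placements inside
each tile, a motif on a tile boundary can only lose one tile's worth of
score. The same hit sets drive the direct/indirect partition of a ChIP
cistrome (occupied windows with vs without the TR's own motif), whose
peak-RPs are percentile-normalized before rank testing so halves of very
different sizes remain comparable.

## The synthetic compendium

Real compendia are external resources; the package instead generates a
synthetic one whose *statistical structure* matches what the method
assumes: a planted regulator whose peaks fall within $\pm\Delta$ of query
TSSs, and a subset of informative profiles whose signal is elevated at
those peaks.

Defaults (chosen once, as the desk-scale study conditions): 2 chromosomes
of 5 Mb, 400 genes on a jittered uniform grid, 12 profiles per assay of
which 3 are informative, 30 cistromes, 60 query genes, log-normal
background signal (log-sd 1) with a boxcar enrichment of `effect_size`
(default 5) at planted-peak windows $\pm 1$, and decoy peaks at rate 0.01
per window (~100 per decoy cistrome; the planted cistrome carries 1–3
peaks per query gene plus 20 uniform peaks). Query genes are the
planted-peak neighbors, matching the causal direction of the model. The
geometry runs the full pipeline in a few seconds while still exercising
the sparse-deletion paths.

`effect_size = 1` is the calibrated null: no structure is planted at all —
the "true" cistrome is drawn exactly like a decoy, every profile is pure
noise, and the query is a simple random sample — so the planted cistrome
is exchangeable with the decoys and its p-values are uniform. This is a
deliberate semantic: an `effect_size = 1` compendium with peaks still
tethered to query TSSs would *not* be null for the peak-RP channel, whose
statistic depends only on geometry.

What the generator does **not** emulate: read-level noise and mappability
artifacts, TAD structure and long-range contacts, copy-number and GC
biases, correlated profiles from related cell types, and realistic motif
composition of real genomes. Passing tests on fixtures therefore validate
the machinery and its statistical calibration, not performance on real
compendia.

## Numerical choices and degenerate inputs

* Coordinates are 0-based, half-open throughout (BED convention); TSS =
  `start` for `+` genes, `end − 1` for `-` genes read from BED.
* One TSS per gene id; duplicate ids are an error (isoform collapsing is
  the caller's job, so each gene's RP is well defined).
* Peak summit defaults to the interval midpoint when no summit column is
  present; a peak spanning a window boundary occupies only its summit's
  window.
* Background selection allocates strata by largest-remainder rounding
  (per-stratum error below 1 before pool-shortage repair) and falls back
  to *all* non-query genes, with a warning, when fewer than the requested
  3000 exist — the desk-scale fixtures always take this path.
* Store files are a single versioned container with an MD5 checksum over
  the serialized payload; version mismatches and byte-level corruption
  fail loudly at load time, and round-trips are bit-identical.
* The L1 binary search errors with "no informative profiles" if even a
  vanishing penalty selects nothing (constant features).
* Gene identifiers resolve exactly first, then case-insensitively (with a
  logged count); unmatched identifiers go to a sidecar file.

## Problem sizes used in the checks

The test suite validates the RP and deletion engines against brute-force
per-window oracles on ~100 random genes (tolerance $10^{-9}$ relative),
rank-sum p-values against exhaustive enumeration at small $n$, null
calibration of the planted cistrome's p-values over 50 null-compendium
seeds (KS test at $\alpha = 0.01$), and end-to-end recovery of the
planted regulator at rank 1 of 30 cistromes across 20 seeds of the
default fixture. The chromatin model's AUC exceeds 0.9 on default
fixtures; the half-weight distance inverts to 10 kb; L1 tuning on a
50-profile compendium stays within the 10-profile cap.

## Known limitations

* The compendium store holds one genome; multi-genome stores, liftover
  and FASTQ/BAM-level processing are out of scope.
* Peak-RP and ISD depend on a single representative TSS per gene;
  isoform-level regulation is invisible.
* The background covariate is one-dimensional; stratification cannot
  jointly match several activity axes.
* The Cauchy combination's $10^{-15}$ clamp floors combined p-values;
  ranks below that floor are resolved by the documented tie-breaks.
* Motif-imputed cistromes inherit PWM quality; the scanner does no
  machine-learned binding imputation.
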