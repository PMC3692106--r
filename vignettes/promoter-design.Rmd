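---
title: "Designing synthetic plant promoters from expression and motif data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing synthetic plant promoters from expression and motif data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promdesign)
```

## The problem

A plant promoter is, to a first approximation, an arrangement of short
cis-regulatory motifs in the few hundred base pairs upstream of the
transcription start site (TSS), sitting on top of a minimal promoter
(TATA box, Y-patch, initiator) that drives basal transcription. Public
*Arabidopsis* resources annotate two complementary things genome-wide:
expression (tissue panels with triplicate log2 RMA values; diurnal time
courses sampled every 4 h over 44 h) and motif occurrences (7-bp motifs
from co-expression analysis, annotated within 200 bp of the TSS; 8-bp
motifs from word-frequency analysis, within 500 bp). If a gene expresses
exactly where or when you want your transgene to express, the motifs on
its promoter are candidate building blocks for a synthetic promoter with
that pattern.

promdesign implements that workflow as a library: mine expression tables
for extreme genes, retrieve their motifs, and arrange the motifs on a
TSS-relative canvas.

## Coordinate conventions

All positions are TSS-relative. The base immediately upstream of the TSS
is position $-1$; a canvas of length $L$ covers $-L \dots -1$ and position
$0$ does not exist (designs are strictly upstream). A motif of length $k$
whose most-upstream base sits at $s$ occupies $s \dots s+k-1$ and is
identified by its **center** $s + (k-1)/2$ — an integer for odd $k$, a
half-integer for even $k$. This reproduces the half-integer-center
convention of the motif sources exactly, and it is enforced at read time:
no annotation with the wrong parity or a footprint outside
$[-\text{region width}, -1]$ can enter the system. The motif sources did
not document whether their distances were recorded signed or unsigned; we
fix signed-negative-upstream throughout.

On export, GFF3 features are written in 1-based inclusive coordinates on a
contig of length $L$ via $\text{pos}_{1} = \text{pos} + L + 1$, always on
the sense strand (reverse-complement placement is out of scope).

## Mining tissue panels

Replicates are collapsed by mean or median (`summarize_replicates()`; the
choice matters only under asymmetric noise). `normalize_by_gene()`
re-expresses each gene relative to its own mean across conditions —
subtraction on the log2 scale, division on the linear scale, so the
per-gene mean of normalized values is exactly 0 or 1 respectively. Log2
panels are mined as-is, with no back-transform to linear intensities.
`build_rank_list()` then orders all genes for one property (condition ×
direction × normalization); ties break lexicographically by gene ID, so
every ordering is deterministic and reproducible.

`motif_express()` walks the rank list and returns the first $k$ genes
carrying at least one motif annotation. Genes without motifs are passed
over and recorded in the result's `skipped` field — the fallback to the
next most extreme gene is part of the method's contract, not an error.
`motif_ranking()` is the same walk with $k = 10$, for choosing among
variant expression patterns.

## Circadian fitting

Each diurnal series (linear scale, by default 12 points at
$t = 0, 4, \dots, 44$ h) is fit by harmonic regression with the period
fixed at 24 h:

$$ y(t) = m + a\cos(2\pi t/24) + b\sin(2\pi t/24) $$

with amplitude $A = \sqrt{a^2+b^2}$ and phase $\varphi$ the clock time in
$[0,24)$ at which the fitted curve peaks. Because the model is linear in
$(m, a, b)$, the least-squares optimum is available in closed form (a QR
solve); we deliberately use this instead of an iterative nonlinear
optimizer — for a single fixed-period harmonic the optimum is identical,
and the closed form cannot fail to converge. Two design choices deserve
note:

* **Period fixed at 24 h.** A free-period fit is unidentifiable from 12
  points over 44 h, and the phase concept ("time of day when expression
  peaks") presumes a 24-h clock.
* **Normalized amplitude is $A/m$.** "Fold-change" has no unique formula
  for an oscillation around a mean; $A/m$ is the symmetric
  half-peak-to-midline ratio, defined whenever $m > 0$. The alternative
  $(m+A)/(m-A)$ ranks identically for equal $m$, diverges as $A \to m$,
  and was rejected for that instability.

Degenerate inputs are handled explicitly: fewer than 3 points or a design
whose times collapse modulo 24 h raise an error; a constant series fits
with $A = 0$, `rmse = 0`, and phase reported as 0 by convention.

`circadian_rank()` buckets genes by fitted phase into the 4-h bins
$\{0, 4, 8, 12, 16, 20\}$ — aligned to the sampling grid, the natural
discretization of "time of day when expression peaks" for 4-h sampling —
and ranks within the bin by $A$ (or $A/m$), descending.
An empty bin is legal and yields an empty rank list; the downstream
selection then reports "no candidate genes".

## The design canvas

`new_design(L, baseline)` creates an all-dash canvas; dashes are the
empty-position sentinel, and a design is a sequence of motifs separated by
empty base pairs until `fill_baseline()` copies the baseline base into
every remaining dash (idempotent, and it can never change
`diff_from_baseline()`, which only reports *written* bases that differ
from the baseline).

Placement resolves overlaps by an explicit `ConflictPolicy` —
`keep_existing`, `use_new`, or `fail`. An interactive front-end can ask
the user which sequence wins an overlap; a library must be transactional
instead, so `fail` raises before any mutation and multi-placement
operations (`collect_all_motifs()`, `stack_motif()`) validate fully before
writing, aborting atomically on the first conflict. The CLI default is
`fail`, the safe non-interactive choice. Note that `fail` treats *any*
occupied footprint position as a conflict, even if the incoming base
matches — occupancy, not base identity, is what the policy arbitrates.

`stack_motif()` places an anchor copy plus $n$ extra copies strictly
upstream at center pitch $k + s$, so adjacent footprints are separated by
exactly $s$ empty positions. "Extra" means extra: $n$ extra copies yield
$n + 1$ placed motifs. Stacking downstream is excluded — the strategy
exists to tile the region upstream of a chosen site.

`suggest_position()` is a frequency heuristic, not a binding-energy model:
the most frequent center among identical motif sequences in the annotation
table, ties to the center closest to the TSS, and for unseen motifs the
closest-to-TSS center that fits ($-1 - (k-1)/2$). Upstream motif
databases ship their own predictors of where a motif is most effective;
those are separate methods that we do not reimplement.

Every operation appends one entry to the edit log (multi-placement
operations append a single summarizing entry). The log is line-delimited
JSON and is the design's persistent state: `replay_design()` applied to a
fresh canvas reproduces canvas, placed-motif list and baseline diff
exactly, and the CLI's design verbs persist state only through this file —
a diff-able, inspectable workflow history rather than a binary blob.

## Synthetic data and what the tests show

The package generates all four input kinds with planted ground truth:

* **Tissue panels**: per-gene constant background drawn uniformly from
  6–10 log2 units (a typical RMA intensity band), planted additive log2
  effects in chosen tissues, additive Gaussian replicate noise (default
  sd 0.1 log2 units). Additive Gaussian noise on the stated scale is the
  simplest model consistent with RMA-style summaries.
* **Diurnal series**: $y(t) = m + A\cos(2\pi(t-\varphi)/24)$ plus Gaussian
  noise on the linear scale, on the 12-point schedule. The peak-time
  parameterization matches the phase concept users select by. Noise can
  in principle push a linear value to zero; values are floored at machine
  epsilon to preserve the positive-scale invariant. Real diurnal noise
  characteristics are not documented upstream; the fixture's `noise_sd`
  is a test parameter, not a claim about real data.
* **Motif tables**: uniformly placed random sequences honoring each
  profile's length and region width. Motifs are decorative here — no
  motif–expression causal link is simulated, so passing tests demonstrate
  the mining/placement machinery, not biological enrichment.
* **Promoters**: i.i.d. bases at a stated GC fraction (default 0.36,
  typical of *Arabidopsis* upstream regions).

Every generator is a pure function of (parameters, seed). The test suite
checks closed-form fits against an independent grid-search oracle, mining
selections against brute-force scans (including forced fallback cases),
stacking against a hand-layout oracle over random $(k, n, s)$, and replay
determinism over randomized designs. Problem sizes — 200 genes for
recovery, 100 randomized mining trials, canvases of a few hundred bp —
were chosen to exercise the contracts thoroughly while keeping the full
suite fast enough to run on every change.

## Limitations

Fitting is single-harmonic: genes with non-sinusoidal rhythms get the
best 24-h cosine approximation, not a rhythmicity test (no JTK-style
statistics). Motif discovery, RMA preprocessing of raw arrays, reverse
strand placement, homology screening of designed sequences and synthesis
vendor constraints (GC windows, repeats) are all out of scope. Designs are
candidate sequences; nothing here predicts whether a placed motif is
functional in its new context.
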