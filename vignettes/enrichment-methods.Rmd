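---
title: "Methods: thresholded gene sets and dual-tail hypergeometric enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thresholded gene sets and dual-tail hypergeometric enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(yeastmarks)
```

## The procedure

`yeastmarks` implements over-representation analysis (ORA) of chromatin
features for yeast gene lists. The pipeline has three stages.

**1. Regions.** Every gene is reduced to two codon anchors: the first base of
the start codon and the (exclusive) end of the stop codon, both in
transcription direction. The promoter is the window from 500 bp upstream to
100 bp downstream of the start codon; the coding region runs from the start
codon to the stop codon, both codons included. Yeast genes are treated as
codon-anchored intervals — no transcript isoforms, UTR models or introns —
which is the appropriate granularity for *S. cerevisiae* promoter analysis.
Internally all coordinates are 0-based half-open, so interval arithmetic is
unambiguous; GFF3 (1-based inclusive) and wiggle (1-based) inputs are
converted on read, bedGraph is native. "Upstream" and "downstream" are
interpreted strand-aware: for a minus-strand gene with start-codon base `a`,
the promoter is the genome interval `[a-99, a+501)`, the mirror image of the
plus-strand `[a-500, a+100)`. Promoters running off a chromosome end are
clamped to the chromosome, not discarded, so the universe of genes is never
silently reduced; away from edges every promoter is exactly 600 bp.

**2. Sets.** For each signal dataset (a ChIP-chip/ChIP-seq track of, e.g.,
`log2(mark/H3)` values, or a precomputed per-gene score table) and each
region kind, the *maximal* data value over the gene's region is extracted. A
gene "contains" the mark when that maximum is at or above a user threshold;
the comparison is inclusive (`>=`), exactly as a user would read it off a
threshold slider. Any interval overlapping the region by at least 1 bp
contributes — the simplest defensible overlap rule for probe-level data whose
exact placement conventions vary by platform. Genes whose region carries no
signal at all score *missing*: they can never enter a mark set, but they stay
in the universe `F`, so `F` is a property of the annotation alone (6572 for
the reference yeast annotation) and does not drift with data coverage.
Regulator target sets are taken as curated input (promoter-binding calls at
5% FDR in the reference data), keyed by regulator and condition (25°C/37°C
heat shock in the reference map; the condition is a free-text tag so other
designs, e.g. H2O2 stress tracks, reuse the same mechanism).

**3. Test.** For an input list `R` (resolved case-insensitively against
systematic names and aliases; unresolved names are reported, never dropped,
and only resolved genes count toward `|R|`), each set `S` is tested with the
exact hypergeometric tails

$$P_{\text{enrich}} = P(x \ge |T|) = \sum_{x=|T|}^{\min(|S|,|R|)}
\frac{\binom{|S|}{x}\binom{|F|-|S|}{|R|-x}}{\binom{|F|}{|R|}}, \qquad
P_{\text{deplete}} = P(x \le |T|)$$

where `T = S ∩ R`. Fold enrichment is the observed ratio `|T|/|R|` divided by
the expected ratio `|S|/|F|`.

## Numerical choices

Binomial coefficients at genome scale (e.g. $\binom{6572}{538}$) overflow
doubles by hundreds of orders of magnitude, so the probability mass is
computed as log-gamma differences (`lchoose`) and tails are accumulated by
log-sum-exp. Tails that underflow the double range are reported as exactly 0
— a genuine statement that the p-value is below ~1e-308 — and the volcano
export maps such rows to a capped $-\log_{10} p$ of 320 with an explicit
`capped` flag, so plots stay finite without inventing precision. Outcomes
outside the support (`R − x > F − S`) carry probability zero (−Inf in log
space). The test suite checks both tails against an exhaustive subset-
enumeration oracle on tiny universes, against a direct binomial-ratio
summation over every valid count combination with `F ≤ 60` (relative error
well under 1e-12), and against `stats::phyper` at genome scale; the analytic
identity $P_{\text{enrich}} + P_{\text{deplete}} = 1 + P(x = |T|)$ is
verified up to `F = 200`.

Display rounding follows the conventions of the reference result tables:
p-values in scientific notation with 3 significant figures, ratios as
percentages with 2 decimal places, fold to 2 decimals. The TSV reports use
these display rules; the JSON reports mirror every column at full double
precision (17 significant digits, which round-trips exactly).

## Multiple testing and calls

Both tails of every mark are tested; this is deliberate — depletion calls
(e.g. of repressive marks in active genes) are first-class results. The
correction family structure is a design choice the underlying procedure
leaves open: `yeastmarks` corrects within three separate families per run —
marks × promoter, marks × coding, and regulators — counting the two tails of
a mark as separate hypotheses in its family. Raw tail p-values are always
reported next to the corrected ones, so any other family convention can be
recovered from the output. Regulator sets are tested for enrichment only,
matching how regulator results are defined in the reference procedure.

A trend is called when the corrected tail p-value is below `alpha`
(default 0.01). `analyze()` never filters: every hypothesis is returned with
a `significant` flag, and the report writer decides whether to print all
rows (the "no p-value cutoff" view, where non-significant rows show trend
`none`) or only calls. In the CLI, `--no-cutoff` therefore conflicts with
`--alpha` and is rejected. If both tails of one set pass — possible only in
degenerate tiny universes — the smaller-p tail is reported with a warning.
Sets that are empty at the chosen threshold (`S = 0`) are flagged
*untestable* rather than failing the run; `T = 0` yields fold 0 by
convention. When the input list is the whole universe, every observed ratio
equals its expected ratio, fold is 1 and nothing is called.

## Tunable parameters

| parameter | units | default | why |
|---|---|---|---|
| signal threshold | signal units (log2 ratio or MAT score) | 1 per track, user-set | `log2 >= 1` means 2-fold over background, the conventional cutoff for calling a region marked |
| `alpha` | corrected p | 0.01 | stringent default so that calls survive family-wise correction at genome scale |
| `correction` | — | `bonferroni` | conservative default; `fdr` (Benjamini–Hochberg) for exploratory runs |
| promoter window | bp | −500 … +100 around the start codon | the fixed region convention of the underlying procedure |

## The synthetic-data generator

`synthetic_plan()`/`generate_study()` emulate the structure of the real
inputs — interval-valued log2-ratio tracks over a small genome, a planted
high-signal gene subset per mark, curated regulator maps with two
temperature conditions, and a gene list with a controlled overlap with the
first ("focal") mark's planted subset. Genes are laid out non-overlapping
with alternating strands, so strand-aware promoter extraction is exercised
by construction; signal intervals are placed strictly inside the promoter
(300–400 bp upstream of the start codon) and strictly inside the coding
region (200–300 bp downstream), so a placement error in either region
definition flips test outcomes. Interval values are Gaussian around
`signal_high` (planted) or `signal_low` (background): signal values are log
ratios, for which additive Gaussian noise is the standard surrogate. The
defaults — 1000 genes on 4 chromosomes, planted fraction 0.2, high 3, low 0,
sd 0.1, a 50-gene input drawn from the planted subset — give noiseless
separation at threshold 1 (the levels sit 20–30 standard deviations from the
cutoff), so planted membership is recovered exactly and the expected
`T, R, S, F` are known by construction and recorded in `truth.json`.
Everything is deterministic given the seed, to the byte.

What the generator does *not* emulate: probe-level microarray noise and
spatial autocorrelation, MAT scoring, real sequence composition, gene-length
and gene-density heterogeneity, or correlated marks. Passing the planted
recovery tests therefore demonstrates that the region logic, thresholding
and statistics are correct — not that any particular biological threshold is
appropriate for a given real dataset.

## Validation scale and known limitations

The validation suite runs at deliberately modest problem sizes chosen to
probe each property sharply: exhaustive oracle enumeration on universes up
to 12 genes, the full count sweep at `F ≤ 60`, per-base brute-force signal
oracles on ≤10 kb fixtures, and ten replicate 1000-gene planted studies for
end-to-end recovery. Null marks in those studies have independently drawn
planted subsets, so under Bonferroni at `alpha = 0.01` the residual
family-wise false-call probability is below 1% per family per replicate;
it is a property of the statistics, not something the generator removes.

Limitations worth knowing: the universe `F` is whatever the supplied
annotation contains — the package does not curate dubious ORFs; per-gene
score tables bypass region extraction entirely, so their provenance is the
user's responsibility; BigWig input is not parsed (convert to bedGraph or
wiggle first); and combinatorial queries over multiple marks are out of
scope — each mark is tested marginally.
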