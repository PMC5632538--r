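---
title: "cernet: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cernet: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cernet)
```

# The problem

Honey-bee queen oviposition can be switched on and off experimentally:
virgin queens (`V`) begin laying after insemination (`Q`), stop when caged
(`C`) and resume within a day of release (`R`). Profiling ovary lncRNA,
miRNA and mRNA expression across these four states (three queens each,
twelve libraries) lets one ask which non-coding RNAs move with the
oviposition switch, and whether they act on miRNAs as *targets* (repressed
by the miRNA) or as *decoys* (competing-endogenous RNAs that sponge the
miRNA away from its mRNA targets). `cernet` packages that analysis as a
tested, reusable pipeline: lncRNA screening, count-based differential
expression for the three transitions (`Q_V`, `C_Q`, `R_C`), correlation
screens, binding-site scanning, ceRNA network assembly, QTL
co-localization and over-representation testing — plus a synthetic-study
generator that plants known structure so every stage has a measurable
truth.

# Candidate lncRNA screen

Novel transcripts survive the cascade iff spliced length ≥ 200 bp, exon
count ≥ 2, assembler coverage ≥ 3, presence in ≥ 2 libraries, no overlap
with a known non-lncRNA transcript, and a noncoding call. All criteria are
evaluated for every record, so reports list *every* violated criterion and
the outcome is order-independent.

Coding potential is deliberately a transparent heuristic rather than a
port of an SVM/HMM tool: the longest forward-frame ORF (ATG to first
in-frame stop, stop included) calls a transcript coding when it reaches
300 nt or half the transcript. Only forward frames are scanned because
assembled transcripts are strand-resolved. External coding/noncoding calls
can be supplied to `filter_candidates()` to override the heuristic.
"Coverage" is read as the assembler-reported mean depth attribute and
"identified in at least two samples" as the transcript's sample-presence
set; both are carried on the GTF records.

# Differential expression

The two-group count test mirrors the classic NB pipeline structure without
porting its local-regression machinery:

* median-of-ratios size factors, `s_j = median_g x_gj / geomean(x_g.)`,
  estimated once per RNA class (miRNA libraries are sequenced separately
  from long-RNA libraries, so their depths are unrelated);
* per-feature moment dispersion from normalized counts,
  `phi = max(0, (v - m)/m^2)` with the within-group pooled variance,
  shrunk halfway toward the across-feature mean and floored at `1e-8`;
* Wald statistic: `log2((m_B + 0.5)/(m_A + 0.5))` over a delta-method
  standard error built from the NB variance `mu + phi mu^2`, two-sided
  normal reference; all features reported; BH adjustment within each
  RNA-class-by-contrast family.

The 0.5 pseudo-count makes fold changes finite at zero counts; the
within-class BH choice mirrors per-class DE tallies (the alternative,
pooling classes, is not what separate library types support). Calibration
is enforced by simulation tests (type-I fraction within [0.025, 0.075] at
nominal 0.05; sensitivity ≥ 0.7 and empirical FDR ≤ 0.10 on 4-fold planted
changes), not by matching any reference tool numerically. A known
limitation: with n = 3 per group the normal reference is slightly liberal
in the far tail, which is visible as empirical FDR estimates fluctuating
around 8% across simulation seeds.

Displayed expression uses the published transforms `log10(FPKM) + 1` and
`log10(TPM) + 1`; since both are undefined at zero, the package computes
`log10(v + 0.01) + 1`. Sample clustering is Euclidean/complete-linkage on
these transforms, with lexicographic sample ordering so ties break
deterministically.

The qPCR helper implements `10^(-dCt/slope)` scaled so the calibrator
group (virgin queens) averages 1. The published formula prints as
`quantity = 10 − ΔCt/slope`, which is typographically garbled; the
standard-curve convention above is the only reading that yields relative
quantities.

# Correlation screens and binding-site scanning

Trans-acting lncRNAs are paired with mRNAs at |Pearson r| ≥ 0.95 across
the twelve samples; network pairing uses |r| > 0.8 (either sign). All
correlations are computed on `log2(normalized counts + 1)` — the source
analysis correlates expression-scale values without stating a transform,
and the log scale keeps a handful of extreme counts from dominating a
12-point correlation. Zero-variance features are excluded and counted.

The site scanner is a seed-weighted Smith–Waterman local alignment of the
reversed miRNA against the scan region (match +5, G:U wobble +2, mismatch
−3, gap open −8, gap extend −2, miRNA positions 2–8 doubled), with duplex
energy from a simplified nearest-neighbor stack table (GC/GC −3.3, AU/AU
−1.1, mixed −2.1, any wobble −1.0 kcal/mol). Sites are extracted greedily
by descending score with non-overlap masking, and retained iff score > 140
and energy < −10 kcal/mol — the published retention thresholds. The scorer
itself is a documented stand-in for Miranda, validated against an
exhaustive dynamic-programming oracle and against planted sites; it makes
no claim of thermodynamic accuracy (no loop entropies, no conservation).
Genes without an annotated 3′ UTR are scanned over the 1,000 bp downstream
of the stop codon, reverse-complemented for minus-strand genes.

A consequence of the scoring arithmetic worth knowing: a perfect
full-length complement of an L-nt miRNA scores 5L + 35, so only miRNAs of
≥ 22 nt can produce a retained perfect site. The synthetic generator
therefore draws site-carrying (triad) miRNAs from 22–24 nt.

# ceRNA network

The cited decoy/target classification method is not described in the
source; `cernet` adopts standard ceRNA logic as its own reconstruction:
for each (lncRNA, miRNA) pair with site evidence, the lncRNA is a *target*
when `r(lnc, mir) ≤ −0.8`, and a *decoy* when it instead co-varies at
`≥ +0.8` with an mRNA already paired to that miRNA. miRNA–mRNA edges
require site evidence **and** |r| > 0.8 by default (`require_site = FALSE`
gives the correlation-only variant, since the source is ambiguous on this
point). Differential-expression membership for network nodes is the union
over the three contrasts; nodes left without an admitted edge are dropped,
which enforces the published rule that every network RNA sits in a
lncRNA–miRNA or miRNA–mRNA pair. Bridge genes are mRNAs adjacent to ≥ 2
distinct miRNAs. QTL co-localization takes DE features fully contained in
chr11:8.9–12.2 Mb (any-overlap semantics behind a flag). Enrichment is a
plain hypergeometric upper tail with BH — a simplification of
length-bias-corrected ontology tools, accepting any category map.

# What the generator emulates — and what it does not

`simulate_study()` produces a 12-sample, 4-group design with log-normal
baselines (median ≈ 150 counts), NB dispersion 0.05, log-normal library
factors (sd 0.2), 10% DE per contrast planted along the V→Q→C→R chain with
|log2FC| ~ U(1, 3), 50 ceRNA triads, planted full-complement binding sites
(1–3 copies per target, in both the mRNA 3′ UTR and the lncRNA), 5% of
long features inside the QTL window, and a 7-record filter fixture (one
violator per criterion plus one compliant candidate).

Design choices that shape what a green test establishes:

* **Coupling acts on group means.** With n = 12 in four groups, sample
  correlations are dominated by the four group means; coupling is
  therefore planted at the group-mean level. Each triad has a latent
  centered unit profile over the groups; a driven partner gets
  `sqrt(c)·latent + sqrt(1−c)·orthogonal noise` (c = coupling strength),
  making partner profiles correlate at exactly `±sqrt(c)` before counting
  noise. A looser construction (noise not orthogonalized) would place a
  fifth of triads below the 0.8 screen purely by 4-point sampling
  variation, which is not the stated world.
* **Decoy triads co-vary with the miRNA.** In target triads the mRNA and
  lncRNA move opposite to the miRNA; in decoy triads both move with it —
  the expression-level signature of effective sponging, and the only sign
  structure under which the decoy classification rule can recover the
  planted roles. The pairing rule accepts either correlation sign, so both
  triad types contribute miRNA–mRNA edges.
* **Triad amplitude 2 (log2 sd across groups).** Large enough that
  between-group variation dominates NB noise — the regime an |r| ≥ 0.8
  screen on 12 samples can detect at all.
* **Triad lncRNAs are emitted as known lncRNAs**, so network recovery does
  not depend on the filter cascade; the cascade is tested on its own
  planted fixture. Real studies intertwine the two; the tests deliberately
  do not.

The generator does not emulate: read-level noise or mapping artifacts,
isoform structure, sequence composition bias (sequences are i.i.d.
uniform), dispersion trends with expression level, batch effects, or
partial/imperfect binding sites. A green end-to-end run therefore
establishes that the pipeline's logic recovers planted structure under its
own statistical assumptions — not that those assumptions hold for any
particular real dataset.

# Numerical and degenerate-input conventions

Internal coordinates are 0-based half-open; GTF converts at the boundary,
BED is native. `log10(0)` guards use ε = 0.01. Zero-variance features are
excluded from correlation screens with a logged count. A group with
all-zero counts yields p = 1 with a warning. Alignment-traceback ties
prefer diagonal over gap-in-region over gap-in-miRNA; best-cell ties take
the leftmost region position. Clustering tie-breaks follow lexicographic
sample order. All randomness flows from one seed per run; every output
file header records package version, seed and a configuration hash, and
identical seeds give byte-identical output trees.

# Known limitations

* The DE test's far-tail behavior at n = 3 is slightly liberal (see
  above); analyses needing strict FDR control at small n should prefer a
  dedicated tool with moderated inference.
* The scanner's energy model is a stack-sum, not a full nearest-neighbor
  folding model; its absolute kcal/mol values are comparable only within
  this package.
* The decoy/target rule is a reconstruction; with site evidence but weak
  correlations a genuinely decoy-acting lncRNA is simply dropped.
* Enrichment ignores feature-length bias.

# A worked example

```{r example, eval = FALSE}
library(cernet)
res <- run_pipeline(tempfile("cernet-"),
                    params = sim_params(n_mrna = 300, n_lncrna = 60,
                                        n_mirna = 30, n_triads = 10,
                                        seed = 7))
res$network
#> <ce_network: 30 nodes (lncRNA 10, miRNA 10, mRNA 10), 20 edges
#>  (lnc_mir_decoy 6, lnc_mir_target 4, mir_mrna 10)>
head(res$qtl$members)
res$bridges
```

The printed network above is the output of that exact call: the ten
planted triads are recovered as ten miRNA–mRNA edges plus ten
lncRNA–miRNA edges with the planted decoy/target split.
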