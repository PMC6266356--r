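---
title: "Methods: a testable HIF-1α ChIP-Seq target screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a testable HIF-1α ChIP-Seq target screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrescreen)
```

## The screen

`hrescreen` re-implements, as a tested pipeline, a genome-wide screen for
direct HIF-1α target genes from transcription-factor ChIP-Seq of mouse
bone marrow under benzene exposure. The scientific logic is a funnel:

1. call regions of IP enrichment over an input control (peaks);
2. find peaks whose enrichment *drops* in the exposed condition
   (down-regulated differentially enriched peaks, DEPs);
3. keep DEPs whose summit lies in a promoter (TSS ± 2 kb) and assign the
   gene;
4. keep genes whose enriched region contains the hypoxia response element
   (HRE), 5′-(A/G)CGTG-3′ — the HIF-1α binding site;
5. optionally keep genes with curated biological function, count pathway
   overlaps with hypergeometric enrichment, and validate expression by
   qPCR (2^−ΔΔCt with ANOVA/LSD statistics).

The raw data behind the original study are not deposited, so the package
ships a synthetic-data generator with planted ground truth; every stage is
exercised end to end against that truth, and the two tabular worked
examples that *are* printed in full (pathway hit counts; the qPCR
validation table) are transcribed as fixtures and recomputed.

## Synthetic data model

`sim_config()` fixes the reference design: a 2 Mb genome (2 × 1 Mb
chromosomes of i.i.d. uniform bases), 200 genes laid out with ≥ 4.2 kb
inter-gene gaps so TSS ± 2 kb promoter windows are pairwise disjoint,
~200,000 single-end 150 bp reads per sample from fragments sheared
uniformly to 150–900 bp. Thirty genes (15%) are "bound": their IP samples
receive Poisson-distributed extra fragments whose centres are Gaussian
(sd 100 bp) around an HRE 5-mer planted at a uniform offset in the
promoter window. Binding drops 4-fold in the exposed condition. Input
samples are uniform background only.

Two generator choices deserve comment.

**Binding rate.** The study conditions pin the genome size, gene count,
number of planted targets, read depth and the 4-fold reduction, but not
the absolute binding strength. A design-time power analysis showed that at
~200k reads/sample on 2 Mb the background fragment-centre density is
0.1/bp (coverage depth ≈ 25 per sample at 250 bp extension), so a
promoter receiving only tens of binding fragments would sit at ≈ 1.4×
local enrichment — invisible to any caller and far below what a real
sharp transcription-factor ChIP shows. The defaults
(`bind_rate_control = 300`, `bind_rate_exposed = 75`) place bound summits
at roughly 4–5× local background and put ~6% of IP reads in peaks,
both typical of a successful TF ChIP. These values were fixed once, before
the recovery tests were written, and are not tuned thereafter.

**Promoter scrubbing.** A uniform 2 Mb genome contains ~2 × 10³ chance
HRE 5-mers. So that recovery can be scored exactly, the generator removes
(by middle-base substitution, iterated to convergence) every HRE within
non-target promoter windows plus a 150 bp margin; planted motifs are then
written into target promoters. Scrubbing is on by default and switchable
off. Chance motifs *outside* promoter neighbourhoods remain — the screen
must reject them via the promoter/direction filters, not because the
genome was sanitised globally.

What the generator does **not** emulate: sequencing errors, PCR
duplicates, mappability structure, GC bias, paired ends, diploidy, and
multi-isoform TSS structure. Passing tests therefore demonstrate the
*logic* of the screen under a clean unimodal binding model, not
performance on real libraries.

## Coverage and peak calling

Reads are extended 3′-wards to 250 bp — the midpoint of the 200–300 bp
fragment-size assumption used on the analysis side — deliberately
*mismatched* to the simulated shear range (150–900 bp), so tests exercise
robustness to extension misspecification. Coverage is the per-base count
of covering fragments (`IRanges::coverage`).

Peaks: a base is a candidate when the one-sided Poisson upper tail of its
IP depth is < 1e-4 against λ = max(scaled local input mean over ± 5 kb,
scaled genome-wide input mean, pseudocount 0.25); input is scaled to the
IP library by total fragment count. Candidates within 100 bp merge;
merged intervals whose maximum depth falls below `min_depth` (default 5)
are dropped. Applying `min_depth` to whole merged peaks (rather than to
seed bases) makes the caller structurally monotone: raising it can only
delete peaks, never split them. The summit is the leftmost coverage
maximum (deterministic tie-break). Per-peak counts use the
fragment-centre rule below.

## Differential enrichment

Both conditions are counted on a *common* region set — the peaks called
from the pooled (control + exposed) IP coverage — avoiding
condition-biased region definition. A fragment counts in a region iff its
centre lies in the half-open interval. For an unreplicated design the
exact conditional test applies: given the total count, the exposed count
is Binomial(n, ratio/(1+ratio)) under the null of equal rates (ratio =
library-size ratio), and `stats::binom.test` gives the two-sided p-value.
Signed linear fold change is ±max(r, 1/r) with
r = (exposed + 0.5)/(ratio · control + 0.5), negative when exposed <
control; Benjamini–Hochberg correction and a strict FDR < 0.05 cut define
the up/down DEP lists. No attempt is made to reproduce the original
study's fold-change magnitudes, whose scale is undocumented.

Expected behaviour at the null is *rate* control, not absence: on a
simulation without any condition effect, ~5% of regions may still clear
FDR < 0.05. Tests assert the rate bound; the HRE screen is what drives
false *candidates* to zero.

## Annotation

Classification is summit-based with priority promoter > exon > intron >
upstream > intergenic; the promoter is the genomic window
[TSS − 2000, TSS + 2000) regardless of strand, upstream is the
strand-oriented window from 2 kb to 10 kb before the TSS (both
configurable), and ties across genes break by smallest |summit − TSS|
then gene id. Summit precedence was chosen over any-overlap because it is
deterministic and total — every region gets exactly one category, so
category percentages always sum to 100%.

## HRE screen

The scanner reports every position whose 5-mer is ACGTG or GCGTG, on both
strands by default (`strands = "forward"` restricts to the literal
single-strand reading — the motif notation is single-stranded, but an HRE
is biologically strand-agnostic, so the ambiguity is exposed as a flag
rather than silently resolved). The scan window is the differentially
enriched region itself; `window = "promoter"` widens it to the full
promoter window. Overlapping hits are all reported; N never matches.
Candidates are the down-regulated promoter DEP genes with ≥ 1 hit;
HRE-free regions are retained in an audit table. A user-supplied
keep-table (stand-in for manual literature curation) optionally filters
candidates further; genes absent from the table default to *dropped*.

## Pathway enrichment

Overlap ("Hits") is a case-normalised set intersection. Significance is
the upper-tail hypergeometric probability with BH correction across the
collection — the simplest defensible choice; the DAVID-style EASE
deflation is deliberately not used. The pathway size is the *declared*
total (which may exceed the members listed for a synthetic stand-in
collection), and the universe is configurable: all genes of the run's
annotation for synthetic runs, or a packaged symbol list for fixture
runs. The packaged pathway membership lists, screened gene list and
~3000-symbol universe are synthetic stand-ins (their filenames say so)
constructed so the printed hit counts of the study's pathway table are
reproduced by honest intersection; the original study's member lists,
background and p-values are not public and are not targets.

## qPCR validation

2^−ΔΔCt follows the Livak convention: per replicate
ΔCt = Ct_target − Ct_reference; ΔΔCt anchors to the *mean* control ΔCt;
per-replicate folds are averaged. One-way ANOVA runs on the ΔCt values
across all groups; the LSD post-hoc is a two-sided t-test of each dose
group against control using the pooled within-group mean square and its
degrees of freedom. Star tiers use strict inequalities
(0.05/0.01/0.001). A gene is "validated" when at least one dose group
shows fold < 1 together with a non-empty star. Replicate counts per group
in the original study are unstated; simulated fixtures declare their own
n (6 by default, Ct noise 0.1 cycles on target and reference
independently). Amplification-efficiency correction (Pfaffl) and
multi-reference normalisation are out of scope.

## Numerical and degenerate-case choices

* Internal coordinates are 0-based half-open everywhere; conversion
  happens only at the GFF3 (1-based closed) boundary.
* Empty input track: the IP/input ratio falls back to 1 and λ to the
  pseudocount, so zero-background simulations remain callable.
* Both counts zero in the differential test: p = 1, fold = +1.
* Zero within-group variance in ANOVA: flagged degenerate; p = 0 when
  means differ, p = 1 when they do not.
* Empty candidate list: precision is reported as NaN, not an error.
* All randomness flows from a single mandatory seed; per-stage and
  per-sample sub-seeds are small fixed offsets, so any stage is
  individually reproducible and a rerun of a configuration is
  byte-identical.

## Problem sizes

The reference design (2 Mb, 200 genes, ~800k reads across the six
samples) runs in roughly 20 seconds; the test suite uses smaller designs
(150 kb, ~12 genes) except where the reference design itself is the
claim under test (10-seed recovery), and statistical properties use
direct count simulations (20 seeds × 200 regions) rather than full
pipeline runs.

## Known limitations

The caller has no broad-peak mode and no fragment-size estimation; the
differential test ignores biological replication (by design, matching an
unreplicated pooled study); the enrichment universe is a free parameter
with real influence on p-values; and none of the recovery guarantees
transfer automatically to real libraries with duplicate structure,
mappability gaps, or multimodal binding.
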