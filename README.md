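# hrescreen

A tested R implementation of a genome-wide ChIP-Seq screen for direct
HIF-1α target genes, built for regulatory genomicists who want every step
of such a screen — peak calling, differential enrichment, promoter
annotation, binding-site filtering, pathway enrichment and qPCR
validation — as reproducible, unit-tested code rather than a chain of
one-off tools.

## The screen

Transcription-factor ChIP-Seq compares an immunoprecipitated (IP) library
against an un-enriched input. The screen is a funnel over two exposure
conditions (control vs exposed):

1. **Peaks** — bases where IP depth is Poisson-improbable
   (p < 10⁻⁴) under λ = max(scaled local input mean ± 5 kb, scaled
   global input mean, 0.25) are merged (≤ 100 bp gaps) into peaks.
2. **Differential enrichment** — on the common peak set, per-condition
   fragment counts (centre-in-region) are compared with the exact
   conditional binomial test: given n = k_ctrl + k_exp, under the null
   k_exp ~ Binomial(n, r/(1+r)) with r the library-size ratio.
   Benjamini–Hochberg FDR < 0.05 and the fold sign split up/down DEPs.
3. **Promoter annotation** — peak summits are classified
   promoter > exon > intron > upstream > intergenic, with the promoter
   as TSS ± 2 kb.
4. **HRE screen** — down-regulated promoter DEP regions are scanned for
   the hypoxia response element 5′-(A/G)CGTG-3′ on both strands; genes
   with ≥ 1 hit are candidate HIF-1α targets, optionally filtered by a
   curated function table.
5. **Enrichment & validation** — candidate sets are tested against
   pathway collections (upper-tail hypergeometric, BH), and expression
   changes are validated by qPCR via 2^−ΔΔCt with one-way ANOVA and LSD
   post-hoc statistics.

Because the original study's raw data are not public, the package ships a
synthetic-data generator (`sim_config()`, `generate_genome()`,
`plant_hre()`, `simulate_reads()`, ...) that plants HRE motifs and
condition-dependent binding with known ground truth, so the whole funnel
is testable offline; small tables that *are* printed in full (pathway hit
counts, the qPCR validation table, primer sequences) are packaged as
text fixtures, with synthetic stand-ins (marked as such) for lists the
study never printed.

## Worked example

The `analysis/` directory is the screen as a numbered narrative; each
script is a thin driver over package functions and writes its tables
under `results/`. Running them in order on the reference design
(2 Mb genome, 200 genes, 30 planted HRE-bound promoters, 4-fold binding
reduction, ~200k reads/sample):

```sh
Rscript analysis/01_simulate_dataset.R
Rscript analysis/02_coverage_and_peaks.R
Rscript analysis/03_differential_enrichment.R
Rscript analysis/04_annotate_and_screen.R
Rscript analysis/05_pathway_enrichment.R
Rscript analysis/06_qpcr_validation.R
```

prints, among other things:

```
wrote 7 files: 200 genes, 30 bound (all with HRE), 811,370 reads
called 33 peaks (median width 815 bp); per chromosome: chr1 13, chr2 20
30/33 peaks differential at FDR<0.05 (0 up, 30 down)
peak categories: promoter 90.9%, upstream 0.0%, exon 0.0%, intron 3.0%, intergenic 6.1%
30 down promoter DEPs -> 30 HRE-positive candidates; sensitivity 1.00, precision 1.00
function filter: 25 of 42 screened genes kept
  Jak-STAT signaling pathway                    total 155 hits 5  p=6.28e-02
validated genes in the transcribed table: 11 of 11
```

Read: all 30 planted binding sites were called as peaks, every one was
detected as down-regulated, annotated to the right promoter, and carried
its planted HRE — no false candidate crept in (precision 1.00). The
pathway stage reproduces the printed overlap counts (5 hits for Jak-STAT,
4 for NK-cell cytotoxicity, ...), and the validation counter finds 11
significantly down-regulated genes in the transcribed qPCR table.

The same funnel is available as one call:

```r
library(hrescreen)
summary <- run_pipeline(run_config(seed = 1, out_dir = "run1"))
#> 36 peaks; DEPs up/down 0/30; promoter down 30; HRE-positive 30
```

## Layout

```
R/                  package code: simulation, coverage/peaks,
                    differential, annotation, HRE screen, enrichment,
                    qPCR, pipeline orchestration
analysis/           numbered narrative drivers over the package
inst/extdata/       plain-text fixtures (transcribed tables and
                    synthetic stand-in gene/pathway lists)
tests/testthat/     unit, property and acceptance tests with
                    independent brute-force oracles
vignettes/methods.Rmd   the model, its assumptions, parameter choices
                        and limitations
scripts/acceptance.R    end-to-end recomputation of headline numbers
```
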