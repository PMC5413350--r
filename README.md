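# symbioseq

Dual RNA-seq analysis for host–endosymbiont systems: one library, two
organisms, very unequal effective sequencing depths.

`symbioseq` is for transcriptomics researchers analysing experiments in
which an intracellular symbiont (for example a green alga living inside
salamander embryo cells) is sequenced together with its host. It
implements the complete chain of organism-aware preprocessing and
testing such data needs:

- **Catalog partitioning** — each transcript of a mixed assembly is
  assigned to host, symbiont or contaminant by best-hit taxon voting
  over BLAST-tabular homology hits (maximal bitscore; fungal/mite best
  hits discarded; conflicting exact ties flagged `ambiguous`), with
  no-homology transcripts rescued by their expression pattern across
  sample classes.
- **Depth-driven expression thresholds** — (i) the *correlation-onset
  lower limit*: genes are sorted by mean FPKM in a reference condition
  and binned into sliding 100-gene windows; the threshold is the window
  median at which Kendall's tau between the two conditions' window
  medians becomes, and stays, positive; (ii) the *absence-call
  threshold*: the deep-condition FPKM above which ≥ 95% of genes are
  detected in every shallow-condition sample — below it, an absence is
  treated as depth dropout, above it as biology.
- **Normalization** — trimmed mean of M-values (TMM: trims 0.30/0.05,
  precision-weighted, geometric mean 1) plus quantile-bin GC offsets
  (zero-sum per sample) that remove library-prep GC bias from
  cross-protocol contrasts, with a Kolmogorov–Smirnov diagnostic for
  prep-dependent GC loss.
- **Differential expression** — per gene, a negative-binomial
  log-linear GLM fit by IRLS with log effective-library-size (+ GC)
  offsets, paired designs via a per-gene blocking factor
  (`~ pair + condition`), Cox–Reid adjusted-profile-likelihood common
  and tagwise dispersions (empirical-Bayes shrinkage, prior df 10),
  likelihood-ratio tests and Benjamini–Hochberg FDR at 0.05.
- **Annotation filtering** — protein-homology annotations are kept only
  when their percent identity exceeds the HSSP length–identity curve
  (100 for L ≤ 11; 480·L^(−0.32(1+e^(−L/1000))) for 11 < L ≤ 450; 19.5
  beyond) by strictly more than 5 points, one best annotation per gene.
- **A ground-truth simulator** — catalogs with organism-specific GC
  (host median 0.43, symbiont 0.62), paired designs, NB counts with
  planted fold changes, prep-linked GC bias and a low symbiont depth
  fraction inside host cells, used to validate every stage.

The data container is a `DualSeqExperiment` (a `SummarizedExperiment`
subclass: counts + per-transcript organism/length/GC + per-sample
class/pair/prep/depth), so the package composes with the usual
Bioconductor tooling.

## Worked example

A fully simulated study — 4 paired host-only / host-plus-symbiont
samples and 3 capsule-symbiont samples, 10% of genes differentially
expressed at |log2FC| = 2 — analysed end to end:

```r
library(symbioseq)
cfg <- symbioseq:::.defaultConfig()
cfg$seed <- 5
cfg$simulation$nHost <- 1200
cfg$simulation$nSymbiont <- 700
cfg$simulation$nContaminant <- 60
report <- runPipeline(cfg)
report
#> RunReport (seed 5 )
#> Stages (input / removed / retained):
#>   input_transcripts                1960        0     1960
#>   homology_partition               1960       75     1885
#>   expression_rescue                 103       16       87
#>   symbiont_gene_set                 707       55      652
#>   absence_filter                    652        0      652
#>   annotation_filter                1869        0     1869
#> Differential expression (tested / DE / up / down / %DE):
#>   host_response                    1162    120    57    63   10.33
#>   symbiont_intracellular            652     71    28    43   10.89
#> Summaries:
#>   symbiont_vs_host_de_ratio          1.1
```

Reading the report: homology voting removed 75 contaminant/ambiguous
transcripts; 87 of 103 no-homology transcripts were rescued by
expression pattern; the symbiont analysis set kept 652 of 707
symbiont-labelled genes after the presence and lower-limit clauses and
the absence-call filter. Both contrasts then recover essentially all of
the planted 10% differential expression (10.33% and 10.89% called at
FDR < 0.05), and the symbiont responds ~1.1× as strongly as the host in
this balanced simulation. The learned thresholds, per-gene DE tables
and window curves are available via `attr(report, "artifacts")`, and
`plotWindowCurve()` / `plotDE()` reproduce the standard threshold and
fold-change dotplot figures.

The printed-table arithmetic helpers work on real study tallies too:

```r
deProportions(277, 6726)               # 4.12  (% symbiont genes DE)
deProportions(300, 46549)              # 0.64  (% host genes DE)
deProportionRatio(277, 6726, 300, 46549)  # 6.4
100 * areaToVolumeFraction(0.56)       # 41.9 (% starch by volume)
```

A thin CLI over the same functions lives at
`inst/scripts/run-pipeline.R`
(`Rscript run-pipeline.R all --config cfg.yaml --out-dir out/`).

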