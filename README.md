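# saberseq

Analysis toolkit for **signal-recording CRISPR barcodes**: transgenic
recorders in which a signaling-responsive promoter drives Cas9, so that
cells write permanent indels into a compact four-target barcode array while
a developmental signal (e.g. Notch) is active in their ancestors. Profiled
later by single-cell RNA-seq or bulk amplicon sequencing, an edited barcode
marks a cell descended from a signal-active progenitor. The readout is
binary by design — repair-outcome homoplasy rules out clonal
reconstruction, but not signal tracing.

The package provides, for experimentalists and methodologists working with
such recorders:

* a **barcode-array data model** (`saber_reference`): sequence, four
  target-site intervals, cut positions, primer flanks; canonical allele
  strings (`"35D+112"`, `"4I+150+ACGT"`, `"-"`) with leftmost-normalized,
  alignment-based encoding;
* a **generative simulator** (`simulate_population()`,
  `generate_reads()`, `generate_bulk_amplicons()`): signal-active vs
  inactive lineages, multi-round cutting with intra-site deletions,
  joint inter-site deletions, occasional insertions, per-cluster detection
  bias, 10x-style paired reads (16-nt cell barcode + 12-nt UMI / 151-cycle
  amplicon read) and UMI-tagged bulk amplicons;
* an **allele caller** (`call_alleles()`): compiled affine-gap alignment
  with deterministic tie-breaks and a free reference tail for truncated
  reads, a <50 nt / identity-floor mappability filter, per-UMI then
  per-cell majority consensus, and exact whitelist matching;
* **signal-tracing statistics** (`edited_fraction()`, `edit_spectrum()`,
  `cluster_divergence()`, `detection_bias()`,
  `tissue_normalized_fractions()`, `coverage_report()`): edited fractions,
  per-nucleotide deletion profiles and site-link (chord) matrices, and
  two-sided exact binomial tests per cell type.

For a cluster with `n` barcoded cells of which `k` are edited, divergence
from the pooled edited fraction `p0` is tested with the exact two-sided
binomial test (all outcomes no more probable than `k` under
`Binomial(n, p0)`), at a minimum of 20 barcoded cells and `alpha = 0.05`,
with a Benjamini–Hochberg column reported alongside the raw decisions.

## Worked example

Simulate a 2,000-cell juvenile-brain-style experiment under sustained
recording, sequence and call it, and trace the signal:

```r
library(saberseq)
cfg <- simulation_config(n_cells = 2000, seed = 7)
out <- run_pipeline(cfg, "run7")

summarize_run("run7")$call$recovery_rate
#> [1] 0.225
cells <- read_tsv(out$call$alleles)
edited_fraction(cells)
#> [1] 0.82
edit_spectrum(cells)$link_matrix
#>       site1 site2 site3 site4
#> site1   236     7     6     6
#> site2     0   231    13     8
#> site3     0     0   213    17
#> site4     0     0     0   233
read_tsv(out$trace$clusters)[, c(1:4, 5, 8)]
#>       cluster n_barcoded n_edited  fraction   p_value significant
#> 1        glia         78       66 0.8461538 0.6586972       FALSE
#> 2      neuron        289      236 0.8166090 0.8783050       FALSE
#> 3  progenitor         83       67 0.8072289 0.7748336       FALSE
```

Reading the output: 22.5% of profiled cells yielded a barcode (the
detection rate of the simulated library), 82% of mappable barcodes carry an
edit in at least one target site, the link matrix shows mostly intra-site
deletions (diagonal) with some multi-site spanning deletions (upper
triangle), and no cell type's edited fraction diverges from the pooled
rate — as it should be here, since the simulation planted no cluster
effect.

The methods vignette (`vignettes/signal-recording.Rmd`) documents the
editing model, the default parameter calibration, the aligner's scoring
and normalization rules, and the statistical choices.

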