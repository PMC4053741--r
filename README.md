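# crosslinkr

Cross-link site analysis for CLIP and iCLIP cDNA libraries.

UV cross-linking and immunoprecipitation (CLIP) and its individual-nucleotide
resolution variant (iCLIP) map where an RNA-binding protein touches its RNA
targets. The covalently cross-linked nucleotide leaves two footprints in the
cDNA library: reverse transcription either stops at the cross-link — the cDNA
*truncates*, and the cross-link site is the nucleotide preceding the read —
or it reads through and tends to introduce a single-nucleotide *deletion* at
the site. crosslinkr is for people analyzing such libraries: it turns mapped
cDNA records into counted cross-link sites, quantifies how much of a library
read through the cross-link, and profiles binding-motif structure around the
sites.

## What it computes

**Unique cDNAs.** PCR duplicates are collapsed by random barcode and read
start; barcode-free libraries are joined by start position. When duplicates
disagree about deletions, the most frequent deletion wins; frequency ties go
to the deletion closest to the read 5' end.

**Read-through mixture.** A library's deletion proportion `p` (deletions in
the first 25 nt of the read, among unique cDNAs) is modeled as a two-component
mixture,

```
p_library = f * p_RT + (1 - f) * p_BG
```

where `p_RT` is measured from a pure read-through (CLIP) library and `p_BG`
from mRNA-Seq background. Solving gives the read-through fraction
`f = (p_library - p_BG) / (p_RT - p_BG)`; the posterior share of
deletion-bearing cDNAs that are read-through is
`k = f p_RT / (f p_RT + (1 - f) p_BG)`, and the read-through share among the
deletion-free cDNAs used for truncation analysis is
`(N f - n_del k) / (N - n_del)`.

**TTT re-definition.** Gapped aligners cannot place a deletion inside a
homonucleotide run and report it at the run's genomically rightmost base,
which shifts plus- and minus-strand motif profiles against each other.
Deletion sites whose transcript-sense context at offsets −2..0 (plus strand)
/ 0..+2 (minus strand) is `TTT` are re-defined to the middle of the motif,
and colliding sites merge with summed counts.

**Motif profiles.** Occurrence and closest-instance profiles of an IUPAC
motif (default `YCAY`, the Nova recognition element) around sites in
transcript orientation, a background built by re-positioning each site 100
times uniformly within its annotated genomic segment, per-offset enrichment
with ±2 smoothing and the maximal two-fold region, nucleotide composition,
and the proportions of the four YCAY variants near versus around the sites.

**YCAY clusters.** A per-position score counting motif instances fully
contained in a 41-nt window, segmentation of the score track into clusters
(zero valleys end clusters; a valley below 0.9× the smaller adjacent maximum
splits at the middle of the minimum run; otherwise peaks merge), and
Spearman correlation between cluster scores and the highest cDNA count per
cluster.

A synthetic-data module (`simulation_config()`, `generate_genome()`,
`simulate_cdnas()`) plants YCAY clusters and TTT runs in a toy genome and
simulates barcoded truncated/read-through cDNA mixtures, so the whole
pipeline is testable without sequencing data.

## Worked example

```r
library(crosslinkr)

cfg <- simulation_config(n_cdnas = 50000L, readthrough_fraction = 0.18,
                         seed = 7L)
sim <- generate_genome(cfg)
rec <- simulate_cdnas(sim, config = cfg)

unique_cdnas <- collapse_barcoded(rec)
ref <- collapse_barcoded(simulate_cdnas(sim, sim$truth,
         simulation_config(n_cdnas = 50000L, readthrough_fraction = 1,
                           seed = 8L)))
bg  <- collapse_barcoded(simulate_cdnas(sim, sim$truth,
         simulation_config(n_cdnas = 50000L, readthrough_fraction = 0,
                           seed = 9L)))
estimate_mixture(deletion_stats(unique_cdnas), deletion_stats(ref),
                 deletion_stats(bg))
```

```
read-through/truncated mixture (window 25 nt):
  deletion proportions: target 0.0219, read-through ref 0.1084, background 0.0039
  f (read-through fraction of library)        = 0.172
  k (read-through share of deletion-bearing)  = 0.851
  read-through share among deletion-free      = 0.156
  truncated share among deletion-free         = 0.844
```

The planted read-through fraction (0.18) is recovered from the deletion
proportions alone. With the published library counts — a CLIP reference of
421,417 windowed deletions in 3,852,778 unique cDNAs, an mRNA-Seq background
of 18,936 in 4,857,809, and a target iCLIP library of 3,749 in 166,330 —
the same three formulas give `f = 0.177` (18% read-through, 82% truncated),
`k = 0.858`, and a 15% / 85% read-through/truncated split among the
deletion-free cDNAs.

`run_pipeline()` chains every stage from files (or in-memory objects) to a
directory of TSV/BED/bedGraph outputs plus a JSON manifest; see
`vignettes/crosslink-analysis.Rmd` for the methods account.

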