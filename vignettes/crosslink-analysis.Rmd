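---
title: "Identifying and characterizing protein-RNA cross-link sites from cDNA truncations and deletions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying and characterizing protein-RNA cross-link sites from cDNA truncations and deletions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crosslinkr)
```

# The two footprints of a cross-link

UV-C irradiation covalently bonds an RNA-binding protein to the RNA it
touches. After immunoprecipitation and proteinase digestion, a peptide
remnant stays on the cross-linked nucleotide and interferes with reverse
transcription in one of two ways. Either the polymerase stops — the cDNA
*truncates*, and in the dominant UV-C mode the cross-linked base is the
nucleotide immediately preceding the read in transcript orientation — or the
polymerase reads through and, much more often than background, skips a base,
leaving a single-nucleotide *deletion* at or near the cross-link.

CLIP library preparation can only amplify read-through cDNAs; iCLIP captures
both classes and adds a random barcode so PCR duplicates can be removed.
crosslinkr implements the analysis built on these facts: site derivation
from both footprints, duplicate collapsing, a correction for how aligners
place deletions inside homopolymer runs, a mixture estimate of the
read-through fraction, and motif analyses around the resulting sites.

All genomic coordinates in the package are 0-based half-open, on disk (BED)
and in memory. Offsets around sites are in transcript orientation with the
site at 0.

# Ingest and duplicate collapsing

A mapped cDNA is a row with `chrom`, `start`, `end`, `strand`, `barcode`,
and the genomic positions deleted in the read. SAM input is supported
(deletions from CIGAR `D` operations, barcode from a tag or read-name
suffix); the native interchange format is a plain TSV.

`collapse_barcoded()` groups reads by (barcode, chromosome, strand, read 5'
end) and keeps one unique cDNA per group. "Starting position" is the 5' end
in read orientation — `start` on the plus strand, `end - 1` on the minus
strand — since that is the position fixed by the reverse-transcription
primer that the barcode travels with. Within a group:

* a read with several deletions contributes only the one closest to its 5'
  end (all downstream deletion analyses use this selected deletion);
* the retained deletion is the most frequent one, with frequency ties broken
  toward the read 5' end;
* groups mixing deletion-free and deletion-bearing reads are not covered by
  the published procedure; we resolve them by majority with ties favoring
  the deletion-free state, which is conservative for truncation analysis,
  and tally the decision so it can be audited.

`join_no_barcode()` handles barcode-free libraries (CLIP, mRNA-Seq) by
behaving as if every read carried the same barcode. Collapsing is
idempotent, and analyses refuse libraries under 10,000 unique cDNAs by
default (`min_library`), the conventional floor for these comparisons.

Truncation sites are taken only from deletion-free cDNAs: deletion-bearing
iCLIP cDNAs are predominantly read-through molecules whose 3' ends do not
mark cross-links.

# Re-defining deletions in TTT context

Deletions concentrate in uridine tracts, and a deletion inside a
homonucleotide run has no unique alignment: the aligner used for the
reference deletion data reports it at the genomically rightmost base of the
run on both strands. In transcript coordinates that is the 3' end of the
TTT for plus-strand cDNAs but the 5' end for minus-strand cDNAs, so the two
strands' motif profiles shift two nucleotides against each other.

`redefine_deletions()` therefore tests the transcript-sense bases at offsets
−2..0 (plus strand) and 0..+2 (minus strand) of each deletion site. Because
transcript direction reverses on the minus strand, both windows are the same
genomic window `[d-2, d]`; the content test is `TTT` on the plus strand and
genomic `AAA` (transcript `TTT`) on the minus strand. On a match the site
moves to the window center `d-1`. This is the reading under which the
correction aligns the two strands exactly, which the test suite verifies by
construction: with aligner-style rightmost placement emulated on both
strands, per-strand closest-YCAY profiles disagree before re-definition and
are identical afterwards, peaking at +1. A genomic-mirror reading of the
minus-strand window (`[d, d+2]`, center `d+1`) cannot trigger on
rightmost-placed deletions and leaves the shift in place, so it was
rejected.

Choices worth noting: the rule is applied as written to the 3-nt window
only — no re-centering over runs longer than 3, though triggered windows
embedded in longer runs are tallied; a single pass is applied (for isolated
TTT runs the center is a fixed point; inside longer runs repeated passes
would walk the site leftwards, which is why the one-shot convention exists);
re-defined sites that collide are merged with summed counts, conserving the
total.

# The read-through mixture

With `p_RT` the windowed deletion proportion of a pure read-through library,
`p_BG` that of mRNA-Seq background, and `p` that of the library of interest,

$$p = f\,p_{RT} + (1-f)\,p_{BG}
  \quad\Longleftrightarrow\quad
  f = \frac{p - p_{BG}}{p_{RT} - p_{BG}},$$

$$k = \frac{f\,p_{RT}}{f\,p_{RT} + (1-f)\,p_{BG}}, \qquad
  \text{read-through among deletion-free} =
  \frac{N f - n_{del}\,k}{N - n_{del}}.$$

Deletions are counted in the first 25 nt of each read (`window_nt = 25`) so
that libraries with different read lengths are comparable; `f` and `k` use
the windowed proportions, while the deletion-free split removes the
full-read deletion-bearing count `n_del`. The model assumes the deletion
rate in read-through cDNAs is the same in the reference and target
libraries (same reverse-transcription and sequencing chemistry); that
assumption is documented, not testable from the counts themselves. Inputs
violating the ordering `p_BG <= p <= p_RT` clip the estimate to [0, 1] with
a warning; `p_RT = p_BG` is an unidentifiable mixture and an error.

On the published counts (CLIP 421,417/3,852,778; mRNA-Seq
18,936/4,857,809; iCLIP 3,749/166,330 windowed, 6,174 anywhere) these give
`f = 0.177`, `k = 0.858`, and a 15%/85% read-through/truncated split among
deletion-free cDNAs — the values the acceptance script recomputes.

# Motif profiles and the randomized background

`motif_occurrence()` counts, per transcript-sense offset, the sites at which
an IUPAC motif instance starts; overlapping instances all count (YCAY
instances can overlap by one base). `closest_motif()` keeps at most one
instance per site — the start offset with the smallest absolute value,
distance ties resolved upstream. Distance is measured to the motif *start*;
measuring to the nearest motif edge is a defensible alternative, but the
start is what the profile records, so it is the anchor used.

The background model re-positions every site uniformly within its containing
annotated segment (same strand; unstranded segments accept both), recomputes
the occurrence profile, and averages over `n = 100` randomizations in a ±50
window. The original position may be redrawn — nothing is excluded — and a
fixed seed makes the background reproducible. On uniformly random sequence
the per-site background rate converges to the closed-form
$(1/2)(1/4)(1/4)(1/2) = 1/64$ per offset for YCAY.

Enrichment is the per-offset ratio of per-site observed to per-site
background occurrence. To report the span of elevated enrichment without
single-offset flicker, each offset is smoothed by the mean over offsets
−2..+2 around it, and the maximal contiguous run at or above two-fold is
reported. Offsets with zero background are missing, not infinite.

`nucleotide_composition()` gives per-offset base frequencies (each offset
sums to 1), and `motif_variant_proportions()` compares the mix of the four
YCAY variants (TCAT, TCAC, CCAT, CCAC) among instances starting at offsets
0..+2 against the wider −20..+20 vicinity — the contrast that exposes
sequence biases of the cross-linking chemistry itself.

Sites whose window would leave the chromosome are excluded from a profile
and tallied in its `n_excluded` attribute.

# YCAY cluster scores and correlation with cDNA counts

The cluster score of a position counts the motif instances *completely
contained* in the 41-nt window centered on it (20 nt each side; positions
near chromosome ends use the truncated window). `find_clusters()` segments
the score track: zero valleys end clusters; between two local maxima, a
valley minimum below 0.9× the smaller maximum splits the cluster at the
middle of the run of minimum-valued positions, and otherwise the peaks
merge, with the merged peak compared to the next maximum. Three conventions
the published five-step description leaves open are fixed here: a plateau of
equal values flanked by strictly smaller values is one maximum anchored at
its midpoint (the splitting rule needs a single anchor); maxima are
processed left to right, re-evaluating after each merge, which makes the
output deterministic; and a valley exactly at 0.9× the smaller maximum is
"not smaller", so it merges. Clusters are a disjoint cover of the
positive-score positions.

`correlate_clusters()` pairs each cluster's maximal score with the highest
cDNA count of the cross-link sites inside it, keeps clusters containing at
least one site (at least three are required), and computes Spearman's rank
correlation with a two-sided p-value from the asymptotic t approximation
(`cor.test(..., method = "spearman", exact = FALSE)`, the convention for
this analysis); ties get average ranks. Zero variance in either variable is
reported as an undefined correlation rather than an error.

# The synthetic-data generator

`generate_genome()` builds a toy genome: uniform-ACGT background from a
seeded RNG (one derived stream per chromosome, so adding chromosomes leaves
earlier ones untouched), planted YCAY clusters (a configurable number of
motif tetramers at fixed spacing, drawn uniformly from the four variants,
optionally TTT-prefixed, on either strand), and isolated TTT runs flanked by
non-T bases. The segment annotation alternates genic/intergenic blocks —
enough structure for background randomization without a gene model. One
cross-link site is recorded per planted motif, one nucleotide
transcript-upstream of the motif start, so truncation analysis should find
motifs starting at +1.

`simulate_cdnas()` draws each molecule's site by occupancy weight, assigns
read-through status with probability `readthrough_fraction`, and places the
read: truncated cDNAs start exactly one nucleotide 3' of the site (the UV-C
convention; a shift of 0, the enzymatic cross-linking mode, would be a
one-line change but is not a default), read-through cDNAs extend 2-20 nt
past it. Deletions are single-nucleotide — the dominant class; consecutive
dinucleotide deletions, which mostly reflect genomic microsatellite
variation, are out of scope — and are placed within the first 25 nt of the
read with positions inside homonucleotide runs up-weighted by
`homopolymer_del_bias`; with `aligner_shift` the reported position moves to
the run's genomically rightmost base, reproducing the ambiguity the
re-definition step corrects. Random barcodes are attached per molecule and
PCR duplicates appended geometrically.

Two generator choices deserve their rationale:

* **Occupancy weights.** Each site's weight is the number of motif
  instances (planted or accidental) fully contained in the 41-nt window
  around it, counted with a plain regex scan independent of the package's
  scorer. This encodes the biology the cluster analysis relies on — affinity
  grows with the local density of proximal motifs — and makes "cDNA counts
  proportional to motif density" true by construction, so the recovery test
  isolates the pipeline (collapsing, site counting, segmentation,
  correlation) rather than re-testing the premise. Weighting by whole-cluster
  motif count instead leaves edge sites over-weighted relative to their
  local density and accidental background motifs unaccounted for, which
  caps the achievable rank correlation well below what strong-coverage data
  show.
* **Read lengths.** No distribution is published for cDNA length variation
  beyond a ~50 nt average; lengths are drawn uniformly in
  `read_length ± read_length_jitter` (default 50 ± 15), a choice of this
  package, and deletion windowing makes the analyses insensitive to it.

Default rates are the study conditions the estimators target: `f = 0.18`,
per-read deletion probabilities 0.11 (read-through) and 0.004 (background)
within the 25-nt window, 0.25 PCR duplication, 9-nt barcodes.

# What the tests do and do not show

Problem sizes were chosen so the whole suite runs in about a minute:
genomes of 20-100 kb, libraries of 2,000-50,000 cDNAs, 5-100 background
randomizations. Parameter recovery of `f` over {0.05, 0.18, 0.5, 0.9} uses
five seeds at 50,000 cDNAs per library, with reference proportions estimated
from simulated barcoded pure libraries run through the same collapse, and a
tolerance of three delta-method-propagated binomial standard errors. The
cluster-score/count recovery fixture uses cluster sizes 1-7 at spacing 2 so
cluster extents (≤ 40 nt) stay within the 41-nt window — larger clusters
saturate the score and produce uninformative ties — and achieves rank
correlations of 0.88-0.97 across probe seeds.

The generator emulates the statistical structure the analysis assumes — the
two cDNA classes, deletion rate contrast, homopolymer placement bias,
aligner shift, barcode duplication — but not sequencing error, mappability,
transcript-abundance variation between regions, or FDR-based site
significance filtering (site lists are accepted as given; significance
calling is upstream of this package). Passing tests therefore show the
estimators and profile machinery are correct under the stated model, not
that any particular real library satisfies the model; in particular the
mixture estimate inherits the equal-deletion-rate assumption, and on real
data the published enrichment factors and correlations depend on sequencing
depth and annotation that a desk-scale simulation does not reproduce.

# Numerical and degenerate-input conventions

Proportions are carried as integer count pairs and divided only where a
formula needs the ratio, so table-scale reproductions are bit-stable.
Truncation sites that would fall off a chromosome are skipped and tallied;
profile windows crossing a chromosome end exclude the site; score windows
truncate instead. Empty deletion lists are a precondition error for
deletion selection; `window_nt <= 0` and empty variant ranges are parameter
errors. The pipeline writes a manifest (config echo, seed, package version,
per-file md5) and a fixed seed reproduces every output byte.
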