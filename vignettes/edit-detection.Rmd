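---
title: "Methods: single-cell CRISPR edit detection from droplet amplicon reads"
author: "sceditr authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell CRISPR edit detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sceditr)
```

## The assay and the quantities the package computes

Droplet single-cell DNA platforms encapsulate individual cells, attach a
composite cell barcode (two 9-nt segments interleaved with constant library
sequences), and amplify a panel of targeted amplicons from each cell's
genome. After CRISPR-Cas9 editing, non-homologous end joining leaves small
insertions and deletions concentrated at the nuclease cut site. The package
turns raw barcoded reads into, per cell and per amplicon:

* the number of aligned reads and the **percent of modified reads**,
* the **top two alleles** with their modification state and frequency,
* a **zygosity class** (WT/WT, WT/Mut, Mut/Mut, Mut/Mut2),

and, per experiment, doublet flags (admixture designs), per-gene edited
fractions, edit-multiplicity histograms and combinatorial-assortment
tables, plus sgRNA presence calls from single-cell qPCR Cq matrices.

## Read model and filtering

A read is `constant1 + BC1 + constant2 + BC2 + constant3 + payload`. The
constants of the commercial library are not public, so the structure is
fully configurable (`read_structure()`); constants are matched exactly by
default, with an optional per-constant mismatch tolerance. Barcode
segments are extracted at fixed offsets and concatenated in read order.
Reads are discarded -- and tallied, never errored -- when the payload is
shorter than 46 bases (`short_read`), the combined barcode shorter than 18
bases (`short_barcode`), or a constant cannot be matched
(`structure_not_found`). Conservation (`input = retained + discards`)
holds by construction and is asserted in the tests. Base qualities are
carried but not used for filtering; they only arbitrate conflicting bases
when read pairs are overlap-merged (`merge_pairs()`, which concatenates
pairs with no acceptable overlap so that every pair yields a read).

Cells are called by total tagged-read count with an inclusive threshold
(`call_cells()`, default 1000). The default suits a panel of roughly 28
amplicons; for the 6-amplicon demonstration panel used throughout the
tests we scale it down (or disable it) so the threshold stays proportionate
to panel size.

## Alignment

Reads are assigned to amplicons by an affine-gap **semi-global** aligner
(global in the read, free at both reference ends), written as compiled
code in this package with an explicit scoring contract rather than
delegating to an external aligner, so its behaviour is fully testable:

* scoring: match +2, mismatch -3, gap open -5, gap extend -1 (a gap of
  length $L$ costs $5 + L$); configurable via `alignment_scoring()`.
* determinism: traceback prefers deletion over insertion over diagonal at
  score ties, and indels are then shifted to their leftmost
  alignment-equivalent placement (the usual left-normalization), so op
  lists are identical run to run.
* orientation: every read is scored in both orientations and the better
  one kept.
* assignment: best-scoring amplicon wins; a read is unassigned when its
  best identity (matches / alignment columns) falls below `min_identity`
  (default 0.65, tolerant of large on-target deletions) or when the best
  score ties across two or more amplicons.

The batch path memoizes alignments over unique read sequences (droplet
amplicon reads are highly redundant) and prescreens candidate amplicons by
shared 8-mers before running the DP; `assign_amplicon()` rescans every
amplicon exhaustively and is the reference behaviour. The aligner is
verified against an independently written brute-force DP on $10^4$ random
pairs and against `Biostrings::pairwiseAlignment` scores.

## Quantification window and modification calls

For each CRISPR amplicon the predicted cleavage site is 3 bp 5' of the
PAM on the protospacer strand (blunt SpCas9 cut; NGG by default,
configurable for other nucleases). Coordinates are 0-based; the cut site
is an inter-base index, and the quantification window is the half-open
interval `[cut - w, cut + w)` with half-width `w = 2` by default (a 4-bp
window). A read is **modified** iff

* a deletion's reference interval intersects the half-open window, or
* an insertion's inter-base anchor lies in the **closed** interval
  `[cut - w, cut + w]`, or
* (optionally) a substitution falls inside the window.

The closed insertion interval treats an insertion exactly at either window
edge symmetrically. Substitution counting is **off** by default: the
assay's signal is NHEJ indels, and counting substitutions would let
sequencing errors inflate modification rates; the flag
`count_substitutions` restores the inclusive behaviour.

Allele identity is the read projected onto `window +/- 10` flanking bases
(deletions drawn as `-`, insertions at their anchors), so errors far from
the cut do not fragment alleles; the flank is a parameter. Cell-amplicon
groups with fewer than `min_reads = 5` reads are NO_CALLs. Count ties
between alleles break lexicographically by projected sequence.

## Zygosity

Heterozygosity is the frequency of the second-most-frequent allele, in
percent. With `lower = 20` and `upper = 80` (both configurable, both
inclusive on the left):

| percent modified | heterozygosity | class |
|---|---|---|
| < 20 | any | WT/WT |
| 20 to < 80 | any | WT/Mut |
| >= 80 | >= 20 | Mut/Mut2 |
| >= 80 | < 20 | Mut/Mut |

The four classes partition the plane; an exhaustive grid test at 0.1%
resolution checks the implementation against a literal transcription of
the rules. No ploidy model beyond this two-allele logic is attempted, and
the Mut/Mut vs Mut/Mut2 distinction rests entirely on the second-allele
rule.

## Multi-target summaries and doublets

A site counts as **edited** in a cell when its called modification rate
reaches 20% (configurable). Doublet flagging applies only to admixture
designs, where each true cell carries edits at a single target, so two or
more edited on-targets betray a droplet with DNA from multiple cells; in
multiplexed lines multi-edited cells are biology and are never auto-
flagged. Insufficient-coverage entries count as unedited for subset
membership, and every profile carries the per-cell covered-target count so
users can filter instead. Pre/post-selection comparisons are expressed as
running the same summaries on two inputs and comparing the combination
tables; no bespoke statistic is defined.

## sgRNA qPCR presence calls

Cq tables (cells x assays with replicates, a no-amplification sentinel
allowed) are reduced by a count-of-positives rule: an sgRNA is present
iff at least `min_positive_reps` (default 4 of 8) replicates amplified at
`Cq <= cq_max` (default 25 of a 30-cycle protocol). A counting rule is
used instead of a median because no-amplification dropouts make medians
unstable in single-cell qPCR. Both thresholds are declared defaults, not
values inferred from data; calls are monotone in `cq_max` and
anti-monotone in `min_positive_reps` by construction.

## The simulator and what passing tests do (and do not) show

`simulate_reads()` generates barcoded droplet reads with full ground
truth. Per barcode it draws a genotype (two for doublets, at the
configured rate), per amplicon a coverage from a negative binomial (mean
26 reads/amplicon/cell, dispersion 8 by default -- the mean matches the
per-amplicon medians typical of this platform; only moderate
overdispersion is assumed since real runs report medians, not variances),
splits reads uniformly across surviving alleles (each allele drops out
independently with probability `ado_rate`; published droplet single-cell
DNA work reports ~5--10%, our presets default to 7.5%), and injects
substitution (default 0.1%/base) and spurious 1-bp indel (default
0.01%/base) errors into the payload.

Two presets define the study designs:

* `admixture_preset()`: one singly-edited line per on-target, 8% doublets.
  Lines are homozygous-edited clones by default: the closed-form flagged-
  doublet expectation `rate x (1 - sum p^2)` presumes cross-line doublets
  are detected with near certainty, which holds when each constituent
  contributes ~50% modified reads per target but not at the ~25% a
  heterozygous constituent would contribute under 26x binomial sampling.
  A `zygosity` weight vector splits lines into het / hom / compound-het
  subclones for zygosity-recovery experiments.
* `multiplexed_preset()`: independent per-target homozygous edit
  acquisition at a transduction probability (default 0.3), producing a
  Binomial multiplicity law. Doublets default to zero here because the
  preset exists to validate that law and no doublet flagging is defined
  outside admixture mode.

Truth records realized per-allele read counts, dropout events, and each
programmed edit's window-overlap flag computed by independent string
logic (including indel left-normalization), so end-to-end identity checks
never route truth through the aligner. Programmed deletions use lengths
{2, 3, 5} at the cut, and the demonstration panel embeds a period-4
context around each cut site, so preset edits cannot left-shift out of
the window; user panels with homopolymeric cut contexts can shift, which
the truth logic follows consistently.

The simulator does **not** model PCR chimeras, ambient DNA, barcode
sequencing errors (errors are payload-only), realistic quality strings,
index hopping, or locus-specific amplification bias. Tests passing on
simulated data therefore demonstrate the correctness of the computational
contract -- filtering conservation, alignment optimality, window rules,
zygosity arithmetic, doublet counting -- under the platform's nominal
noise regime, not robustness to every artefact of real libraries.

## Numerical and design choices

* 0-based coordinates, inter-base cut sites, half-open windows: insertion
  points are unambiguous and the reverse-complement symmetry
  `cut -> L - cut` is exact.
* Gap cost `open + L * extend` matches the convention of
  `Biostrings::pairwiseAlignment`, enabling a direct cross-check.
* Floating-point: percent modified is `100 * k / n` for integer counts;
  matrix-identity tests compare at 1e-12 tolerance to absorb the
  different summation orders of pipeline and truth.
* Problem sizes in tests and the acceptance script (500-cell noiseless
  identity, 5000-barcode admixture and multiplexed runs, 400-cell
  zygosity-recovery grids, $10^4$ aligner oracle pairs) were chosen to
  give the stochastic checks comfortable statistical margins while
  keeping a full run in the low minutes on a single core.
* The per-cell read threshold of 1000 is kept as the package default
  (matching the ~28-amplicon regime it was defined for) and scaled in
  simulations to the 6-amplicon demonstration panel.

## Known limitations

* No HDR or base-editing quantification; no frameshift annotation.
* Zygosity assumes a diploid two-allele model; copy-number variation at a
  target will mislead the 20/80 thresholds.
* The k-mer prescreen in the batch aligner could in principle miss an
  equally-scoring amplicon that shares no 8-mer with the read; the
  exhaustive per-read path is available where that matters.
* Barcode collision between distinct cells is not corrected (no
  whitelist); optional Hamming-1 merging is deliberately off by default
  because the platform's barcode chemistry is not public.
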