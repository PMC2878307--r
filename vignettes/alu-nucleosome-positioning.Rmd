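---
title: "Methods: nucleotide periodicity and nucleosome positioning around Alu elements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nucleotide periodicity and nucleosome positioning around Alu elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alunuc)
```

## The scientific problem

Roughly 147 bp of DNA wrap each nucleosome core, with ~20 bp of
linker-histone-bound DNA between cores, so the nucleosome repeat length is
about 170--200 bp.  In yeast, worm, fly and plant genomes, nucleosome
positioning leaves a well-known ~10-bp periodicity of AA/TT (and related)
dinucleotide steps.  Primate genomes behave differently: their dominant
sequence periodicities sit at ~84 bp and ~167 bp and are carried almost
entirely by Alu short interspersed elements (SINEs), the most abundant
repeat family in the human genome.  A dimeric Alu (~300 bp) consists of
two GC-rich monomers flanking an A-rich linker and ending in a poly(A)
tract; the free left and right monomers (FLAM, FRAM) occur on their own.
Nucleosomes occupy one or two preferred slots inside these elements (the
right arm of the dimer being disfavoured), are excluded from the A-rich
linker and tail, and phase the neighbouring nucleosomes at the repeat
length; Alu bodies and their immediate flanks are transcriptionally
near-silent.

`alunuc` implements the complete analysis behind those statements as a
tested pipeline: spectral periodicity of nucleotide steps, Alu
classification, paired-end nucleosome-centre metaprofiles, tiling-array
distance profiles against a shuffled null, and 5'-tag expression rates —
together with a synthetic-data generator that plants all of these
structures so that every stage can be verified in a closed loop without
external downloads.

## Spectral periodicity of nucleotide steps

A *step class* is a strand-symmetric mono- or dinucleotide category: 2
mononucleotide classes (A/T, G/C) and 10 dinucleotide classes (6
complementary pairs such as AA/TT plus the palindromes AT, CG, GC, TA).
For a fragment of length $L$ the target step is encoded as a 0/1
indicator $B(k)$ of length $N = L-1$ (mononucleotide indicators are
truncated by one position so that both kinds share the same transform
length).  The power spectrum is

$$F(n) = \left|\sum_{k=0}^{N-1} \big(B(k)-\bar B\big)\,W(k)\,
  e^{-2\pi i nk/N}\right|^2, \qquad n = 0,\dots,N/2-1,$$

with the Welch window $W(k) = 1-\big((k-\tfrac{N-1}{2})/\tfrac{N-1}{2}\big)^2$,
and the signal-to-noise ratio is $R(n) = F(n)\,/\,\overline{F}$, where
$\overline F$ is the mean of $F$ over all reported bins, the DC bin
excluded.  $R(n)$ measures the relative strength of the periodicity
$p = N/n$ bp.  Per-fragment $R$ values are averaged bin-wise over
fragments sampled from the genome.

Three choices here deserve comment:

* **Mean-centring.** A step indicator has a large positive mean, and the
  window shape leaks that mean into the lowest two or three frequency
  bins: without centring, an i.i.d. random sequence shows S/N above 100
  at $n=1$--$2$.  We therefore subtract $\bar B$ before windowing
  (`power_spectrum(center = TRUE)`, the default); all other bins are
  essentially unchanged, and the DC bin is additionally excluded from
  both output and background mean.
* **The random control is not flat at 1.**  Overlapping dinucleotide
  indicators are lag-1 correlated even on i.i.d. sequence (AA at $k$ and
  $k+1$ both require AAA), so the long-period S/N baseline of a random
  genome is ~1.3, not 1.  This is precisely why the pipeline computes a
  matched random-composition control (`mode = "random"`): peak heights
  are judged as the *excess* over that control, never over 1.
* **Fragments.**  The standard fragment length is 8193 bp ($2^{13}+1$,
  giving $N = 8192$), sampled uniformly over all gap-free (N-free) start
  positions, independently (overlap between fragments is allowed — at
  genome scale it is negligible, and at the simulation scale it only
  reduces the effective sample size, which the tests account for).  In
  `mode = "masked"` the element intervals are replaced by N first, and
  fragments are then drawn from the remaining N-free windows, so masked
  spectra measure the genome *outside* the masked family.

Peak reporting (`find_spectrum_peaks`) smooths the spectrum with a 5-bin
moving average before locating local maxima, because long-period bins are
sparse ($p = N/n$ jumps in large steps at small $n$); ties rank the
longer period first.  For *height* comparisons between raw, masked and
random spectra at long periods we use a wider 21-bin moving average: the
peaks in question are broad, and in masked mode fragments come from a
limited set of element-free windows, so a narrow-bandwidth height
estimate is noisy while a wide one is stable.

## Alu classification

RepeatMasker-style annotations are classified by `repName` pattern —
names containing `FLAM` (or equal to the historical `FAM`) are free left
monomers, names containing `FRAM` free right monomers, any other name
starting with `Alu` a dimer candidate — and then filtered by class length
window: dimers 280--320 bp, FLAM 110--150 bp, FRAM 150--190 bp.  Copies
outside their window are discarded as incomplete.  The name map is a
plain two-column table and can be replaced (`read_name_map`) when a
curated list is available; the default reproduces the three-way split for
the standard UCSC names.  All coordinates are 0-based half-open
internally (BED convention; `rmsk` `genoStart` is already 0-based), and
an element's centre is `floor((start+end)/2)`.

## Nucleosome signal from paired-end tags

Both 5' ends of each mononucleosomal fragment are sequenced, so the
midpoint of the two 5' ends (`floor((fwd5+rev5)/2)`) estimates the
nucleosome core centre.  Pairs are accepted when the insert
`rev5 - fwd5 + 1` lies in 122--172 bp (inclusive), the window used when
mapping 36-bp mononucleosome reads.  Because MNase digestion is
imprecise, the midpoint histogram is coarse-grain smoothed; we implement
this as convolution with a uniform kernel whose width (odd, default
21 bp) is a parameter, the simplest kernel consistent with a smoothed
positional distribution of tag frequency.  The result is normalised so
the genome-wide sum is $10^9$ — parts-per-billion (p.p.b.) units — making
libraries of different depth directly comparable; this mass is conserved
exactly through every downstream step and is asserted in the tests.

The matched background drops paired fragments with a fixed 147-bp insert
(a complete core) uniformly on the genome and pushes them through the
identical pipeline.  Element-anchored metaprofiles average the signal at
each offset in a +/-1000-bp window around the element centre (or either
end), flipping minus-strand elements so that "left" always means the
element's 5' side — Alu elements are oriented structures, so
strand-aware averaging is the default.  Elements whose window leaves the
chromosome are excluded and counted.

Unique tags are attributed to an Alu by their *midpoint* (midpoints are
the analysis currency throughout).  Multi-hit tags are classified by the
fraction of their hits whose midpoints fall in Alu elements (complete /
partial / none); for profile construction one hit can be drawn uniformly
per sufficiently Alu-associated tag (`complete_only`, or `ge85` for tags
with more than 85% of hits in elements).  The accompanying dispersion
statistic — the per-tag standard deviation (sample SD) of the absolute
distances between each hit's midpoint and its nearest element centre —
quantifies how interchangeable the hits are: values near zero mean every
hit sits at the same position relative to some element copy, so the
random choice cannot distort an element-anchored profile.  Distances are
taken as absolute values so that a hit in a reverse-oriented copy
(mirrored offset) counts as equidistant.

Reading slots and phasing off a metaprofile uses
`profile_local_maxima`: a 31-position moving average suppresses sampling
noise, and flanking-peak analyses keep maxima of at least 30% of the
strongest flanking peak before measuring successive spacings — minor
noise bumps between genuine phased peaks would otherwise corrupt the
spacing estimate.

## Tiling-array distance profiles

Probes whose centres lie within 600 bp of an element edge are associated
with that edge, with signed distances: for the 5' edge, 0 is the first
base inside and negative distances are outside; for the 3' edge, 0 is
the first base outside and negative distances are inside.  A probe may
associate with both edges of a short element, but an edge only claims
probes on its own side — a probe beyond the element's far edge is not
given an inside-direction distance larger than the element itself (the
alternative double-counts every downstream-flank probe as "deep inside"
through the 5' edge of a 300-bp element, which is both misleading and
destroys the interpretability of the inside bins).  Values are averaged
per distance bin (bin width 1 by default; 50 bp in the examples, matching
the probe spacing).  The null band permutes hybridisation values across
all probes (positions fixed), recomputes the profile, and repeats 10
times; per-bin mean and SD of the shuffled profiles define the
background.  Since the shuffled mean is the array-wide average, neutral
bins of an on-average-enriched profile sit *below* it — depletion calls
should therefore use an effect-size criterion alongside the 2-SD rule,
as the tests do.

## Expression rates

5'-end cDNA tag rates are compared across region categories: Alu bodies;
six 300-bp flank windows per element (`[-900,-601] ... [+601,+900]`,
where -1 is the last base upstream of the 5' end and +1 the first base
downstream of the 3' end, oriented by element strand); 301-bp windows
(+/-150 inclusive) around gene TSSs; and equally many +/-150-bp windows
around random N-free sites, drawn 10 times independently so the random
control carries a mean and SD.  A tag counts once per category when its
5' position falls in any region of the category.  The per-category rate
is

$$\mathrm{rate} = \frac{\text{tags in category}}{\text{total mapped tags}}
  \times 10^6 \;/\; \text{number of regions},$$

i.e. tags-per-million-mapped per region.  The exact published form of
this normalisation was not reproducible from the source text; this
reconstruction matches the reported orders of magnitude (tens of p.p.m.
at TSSs with ~26k regions and ~40M tags) and is flagged here
prominently.  Tags count regardless of strand by default; `stranded =
TRUE` restricts TSS windows to sense tags.

## The synthetic-data generator

`sim_config()` defines the study conditions; `simulate_genome()` and its
companions emit a genome FASTA, element BED, tag pairs, probe tables and
5' tags that round-trip bit-exactly through the package readers and are
byte-deterministic given the seed.  Defaults, with reasons:

| parameter | default | why |
|---|---|---|
| `genome_len` | 1 Mb | smallest scale at which ~8-kb fragments, ~200 elements and phased flanks coexist comfortably |
| `base_composition` | A/T 0.295, C/G 0.205 | human-like 41% GC |
| `alu_coverage` | 0.07 | genome-wide dimer coverage of Alu in human (~7%) |
| `class_weights` | 0.92/0.06/0.02 | relative abundance of dimer/FLAM/FRAM annotations |
| `dimer_template` | 132+20+150+15 bp | left monomer, A-rich linker, right monomer, poly(A); left monomer slightly shorter than right |
| `monomer_homology` | 0.8 | the two arms of a dimer are homologous |
| `monomer_gc`, `linker_a` | 0.6, 0.85 | GC-rich monomers, A-rich linker |
| `mutation_rate` | 0.05 | per-copy divergence from the family consensus |
| `slot_offsets` | 66, 230 | monomer centres: one nucleosome slot per arm |
| `slot_weights` | 1, 0.4 | right-arm slot disfavoured |
| `phasing_period` | 185 bp | middle of the 170--200-bp nucleosome repeat range |
| `phasing_decay` | 0.7 per nucleosome | phasing fades with distance; weights scale as `decay^k` so `decay = 0` gives flat flanks |
| `tag_insert_range` | 122--172 | matches the mapping filter |
| `n_tags` | 200,000 | enough for ~10-bp-resolution profiles at this genome size |
| `lambda_tss, bg, flank, alu` | 0.05, 2e-3, 5e-4, 1e-4 /bp | tag intensities ordered TSS >> background > flank > Alu, as in the expression comparison |

Nucleosome centres are drawn from a mixture of in-slot Gaussians (SD
10 bp), phased flanking Gaussians at $(k-\tfrac12)\times$ repeat length
outside each edge with geometric decay, and a 10% uniform background;
centres landing in the A-rich linker or poly(A) intervals are redrawn
(nucleosome-free regions).  A fraction of in-slot tags is flagged
multi-hit with alternative hits at the strand-aware homologous offset of
other copies of the same class, mimicking the ambiguity of mapping into
a high-identity repeat family.

What the generator deliberately does **not** model: Alu subfamily
phylogeny and age structure, indels (copies have fixed class lengths),
CpG decay, sequencing errors, mappability biases, chromatin-state
heterogeneity between cell types, and the genome-wide isochore
structure.  Closed-loop passes therefore demonstrate that the *analysis
machinery* recovers planted structure of the expected shape and
magnitude — they do not by themselves validate conclusions about real
chromatin data, where these unmodelled features matter.

## Numerical conventions and degenerate inputs

* Coordinates 0-based half-open everywhere; midpoints and element
  centres round down.
* Insert bounds inclusive; spectra exclude the DC bin; spectral ties
  rank longer periods first.
* `sn_ratio` on an all-zero spectrum, fragment sampling on an all-N
  genome, empty probe sets, and zero-region categories raise immediate
  errors rather than returning NaN.
* All stochastic functions accept a seed and are bit-reproducible;
  `run_alu_pipeline` derives per-stage seeds as `seed + 100*stage` and
  records them, with parameter and output hashes, in a manifest.

## Problem sizes used by the tests

The unit suite uses a 300-kb genome with 60k tags; the end-to-end
checks and `scripts/acceptance.R` use the default 1-Mb genome, 200k
tags, 300 fragments per spectral mode and 120 fragments per planted
period.  These sizes keep the whole suite in a few minutes while leaving
comfortable statistical margins for every assertion; all thresholds
(slot tolerance +/-15 bp, spacing in 170--200 bp, right/left ratio in
0.25--0.6, 5-fold masking reduction, exact planted-band recovery) are
stated at the sizes above.

## Known limitations

* The coarse-grain smoothing kernel (uniform, 21 bp) is one reasonable
  reading of "coarse-grain smoothing"; the width is exposed as a
  parameter precisely because the original is underspecified.
* The p.p.m. normalisation is a reconstruction (see above).
* The default repeat-name map approximates the curated class list; use
  `read_name_map()` with a curated table for production annotation work.
* Masked-mode spectra sample only element-free windows, which at high
  masking density biases fragments toward repeat-poor regions; this is
  inherent to the gap-free sampling rule.
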