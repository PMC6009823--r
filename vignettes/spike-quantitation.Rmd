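---
title: "Absolute microbiota quantitation with synthetic spike-in standards"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Absolute microbiota quantitation with synthetic spike-in standards}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikequant)
```

## The problem and the model

Amplicon sequencing of marker genes — prokaryotic 16S rRNA, eukaryotic 18S
rRNA, fungal ITS — yields read *proportions*. Proportions say nothing about
microbial load, and reads produced with different primer pairs cannot be
compared at all. A shift in a taxon's relative abundance can therefore be an
artefact of what the rest of the community did: a taxon whose absolute
abundance rises can still fall in relative terms if its neighbours rise
faster.

`spikequant` implements the spike-in internal-standard solution. A chimeric
synthetic DNA construct — the primer pair's two binding sites (PBSs)
flanking a random "stuffer" matched in length and GC content to the natural
amplicon — is added to the raw sample in a known copy number $N_S$ per gram
(or ml). Spike and community DNA are then co-isolated, co-amplified and
co-sequenced, so every multiplicative distortion along the way (isolation
loss, PCR efficiency, loading) hits both alike and cancels in the read
ratio. The estimator is

$$\widehat{A} \;=\; \frac{R_{\text{micro}}}{R_{\text{spike}}} \times N_S,$$

gene copies per unit of sample, where $R_{\text{micro}}$ counts taxon-
annotated (non-synthetic, non-unassigned) reads and $R_{\text{spike}}$ the
synthetic reads of the same amplicon family (`absolute_abundance()`).
Conditional on the sequencing depth, reads are modelled as a multinomial
draw with category probabilities proportional to template copies; the
estimator is the maximum-likelihood plug-in for the copy ratio and is
consistent as depth grows.

Per-taxon absolute profiles follow by distributing $\widehat{A}$ over taxa
in proportion to their microbial read fractions (`taxon_absolute()`), which
preserves the family total under any coarser aggregation.

## Spike design

`design_spike()` assembles `forward PBS + stuffer + revcomp(reverse PBS)`
so that PCR on the spike yields a product of exactly the family's expected
amplicon length. The stuffer is rejection-sampled from i.i.d. base draws
biased to the GC target, and a candidate is accepted only if

* its GC fraction is within `gc_tolerance` of `gc_target` (defaults 0.5
  and 0.02 — the natural amplicons of all three families sit near 50% GC,
  and matching GC equalises denaturation and amplification efficiency);
* no sliding window lies within 2 substitutions of any primer-binding site
  in the experiment, forward or reverse-complement (a PBS inside the
  stuffer would create nested amplification artefacts);
* no homopolymer exceeds 8 bases (synthesis and sequencing both degrade on
  long runs).

The attempt budget is 10,000 draws; exhausting it raises an error, which is
the desired behaviour for over-constrained inputs (e.g. a GC target of 1
with a forbidden single-base motif `G`). Ambiguity codes in the primers
(e.g. `Y`, `M` in 515F) are resolved to concrete bases in the synthesised
construct; the resolved bases still match the degenerate primers.

Default amplicon length targets are 253 bp (16S V4, window 252–254), 211 bp
(18S, window 210–212) and 272 bp (ITS, window 250–300). The first two are
the centres of the read-length windows applied downstream; 272 bp is the
modal fungal ITS amplicon size in soil. We read the "272 bp" design figure
as the full amplicon length (consistent with the 250–300 bp ITS window);
users who want a 272 bp stuffer *between* the primers can set a larger
target in the primer config. `validate_spike()` re-checks all design
constraints and `in_silico_pcr()` confirms that each spike yields exactly
one product with its own primer pair and none with the other families'.

## Dose tables and the planner

`mass_to_copies()` converts picogram doses through a measured stock
calibration (copies per ng); `spike_level_table()` ships the standard
eight-level gradient dosing 1–100% of a per-family top mass. The measured
stock takes precedence over the first-principles length conversion
(`copies_per_ng_from_length()`, 650 Da per base pair) because dose tables
are calibrated against the stock. Copies are reported internally at full
precision; printed tables round to 2 significant figures.

How much spike should be added? If $E$ environmental gene copies compete
with $N_S$ spike copies, the expected synthetic share of the output is

$$SR_{1000} = \frac{N_S}{(N_S + E)/1000}$$

synthetic reads per 1000 total (`sr1000()`). Useful quantitation needs the
spike neither lost in the community (too few synthetic reads) nor drowning
it (too few microbial reads); the acceptance window is 200–800 synthetic
reads per 1000, strict at both ends, equivalently a spike dose of 20–80% of
the total template pool. The window and the dose rule are the same
predicate at these bounds, and both are reported by `select_levels()`.
Against expected soil abundances of $3.0\times10^9$ (16S),
$1.85\times10^8$ (18S) and $6.65\times10^6$ (ITS) copies per gram, the
default gradient places levels 7–8 (16S), 3–6 (18S) and 1–2 (ITS) in the
window. When a pilot's per-level estimates are averaged to set $E$, we
average over all levels by default; averaging only in-window levels is a
configuration choice.

```{r planner}
tab <- spike_level_table()
sel <- select_levels(tab, c(P = 3.0e9, E = 1.85e8, F = 6.65e6))
subset(sel, in_window, select = c(family, level, sr1000))
```

## Read processing

Reads are merged/single-end amplicons laid out as
`barcode + pad + amplicon + revcomp(pad) + revcomp(barcode)` (dual
barcoding against 12 bp amplification pads added in a first PCR).
`demultiplex()` assigns each read to exactly one sample or to the
unassigned pool (barcodes exact by default, pads allowed 1 substitution),
trimming barcodes and pads. `assign_family()` requires the forward PBS at
the 5' end and the reverse PBS reverse-complement at the 3' end, each
within 1 substitution by default; multi-family matches resolve to the
fewest total mismatches, ties to the first family in the configured order.
Length windows apply to the *primer-inclusive* amplicon length — it is
sequenced read lengths that are filtered, before primer trimming.

Classification is nearest-neighbour by Hamming distance (default budget 2
substitutions) against a labelled reference set, with the family's spike
sequence taking priority and ties between taxon references breaking to the
lexicographically first label, deterministically. Denoising (zOTU
inference) is deliberately out of scope: the reference set plays the role
of the denoised sequence table in simulations, and real studies can supply
a pre-annotated count table as TSV instead. Read counts are conserved at
every stage: input = classified + unassigned.

## Quality filters

All filters operate per (sample, family) and are independent and
idempotent; removing a flagged sample never changes the survivors' values.

* **Low depth** — total reads below 40% of the sample-group mean (the
  sample itself included in the mean; a leave-one-out variant is
  available). A single-sample group is never flagged under the default.
* **Spike ratio** — synthetic/microbial read ratio at least 2.5× the group
  mean ratio; zero microbial reads flag unconditionally.
* **Magnitude outlier** — a replicate whose estimate differs from the
  median of the *other* replicates by ≥ 1 in log10. The order-of-magnitude
  rule has no published formula; the median-of-others form is robust to a
  single bad replicate and symmetric in its treatment of high and low
  outliers.
* **Window** — observed $SR_{1000}$ outside the strict 200–800 window.
  Descriptions of the window differ between an inclusive and a strict
  reading; the strict form is implemented with `strict = FALSE` available.
* **Contamination** — a manual manifest annotation passed through; no
  automated contaminant detection is attempted.

The per-1000 normalisation is computed after the length filter, on the
same read universe that is analysed; computing it before filtering is a
configuration choice away (filter order is explicit in `process_reads()`).

## The isolation-loss correction

When spikes are added *before* DNA isolation, isolation loss multiplies
spike and community templates alike and cancels in the ratio — this is the
recommended protocol. When spikes are added to already-isolated DNA the
loss is invisible to the spike, the estimate is biased low by the isolation
efficiency, and `isolation_correction()` rescales by predicted total DNA
over the DNA actually used. The function refuses to run on
spike-before-isolation samples, where applying it would double-correct.
The simulator reproduces this contrast (`spike_timing = "before"/"after"`),
and the package's tests verify that a 50% simulated loss is recovered by
the correction and invisible to the before-isolation protocol.

## Comparing relative and absolute profiles

`compare_groups()` runs per-taxon two-sample t-tests between groups with
Bonferroni adjustment over the taxa tested
(`p_adj = min(1, p × n_tested)`) and tiers `*`, `**`, `***` at adjusted
p < 0.05, 0.01, 0.001. Welch's unequal-variance test is the default — the
equal-variance assumption buys nothing here and fails for absolute
profiles whose variance scales with load; Student's test is a flag away.
Zero-variance-in-both-groups taxa are reported as untestable rather than
failing the run. Tests are applied to per-sample values, not level
averages.

Community structure is summarised by Bray–Curtis dissimilarity
($d = \sum|x-y| / \sum(x+y)$, via `vegan`) after the PRIMER-style
pre-treatment — per-sample standardisation to proportions, then square
root — and ordinated by classical metric MDS (`cmdscale`), chosen for
exact determinism; Kruskal non-metric MDS is available, initialised from
the classical solution so it too is reproducible. Standardisation makes
the dissimilarity invariant to sample-wise rescaling, which is exactly why
removing spike reads upstream cannot distort the community comparison.

## The simulator and what it does (and does not) show

`make_community()` draws taxon abundances lognormally (default natural-log
SD 1.5, a heavy-tailed soil-like rank-abundance curve) and scales them to
per-family totals of $10^9$ / $10^8$ / $10^7$ copies per gram for 16S /
18S / ITS — the magnitudes expected of temperate soils.
`sequence_sample()` draws reads multinomially with probabilities
proportional to (isolation-scaled) template copies, and `emit_fastq()`
realises the latent counts as raw reads with barcodes, pads and optional
i.i.d. substitution errors (default 0, so that oracle tests can demand
exact round trips; qualities are a constant 'I' as nothing downstream
consumes them). `simulate_experiment()` wraps the standard two-soil,
eight-level, triplicate design with per-replicate lognormal biological
noise (SD 0.1 on the log scale). PCR amplification bias is neutral by
default — length- and GC-matching of the spike is precisely the design
argument for that default — and chimera formation, polymerase error
spectra and size selection are not modelled.

`scenario_relative_vs_absolute()` constructs the signature compositional
trap: group B carries 1.5× more of a designated taxon in absolute terms
but 3× more of everything else, so the taxon's relative abundance falls
while its absolute abundance rises. The pipeline recovers both directions
with Bonferroni-significant tests at 10 replicates per group and
$10^5$ reads.

Passing simulations demonstrate correctness of the computation — the
estimator, the filters, the accounting — under the multinomial model. They
do not demonstrate robustness to what the simulator does not contain:
taxon-specific amplification bias, chimeras, reagent contamination, or
spike adsorption to environmental matrices (low spike doses can be
retained by soil particles, a real-data effect outside the model).

## Numerical and design notes

* Stuffer generation and every simulation are deterministic given a seed;
  derived child seeds stay within 32-bit integer range.
* Mass↔copies conversions round-trip to 1e-9 relative tolerance; reporting
  rounds to 2 significant figures only at the edge.
* The first-principles genomic conversion (`genome_copies_per_ng()`)
  yields ≈ 4.52e5 16S copies per ng for a 4e9 Da genome with 3 operons
  with standard constants (650 Da/bp, $N_A = 6.022\times10^{23}$);
  published figures computed with unstated constants may differ, and the
  function documents rather than reproduces such discrepancies.
* Monte Carlo acceptance of a bounded error rate (the family-wise type-I
  error of the Bonferroni procedure, nominally ≤ 0.05) is tested as a
  one-sided binomial check at 500 replicates — a point assertion
  `estimate ≤ 0.05` would reject a correct implementation almost half the
  time, since the true FWER at 20 independent taxa is ≈ 0.049.
* Problem sizes in the test-suite simulations (depths of $10^4$–$10^5$
  reads, 100–500 Monte Carlo replicates, communities of 8–30 taxa) were
  chosen to put sampling error well below the tolerances being asserted
  while keeping the suite quick to run routinely.

## Known limitations

* Gene copies are not converted to cell counts: rRNA operon copy number
  varies across taxa by an order of magnitude, and any fixed divisor would
  fabricate precision.
* Paired-end merging, quality trimming, denoising and database annotation
  are upstream concerns; the package consumes merged reads plus labelled
  references, or a pre-made count table.
* The annotation rank is whatever the reference labels encode; the package
  does not harmonise ranks across families.
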