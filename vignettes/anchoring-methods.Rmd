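---
title: "Genetic-map and linked-read anchoring: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetic-map and linked-read anchoring: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anchormap)
```

# The problem

A long-read draft assembly of an inbred plant genome arrives as a few
hundred contigs. Two independent sources of long-range information can
organise them into chromosome-scale pseudomolecules:

* **Linked reads** (10x-style): short reads tagged with a barcode
  identifying their long source molecule. When one molecule spans the
  junction between two contigs, its barcode shows up near the facing
  ends of both, so barcode sharing between contig ends is physical
  adjacency evidence at the 10-100 kbp scale.
* **A biparental RIL genetic map**: genotyping-by-sequencing markers
  segregating in an F8 recombinant inbred population. Markers that
  co-segregate are genetically linked regardless of which contig they
  sit on, so linkage disequilibrium between contigs assigns them to
  chromosomes (linkage groups) and recombination-breakpoint counts
  order and orient them at the 0.1-10 cM scale.

`anchormap` implements both evidence channels, their combination into
AGP-representable pseudomolecules, misassembly (chimeric contig)
detection, and the downstream recombination landscape (Marey maps,
sliding-window rates, pericentromere calls). A synthetic-data module
generates the whole world — genome, RIL population, fragmented contigs,
barcoded molecules — with known truth, so every stage is testable
without external data.

# Models

## RIL genotypes and the imputation HMM

An F8 single-seed-descent line is a near-homozygous mosaic of the two
parental genomes; residual heterozygosity halves each selfing
generation, to $2^{-7} \approx 0.8\%$ at F8. Genotype calls are coded
A/B/H/missing after polarising by the parents (markers whose parents
are not opposite homozygotes are dropped).

Marker-level filters mirror the published GBS pipeline: calls with
genotype quality below 30 are masked, then markers with minor allele
frequency below 0.3, heterozygosity above 0.05, or fewer than a minimum
number of genotyped individuals are removed. Removal is attributed to
the first failing rule in the order *coverage, MAF, heterozygosity* —
coverage first because MAF is undefined on an ungenotyped marker.

Parental assignment and imputation use a two-state HMM per sample per
contig (states = parents), with per-step switch probability
`hmm_switch_prob = 0.003` and emissions: matching homozygote
$1 - e$, opposite homozygote $e = 0.01$, heterozygous call 0.05 from
both states, missing uninformative. The Viterbi path labels every
marker. Emissions for H and missing are fixed rather than estimated
because F8 heterozygosity is below 1% and estimating them from one
contig's data would be noise.

One property of the MAP path matters downstream: a segment supported by
a *single terminal marker* is cheaper to explain as a genotyping error
($\ln 0.01$) than as a crossover ($\ln 0.003$), so real crossovers
falling between a contig's last two markers are smoothed away for a few
percent of samples at every contig end. The exhaustive-enumeration
oracle in the test suite confirms this is the true argmax, not a bug.
Consequently **linkage-group inference runs on the filtered genotype
calls**, whose errors are unbiased, rather than on the imputed labels;
imputed labels are used where their completeness matters (breakpoint
counting, scaffold chaining).

## Breakpoints to centimorgans

For adjacent markers in the anchored order, the breakpoint count is the
number of samples whose parental label changes; the interval distance
is
$$\mathrm{cM} = 100 \cdot \frac{\#\text{breakpoints}}{G \cdot n},$$
with $n$ samples and $G$ "generations of crossover". The published
analysis uses the round constant $G = 5$ with one expected crossover
per chromosome per generation. The simulator lets this be checked: the
expected junction density of a selfed line at generation $F_t$ is
$2\,(1 - 2^{-(t-1)})$ per Morgan (the Haldane–Waddington limit is 2),
so `ril_effective_meioses(7)` $= 1.984$ makes the estimator unbiased
against the F8 simulation — the calibration test recovers a 100 cM
chromosome within 10% at $n = 200$. Both constants are configurable;
the package default remains 5 to match the published rule, and
`kosambi_cm()` provides the mapping-function conversion
$25\ln\!\frac{1+2r}{1-2r}$.

## LD linkage groups

$r^2$ is the squared Pearson correlation of 0/1 allele indicators over
samples that are non-missing homozygotes at both markers (the
population is inbred; H and missing are excluded pairwise). An
undefined $r^2$ (monomorphic after exclusion, or fewer than two
complete samples) is `NA`, never 0, so it cannot bias decay curves.

Two contigs are joined when at least `min_ld_pairs = 3` inter-contig
marker pairs exceed `r2_threshold = 0.8`; connected components are the
linkage groups. The published rule is the bare threshold; the
pair-count floor suppresses single-pair spurious joins and can be set
to 1. For tractability, marker pairs per contig pair are capped
(default 200) by a deterministic subsample taken **from the two ends of
each contig** — junction-proximal pairs carry the linkage signal, and
an evenly spread subsample was measurably worse at recovering true
junctions.

## Barcode scaffold graph

Barcodes are collected in windows of `end_window_bp = 20` kbp at each
contig end (truncated to half the contig). Barcodes seen at more than
4 ends are discarded as repeat-driven. Edges between ends on different
contigs keep the shared-barcode count (minimum 5) and a weight
normalised by the smaller end-set size, correcting coverage asymmetry.
A Salsa-like greedy pass visits edges by decreasing weight and accepts
an edge iff both ends are unused and no cycle over contigs arises
(union-find); accepted edges plus each contig's internal edge decompose
into simple paths whose orientations follow from the joined end types.
Tie-breaking is total (weight, count, lexicographic end pair), so the
output is invariant to input order. The exact scoring used by Salsa is
not reproduced — only the genre of greedy, cycle-free edge clustering —
and the rule is labelled as a stand-in.

## Misassembly detection

A chimeric contig joins sequence from two genomic locations. Two
complementary detectors are combined, mirroring the two data types the
source analysis says it used:

1. **Marker-linkage rule.** Within each contig, adjacent-marker $r^2$
   below `segment_r2_threshold = 0.2` splits the contig's markers into
   segments; segments (not whole contigs) are the nodes of linkage-group
   inference, so a chimera cannot silently bridge two chromosomes. A
   contig whose segments land in different groups, each contiguous
   along the contig, gets one break per discordant gap; interleaved
   groups flag the contig unresolvable.
2. **Barcode continuity scan.** On a 10 kbp grid, the number of
   barcodes with reads within 20 kbp on *both* sides of the grid point
   — excluding a 6 kbp guard strip around it — collapses to ~0 at a
   junction no molecule spans, while staying near molecule coverage
   elsewhere. The guard strip guarantees a near-zero grid point within
   5 kbp of any junction. A low run qualifies only with healthy
   continuity within 60 kbp on both flanks, because molecule coverage
   also ramps down at true sequence termini. This catches chimeras
   whose minor part carries no post-filter markers, which the LD rule
   cannot see.

Break positions are the continuity minimum within the implicated gap.
Split fragments re-enter the pipeline as first-class contigs; the two
ends newly created by a split are excluded from the barcode graph
because the break position is uncertain at the 5-10 kbp scale — the
genetic map still anchors both fragments.

## Ordering and orienting

Scaffold paths are assigned to linkage groups by marker majority
(minority share above 0.2 flags a conflict). Within a group, scaffolds
are chained by greedy joining of nearest scaffold ends, where the
distance between two ends is the fraction of samples whose consensus
parental labels (over up to 5 terminal markers) differ — a two-point
recombination-fraction estimate. The chained order fixes a global
marker order; breakpoint counting along it yields cumulative cM.
`order_and_orient()` then applies the stated rules: scaffolds sorted by
median marker cM (ties: more markers, then smallest contig id; median,
not mean, for robustness to stray markers) and oriented by the sign of
the Spearman correlation between within-scaffold physical position and
cM (Spearman, not Pearson, because the Marey relation is monotone, not
linear). Single-marker or zero-correlation scaffolds get `+` and an
orientation-unknown flag. How the original analysis reconciled scaffold
order with genetic order when they disagreed is unstated; here the
scaffold-internal order always wins unless the conflict flag routes the
scaffold to misassembly logic.

Pseudomolecules are emitted as AGP v2.1 (component lines `W`, gaps `U`
of 100 bp, `scaffold`/`yes`/`paired-ends;map`), 1-based inclusive;
internal coordinates are 0-based half-open throughout.

## Recombination landscape

Marey points are (anchored bp, cumulative cM) per chromosome, with
duplicate bp collapsed to the maximum cM. Rates use the sliding-window
interpolation the source describes: windows of 1 Mbp every 200 kbp from
position 0 (trailing partial windows dropped, so a chromosome of length
$L \ge w$ has $\lfloor (L-w)/s \rfloor + 1$ windows), with cM at
arbitrary bp linearly interpolated between flanking markers and
constant beyond terminal markers. At step = window the rates telescope
exactly to the chromosome's total cM — a test asserts this identity.

Pericentromeres: the published rule "recombination rates exceeded
2 Mbp/cM" is converted to the strict window inequality
rate $< 0.5$ cM/Mbp; the boundary is assigned to *not* pericentromeric
(a side had to be picked; strict keeps calls conservative). Whether the
rule applies to loci or windows was ambiguous; windows were adopted to
match the sliding-window workflow. Consecutive low-rate windows merge
into maximal intervals. kbp-per-cM is physical length over genetic
length, consistent with the paired phrasing of the published summary
statistics.

# The synthetic world

The generator is a stated world, not a tuning dial. Where the source
analysis states a condition it is reproduced; the remaining
distributional choices are stand-ins, made once:

* **Genome**: 11 chromosomes. The reference simulation uses
  11 x 5 Mbp = 55 Mbp with 50 cM per chromosome. The genetic length is
  the one deliberate scale-down decision: the real map has ~97 cM per
  ~46 Mbp chromosome across ~19 anchored contigs, i.e. ~5 cM per
  contig; at 5 Mbp per chromosome, 50 cM preserves that per-contig
  genetic spacing (~4.5 cM across ~11 contigs), whereas keeping ~100 cM
  would impose 10x the real recombination density per kbp and defeat
  the $r^2 > 0.8$ rule for reasons that are artifacts of physical
  shrinkage, not properties of the method. The cM-calibration check
  uses a single 100 cM chromosome, as its contract states.
* **Marey shape**: piecewise linear with an optional central plateau
  (fraction of length, rate ratio) standing in for the pericentromere;
  the plateau-recovery check uses fraction 0.4 at ratio 0.1 on a 50 Mbp
  chromosome so the plateau rate (0.31 cM/Mbp) sits below the 0.5
  cM/Mbp call threshold, as real pericentromeres do.
* **Meiosis**: crossover count per chromosome per gamete is
  Poisson(genetic length / 100) — no interference (Haldane); the
  source states no interference model. Positions are uniform in cM via
  the inverse Marey map. Single-seed descent: one selfed offspring per
  line per generation, 7 generations to F8.
* **Genotyping**: missingness 10% and error 1% (uniform random
  different call) in the reference world — GBS-like after quality
  filtering; the HMM check uses 20%/1% as its contract states. All
  calls carry GQ 40; the coverage filter is scaled to the population
  (50 of 100), preserving the published 100-of-238 proportion.
* **Contigs**: exponential lengths, mean 460 kbp (long-tail mix, ~120
  contigs over 55 Mbp), with a 20 kbp minimum — assemblers do not emit
  sub-20 kbp slivers into anchoring, and a 500 bp "contig" with no
  reads or markers is not a meaningful test subject. Half the contigs
  are strand-flipped; chimeras concatenate two fragments from
  different chromosomes.
* **Linked reads**: exponential molecules (mean 50 kbp), two molecules
  per barcode, 0.3 reads per kbp, 30x molecule coverage. Molecules are
  drawn on the true genome and projected through the placement, so
  chimeric junctions receive no spanning molecules — exactly the
  signal real linked reads carry.

What a green test does **not** establish: the generator has no
sequencing-error model at the base level, no segregation distortion, no
repeat-driven multi-mapping (promiscuous barcodes arise only from
barcode reuse), no missing-data structure correlated with genotype, and
uniform marker informativeness. Real data would stress the pipeline in
those directions; the module boundaries (config thresholds, the
promiscuity cap, the conflict flags) are where that stress would be
absorbed.

# Numerical choices and degenerate inputs

* All randomness flows from one master seed through named substreams
  (`substream_seed`), so each stage is independently reproducible and
  identical across runs.
* Viterbi runs in log space; ties prefer the current state and then
  state 1, making decoding deterministic.
* Greedy edge acceptance and scaffold ordering have total tie-breaks
  (documented above); both are permutation-invariant by test.
* Contigs with fewer than two informative markers fall back to
  majority-call labels and are flagged; single-marker scaffolds are
  orientation-unknown, not guessed.
* `marey_step_bp` > `marey_window_bp` is rejected at configuration
  time; chromosomes shorter than one window are skipped in profiles.
* Unknown GQ passes quality filters (the synthetic world always emits
  GQ; real VCFs that lack it are not silently discarded).

# Known limitations

* Linkage-group recovery is honest about power: a junction whose
  flanking contigs have no markers within ~0.3 of the chromosome's cM
  span can fail the $r^2$ rule, leaving an extra singleton group;
  the barcode channel usually rescues the placement but not the
  component count. Two of eight tested seeds show one such extra group.
* A chimera whose junction lies within ~26 kbp of a contig end is
  invisible to the continuity scan (no healthy left flank) and nearly
  invisible to the marker rule; such contigs would reach the output
  unbroken, as some of the real assembly's misassemblies presumably
  did.
* De-novo marker ordering (ASMap/mstmap-style) is deliberately not
  reimplemented; ordering always descends from physical positions
  within contigs plus anchoring evidence, matching the assembly-facing
  use of the map.
* NGSEP's `-c 0.003` is interpreted as a per-adjacent-marker switch
  probability (the tool's marker-indexed chain), and the 0.05
  heterozygosity filter as per-variant across samples; both
  interpretations are flagged in the operation documentation.
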