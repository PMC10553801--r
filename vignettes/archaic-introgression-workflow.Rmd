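---
title: "Detecting selection and archaic adaptive introgression with archintro"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting selection and archaic adaptive introgression with archintro}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(archintro)
```

## The scientific problem

A haplotype at high frequency in non-African populations that closely
matches an archaic (Neanderthal or Denisovan) genome admits three
explanations: positive selection on standing modern variation, adaptive
introgression of archaic sequence, or incomplete lineage sorting (ILS) of
ancestral polymorphism.  Distinguishing them requires several lines of
evidence assembled from phased haplotype panels and high-coverage archaic
genomes:

1. **Selection scans** — windowed F\_ST, Fay and Wu's H and XP-EHH, with
   signals called against the genomic background (mean ± 2 SD).
2. **Candidate filtering** — restricting the variants that could carry the
   signal to those that are common, strongly differentiated between the
   outgroup and target populations, and functionally plausible
   (non-synonymous, UTR, or CADD Phred ≥ 10).
3. **Haplotype structure** — distances of every phased haplotype to the
   archaic reference genome, haplostrips-style ordered displays, shared
   derived-allele counts and minimum spanning haplotype networks.
4. **Archaic-sharing scans** — the U(w, x, y) and Q95(w, y) statistics in
   40 kb windows, calibrated against their own genomewide distribution.
5. **The ILS length test** — whether a shared segment as long as the one
   observed could have survived recombination since the archaic split.

`archintro` implements this full path over phased VCF input, and ships a
seeded simulator that generates structured panels with a *known*
introgressed tract so that every stage can be validated against ground
truth.

## The statistics

**Hudson's F\_ST.**  Per site,
$\hat F_{ST} = \frac{(p_1-p_2)^2 - p_1(1-p_1)/(n_1-1) - p_2(1-p_2)/(n_2-1)}
{p_1(1-p_2)+p_2(1-p_1)}$,
with windows summarized as the ratio of summed numerators to summed
denominators.  The ratio-of-averages form has smaller bias than averaging
per-site ratios; per-site negatives are clamped to zero only for display,
never inside the window sums.

**Fay and Wu's H.**  The unnormalized form
$H = \theta_\pi - \theta_H$ with
$\theta_\pi = \sum 2i(n-i)/(n(n-1))$ and $\theta_H = \sum 2i^2/(n(n-1))$
over segregating sites with derived count $i$.  Both estimators are
unbiased for $\theta$ under neutrality, so $E[H] = 0$; a strong excess of
high-frequency derived alleles drives H negative.  The package tests this
expectation empirically on neutral simulated windows.

**XP-EHH.**  For a core site, EHH at position $x$ is the fraction of
haplotype pairs identical at every site from the core to $x$, the core
included; EHH at the core itself is 1 by convention.  iHH is the
trapezoidal integral of EHH over physical distance on both sides,
truncated after the first position where EHH drops below 0.05 (that final
trapezoid is included) or at the region edge.  The statistic is
$\ln(\mathrm{iHH}_A/\mathrm{iHH}_B)$, standardized to mean 0 and unit SD
over all computed cores.  These conventions (pooled-sample EHH, physical
distance, 0.05 truncation, no gap penalty) are fixed package-wide since
different published implementations vary in the details.

**U and Q95.**  In each 40 kb window, U(w, x, y) counts sites whose
derived allele is rare in the unadmixed outgroup (frequency `< w`),
common in the target (`> x`) and present in the archaic genome at dosage
fraction `≥ y`; Q95(w, y) is the interpolated 95th percentile of target
frequencies over sites passing the outgroup and archaic conditions.  The
inequalities are deliberately strict/non-strict exactly as written.
Significance is empirical: the 99th and 99.9th percentiles of each
statistic computed genomewide.  Windows with no qualifying site
contribute U = 0 to the U distribution but are excluded from the Q95
distribution — an undefined percentile cannot rank.  Both choices are
stated here because different conventions exist and the choice affects
thresholds.

**The ILS clock.**  A segment shared by ancestry alone is broken by
recombination at rate $r$ per bp per generation over the $t_1 + t_2$
years separating the modern and archaic lineages, so the expected shared
length is $L = 1/(r\,(t_1+t_2)/g)$ and an observed length $x$ survives
with probability $1 - \Gamma_{CDF}(x;\, k,\, 1/L)$, shape $k = 2$
because the segment extends independently to each side of its focal
site.  At the calibration used throughout (r = 1.58 × 10⁻⁸ from the
region's average recombination rate, $t_1 = 275{,}000$ and
$t_2 = 190{,}500$ years under a mutation rate of 10⁻⁹ per bp per year,
g = 25), $L \approx 3.4$ kb, and a 70,614 bp shared haplotype has
$p \approx 2.1 \times 10^{-8}$:

```{r ils}
params <- IlsParams()
params
ilsPvalue(70614, expectedIlsLength(params))
```

An independent Monte-Carlo oracle (`ilsMcOracle()`, the empirical
survival of a sum of two exponentials) validates the closed form in the
test suite.

## The synthetic-data generator

The generator (`simulateStructuredPanel()`) is a fixed-topology
donor-copying model, deliberately simpler than a coalescent with
recombination so that every expectation is analytically checkable:

* **Modern background.**  Haplotypes descend from a neutral Kingman
  coalescent drawn independently per 40 kb block (free recombination
  between blocks, none within), with mean pairwise coalescence time
  `tModernCoalescence` (default 10,000 generations).  A coalescent
  background — rather than independent star-like branches — is essential:
  it gives the neutral site-frequency spectrum under which $E[H] = 0$,
  the property the selection-scan validation relies on.  All four modern
  populations are drawn exchangeably from one panmictic genealogy, so
  off-tract F\_ST is ≈ 0 and all between-population structure comes from
  the introgression pulse.  Real panels have baseline drift
  differentiation and linkage within windows that this model does not
  emulate; passing tests demonstrate correctness of the statistics, not
  calibration against real human data.
* **Archaic lineage.**  Two archaic haplotypes carry Poisson branch
  mutations: a shared branch of `tArchaicSplit − tArchaicCoalescence`
  generations (homozygous in the emitted diploid) and private branches of
  `tArchaicCoalescence` generations (heterozygous), so heterozygous sites
  occur naturally and per-lineage mutation counts have mean
  `mu · L · tArchaicSplit`.
* **Introgression.**  One tract is anchored at a uniformly placed focal
  adaptive site and extends an independent Exp(`recRate · tAdmixture`)
  distance to each side — the correct length model for a tract
  *ascertained around its selected variant* (the total length is
  Gamma-distributed with shape 2, the same shape the ILS clock uses).
  An unconditioned single-exponential length would put ~10% of its mass
  on tracts too short to carry even one archaic-tagging site, which no
  scan could recover.  Carriers — a fixed fraction
  `postAdmixtureTargetFreq` (default 0.7) of each target and the
  Oceanian-like population, and `outgroupLeak` (default 0.05) of the
  outgroup, emulating back-migration — copy archaic haplotype 1 across
  the tract and add private Poisson post-admixture mutations.  Frequency
  is *set*, not evolved: selection dynamics are out of the model by
  design.
* **Infinite sites.**  Every mutation occupies a new integer position;
  collisions are re-drawn.

Default parameters, chosen once as the study conditions: a 4 Mb
chromosome (one hundred 40 kb windows), mutation rate 1.25 × 10⁻⁸ per bp
per generation, recombination rate 1.58 × 10⁻⁸ (the target region's
average), archaic split 22,000 generations (550 kya at 25 yr/gen),
admixture 1,500 generations ago (~37.5 kya), and 50/50/50/20 haplotypes
for outgroup/target1/target2/oceanian.  The mean total tract length is
~84 kb, the scale of the ~70.6 kb haplotype the statistics are designed
to recover.  `tModernCoalescence = 10,000` generations keeps within-
population diversity about fourfold below real human levels; this is a
stylized choice that keeps panels desk-sized while leaving thousands of
segregating sites per chromosome.

```{r sim}
sim <- simulateStructuredPanel(SimulationConfig(seed = 42L))
sim$panel
head(sim$tracts, 3)
```

## Numerical and procedural choices

* **Coordinates**: 1-based inclusive in VCF, ancestral-allele tables and
  region strings; 0-based half-open internally and in BED.  Conversion
  happens only at the I/O boundary.
* **Polarization**: sites with unknown or third-allele ancestral states
  are dropped (every downstream statistic requires derived polarization);
  the report counts unchanged/flipped/dropped sites.  Missing modern
  genotypes drop the site panel-wide; unphased genotypes likewise.
* **Archaic merging**: only sites genotyped *and homozygous* in the
  reference archaic individual (the Denisova role) are retained; other
  archaics may be heterozygous or missing there.  In distance and
  sharing computations a heterozygous archaic site contributes 0.5 and a
  missing one contributes 0 while shrinking the comparable-site count —
  the diploid is treated as an unphased pair.  The 0.5 weight is a
  documented sensitivity knob; published analyses do not state their
  rule for the few retained heterozygous Neanderthal sites.
* **Haplostrips ordering**: sites are dropped when their largest
  within-population minor allele frequency is below 0.05; rows (with the
  reference prepended) are clustered on Manhattan distance with complete
  linkage and dendrogram branches rotated so distance-to-reference is
  non-decreasing wherever the tree permits, ties broken in favour of the
  reference.  The distance ordering is therefore monotone only up to the
  dendrogram constraint, as in the published haplostrips tool.
* **Network**: a minimum spanning network — Kruskal's algorithm by weight
  class, keeping every co-minimal edge joining components that were
  distinct at the start of its class.  The test suite checks that the
  kept edge set always contains a minimum spanning tree (igraph oracle).
* **Percentiles**: linear interpolation between order statistics
  everywhere (Q95 and the genomewide 99/99.9 thresholds), so small window
  counts behave predictably.
* **Windows**: non-overlapping, tiled from the first position rounded
  down to a multiple of the window size; a trailing partial window is
  kept and flagged.
* **Degenerate inputs**: monomorphic sites give undefined r²/F\_ST
  (flagged, never silently 0); an all-identical vector produces no
  outlier flags; an empty qualifying set gives an undefined Q95; a zero
  reference iHH gives an undefined XP-EHH score with a warning.
* **Candidate filter**: MAF is computed from the mean of the supplied
  group frequencies; the differentiation rule (default: |ΔDAF| ≥ 0.2
  between outgroup and at least one target) is configurable because the
  threshold behind "high population differentiation" is a judgement
  call; missing CADD scores count as 0 with a warning so that a missing
  annotation can only make the filter stricter.
* **Scan recovery** (validation): a replicate counts as recovered when a
  window overlapping the true tract reaches the genomewide 99.9th
  percentile with U > 0; the U > 0 clause prevents the degenerate
  all-zero genome (whose empirical percentile is 0) from counting.

## Sizes used by the validation suite

The test suite and acceptance script run entirely at desk scale: 100
seeded replicates of the default 4 Mb / 170-haplotype configuration for
the recovery study, 50 random toy panels for the brute-force U/Q95
oracle, ≥ 500 neutral windows for the $E[H] = 0$ check, and 10⁶ draws for
the Monte-Carlo ILS oracle.  These sizes were chosen so the whole suite
completes in minutes while keeping Monte-Carlo standard errors well below
the tested tolerances.

## Applying the pipeline to real data

The full-scale analysis the package is designed for needs external data
that cannot ship with it: phased 1000 Genomes Phase 3 and HGDP VCFs, the
four high-coverage archaic genomes (Altai, Vindija, Chagyrskaya
Neanderthals; Denisova) lifted to one assembly, and ancestral states from
the EPO multiple alignments.  The recipe is:

1. `readPhasedVcf()` on the phased modern VCF restricted to
   `--region chr4:41977828-42048441` (or any region of interest) with a
   sample→population panel; `polarize()` with the EPO ancestral table.
2. `readArchaicVcf()` + `polarize()` for each archaic genome;
   `mergeWithArchaic()` with the Denisova as reference.
3. `windowedFst()`, `windowedFayWuH()`, `xpehhScan()` +
   `flagOutlierWindows()` for the selection compilation;
   `filterCandidateVariants()` on an annotation table with continental
   frequencies and CADD scores.
4. `selectLinkedSites()` around the focal variant,
   `haplostripsOrder()`, `archaicDistances()`, `derivedAlleleSharing()`
   and `haplotypeNetwork()` for the haplotype structure.
5. `windowedArchaicScan()` genomewide for U/Q95 percentile calibration,
   and `expectedIlsLength()`/`ilsPvalue()` with the region's
   recombination rate for the ILS test.

`runScan()` wires these together; published haplotype counts and
sharing figures for the real data are reproducible with this pathway but
not from the bundled fixtures, which exercise the identical computations
on synthetic panels with known truth.

## Known limitations

* The simulator's fixed-topology model has no within-block recombination,
  no drift-based population structure and no selection dynamics; it
  validates the statistics, not demographic realism.
* XP-EHH conventions differ between published implementations; absolute
  scores are comparable only within one implementation (standardized
  scores are robust to this).
* The archaic heterozygote weight (0.5) and the treatment of archaic
  missingness are conventions; results at a handful of sites can shift
  under alternatives.
* Assembly liftover is out of scope: all inputs must share one assembly.
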