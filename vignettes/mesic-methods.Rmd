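---
title: "Estimating single-CpG methylation from MeDIP-seq: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating single-CpG methylation from MeDIP-seq: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

MeDIP-seq enriches methylated DNA fragments with an anti-5mC antibody, so
read depth reflects the *regional* methylated-CpG content of each ~200 bp
fragment, not the methylation level of an individual cytosine. Two
consequences follow. First, resolution is limited to 100–500 bp. Second,
signal is confounded by CpG density: a CpG-poor region that is fully
methylated attracts fewer fragments than a half-methylated CpG island, so
raw reads-per-million (RPM) under-reports methylation exactly where most of
the highly methylated genome lies. `window_summary()` +
`window_density_groups()` expose this bias directly: windows stratified by
CpG count show high reference methylation in CpG-poor strata without a
matching RPM enrichment.

`mesic` treats the problem as supervised regression. Under the assumption
that neighbouring CpGs have similar methylation and that a CpG's local read
pile-up is driven by its own and its neighbours' methylation, the 5mC level
of a single CpG is predictable from the signal and sequence context of a
400 bp window around it.

## The model

For a CpG site $s$ the feature region is the $2m$ bp window holding
$m-1$ bp upstream and $m$ bp downstream of the C ($m = 200$ by default, the
average sonicated fragment size, giving the 400 bp window centred on the
site). The feature vector has $2m + 4 = 404$ entries:

* **Signal features** $x_1 \dots x_{2m}$: $x_i$ is the RPM value at base
  $i$ if that base is the C of a CpG dinucleotide, else 0. RPM is coverage
  of 5'-anchored, 200 bp-extended reads scaled by $10^6/\text{total reads}$.
* **Coupling factor** $cf = \sum_i w(d_i)\,c_i$, a distance-weighted CpG
  count ($c_i$ indicates a CpG C; $d_i$ is the distance to $s$). The weight
  is linear decay $w(d) = 1 - d/m$, 1 at the site and 0 at the region edge.
* **GC fraction**, **CpG density** (CG dinucleotides per bp of region) and
  **mean conservation** over the region.

One random-forest regression per genomic-element category maps features to
reference 5mC: 500 trees, each grown on a 70% bootstrap sample, 30% of
features tried per split (taken literally, ≈121 of 404, rather than the
usual $p/3$), trained on a random 25% of the element's eligible sites.
Eligible means a defined reference level and at least one read over the
feature region. Twelve categories are assigned (CpG island, shore, shelf,
5'UTR, promoter, exon, intron, 3'UTR, SINE, LINE, LTR, others); the eight
CGI- and gene-related ones are modelled by default because repeat elements
carry unreliable MeDIP signal. A site in several modelled elements gets the
unweighted mean of the element predictions, clamped to $[0,1]$. Sites with
zero coverage still receive predictions — the genomic features carry the
information there, which is what the no-read discrimination harness checks.

Reference levels come from paired bisulfite assays: BS-seq measures
5mC + 5hmC, TAB-seq measures 5hmC alone, and the 5mC level is
$\beta_{BS} - \beta_{TAB}$ clamped to $[0,1]$, with $\beta = N_C/(N_C+N_T)$.
Records need ≥4× coverage in both assays; each beta is kept only if its
upper-tail binomial p-value against the assay's non-conversion rate (0.5%
BS, 2.2% TAB), BH-adjusted per assay, reaches FDR 1% — otherwise the beta
is taken as 0, i.e. indistinguishable from failed conversion. We read the
"false-positive" test this way (rather than as a record-exclusion rule)
because excluding non-significant records would discard every unmethylated
CpG on the BS side and every site without significant 5hmC on the TAB
side, leaving no usable truth set; treating non-significant betas as zero
is also how the combined BS/TAB subtraction is used in practice.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `m` | 200 bp | feature-region half-size; width is `2m`, features `2m+4` |
| `extension` | 200 bp | read extension to fragment length |
| `ntree` | 500 | trees per element forest |
| `sample_frac` | 0.7 | bootstrap fraction per tree |
| `mtry_frac` | 0.3 | feature fraction tried per split |
| `train_frac` | 0.25 | per-element training fraction |
| `min_sites` | 50 | minimum eligible sites to train an element |
| `min_cov` | 4 | per-assay coverage floor for reference 5mC |
| `p_bs`, `p_tab` | 0.005, 0.022 | non-conversion rates |
| `fdr` | 0.01 | BH threshold for the binomial filter |
| concordance threshold | 0.25 | \|pred − truth\| bound counted as agreement |
| DMR window/step/min CpG | 1000/500/5 | sliding-window DMR screen |
| DMR PCC ceiling / FDR | 0.25 / 0.05 | candidate screen and BH threshold |

## What the simulator emulates

`sim_config()` defines the study conditions; its defaults are the ones the
estimator is tested under, and they are not adjusted per test:

* a 30 kb single-chromosome genome in which every CpG is planted: mean
  spacing 7 bp inside three CpG islands, 40 bp elsewhere (≥5× density
  contrast), with all accidental background CGs removed first so density is
  fully controlled;
* two genes (one per strand) with promoter/UTR/exon/intron structure, a CGI
  at each TSS plus one intergenic island, and one SINE/LINE/LTR block each,
  so that all 12 categories are exercised;
* element-conditional methylation: unimodal low in islands, bimodal at
  promoters, multimodal in introns, unimodal high in CpG-poor contexts. A
  Gaussian copula with exponential correlation (length scale 200 bp) gives
  exact mixture marginals plus the neighbour correlation real methylomes
  show (r > 0.5 under 100 bp);
* MeDIP capture: 200 bp fragments sampled proportionally to
  $\varepsilon + \sum$ (5mC of covered CpGs), $\varepsilon = 0.05$, one
  50 bp read per fragment from a random end; a 2×10⁵-read library. This is
  the simplest capture model consistent with antibody enrichment, and it
  reproduces the CpG-density bias in raw RPM, which is what makes the
  calibration claim testable;
* BS/TAB counts at Poisson 50× with the non-conversion rates above, 5hmC
  on 5% of methylated sites (levels 0.05–0.25) so the BS − TAB subtraction
  is non-trivial.

What it does **not** emulate: mappability and alignment artefacts, GC
amplification bias, copy-number variation, non-CpG methylation, strand-
asymmetric methylation, chromosome-scale heterogeneity, or SNPs. Passing
tests therefore demonstrate internal correctness and the method's
statistical behaviour under its own assumptions — not performance on real
libraries, where those artefacts dominate repeat elements in particular.

## Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive in memory (GRanges convention);
  BED/bedGraph files are 0-based half-open on disk.
* The coupling-factor weight is pluggable (linear, exponential, tricube, or
  any `function(d, m)` into $[0,1]$); linear decay is the default as the
  simplest non-increasing weight with $w(0)=1$ vanishing at the edge. A
  signal-weighted variant ($\sum w\,c\,x$) is available for sensitivity
  analysis, since coupling factors are sometimes described as integrating
  signal; the default uses genomic CpG occurrence only.
* Feature regions truncated by contig ends are zero-padded (zero signal,
  non-GC, zero conservation; the denominator stays $2m$, matching
  `bedtools nuc` semantics where N bases count), so every site has a
  full-width vector.
* Betas with zero coverage are `NA`; Pearson correlation is `NA` with a
  warning under zero variance or n < 3; a constant training target trains
  but warns.
* Splits and forests are seeded; one master seed fans out deterministically
  per element, so refitting reproduces byte-identical predictions.
* DMR windows whose inter-sample correlation is undefined (constant
  values) are treated as candidates and left to the rank-sum test, whose
  NaN p-value for identical groups is read as "no difference".

## Problem sizes used in the test-suite

The held-out accuracy check runs the full pipeline at the default
conditions over 5 simulation seeds and takes the median (PCC ≥ 0.7,
concordance ≥ 0.8). The depth harness compares the full library with 40%
subsamples (3 repetitions). The full-label-noise null uses a 60 kb
(~2000-CpG) fixture with 10 repeated noise draws and tests the mean PCC:
with element-stratified models a *single* noise draw has few effective
degrees of freedom (prediction fluctuations are shared within elements),
so single-run null PCCs scatter by ±0.2 even at 2000 sites; averaging
draws, as the depth harness also does, estimates the underlying null
correlation honestly.

## Known limitations

* Repeat-element models are trainable but excluded from default reporting;
  on real data their MeDIP signal and mappability are poor.
* The 30%-of-features split rule is kept as stated even though it is an
  unusual regression default; with 404 correlated features the forests are
  insensitive to this choice.
* The DMR caller's window/step/minimum-CpG defaults suit the toy scale and
  are exposed in configuration; the unpaired rank-sum comparison is one of
  two defensible readings (a paired test is the other).
* Multi-element predictions use an unweighted mean; no attempt is made to
  weight elements by model quality.
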