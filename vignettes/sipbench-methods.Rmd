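---
title: "Simulating DNA-SIP experiments and benchmarking incorporator detection"
author: "sipbench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating DNA-SIP experiments and benchmarking incorporator detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sipbench)
```

## The problem

DNA stable isotope probing (DNA-SIP) identifies the members of a microbial
community that assimilate an isotopically labeled substrate: their DNA
becomes denser, and after isopycnic CsCl centrifugation, fractionation and
amplicon sequencing of the fractions, "incorporators" should be enriched
in heavy-buoyant-density fractions of labeled gradients relative to
unlabeled controls.  Separation is never clean — G+C content moves
unlabeled DNA over a wider buoyant-density (BD) range (0.098 g/ml across
the full G+C range) than full ¹³C labeling does (0.036 g/ml) — so
incorporators must be inferred statistically, and the competing inference
methods (Heavy-SIP presence rules, HR-SIP and MW-HR-SIP differential
abundance, qSIP weighted-mean BD shifts, ΔBD centers of mass) differ
sharply in sensitivity and specificity.  Because ground truth is unknowable
in real experiments, sipbench simulates the entire measurement chain from
first principles, with per-taxon truth recorded, and scores each method
against it.

## The physical model

A homogeneous pool of DNA fragments at sedimentation equilibrium forms a
Gaussian band.  Its mean is set by the empirical linear BD–G+C relation

$$\rho = 0.098\,[\mathrm{G{+}C}] + 1.66 \quad (\mathrm{g\,ml^{-1}}),$$

and its standard deviation by the equilibrium band-width formula

$$\sigma = \sqrt{\frac{\rho R T}{\beta^2 G M_C \ell}},$$

with fragment length $\ell$ in bp: long extraction fragments (~12 kb) form
bands of $\sigma \approx 0.002$ g/ml.  Heavy-isotope incorporation shifts a
band linearly in atom % excess $A$, $\Delta\rho = I_{max} A/100$ with
$I_{max} = 0.036$ (¹³C) or $0.016$ (¹⁵N) g/ml.  BD maps to radius through
the gradient relation $\rho(x) = \rho_m + \omega^2(x^2 - r_c^2)/(2\beta_0)$
(`bd_to_radius()`), which supports geometry-resolved extensions.

Two empirical facts break the pure-Gaussian picture and are modeled
explicitly:

* **Diffusive boundary layer (DBL).**  A thin layer of the gradient along
  the tube wall is entrained during rotor deceleration and reorientation,
  placing a small fraction of every taxon's DNA at non-equilibrium
  positions.  We model the entrained fraction of taxon $t$ as
  $D_t = \gamma A_t + \alpha$ ($A_t$ = pre-fractionation relative
  abundance) and spread it uniformly over the gradient span.  Defaults
  $\gamma = 1$, $\alpha = 10^{-4}$ reproduce the qualitative empirical
  pattern that abundant taxa (relative abundance above ~0.1%) are detected
  in essentially all fractions while rare taxa are confined to their
  equilibrium bands.  The DBL component is deliberately *not* shifted by
  isotope labeling: entrained DNA sits at arbitrary positions regardless
  of its label.
* **Smoothing bandwidth.**  Per-taxon BD profiles are represented as 1-D
  Gaussian KDEs over Monte-Carlo draws.  On composition-only synthetic
  genomes, Scott's rule produces bands much narrower than real amplicon
  bands (real genomes have within-genome G+C structure, and real gradients
  additional dispersion).  `build_taxon_profiles()` therefore defaults to
  a calibrated bandwidth of 0.002 g/ml, at which a taxon's band spans
  roughly 2–4 gradient fractions, as in empirical data.  Scott's rule
  remains the default for a single `build_bd_profile()` call and is
  available everywhere via `bandwidth = NA`.

## The simulation pipeline

**Stage 1 — fragments to BD profiles.**  For each genome, a pool of
extraction fragments is simulated (left-skewed normal lengths, mean 12 kb,
4 kb floor; 10⁴ fragments/genome), either from a real sequence (with
in-silico PCR against degenerate primers restricting fragments to those
containing an amplicon locus) or from base composition alone
(`simulate_fragments_binomial()`, the exact marginal for i.i.d. synthetic
genomes).  A 2-D Gaussian KDE over (length, G+C) is fitted, resampled
`n_mc` times, each draw converted to a Gaussian band via the physics above,
and one BD value drawn per fragment; the pooled draws define the
equilibrium profile.  DBL smearing and isotope incorporation transform it
in that order.

**Stage 2 — gradients and communities.**  Fraction widths are drawn
Normal(0.004, 0.0015) g/ml (floored at 0.001) and laid heavy-to-light over
the 1.67–1.78 g/ml span (~27 fractions/gradient).  Pre-fractionation
abundances are lognormal (meanlog 10, sdlog 2 of the underlying normal —
the convention of classic community simulators).  Beta-diversity between
replicate gradients is controlled by the fraction of shared taxa
(non-shared taxa are replaced by replicate-private taxa inheriting the
vacated rank abundance, which keeps the rank-abundance curve fixed) and by
rank-permuting a chosen fraction of taxa (as a derangement, so every
selected taxon really changes rank).

**Stage 3 — counts.**  10⁹ fragments per gradient are allocated as
Poisson draws per (taxon, fraction) cell with expectation
`total * abundance * profile mass in the fraction` (exact multinomial
below 10⁷ fragments; identical expectations).  qPCR totals per fraction
are gamma draws moment-matched to the empirical mean–variance relation
$\sigma^2 = 5889 + \mu + 0.714\mu^2$ (a fraction with $\mu = 0$ reports 0,
since no non-negative distribution has mean 0 and positive variance).
PCR amplification bias follows a kinetic model with three ingredients:
Poisson subsampling of templates to `template_frac` (default 1%) of the
fraction's DNA, so sub-molecule template quantities drop out; a
per-template-species re-annealing efficiency
$e = e_{max} K/(K + P_t)$ that saturates the most abundant templates
first and compresses ratios toward 1:1; and a reaction plateau
(`total_max`, primer/dNTP exhaustion) that halts all amplification in a
fraction, calibrated so saturation begins near cycle 20 at the default
loading.  Without the plateau, 30 unbounded cycles would amplify any
surviving template ~10⁸-fold and erase rank information entirely — a
behavior no real reaction shows.  Finally, reads are multinomial
subsamples per fraction at the configured depth (default 10⁴).

## The detection methods

* **Heavy-SIP (methods 1–4)**: presence/absence rules over a heavy window
  (1.71–1.75 g/ml) and optionally a light window (1.68–1.70 g/ml).
  Method 1 (presence in treatment-heavy) is the most accurate variant and
  the one reported as "Heavy-SIP" in benchmarks.
* **HR-SIP**: one-sided negative-binomial Wald test of treatment
  enrichment within the heavy window, after a sparsity filter (presence in
  > 25% of window samples), BH correction, calls at FDR 10% with a log₂
  fold-change null of 0.25.  The internal NB engine uses median-of-ratios
  size factors and method-of-moments dispersions squeezed empirical-Bayes
  style toward a loess mean–dispersion trend, with the prior degrees of
  freedom d₀ estimated from the residual scatter of log-dispersions
  (capped at 20) and the Wald statistic referred to t(d + d₀).  A plain
  normal reference is anti-conservative at 3v3 (type-I ≈ 2× nominal under
  NB nulls), a plain t₄ reference collapses power at FDR thresholds; the
  moderated t keeps type-I within 1.5× nominal while matching the
  published sensitivity of the trend-moderated engines it emulates.
  The default sample unit is the *gradient* (window fractions summed per
  gradient, edge fractions overlap-weighted).  With fraction-level
  samples, a cleanly shifted incorporator is absent from every control
  window fraction, capping its prevalence near 0.5 × band-width /
  window-width ≈ 0.15 — below the 0.25 sparsity cutoff — so the filter
  would discard precisely the strongest true positives; the gradient unit
  avoids this pathology and matches published sensitivity.  The
  fraction unit remains available (`collapse = "fraction"`).
* **MW-HR-SIP**: HR-SIP independently in three overlapping windows
  (1.70–1.73, 1.72–1.75, 1.74–1.77 g/ml), BH within each window, a taxon
  called if significant in any window (a global-BH mode exists).
* **qSIP**: per gradient, each taxon's qPCR-scaled weighted-mean BD; the
  shift Z = treatment mean − control mean; 90% percentile bootstrap CIs
  from 1000 resamples of gradients within arms; called when the lower CI
  bound exceeds 0 and the taxon is detected in every labeled gradient
  (the replicated-design convention: a shift claim whose treatment arm
  has missing replicates is not supported; policies `"all"` and `"none"`
  are available).  This detection requirement is also what makes qSIP
  sensitivity decline when replicate communities share fewer taxa.  Atom % excess is estimated by default through the
  G+C-dependent molecular-weight formulation of the original qSIP method
  (G+C inferred from the light-arm BD with its 0.0835/1.646 calibration,
  masses scaled by the maximum mass gain at full labeling with
  natural-abundance correction); this is what produces the documented
  systematic ~30–40% underestimation of ¹³C atom % excess when applied to
  data generated under the linear shift model, and the left skew of heavy
  bands adds to it.  `mode = "linear"` gives the naive inversion
  $100\,Z/I_{max}$.
* **ΔBD**: per-gradient centers of mass of within-fraction relative
  abundances linearly interpolated onto 20 evenly spaced BD points;
  ΔBD = treatment mean − control mean, converted linearly to atom %.

Scoring uses specificity, sensitivity, precision, and balanced accuracy;
balanced accuracy defaults to the mean of specificity and sensitivity (the
standard definition), with the product available and reported alongside in
sweep outputs, since both definitions circulate.  Sensitivity is NA when
there are no true positives (0 atom % cells) and excluded from aggregates.

## What the synthetic generator does and does not emulate

Synthetic genomes are i.i.d. base sequences at a target G+C; genome-level
G+C values are drawn from a truncated normal (mean 0.50, sd 0.12 on
[0.22, 0.75] — roughly the spread of complete bacterial genomes) with the
proportion below 30% G+C capped at 1%, emulating the down-weighting of
endosymbiont-like genomes in curated reference sets.  What this does *not*
emulate: within-genome G+C heterogeneity (real 12-kb windows vary by
several % G+C, widening and skewing real bands — partly absorbed by the
calibrated bandwidth), amplicon G+C conservation (rRNA loci are more
G+C-uniform than their genomes), chimeras and sequencing error, and
phylogenetic structure in communities.  A green benchmark therefore
establishes that a method behaves as published under the physical model
and these community assumptions, not that it will achieve identical
numbers on any particular real community.

## Numerical choices and degenerate inputs

Profiles store kernel centers, so per-fraction masses are exact Gaussian
CDF sums (no quadrature); full-span mass is 1 to numerical precision and
the test suite verifies trapezoid quadrature agreement at 10⁻³.  Every
stochastic operation takes an explicit seed; run-level seeds derive
per-taxon/per-stage streams by stable string hashing (32-bit safe), so any
simulation is bit-reproducible from one integer.  Fractions are indexed
heavy→light with lower-inclusive intervals.  Zero-count fractions produce
zero reads (with a warning) and zero qPCR copies; all-zero taxa get p = 1
(HR-SIP), no estimate (ΔBD), or a flagged non-call (qSIP).  Taxa absent
from an entire arm are never called by qSIP.  Monte-Carlo scale defaults
to the full 10⁵ replicates for a single profile and to a desk-scale 2,000
in `build_taxon_profiles()`; this changes profile means and fraction
masses only within Monte-Carlo error and keeps grid-scale benchmarks
tractable.

## Known limitations

The two Heavy-SIP-adjacent quantities most sensitive to unpublished
upstream parameters are the PCR bias strength (the kinetic model's
constants are not printed anywhere; ours are pinned to "saturation near
cycle 20" and a 1% template loading) and the smoothing bandwidth
(empirically fitted upstream, unprinted; calibrated here as described).
The 90% percentile bootstrap over three gradients per arm has an intrinsic
false-call floor near 13% under exchangeable noise — a property of the
method at this replication level, visible in any faithful implementation
as ~8–15% qSIP false positives even with zero labeling.  Time-to-
equilibrium physics and non-CsCl media (beyond a configurable $\beta_0$)
are out of scope.
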