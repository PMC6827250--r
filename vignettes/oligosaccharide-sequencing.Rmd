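---
title: "Sequencing alginate oligosaccharides from exolytic truncation series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequencing alginate oligosaccharides from exolytic truncation series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alginseq)
```

## The problem

Alginate is a linear polyuronate of β-D-mannuronate (M) and its C5 epimer
α-L-guluronate (G), arranged in homopolymeric (polyM, polyG) and
heteropolymeric (polyMG) blocks. Alginate lyases depolymerize it by
β-elimination, which severs a glycosidic bond and leaves a 4,5-unsaturated
ring — the Δ unit — at the non-reducing end (NRE) of the fragment on the
reducing-end side of the cut. Crucially, β-elimination destroys the M/G
identity of that ring: an unsaturated oligosaccharide of degree of
polymerization (DP) *n* has only *n − 1* assignable residues. `alginseq`
therefore stores unsaturation as a terminal *state* of a chain, never as a
residue letter, and every sequence string like `ΔGMM` carries dp − 1
letters.

Endolytic lyases cleave internal bonds and stop at oligosaccharides;
exolytic lyases peel single rings off the NRE and are what converts
alginate into fermentable monosaccharide units (the released unsaturated
monomer spontaneously rearranges to DEH and then hydrates to TPC). The
package models three linked questions about this system:

1. **What are the products?** Negative-mode ESI-MS of size fractions shows
   an `[M − H]⁻` ladder with exactly one residue mass (monoisotopic
   176.0321 Da) between consecutive unsaturated species; `mz_negative()`
   reproduces it, along with the isobaric coincidence of TPC and a free
   saturated uronic acid at nominal 193.
2. **What are their sequences?** The sequencing procedure below.
3. **Why do the two enzyme classes synergize?** The digestion simulator
   and the synergy module.

## The sequencing procedure

A ¹H NMR spectrum of an unsaturated size fraction exposes two positions
directly. The H-4 proton of the Δ ring resonates at ≈5.71/5.67 ppm when
the *neighbouring* residue is G and at ≈5.61/5.56 ppm when it is M, so the
ratio of those two integrated areas is the molar G:M split at position 1.
The β-anomeric proton of the reducing-end residue is a 4.71 ppm doublet
(³J 8.4 Hz) for G versus a 4.70–4.80 ppm singlet for M, giving the last
position. Interior positions are invisible — until an exolytic lyase
removes k rings from the NRE, which promotes position k + 1 to be the new
Δ neighbour. A *truncation series* (readouts after 0, 1, 2, … cuts,
re-fractionated by size) therefore scans the whole chain:

* `marginals_from_series()` turns the series into per-position G
  fractions p₁ … p₍dp−1₎ (positions 1..dp−2 from H-4 areas of the
  0..dp−3-cut readouts; the last position from the parent's anomeric
  areas, which truncation never touches).
* `joint_under_independence()` reconstructs the mixture as the outer
  product of those marginals.
* `sequence_small()` handles DP 2 and DP 3, where one readout already
  covers every position.

```{r}
series <- truncation_series(5, list(
  `0` = nmr_readout(3.5, 1, 0, 1),
  `1` = nmr_readout(1.5, 1, 0, 1),
  `2` = nmr_readout(0, 1, 0, 1)))
infer_sequences(series)
```

### Why positional independence?

Marginals alone cannot identify correlations between positions: the
anti-correlated mixture {ΔGM 50%, ΔMG 50%} has exactly the same marginals
as the independent four-species joint. The outer product is the
maximum-entropy completion of the data the readouts actually deliver, and
it is self-consistent: the reconstructed joint always reproduces the
observed marginals (a moment-matching identity the test suite checks).
Every report object therefore carries the assumption in text, and
`consistency_check()` states the identifiability caveat even at zero
residual. Before adopting the rule we verified arithmetically that the
outer product of the two non-degenerate pentasaccharide marginals
(3.5/4.5 and 1.5/2.5) equals the published four-species ratio
1 : 1.5 : 3.5 : 5.25 after normalization — the construction is exact for
the system that motivated it, not merely convenient.

### Display conventions

Composition tables are printed as percentages, integers for two-species
fractions and one decimal otherwise (`table2_percent()`); full precision
is kept internally. Qualitative "ΔM only" readouts are encoded as area
pairs (0, 1). The default pruning threshold of 0.5% drops enumeration
products below detectability and renormalizes; pruning can remove at most
`threshold × 2^(dp−1)` of total mass, and the tests bound it accordingly.

## The digestion simulator

`simulate_digest()` runs a continuous-time Markov (Gillespie) simulation
over a pool of chains.

* **Endolytic events.** Each bond between residue letters a and b carries
  propensity `u_endo · k(a, b)`. A 2 × 2 bond-pair table is the smallest
  model able to express block preference; the `endo_rate_table()` default
  (k(G,G) = 1, k(M,G) = 0.25, k(G,M) = 0.1, k(M,M) = 0.01) is a
  G-block-preferring *preset*, exposed as configuration rather than
  asserted as measurement. Minimum fragment sizes (2 rings on either side
  by default) encode the observation that endolytic digests contain no
  monomer.
* **Exolytic events.** Each chain NRE carries propensity
  `u_exo · r(dp)`. `exo_rate_profile()` is piecewise linear in DP with a
  flat polymer tail; the default is anchored by exactly two facts — the
  optimum sits at DP 4 and r(4)/r(polymer) = 6.5 — with the remaining
  knots chosen once as a smooth unimodal fall-off (bar heights were not
  transcribed from any figure). `size_activity_curve()` tabulates
  r(dp)/r(polymer).
* **Cleavage chemistry.** `endo_cleave()` gives the upstream fragment a
  free saturated reducing end and erases the identity of the downstream
  fragment's new Δ ring. `exo_step()` releases the NRE ring (UDP1 if the
  parent was unsaturated, otherwise the saturated free acid of residue 1)
  and erases the newly exposed ring — except the final reducing-end ring
  of a disaccharide, which is released saturated with identity intact,
  because no glycosidic bond remains to eliminate into. Whether that last
  ring is really released saturated is not decidable from solution data;
  the rule is isolated in `exo_step()` and documented here as the open
  choice it is. The same applies to the first cut on a saturated polymer,
  which under this rule releases a saturated monomer.
* **2-AB labels.** A reducing-end 2-aminobenzamide label rides every
  downstream fragment and sterically blocks exolytic cleavage of the
  labelled disaccharide, so labelled trajectories terminate at the
  labelled unsaturated disaccharide with probability 1.
* **Units.** Activities are in mU (1 U = 1 µmol reducing ends released
  per minute). One calibration constant, `activity_scale = 0.002`
  propensity per mU per minute per relative-rate unit, maps activity to
  propensity; it was frozen once so that a 100 mU exolytic digest of a
  small polymer pool plays out on the ~10-minute scale of a co-digestion
  assay, and is config-exposed.
* **Monomer relabelling.** UDP1 → DEH → TPC conversion is spontaneous and
  effectively instantaneous on digestion timescales, so the simulator
  keeps one conserved unsaturated-monomer count and
  `monomer_speciation()` applies a configurable expected split only at
  reporting time. This keeps trajectories byte-reproducible under a
  seed, which the serialization tests rely on.

Ring count is conserved exactly at every snapshot, and the simulator is
validated against an exact enumeration of the absorbing-state distribution
of small substrates (total-variation distance within Monte-Carlo error at
10⁴ replicates).

## Synergy

`run_synergy()` runs three matched-activity arms — combined, endo-only,
exo-only, the single-enzyme arms at the summed activity — and reports the
released unsaturated-monomer yield and the combined/exo-only ratio.
The mechanism needs no fitting: the endolytic enzyme converts a polymer
(low r) into oligosaccharides near the DP-4 optimum (high r), so adding it
to a fixed exolytic activity raises monomer yield on polymeric substrate.
The wet-lab fold-increase depends on absolute rate calibrations the model
does not claim; the package's own claim, enforced by the acceptance tests,
is qualitative: the combined arm beats the exo-only arm for every seed and
by more than two-fold on average under the frozen defaults.

## The synthetic-data generators

* `generate_chains()` samples chains from a first-order Markov model over
  {M, G} with stay probabilities (mean block length = 1/(1 − stay)) and
  Poisson lengths; presets emulate polyM / polyG preparations (≥ 90% of
  the named residue at stationarity) and a balanced blocky alginate.
  First-order structure is a deliberate floor: real alginates have
  longer-range block correlations the generator does not emulate, so
  passing tests speak to the inference machinery, not to any particular
  seaweed.
* `generate_series()` composes truncation, the forward readout and
  multiplicative lognormal noise (unit mean, specified CV). With zero
  noise it is an exact inverse of the inference on factorizing mixtures;
  at 5% CV the recovered fractions stay within a few percentage points
  (the tests bound the mean absolute error at 0.03 over 200 seeds). Real
  spectra add baseline, overlap and relaxation effects the noise model
  does not represent; readouts are assumed to be correctly integrated
  areas.
* `fixture_chromatogram()` renders molar proportions as Gaussian
  gel-filtration peaks (area ∝ moles, one 235 nm chromophore per
  unsaturated chain) and `integrate_chromatogram()` inverts them by
  valley-to-valley trapezoidal integration, warning when centres sit
  closer than 4σ. Column dispersion physics is out of scope.

## Problem sizes and numerical choices

The shipped tests run on deliberately small instances, chosen as the
smallest sizes that exercise every rule: pools of 3–4 chains of mean
length 25–30 for digestion properties, 100 seeded synergy runs, 10⁴
replicates for the enumeration comparison, 200 seeds for noisy-recovery
calibration. Mixture fractions must sum to 1 within 1e−9 (file loaders
renormalize with a warning beyond 1e−6); marginal extraction errors on
all-zero area pairs rather than guessing; nominal m/z is the rounded
monoisotopic `[M − H]⁻` value, which coincides with nominal mass at
integer precision for these compositions; interpolation of the exolytic
profile uses `stats::approx` between knots. All generators and the
simulator are pure functions of their parameters and a seed.

## Limitations

* Joints beyond marginal information are not resolvable by this method;
  fractions whose positions are correlated are reported as their
  maximum-entropy surrogate with an explicit caveat. Hexasaccharide and
  larger fractions compound small per-position errors and were left
  undetermined in the motivating data.
* Isotope envelopes, multiple charging, in-source fragmentation and the
  2-AB adduct mass are not modelled.
* Enzyme inactivation, pH/temperature/metal dependence and absolute
  specific activities are outside the model; activities enter only
  through the single calibration constant.
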