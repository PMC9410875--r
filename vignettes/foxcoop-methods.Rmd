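---
title: "Models and methods behind foxcoop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind foxcoop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foxcoop)
```

foxcoop quantifies how forkhead-box (FOX) transcription factors assemble on
promoter elements that carry two adjacent binding sites — a homotypic
cluster. This vignette is the package's own account of the models it
implements, the parameters that matter, and the choices made where the
design was genuinely open.

## The two-site binding model

A DNA duplex carries two microscopic sites with association constants $K_1$
and $K_2$ (per molar). At free protein concentration $p$ the statistical
weights of the four microstates {empty, site 1 bound, site 2 bound, both
bound} are $1$, $K_1 p$, $K_2 p$ and $\omega K_1 K_2 p^2$, where the
unitless cooperativity factor $\omega$ multiplies the doubly-bound weight:

$$Z(p) = 1 + (K_1 + K_2)\,p + \omega K_1 K_2\, p^2.$$

The species fractions follow directly: $f_0 = 1/Z$ (free DNA),
$f_1 = (K_1+K_2)p/Z$ (singly bound, the monomer shift of a gel),
$f_2 = \omega K_1 K_2 p^2/Z$ (doubly bound, the dimer shift). $\omega > 1$
is positive cooperativity, $\omega = 1$ independent sites, $\omega < 1$
negative cooperativity. `partition_fractions()` implements this; its tests
compare against an independent four-microstate Boltzmann enumeration.

**Ligand depletion.** In a mobility-shift assay the probe (2.5 µM here) and
the protein are at comparable concentrations, so bound protein is a large
share of the total and $p$ must be solved from
$p_\mathrm{tot} = p + d_\mathrm{tot}\,(f_1 + 2 f_2)$.
Bound protein is monotone in $p$, so the root on $[0, p_\mathrm{tot}]$ is
unique; `solve_free_protein()` uses a bracketed, safeguarded Newton
iteration converged to a conservation residual below $10^{-10}$ relative.

## Estimating the cooperativity factor from band fractions

`omega_from_lane()` computes the statistical-factor-corrected ratio

$$\hat\omega = \frac{4 f_0 f_2}{f_1^2},$$

which for two equivalent sites equals the generating $\omega$ exactly at
*every* protein concentration — no knowledge of $K$ or of the free
concentration is needed, which is what makes it usable on gel densitometry.
For unequal sites the ratio equals
$\omega \cdot 4K_1K_2/(K_1+K_2)^2 \le \omega$, an attenuation that is exact
at $K_1 = K_2$ and reaches $40/121 \approx 0.33$ at a ten-fold affinity
difference. The closed form is verified in the tests; users with strongly
unequal sites should prefer `fit_affinities()`.

**Lane usability.** The ratio's variance explodes when any band approaches
densitometry background: $f_1$ enters squared in the denominator, and
near-zero $f_0$ or $f_2$ has unbounded relative error and skews the ratio
upward. `estimate_omega()` therefore uses only lanes with $f_1 > 0.05$ and
$f_0, f_2 > 0.1$ (both configurable). Under the package's own noise model
(3% Gaussian fraction noise) this keeps the median estimate within 20% of
the truth for $\omega$ from 1 to 21; with the monomer threshold alone the
estimate can be inflated several-fold, which is why the band floor exists.

**Summary and classification.** The point estimate is the mean over usable
lanes; with replicate series the standard error is the SEM across
replicates (matching the triplicate-gel convention). The classification is
`positive`/`negative` when $\hat\omega$ is more than two standard errors
from 1 (±0.25 when no spread is available), else `none`.

## Fitting the full model, and what is identifiable

`fit_affinities()` is the assumption-free alternative: weighted least
squares of predicted versus observed $(f_0, f_1, f_2)$ across lanes, free
protein solved per lane inside the objective, parameters in log space,
Levenberg–Marquardt with five fixed starts.

The species fractions depend on the microscopic parameters only through
$K_1 + K_2$ and $\omega K_1 K_2$, so a titration alone cannot separate the
three parameters — the degeneracy is continuous, not just the
$K_1 \leftrightarrow K_2$ exchange. The default fit therefore ties
$K_2 = K_1$ (the equivalent-sites convention); supplying outside
information through `fix` — for example $K_1$ measured on a single-site
probe by calorimetry — lifts the degeneracy and frees the rest. Fitted
output is canonicalised to $K_1 \ge K_2$. A series with no dimer band
drives $\omega$ to its lower boundary and is flagged.

The macroscopic stepwise constants used by sequential calorimetry models
are $K_{a1} = K_1 + K_2$ and $K_{a2} = \omega K_1 K_2 / (K_1 + K_2)$
(`macroscopic_constants()`); for equal independent sites this is the
familiar statistical-factor pair $(2K, K/2)$.

## Calorimetry simulation and model comparison

`itc_protocol()` records cell concentration, syringe concentration and the
injection schedule. Defaults follow the experimental protocols the package
emulates: 50 µM DNA in a 200 µl cell, 750 µM protein in 2.5 µl injections
(single-site probes) or 850 µM in 40 × 2 µl injections (two-site probe);
cell volume and injection count are instrument-typical values and fully
configurable.

Each injection of volume $v$ into active volume $V_0$ displaces cell
contents: existing concentrations are diluted by $(1 - v/V_0)$ and newly
injected titrant enters with the average factor $(1 - v/(2V_0))$. The
cumulative cell heat is $Q_i = V_0 d_i (f_1 \Delta H_1 + f_2 (\Delta H_1 +
\Delta H_2))$ for the sequential two-site model (or $V_0 B_i \Delta H$ with
bound concentration $B_i$ from the one-site quadratic), and the observed
per-injection heat is $q_i = Q_i - Q_{i-1} + \frac{v_i}{V_0}\frac{Q_i +
Q_{i-1}}{2}$, the last term crediting heat carried out with the displaced
volume. Without that correction the per-injection heats sum exactly to the
final cumulative heat, which is how the bookkeeping is tested. A two-site
trace with $\omega = 1$ and equal sites reproduces the one-site trace with
$n = 2$ to $10^{-8}$, connecting the two models.

`fit_itc()` fits normalized heats by Levenberg–Marquardt (log-space
association constants, fixed multi-starts) with a constant heat-of-dilution
offset always included as a nuisance parameter (zero in simulation by
default). `compare_models()` fits both models and selects by AICc — chosen
over an F-test because the models have unequal parameter counts and are
*not* nested (the one-site model has a free site multiplicity $n$). On pure
noise the AICc gap is small but not exactly zero for the same reason; the
`indeterminate` flag uses the conventional $|\Delta\mathrm{AICc}| < 2$
band. A biphasic index — sign changes of the first differences after
3-point median smoothing — flags isotherms with two thermodynamically
distinct events of opposing enthalpy, the qualitative signature of
sequential two-site binding.

## Stoichiometry from solution masses

`duplex_mass()` sums average nucleotide-monophosphate residue masses over
both strands with the standard −61.96 Da end correction per 5′-hydroxyl
strand; the printed 16-mer two-site probe gives 9.76 kDa.
`infer_stoichiometry()` rounds (complex − DNA)/protomer to the nearest
integer and reports the residual; with the measured masses (32.7 and
20.1 kDa against a 12.4 kDa protomer) this yields 2:1 on the two-site probe
and 1:1 on the single-site probe.

## Minor-groove geometry

`minor_groove_widths()` implements the standard phosphate-distance
convention: for each phosphate of the reference strand, the minimum P–P
distance to partner-strand phosphates across the minor groove (register
offsets $i-5 \dots i-1$ relative to the Watson–Crick partner level), minus
5.8 Å for the two phosphate-group radii. Two levels at each end are
excluded (end fraying), and missing phosphates produce gaps, not
interpolation. This convention is fully specifiable and reproduces the
canonical B-DNA baseline; spline-based helicoidal analyses (Curves+-style)
differ by up to a few tenths of an Å, so comparisons against structures
analysed that way should allow ±0.5 Å.

`make_fiber_bdna()` generates the reference: phosphates on two antiparallel
helices with radius 8.91 Å, twist 36°/bp, rise 3.38 Å/bp, and a 144°
inter-strand phase. In cylindrical coordinates the cross-groove P–P
distance is $d^2 = 2r^2(1 - \cos\Delta\theta) + \Delta z^2$, minimised at a
−3 level offset for these parameters, giving an interior width of
$\sqrt{2 \cdot 8.91^2 (1-\cos 36^\circ) + (3 \cdot 3.38)^2} - 5.8 =
5.74$ Å — constant along the interior by screw symmetry, and the widely
quoted ~5.7 Å B-DNA value. Shrinking the phase angle narrows the minor
groove monotonically, which is how groove-narrowing comparisons are
exercised without downloading deposited structures. `read_structure()`
(PDB text via bio3d) assumes matched antiparallel residue numbering when
assigning base-pair levels, which holds for the generator's output and
typical duplex entries; mixed protein–DNA files are handled by keeping
only nucleotide phosphates.

## Synthetic data: what it emulates and what it does not

The generators emulate the experimental inputs so that the entire pipeline
is testable offline:

* `gen_emsa_series()` — titration fractions with independent Gaussian noise
  (SD 0.03 by default) clipped and renormalised per lane, optionally in
  replicates. Real densitometry error is heteroscedastic and correlated
  between bands of one lane; passing tests show estimator behaviour under
  the stated model, not under every gel artefact.
* `gen_itc_trace()` — simulated heats plus Gaussian noise with SD equal to
  2% of the largest heat. Real thermograms add baseline drift and
  integration error.
* `gen_promoter()` — i.i.d. uniform background with implanted sites; real
  promoters have composition bias, so genomic hit rates will differ from
  the analytic uniform-background rate ($8/4^7$ per strand-window for the
  canonical consensus) that the tests verify.
* Default wild-type parameters: both site constants from the measured
  single-site dissociation constant (0.79 µM), $\omega = 3$ — a documented
  convention anchored to the measured single-site affinity, not a fitted
  two-site result (fitting those would require the raw thermograms).

**Scenarios** (`apply_scenario()`) represent probe variants as parameter
changes, not structure-based predictions: `mut1` floors the first site to
0.002 of its constant (a scrambled element retains only
nonspecific-level affinity) and removes cooperativity; `mut2` sets
$\omega = 1$ with a mild (×0.8) second-site reduction — a strong reduction
would attenuate the lane estimator far below the near-1 value this variant
shows, because of the closed-form bias above; `mut3` floors both sites
(no occupancy at gel concentrations); the spacer and cation-depletion
scenarios retain 30%, 10% and 25% of the cooperative excess respectively,
reflecting progressively disrupted coupling.

## Numerical choices

* Root finding: safeguarded Newton within $[0, p_\mathrm{tot}]$, residual
  tolerance $10^{-12}\max(p_\mathrm{tot}, d_\mathrm{tot})$.
* Optimisation: `minpack.lm::nls.lm`, `ftol = ptol = 1e-14`, association
  constants in log space, parameters clamped to $[10^{-30}, 10^{30}]$
  during line search; five (EMSA) or four (ITC) fixed starts around the
  stoichiometric concentration scale. Non-convergence returns best-so-far
  with a flag.
* AICc: $n\log(\mathrm{RSS}/n) + 2k + 2k(k+1)/(n-k-1)$.
* Ties and degeneracies: equal-sites tie in the default fit (above);
  $\omega$ at the $10^{-6}$ boundary sets the `boundary` flag; scan output
  is sorted by start with plus strand before minus.
* Problem sizes used by the test-suite simulation studies: 8-lane
  titrations, 50 seeds for estimator accuracy; 40-injection traces, 100
  seeds for model selection; 500 random ≤30-mers for the scanner oracle;
  1000 parameter draws for the partition-function oracle.

## Known limitations

* The lane estimator is exact only for equivalent sites; its unequal-site
  attenuation is documented and tested, but correcting it requires fitted
  constants.
* Only two sites and one protein species are modelled: no heterotypic
  clusters, no kinetics, and the spacer/cation scenarios are parameter
  conventions rather than predictions from structure.
* Groove widths use the phosphate-distance convention; absolute agreement
  with spline-based helicoidal analyses is expected only within a few
  tenths of an Å.
* The consensus scanner is degeneracy matching, not a weight matrix: it
  reports architecture (site presence, spacing, overlap), not affinity
  scores, and genome-scale scanning statistics are out of scope.
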