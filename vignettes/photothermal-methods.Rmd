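---
title: "Models and methods in photothermal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in photothermal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photothermal)
```

`photothermal` implements the quantitative chain used to ask whether wheat
photosynthesis acclimates to warm nights: FvCB model fitting to A–Ci
curves, temperature-response modelling of the fitted capacities with
optimum extraction, breakpoint estimation of the critical temperature of
PSII (T~crit~) from chlorophyll-fluorescence ramps, comparative-regression
and ANOVA statistics, and metabolite-table normalization with permutation
MANOVA. This vignette documents the models, their assumptions, the
numerical choices, and what the synthetic-data tests do and do not
establish.

## The forward photosynthesis model

Net CO~2~ assimilation of a light-saturated C~3~ leaf is the minimum of
three limitation-specific rates evaluated at the chloroplastic CO~2~
partial pressure $C_c$:

$$A_c = \frac{V_{cmax}(C_c - \Gamma^*)}{C_c + K_{air}} - R_d,\qquad
  A_j = \frac{J(C_c - \Gamma^*)}{4C_c + 8\Gamma^*} - R_d,\qquad
  A_p = 3\,\mathrm{TPU} - R_d.$$

$K_{air}$ is the apparent Michaelis–Menten constant for carboxylation at
21% O~2~ (oxygen inhibition folded into a single constant; there is no
separate $K_c$/$K_o$ treatment). Mesophyll conductance couples $C_c$ to the
measured intercellular mole fraction through $C_c = C_i - A_n/g_m$; each
limitation then becomes a quadratic in $A_n$ solved in closed form (lower
root), and $A_n$ is the minimum of the three coupled solutions. The closed
form is verified against an independent fixed-point bisection solver in the
test suite (1000 randomized inputs, agreement `< 1e-7`).

Units: user-facing interfaces use °C and µmol mol⁻¹; internally
temperatures are Kelvin and CO~2~ quantities are Pa (required by the
Pa⁻¹ units of $g_m$), converted once at the boundary with the configured
atmospheric pressure (default 96 kPa, so 400 µmol mol⁻¹ ↔ 38.4 Pa).

Two modelling notes:

* **$A_n = -R_d$ occurs where $C_c = \Gamma^*$**, i.e. at
  $C_i = \Gamma^* - R_d/g_m$, not at $C_i = \Gamma^*$; the two coincide
  only as $g_m \to \infty$. Both facts are asserted in the tests.
* **$R_d$ is an explicit, fitted parameter** (bounded [0, 10]
  µmol m⁻² s⁻¹). If it is pinned to zero, fitted $V_{cmax}$ and $J$ absorb
  it; this is documented rather than hidden.

## Fitting A–Ci curves

`fit_aci()` minimizes the residual sum of squares between observed $A_n$
and the full min-rule forward model over (V~cmax~, J, TPU, R~d~), so the
limitation assignment at each observation is an output of the fit, never a
user-chosen transition point. Mesophyll conductance is fixed from the
kinetic configuration (temperature-scaled), never fitted.

The objective is piecewise smooth with kinks where the minimizing
limitation changes, and limitation-assignment basins can trap
gradient-based optimizers. The fitter therefore uses bounded multistart
L-BFGS-B: ten deterministic starts — a coarse physiological grid plus
single-point *inversions* of the carboxylation and regeneration formulas at
the temperature-scaled kinetics, which seed distinct assignment basins —
and three seeded random starts (default seed 1704), followed by a polish
pass with parameter-relative finite-difference steps. Bounds are generous
physiological envelopes (V~cmax~ ≤ 1500, J ≤ 800, TPU ≤ 60, R~d~ ≤ 10).

**Identifiability.** TPU is only constrained by observations on the TPU
plateau; if the fitted model assigns no point to TPU limitation the fit is
flagged (`tpu_identifiable = FALSE`) and TPU must be read as a lower bound.
Two subtler degeneracies surfaced during validation and shape the
acceptance tests:

* a limitation expressed with a margin below ~0.1 µmol m⁻² s⁻¹ over its
  competitors cannot be resolved even from noiseless data (the objective
  difference is below solver tolerance);
* because the plateau pins only the combination $3\,\mathrm{TPU} - R_d$,
  a curve with just three non-plateau points admits *multiple exact
  solutions* for (V~cmax~, J, R~d~, TPU) under permuted limitation
  assignments — we exhibited distinct parameter sets with rss ≈ 1e-16.
  Recovery there is mathematically impossible, so such draws are excluded
  from recovery checks by an identifiability rule stated on the truth (not
  on the fit): margin ≥ 0.1 and ≥ 4 non-plateau observations.

The duplicated 400 µmol mol⁻¹ points (two mid-sequence, one final
recovery) are all retained; a drift warning (never an exclusion) fires if
the recovery point deviates > 15% from the mid-sequence mean.

## Temperature responses and optima

V~cmax~ follows a peaked Arrhenius (Arrhenius rise moderated by
entropy-driven deactivation), in the normalized parameterization that
passes through `k_ref` at the 25 °C reference:

$$k(T) = k_{ref}\, e^{E_a (T - T_{ref})/(T_{ref} R T)}\;
  \frac{1 + e^{(T_{ref}\Delta S - E_d)/(T_{ref} R)}}
       {1 + e^{(T\Delta S - E_d)/(T R)}},$$

with $E_d$ held fixed at 200 kJ mol⁻¹ and ($k_{ref}, E_a, \Delta S$)
estimated by multistart least squares. The optimum has the closed form
$T_{opt} = E_d / (\Delta S - R\ln(E_a/(E_d - E_a)))$, verified against
grid-search argmax to 0.01 K. We chose the reference-normalized rather than
optimum-referenced parameterization because T~opt~ and the value at T~opt~
are derived quantities here, not fitted ones. A series whose best peaked
fit places the optimum outside the measured temperature range returns an
explicit "no optimum resolvable" flag instead of an extrapolated optimum —
mirroring how unresolvable fits must be reported rather than fabricated.

J~1500~, TPU and A~n~ use ordinary least-squares quadratics
($T_{opt} = -b/2a$, reported only when curvature is negative). The
trait→model mapping is configurable but defaults to peaked for V~cmax~ and
quadratic for the rest, following the observation that electron transport
and TPU do not show clean Arrhenius rises in wheat.

Treatment comparisons use (i) comparative regressions — nested quadratics
M0 (common), M1 (separate intercepts), M2 (fully separate) compared by
extra-sum-of-squares F tests, selecting the simplest unrejected model at
α = 0.05 — and (ii) fixed-effects one- or two-way ANOVA with Fisher's LSD
or Tukey's HSD mean separation (HSD default, being more conservative; the
method is recorded in every report). Letters come from an interval-based
compact-letter display, exact for balanced designs. Curve fits use all
replicate points rather than cell means, preserving residual degrees of
freedom for the F tests. No mixed-effects modelling of chamber/plant
nesting is attempted.

## T~crit~ from fluorescence ramps

T~crit~ — the temperature at which minimum fluorescence F~0~ begins its
steep rise, marking incipient PSII damage — is the intersection of two
regression lines fitted to the flat and steep portions of the
F~0~–temperature curve. Rather than an operator choosing windows, the
flat/steep boundary is found by exhaustive two-segment least squares over
every admissible split (each segment ≥ max(5, 10% of samples)), which is
deterministic and reproducible; prefix-sum regression makes the scan O(n).
Samples above the F~0~ maximum (the post-peak decline near the top of the
ramp) are excluded first, since the method targets the initial rise.

A breakpoint is declared only when the steep slope exceeds
`5·|flat slope| + 3·residual SD per °C`; flat traces raise an error instead
of fabricating a T~crit~. The default 0.5 °C moving-average smoothing
suppresses fluorimeter noise; for noiseless synthetic input smoothing is
unnecessary (it rounds the kink) and the exactness tests disable it.
Whether the original instrument pipeline smoothed or subsampled its
continuous traces is unknown to us; the window is therefore a documented,
configurable choice.

## Metabolite statistics

Normalization follows the three-step chain: divide each sample by its
internal-standard signal relative to the mean signal, divide by fresh mass,
then weight each compound by its across-sample mean — leaving every
compound with mean exactly 1 (hence idempotence, tested). Missing values
are imputed as half the compound's minimum observed abundance (a common
GC-MS convention; counts reported); all-zero compounds are excluded with a
warning.

PERMANOVA partitions squared Euclidean distances on per-compound
autoscaled abundances — the distance and scaling are *our* declared
defaults, since the source analysis names neither; autoscaling stops
high-abundance compounds from dominating. The implementation uses the
hat-matrix identity: sequential multivariate sums of squares
$\|(H_k - H_{k-1})Y\|_F^2$, so with a single compound the pseudo-F equals
the classic ANOVA F exactly (tested to 1e-8, and against
`vegan::adonis2` to 1e-10). p-values are
$(\#\{F^{perm} \ge F^{obs}\} + 1)/(n_{perm} + 1)$ with free row permutation
for main effects and reduced-model residual permutation for the
interaction (flagged as the approximation it is). Defaults: 999
permutations, seed 2254.

One calibration caveat worth keeping in mind when designing studies: with
two groups of four samples there are only 35 distinct label splits, so a
permutation test cannot reject at rates above 1/35 ≈ 2.9% — the α = 0.05
calibration checks use the three night-temperature levels (12 samples),
where the empirical type-I error is ≈ 0.047.

`responsive_metabolites()` ranks compounds by |mean log~2~ fold-change| of
warm (25 °C) versus cool (15 °C) nights within genotypes, flagging
consistent (same-sign across all genotypes) responders, with class labels
carried through so monosaccharide / saturated-fatty-acid enrichment can be
read off directly.

## The synthetic world

The generators state a ground-truth world and realize it with the
experimental design the analysis assumes: 4 genotypes (two heat-tolerant,
two heat-susceptible) × night temperatures {15, 20, 25} °C × {newly
developed, pre-existing} leaves; A–Ci curves over the 13-step CO~2~
staircase (30…1400 plus the 400 recovery point) at measurement
temperatures {20, 25, 30, 35, 40, 50} °C with 4 replicates; F~0~ ramps
20→65 °C at 10 samples per °C with 6 replicates; 162-compound metabolite
tables with 4 replicates.

Stated-world defaults (documented once, not revisited):

* **Archetypes.** In newly developed leaves, tolerant genotypes raise
  V~cmax~ ×1.3 at 25 °C nights (within the reported 24–43% range) and J
  ×1.2; susceptible genotypes lower J ×0.8; pre-existing leaves carry no
  effect. True T~crit~ genotype means are the published ones (1704 45.7,
  1898 45.2, 2254 44.6, Mace 43.8 °C) with no night effect in newly
  developed leaves.
* **Noise.** A~n~ sd 0.5 µmol m⁻² s⁻¹ (typical IRGA repeatability), F~0~
  sd 1% of baseline, between-leaf T~crit~ sd 0.5 °C, metabolite log-sd
  0.3, homoscedastic throughout (heteroscedastic A~n~ noise at high CO~2~
  is plausible but unreported, so not modelled).
* **Metabolite effects.** Monosaccharides and saturated fatty acids ×2 at
  25 °C nights (log-interpolated at 20 °C) in the three responsive
  genotypes; the non-responsive genotype carries none. Internal-standard
  and fresh-mass nuisance variation is layered on so normalization must
  invert it.
* Stomatal conductance is simulated as a descriptive covariate only
  (curvilinear in temperature with archetype-dependent night shifts) and
  never enters fitting.

Every generator is deterministic for a fixed seed and, at zero noise, is
inverted by its pipeline stage — that round trip is the module's core
contract. What a green test therefore establishes is *self-consistency of
the chain and correctness of the estimators under the stated noise model*;
it does not establish that real leaves obey the generator (real curves
carry operator artifacts, drift, heteroscedastic noise and biological
structure the generator does not emulate), and it cannot reproduce the
study's empirical tables, whose raw data live in an external repository.

## Known limitations

* Capacities are fitted at measurement temperature and then modelled
  across temperature; whether the original analysis fitted C~i~- or
  C~c~-based capacities before Arrhenius fitting is one defensible reading
  among two.
* The 93.72 kJ mol⁻¹ activation energy is applied to K~air~, though the
  source text labels it as belonging to K~c~ while supplying only a K~air~
  constant.
* No light-response submodel: J is defined at the single measurement
  irradiance of 1500 µmol photons m⁻² s⁻¹.
* The TPU limitation omits a glycolate-export term.
* PERMANOVA interaction p-values use reduced-model residual permutation,
  an approximation; and the post-hoc letter display assumes mean-ordered
  non-significance intervals, exact for balanced designs only.
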