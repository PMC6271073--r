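---
title: "Methods: pKa and tautomeric equilibria from NMR titrations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pKa and tautomeric equilibria from NMR titrations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmrtitr)
```

## The physical model

All analyses in this package rest on the fast-exchange assumption: the
species interconverting along the titration (protonated/deprotonated forms,
or the two tautomers of an intramolecular O···H···N bridge) exchange fast on
the NMR timescale, so each probe nucleus shows a single resonance at the
population-weighted mean of its state shifts. The observed shift is then an
affine function of the species fractions, and the fractions are smooth
functions of pH through the dissociation constants. Everything the package
estimates is read off consequences of that linearity.

For a single deprotonation step with constant $K_a$, the deprotonated
fraction at proton activity $[H^+]$ is $f = K_a / (K_a + [H^+])$ and the
observed shift is $\delta = \delta_{HA} + f(\delta_{A} - \delta_{HA})$. For
a diprotic system the three states populate as
$1 : K_1/[H^+] : K_1 K_2/[H^+]^2$. For a tautomeric system with two
deprotonation paths — through the O–H bond (site constant $K_{HO}$) or the
N–H bond ($K_{HN}$) — each path is monitored by its own reporter nucleus
(conventionally H6 for the oxygen site and H9 for the nitrogen site), taken
here as pure reporters; cross-response of one probe to the other site is
outside the model. The quotient $\Delta K_{NHO} = K_{HN}/K_{HO}$ is the
equilibrium constant of the 1,5 prototropic shift and decides the proton
position: above 1 the proton sits on nitrogen (zwitterion), below 1 on
oxygen (neutral form), at 1 it is shared.

## Henderson–Hasselbalch stage

With limiting shifts $\delta_{min} < \delta_{max}$, the transform
$y = \log_{10}[(\delta_{max}-\delta_{obs})/(\delta_{obs}-\delta_{min})]$ is
exactly $\pm(\mathrm{pH} - \mathrm{p}K_a)$ for two-state data, so `fit_pka()`
regresses $y$ on pH and reports $\mathrm{p}K_a = -b_0/b_1$ — the same zero
crossing read graphically from the classical plot, but with a standard
error propagated from the coefficient covariance. Points at or beyond the
limits (plateau observations, where the log argument is non-positive) are
excluded and counted, not treated as errors. Two guards matter in practice:
a fit with $|b_1| < 0.1$ is refused outright (no transition in the window),
and $|b_1|$ outside $[0.8, 1.2]$ raises a deviation flag, since a unit
magnitude is what the two-state model predicts.

Limiting shifts default to the means of the first and last `n_plateau = 3`
observed points. Two properties of this choice are worth knowing. First, on
a pH grid symmetric about the pKa the small residual bias of the two
plateau means cancels exactly in the zero crossing, which is why the
closed-loop tests recover the generating pKa to machine precision even
though each limit is a fraction of a percent short of the true state shift.
Second, on truncated titrations the unreached plateau's spread exceeds
`plateau_tol` (5 % of the range) and the result is flagged; for such data
the anchor/limit overrides should be used instead.

For multi-step systems a single transform spanning both transitions is
meaningless. When the δ-diagram stage (below) detects $k \ge 1$
breakpoints, `run_pipeline()` fits one window per transition, split at the
breakpoint pH values. Near a breakpoint the intermediate species never
fully populates — there is no true plateau — so when the Gibbs-triangle
fit has located the pure-intermediate vertex $B$, its coordinate supplies
the window's inner limiting shift; with it, both pKa values of a
separation-2 diprotic system are recovered within 0.1 pH units at the
default grid, while plain plateau means err by about 0.2.

## The δ-diagram stage

Plotting one probe's shift against another's removes pH from the analysis
entirely — both remaining axes are shift measurements, so titrant volumes
and meter drift drop out. The shape of this trajectory classifies the
system:

* a single step gives an exact straight chord (both probes are affine in
  the same fraction $f$);
* two steps give two chords meeting at the pure-intermediate point, rounded
  over the pH range where both transitions overlap;
* strongly overlapping steps give a broad arc with no straight portion.

`linearity_check()` fits continuous piecewise-linear models with 0–2
interior vertices by total least squares on the planar trajectory
(orthogonal residuals; vertices restricted to data points; exhaustive
vertex search) and selects the smallest vertex count whose residual sum is
within a factor $(1 + {tol\_model})$ of the best, *plus* an absolute floor
of $2 n \cdot \mathrm{resolution}^2$. The floor is essential: at zero noise
every residual tends to zero and a purely relative rule would always prefer
more vertices. Its scale, `resolution = 0.002` ppm, is the typical digital
resolution of a 500 MHz ¹H spectrum — residual differences below the
digitizer are not evidence of structure. With the defaults
(`tol_model = 0.05`), a monoprotic trajectory reports 0 breakpoints, a
separation-2 diprotic reports 1, and a close-pKa three-state reporter pair
(separation 0.1, the hydroquinone-like case where a second hydroxyl
deprotonates just above the NHO bridge) reports 2. The counts are
qualitative geometry labels, not hypothesis tests; on real data the floor
should be set to the instrument's resolution.

## Perrin linearization

For two coupled single-step responses, eliminating pH between the two site
equations yields the bilinear identity
$$(\delta_y - \delta_y^\circ)(\delta_x^e - \delta_x)
  = \Delta K \,(\delta_x - \delta_x^\circ)(\delta_y^e - \delta_y),$$
where $\circ$/$e$ mark the start/end species shifts. `perrin_fit()`
regresses the left product on the right product with a free intercept —
the intercept absorbs small anchor errors (real data show small nonzero
intercepts) and is numerically zero on clean synthetic data. The slope is
$\Delta K = K_y/K_x$ (y-site over x-site); exchanging the probe roles maps
it to its reciprocal, exactly.

Two practical notes. The endpoint symbols refer to the *species* shifts: by
default the diagram anchors are the first/last observed points, which on a
±2.5 pH grid sit a few tenths of a percent short of saturation and bias
the slope by about half a percent; when the state shifts are known (or a
plateau is well-established) they should be passed as anchor overrides,
which is what the closed-loop tests do to reach $10^{-6}$ recovery. Second,
as $\Delta K \to 1$ the two products become equal point-wise and the
regression loses leverage on the quotient's *deviation* from 1; the
`near_unity` flag (band `tol_unity = 0.005`, or twice the slope's standard
error if larger) marks that regime. It is a flag, not an error — the
estimate itself remains valid.

## Polster–Lachmann Gibbs-triangle analysis

A two-step trajectory lives inside the triangle of state points $A$
(initial), $B$ (pure intermediate — the neutralization vertex) and $C$
(final). The barycentric coordinates $(b_0, b_1, b_2)$ of a trajectory
point with respect to that triangle *are* the species fractions, so
$$\frac{b_1^2}{b_0\, b_2} = \frac{K_1}{K_2}$$
at every point of the curve — a ratio of distances in the diagram,
independent of pH. Geometrically, the cevian from $A$ through an
experimental point meets side $B$–$C$ at $X$ with $|BX|/|XC| = b_2/b_1$
(reported as `distance_ratio`), the cevian from $C$ meets $A$–$B$ at $Y$
with $|AY|/|YB| = b_1/b_0$, and the product of the two ratios is the
quotient.

$A$ and $C$ are the anchors, but $B$ is never observed: the intermediate
peaks at a fraction $\sqrt{K_1/K_2}\,/\,(2 + \sqrt{K_1/K_2})$ short of
unity, so the trajectory's apex undershoots $B$ — by 17 % of the vertex
height even at a separation of two pH units. The constant-quotient relation
above says the trajectory is exactly a conic tangent to side $AB$ at $A$
and to side $CB$ at $C$; $B$ is therefore the intersection of the end
tangents. `polster_lachmann()` estimates it by geometric least squares of
that conic, parametrized directly by $(B, \Delta K)$, with residuals
normalized by the local gradient (first-order orthogonal distances),
initialized from the intersection of the first and last piecewise-linear
segments. At zero noise this reproduces the tangent construction exactly:
recovered quotients for $K_1/K_2 \in \{2, 5, 10\}$ are within 0.7 % on the
default 25-point grid (the residual error comes from the anchors sitting
slightly short of the pure end states, as with Perrin). Naive alternatives
are much worse — reading the quotient off the raw segment-line
intersection errs by over 100 % even without noise, because fitted
segments span curved regions and their intersection lands well inside the
true vertex.

The construction is refused when no breakpoint was detected (collinear
diagram — the triangle is degenerate and the system is Perrin territory),
when the end segments are parallel, or when the experimental point nearest
the detected vertex coincides with an anchor.

One symmetry is worth stating explicitly: the stepwise quotient is
direction-independent. Reading the titration backwards exchanges the roles
of the two steps, and the apparent quotient of the reversed process is
$(1/K_2)/(1/K_1) = K_1/K_2$ again; the package's estimator accordingly
returns the same value (within tolerance) on a reversed trajectory, and
the test suite checks exactly that.

## Thermodynamic layer

$\Delta pK_{NHO} = -\log_{10} \Delta K_{NHO}$ and
$\Delta\Delta G^\circ = -RT \ln \Delta K_{NHO}$ in kJ mol⁻¹ (the sign
convention makes both negative when the proton prefers nitrogen). The two
columns are proportional by construction,
$\Delta\Delta G^\circ = (RT \ln 10 / 1000)\, \Delta pK$, and antisymmetric
under $\Delta K \to 1/\Delta K$; both identities are tested to $10^{-12}$.
The default temperature is 296.15 K with $R = 8.314$ J mol⁻¹ K⁻¹; both are
configurable. Classification applies the quotient thresholds directly,
with a `near_unity` flag when $|\Delta K - 1|$ is within
$\max(tol\_unity,\, 2\,\mathrm{SE})$ — in that regime the proton is best
described as shared and the sign of the displacement is not resolved.

Display rounding follows the conventional table format (pKa to one
decimal, ΔΔG° to three); JSON reports keep full precision.

## The synthetic generator and what passing tests mean

The generator emulates exactly the model the estimators assume:
population-weighted shift averaging along a noiseless pH ramp, plus
Gaussian noise on shifts (`sigma_shift`, default 0.002 ppm — digitizer
scale) and on the *recorded* pH (`sigma_pH`, default 0.02; the chemistry
follows the true ramp). Default grids place 25 points across the bracketing
exponents ±2.5 pH units. A fixed seed fixes the full output stream and the
generator restores the caller's RNG state.

It does **not** emulate: slow or intermediate exchange (lineshape effects),
activity/ionic-strength corrections, solvent isotope effects on the
electrode reading (pH is stored as read, uncorrected), cross-responding
probes, titrant-induced decomposition (e.g. imine hydrolysis on the acid
branch — the data model's branch tags exist so such points can be stored
but excluded), or drifts in referencing. Closed-loop recovery therefore
demonstrates correctness of the estimators *under the stated model*, not
robustness to every pathology of real spectra. The noise study (200
replicates at the default noise) bounds the pKa mean absolute error at
0.05 pH units; the Gibbs-triangle vertex estimation, by contrast, is
genuinely noise-sensitive — at 0.002 ppm noise the quotient can err by
tens of percent because the end-tangent geometry is ill-conditioned — and
is validated here at zero noise, matching its graphical origins. For noisy
multi-step data the honest route is replicate titrations or denser
sampling around the vertex.

## Numerical choices and edge cases

* Breakpoint search is exhaustive over data-point vertices with a minimum
  segment occupancy of 3 points (2 when fewer points are available);
  feasibility requires 4 points for one break and 6 for two.
* The constant-quotient conic fit runs two rounds of Nelder–Mead on
  $(B_x, B_y, \log \Delta K)$ with analytic residual gradients in shift
  space; the log parametrization keeps the quotient positive.
* Degenerate inputs fail loudly and early: series with fewer than two
  points, equal limiting shifts ("no transition"), all-equal pH (singular
  design), identical bilinear abscissae (singular Perrin fit), collinear
  triangles. `run_pipeline()` converts stage errors into named entries of
  the report and emits explicit nulls for downstream stages.
* CSV round-trips preserve 15 significant digits and are byte-stable from
  the second write onward; JSON reports are byte-identical for identical
  input and configuration (no timestamps, full-precision numbers).

## Problem sizes used by the tests and acceptance script

Fixtures use the default 25-point grids throughout; the Monte-Carlo noise
study uses 200 seeded replicates; the Perrin sweep covers quotients
$10^{-1}$–$10^{1}$ in quarter-decade steps; Polster–Lachmann recovery is
checked at stepwise quotients 2, 5 and 10. These sizes mirror a realistic
titration (20–30 aliquots) and keep the full suite fast.
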