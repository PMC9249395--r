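---
title: "Models and methods in cuspkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in cuspkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`cuspkit` joins two workflows around shark tooth-cusp morphogenesis: a
reaction–diffusion simulator of cusp patterning with a perturbation-sweep
engine, and a landmark-based geometric-morphometrics pipeline for measuring
shape and size change across treatment groups. This vignette documents the
models, the numerical choices, and what the package's tests do and do not
establish.

## The patterning model

Dental signalling centres (enamel-knot-like foci) behave like the peaks of
an activator–inhibitor system: a locally self-enhancing signal induces a
longer-range antagonist, and spaced foci emerge along the jaw's
anterior–posterior axis. The crown is modelled as a one-dimensional strip
of epithelial cells because every phenotype of interest here — unicuspid,
tricuspid, multicuspid, serrated-like — is a pattern of cusps along that
single axis. Per cell, with explicit-Euler time stepping (one iteration =
one time unit, unit grid spacing):

$$a' = a + b_a + \frac{act\,a^2}{(1 + inh\,i)(1 + sat\,a^2)} - deg\,a + d_a \nabla^2 a$$
$$i' = i + aip\,a^2 - idr\cdot deg\,i + d_i \nabla^2 i$$

both clamped at zero, with zero-flux boundaries at the active borders.
The terms and their roles:

* `act` — activator auto-activation; the principal "activation" dial.
* `inh` — strength with which the inhibitor suppresses auto-activation.
* `deg` — shared degradation rate; the inhibitor turns over `idr`× faster
  (`idr` = 3), which is what makes the uniform state Turing-unstable.
* `sat` — saturation of auto-activation; bounds peak amplitude so the
  activator stays below the knot-differentiation threshold in the
  calibrated regime and peaks stay discrete.
* `b_a` — small basal production; seeds lateral peak nucleation as the
  domain outgrows the inhibitor's reach.
* `d_a`, `d_i` — diffusivities. Lateral inhibition requires
  `d_i`/`d_a` ≫ 1 (default 45).

Growth is morphodynamic in two senses. First, the active site widens every
iteration by `bgr · min(1, sec · mean(a))`: `bgr` is the maximum border
growth rate and `sec` couples realized growth to the network's mean
activation, standing in for the growth factors secreted by the signalling
foci. Total width is therefore bounded by `bwi + n_iter · bgr`, and
activation surplus (more cusps) and widening arrive together, as they do in
upregulated teeth. The split between the two borders follows the
anterior–posterior bias `bia`. Second, crown height accumulates as
`pro · a` in every non-knot cell: growth is concentrated beneath strongly
signalling regions, so the integrated activator history is the occlusal
profile, and cusps that appear late in development end up smaller —
matching the lateral addition of small secondary cusps. Cells whose
activator exceeds the differentiation threshold become knot cells:
irreversibly non-proliferative, their height frozen. The threshold default
(3.0) sits above the calibrated peak amplitude; a literal threshold at the
peak amplitude would freeze peak tips while their shoulders keep growing,
splitting every cusp in two, which is why the differentiated-knot regime is
exercised by dedicated tests rather than by the baseline presets.

### Numerical stability

Explicit Euler on a unit grid is stable for diffusion up to 0.5, but with
the inhibitor decay added the bound tightens slightly below 0.5 at the
Nyquist mode; at exactly `d_i` = 0.5 the scheme sustains a period-2
checkerboard that the zero-clamp converts into a bounded artefact.
Parameters above 0.5 are rejected; above 0.45 a warning is issued, and the
default is `d_i` = 0.45. Any non-finite field value aborts with the
iteration number.

### Calibration of the presets

The `shark` preset (`act` = 0.25, `inh` = 52, `deg` = 0.005,
`d_a` = 0.01, `d_i` = 0.45, `sec` = 1.1, `bwi` = 10, `bgr` = 0.01,
`bia` = 1, `pro` = 0.001; network constants `sat` = 0.05, `b_a` = 5e-4,
`aip` = 0.02, `idr` = 3) is calibrated so that, at the standard 11,000
iterations:

* the baseline is tricuspid with the primary cusp central and tallest;
* a 10% increase in `act` together with raised `deg` gives five cusps
  (faster turnover shortens the pattern wavelength);
* decreasing `act` or increasing `inh` passes through unicuspid before the
  tooth is lost, and cusp count is monotone along both ladders;
* increasing `act` or decreasing `inh` adds cusps and widens the crown.

The `seal` preset is the low-activation baseline (`act` = 0.10, otherwise
identical): unicuspid at default, tricuspid near `act` ≈ 0.22, quadricuspid
above — the same activation progression at phenotype level. Both presets
are phenotype-level calibrations on this model's own parameter scale; they
are not numerical transcriptions of any other simulator's parameter files.

"No-tooth" is declared when the maximum height does not exceed twice the
patternless expectation `(b_a/deg) · pro · n_iter` (or when no cusp
passes prominence screening); "widened" requires an explicit reference
width (1.25× it), which `mimic_treatment()` supplies from its baseline.
Cusp detection takes local maxima of the height profile with topographic
prominence at least 10% of the maximum height, a floor that separates
fully formed cusps from incipient bulges; ties break to the
first-encountered cell.

## Landmarks and superimposition

The 38-point scheme places fixed landmark 1 at the primary cusp tip and 20
at the tooth base, with 18 sliding semilandmarks per side at equal
arc-length spacing (each side divided into 19 equal arcs). TPS files store
image-convention coordinates; the reader flips y to mathematical
convention and applies the per-record scale factor, and the writer inverts
both, so round-trips are lossless. Right-jaw teeth are mirror images of
left-jaw teeth; by default the pipeline reflects them about their own
apex–base axis and relabels the two curves so both sides share one shape
space. Whether the original analyses of such designs reflect one side is
typically unrecorded, so it is a switch.

Generalized Procrustes analysis centres each configuration, scales it to
unit centroid size, rotates it onto the running consensus (rotations only;
reflections are disallowed because outlines have fixed chirality after the
side policy), and iterates to a consensus tolerance of 1e-10. Semilandmark
sliding then alternates with re-superimposition: each semilandmark moves
along the tangent through its curve neighbours, with per-specimen
displacements solving the joint quadratic minimization of either
thin-plate-spline bending energy against the consensus (default) or
squared Procrustes distance; displacements are capped at half the distance
to the nearer neighbour, and when the cap binds the whole displacement
vector is shrunk toward zero, which keeps the objective non-increasing.
Because sliding moves points along directions the superimposition cannot
pin down, the consensus never settles to 1e-10 under sliding; the sliding
phase instead stops when its summed objective is stable to 1e-7 relative
(at most 10 passes). Finally the consensus is rotated to its principal
axes with a deterministic 180° tie-break, making the fit invariant to a
common rotation of all inputs.

## Statistics

`procrustes_anova()` computes sequential (type-I) sums of squares of the
flattened aligned coordinates over treatment, then animal nested within
treatment — the only ordering consistent with per-tooth measurements
grouped in animals, and the one that yields degrees of freedom 2, 20, 115
for 3 treatments, 23 animals and 138 teeth. Significance uses residual
randomization (RRPP): for each term, residuals of its reduced model are
permuted and added back to the reduced fit, the term's F is recomputed,
and the p-value is the fraction of permuted F values at or above the
observed one, the observed arrangement included. `df`, `SS`, `R²` and `F`
are deterministic; permutations derive from a mandatory seed. On scalar
centroid sizes the same code path reduces exactly to univariate sequential
ANOVA, which is how it is cross-checked against `lm()`.

Shape PCA runs at two levels: sample-mean (the six teeth of each animal
averaged first — the level for ordinating treated animals in shape space)
and tooth (for the variance F-test, which compares within-group PC1
variance between a control and a treated arm, control variance in the
numerator so F < 1 flags inflated treated-arm variance). The centroid-size
model is the same sequential design on CS in original units, followed by
Tukey HSD on treatment means and percent change against the control.
`chisq_proportions()` is a Pearson chi-square on a 2×2 table with the
continuity correction off by default.

## The synthetic-data generator

The generator emulates the three-arm study design: 7/8/8 animals for
DMSO/IWR/CHIR, six teeth each (positions 1–3, both sides). Per tooth,

* coordinates = template + treatment effect × cusp-reduction axis +
  animal offset + tooth noise (+ a fourth-cusp displacement with
  per-treatment probability), all scaled by treatment size multiplier ×
  animal size factor × tooth size factor;
* the template is an analytic bilaterally symmetric tricuspid outline, and
  the cusp-reduction axis is the unit-norm displacement from it to its
  secondary-cusp-suppressed variant, so positive effects shrink secondary
  cusps (the downregulated direction) and negative effects enhance them.

The documented study quantities are configuration, not hard-coded truth:
size multipliers 0.641/1.128 (−35.9%/+12.8%), IWR tooth-noise SD
multiplier 1.9 (variance ratio ≈ 3.6, i.e. an expected control/treated
variance ratio near 0.28), fourth-cusp probabilities 0.01/0/0.12. The
noise scales — which the study this design mirrors does not publish — were
chosen once so that the emulation lands near the published test
statistics: `sigma_sample` = 0.012 and `sigma_tooth` = 0.02 put the
shape-ANOVA treatment F near 8 and its R² near 0.1, and log-scale size
SDs of 0.11 at both levels put the centroid-size treatment F in the low
hundreds with a clearly significant animal term. Two printed quantities
cannot be matched simultaneously under isotropic per-animal noise: pushing
the animal-level share of shape variance up toward the published sample R²
(~0.27) necessarily pulls the PC1 variance ratio away from its published
~0.28; the generator prioritizes the ratio, and its sample R² sits near
0.16. Sample-mean PC1 carries roughly 40–50% of variance rather than the
published 58%, for the same reason.

Two estimator notes. Percent-change recovery is unbiased (the lognormal
size factors cancel in group-mean ratios) but animal-level size noise makes
single-study estimates scatter by several percentage points, so recovery
is asserted against confidence intervals, and across seeds on the mean.
The variance F-test is measured on the unslid alignment: bending-energy
sliding pulls each specimen toward the consensus and so attenuates exactly
the inflated deviations the test is meant to detect, biasing the slid
ratio toward 1.

## What the tests show — and what they do not

Oracle tests pin the numerics: cusp prominence against an exhaustive
scan, GPA against an independent alternating-minimization implementation,
sliding against a coarse-to-fine grid search, sequential shape ANOVA
against explicit hat matrices, PCA against a direct eigen-decomposition,
and the RRPP null distribution against its nominal type-I error (500 null
data sets). Calibration tests establish that the full pipeline — generate,
write TPS, read, reflect, superimpose, slide, test — recovers the
configured effect directions and magnitudes. None of this shows that real
digitised teeth behave like the generator: real landmark noise is
correlated along outlines rather than isotropic, mineralisation timing and
jaw position add structured variation the generator does not model, and
the simulator is a phenotype-level abstraction whose parameter values are
not measurements. Problem sizes in the routine suite (toy configurations
of 3–12 landmarks, the 138-tooth default design, 200-seed recovery runs,
simulator ladders at 10% resolution) were chosen to exercise every code
path at full fidelity while keeping the whole suite in the minutes range.

## Known limitations

* The simulator is 1-D; phenotypes that depend on off-axis cusp placement
  (true serration geometry, cusp rows) are out of reach by construction.
* Sliding semilandmarks assume the consensus is a sensible tangent
  reference; with very few specimens or extreme shape effects the
  bending-energy matrix can be ill-conditioned (a small ridge is added).
* The Procrustes ANOVA treats animal as a fixed nested effect, matching
  the published degrees of freedom; no random-effect variant is provided.
* The chi-square of fourth-cusp proportions is implemented and simulated,
  but the underlying real counts are not published, so only its power
  properties are testable here.
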