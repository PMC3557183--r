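---
title: "Multi-exponential analysis of photon-beam-induced positron activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-exponential analysis of photon-beam-induced positron activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photopet)
```

## The measurement and the model

Radiotherapy photons above the (γ,n) threshold activate tissue: ¹²C, ¹⁶O
and ¹⁴N become the positron emitters ¹¹C (20.39 min), ¹⁵O (2.04 min) and
¹³N (9.97 min). Hydrogen, almost a quarter of soft tissue by atom count,
produces nothing — which is why all composition statements in this package
are over C, N and O only. After the patient is transported to the scanner
(about 7 minutes) a dynamic acquisition records the decaying mixture,
here as 15 frames of 2 minutes.

The count rate of a volume of interest is modelled as

$$S(t) = \sum_{k} S_k\, 2^{-t/T_{1/2,k}} + K,$$

with $t$ in minutes since the end of irradiation and the amplitudes $S_k$
defined at that instant. The model makes three assumptions worth naming:

* **No washout.** Perfusion-driven clearance of the induced nuclides is
  not modelled. For an enclosed compartment like bladder urine or for
  mostly static subcutaneous fat this is a good approximation; for lung or
  liver it would not be. A washout hook exists in the generator's design
  but deliberately ships disabled.
* **No production ramp.** The irradiation itself (minutes long, several
  beam directions) is collapsed to a point: the $S_k$ are defined at
  beam-off. Since fitting starts after a further multi-minute transport,
  the ramp's shape only rescales the amplitudes.
* **Three nuclides.** Bone would add ³⁰P (2.5 min) and ³⁹Ca (0.86 s).
  ³⁹Ca is gone long before the first frame; ³⁰P sits so close to ¹⁵O that
  the two are not separable at these statistics. Both exist in the
  nuclide table and the generator so this claim can be demonstrated
  rather than asserted.

## Frame values are integrals

A PET frame sums coincidences over its duration, so the package models
frame values as the time-average of $S(t)$ over the frame, in closed form
per component. With a 2.04-min component and 2-min frames, the difference
between the frame average and a midpoint sample is on the percent scale —
material at the accuracy the round-trip tests demand. Whether the original
VOI analysis sampled midpoints or integrals is not documented; what
matters for validity is that generator and fitter share one convention,
and here both use the integral. No decay correction is applied at
extraction or read-in: frames stay raw, and all decay handling lives in
the model.

## Fitting

**Fixed mode.** With half-lives pinned, the model is linear in
$(S_1,\dots,S_k,K)$ and the non-negativity-constrained optimum is unique
and global: it is solved by non-negative least squares over the
frame-basis matrix. No starting values, no multi-start, no convergence
question. Basis columns are normalized to unit length before the solve
(and the scaling undone after) because a short-half-life column can
otherwise have a norm near 1e-11 and defeat the solver's internal
tolerance.

**Free mode.** Estimating half-lives too makes the problem notoriously
ill-conditioned. The package uses variable projection: the nonlinear
search runs over the half-lives only, with amplitudes and $K$ solved
exactly by NNLS at every candidate, followed by a full-parameter
Levenberg–Marquardt polish with an analytic Jacobian (the
finite-difference default stalls around relative objectives of 1e-10;
the analytic form reaches machine precision). Starts combine the three
physical half-lives scaled by {0.5, 1, 2} with the best five combinations
from a coarser screened grid (physical values × {0.25, 0.5, 1, 2, 4}),
so the optimiser cannot be trapped away from, for example, a sub-minute
noise component. Lowest objective wins; ties go to fewer non-zero
components.

Free half-lives are bounded below at 0.1 min. The bound excludes the
degenerate spike solution at zero half-life while leaving room for
components far faster than anything measurable after a 7-min transport.
A consequence the code must handle explicitly: a component at the fast
end can carry an astronomically large amplitude *at beam-off* while
contributing almost nothing inside the scan window. Components are
therefore declared "unidentified" (amplitude set to exactly 0, half-life
treated as noise) based on their peak contribution to the modelled
signal, never on the raw amplitude. Components are returned sorted by
descending half-life, which keeps labelling deterministic across runs.

**Objective.** Unweighted sum of squared residuals is the default, with
inverse-variance Poisson weighting available as an option
(`weights = "poisson"`). At the count levels of interest the unweighted
fit is what the round-trip and coverage tests characterise.

## Confidence intervals

The default is the linearized interval: covariance
$\hat\sigma^2 (J^\top J)^{-1}$ from the Jacobian at the optimum, t
quantile with $n-p$ degrees of freedom. A parametric bootstrap
(Gaussian resampling at the estimated residual s.d., percentile interval,
seed-reproducible) is provided as an alternative because the interval
method behind the original analysis is not documented. On simulated
Poisson data at high counts (5·10⁴ scale, 500 replicates) the linearized
intervals cover the true dominant amplitudes at 95–98 % — the acceptance
suite recomputes this. The percentile bootstrap undercovers at 15 frames
(around 80–86 % in the same experiment), the familiar small-sample
behaviour of percentile intervals; it is kept for its distribution-free
shape, not recommended as the default. A singular Jacobian — e.g. a
component pinned at zero — flags the intervals unreliable instead of
raising an error. The reported "± 0.00" style of rounded published
intervals is not reproduced literally; intervals are computed, not
transcribed.

## From fractions to composition

Normalized amplitudes are identified with elemental mass fractions
directly (¹¹C→C, ¹⁵O→O, ¹³N→N). Two open choices are resolved as follows,
both revisitable through arguments rather than code changes:

* **Unit activation yields.** Counts per unit mass fraction actually
  depend on each element's photonuclear cross section folded with the
  beam spectrum. The package follows the direct identification (all
  yield weights 1) and exposes `yield_weights` for users who have
  spectrum-specific values; fractions are divided by the weight and
  renormalized.
* **Mass fractions, not atom fractions.** Reference values are compared
  as printed in ICRU-style mass-percent tables; no conversion to atom
  fractions is attempted.

Free-mode components are labelled by the nearest physical half-life
within 35 % relative tolerance. The window is wide by design: fitted
values like 19.4 or 20.9 min must label as ¹¹C and 1.99 or 2.01 min as
¹⁵O, and a 2.5-min ³⁰P contaminant *should* fall inside the ¹⁵O window,
because physically it is not distinguishable. Only the three C/N/O
nuclides are label candidates; anything outside every window is reported
as unassigned rather than guessed. The comparison report gives
per-element differences and descriptive CI-overlap flags — no hypothesis
test, since agreement here is a qualitative statement.

The bundled reference compositions are raw ICRU-style mass percentages
for adult adipose tissue (#2) and the filled urinary bladder; the
hydrogen-omitted values the package compares against are computed from
them by renormalizing C/N/O over their own sum (`h_adjust()`), an
idempotent, scale-invariant operation. The renormalized values agree with
the independently published hydrogen-omitted figures to the printed
decimal, which is the bundled data's consistency check.

## The synthetic-data generator

The generator is the package's stand-in for a patient acquisition, and
its defaults are the study conditions: 7-min transport, 15 × 2-min
frames, amplitudes driven by a bundled tissue composition, K = 0. Noise
is Poisson on expected frame counts
(`amplitude_scale` × mean rate × duration), converted back to rates, so
the noiseless curve is the exact expectation of the noisy one; the
acquisition of interest is explicitly low-count (roughly 5 % of FDG
statistics), which is why no Gaussian approximation is used. The default
`amplitude_scale` of 1e4 puts a bladder-like first frame near 3·10³
counts; coverage experiments use 5·10⁴ (≈1.4·10⁴ first-frame counts) to
sit safely in the "high-count" regime they describe. Exact per-frame
count levels of the original acquisition were never published, so this
scale is a free parameter, not a calibrated one.

The phantom generator places a bladder-like sphere inside a fat-like
shell on grids up to 64³, each region sharing its tissue's TAC, with
independent per-voxel Poisson draws when noise is on. What the phantom
does **not** emulate: scanner resolution and partial-volume effects,
attenuation, scatter, randoms, reconstruction artefacts, registration
error, and anatomy. Passing the end-to-end pipeline test therefore shows
the analysis chain is self-consistent, not that it is robust to
reconstruction physics — those corrections are upstream of this package
by design.

## Problem sizes and numerical choices

The test suite works at desk scale, chosen to characterise behaviour
rather than exhaust it: 15-frame curves throughout; 20 randomized curves
for optimizer-vs-oracle comparisons; 200 replicates for the
noise-recovery regression and 500 for interval coverage; 2000 draws for
the Poisson unbiasedness check; phantoms at 8–16³ voxels. Grid oracles
refuse more than 2·10⁵ combinations by default. Degenerate inputs follow
one rule — validation failures raise typed input errors, while
statistically meaningful edge cases (all-zero TAC, zero amplitude sum)
return flagged results instead of raising.

## Known limitations

* Compositions are only ever over C/N/O; tissues whose activation is
  dominated by other elements (bone calcium/phosphorus) are outside the
  model, and the ³⁰P demonstration shows what happens when they leak in.
* Free-mode fractions at low counts can be dominated by a spike
  component at the half-life lower bound; fixed mode is the regime meant
  for composition estimates, free mode for half-life verification.
* The percentile bootstrap's undercoverage at 15 frames is documented
  above rather than corrected (BCa or basic intervals would be the next
  step).
* NIfTI frame timing travels in a JSON sidecar; standards-conformant
  timing embedded in the image header is not attempted.
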