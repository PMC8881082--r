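---
title: "Scoring molecular-replacement search models without diffraction data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring molecular-replacement search models without diffraction data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rellg)
```

## The problem

Molecular replacement (MR) phases a crystal diffraction pattern by placing a
homologous model in the unit cell; whether it works depends on how well the
model's electron density overlaps the target's. The conventional quality
measure, the refined log-likelihood-gain (LLG) against measured intensities,
requires diffraction data and varies with crystal form: resolution, number of
copies in the asymmetric unit, and the fraction of the cell the model
accounts for all enter the score. That makes LLG-based comparisons across
targets awkward and rules out targets solved by cryo-EM or NMR.

The **relative expected LLG (reLLG)** implemented here needs only the target
coordinates. It scores the model's density overlap with the target in a
virtual cell of its own, and normalizes so the score is independent of the
cell, of the number of Fourier terms, and hence of any crystal form.

## The score

Both structures are placed in a common orthogonal P1 box and their structure
factors computed to a resolution limit $d_{\min}$, then normalized within
resolution shells to E-values with $\langle|E|^2\rangle = 1$. Under the
central-limit assumption that the two structure-factor sets are bivariate
complex normal, the conditional probability of the target E-value given the
model's is a complex normal whose off-diagonal covariance is the real
correlation $\sigma_A$. One Fourier term contributes to the phased
log-likelihood-gain

$$\mathrm{LLG}(E_t, E_m) =
  \frac{2 E_t \sigma_A E_m \cos\Delta\phi - \sigma_A^2 (E_t^2 + E_m^2)}
       {1 - \sigma_A^2} - \ln(1 - \sigma_A^2),$$

zero when $\sigma_A = 0$ (the Wilson null). If all coordinate errors are
drawn from one 3D Gaussian with radial RMS $r$,

$$\sigma_A(r; s) = f_p \exp\!\left(-\tfrac{2\pi^2}{3} r^2 s^2\right),$$

with $f_p$ the fraction of the target the model explains (taken as 1
throughout) and $s = 1/d$ the diffraction-vector magnitude.

The model pose (3 rotations about its centroid, 3 translations) and the $r$
parameter are refined to maximize the total phased LLG, so the score is taken
at the model's best density overlap, not at whatever superposition it arrived
in. The Fourier shell correlation (FSC) between the refined model's E-values
and the target's is then accumulated into an expected LLG,

$$\mathrm{eLLG} = \sum_k n_k\, \mathrm{FSC}_k^4 / 2,$$

over shells $k$ with $n_k$ terms. Using the measured FSC rather than the
fitted $\sigma_A$ curve means no assumption is made about the error
distribution at this stage; models with locally varying errors are scored by
what their density actually matches.

The eLLG grows with the number of Fourier terms, i.e. with the target's
size, so it is normalized by the eLLG of an **ideally imperfect model**: a
complete model with radial RMS error 0.4 Å, the best plausibly obtainable
from an independent high-resolution structure determination of the same
protein. The reLLG is the ratio. A perfect copy of the target scores
slightly above 1; an unrelated structure scores essentially 0.

## Error-estimate weighting

Predicted models can carry per-atom RMS coordinate-error estimates
$\sigma_r$ in the B-factor column. Converting them with

$$B = \tfrac{8\pi^2}{3}\, \sigma_r^2$$

smears each atom over its positional uncertainty, which optimizes the density
overlap: confident atoms stay sharp, doubtful ones fade. `rellg()` scores
each model both ways — error-weighted and with a constant B of 25 Å² — and
`score_models()` reports the difference as the value added by the estimates.
Because the calculation uses normalized E-values, the constant's actual value
is irrelevant. Implausible estimates above 100 Å are clamped rather than
rejected; a model whose atoms are all effectively downweighted to nothing is
given a score of zero (with the reason recorded), not an error. The target's
own B-factors are used as found in its file; only models are re-weighted.

## Tunable parameters

* `d_min` (default **2 Å**): the resolution limit. Higher resolution is more
  sensitive to model error, lower more forgiving; 2 Å is near the median
  resolution of deposited crystal structures and roughly where a partial MR
  solution can usually be completed.
* `pad` (default **10 Å**): box padding per side — several times `d_min`, so
  density overlap between periodic images is negligible.
* `n_shells` / `min_terms` (defaults **20** / **50**): equal-term-count
  resolution shells; equal counts give uniformly stable FSC estimates, and
  the shell count shrinks automatically if the term list is small.
* `constant_b` (default **25 Å²**): the constant-B control.
* Refinement: alternation stops when a cycle gains less than `tol = 0.01`
  nats or after `max_cycles = 20`; the rmsd parameter is refined on a log
  scale within [0.05, 10] Å; pose gradients are central differences with
  steps of 1e-3 Å and 1e-4 rad.

## Numerical choices

* **Structure factors.** Standard four-Gaussian atomic scattering factors;
  occupancy multiplies each atom's contribution, so zero-occupancy atoms are
  retained but weightless. Two computation paths exist and must agree: exact
  direct summation (used up to 5000 atoms, and always the oracle in tests)
  and an FFT over sampled density. The FFT path smears every atom by an
  extra 20 Å² before sampling and removes that factor in reciprocal space;
  with the grid at `d_min`/4 spacing the aliased images are attenuated by
  more than e^{-10}, and the two paths agree to well under 0.5%
  (scale-relative) at the resolution limit. The constant term of the
  scattering factor rides on a Gaussian of exactly the smearing width, so
  the unsmearing removes it exactly.
* **Friedel pairs.** One representative per pair is kept and counted once in
  $n_k$. This halves the absolute eLLG relative to counting both mates, but
  the reLLG is a ratio over the same term set and is insensitive to any
  global factor.
* **Normalization of the ideal eLLG.** $\sigma_A(0.4; s)$ is accumulated per
  term, not per shell mean, so the normalization constant carries no binning
  sensitivity; numerator and denominator use the identical term list, making
  the reLLG a pure ratio.
* **FSC clamping.** Negative shell correlations are clamped to zero before
  the fourth power (anti-correlation must not be rewarded); the raw value is
  kept for diagnostics.
* **Refinement.** Block alternation between the 6-parameter pose
  (quasi-Newton BFGS, numerical central-difference gradients — pose
  perturbations of a pre-oriented model are small, so analytic gradients
  would be an optimization, not a contract) and the 1-D rmsd parameter with
  $\sigma_A$ refreshed each cycle. The first cycle runs the pose block to
  convergence; later cycles only polish after the $\sigma_A$ update. The
  rmsd starts from the model's median error estimate when available, else
  1 Å; its bounds keep $\sigma_A$ away from the singular perfect-correlation
  limit, which is additionally clamped at $1 - 10^{-6}$ with a warning. The
  returned state never scores below the starting state.
* **Degenerate inputs.** Oversize grids (an unfolded chain spanning hundreds
  of Å), empty models after filtering, unreadable files, and fully
  downweighted models all map to zero-score results carrying a reason, so a
  batch run never dies on one bad model.

## Sequence-identity calibration

Experience relates MR success to sequence identity; identity relates to the
effective coordinate error (VRMS), the parameter behind $\sigma_A$. The
calibration here uses the classic exponential form with a molecule-size
factor,

$$\mathrm{VRMS}(I, n) = 0.4 \cdot e^{1.5222\,(1 - I)} \cdot (n/175)^{1/3},$$

with the two constants anchored to the published behaviour of the
established identity-to-VRMS relation: a complete model of a 175-residue
protein at 100% identity has VRMS 0.4 Å (reLLG exactly 1), and 30% identity
translates to reLLG 0.091 at the 2 Å limit. The $n^{1/3}$ size factor is a
radius-of-gyration-like scaling chosen here; it is exactly 1 at the
175-residue reference. `rellg_analytic()` converts a VRMS to the score it
implies by the ratio of $\int_0^{1/d_{\min}} s^2 \sigma_A(r; s)^4\, ds$ to
the same integral at 0.4 Å — the $s^2$ weight being the density of Fourier
terms in a fixed cell — evaluated in closed form via the error function and
cross-checked against adaptive quadrature in the tests. A lattice-pipeline
run on a Gaussian-degraded dilute atom set agrees with this analytic curve
to within a few percent, validating the weight. On a connected chain the
agreement is exact only for small errors: once displacements approach bond
lengths, the density an atom leaves behind partly overlaps its neighbours'
original positions, so the low-resolution FSC — and hence the lattice reLLG
— runs somewhat above the single-Gaussian self-term curve. That is a
property of the error model, not of the score: the FSC-based eLLG measures
the overlap that is actually there.

```{r calibration}
head(calibration_curve(identity = seq(0.3, 1, by = 0.1)))
```

## Ranking

For score tables (group, target, model rank, GDT_HA, score) the package
implements the CASP aggregation conventions:

* `null_model_llg()` extrapolates the low-GDT_HA region of a GDT_HA-vs-LLG
  scatter to its intercept — the score pure-noise models achieve — via
  100 equal-width bins on the 0–100 GDT_HA axis, an iterative one-sided trim
  within each bin (drop points more than 1 SD below the bin mean, repeat to
  stability), selection of the populated bins in the bottom 35% of the axis,
  a 3-SD filter on bin averages, the middle 80% of the sorted remainder, and
  a least-squares line. The trim exists to reject sparse low outliers
  (failed calculations); on pure Gaussian noise it necessarily biases bin
  means upward, which the tests quantify with an independent oracle.
  `dllg()` subtracts the intercept and floors at zero.
* `zscore_ranking()` is the two-pass Z-score: population-SD Z-scores over
  rank-1 models, exclusion of first-pass outliers below −2, recomputation,
  a final floor at −2, and a −2 penalty per missing target. The SD
  convention (population vs sample) is exposed as an argument; Z-scores are
  invariant under positive affine transformations of the scores, so the
  choice of constant B never matters.

Interpretation choices that the source conventions leave open are arguments
with documented defaults: the GDT_HA axis is taken as the fixed 0–100 score
range (not the data range); the trim SD is that of the bin's current
survivors; the 3-SD filter uses the SD of bin averages; the middle 80% drops
⌊0.1 m⌋ bins from each end.

## What the synthetic fixtures do and do not show

`make_toy_structure()` builds idealized backbone+CB chains (helix, paired
strands, or a compact random-coil walk); `degrade()` realizes exactly the
error model $\sigma_A$ assumes — iid displacements from one 3D Gaussian (or
a per-atom profile), plus an optional rigid pose offset — and writes
truthful, constant, or shuffled error estimates. Tests built on these
fixtures verify the machinery: the FSC of a degraded model follows
$\sigma_A(r; s)$, refinement recovers injected errors and poses, truthful
estimates beat a constant B on spatially varying noise, and the score is
invariant to rigid motions. They do not establish how real predicted models
behave: real errors are correlated along the chain, non-Gaussian, and
correlated with atomic environment, and real error estimates are imperfect
in ways "misleading" shuffling only caricatures. The fixtures also make no
attempt at side-chain chemistry or Ramachandran statistics — at a 2 Å limit
with E-normalization the score machinery does not care.

Problem sizes were chosen to exercise the asymptotics the properties rely
on while keeping the suite quick: 500-atom (100-residue) fixtures for the
rmsd-recovery and normalization checks, 200–400 atoms for pose recovery,
invariance, and weighting comparisons, and 1000 atoms for the displacement
concentration check.

## Known limitations

* Superposition requires a residue correspondence (matching chain and
  residue numbers); there is no sequence-independent structural alignment,
  so models renumbered relative to the target must be pre-oriented.
* Pose refinement is local. A model outside the basin of attraction of the
  correct overlap converges to a nearby optimum and scores low; no search is
  attempted.
* $f_p = 1$ always: a model covering part of a target is scored against the
  whole target's normalization (exposed as an argument for
  experimentation).
* No space-group symmetry, bulk solvent, anisotropic displacement, or
  anomalous scattering: the virtual cell is P1 and the score intentionally
  crystal-form-free.
* Absolute LLG prediction for a particular crystal (data resolution,
  composition, copy number) is out of scope; the package ranks models, it
  does not promise an MR search will succeed.
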