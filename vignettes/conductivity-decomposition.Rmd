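---
title: "Decomposing Larmor-frequency conductivity into extracellular properties"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing Larmor-frequency conductivity into extracellular properties}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbcti)
set_log_level("warn")
```

## The problem

Phase-based MR electrical properties tomography (MREPT) reconstructs the
electrical conductivity of tissue at the Larmor frequency (about 128 MHz at
3 T) from the B1 transceiver phase. At that frequency current crosses cell
membranes freely, so the high-frequency conductivity $\sigma_H$ mixes
intra- and extracellular contributions. Below roughly 1 kHz the membranes
insulate and only the extracellular space (plus CSF) conducts; that
low-frequency regime is the one relevant to electrical stimulation
modelling and to ion-concentration physiology, but it is not directly
measurable without injecting current.

This package implements an electrodeless decomposition: conductivity is the
product of charge-carrier concentration and mobility, and mobility is
proportional to water diffusivity (Einstein relation). Multi-b-value
diffusion MRI therefore provides the mobility information needed to split
$\sigma_H$ into an apparent extracellular ion concentration $\bar c_e$, a
low-frequency mean conductivity $\sigma_L$, and — with a diffusion tensor
at one b-value — a low-frequency conductivity tensor $C_L$.

## The model chain

**1. High-frequency conductivity.** The transceiver phase
$\varphi^{tr}$ satisfies, under the assumption
$\sigma_H \gg \omega\epsilon_H$,

$$\nabla\varphi^{tr}\cdot\nabla\frac{1}{\sigma_H}
  + \frac{\nabla^2\varphi^{tr}}{\sigma_H} = 2\omega\mu_0 .$$

Solving this convection–reaction equation for $u = 1/\sigma_H$ is unstable
along the convective field, so an artificial diffusion term is added:

$$-c\,\nabla^2 u + \nabla\varphi^{tr}\cdot\nabla u
  + (\nabla^2\varphi^{tr})\,u = 2\omega\mu_0 ,$$

discretized with three-point central differences on the metre lattice and
solved as one sparse system per slice. `c = 0.025` is the default working
value: large enough to suppress the streak artefacts of pure convection,
small enough that plateau regions are unaffected (where $\nabla u = 0$ the
reaction term alone fixes $u$ exactly, which is why homogeneous phantoms
are recovered to machine precision for any `c`).

**2. Compartment model.** The normalized diffusion-weighted signal is
modelled with four unknowns — intracellular volume fraction $\nu_{ic}$,
extracellular diffusivity parameter $d^*_e$, isotropic (CSF) fraction
$\nu_{iso}$, and a noise-floor offset $\nu_0$:

$$\hat S_j/S_0 = (1-\nu_{iso})\left[\nu_{ic}\,
  e^{-b_j \nu_{ic} d_{ic}} + (1-\nu_{ic})\,
  e^{-b_j (1-\nu_{ic}) d^*_e}\right]
  + \nu_{iso}\, e^{-b_j d_{iso}} + \nu_0 ,$$

with $d_{ic} = 1.7\times10^{-3}$ and $d_{iso} = 3.0\times10^{-3}$ mm²/s
fixed a priori. The composite decay rates $\nu_{ic} d_{ic}$ and
$(1-\nu_{ic}) d^*_e$ are what make the model identifiable from b-value
decays alone, with no orientation modelling. Derived quantities:

$$\alpha = (1-\nu_{iso})(1-\nu_{ic}) + \nu_{iso}, \qquad
  d_w^e = \frac{(1-\nu_{iso})(1-\nu_{ic})^2 d^*_e
          + \nu_{iso} d_{iso}}{\alpha}, \qquad
  d_w^i = \nu_{ic}\, d_{ic} .$$

$\alpha$ counts CSF as extracellular, so it is an "extracellular + CSF"
fraction. A six-parameter three-pool multi-exponential baseline
(`fit_three_pool`) is included for comparison; it is deliberately the
less-constrained model that the four-parameter model improves upon.

**3. Decomposition.** With the ion-concentration ratio
$\beta = \bar c_i/\bar c_e$ taken from literature ion tables (0.41),

$$\bar c_e = \frac{\sigma_H}{\alpha d_w^e + (1-\alpha)\beta d_w^i},
  \qquad
  \sigma_L = \alpha\, \bar c_e\, d_w^e, \qquad
  \sigma_I = \sigma_H - \sigma_L .$$

**4. Tensor stage.** The measured diffusion tensor $D_b$ (log-linear fit
at b = 1000 s/mm²) is rescaled to the extracellular tensor under the
shared-eigenvector hypothesis, $D_{ext} = \eta D_b$ with
$\eta = 3 d_w^e / \mathrm{tr}(D_b)$, and
$C_L = \alpha\, \bar c_e\, D_{ext}$. Three identities then hold by
construction and are enforced to $10^{-12}$ in the tests:
$\sigma_L + \sigma_I = \sigma_H$, $\mathrm{tr}(D_{ext}) = 3 d_w^e$, and
$\mathrm{tr}(C_L)/3 = \sigma_L$.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `omega_hz` | 128e6 | Hz | Larmor frequency (3 T) |
| `c_diffusion` | 0.025 | – | artificial diffusion of the inversion |
| `d_ic` | 1.7e-3 | mm²/s | fixed intracellular diffusivity |
| `d_iso` | 3.0e-3 | mm²/s | fixed free-water diffusivity |
| `beta` | 0.41 | – | intra/extracellular concentration ratio |
| `tensor_b_value` | 1000 | s/mm² | diffusion-tensor shell |
| `snr` | 100 | – | phantom S0-to-noise ratio |

Units are handled in two regimes. PDE kernels convert voxel spacing to
metres because $\omega$ and $\mu_0$ are SI. The decomposition converts
diffusivities from mm²/s to µm²/ms (×10³) before dividing, which puts
$\bar c_e$ on the conventional 0–1.5 scale (units S·ms/(m·µm²)); CSF then
sits near 0.45 and grey matter near 0.9.

## The synthetic phantom

No imaging data ship with the package; every stage is verified against a
generator whose defaults emulate the reference acquisition geometry: a
128×128 single slice at 1.875 mm in-plane spacing (4 mm slice), a CSF
background ring at 1.19 S/m, a grey-matter annulus at 0.55 S/m and a
white-matter core at 0.41 S/m — segmented-ROI conductivity levels — with
compartment truths chosen at tissue-like values (WM cell-rich,
$\nu_{ic} = 0.6$; GM intermediate, 0.4; CSF almost purely isotropic,
$\nu_{iso} = 0.9$; $\nu_0 = 0.02$ everywhere). Interfaces are smoothed
with a 1-voxel Gaussian so the piecewise-constant regions meet smoothly.

The forward phase is produced by solving the *divergence-form* problem
$\nabla\cdot(\sigma^{-1}\nabla\varphi) = 2\omega\mu_0$ with a conservative
flux scheme and Dirichlet values from the homogeneous closed form
$\varphi = (\omega\mu_0\sigma_{bg}/2)(x^2+y^2)$; the inversion uses a
*non-conservative* central-difference discretization, so forward and
inverse solvers do not share a stencil and the round trip is a genuine
test.

DWI synthesis evaluates the compartment model per voxel (the model
describes diffusion-weighted signals; b = 0 acquisitions carry the
reference amplitude $S_0$ itself) and applies Rician noise — the magnitude
of a complex Gaussian perturbation with per-channel sd $S_0/\mathrm{SNR}$
— reproducibly from a seed. The default protocol is the 15 b-values
(50–5000 s/mm²) in 15 gradient directions plus one b = 0.

What the phantom does *not* emulate: $T_2$ decay and echo-time effects,
partial-volume anisotropy (signals are orientation-isotropic, so the
fitted tensor is isotropic), eddy-current or motion artefacts, spatially
varying coil sensitivity, and realistic anatomy. Passing tests therefore
demonstrate correctness of the numerics and internal consistency of the
method, not clinical accuracy.

## Numerical choices

- **Inversion boundary condition.** On the mask's boundary layer the
  unknown $u = 1/\sigma_H$ is pinned to the pointwise Helmholtz estimate
  $2\omega\mu_0/\nabla^2\varphi^{tr}$, median-filtered over a 3×3 window
  (standard practice for convection–reaction EPT; keeps the interior
  solve well-posed). A `fixed_value` mode is available for phantoms with
  known background conductivity.
- **Per-slice solves.** The acquisition geometry this targets uses a few
  4 mm slices, so through-plane second derivatives are unreliable; the
  default solves each slice in 2-D. A volumetric 3-D mode exists
  (`slicewise = FALSE`).
- **No upwinding.** Plain central differences; the artificial diffusion
  term is the only stabilization.
- **Fit bounds and multistart.** $\nu_{ic}, \nu_{iso} \in [0,1]$,
  $\nu_0 \in [0, 0.2]$ (a noise floor), $d^*_e \in [0.1, 3.0]\times
  10^{-3}$ mm²/s. Five deterministic starts ($\nu_{ic}$ sweeping 0.1–0.9,
  $\nu_{iso}$ alternating 0.05/0.5, $d^*_e = 10^{-3}$, $\nu_0 = 0.02$);
  best residual wins, ties broken by the smallest $\nu_0$. The optimizer
  is bounded Levenberg–Marquardt with parameter tolerance $10^{-8}$ and
  at most 500 iterations per start. Voxels are independent and results do
  not depend on execution order.
- **b = 0 handling.** The b = 0 volumes define $S_0$; their own
  normalized ratio is identically 1 and carries no information, so the
  per-voxel fit table contains the positive b-values only, and fits
  require at least five distinct b-values (one more than the number of
  unknowns).
- **Direction aggregation.** The compartment models are isotropic; the
  geometric mean of $S_j/S_0$ over directions at each b equals
  $\exp(-b\,\overline{\mathrm{ADC}})$ for a tensor substrate, so
  aggregation is exact for Gaussian anisotropy.
- **Three-pool second term.** The published form of the three-pool model
  repeats the $\nu_{ecm}$ coefficient on the free-water term; the
  implementation uses $\nu_{ecw}$ there, which is what the model's own
  derived $\alpha$ and $d_w^e$ formulas require. Its intracellular
  diffusivity map is the fitted $d_i^w$.
- **Eigenvalue clipping.** Noisy tensor fits can lose positive
  definiteness; eigenvalues are clipped at $10^{-6}$ mm²/s (counted and
  logged) before $\eta$ and $C_L$ are formed. Eigenvector sign is fixed
  deterministically (largest-magnitude component positive, third vector a
  cross product, so bases are right-handed).
- **$\beta$ sensitivity.** $Er(\beta)$ is the region mean of the
  voxelwise relative change of $\bar c_e$ against the reference
  $\beta = 0.41$; it is exactly zero at the reference and monotone in
  $|\beta - 0.41|$, with first-order slope
  $(1-\alpha)d_w^i / (\alpha d_w^e + (1-\alpha)\,0.41\, d_w^i)$ averaged
  over the region.

## Known limitations

**Ridge degeneracy of the compartment fit.** When the two composite rates
$\nu_{ic} d_{ic}$ and $(1-\nu_{ic}) d^*_e$ are close — e.g. the
grey-matter-like truth $(\nu_{ic}, d^*_e) = (0.5, 1.2\times10^{-3})$,
rates 0.85 vs 0.60 — the objective has a second basin near
$\nu_{ic} \approx 0$ whose residual differs by only $\sim 6\times10^{-4}$
RMS from the truth basin. With noise, the *global* minimum genuinely
falls into the wrong basin for a sizeable fraction of voxels: this is an
identifiability limit of the model, not an optimizer failure (restarting
from the truth gives a *worse* residual in most such voxels). A
Cramér–Rao analysis at SNR 50 gives $\mathrm{sd}(\hat\nu_{ic}) \gtrsim
0.09$ even when all 15 directions are averaged. The derived maps
$\alpha$, $d_w^e$ and $\sigma_L$ are considerably better determined than
the raw parameters because the ridge largely trades $\nu_{ic}$ against
$d^*_e$ and $\nu_{iso}$, but cell-rich regions still show median errors
around 10–20% at SNR 100. Noiseless data are recovered exactly; errors
shrink to zero as SNR grows.

**Shared-eigenvector hypothesis.** $D_{ext} = \eta D_b$ is a modelling
assumption, not a derived fact; the intracellular tensor
$D_{int} = (D_b - \alpha D_{ext})/(1-\alpha)$ is exposed but unused
downstream.

**Resolution matching.** Inputs are assumed co-registered on one grid; no
resampling is performed (the 64→128 upsampling used in practice is left
to upstream tooling).

**Problem sizes in the test-suite.** The PDE criteria run at the full
128×128 slice. The fitting-heavy experiments run on phantom instances the
suite can afford: the end-to-end consistency fixture at 48×48 and the
b-value sub-sampling comparison at 64×64 (both SNR 100, seed 1, the full
15-direction protocol); per-voxel behaviour is size-independent, so these
choices only trade statistical sharpness of region medians.
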