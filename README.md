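# mbcti — low-frequency conductivity imaging from B1 phase and multi-b-value diffusion MRI

MR electrical properties tomography (MREPT) reconstructs tissue
conductivity at the Larmor frequency (~128 MHz at 3 T), where current
crosses cell membranes and the measurement mixes intra- and extracellular
space. The conductivity that matters for electrical-stimulation modelling
and ion physiology is the *low-frequency* one, where membranes insulate
and only the extracellular space conducts — but it cannot be measured
without injecting current. `mbcti` implements an electrodeless
decomposition for researchers working on conductivity imaging: it combines
phase-based MREPT with multi-b-value diffusion-weighted imaging (DWI) to
split the high-frequency conductivity into extracellular quantities.

The chain, in the field's standard notation:

1. **cr-MREPT inversion.** For u = 1/σ_H, solve the stabilized
   convection–reaction equation
   `-c ∇²u + ∇φ_tr·∇u + (∇²φ_tr) u = 2ωμ₀`
   (three-point central differences, sparse solve per slice; c = 0.025),
   where φ_tr is the B1 transceiver phase, optionally combined from odd
   echoes with magnitude-squared weights.
2. **Constrained compartment model.** Fit per voxel, by bounded
   multi-start least squares over b-value decays,
   `Ŝ_j/S₀ = (1−ν_iso)[ν_ic e^(−b_j ν_ic d_ic) + (1−ν_ic) e^(−b_j (1−ν_ic) d*_e)] + ν_iso e^(−b_j d_iso) + ν₀`
   with d_ic = 1.7e-3, d_iso = 3.0e-3 mm²/s fixed; derive the
   extracellular volume fraction α = (1−ν_iso)(1−ν_ic) + ν_iso and mean
   diffusivities d_w^e, d_w^i. A three-pool multi-exponential baseline is
   included for comparison.
3. **Decomposition.** With the literature concentration ratio β = 0.41:
   apparent extracellular ion concentration
   `c̄_e = σ_H / (α d_w^e + (1−α) β d_w^i)`, low-frequency mean
   conductivity `σ_L = α c̄_e d_w^e`, and — rescaling the b = 1000 s/mm²
   diffusion tensor D_b by η = 3 d_w^e / tr(D_b) — the conductivity
   tensor `C_L = α c̄_e η D_b`, whose mean diagonal equals σ_L.

Because no imaging data are distributed, the package ships a synthetic
phantom generator (three-region CSF/GM/WM slab at segmented-ROI
conductivity levels 1.19/0.55/0.41 S/m, Rician-noise DWI at the 15-b-value
protocol) that makes every stage verifiable end to end.

## Worked example

```r
library(mbcti)
set_log_level("warn")

spec <- default_phantom_spec(n = 64, snr = 100, seed = 7)
out  <- run_pipeline(spec, phantom_protocol(), seed = 7)

roi_statistics(out$sigma_h$sigma_h, out$truth$labels)   # reconstructed sigma_H
roi_statistics(out$sigma_l$sigma_l, out$truth$labels)   # low-frequency sigma_L
```

```
  label      mean        sd    n          label      mean         sd    n
1     1 1.1690245 0.0403500 1448      1     1 1.1532906 0.05373261 1448
2     2 0.6179005 0.1112052  828      2     2 0.5502100 0.12511327  828
3     3 0.4517029 0.0319671  332      3     3 0.2703245 0.10961675  332
```

Label 1 is the CSF ring, 2 the grey-matter annulus, 3 the white-matter
core. The inversion recovers the true conductivities (1.19, 0.55, 0.41
S/m) to a few percent in the region interiors. The decomposition behaves
as the physics demands: in CSF, σ_L ≈ σ_H (1.15 vs 1.17 S/m — free fluid
conducts at all frequencies), while in white matter σ_L (0.27 S/m) is
well below σ_H (0.45 S/m) because most of the voxel is intracellular and
stops conducting at low frequency.

Sensitivity of the concentration map to the assumed ratio β:

```r
bs <- beta_sensitivity(out$sigma_h, out$maps,
                       beta_grid = c(0.31, 0.36, 0.41, 0.46, 0.51, 0.56))
data.frame(beta = bs$beta_grid, Er = round(bs$er_values, 3))
```

```
  beta    Er
1 0.31 0.026
2 0.36 0.012
3 0.41 0.000
4 0.46 0.011
5 0.51 0.022
6 0.56 0.031
```

Er is exactly zero at the reference β = 0.41 and grows monotonically with
|β − 0.41|; a ±0.1 error in the assumed ratio perturbs c̄_e by only a few
percent on this phantom.

A command-line interface over the same functions is installed at
`inst/cli/mbcti.R` with subcommands `phantom`, `mrept`,
`fit-compartments`, `decompose`, `tensor`, `metrics`, `pipeline`, e.g.

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","mbcti.R",package="mbcti"))')" \
    phantom --n 128 --snr 100 --seed 1 --out-dir phantom/
```

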