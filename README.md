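# cryodecay

Quantifying dose-dependent information loss in electron cryomicroscopy at
liquid-helium versus liquid-nitrogen specimen temperatures.

Cryo-EM image quality is limited by radiation damage, and cooling below
liquid-nitrogen temperature reduces damage — but at helium temperatures the
specimen starts to move: the support foil relaxes under the beam and the
amorphous frozen water expands during the first few e⁻/Å² of irradiation.
`cryodecay` is an analysis toolkit for separating and measuring these
effects. It is aimed at microscopists and methods developers who have (or
want to simulate) particle tracks, diffraction profiles, EELS spectra,
per-frame FSC curves, or the small calibration measurements around them.

What it computes:

* **Motion metrics** from particle coordinate tracks: RMS pairwise-distance
  expansion, radial motion from the hole centre, tilt-projected foil
  displacement, in/out-of-plane decomposition, plus greedy
  nearest-neighbour track linking.
* **Peak fitting**: Voigt + linear-background fits (complex-error-function
  Voigt) of diffraction rings — reported as spacings in Å with q = 1/d —
  and of EELS zero-loss/plasmon peaks; camera-length calibration against
  the gold (111) ring at 2.35 Å; the plasmon-energy ↔ density model
  `E = E_ref √(ρ/ρ_ref)` and its exclusion statistic.
* **Per-frame B-factor pipeline**: half-set FSC → amplitude ratios
  τ_f/τ_1 = √[FSC_f(1−FSC_1)/(FSC_1(1−FSC_f))] → weighted ln-linear fits
  giving ΔB_f = −4·slope (amplitude ∝ exp(−B q²/4)) → linear decay rate in
  Å²/(e⁻/Å²); Rosenthal–Henderson regression; per-frame blurring budget.
* **Dose-independent blurring sources**: pseudo-Brownian motion σ₀² from
  frame-grouped power-spectrum peak intensities
  (W ∝ (2Md/α_u)·[α_u m d + e^(−α_u m d) − 1]/(α_u m d),
  α_u = 2π²σ₀²u²), and the source semiangle α from spot power versus
  defocus via the spatial-coherence envelope.
* **Instrument physics**: coincidence-loss correction l = DQE·e^(−Ds/F),
  blank-beam interpolation, intensity → ice-thickness inversion with
  foil-pixel thresholding, four-point-probe sheet resistance
  R_s = (π/ln2)(dV/dI)C₁C₂, and electron-flux calibration.
* **Synthetic data generators** for every one of these inputs, seeded and
  exactly invertible in noiseless mode, with named presets encoding the
  study's acquisition conditions.

## Worked example

```r
library(cryodecay)

## Did the frozen water collapse to the high-density phase? Fit nine
## synthetic EELS spectra and compare with the density-model prediction.
pe <- plasmon_energy(gen_preset("eels_LDA", seed = 1))
pe
#> Plasmon energy: 20.42 +/- 0.00 eV (SEM over 9 spectra)
pred <- plasmon_from_density(20.4, 0.93, 1.1)
round(pred, 1)
#> [1] 22.2
round(density_exclusion_z(list(E_p = pe$E_p, SE = 0.2), pred), 1)
#> [1] 8.8

## Per-frame B-factor decay from FSC curves, nitrogen vs helium presets.
bd81 <- per_frame_bfactor(amplitude_decay(gen_preset("fsc_81K", seed = 1)))
bd81
#> Per-frame B-factor decay: rate 5 +/- 8.3e-16 A^2/(e-/A^2), intercept -1.575 A^2
#>   30 frames, q range 0.02-0.3 A^-1, amplitude-scale ratios
bd13 <- per_frame_bfactor(amplitude_decay(gen_preset("fsc_13K", seed = 1)))
decay_rate_ratio(bd81, bd13)$ratio
#> [1] 1.5

## Expansion of the frozen water at 13 K, seen as interparticle spreading.
pds <- pairwise_distance_series(gen_preset("tracks_13K", seed = 1))
pds[which(pds$fluence >= 5)[1], ]
#>   fluence rms_change
#> 8    5.25   6.909982
```

Reading the numbers: the fitted plasmon energy (20.42 eV) sits 8.8 standard
errors below the 22.2 eV a collapse to high-density amorphous water would
produce, excluding the density change; the B-factor decay rate of
5 Å²/(e⁻/Å²) at 81 K is recovered exactly from the synthetic FSC series and
is 1.5× the helium-temperature rate; and the RMS interparticle distance in
the 13 K expansion preset grows by ~6.9 Å over the first 5 e⁻/Å²,
exceeding the 5 Å observable bound.

A multi-stage run driven by one JSON-serialisable config:

```r
rep <- run_pipeline(list(seed = 1, stages = list(
  fsc = list(preset = "fsc_81K"),
  eels = list(preset = "eels_LDA"))))
rep$stages$fsc$rate
#> [1] 5
```

The methods vignette (`vignettes/information-loss-budget.Rmd`) documents
the models, conventions, preset parameters and numerical choices.

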