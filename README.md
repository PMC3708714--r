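# smloop

Single-molecule analysis of transcription-factor-mediated DNA looping, and
a statistical-thermodynamic model of λ repressor (CI) autoregulation.

## The problem

In λ lysogens, CI dimers bound at the operators O~L~ and O~R~ (2.3 kb
apart) oligomerize into an octamer — optionally reinforced by a tetramer
across the O~L~3/O~R~3 subsites — that loops the intervening DNA and
rewires P~RM~ autoregulation. A two-color localization experiment can watch
this directly: label the two flanking loci with red/yellow
fluorescent-protein arrays, fit each diffraction-limited spot with a 2D
Gaussian, register the channels with a projective transform, and measure
the projected inter-locus vector **r** frame by frame. Looped DNA gives
short `r = |r|`; the looping frequency of a strain is the weight `f` that
best explains its `r` distribution as a mixture

    P(r) = f · P_looped(r) + (1 − f) · P_unlooped(r)

of the distributions measured for a permanently juxtaposed control and a
loop-deletion control. The package implements that entire pipeline —
including a synthetic-data generator that stands in for the unavailable raw
movies — plus the downstream science:

- worm-like-chain simulation of apparent distances (Daniels approximation,
  random projection, localization noise), and inversion to an apparent
  persistence length;
- vector autocorrelation, which bounds looping kinetics;
- smFISH transcript counting via quantized spot intensities, normalized to
  wild-type λ units (WLU);
- a Shea–Ackers partition-function model of P~RM~: 176 microstates / 122
  unique states for the wild type, steady-state autoregulation, and a
  4-parameter fit (octamer/tetramer looping free energies ΔG_oct, ΔG_tet
  and unlooped/looped activated rates) to seven measured observables.

Audience: quantitative biologists analysing two-color locus-tracking or
smFISH data, and modellers of the λ switch.

## Worked example

Estimate a looping frequency from synthetic measurements with known truth:

```r
library(smloop)
looped   <- gen_displacement_trajectories(1, n_mol = 1000, n_frames = 1, seed = 1)
unlooped <- gen_displacement_trajectories(0, n_mol = 1000, n_frames = 1, seed = 2)
target   <- gen_displacement_trajectories(0.79, n_mol = 1000, n_frames = 1, seed = 3)
fit <- bootstrap_loop_fraction(target$r, looped$r, unlooped$r,
                               n_boot = 1000, seed = 4)
cat(sprintf("f = %.2f +/- %.2f\n", fit$f_loop, fit$sem))
#> f = 0.79 +/- 0.05
```

The mixture recovers the generating frequency 0.79 within its bootstrap
error. The full image-level version (movies → localization → registration
→ pairing → mixture) is one call:

```r
res <- run_looping_pipeline(0.79, n_mol = 150, n_frames = 5,
                            config = movie_config(image_shape = c(160, 160),
                                                  n_frames = 5),
                            seed = 11)
res$fit$f_loop
#> [1] 0.8028884
```

Fit the thermodynamic model to the measured observables (looping
frequencies 79/53/60% and expression levels 1.38/1.00/2.50/2.51 WLU):

```r
fit <- fit_free_parameters(observable_set())
round(fit$par, 2)
#>   dG_oct   dG_tet R_unloop   R_loop
#>     0.25    -3.29     2.26     4.55
round(fit$activation_ratio, 2)
#> [1] 2.01
```

ΔG_oct ≈ 0.25 kcal/mol (octamer-only looping is roughly isoenergetic),
ΔG_tet ≈ −3.3 kcal/mol (the tetramer strongly stabilizes the loop), and
looping activates P~RM~ about 2-fold; rates are nM/min.

Run the full analyses:

```sh
Rscript analysis/01_simulate_controls.R
Rscript analysis/02_looping_frequency.R
Rscript analysis/03_kinetics_autocorrelation.R
Rscript analysis/04_polymer_simulation.R
Rscript analysis/05_smfish_expression.R
Rscript analysis/06_thermo_fit.R
```

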