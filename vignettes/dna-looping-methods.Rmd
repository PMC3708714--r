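---
title: "Methods: single-molecule DNA-looping analysis and the CI autoregulation model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-molecule DNA-looping analysis and the CI autoregulation model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The measurement and its model

The package analyses a two-color single-molecule experiment that tracks the
projected separation between two chromosomal loci flanking the 2.3-kb
segment between the bacteriophage λ operators O~L~ and O~R~ in live
*E. coli*. Each locus carries a short tandem array of operator sites bound
by a fluorescent fusion protein (red and yellow channels); both spots are
diffraction limited, so their centroids are found by fitting a symmetric 2D
Gaussian, the yellow channel is mapped into red-channel coordinates with a
projective transform estimated from fiducials, and the per-frame vector
between the paired spots — `r` below — is the 2D projection of the
locus-to-locus separation. When the λ repressor CI loops the DNA by
bridging O~L~ and O~R~ with an octamer (optionally stabilized by an
additional tetramer across the third subsites), `r` shrinks.

Because the raw movies of the original experiment are not available, a
first-class synthetic-data generator reproduces every input the pipeline
consumes, with known ground truth. All stages are therefore testable end to
end: images → localizations → registered displacement vectors → distance
distributions → looping frequencies → kinetics, plus the thermodynamic
model that ties looping to CI expression.

# Synthetic data: what it emulates and what it does not

`movie_config()` fixes the acquisition geometry: 81 nm/pixel (a 13-µm
camera pixel at 160×), 100-ms frames, an integrated-Gaussian PSF of sd
1.2 px rendered per pixel (not point-sampled, matching the fitting model),
Poisson photon noise on a flat background, and per-channel geometric
photobleaching. No photon budget is documented for the original acquisition; the default of
350 photons/spot/frame over a 20-photon background was calibrated once so
that the Gaussian-fit localization precision of synthetic spots lands near
16 nm, inside the 14–17 nm per-channel precisions reported for the real
fluorophores. Optional Gaussian read noise is off by default (camera
details unspecified).

`gen_displacement_trajectories()` draws each molecule looped with
probability `f_loop`. The looped geometry is a fixed 22-nm 3D separation
(the 66-bp spacing of the permanently juxtaposed control construct,
0.34 nm/bp); the unlooped geometry draws a worm-like-chain end-to-end
distance with a 782-nm contour and, by default, a 3-nm *apparent*
persistence length — the compact in vivo geometry implied by the measured
71-nm unlooped mean, not the 50-nm in vitro stiffness. Conformations are
projected onto the plane at a random orientation and held fixed
(`switch_rate = 0`), since the measured autocorrelation shows conformations
persisting beyond the 0.5-s observation window; per-frame measurement noise
(22 nm per coordinate per spot) is fresh every frame. A finite switching
rate is available for kinetics tests.

Not emulated: optical aberrations beyond a global projective map, stage
drift, cell autofluorescence structure, spot-selection curation by eye, and
chromosomal context effects. Passing tests therefore demonstrate that the
*analysis* recovers truth under the stated statistical structure, not that
the structure captures every systematic of real microscopy data.

# Localization, registration, pairing

Spots are detected as local maxima above a threshold with 3-px non-maximum
suppression, then fit by unweighted least squares with a symmetric 2D
Gaussian over a 7×7 patch (pixels within 3 px of the initial location),
with the width bounded above by 2 px. Coordinates are 0-based pixel
indices; nm = px × 81. Per-spot precision is estimated by residual
permutation: the fit residuals are scrambled uniformly over the patch in 10
seeded permutations, added back to the data, refit, and the rms distance of
the perturbed locations from the original fit is reported in nm. Tests
verify this calibrates within 30% of the spread of independent-noise
refits.

Registration uses a global projective (8-parameter) transform: a normalized
direct linear transform refined by geometric least squares when more than
four fiducial pairs are available, keeping whichever solution has the lower
RMS residual. Locally weighted maps are deliberately out of scope (a global
map sufficed at ~10-nm registration error in the original setup). Pairing is
per-frame nearest neighbour with a 200-nm gate; rejected and ambiguous
pairings are counted. Molecules are linked across frames by 3-px
nearest-neighbour gating on the red channel — the original tracking was
manual, so this rule is a stated package choice. The reported
`combined_error` adds the two localization errors and the registration
error in quadrature.

# Distance distributions and mixture estimation

Distance PDFs and CDFs are boxcar-kernel estimates on positive support,
evaluated on a 10-nm grid over 0–200 nm. Mass is preserved exactly by
reflecting the kernel at r = 0, and the reported PDF value in each bin is
the increment of the smoothed CDF divided by the bin width, which makes PDF
and CDF mutually consistent to machine precision and keeps the total mass
at one. The kernel width is chosen as the largest candidate whose smoothed
CDF stays within `max(0.01, 0.5/sqrt(n))` of the empirical CDF — the
strongest smoothing that introduces no systematic error. (The qualitative
rule in the original description — a width small enough to follow the empirical CDF — is
made quantitative here.)

Looping frequency is the least-squares weight `f` in
`target ≈ f·looped + (1−f)·unlooped`, computed in closed form before
clamping to [0, 1], on CDF bins by default (PDF basis available). One
kernel width is shared by target and both controls: smoothing is linear, so
the mixture identity survives only under identical smoothing. Errors come
from 1000 bootstrap iterations in which the target *and both controls* are
resampled — at the molecule level by default, respecting within-molecule
frame correlation; per-observation resampling is available. Monte-Carlo
calibration shows bias below 0.02 at 5000 draws and a bootstrap sem within
30% of the repeated-run spread.

Kinetics: `vector_autocorrelation()` averages the dot product of `r`
vectors separated by each lag (multiples of the 100-ms frame interval up to
0.5 s), pooled over molecules, with molecule-level bootstrap errors. For
frozen conformations the curve drops between lag 0 and lag 1 by exactly the
measurement-noise variance of the vector (4σ² for σ per coordinate per
spot) and is flat afterwards; this is both a unit test and the scientific
signature bounding the looping rate.

# Worm-like-chain simulation

3D end-to-end distances are sampled from the Gaussian radial density with
per-coordinate variance 2·L~p~·L/3 multiplied by the first-order Daniels
correction `1 − 5Lp/4L + 2r²/L² − 33r⁴/(80·Lp·L³)` (rejection sampling
against the Gaussian envelope; the correction's coefficients reproduce the
exact WLC second moment 2·L~p~·L − 2·L~p~², which the tests verify).
Samples beyond the contour length are rejected as unphysical, and a warning
flags L/L~p~ < 10 where the approximation degrades. An uncorrected
Gaussian-chain sampler is kept as an independent oracle. Projection
multiplies by sin θ with cos θ uniform; endpoints then receive independent
22-nm Gaussian errors per coordinate. With L = 782 nm, L~p~ = 50 nm and
22-nm noise the mean apparent distance is ≈200 nm — the expectation for
relaxed B-form DNA that the measured 71 nm falls far short of.

`infer_apparent_lp()` inverts the forward map by bisection in log-L~p~
using common random numbers (n = 2·10⁵ per evaluation), matching the
*mean* apparent distance. The 71-nm target yields ≈4 nm here; the original study
quotes 3 nm without stating whether mean, median or full distribution was
matched, so the inversion convention is flagged as a package choice rather
than forced to the quoted value.

# The thermodynamic model

States of the six operator subsites are enumerated with explicit
conventions (the defining supplementary table of the original study is not
machine-readable, so the conventions were resolved to reproduce its exact
counts): each triple may carry dimers on any subset of subsites with an
optional cooperative pairing of one adjacent pair; a looped state joins one
cooperative pair on O~L~ and one on O~R~ into an octamer (any of the four
pair combinations, configurable to O~L~12:O~R~12 only); third subsites may
be bound in looped states; when the octamer is at O~L~12:O~R~12 and both
3-subsites are bound, the loop-spanning tetramer forms obligately — it is
what holds those dimers in the loop, so no "both bound, no tetramer" looped
state exists; loop orientation (parallel/antiparallel) contributes
degeneracy 2 with orientation-independent energies. Microstates with equal
occupancy, cooperative-pair count, looping status and rate class merge into
unique states with integer degeneracy `d`. For the wild type this gives 176
microstates in 122 unique states; the minimal mode keeps the lysogenic
family (O~L~1·O~L~2 occupied; O~R~ empty or O~R~1·O~R~2 occupied).

State weights are `d·[CI₂]^i·exp(−ΔG/RT)` (log-domain), with RT =
0.593 kcal/mol (25 °C). Fixed intrinsic binding energies (−12.5, −10.5,
−9.7/−9.5 kcal/mol for subsites 1/2/3) and a single adjacent-pair
cooperativity (−3.0 kcal/mol) ship in an editable YAML config; they are the
standard λ-operator equilibrium values from the quantitative-footprinting
literature, since the exact fixed set used originally is not recoverable
from its text. Free CI dimers are a fixed fraction φ = 0.1 of total CI
([CI₂] = φ·c/2) — consistent with published estimates of nonspecific
chromosomal sequestration at lysogenic levels — and the sensitivity scan
varies both φ and the wild-type CI level. Transcription classes: repressed
(rate 0) whenever O~R~3 is occupied; activated (R_unloop or R_loop)
when O~R~1·O~R~2 is occupied with O~R~3 free; basal (0.2·R_unloop,
configurable — the originally used value is not recoverable and is reported
as inconsequential) otherwise. Rates are nM/min internally: the
per-minute figures quoted in the original methods are the only ones consistent
with its ln 2/120 min⁻¹ degradation rate and 220-nM steady state, so the
per-second figures in its main text are treated as a units slip (outputs
print both).

Steady states solve production = dilution by bracketed root finding;
expression in wild-type λ units is the steady-state concentration over the
fixed 220 nM (150 molecules × 1.47 nM). The four free parameters
(ΔG_oct, ΔG_tet, R_unloop, R_loop) are fit to the seven observables
(three looping frequencies, four WLU levels) by unweighted least squares:
a coarse deterministic grid, then Nelder–Mead. With the shipped fixed
parameters the fit lands at ΔG_oct ≈ 0.25 and ΔG_tet ≈ −3.3 kcal/mol with
a looped/unlooped activation ratio ≈ 2.0, and the sensitivity scan moves
ΔG_tet over roughly −2 to −4.4 kcal/mol while ΔG_oct stays near zero —
the same picture the original study reports (0.3, −3.2, ratio 2.4, scan band −2.8
to −4.6). Exact numerical agreement is not expected without the original
exact fixed-parameter set.

# smFISH counting

Spot intensities are quantized at multiples of the single-transcript
intensity because co-localized transcripts merge into one
diffraction-limited spot. The unit is the first mode of a kernel density of
spot intensities (bandwidth one tenth of the median; a flat distribution is
an error). Per cell, transcripts = round(total spot intensity / unit);
per-spot molecule counts are also reported, and the two routes agree on
synthetic data. Expression in WLU divides a strain's mean count by the
reference strain's, with cell-level bootstrap errors. Segmentation is
consumed as given labeled masks — the generator emits rectangular cells —
since no segmentation algorithm is described for the original analysis.

# Numerical choices and problem sizes

Key tolerances: probability normalization to 10⁻¹²; registration DLT
degeneracy at a 10⁻¹⁰ singular-value ratio; spot-fit convergence via
L-BFGS-B with analytic gradients (factr = 10); steady-state roots to
10⁻⁹ nM. Seeds are explicit arguments everywhere and generators restore
the caller's RNG state. The shipped analyses use 1000–5000 molecules for
distribution work, 10⁵ draws for WLC expectations, 150 molecules × 5
frames for the image-level pipeline (~430 gated pairs, comparable to the
source's per-strain samples), and 1000 bootstrap iterations — sizes chosen
so each analysis states its uncertainty honestly while a full run of the
test suite and analyses completes in minutes.

# Known limitations

Mixture estimation assumes the unlooped conformations of regulatory
strains match the unlooped control — if broken loops re-form before
relaxing, estimates are upper bounds (inherited from the method itself).
The enumeration conventions, fixed energies and φ are reconstructions
where the original machine-readable values are unavailable; all are
config-gated so better values drop in without code changes. The KS test
pools frames, ignoring within-molecule correlation (as the original analysis did);
the bootstrap does not. Asymptotic two-sample KS p-values are mildly
conservative at n ≈ 100. No hidden-Markov segmentation of trajectories is
attempted: the data cannot resolve individual looping transitions, which
is exactly why the autocorrelation bound is the kinetic statement.
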