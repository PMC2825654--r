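# darkscatter

Monte Carlo simulation of dark-field X-ray imaging by varying collimation.

Soft tissues with nearly identical attenuation coefficients are hard to
tell apart in conventional (bright-field) radiography. Their small-angle
— predominantly Rayleigh — scattering, however, can differ several-fold.
`darkscatter` simulates a detection scheme that extracts this *dark-field*
signal with standard hardware: acquire the same projection behind
anti-scatter grids of two collimation aspect ratios, a high ratio
`H/D = 50` whose image `IH` contains essentially only the primary beam,
and a reduced ratio 10 whose image `IL` additionally contains the
small-angle scatter. The difference `IL − IH` cancels the primary beam and
images the scatter; the same signal can be extracted by subtracting a
long-distance acquisition from a short-distance one with a single grid.
The intended users are researchers in computational medical-imaging
physics prototyping scatter-based contrast mechanisms.

## The models

**Photon transport.** Each material is described by an absorption
coefficient μₜ, a scattering coefficient μₛ (both 1/cm) and a Rayleigh
fraction β. A photon history alternates free flights — step sizes drawn
from ∑ᵢ(μₜᵢ + μₛᵢ)sᵢ = −ln ξ across material boundaries — with
interactions that absorb (probability μₜ/(μₜ+μₛ)) or scatter. Compton
deflections follow the Klein–Nishina cross-section

> p_c(θ) = (r_e²/2) · (1 + cos²θ + α²(1−cosθ)²/(1+α(1−cosθ))) / (1+α(1−cosθ))²,  α = E/mₑc²,

and Rayleigh deflections follow (r_e²/2)(1+cos²θ)F²(θ) with the analytic
form factor F = c₁ θˡ e^(−c₂θ), calibrated so the mean Rayleigh deflection
is 4.3° (l = 2, c₂ = 33.2666 rad⁻¹). Detector scoring applies the
collimator as an angular gate at arctan(1/aspect) plus an ideal septal
rule (the photon must traverse the grid height within one cell).

**Single-scattering model.** An analytic forward model integrates
I₀ · w_in · w_out · μₛ · P(accept) over the phantom volume, where the
acceptance probability of a detector cell at lateral offset r uses the
angular window θ₁ = arctan((r−D/2)/(R−H)), θ₂ = arctan((r+D/2)/R),
φ₂ = −φ₁ = arctan(D/2r), precomputed per scattering depth and material.
The Monte Carlo image exceeds this model by the multiple-scattering
contribution, which the package measures directly.

## Worked example

The reference experiment at desk scale: a 10 × 10 × 5 cm³ water slab with
four 1 cm³ cubes that differ from water only in their Rayleigh/Compton
split, imaged on a 60 × 60 detector (2 mm pitch) behind aspect-50 and
aspect-10 grids at 2.5 cm, 10⁷ photon histories:

```r
library(darkscatter)
physics  <- scatter_physics()          # 50 keV, form factor calibrated to 4.3 deg
phantom  <- build_table1_phantom()
detectors <- list(detector_config(collimator_spec(50), 2.5),
                  detector_config(collimator_spec(10), 2.5))
run <- simulate_transport(phantom, physics, detectors,
                          n_photons = 1e7, seed = 42)
print(run)
#> <scatter_run>  1e+07 photons (seed 42)
#>   absorbed 1.37978e+06 (13.80%)   escaped 8.62022e+06 (86.20%)   capped 0
#>   escaped by class: primary=3.49767e+06  rayleigh_only=256899  compton_involved=4.86566e+06
#>   detected (counts):
#>               primary rayleigh_only compton_involved
#> aspect50_d2.5 3497667           631            14069
#> aspect10_d2.5 3497667         69856            75202
```

13.8% of photons are absorbed (water's absorption share of the 0.21/cm
attenuation budget is 13.3%; the cubes and multiple flights shift it
slightly), and 35.0% of launched photons survive unscattered —
exp(−0.21·5) = 0.35. Both grids pass the identical primary counts (the
matched photon stream cancels primaries exactly in the subtraction), while
the aspect-10 grid accepts two orders of magnitude more Rayleigh-only
photons than the aspect-50 grid: that asymmetry is the dark-field signal.

```r
df <- darkfield_subtract(run_image(run, "aspect10_d2.5", "total"),
                         run_image(run, "aspect50_d2.5", "total"))
region_stats(df, phantom, detector_grid())
#>   region   beta n_pixels     mean      var
#> 1  water 0.0769     2108 5.15e-06 4.95e-13
#> 2  cube1 0.0192        9 4.76e-06 3.63e-13
#> 3  cube2 0.0385        9 5.02e-06 4.24e-13
#> 4  cube3 0.1429        9 5.94e-06 6.40e-13
#> 5  cube4 0.2857        9 6.88e-06 9.97e-13
```

The dark-field means (counts per launched photon per pixel) rank the five
regions exactly by their Rayleigh fractions β even though all five are
identical in transmission. Note the scale: each cube occupies only 1 cm of
the 5 cm water column, so the contrast between the closest pair
(cube1 vs cube2) is a few percent of the signal and sits near one standard
error at 10⁷ histories — at some seeds that single pair can swap. The
full-scale configuration (600 × 600 pixels, 2 × 10¹⁰ photons,
`make_fixture("table1_full")`) separates all pairs cleanly.

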