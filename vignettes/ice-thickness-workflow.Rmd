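---
title: "Measuring ice thickness and targeting holes: methods and design"
author: "icethick"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring ice thickness and targeting holes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icethick)
```

## The measurement model

Zero-loss energy filtering removes electrons that lost energy by
inelastic scattering.  Over a sample of thickness $D$ the surviving
(zero-loss) intensity decays exponentially, so with an unfiltered image
$I$ and a filtered image $I_{zl}$ of the same field,

$$D \;=\; \lambda_{inel}\,\ln\!\frac{I}{I_{zl}} \;-\; C .$$

Two things in this relation are *apparent*, not physical.  First,
$\lambda_{inel}$ is an effective scaling constant for a particular
instrument, voltage and magnification regime; it absorbs collection
angles, filter settings and sample composition, and must be calibrated,
not looked up from theory.  Second, an empty hole imaged over vacuum
does not read zero: the filtered channel loses slightly more intensity
inside holes than pure vacuum transmission predicts.  The constant $C$
is *defined* as the offset that brings empty holes back to zero; it is
fitted from vacuum measurements (`fit_correction_term()`) and is much
larger in the LM regime (tens of nm) than at M/SA magnification (a few
nm).

Without an energy filter, the aperture-limited scattering (ALS) variant
uses the loss of elastically scattered electrons at the objective
aperture against a vacuum reference $I_0$:

$$D \;=\; \lambda_{ALS}\,\ln\!\frac{I_0}{I},$$

with no correction term, because $I_0$ is itself measured inside an
empty hole and the offset cancels.  For the same reason the reference
must *not* be taken over a broken film or open area: empty holes are
consistently brighter than open vacuum, and a reference taken outside a
hole would bias every measurement.

Built-in constants (200 kV and 300 kV instruments):

| voltage | regime | method | scale (nm) | C (nm) |
|--------:|:------:|:------:|-----------:|-------:|
| 200 | M/SA | filter | 305 | 4 |
| 200 | LM | filter | 485 | 35 |
| 300 | M/SA | filter | 435 | 1 |
| 300 | LM | filter | 805 | 65 |
| 200 | LM | ALS | 600 | 0 |
| 300 | LM | ALS | 1750 | 0 |

These values appear stable across sessions on a given configuration but
should be refitted after any major change (new filter tuning, different
aperture, camera swap).  The registry therefore records a free-text
`source` with each profile and implements no drift model.

## Calibration fits

All λ estimators are least-squares fits, returned as classed
`lambda_fit` model objects (`coef()`, `summary()`, `predict()`,
`residuals()`).

* `fit_lambda_filter()` regresses reference thicknesses (for example
  from tomogram cross-sections) on measured log-attenuations.  The
  default is a **two-step** fit: $C$ is fixed first — from the vacuum
  holes, since $C$ is operationally defined as the vacuum zero offset —
  and λ is then a one-parameter through-origin regression of $D + C$ on
  $\ln(I/I_{zl})$.  Because $C = \lambda\,\overline{\ln r}_{vac}$
  itself contains λ, the implementation substitutes the vacuum mean
  log-attenuation and fits
  $D = \lambda(\ln r - \overline{\ln r}_{vac})$, which is exactly the
  two-step model without iteration.  A joint two-parameter OLS fit is
  available behind `joint = TRUE`.
* `transfer_lambda_cross_regime()` calibrates a second magnification
  regime from thicknesses already measured on the same holes in a
  calibrated regime (the standard way to obtain the LM constants).
* `fit_lambda_als()` is the through-origin regression
  $\lambda_{ALS} = \sum D\,\ln r / \sum (\ln r)^2$ of filter-method
  thicknesses on ALS log-attenuations.

A single calibration point determines λ when $C$ is held fixed, so the
fitters accept one usable sample (standard error `NA`); they refuse
inputs where all log-attenuations are zero.  Uncertainties are ordinary
least-squares standard errors; no bootstrap.  A negative fitted $C$ is
floored at zero with a data-quality warning — it indicates a problem in
the vacuum measurements, not a physically meaningful offset.

## From images to a map

1. **Binning** (`bin_image()`) is block *mean* pooling, not summing, so
   intensity ratios — and therefore thickness — are invariant under
   binning; fourfold binning is the usual survey setting.
2. **Registration** (`estimate_shift()`, `align_pair()`): applying an
   energy shift for the slit at low magnification displaces the
   filtered image.  The translation is estimated by phase correlation
   with separable parabolic sub-pixel refinement and undone by bilinear
   resampling with periodic boundary; the wrapped border band is marked
   invalid downstream.  Only rigid translation is modelled — the energy
   shift introduces no rotation or scale change.  Bilinear
   interpolation was chosen over spectral resampling to avoid ringing
   on Poisson data; integer shifts are undone exactly either way.
3. **Mapping** (`thickness_map()`): the ratio image $I/I_{zl}$ is
   median-filtered (default 3 × 3, reflected edge padding) *before*
   taking the log.  Whether smoothing precedes or follows ratio
   formation is a genuine choice; filtering the ratio directly targets
   the quantity being displayed and is exposed as a switch
   (`apply_median`, `median_kernel`).  Pixels with non-positive counts
   in either channel are invalid; invalidity is carried as `NaN` with a
   parallel logical mask, and every reduction in the package is
   invalid-aware.  Thickness values are stored raw — slightly negative
   values over vacuum are information about noise, and clamping is
   applied only for display and selection.
4. **Point measurements** (`local_thickness()`) average the *ratio*
   over a box and then take the log (mean-of-ratio), which mirrors
   interactive cursor measurements.  Per-hole measurements
   (`measure_holes()`) instead take the *ratio of the mean
   intensities* over a disk, which mirrors acquisition-time scripts.
   The two conventions agree to first order and both are kept, each
   where its workflow uses it.

Heatmaps follow two display conventions: survey style (too thin red,
in-window green, too thick uncoloured over the grayscale base) and
targeting style (magenta / green / blue), at fixed overlay alpha 0.5.
Classification uses clamped thickness, so a noisy −1 nm pixel renders
as "too thin", not as a fourth class.

## Hole detection and targeting

Holey support films are periodic, and the detector leans on that: the
lattice basis is read from the two shortest non-collinear peaks of the
image autocorrelation (sub-pixel refined, threshold 0.1 of the central
peak to reject noise maxima), the hole radius from the bright-area
fraction per unit cell ($\pi r^2 = f\,|v_1 \times v_2|$), and candidate
centres from the normalized cross-correlation with a disk template,
snapped to lattice nodes and accepted above an NCC of 0.3.  Holes
closer than one hole radius plus 2 px to the border are flagged `edge`
and excluded by default.

Selection is an inclusive window test on clamped thickness — the
stated optimal range 20–40 nm is treated as a closed interval, so a
hole at exactly 20 nm is selected.  That window suits small membrane
proteins; a practical starting point for other projects is the
expected particle size plus 5–20 nm, refined from on-the-fly CTF
feedback (`correlate_quality()` joins such a table and reports the
binned means and Spearman rank correlation).

Grouping for beam-image shift tiles the *lattice index plane* into
`rows × cols` blocks anchored at the minimal selected index — greedy
block tiling, chosen because it is deterministic, order-independent and
trivially partitions the selected set.  Groups contain only selected
holes and may be partial; each group's anchor is the member nearest the
group centroid.  Navigator export writes one item per hole (thickness
in the Note at 0.1 nm, `Acquire` flag, a Color index 0/1/2 for
within/below/above and 3 for unmeasured, stage coordinates through an
affine pixel-to-micrometre transform that defaults to pure pixel-size
scaling).

Pixel coordinates throughout the package are 1-based `(row, col)` with
row 1 at the top — the native R matrix convention; adopting a 0-based
convention inside an R package would guarantee off-by-one errors at
every boundary with user code.  Stage coordinates in exported files are
unaffected.

## The count-rate guard

Electron-counting cameras undercount at high per-pixel rates
(coincidence loss).  `check_count_rate()` compares the mean rate with
the camera ceiling — 10 counts/px/s for a K2 — and *warns* rather than
aborts, with an inclusive comparison: reference acquisitions run at
10.7 counts/px/s on the native pixel, i.e. essentially at the ceiling,
so a blocking guard would reject the very conditions the method was
established under.  The K3 counts close to one count per electron at
roughly four times the K2 frame rate; its defaults
(`counts_per_electron = 1`, ceiling 40) are calibration knobs, not
constants.

## The synthetic generator

`synthetic_scene()` forward-simulates exactly the phenomena the
measurement relies on:

* a square hole lattice (optionally rotated) in a darker support film,
  with Quantifoil R1.2/1.3-like defaults — 2.5 µm pitch, 0.6 µm hole
  radius, 144.6 Å native pixels;
* a thickness field $D(\mathrm{px})$ (uniform, gradient, or smoothed
  Gaussian blobs);
* zero-loss attenuation $\exp(-(D + C)/\lambda)$ in the filtered
  channel, with the empty-hole offset modelled phenomenologically as
  the constant extra attenuation $C$ inside holes — precisely the
  effect the correction term removes, with no claim about its physical
  origin;
* empty-hole intensity above open vacuum by a factor 1.02 (the effect
  is documented qualitatively but not quantified; the default is a
  small, plausible value and nothing in the package asserts its
  magnitude);
* film transmission 0.40 — survey-magnification carbon film is
  markedly darker than open holes;
* an optional lateral shift of the filtered image, then independent
  per-pixel Poisson noise at 10.7 counts/px/s and 1 s exposure.

All randomness flows from the single scene seed, so identical seeds
give bit-identical images.  What the generator does *not* emulate —
carbon texture, grid bars, contamination, particles, CTF, beam-induced
motion, tilted or wedge-shaped ice in 3-D — bounds what passing tests
show: they validate the measurement and targeting logic under the
stated noise model, not robustness to every pathology of real grids.
Contamination in particular (a known cause of a few percent of targeting
losses in practice) has no detector here.

## Counting-noise budget and the measurement radius

For a disk containing total counts $N_I$ and $N_{zl}$ in the two
channels, the thickness standard error is

$$\sigma_D \;=\; \lambda\,\sqrt{\tfrac{1}{N_I} + \tfrac{1}{N_{zl}}}.$$

At the survey statistics above (10.7 counts/px/s, 1 s, 0.6 µm holes at
144.6 Å pixels) the *entire* hole interior carries about
$5.9\times10^4$ counts per channel, putting the single-hole noise floor
near 1.8 nm.  A disk of half the hole radius — the conservative default
`radius_fraction = 0.5`, robust to centring error and rim contamination
— reaches only a quarter of those counts (σ ≈ 3.7 nm).  The
measurement radius must therefore be chosen per configuration, as
acquisition practice demands: for per-hole precision at survey
statistics the package's own tests detect on the fourfold-binned image
and then integrate the full hole (`radius_fraction = 1`) at native
sampling, where the disk boundary is sharpest.  With sub-pixel centre
errors the film contamination this admits is a few boundary pixels and
biases the result by well under 0.5 nm.

## Problem sizes and tolerances used by the tests

Whole-workflow tests run on compact scenes (256² px, 24 px pitch, 6 px
hole radius, ~80 interior holes) so the suite completes in seconds;
counting-statistics tests use the full-scale scene (2048² native px,
121 holes, two seeds pooled) where the numbers above apply.  Noiseless
round trips are asserted to 10⁻⁶ nm (the limit of the float path
through the map), fit recoveries to machine-level tolerances on
noiseless data and 2–3 % on seeded noisy data, detection to ≤ 1 px
centres, and Navigator round trips to the 0.1 nm precision of the Note
field.  Degenerate inputs are contracts, not crashes: constant images
give zero shift with zero confidence, blank images give empty hole
lists, dead pixels give flagged holes, and empty selections give empty
group lists.

## Known limitations

* λ values are apparent constants of a configuration; transferring them
  across instruments is plausible but not guaranteed, and no long-term
  drift model is provided.
* The per-pixel map and the per-hole measurement use different
  averaging conventions (log-of-mean vs mean-of-log at the hole scale);
  they differ at second order in the intensity spread.
* Registration is translation-only; rotation or magnification change
  between the two channels is out of scope.
* The ALS path provides maps and point measurements; hole targeting
  runs on filter-method pairs.
* Thickness is a 2-D projection average; wedge-shaped or layered ice is
  not resolved.
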