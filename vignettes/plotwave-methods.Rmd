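---
title: "Quantifying crop-row movement from hemispherical field video"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying crop-row movement from hemispherical field video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plotwave)
```

## The problem

Lodging - the permanent failure of cereal stems under wind - is a major
yield-loss factor in oat, barley, and wheat. Before a stem fails it moves,
and the rate (natural frequency, $\omega_n$) and amount (amplitude) of that
movement are heritable-looking phenotypes a breeder could select on. No
mechanical method scales to a replicated field trial: accelerometers on
hundreds of rows are impractical, and manual free-vibration tests are slow
and subjective. plotwave implements a video-based alternative: a stationary
hemispherical (360-degree field of view) camera films many single-row plots
at once, a painted fiducial panel anchors the geometry and the color scale,
and each plot's movement is read out as a time-varying color signal.

The pipeline has two coupled halves:

1. **Plot demarcation** - map a researcher-defined 2D field design (plot
   names plus canopy-corner coordinates) onto pixel polygons in the
   hemispherical frame, using the panel's red square to estimate how the
   camera axes are rotated relative to the field axes.
2. **Movement quantification** - average the red channel inside each plot
   polygon in every frame, normalize by the panel's red square, bandpass
   filter, detect peaks, convert peak spacing into per-cycle frequencies and
   inter-peak areas into amplitudes, and analyze the per-plot summaries in a
   randomized-complete-block (RCB) ANOVA with expected-mean-squares (EMS)
   F tests.

## Plot demarcation

### Panel detection

The panel carries a red square in its northwest corner. Pixels within the
RGB box R 251-255, G 0-159, B 0-255 are masked, the mask is cleaned by a
morphological closing and opening with a small square structuring element
(default 4 px), and connected components below `min_square_area_px`
(default 5000 px; the true square covers roughly 6000 px near frame center
at 2880 px resolution) are discarded. Exactly one component must survive;
zero components is "panel not found" and several is "ambiguous panel". All
thresholds live in `camera_config()` because saturated light can require
retuning.

The *reference corner* is the leftmost masked pixel (minimum column, then
minimum row). The 40 px probe segments directly above and below that corner
classify the rotation direction: a mean red value above 245 means white
panel surface, lower means ground. White below / ground above marks a
northeastward rotation. The convention for the remaining combinations
(ground below / white above = SW, both white = NW, both ground = SE) is a
reconstruction - only the NE case is fixed by the original protocol - and
is validated purely against the synthetic renderer, which places its white
blocks by the same rule. This is a known circularity for the direction
labels (not for the angle), and it is the reason the direction convention
is exercised by a full synthetic sweep rather than asserted from first
principles.

### The offset angle

The offset angle $\Theta_{off}$ between camera and field axes comes from a
row/column triangulation of the square edge adjacent to the reference
corner: with $\overline{AB}$ the edge's row extent and $\overline{BC}$ its
column extent,

$$\Theta_{off} = -90 - \tan^{-1}(\overline{AB}/\overline{BC})$$

for northeastward rotations and
$\Theta_{off} = \tan^{-1}(\overline{AB}/\overline{BC})$ for the other
three directions. Which adjacent edge is "the" edge is not fully specified
by the protocol; plotwave reads the corner coordinates off the minimum-area
rotated rectangle fitted to the mask's convex hull (rotating calipers).
For an ideal square this is identical to taking the mask's extreme pixels,
but it is subpixel-stable on rasterized masks, where the raw extreme pixels
can sit half an edge-plateau away from the true corner and cost 2-3 degrees
near axis-aligned rotations. On rendered scenes the recovered angle is
within 0.1 degree of truth across 5-85 degree rotations in all four
directions (the acceptance suite enforces 1 degree).

### Projection onto the hemisphere

Field coordinates (origin at the panel center, x along the camera track)
are rotated clockwise by an effective angle: $\Theta_{off}$ for NE/NW,
$\Theta_{off} + 180$ for SW, $\Theta_{off} + 90$ for SE, with all
coordinates negated first for SW/SE. The rotation matrix acts on stacked
(y; x) vectors, matching the field convention in which y is the
perpendicular distance from the track.

Each canopy corner then becomes spherical coordinates. With $z$ the
vertical distance from the lens to the canopy point,

$$\varphi = \sin^{-1}\!\frac{z}{\sqrt{x'^2 + y'^2 + z^2}}, \qquad
\Theta = \mathrm{atan2}(y', x'),$$

latitude $\varphi \in [0, 90]$ and longitude $\Theta \in (-180, 180]$. Two
conventions deserve note. First, the radicand is the full Euclidean norm:
the printed source formula omits the squares, but dimensional analysis and
the accompanying geometry figure force them. Second, the z column of the
coordinate files holds *plant heights*; `camera_config(z_mode = "drop")`
(the default) converts them to the lens-to-canopy drop
`camera_height - plant_height`, which is what the latitude formula needs.
`z_mode = "literal"` passes the column through for designs whose files
already store drops. Plant heights and `camera_height` must share units;
the units themselves are arbitrary.

The camera's lens mapping is a fixed empirical quadratic from latitude to
the radial fraction of the image:

$$D = \varphi^2 \times 10^{-7} - \varphi \times 5 \times 10^{-3} + 0.3609,$$

strictly decreasing on 0-90 degrees (its derivative is negative
throughout), so points nearer the horizon land further from image center.
The printed coefficient "$5^{-3}$" is read as $5 \times 10^{-3}$: the
literal reading $5^{-3} = 0.008$ contradicts both the stated fit and the
monotone geometry. The fraction is split into signed row and column
fractions by a law-of-sines step, $R = D \sin\Theta / \sin 90$ and
$C = \sqrt{D^2 - R^2}$, then signed from the longitude quadrant (longitude
in (0, 180] puts the point above image center, i.e. negative row
fraction; longitude in [-90, 90) puts it right of center). Boundary
longitudes carry a zero component, so the half-open choice is
consequence-free. Finally pixels are
`fraction * image_size + image_size / 2`, kept as continuous 0-based
coordinates until cropping. The protocol is internally inconsistent about
whether fractions scale by the radius (1440 px) or the full image size
(2880 px); plotwave multiplies by the full size because the quadratic's
constants were fitted inside that convention, and because only that choice
reproduces the stated center offset of 1440.

One geometric consequence worth knowing: since $|D| \le 0.3609$, projected
corners always land inside the frame - the out-of-frame warning in
`project_field()` can only trigger on non-standard lens models.

### Rasterization

Plot polygons are rasterized by the even-odd crossing rule over pixel
centers, with corners taken in perimeter order (SW, SE, NE, NW - the file
order SW, SE, NW, NE describes corners, not a perimeter, and would trace a
bowtie). The crossing test is half-open, so a pixel center exactly on a
shared edge belongs to exactly one of the two adjacent polygons; the
rasterization is deterministic and agrees with an independent convex-hull
oracle in the test suite.

## Movement quantification

### Waveforms

For every frame, the mean red value inside each plot polygon is divided by
the mean red value of the panel's red square in that frame. The mask
geometry is frozen from the analysis still (the camera does not move within
a video) but the red value is re-sampled per frame, so any global
illumination gain - passing clouds - cancels exactly in the ratio. This is
tested as an invariance: multiplying all frames by an arbitrary positive
gain sequence leaves the waveform table unchanged to 1e-9.

Red is the channel of interest because chlorophyll absorbs red: the soil
between rows reflects it. A swaying row alternately covers and uncovers
bright ground inside the fixed 929 cm^2 analysis sub-region (supplied in
the coordinates files as ordinary polygons), so the mean red value
oscillates at the sway frequency.

### Filtering

Raw waveforms mix the sway signal (roughly 1-2 Hz, low amplitude) with
slow, high-amplitude lighting drift (< 0.5 Hz) and camera-vibration noise
(> 5 Hz). The bandpass template is expressed as percentages of the
analyzable band (0 to half the frame rate; 0-12 Hz at 24 fps): stop up to
3%, pass 4-40%, stop from 50% - i.e. 0.36 / 0.48 / 4.8 / 6.0 Hz - with
100 dB stopband attenuation and 5 dB passband ripple.

The realization is a linear-phase Kaiser-windowed sinc FIR whose length is
grown from the analytic estimate until the measured response (dense
frequency grid at design time) meets the template; at the default spec
this lands near 1700 taps, and the achieved response (about 110 dB
stopband, < 0.001 dB passband ripple) is stored on the filter object. A
minimum-order equiripple exchange design was considered and rejected: at
this transition width (1% of the sampling rate) and depth the exchange
algorithm available to the package is numerically unstable above a few
hundred taps, while the windowed design is unconditionally stable and the
method's requirements are stated entirely in terms of the magnitude
response, which `design_bandpass()` verifies explicitly.

Filtering is a single causal forward pass over the mean-centered signal.
Mean-centering changes nothing in the passband (the filter rejects DC
regardless) but suppresses the start-up step transient of a zero-initial-state
convolution. The group delay shifts every feature equally, so peak spacing
and inter-peak areas - the only quantities consumed downstream - are
unaffected, and no delay compensation is applied. Signals shorter than the
filter are refused with the minimum usable length; short recordings can use
a relaxed template (wider transitions, less attenuation) at the cost of
drift leakage near 0.5 Hz.

### Cycles and summaries

Peaks are local maxima of the filtered signal with topographic prominence
of at least 0.005 normalized red units (a 0.5% red change); plateau maxima
count once, at their leftmost sample. Each consecutive peak pair is one
cycle: frequency is the frame rate divided by the spacing in frames (the
only reading of the protocol that yields Hz and matches its reported 1-2 Hz
values - the literal text describes a period), and amplitude is the summed
absolute filtered value between the peaks (rectangle rule, left peak
exclusive, right peak inclusive; the protocol does not say whether peak
samples are included, so the convention is fixed here and tested). The
first peak anchors the first cycle but contributes no row.

Cycles outside the 0.5-4.9 Hz pass range are discarded; retained
frequencies give the plot's mean ($\omega_n$), median, and standard
deviation (zero, by convention, for a single cycle), and retained areas are
accumulated into 21 half-open 0.2 Hz bins covering 0.5-4.7 Hz. Bin areas
are reported in percent normalized-red units (raw areas stay on the cycle
table). The pass range (to 4.9 Hz) and the filter passband (to 4.8 Hz) are
inconsistent in the source protocol; both are implemented exactly as stated
in their respective stages rather than harmonized.

## The RCB analysis

Each response (mean frequency, or one amplitude bin - the 1.1-1.3 Hz bin is
the headline) is modeled per video date as

$$y = \mu + \text{Cultivar} + \text{PlantingDate} + \text{Pos(PlantingDate)}
    + \text{Cultivar:PlantingDate} + \text{Cultivar:Pos(PlantingDate)} + \varepsilon$$

with sequential (model-order) sums of squares. Position (inner vs outer
replicate band) is nested within planting date - the source's prose once
says "nested within cultivar", but its EMS table and all of its reported
results use planting date, so that is what is implemented. F ratios follow
the expected mean squares: Cultivar and Cultivar:PlantingDate are tested
against Cultivar:Pos(PlantingDate) (the printed denominator symbol for the
interaction row is read as a typo for that term - it is the only choice
that isolates the tested component), PlantingDate against
Pos(PlantingDate), and the two position terms against the residual. On
balanced data the table matches a brute-force group-mean decomposition to
1e-8 relative, and the null rejection rate of the Cultivar test is 0.05
within Monte Carlo error.

LSD mean separations use the same denominator mean square as the factor's
F test, adjust pairwise p values (FDR by default for movement responses,
Bonferroni for the demarcation-agreement protocol), and assign compact
letters by sweeping maximal runs of mutually non-significant levels in
descending-mean order (ties broken by level name, for determinism).

`demarcation_agreement()` implements the accuracy protocol: Pearson
correlation between manually and automatically demarcated waveforms per
plot, then a position-only linear model and a Bonferroni LSD on inner vs
outer means.

Video dates are analyzed separately, as the protocol prescribes; no
repeated-measures model is fitted across dates (that extension is left to
the analyst, and matters when absolute amplitudes are compared across
lighting conditions).

## The synthetic generator

Every input the pipeline consumes can be generated with known truth:

- `synth_field_design()` mimics the reference trial layout: single rows
  3.04 m long at 30 cm spacing, analyzed as 929 cm^2 canopy-height
  sub-regions, an inner band 2.28 m and an outer band 6.86 m from the
  track, 0.9 m canopy under a 2.7 m camera.
- `render_panel_frame()` draws seeded ground texture, the white blocks
  implied by the direction convention, the red square rotated so the
  triangulation recovers the scene's angle, and plot stripes placed by the
  package's own forward projection. That last choice is a deliberate,
  documented circularity: polygon-overlay checks are consistency tests of
  the chain, while angle and direction recovery are genuine measurements
  of the detection code against geometry it does not share.
- `render_synthetic_video()` modulates each plot's red channel by
  `1 + A sin(2 pi f t) + drift + noise` and the whole frame by a slow
  illumination gain tracked by the red square. Frames are 8-bit; the
  seeded per-pixel ground texture dithers the quantization so region means
  preserve amplitudes well below one count.
- `simulate_waveform()` produces the same structure directly as a series
  (defaults: 0.01 sway amplitude on a 0.6 baseline, 0.05-amplitude drift
  below 0.5 Hz, 0.002 white noise, 120 s at 24 fps - the scales visible in
  real panel-normalized waveforms).
- `simulate_movement_dataset()` draws RCB responses around a 1.37 Hz grand
  mean, the average natural frequency this method is built around.

What the generator does *not* emulate: real canopy texture and parallax,
wind intermittency (sway is a stationary sinusoid), panel wear, saturation,
or rolling-shutter artifacts. Passing the synthetic suites therefore
demonstrates that the geometry, signal path, and statistics are correct and
self-consistent - not that the color thresholds or the lens quadratic fit
any particular camera; those are empirical constants taken as given.

## Problem sizes and numerical choices in the test suite

Tests render detection scenes at 720 px with a 150 px fiducial square (the
square-to-frame ratio is larger than in the field so that corner
quantization stays an order of magnitude below the 1-degree acceptance
tolerance), and video scenes at 360 px over 240 frames (10 s), the scale at
which a full extract-filter-summarize round trip runs in seconds. Waveform
recovery uses 120 s series at 24 fps with the full 100 dB filter; the
240-frame videos use the relaxed short-signal template. The ANOVA null
calibration runs 1000 seeded simulations of a 2x2x2x2 design; power and
recovery checks use 16 cultivars x 4 planting dates x 2 positions x 2 reps,
the reference trial's replication. All randomness is seeded; generators are
bit-reproducible given (parameters, seed).

## Known limitations

- The direction truth table beyond the NE case is a reconstruction
  (validated synthetically, see above).
- The lens model is one fixed quadratic; no calibration fitting is
  provided, and cameras with different optics need their own constants.
- MP4 containers are not decoded; frames are consumed as PNG directories
  or in-memory arrays, with container decoding left to standard external
  tools.
- Absolute amplitudes depend on lighting at recording time; only contrasts
  within a video date are interpretable, which is why dates are analyzed
  separately.
- Unbalanced designs fall back to sequential SS semantics; missing plots
  (no in-band cycles) are flagged and dropped with a warning rather than
  imputed.
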