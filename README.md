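# cellmag

Motion magnification analysis of time-lapse microscopy videos of
biological cells.

Many non-muscle cells perform small periodic motions — membrane
protrusion/retraction cycles, rhythmic traction on micropillars,
substrate-dependent shape fluctuations — whose amplitude is below a
pixel at practical magnifications and therefore invisible in the raw
footage. `cellmag` is for cell biologists and bioimage analysts who
want to (1) find out *whether* and *at what frequency* a cell in a
clip oscillates, (2) *see* that motion by amplifying it, and (3) map
*where* it happens and *along which direction*, with a validation
procedure that separates real amplified motion from amplified pixel
noise.

## The method

Given a video $I[x, y, t]$ with frame rate $f_s$:

1. **Edge pixels.** Analysis is restricted to pixels where the spatial
   gradient of the temporal-mean image exceeds a threshold in every
   channel: $|\nabla \frac1N \sum_t I_i[x,y,t]| > G_{TH}$ (cells move
   mostly at their edges).
2. **Spectrum.** Each edge-pixel series is mean-removed; its biased
   sample autocorrelation $\hat R_j[\tau] = \frac1N \sum_t \tilde
   x_j[t] \tilde x_j[t+\tau]$, truncated at lag $L$, is cosine
   transformed and averaged over the $M$ edge pixels (Blackman–Tukey
   estimation; averaging shrinks the variance as $M$ grows). The
   dominant motion frequency is the spectrum's global maximum excluding
   the DC bin.
3. **Magnification.** Phase-based Eulerian video magnification: frames
   are decomposed into a complex steerable pyramid, the local phase of
   every band is band-pass filtered around the chosen frequency,
   multiplied by $\alpha$, and added back; sub-pixel displacements grow
   by about $1 + \alpha$ while amplitude noise is not amplified.
4. **Motion directors.** On a grid of one-pixel-wide segments of pitch
   $l$, a segment moves when $\sum_t \sum_{(x,y)} |I[t] - I[t+1]| >
   M_{TH}$; four probe lines (0°, 45°, 90°, 135° from the image Y
   axis) through its center get a gray-level center-of-mass signal
   $P_\theta^{CM}(t) = \sum_h h I / \sum_h I$, and the direction with
   the largest rms $\bigl[P_\theta^{CM}(t) -
   \overline{P_\theta^{CM}}\bigr]$ wins.
5. **Phase.** On a kymograph of the chosen probe line, each frame is
   colored by the sign of the temporal derivative of $P^{CM}(t)$,
   taken from a locally fitted quintic polynomial — expansion versus
   contraction half-cycles.
6. **Validation.** The "degree of motion" (total Lucas–Kanade optic
   flow magnitude over all pixels and frame pairs) is swept over
   amplification factors for the sample and for a static control; the
   sample's motion counts as real only where it exceeds the control's
   noise floor.

A synthetic fixture generator (pulsating ring, sub-pixel oscillating
texture with exact Fourier-shift displacement, static noise control,
constant drift) ships with ground truth so the whole pipeline is
testable without microscope data.

## Worked example

Detect a sub-pixel oscillation and magnify it:

```r
library(cellmag)

## 10 s clip at 24 fps: a texture oscillating by 0.36 px at 1 Hz,
## with additive intensity noise (sd 0.01)
fx <- makeOscillatingTexture(fixtureSpec("oscillating_texture",
                                         size = c(64, 64), frames = 240,
                                         frameRate = 24, motionFreq = 1,
                                         amplitudePx = 0.36,
                                         noiseSigma = 0.01, seed = 1))
em <- detectEdges(fx$video, gth = 0.05, method = "sobel")
em
#> EdgeMask: 1532 edge pixels of 64 x 64 (sobel, gth = 0.05)

sp <- estimateSpectrum(fx$video, em)
sp
#> PowerSpectrum: 121 bins to 12 Hz (L = 240, M = 1532 pixels)
#>   dominant frequency 1 Hz (period 1 s), 8294.9% above mean non-DC power
```

The 0.36 px drive — invisible frame to frame — produces a dominant
spectral peak exactly at the 1 Hz drive frequency, standing some 80x
above the mean non-DC power level.

Magnify a pulsating ring at its dominant frequency and read off the
motion direction and phase at its rightmost edge:

```r
ring <- makeRing(fixtureSpec("ring", size = c(63, 63), frames = 96,
                             frameRate = 24, motionFreq = 1,
                             amplitudePx = 0.3, noiseSigma = 0.01,
                             seed = 2, radius = 16))
mag <- magnify(ring$video, magnificationParams(alpha = 10,
                                               centerFreq = 1,
                                               halfBand = 0.3))
## probe the ring's rightmost edge (ring center (31, 31), radius 16)
assignDirection(ring$video, list(center = c(47L, 31L)), l = 9)@scores
#>   rms0  rms45  rms90 rms135
#> 0.0099 0.1863 0.1824 0.1931
assignDirection(mag, list(center = c(47L, 31L)), l = 9)@scores
#>   rms0  rms45  rms90 rms135
#> 0.1648 1.6845 1.6750 1.7028

ky <- phaseAnnotate(mag, center = c(47L, 31L), thetaDeg = 90, l = 9,
                    nFit = 5)
ky
#> PhasedKymograph: 9 x 96 along 90 deg at (47, 31); 49 expansion / 47 contraction frames
plotKymograph(ky)
```

The radial (90°) probe's center-of-mass wave is ~9x larger after
10x amplification, the tangential (0°) probe shows essentially
nothing, and the phase labels split the 96 frames into alternating
expansion and contraction half-cycles of the 1 Hz breathing.

`runPipeline("run.yaml")` chains the stages (synthesize or read →
preprocess → edges → spectrum → magnify → directors → phase →
validate) from a YAML config and writes every artifact plus a manifest
with md5 checksums; `inst/scripts/cellmag.R` exposes each stage as a
shell subcommand.

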