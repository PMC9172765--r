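# moco — motion tracking and motion-artifact compensation for cardiac optical mapping

Voltage- and calcium-sensitive optical mapping films electrical activity
in cardiac tissue as high-speed fluorescence video.  On contracting
tissue, every pixel's optical trace mixes the physiological fluorescence
signal (a few percent ΔF/F) with much larger fluctuations caused by the
tissue moving through the pixel — *motion artifacts* that historically
forced experimenters to paralyze the heart pharmacologically.  `moco`
inhibits them numerically: it estimates a dense displacement field
**u**(x, y, t) of every frame relative to a reference frame and warps the
raw frames into the tissue's co-moving coordinate system, where material
points stay put and their fluorescence can be read off directly.

The catch is that dense optical flow assumes *brightness constancy*,
which fluorescence reporting deliberately violates: an action-potential
wave is itself a moving brightness pattern that trackers can lock onto.
The package therefore also implements the standard counter-measure —
local contrast enhancement, `I_c = (I − min S)/(max S − min S)` over a
small disc `S` around each pixel, which amplifies tissue texture and
cancels the spatially smooth fluorescence modulation — and a synthetic
benchmark with exact ground-truth displacements that quantifies, per flow
algorithm, the tracking error (mean end-point error, EPE, in pixels)
as a function of fluorescence strength |ΔF/F| and image noise σ.

What's inside:

* S4 containers `VideoStack` (H×W×T grayscale stacks, 8/12/14/16-bit or
  unit-range) and `FlowSequence` (per-frame displacement fields,
  ref-to-frame convention), with multi-page TIFF, raw-binary + INI
  sidecar, CSV trace and flow-archive IO.
* Pre-/post-processing: spatio-temporal box smoothing, disc-based local
  contrast enhancement, flow smoothing, bilinear warping.
* Four natively implemented dense optical-flow backends behind a plug-in
  registry: coarse-to-fine dense Lucas–Kanade, Farnebäck polynomial
  expansion, duality-based TV-L1, and a Brox-style brightness+gradient
  constancy variational method.
* Analysis: pixel-wise sliding-window normalization (optical maps), ROI
  trace extraction, end-point-error computation.
* A synthetic scene generator (texture × action-potential wave ×
  contractile deformation × noise) with analytic ground truth, and a
  benchmark harness (`sweepFluorescence()`, `sweepNoise()`) that sweeps
  backends over signal and noise strengths.
* A command-line front end (`inst/cli/moco`) with `compensate`, `synth`,
  `bench` and `trace` subcommands.

## Worked example

```r
library(moco)
sc  <- syntheticScene(f = -0.05)      # 128x128, planar wave, 5 px contraction
mv  <- makeVideo(sc, 60)              # video + exact ground-truth flow
cfg <- pipelineConfig(backend = "farneback", contrastKernel = 5L)
res <- runCompensation(mv$video, cfg)

# tracking accuracy of the unsmoothed fields against the exact truth
mean(sapply(2:60, function(t)
  computeEPE(getField(res$rawFlow, t), getField(mv$flow, t))))
#> [1] 0.2362

# motion-artifact suppression at a strongly moving tissue ROI
sd(extractTrace(mv$video,        roi(30, 64, 6L)))   # raw trace
#> [1] 0.04145
sd(extractTrace(res$compensated, roi(30, 64, 6L)))   # stabilized trace
#> [1] 0.003557

res$flow
#> FlowSequence: 60 fields of 128 x 128 px, reference frame 1 (ref-to-frame)
#>   max |u| = 5.01 px, mean |u| = 0.577 px
```

The mean end-point error of 0.24 px says the Farnebäck backend tracks the
synthetic contraction to sub-pixel accuracy despite the 5 % fluorescence
signal; the ~12× drop in trace standard deviation is the motion artifact
being removed.  `pixelwiseNormalize(res$compensated, 20)` then renders
optical maps of the propagating wave.

From a shell, the same pipeline is:

```sh
moco synth -o scene --size 128 --frames 60 --f -0.05
moco compensate scene/video.tif -o stabilized.tif --backend farneback \
     --contrast-kernel 5 --frame-interval-ms 2
moco trace stabilized.tif --roi 30,64,6 -o traces.csv --frame-interval-ms 2
```

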