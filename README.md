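# kymowave

Oscillation analysis for tip-growing cells from kymographs and
concurrently measured time series.

Tip-growing cells such as pollen tubes oscillate: growth rate, apical
cytosolic Ca²⁺ (reported by ratiometric probes like YC3.6 through the
YFP/CFP emission ratio), and extracellular ion fluxes all fluctuate with
periods of tens of seconds, with frequency and amplitude that drift over
time and with phase relationships that can flip as the cell changes
state. Quantifying this requires tracking the growing apex with
subpixel precision, turning kymographs into clean fluorescence series,
and using *time-resolved* spectral methods — stationary tools (Fourier,
autocorrelation) blur exactly the non-stationarity of interest.

`kymowave` provides that pipeline for R, end to end:

* **Tip detection** on kymograph frames (rows = frames, columns =
  pixels): a whole-pixel threshold method for comparison, and the
  featured subpixel estimator — an ordinary least-squares line fitted to
  the steepest flank of the (lightly smoothed) edge profile, with the
  tip at the crossing of a reference level. Tip traces become growth
  rate series in µm min⁻¹ (`traceTip`, `smoothTrace`, `growthRate`).
* **Ratiometric kymograph processing**: per-channel background from the
  region beyond the tip (99% quantile cutoff), the background-subtracted
  YFP/CFP ratio, tip-aligned resampling, and fluorescence series at
  chosen distances from the apex — e.g. tip (~2.2 µm) vs shank
  (~19.4 µm) and the normalized gradient (tip − shank)/shank
  (`estimateBackground`, `ratioKymograph`, `alignToTip`,
  `extractRegionSeries`, `scanSeriesAlongTube`). A 2-D multiresolution
  filter removes drift, stripes and refocusing blocks from
  single-channel kymographs (`filterKymograph2d`).
* **Series preparation**: loess resampling of irregular series onto a
  uniform grid and MAD-based outlier detection with local-regression
  restoration; level shifts are reported, not silently "fixed"
  (`regularize`, `removeOutliers`).
* **Wavelet machinery**, implemented in-package: a shift-invariant
  discrete wavelet multiresolution analysis whose detail levels act as
  a band-pass filter (periods (2^j dt, 2^(j+1) dt]; with dt = 4 s the
  16–128 s band is levels 2–4), and a continuous Morlet wavelet
  spectrum with red-noise (AR(1)) significance, cone of influence, and
  ridge extraction giving period and amplitude per time point (`mra`,
  `bandpass`, `cwt`, `significance`, `extractRidges`,
  `detectionProportion`).
* **Synchronization**: cross-wavelet transform of two concurrently
  measured series, phase difference Δφ = φx − φy, and the time-resolved
  delay Δφ·P/2π at joint-ridge points — positive delay means the first
  series leads. Circular phase histograms and per-window synchrony
  flags included (`matchSeries`, `xwt`, `phaseToDelay`,
  `phaseHistogram`, `synchronyFlag`).
* **Summary statistics**: two-component Gaussian mixture summaries of
  period/delay distributions, growth-regime classification from the
  growth trend (growing > 2 µm min⁻¹, non-growing < 0.5 µm min⁻¹),
  Welch tests with Bonferroni correction, McNemar paired detection
  comparison, and tracking-noise quantification from the finest
  wavelet band (`fitGmm2`, `classifyGrowthRegime`, `welchBonferroni`,
  `mcnemarTest`, `noiseBandDensity`, `compareDetection`).
* **Synthetic generators with ground truth** for every stage
  (`simulateKymograph`, `simulateRatiometricPair`,
  `simulateSeriesPair`), so each estimator can be scored against truth.

## Worked example

Simulate a realistic oscillatory kymograph (dt = 4 s, dx = 0.22 µm,
growth 2 µm min⁻¹ with a 0.25 µm, 48-s oscillation, contrast-to-noise
10), track the tip, and analyse the growth-rate oscillation:

```r
library(kymowave)

sim <- simulateKymograph(nFrames = 300, nPx = 260, x0 = 40, seed = 1)
sim$kymo
#> Kymograph [synthetic]: 300 frames x 260 px, dt = 4 s, dx = 0.22 um

trace <- traceTip(sim$kymo, method = "regression")
err <- tipPositions(trace) - sim$truth$tipPx
sqrt(mean((err - mean(err))^2))       # subpixel precision, px
#> 0.282

rate <- growthRate(trace)             # um/min at frame midpoints
res <- analyzeOscillations(rate, periodMin = 16, periodMax = 128)
res$detection                         # fraction of time with a ridge
#> 0.96
median(ridgePoints(res$ridges)$period_s)    # true period: 48 s
#> 46.8
median(ridgePoints(res$ridges)$amplitude)   # true rate amplitude: 1.96
#> 1.94
```

The 0.28 px tracking precision is what makes the 1.9 µm min⁻¹ rate
oscillation measurable at all: the threshold method's one-pixel
quantization corresponds to 3.3 µm min⁻¹ jumps between adjacent frames.

Cross-wavelet delay between two series sharing a 48-s rhythm, the second
lagging by 4 s:

```r
pair <- simulateSeriesPair(n = 256, dt = 4, period = 48, lag = 4,
                           ar1 = 0.3, noiseSd = 1/3, seed = 1)
m <- matchSeries(pair$x, pair$y, dtTarget = 4)
xs <- significance(xwt(m$a, m$b, nullA = m$prepA, nullB = m$prepB), 0.05)
delays <- phaseToDelay(xs, extractRidges(xs, maxPerTime = 1))
median(delays$delay_s)                # positive: first series leads
#> 3.8
```

## Command line

A thin CLI over the same functions lives at
`inst/cli/kymowave.R` (after installation:
`system.file("cli", "kymowave.R", package = "kymowave")`), with
subcommands `simulate`, `tip`, `kymo`, `prep`, `analyze`, `sync`,
`summary`; every run writes a `run_log.yaml` with the resolved
parameters and seed, and a YAML config file can supply any flag.

```sh
Rscript kymowave.R simulate --out-dir sim --n-frames 300 --seed 1
Rscript kymowave.R tip --input sim/kymograph.tif --out-dir tip --smooth
Rscript kymowave.R analyze --input tip/growth_rate.csv \
    --value-col rate_um_min --band-min 16 --band-max 128 --out-dir osc
```

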