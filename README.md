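# endomapper

Object-based colocalization analysis for fluorescence microscopy: how often
is a protein of interest present at endomembrane compartments (early and
recycling endosomes, autophagosomes, trans-Golgi), beyond what chance
colocalization would produce?

Pixel-correlation measures (Pearson, Manders) depend on signal
proportionality between channels. This package instead works object by
object: one channel carries a compartment marker (e.g. EEA1, Rab11, LC3,
Rab6) and is segmented into compartments; the second channel carries the
protein of interest (e.g. an anti-RalB or anti-RGL2 immunostain) and is
quantified inside each compartment. Two safeguards make the readout robust
on dim or crowded images:

1. **Positivity threshold.** A compartment is called *positive* when its
   mean protein intensity strictly exceeds

   *T* = *μ*<sub>ROI</sub> + *k* · *σ*<sub>ROI</sub>

   where *μ*<sub>ROI</sub> and *σ*<sub>ROI</sub> are the mean and
   (population) standard deviation of the protein channel over the whole
   region of interest and *k* = 1 by default.
2. **Randomized pseudo-compartment null.** *n* disks of compartment-like
   area are dropped uniformly at random in the ROI (defaults *n* = 1000,
   1.2 µm² at endosome scale; *n* = 10, 9.2 µm² at trans-Golgi scale). The
   same measurement applied to these pseudo-compartments estimates the
   colocalization expected by chance, and a two-sided Mann–Whitney
   rank-sum test compares real against pseudo per-region mean intensities.

The package also implements ratiometric FRET-biosensor quantification
(per-pixel background-subtracted YFP/CFP ratio, optional 2×2 / 3×3
binning, summarized over the whole cell, a 1.67 µm cell-edge band, or
segmented compartments) and a synthetic-image generator with known ground
truth used to validate every stage.

## Worked example

Generate a ground-truthed image (50 disk compartments of ~1.2 µm² at
0.1 µm/px, half of them 10× enriched in the protein channel) and run the
full analysis:

```r
library(endomapper)

fx  <- generate_colocalization_fixture(synthetic_params(seed = 42))
rep <- endomapper(fx$image, seed = 42)
summary(rep)
#> Endomembrane colocalization analysis
#>   compartments segmented : 50
#>   % positive (real)      : 50.0
#>   % positive (pseudo)    : 7.0
#>   rank-sum real vs pseudo: U = 36827, p = 1.59e-08
#>   threshold              : 140.5 (baseline roi, k = 1)
#>   ROI protein mean / sd  : 65.74 / 74.75
#>   pseudo-compartments    : n = 1000, area 1.2 um^2, radius 6 px, seed 42
```

All 50 true compartments are recovered; the estimated percent positive
(50.0%) matches the simulated enriched fraction (0.5), while randomly
placed pseudo-compartments are positive only 7% of the time (their
occasional overlap with enriched compartments is exactly the chance
colocalization the null is meant to capture). The tiny rank-sum p-value
confirms that real compartments carry more protein signal than chance
placement explains. `write_reports(rep, "out/")` saves
`real_compartments.csv`, `pseudo_compartments.csv` (columns `id`,
`area_px`, `mean_intensity`, `sd_intensity`) and a `report.json` with all
parameters and the seed.

FRET example:

```r
fx  <- generate_fret_fixture(true_ratio = 2, noise_sd = 0)
s   <- fret_summary(fx$input)
s$summary
#>       region mean_ratio n_pixels
#> 1 whole_cell          2     8100
#> 2  edge_band          2     1700
```

## Command line

A thin wrapper over the same functions, installed as `exec/endomapper`:

```sh
endomapper simulate --seed 7 --out sim/
endomapper map --input sim/image.tif --marker-ch 1 --protein-ch 2 \
    --pixel-size 0.1 --n-pseudo 1000 --pseudo-area 1.2 --seed 7 --out out/
endomapper count --input sim/image.tif --pixel-size 0.1 --out out/
endomapper fret --input fret.tif --cell-mask mask.tif \
    --background-json bg.json --bin 2 --out out/
```

Channel indices are 1-based. A YAML/JSON `--config` file can supply any
option; explicit flags override it.

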