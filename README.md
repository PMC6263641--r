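# olivescan

Olive oil quality is largely decided before the first drop is pressed: the
ripeness and health of the incoming fruit drive the acidity index, the
oxidation indicators, the fermentative ethyl esters and the minor compounds
(polyphenols, chlorophyll, carotenoids) of the oil a mill will obtain from
a batch. At the reception yard this assessment is still done by eye.
`olivescan` implements an image-based alternative for R users: it turns RGB
photographs of olive batches on a white tray into a 23-element colour +
texture feature vector and calibrates one partial-least-squares regression
per chemical quality parameter, validated by repeated random holdout.

The package is aimed at chemometricians and agri-food imaging researchers
who want a fully reproducible, end-to-end reference pipeline. Because no
public image/chemistry dataset of this kind exists, `olivescan` ships a
first-class synthetic-data module that generates tray scenes and matched
chemistry tables with the statistical structure the analysis assumes, so
every stage can be exercised, tested and benchmarked offline.

## The method

**Segmentation.** A tray image `A` is converted to Rec. 601 luminance,
binarised with a global threshold (Otsu's between-class-variance criterion
by default, or a fixed level), and the inverse of the background mask is
applied channelwise:

    I = A × M̄

so background pixels are exactly zero and fruit pixels are untouched.

**Features (23 per batch).** Nine colour means — the mean intensity
`Ī_c = Σ I_c(n,m) / (N·M)` of each channel of the masked image in RGB, HSV
and CIELAB — plus the 14 Haralick descriptors (angular second moment,
contrast, correlation, variance, inverse difference moment, sum
average/variance/entropy, entropy, difference variance/entropy, the two
information measures of correlation, and the maximal correlation
coefficient) of a grey-level co-occurrence matrix computed over fruit-pixel
pairs only (64 levels, distance 1, four directions, symmetric).

**Regression.** For each quality parameter `y`, PLS1 by NIPALS on the
autoscaled feature matrix:

    X = T·P' + E ,   y = T·q + f

The latent-variable count `lv` is swept from 1 to 23; each candidate is
trained and validated on repeated random 50/50 splits (1000 by default),
and the model minimising the mean validation RMSE is selected. Reported
per parameter: `Rc²`, `Rv²`, `RMSEc`, `RMSEv`, `lv` and the ratio of
performance to deviation `RPD = sd(y) / RMSE`.

## Worked example

Simulate a 74-batch campaign at quarter resolution, extract features and
fit all ten quality models (about a minute on a laptop):

```r
library(olivescan)

ds     <- generate_dataset(74, scene_config(), seed = 1)
feats  <- extract_feature_table(ds$images)
plan   <- holdout_plan(repetitions = 200, seed = 2)
report <- fit_quality_models(feats, ds$chemistry, plan = plan)
report
```

```
olivescan quality report (v0.1.0, seed=2)
       parameter   Rc2   Rv2   RMSEc    RMSEv lv   RPD
         acidity 0.819 0.744  0.0431   0.0513  2 2.037
        peroxide 0.779 0.711  1.2700   1.4700  2 1.934
            k270 0.530 0.367  0.0150   0.0176  2 1.302
            k232 0.825 0.750  0.0352   0.0420  3 2.095
     ethyl_ester 0.887 0.810  4.1600   5.4700  5 2.375
 ethyl_palmitate 0.736 0.646  1.1700   1.3500  2 1.740
    ethyl_oleate 0.712 0.647  6.0900   6.7200  2 1.728
     polyphenols 0.783 0.651 87.6000 111.0000  4 1.755
     chlorophyll 0.753 0.614  2.6700   3.3000  3 1.654
     carotenoids 0.451 0.216  1.5700   1.8900  2 1.166
```

Each row is one chemical parameter. `Rc²`/`RMSEc` are means over the
calibration halves of the 200 splits, `Rv²`/`RMSEv` over the validation
halves (in the parameter's own units — % free oleic acid for acidity,
mg/kg for esters and polyphenols, and so on), `lv` is the selected
latent-variable count and `RPD` the validation-set standard deviation over
`RMSEv` (≈2 or more indicates a model usable for screening). On this
synthetic campaign the parameters most strongly coupled to skin colour and
texture (acidity, ethyl esters, K232) validate best, while carotenoids —
given a weak latent link and relatively high noise by the generator — trail
behind, as expected.

A thin command-line wrapper with `simulate`, `extract`, `fit` and
`fov-check` subcommands is installed under `inst/cli/olivescan.R`.

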