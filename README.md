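# dociR

Relative fluorescence-lifetime image analysis for dynamic optical contrast
imaging (DOCI), with a physics-based phantom generator for labelled surgical
scenes.

## The problem

Intraoperative discrimination of tumor from healthy tissue — and of nerves
harbouring perineural invasion (PNI) from healthy nerves — is usually done by
eye, palpation and frozen-section histology. Tissue autofluorescence offers a
label-free alternative: the lifetimes of endogenous fluorophores (NADH, FAD,
collagen) differ between malignant and healthy tissue. DOCI maps a *relative*
lifetime per pixel without fitting exponentials: under pulsed excitation,

```
DOCI(x, y) = ∫_decay gate I(x, y, t) dt / ∫_steady-state gate I(x, y, t) dt
```

the aggregate decay-tail intensity after excitation turn-off normalised by
the aggregate steady-state intensity during the pulse plateau. For a
mono-exponential pixel with lifetime τ and a long decay gate this ratio
reduces to τ / W_ss (W_ss = steady-gate width): it is monotonically related
to the amplitude-weighted mean lifetime, so tissues with distinct lifetime
composition produce distinct DOCI values across the nine emission band-pass
channels (405–605 nm).

`dociR` implements, for image analysts and imaging-systems researchers:

* the forward physics: multi-exponential decays under a square excitation
  pulse (`decayTrace()`, analytic `dociClosedForm()`);
* a phantom generator for labelled scenes (tumor, muscle, adipose, dermal
  adipose tissue, nerve, PNI+ nerve) with Poisson shot noise and Gaussian
  read noise (`defaultScene()`, `renderStacks()`);
* the gated-integration DOCI computation with low-signal masking
  (`computeDOCI()`, `computeAllChannels()`);
* ROI statistics: per-instance means, reference (tumor) normalisation, and
  per-channel one-sample t-tests with Manhattan-plot output
  (`roiMeans()`, `significanceSweep()`);
* nerve-axis profiling and a threshold-plus-run-length PNI caller with
  transition-point localisation (`extractProfile()`, `callPNI()`,
  `evaluateDetection()`);
* pseudo-color margin rendering and TIFF/YAML/JSON I/O plus a small CLI
  (`renderPseudocolor()`, `dociCLI()`, `inst/scripts/doci`).

## Worked example

```r
library(dociR)

tm <- PulseTiming()                     # 100 ns pulse, gates [50,100] / [100,200] ns
sc <- defaultScene("margin", seed = 1)  # 15 ROI instances each of 4 tissue classes
lm <- renderLabelMap(sc$spec)

st    <- renderStacks(sc$spec, sc$tissues, tm, channels = 465)
doci  <- computeAllChannels(st)
rois  <- ROISet(lm$map, lm$legend, referenceTissue = "tumor")
sweep <- significanceSweep(doci, rois)
statsTable(sweep)
#>    tissue channel_nm  n  mean_doci normalized_mean         t df            p
#> 1   tumor        465 15 0.03034812        1.000000        NA NA           NA
#> 2  muscle        465 15 0.05022479        1.654956  3822.094 14 1.555253e-43
#> 3 adipose        465 15 0.12010918        3.957714 16968.772 14 1.345605e-52
#> 4     dat        465 15 0.10012269        3.299140 11755.215 14 2.295065e-50
```

Reading the table: the tumor reference normalises to exactly 1; muscle's mean
DOCI is 1.65× tumor's (its 2.5 ns lifetime vs tumor's 1.5 ns), and with 15
ROI instances the one-sample t-test against 1 rejects decisively at every
healthy tissue (p ≪ 0.05). For the PNI analysis:

```r
scp <- defaultScene("pni", seed = 2)    # control nerve band + band invaded from column 32
stp <- renderStacks(scp$spec, scp$tissues, tm, channels = 465)
d   <- computeDOCI(stp[[1]])
ctl <- extractProfile(d, nerveBands(scp$spec)[[1]])
tst <- extractProfile(d, nerveBands(scp$spec)[[2]])
thr <- calibrateThreshold(list(ctl, ctl), k = 3)
callPNI(tst, thr)
#> PNICallResult: pni (score 0.05823 vs threshold 0.07977, transition at position 32)
```

The invaded band drops from the healthy-nerve DOCI (~0.080) to the invaded
level (~0.036) at the configured transition column, and the caller localises
it exactly.

The same pipeline is scriptable from a shell:

```sh
Rscript inst/scripts/doci simulate --scene pni --seed 5 --out raw
Rscript inst/scripts/doci compute  --in raw --out doci
Rscript inst/scripts/doci pni      --doci doci --scene raw --out calls
```

## Documentation

`vignettes/doci-methods.Rmd` describes the decay model, the noise model and
its defaults, the statistical design (sampling unit, normalisation,
calibration regime), the PNI decision rule, and known limitations.
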