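# pvcdct

Detection of premature ventricular contractions (PVCs) in single-beat ECG
windows from the decay rate of the beat's DCT-Teager energy envelope, with
the classical DCT-cepstrum envelope as a baseline.

## The idea

A PVC originates in the ventricular muscle, bypassing the fast conduction
system: its QRS complex is wide and has no preceding P wave. A wide, smooth
deflection concentrates its spectral energy at low frequencies, so in the
DCT domain a PVC packs its energy into fewer leading coefficients than a
narrow-QRS normal beat.

For a beat window *x*[*n*] centred on the R peak, the pipeline is

1. orthonormal DCT-II:
   *X*<sub>c</sub>[*k*] = *c*<sub>k</sub> √(2/*N*) Σ<sub>n</sub> *x*[*n*] cos(π/*N* (*n*+½)*k*);
2. Teager–Kaiser energy along the coefficient index:
   *E*[*k*] = *X*<sub>c</sub>[*k*]² − *X*<sub>c</sub>[*k*−1] *X*<sub>c</sub>[*k*+1]
   — the envelope of the beat's system function (for a sinusoid the
   operator returns *A*² sin²Ω, energy of the generating oscillator, not of
   the signal);
3. energy packing efficiency over the first *M* = min(*N*, 150)
   coefficients: ε<sub>i</sub> = Σ<sub>j≤i</sub> *E*<sub>j</sub>² / Σ<sub>j<M</sub> *E*<sub>j</sub>²;
4. the **decay rate** — the first index with ε<sub>i</sub> ≥ 0.9 — is small
   for PVCs and large for normal beats; a calibrated threshold
   (`decay rate ≤ 13` at the package defaults) calls the beat.

The package includes beat containers with CSV and WFDB (format-212)
readers, a synthetic Gaussian-wave beat generator (normal, PVC, paced,
LBBB, RBBB morphologies with reproducible jitter), additive noise models
(baseline wander, mains interference, white Gaussian noise at a target
SNR), detection metrics (sensitivity, positive predictivity, detection
error rate) and a command-line interface. See the methods vignette
(`vignettes/dct-teo-pvc-detection.Rmd`) for the model, conventions and
measured operating envelope.

## Worked example

```r
library(pvcdct)

set <- generate_beatset(100, 100, seed = 0)   # 100 normal + 100 PVC, 5% jitter
cls <- classify_beatset(set, method = "teo")
head(cls, 3)
#>      beat_id method decay_rate threshold predicted_label true_label
#> 1    pvc-021    teo          7        13             pvc        pvc
#> 2    pvc-003    teo          7        13             pvc        pvc
#> 3 normal-077    teo         21        13          normal     normal

evaluate_detection(cls)
#> <performance_report> method=teo threshold=13
#>   PVCs 100  TP 100  FP 0  FN 0  (total beats 200)
#>   Se 100.00%  +P 100.00%  DER 0.00%
```

Every PVC decay rate (5–8 here) sits below every normal decay rate
(16–22): the two classes separate completely, so sensitivity (Se),
positive predictivity (+P) and detection error rate (DER) are perfect on
clean synthetic beats. Comparing methods and adding noise:

```r
compare_methods(set, noise_specs = list(noise_spec("gaussian", snr_db = 0, seed = 1)))
#>       condition   method threshold pvc_min pvc_max normal_min normal_max sensitivity
#> 1         clean      teo        13       5       8         16         22         100
#> 2         clean cepstrum        19      10      10         24         29         100
#> 3 gaussian 0 dB      teo        13       3      11         16         84         100
#> 4 gaussian 0 dB cepstrum        19      75     145         87        140           0
#>   positive_predictivity detection_error_rate
#> 1                   100                    0
#> 2                   100                    0
#> 3                   100                    0
#> 4                   NaN                   50
```

The Teager method needs fewer coefficients than the cepstrum baseline
(PVC decay rates 5–8 vs 10 in the table above) and keeps perfect detection
under 0 dB white noise, where the cepstral envelope has already broken
down. The frequency-sensitivity demonstration behind the operator:

```r
demo_teo()
#>   frequency_hz conventional_energy mean_teager_energy closed_form_teager
#> 1           50                1280           7.900000           8.000000
#> 2           20                1280           1.508766           1.527864
```

Equal-amplitude tones at 50 and 20 Hz carry identical sum-of-squares
energy (1280), yet their Teager energies differ by the factor
sin²(π/4)/sin²(π/10) ≈ 5.24 — the operator sees the frequency.

## Command line

```sh
Rscript inst/cli/pvcdct.R simulate --seed 0 --out runs/demo
Rscript inst/cli/pvcdct.R classify --out runs/demo runs/demo/beats.csv
Rscript inst/cli/pvcdct.R evaluate --out runs/demo runs/demo/classification-teo.csv
```

(after installation, the script lives at
`system.file("cli", "pvcdct.R", package = "pvcdct")`). Commands:
`simulate`, `classify`, `evaluate`, `compare`, `demo-teo`; options come
from a YAML config (`--config`) with `--seed`, `--out`, `--method`
overrides.

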