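# egmprint

Signal fingerprinting of unipolar atrial electrograms.

`egmprint` is for cardiac electrophysiologists and signal analysts who map
the atria during sinus rhythm with high-resolution epicardial electrode
arrays (128/192 unipolar electrodes, 2.0 mm spacing, 1 kHz) and want a
quantified, per-region summary of how inhomogeneously the tissue conducts.
Inhomogeneous conduction fragments the unipolar electrogram (EGM) and
lowers its voltage; the package turns raw multichannel recordings into a
per-patient **signal fingerprint** that captures exactly that.

## What it computes

Per electrode and beat, after beat segmentation and noise estimation:

* **Deflections and LAT** — negative deflections are local minima of the
  band-limited derivative whose peak-to-peak amplitude reaches twice the
  channel noise; the local activation time (LAT) is the time of the
  steepest negative slope, `t* = argmin dV/dt`.
* **Type** — SP (1 deflection), SDP / LDP (2 deflections, interval
  < 15 ms / ≥ 15 ms), FP (≥ 3 deflections); fractionation duration
  FD = t_last − t_first.
* **R/S ratio** of single potentials, mapping relative R- and S-wave
  amplitude onto [−1, 1]:

  R/S = 1 − (R/S)  for R/S ≤ 1,  and  1/(R/S) − 1  for R/S > 1

  so −1 is a pure R-wave, +1 a pure S-wave.
* **Voltage** — peak-to-peak amplitude; < 1.0 mV flags a low-voltage
  potential.
* **Conduction block (CB)** — |ΔLAT| ≥ 12 ms between adjacent electrodes
  on the grid, after excluding simultaneous-activation (far-field)
  plateaus; CB% = blocked / evaluable adjacent pairs.

Per region (RA, BB, PVA, LA) and pooled, these aggregate into the
fingerprint: medians, type percentages, low-voltage and CB percentages,
and stacked voltage / R/S / FD distributions. A statistics layer provides
Spearman correlations with weak/moderate/strong categories (|rho| < 0.4 /
0.4–0.6 / > 0.6), Kruskal–Wallis and pairwise rank-sum comparisons at the
Bonferroni-corrected level 0.05/6, and patient ranking by fractionation
burden (LDP% + FP%).

A built-in forward simulator (geodesic wavefront propagation over a
tissue lattice with delaying block lines, signed distance-weighted source
summation into unipolar EGMs) generates recordings with known
per-electrode ground truth; the whole pipeline is validated against it.

## Worked example

Simulate one right-atrial site crossed by a 20 ms line of conduction
block, run the pipeline, and inspect the result:

```r
library(egmprint)
cfg <- SimulationConfig(blockLines = blockLine(7.5, -10, 7.5, 24, 20),
                        seed = 42L)
sim <- simulateSite(cfg, region = "RA", siteId = "RA_s1")
res <- analyzeSite(sim$site)
table(res$potentials$type)
#>
#>  FP LDP  SP
#>   9 145 166

fp <- buildFingerprint(PatientDataset("demo01", list(sim$site)))
fp
#> PatientFingerprint 'demo01': 1 region(s), n = 320, LDP+FP burden 48.12%
#> RegionFingerprint [RA]: n = 320
#>   voltage 4.85 mV | low-voltage 0.00% | R/S 0.06 | SP/SDP/LDP/FP 51.9/0.0/45.3/2.8% | FD 19.00 ms | CB 7.14%

res$maps[[1]]
#> ActivationMap (beat 1): 64/64 LATs, 0 excluded, 8 CB edge(s) (CB 7.14%)
```

Reading the numbers: the block line splits the 8×8 map into two late/early
halves — the 8 electrode pairs straddling it all exceed the 12 ms block
threshold (8 of 112 evaluable pairs = 7.14% CB). Electrodes within reach
of the line record the far side's delayed activation as a second
deflection ~20 ms after the first, so roughly half of all electrode-beats
classify as long double potentials and the fractionation burden is high;
a block-free simulation instead yields ≥ 99% single potentials, 0% CB and
a burden near zero. Interior voltages sit near the ~5 mV scale of healthy
atrial unipolar EGMs.

For shell use there is a thin command-line wrapper over the same
functions:

```sh
Rscript inst/cli/egmprint.R simulate    --out bundle/ --seed 7 --block-density 1.5
Rscript inst/cli/egmprint.R fingerprint --bundle bundle/ --out results/
Rscript inst/cli/egmprint.R cohort      --out cohort/ fp1.yaml fp2.yaml fp3.yaml
```

File formats: recordings travel as a bundle directory (JSON manifest +
float32 payloads, mV); classified potentials as CSV with the fixed header
`patient_id,region,site_id,row,col,beat,type,lat_ms,r_mv,s_mv,rs_ratio,vpp_mv,low_voltage,fd_ms,deflection_times_ms`
(deflection times `;`-joined); fingerprints as structured YAML carrying
every scalar, histogram and the full parameter echo.

## Documentation

The methods vignette (`vignettes/signal-fingerprinting.Rmd`) describes the
detection model, every threshold and its default, the forward simulator
and its limitations, and the numerical conventions.
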