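# bladdermod

Swim-bladder modulation modelling and acoustic air-volume identification.

Many sound-producing fish drive a gas-filled swim bladder with fast sonic
muscles. `bladdermod` models the bladder as a resonant air volume that
**amplitude-modulates** the muscle-driven call, so the radiated sound
carries an envelope signature of the bladder's size — and asks the inverse
question: given only a received call, which air volume produced its
modulation? The package is aimed at bioacousticians studying
size-signalling in vocal fish (the test signal emulates a red hind grouper
"growl"), and at signal-processing users who want a compact, fully
reproducible cyclostationary template-matching example.

## The model

A spherical air volume of radius *R* in water resonates at the Minnaert
frequency

    f0 = (1 / 2πR) √(3 γ P / ρ)

(γ specific-heat ratio, P combined atmospheric + hydrostatic pressure,
ρ water density). Over a record centred on t = 0 the bladder applies the
raised-cosine envelope

    M(t) = | 1 − a (1 + cos 2π f_b t) / 2 |,   a = f0/(f0 + F),   f_b = |F − f0|

to a vocalization forced at frequency *F*: deep, slow modulation from a
small bladder near resonance, and an ideal all-pass (M → 1) as radius or
forcing frequency grow.

Two independent methods recover the volume from a received record:

1. **Demodulation / Z1** — coherent AM-SSB demodulation (cosine mixing +
   zero-phase 5th-order Butterworth), removal of the remodulated
   information signal by least-squares projection, STFT region-of-interest
   (150–200 Hz) mean time series, and normalized cross-correlation against
   per-volume templates.
2. **Cyclostationary / Z2** — time-smoothed cyclic periodogram estimate of
   the spectral correlation density S^α(f), unit-energy coherent-spectrum
   surfaces (template T from the record and its demodulation, input G from
   the candidate record), ROI-averaged cyclic content, and the same
   normalized correlator over cyclic frequency.

## Worked example

```r
library(bladdermod)

env <- environment_spec()                    # fresh water, 0.1 m depth
resonance_frequency(bladder_spec(1), env)
#> [1] 329.9099

modulation_envelope(vocalization_frame(185, 2, 10000), bladder_spec(3), env)
#> <modulation_envelope> R = 3 cm: f0 = 109.97 Hz, depth a = 0.373, ripple 75.03 Hz

res <- run_experiment(default_experiment_config(), verbose = FALSE)
res$report
#>  method input best correct     margin
#>   demod  d3cm d3cm    TRUE 0.26659847
#>   demod  d4cm d4cm    TRUE 0.23289881
#>   demod  d6cm d6cm    TRUE 0.07504476
#>   demod  d8cm d8cm    TRUE 0.07421070
#>   cyclo  d3cm d3cm    TRUE 0.04492867
#>   cyclo  d4cm d4cm    TRUE 0.03934989
#>   cyclo  d6cm d6cm    TRUE 0.01059849
#>   cyclo  d8cm d8cm    TRUE 0.02215780
```

A 1 cm bladder rings at ≈330 Hz; a 3 cm volume driven at 185 Hz modulates
with depth 0.37 and 75 Hz ripple. The experiment synthesizes the growl,
passes it through four volumes (radii 1.5/2/3/4 cm — pipe diameters
3/4/6/8 cm), builds template banks for both methods, and classifies
independently re-noised inputs: all eight assignments are correct, with
`margin` the gap between the best and runner-up peak correlation. The
per-method peak-correlation matrices are in `res$correlations`, e.g. for
method 1 the self-match diagonal is 1.000 against off-diagonal values of
0.58–0.93.

A thin command-line front end (`inst/scripts/bladdermod-cli.R`) exposes
`simulate`, `templates`, `classify`, `experiment`, `demod` and `scd`
subcommands over WAV files and serialized template banks; see
`inst/extdata/default_config.yaml` for the configuration format.

## Documentation

The methods vignette (`vignettes/volume-identification.Rmd`) describes the
model and its assumptions, the parameter choices that matter (STFT window
versus envelope-ripple bandwidth, cyclic-periodogram segment hop and alias
spacing, alpha-grid resolution), what the synthetic playback does and does
not emulate, and known limitations.
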