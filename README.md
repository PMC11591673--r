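# zfRaman

Raman spectral fingerprinting of zebrafish organ development.

During early zebrafish development (24–168 hours post-fertilisation, hpf),
the molecular composition of organs and tissues changes rapidly, and those
changes leave traces in their Raman spectra. zfRaman implements a complete
chemometric pipeline that turns per-organ Raman acquisitions — iris,
forebrain, melanocytes, heart, muscle and swim bladder, from six animals of
two clutches — into a compact developmental *fingerprint* per organ. It is
aimed at vibrational-spectroscopy and ecotoxicology groups who want baseline
organ profiles against which toxicant-elicited spectral changes can be
compared.

## What it computes

**1. Band deconvolution.** Each spectrum (100–4000 cm⁻¹) is fitted as a
smooth background plus a sum of damped-harmonic-oscillator (DHO) profiles,

&nbsp;&nbsp;&nbsp;&nbsp;*I*(ν) = *b*(ν) + Σⱼ *A*₀ⱼ · *F*ⱼ²*W*ⱼν / [(*F*ⱼ² − ν²)² + (*W*ⱼν)²],

by bounded Levenberg–Marquardt least squares with automatic peak seeding,
yielding per band its natural frequency *F* (cm⁻¹), damping width *W*
(cm⁻¹) and integrated area *A* (counts·cm⁻¹).

**2. Band registry and retention.** Fitted frequencies are grouped across
the dataset into canonical bands (single-linkage gap clustering, δ =
10 cm⁻¹). A band is retained for an organ when, at some stage, strictly more
than 60% of the measured animals present it.

**3. Per-organ PLS-DA.** For each organ, the descriptors A/W/F of its
retained bands (rows = animal × stage, autoscaled) are regressed on the
centered stage-indicator matrix by NIPALS PLS2; the number of components A\*
is chosen from the leave-one-animal-out Q² trace.

**4. Fingerprint statistics.** In the A\*-component space, each stage's
Y-loading *q*ₖ is compared with each descriptor's X-loading *p*ⱼ through
signed scalar projections *s*ₖⱼ, and each descriptor is summarised by its
vector module *m*ⱼ = √(Σₖ *s*ₖⱼ²) — an importance measure that tracks VIP.
The per-organ output table (descriptors sorted by module, one signed
projection per stage) is the tabular analogue of a fingerprint heatmap.

A synthetic generator (`simulateDataset()`) reproduces the full study design
— 24 canonical bands with published per-organ memberships, stage trends,
animal effects, fluorescence-like baseline, noise — together with exact
ground truth, so the whole chain is verifiable without instrument data.

## Worked example

Simulate a swim-bladder dataset under the study design and run the whole
pipeline:

```r
library(zfRaman)

sim <- file.path(tempdir(), "sim"); out <- file.path(tempdir(), "out")
cfg <- pipelineConfig(sim, out, simulate = TRUE, seed = 63,
                      organs = "swim_bladder")
runPipeline(cfg)
#> [simulate] seed 63 -> /tmp/RtmpyFf5gJ/sim
#> [manifest] 24 spectra, 1 organs
#> [fit] 192 components from 24 spectra (6.6 s)
#> [registry] 8 canonical bands
#> [retention] 8 bands retained across organs
#> [fingerprint] swim_bladder: 24 descriptors, A* = 2
#> [done]

head(read.csv(file.path(out, "fingerprint_swim_bladder.csv")), 5)
#>   descriptor    module     proj_96   proj_120    proj_144   proj_168
#> 1      W3431 0.6376867  0.37446385 -0.3386269 -0.36745040  0.1293569
#> 2      F1603 0.6244094  0.31901752  0.2038235 -0.32676665 -0.3738909
#> 3      F1158 0.6066695 -0.40461557  0.2071065  0.40146389  0.0163639
#> 4      F1409 0.6032690 -0.28716917 -0.2260003  0.29533015  0.3783798
#> 5      W1003 0.5958771  0.05082066 -0.4359985 -0.03899566  0.4010878
```

24 spectra (6 animals × 4 stages) are deconvoluted into ~8 components each,
the registry identifies exactly the 8 planted swim-bladder bands (labels are
rounded medians of the fitted frequencies, so a band with a planted stage
trend on its frequency can label as 1158 rather than 1156), the presence
rule retains all 8, and the fingerprint ranks descriptors of the bands
carrying planted stage trends (1409, 1603, 1002, 1156) near the top.
Positive projections mean above-average descriptor values at that stage:
F1409 runs low at 96 hpf and high by 168 hpf, with F1603 moving oppositely —
exactly the trends the generator planted.

The same end-to-end run over all six organs (216 spectra) recovers the
complete planted band structure: 24 retained bands, per-organ counts
6/8/9/9/12/17, and only {1603, 2929, 3431} common to every organ.

## Command line

A thin CLI over the same functions is installed at `exec/zframan`:

```sh
zframan simulate --input data/sim --seed 42
zframan run-all  --input data/sim --output results/run1 --seed 42
```

Subcommands re-read the previous stage's CSV outputs, so stages are
independently re-runnable; every run writes `run.log` and the effective
`config.json` next to its outputs.
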