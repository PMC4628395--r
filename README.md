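# bssfp2pt

Gadolinium-free cardiac tissue characterization with two-point cine bSSFP.

## The problem

Late gadolinium enhancement (LGE) CMR is the standard of care for
identifying myocardial edema, necrosis and focal fibrosis, but it requires
a contrast agent. The bSSFP cine signal itself carries an endogenous
alternative: it is weighted by √(T2/T1) *and* by magnetization transfer
(MT) from extracellular-matrix macromolecules. Diseased myocardium with an
expanded extracellular space has longer T1/T2 and *reduced* MT, so at a
high excitation flip angle it is brighter than healthy tissue, while a
very-low-flip-angle image is essentially a proton-density reference.

Two-point bSSFP acquires the same slice at 5° and 45° and maps the
normalized signal change per voxel *i*,

    (ΔS/S₀)ᵢ = (S₄₅ − S₅)/S₅ × 100  (%),

averaged over three motion-free diastolic phases and median filtered
(3×2 kernel). Myocardial voxels above an enhancement threshold (a fixed
healthy-control-derived 197 %, a control-cohort mean + 3 SD, or a
remote-ROI mean + n SD rule) are classified as enhanced, in direct analogy
to the LGE "mean + 5 SD of a remote ROI" rule. From the label maps the
package quantifies the enhanced area (% of myocardial voxels),
transmurality (% of wall thickness enhanced along the central radial
direction of the lesion), gadolinium partition coefficient maps
GPC = ΔR1,myo/ΔR1,blood from pre/post-contrast T1 maps, DICE overlap, and
Bland–Altman/association agreement between methods.

The package is aimed at CMR methods researchers: it includes a two-pool
(free + macromolecular-bound) MT-bSSFP steady-state signal simulator and a
seeded synthetic short-axis phantom with known ground truth, so every
stage of the chain is testable without patient data.

## Worked example

```r
library(bssfp2pt)

# a 128x128 short-axis phantom: 60-degree full-thickness lesion,
# Rician noise near SNR 5 in the 5-degree reference image
ds <- generate_phantom(phantom_spec(noise_sigma = 0.007, seed = 3))
report <- run_pipeline(ds, pipeline_config())
report
#> <slice_report> deltaS/S0: 18.73% enhanced (thr 86.69% [mean+2SD remote])
#>   LGE: 16.58% enhanced; DICE(enhanced) 0.861
```

The phantom's true enhanced area is 16.69 % of the myocardium. At this
noise level the ΔS/S₀ pathway recovers 18.73 % (threshold 86.69 %,
derived as remote-ROI mean + 2 SD on the averaged, median-filtered map)
and the LGE pathway 16.58 % (remote mean + 5 SD rule); the two enhanced
masks overlap with DICE 0.861, and the recovered transmurality is 100 %
(the lesion is full-thickness). The GPC map medians recover the phantom's
ground truth (enhanced 1.079, non-enhanced 0.505).

Method agreement across subjects uses the usual Bland–Altman quantities:

```r
bland_altman(c(10, 20, 30), c(12, 18, 33))
#> <agreement_result> n=3 bias=-1 LoA [-6.186, 4.186] CoV=0.1291
```

A thin CLI over the same functions lives at `inst/cli/bssfp2pt`
(subcommands `simulate`, `dsmap`, `classify`, `quantify`, `agree`, `run`;
NIfTI in/out with JSON sidecars).

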