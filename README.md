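# fpact

Two-volume first-pass CT myocardial perfusion, coronary flow reserve, flow
capacity and protocol dosimetry.

## The problem

Assessing coronary artery disease needs both morphology (CT angiography)
and physiology (myocardial perfusion in mL/min/g, coronary flow reserve).
Classical dynamic CT perfusion acquires ~20 consecutive whole-heart volumes
per condition, at a substantial radiation cost.  The low-dose alternative
implemented here needs only **two** volume scans per condition: V1,
acquired just after the aortic enhancement crosses a bolus-tracking
threshold (140 HU above baseline), and V2 at approximately the aortic peak
(which doubles as the CTA when run at diagnostic current).

During the first pass, and before venous outflow, the myocardium acts as a
single compartment, and conservation of mass gives

    P_AVE = dHU_AVE / (dt * C_in * rho),      P(v) = P_AVE * dHU(v) / dHU_AVE

with `dHU` the voxel enhancement change between V1 and V2, `dHU_AVE` its
mask average, `dt` the inter-scan time in minutes, `C_in` the aortic
blood-pool enhancement averaged between the scans (HU above baseline), and
`rho = 1.055 g/mL` the myocardial tissue density.  The HU-to-concentration
constant cancels in the ratio, so everything runs in Hounsfield units.
Stress/rest ratios give CFR; minimum-cost-path assignment against the LAD,
LCx and RCA centerlines gives vessel territories (with distal partitioning
at a stenosis); joint (CFR, stress perfusion) thresholds give a coronary
flow-capacity classification; and CTDIvol / SSDE / DLP / effective-dose
arithmetic quantifies the protocol's radiation cost.

The package is aimed at imaging scientists who want a tested, scriptable
reference implementation of this pipeline, including a synthetic 4D cardiac
phantom with known ground truth so every stage is verifiable without scans.

## Worked example

Simulate the default swine-like phantom under stress, select V1/V2 by the
protocol rule, quantify perfusion per territory and report the protocol
dose:

```r
library(fpact)

spec <- default_swine_spec()                      # 96^3 grid, 0.72 s frames
sim  <- simulate_acquisition(spec, condition = "stress")
sel  <- select_v1_v2(sim$series, sim$truth$aorta, baseline_hu = spec$hu_blood)
perf <- compute_perfusion(sel$v1, sel$v2, sim$truth$myo, sim$truth$aorta,
                          spec$hu_blood)
perf
#> <fpa_perfusion> P_AVE 1.979 mL/min/g  (C_in 176.0 HU, M_T 9.88 g, dHU 35.27, dt 0.096 min)

territory_stats(perf$map, sim$truth$territories)
#>      territory label n_voxels n_defined   mass_g     mean        sd
#> 1 LAD-proximal     1    18991     18991 1.852282 2.184155 0.9908654
#> 2          LCx     2    34230     34230 3.338614 2.267952 0.9883769
#> 3          RCA     3    33507     33507 3.268097 1.873520 0.9886855
#> 4   LAD-distal     4    14584     14584 1.422447 1.275192 0.9966667

dose_report(lowdose_protocol_model())
#> <fpa_dose_report> effective diameter 23.0 cm, SSDE factor 1.592
#>  component n_volumes ctdi_mgy ssde_mgy dlp_mgy_cm effective_dose_msv
#>   rest+CTA         2     5.75    9.154       92.0             1.2880
#>     stress         2     2.30    3.662       36.8             0.5152
#>      total         4     8.05   12.815      128.8             1.8032
```

Reading the output: the phantom's true mean stress perfusion is
1.90 mL/min/g, and the two-volume estimator recovers 1.98 -- the ~4%
overestimate is the two-point input-average (trapezoid) bias analysed in
the methods vignette.  Territory means sit within noise of their configured
truths (LAD 2.07, LCx 2.15, RCA 1.79, stenosed distal LAD 1.20 mL/min/g).
The four-volume low-dose protocol totals 8.05 mGy CTDIvol and 12.8 mGy
SSDE at a 23 cm effective diameter (1.8 mSv effective dose at 16 cm
coverage) -- versus 184 mGy for the 40-volume reference technique,
`dose_report(reference_protocol_model())`.

Method-comparison statistics (regression, Lin's CCC, RMSE/RMSD,
Bland-Altman) come from `agreement(reference, test)` with `tidy()` /
`glance()` / `autoplot()` methods.

## Layout

- `R/phantom.R` -- synthetic 4D phantom (spec, gamma-variate input, simulator)
- `R/acquisition.R` -- time-density curves, trigger, delay, V1/V2 selection
- `R/perfusion.R` -- MIP, C_in, tissue mass, two-volume perfusion, CFR, binning
- `R/territories.R` + `src/grid_dijkstra.cpp` -- minimum-cost-path territories
- `R/capacity.R` -- flow-capacity staircase classification and summaries
- `R/dosimetry.R` -- CTDIvol / SSDE / DLP / effective dose
- `R/evalstats.R` -- agreement statistics
- `R/io.R`, `R/pipeline.R`, `exec/fpact` -- NIfTI/JSON/YAML I/O, pipeline, CLI
- `vignettes/first-pass-ct-perfusion.Rmd` -- model, phantom and design notes
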