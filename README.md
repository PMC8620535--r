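# anharmonicIR

Post-processing for anharmonic vibrational calculations of mid- and
near-infrared spectra of molecular crystals.

Whole windows of MIR spectra — the C–H stretching region near
3000 cm⁻¹, the "fundamental-free" windows at 4000–3600 and
2800–1800 cm⁻¹ — and the entire NIR are shaped partly or wholly by
**first overtones** (one normal mode raised by two quanta) and **binary
combination bands** (two modes raised by one quantum each).  Anharmonic
(VPT2-type) quantum-chemistry calculations produce the long transition
lists needed to interpret these regions; `anharmonicIR` is the analysis
layer on top of such lists, for spectroscopists pairing measured ATR /
DRIFT / NIR spectra with calculated transitions.

It provides, as S4 classes and functions:

* transition classification and second-order position arithmetic,
  `E(v) = Σᵢ ωᵢ(vᵢ+½) + Σ_{i≤j} χᵢⱼ(vᵢ+½)(vⱼ+½)`, with the exact
  identities (overtone shift `2χᵢᵢ`, combination shift `χᵢⱼ`) enforced
  as tests (`classifyTransition()`, `vpt2TransitionPosition()`,
  `buildTransitionLedger()`);
* Gauss–Lorentz *product* band-shape synthesis,
  `f(ν) = h·exp(−4 ln2 ((ν−ν₀)/Γ_G)²)·[1+4((ν−ν₀)/Γ_L)²]⁻¹`, with
  area-proportional normalisation so integral intensities are conserved
  (`bandProfile()`, `synthesizeSpectrum()`, `modeContributionMap()`);
* wavenumber-linear scaling `ν → ν(a + bν)` fitting and application,
  and ATR penetration-depth correction `d_p(ν) ∝ 1/ν`
  (`fitWLS()`, `applyWLS()`, `atrCorrect()`, `penetrationDepth()`);
* regional integrated-intensity decomposition by transition class
  (`integrateClassFractions()`);
* peak picking with topographic prominence, and experimental↔calculated
  matching by greedy, optimal (Hungarian) or order-preserving alignment
  strategies, emitting publication-style assignment tables
  (`pickPeaks()`, `matchPeaks()`, `assignmentTable()`);
* a synthetic study generator with exact ground truth for end-to-end
  validation (`generateStudy()`, `evaluateStudyRecovery()`);
* JCAMP-DX / two-column / CSV / JSON / YAML readers and writers and a
  thin command-line driver (`inst/exec/anharmonicIR`).

Curated band tables for crystalline menadione (vitamin K₃) ship as the
reference dataset (`menadioneBandTable()`, `menadioneLedger()`).

## Worked example

Decompose the menadione C–H stretching window and regenerate the top of
its assignment table:

```r
library(anharmonicIR)

led <- menadioneLedger("ch-region")
integrateClassFractions(led, lineShapeParams(8, 8), c(2600, 3600))
#> RegionReport 2600-3600 cm-1, total integral 518.6
#>   fundamental           45.78%
#>   first_overtone        11.70%
#>   binary_combination    42.52%
#>   higher_order           0.00%

t2 <- menadioneBandTable("ch-region")
ok <- is.finite(t2$exp_position)
rec <- matchPeaks(t2$exp_position[ok],
                  data.frame(position = t2$calc_position,
                             intensity = t2$calc_intensity,
                             label = t2$assignment),
                  tolerance = 65, method = "aligned")
head(assignmentTable(rec, expHeights = t2$exp_intensity[ok] / 100), 3)
#>   exp_position exp_intensity calc_position calc_intensity difference
#> 1         3310             m          3360           35.1        -50
#> 2         3272             m          3331           10.2        -59
#> 3         3234             w          3285            3.5        -51
```

The decomposition says that in 2600–3600 cm⁻¹ only 45.78% of the
*tabulated* integral intensity is fundamental — the C–H stretching
region of this molecule is nearly half overtone/combination absorbance.
The matching step regenerates the signed position differences
(exp − calc, e.g. −50 at the 3310 cm⁻¹ combination band) exactly as
printed in the reference tables.

End-to-end validation against known ground truth:

```r
st <- generateStudy(seed = 1)          # 31 modes, 527 transitions, noisy spectrum
r <- evaluateStudyRecovery(st)
#> WLS slope: true 8.397e-06, recovered 8.397e-06 (rel. err. 0.0091%)
#> peaks picked: 109, correctly assigned: 89.9%
```

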