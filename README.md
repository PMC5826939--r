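# hepatoquant

Quantitative, label-free assessment of non-alcoholic fatty liver disease
(NAFLD/NASH) from two complementary measurements:

- **Hyperspectral stimulated Raman scattering (SRS) imaging** of liver
  tissue in the C–H stretch region (~2800–3000 cm⁻¹). Each pixel carries a
  Raman spectrum; lipid (2850 cm⁻¹), protein (2930 cm⁻¹) and DNA
  (2960 cm⁻¹) form distinct spectral clusters. The package segments
  stacks by **spectral phasor analysis** — each pixel's spectrum is mapped
  to its normalized first-harmonic Fourier coefficients

  g = Σₖ Iₖ cos(2πk/N) / Σₖ Iₖ,  s = Σₖ Iₖ sin(2πk/N) / Σₖ Iₖ,

  classes are gated as polygons in the (g, s) plane, and **percentage
  steatosis** is computed as 100 × lipid SRS signal / (lipid + protein +
  DNA SRS signal), alongside lipid-droplet morphometry (8-connected
  components, equivalent circular diameter, micro/macrovesicular split at
  1 µm).

- **Capillary isoelectric focusing (cIEF) immunoassays** of protein PTM
  isoforms. Electropherograms (intensity vs pI on a pH 5–8 gradient) are
  normalized, baseline-subtracted and decomposed into Gaussian peaks;
  peaks are assigned PTM identity by their pI shift from the unmodified
  isoform (phospho and acetyl shift to lower pI, acetyl much farther;
  glycosyl to higher pI), and each isoform's **relative concentration**
  is its fitted AUC over the total AUC. Replicate CV, λ-phosphatase
  sensitivity scoring, cohort heat maps and paired differential
  statistics complete the workflow.

A fully ground-truthed **synthetic-data module** generates liver tissue
phantoms (microvesicular "normal" and macrovesicular "NASH" modes) and
multi-isoform electropherograms, so the entire pipeline is testable
without any tissue data. It is intended for method developers and
analysts who want a reproducible, scriptable alternative to manual
ImageJ/plugin workflows for SRS steatosis scoring and cIEF isoform
quantification.

## Worked example

```r
library(hepatoquant)

# one synthetic NASH liver frame, 200x200 px, 40 spectral channels
spec <- tissue_phantom_spec("nash", seed = 42)
ph   <- generate_phantom(spec)

seg  <- segment_by_gates(phasor_transform(ph$stack), default_gates())
seg
#> <segmentation_map>
#>   lipid          7041 px, signal 1.159e+05
#>   protein       32528 px, signal 2.935e+05
#>   dna             431 px, signal 4484
#>   unassigned        0 px, signal 0

percentage_steatosis(seg)$percent_steatosis
#> [1] 28.00034        # ground truth: 28

dro <- detect_droplets(seg, spec$pixel_size)
nrow(dro); mean(dro$equivalent_diameter_um)
#> [1] 566
#> [1] 1.423665        # um; 45% macrovesicular in this frame

# one synthetic cIEF trace (unmodified 0.5 / phospho 0.3 / acetyl 0.2)
e  <- generate_electropherogram(electropherogram_spec(seed = 101))
pr <- quantify_cief(e$trace, unmodified_pI = 6.5)
round(pr$relative_concentration, 3)
#>     acetyl    phospho unmodified
#>      0.215      0.287      0.498
```

The segmentation recovers the phantom's 28% lipid signal share to within
a few thousandths of a percentage point, and the cIEF pipeline recovers
the simulated isoform composition to within ~0.015 absolute at the
default 1% noise.

For a full synthetic study — 9 normal + 9 NASH samples with stacks,
replicate electropherograms, group statistics and the two cohort heat
maps — see `generate_cohort()` and `full_report()`; the methods vignette
(`vignettes/hepatoquant-methods.Rmd`) documents the models, defaults and
numerical choices.

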