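# callusHisto

Quantitative histomorphometry for longitudinal sections of healing
long-bone osteotomies, with a local **new Bone Density (nB.Dn)** map that
quantifies not just how much bone a fracture callus contains, but how
compactly it is arranged.

The package is written for researchers analysing pre-segmented histology:
the input is a tissue-label raster (one integer per pixel: background,
cortical bone, new bone, cartilage, fibrous tissue, marrow) plus a small
metadata sidecar (pixel resolution, osteotomy-gap centre, anatomical
orientation, animal/group identity). From that it

* constructs the **callus ROI**: all newly formed tissue within ±15 mm of
  the gap centre along the bone axis, excluding original cortical bone,
  background, and marrow open to the medullary canal (enclosed fibrous
  pockets are kept), then splits it into anterior and posterior halves;
* measures the classical morphometry per region — callus area `Cl.Ar`,
  new-bone area `nB.Ar`, cartilage area `Cg.Ar` (mm²) and the area
  fractions `nBV/TV`, `CgV/TV` (%); anterior + posterior = total holds
  exactly because all logic runs in integer pixel counts;
* computes the **nB.Dn map**: for each callus pixel `p`,

  ```
  nB.Dn(p) = |NEW_BONE ∩ ROI ∩ D(p)| / |ROI ∩ D(p)|
  ```

  where `D(p)` is the Euclidean disk of radius 0.8 mm, classified
  low (< 0.33), medium (0.33–0.66) or high (> 0.66); the three class areas
  partition `Cl.Ar` exactly;
* fits the study-level **linear mixed models**
  (`value ~ group * region + (1 | animal_id)`, REML, Satterthwaite
  F-tests; an animal-by-class random level for density compositions);
* generates **synthetic sections and studies with known ground truth**, so
  the whole pipeline is testable without any data download;
* writes report CSVs, false-colour overlays (low = red, medium = turquoise,
  high = light blue) and a machine-readable run manifest.

## Worked example

```r
library(callusHisto)

g   <- generateSection(sectionConfig(seed = 42, profile = "treatment"))
roi <- splitAnteriorPosterior(buildROI(g$section), g$section)

measureSection(g$section, roi)[, c("region", "Cl.Ar", "nB.Ar", "Cg.Ar",
                                   "nBV/TV", "CgV/TV")]
#>      region Cl.Ar  nB.Ar Cg.Ar nBV/TV CgV/TV
#> 1  anterior 146.6 101.81 4.578  69.44  3.122
#> 2 posterior 107.9  70.86 2.787  65.67  2.583
#> 3     total 254.5 172.67 7.364  67.84  2.893

dres <- densityAnalysis(g$section, roi)
ca <- classAreaTable(dres)
ca[ca$region == "total", ]
#>   region  class    px   area percent
#> 7  total    low  3136  13.94   5.476
#> 8  total medium 18217  80.96  31.811
#> 9  total   high 35914 159.62  62.713
```

The synthetic treatment-like section carries a 254.5 mm² callus, 172.7 mm²
of it new bone (nBV/TV 67.8%), with more bone anteriorly than posteriorly —
and its local density composition (5.5% low / 31.8% medium / 62.7% high)
says that the bone is predominantly compact, the quality information the
scalar nBV/TV cannot express. `writeOverlay()` renders the same class map
as a false-colour image over the tissue palette.

Study-level inference runs on per-animal tables:

```r
tab <- generateStudy(studyConfig(seed = 7))   # 5 groups, 6/6/7/8/4 animals
fitAreaModel(tab)                             # group, region, interaction F-tests
```

A full batch — sections in, CSVs/overlays/models/manifest out — is one
call: `runPipeline("run.yaml")` (see `?readRunConfig` for the YAML schema),
or from a shell via `inst/scripts/callus.R`.

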