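# bearcond

Noninvasive monitoring of brown bears (*Ursus arctos*) often rests on two
data streams that never touch the animal: scats, which record what the bears
ate, and lateral photographs, which record how their body condition changes
through the season. `bearcond` implements both analysis chains and the model
that links them, for wildlife nutritional ecologists working with this kind
of long-term monitoring data:

1. **Diet quantification from scats.** Point-frame counts on washed scat
   material give each food item's *occupancy* (its share of counted grid
   intersections), used as the volumetric proportion. Because food items
   differ enormously in digestibility, volumetric shares are corrected with
   literature-derived correction factors: the **estimated dietary content**

   `EDC_i = 100 · V_i · CF_D,i / Σ_j V_j · CF_D,j`

   (ingested dry matter) and the **estimated digestible-energy content**

   `EDEC_i = 100 · V_i · CF_D,i · CF_E,i / Σ_j V_j · CF_D,j · CF_E,j`,

   both renormalized over food items after excluding nonfood material (and
   grooming hair at ≤ 0.5 % per scat). Scat inclusion follows the ≥ 200-point
   rule with the salmon exception (salmon digests almost completely, so
   salmon-bearing scats are kept when wet weight ≥ 50 g). Visually estimated
   percent fecal volumes (vFV) from years without laboratory analysis are
   made EDC-equivalent by per-category through-origin regression
   (slope = Σxy/Σx²). Years are classified as high or low consumption years
   by whether August pine-nut and September salmon EDC strictly exceed their
   all-year means.

2. **Photogrammetric body condition.** Graded lateral photographs (any
   attribute scored 3 = discard) are rectified by the ground angle; torso
   height **TH** (vertical abdomen-to-waist distance) and horizontal torso
   length **HTL** (horizontal tail-to-shoulder distance) are measured three
   times per photo, and **TH:HTL** — the body-condition index — is the ratio
   of replicate means. Session values (eight sessions per year, June = 1 …
   November = 6 with half-month steps in August–September) are medians over
   ≥ 2 photos; bear-years need ≥ 2 sessions, and sessions after an offspring
   loss are excluded.

3. **Seasonal condition models.** Thirteen candidate GAMMs of TH:HTL with a
   gamma family and log link: thin-plate regression splines of session
   (optionally one smooth per diet-year class or reproductive status), fixed
   effects for reproductive status and diet-year class, and crossed random
   intercepts for year and bear. Candidates are compared by AICc with Akaike
   weights `w_i = exp(-Δ_i/2)/Σ exp(-Δ_j/2)`; the package reports selection
   tables, smooth summaries (edf, approximate F and p) and population-level
   prediction curves with 95 % confidence bands.

A synthetic-study generator (`study_config()`, `gen_study()`) produces
complete studies — Dirichlet-multinomial scats distorted by inverse
correction factors, photos with landmarks constructed from known TH:HTL
draws — with ground truth saved alongside, so every stage is testable
without field data.

## Worked example

```r
library(bearcond)

cfg <- study_config(seed = 1)          # a 7-year, 12-bear synthetic study
gen_study(cfg, "study")                # scats.csv, taxonomy.csv, photos.csv, repro.csv, truth.json

pcfg <- pipeline_config(
  scats = "study/scats.csv", taxonomy = "study/taxonomy.csv",
  photos = "study/photos.csv", repro = "study/repro.csv",
  out_dir = "out", seed = 1)
res <- run_pipeline(pcfg)
res$year_classes
```

```
  year pine_edc salmon_edc pine_high salmon_high diet1 diet2
1 2012     16.3       8.36     FALSE       FALSE FALSE  TRUE
2 2013     46.6      54.06      TRUE        TRUE  TRUE FALSE
3 2014     48.7      21.42      TRUE       FALSE FALSE FALSE
4 2015     20.2      14.78     FALSE       FALSE FALSE  TRUE
5 2016     47.9      67.27      TRUE        TRUE  TRUE FALSE
6 2017     20.5      16.83     FALSE       FALSE FALSE  TRUE
7 2018     43.4      72.55      TRUE        TRUE  TRUE FALSE
```

`pine_edc` is each year's mean August pine-nut EDC recovered from the scats
(2012 via the vFV calibration); years above the mean on both foods are
`diet1` (high-consumption) years. The model stage then ranks the candidates:

```r
head(as.data.frame(res$selection), 3)
```

```
                                                      model  aicc  delta    weight
1 s(session,by=diet1) + status * diet1 + re(year) + re(id) -3099   0.00 1.000e+00
2 s(session,by=diet2) + status * diet2 + re(year) + re(id) -3031  68.94 1.071e-15
3                  s(session) + status + re(year) + re(id) -2981 118.94 1.486e-26
```

The data-generating specification (separate session smooths per diet-1
class) wins decisively, and its reproductive-status coefficient
(−0.0277 ± 0.0028 on the log scale, from `res$estimates`) recovers the
generator's −0.025 offset: females with dependent young run about 2.5 %
lower TH:HTL. The seven outputs (diet summary, annual EDC series, year
classification, observations, selection, estimates, prediction curves) are
written as CSV with a provenance header.

A thin CLI wraps the same functions:

```sh
Rscript exec/bearcond simulate --out study --seed 1
Rscript exec/bearcond report --scats study/scats.csv --taxonomy study/taxonomy.csv \
  --photos study/photos.csv --repro study/repro.csv --out out --seed 1
```

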