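# kinophore

Structure-based pharmacophore screening and type-II kinase-inhibitor
profiling in R.

Type-II kinase inhibitors bind the inactive (DFG-out) kinase
conformation and hydrogen-bond simultaneously to the ATP-site *front
pocket* (for VEGFR-2: Glu917, Cys919) and the allosteric *back pocket*
(Glu885, Asp1046). `kinophore` implements the virtual-screening funnel
built around that idea, for computational chemists who want each stage
as a testable, scriptable component:

* **Pharmacophore perception** — HBD/HBA/HyP features from a ligand's
  chemistry or complementarily from a receptor binding site (residues
  within a 10 Å radius of the bound ligand), model enumeration and
  deterministic ranking.
* **3D matching** — tolerance-constrained correspondence search with
  optimal rigid superposition (Kabsch); fit = max(0, 1 − RMSD/mean
  tolerance).
* **Validation** — Güner–Henry decoy-set statistics and ROC/AUC. For a
  database of `D` molecules with `A` actives, a screen retrieving `Ht`
  hits of which `Ha` are active gives

  ```
  EF = (Ha·D)/(Ht·A)
  GF = [Ha·(3A+Ht)/(4·Ht·A)]·[1 − (Ht−Ha)/(D−A)]   (and the (3Ha+Ht) variant)
  ```

  Both goodness-of-fit numerator conventions are computed and reported
  side by side, because they disagree whenever `Ha < A`.
* **Drug-likeness** — Lipinski Rule-of-5 profiling (strict `<` by
  default, classic `≤` on request).
* **Interaction profiling** — geometric detection of hydrogen bonds
  (< 3 Å), π–π stacked/T-shaped, π–cation, π–σ, π–alkyl, alkyl–alkyl,
  sulfur–X and van der Waals contacts, and the back-to-front verdict
  that selects type-II candidates.
* **Synthetic data** — seeded, cross-platform-deterministic generators
  for matching/decoy ligands, labelled libraries with planted confusion
  counts, and mini-complexes with contacts planted at exact distances.

Docking and molecular dynamics are out of scope; docked poses are
consumed as PDB inputs by the profiling stage.

## Worked example

```r
library(kinophore)

model <- vegfr2_reference_model()          # 2x HBD, 2x HyP, 1x HBA
spec  <- library_spec(D = 720, A = 24, planted_Ht = 26, planted_Ha = 23,
                      seed = 42)
lib   <- make_library(model, spec)         # 720 labelled 3D molecules
report <- validate_model(model, lib)       # screen + count + metrics
print(report)
```

```
Guener-Henry decoy-set validation
  Database (D) 720 | actives (A) 24 | hits (Ht) 26 | active hits (Ha) 23
  % yield of actives      88
  % ratio of actives      95.8
  Enrichment factor (EF)  26.53
  False negatives (A-Ha)  1
  False positives (Ht-Ha) 3
  Goodness of fit: 0.87 [(3Ha+Ht) numerator] vs 0.90 [(3A+Ht) numerator]
  (both GF numerator conventions are reported; see ?gh_metrics)
  ROC AUC                 0.976
```

Reading: of 720 screened molecules the model retrieved 26, of which 23
are true actives — 88% of the hit list is active (yield), 95.8% of all
actives were recovered (ratio), and actives are 26.5-fold enriched in
the hit list over the database background rate. The two goodness-of-fit
numbers are the two numerator conventions of the same formula.

Profiling a docked pose and asking the type-II question:

```r
cx  <- read_structure("pose1.pdb", "pdb")      # receptor + ligand
row <- interaction_table(cx, pocket = vegfr2_pocket())
as.data.frame(row)       # H-bonds with distances, pi partners, vdW, verdict
row$verdict              # back-to-front TRUE/FALSE
```

A thin command-line front end lives in `inst/scripts/phore.R`
(`screen`, `validate`, `druglike`, `profile`, `synth`, `run`
subcommands); `run_pipeline()` executes the whole funnel from a single
config and writes `funnel.json`, `hits.csv`, `validation.json` and
`interactions.csv`.

## Package layout

```
R/                      implementation (io, pharmacophore, screening,
                        validation, druglikeness, interactions,
                        synthetic generators, pipeline)
tests/testthat/         unit, property and acceptance tests
scripts/acceptance.R    headline-number reproduction
inst/scripts/phore.R    command-line front end
vignettes/              methods vignette
```
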