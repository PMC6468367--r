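---
title: "Structure-based pharmacophore screening with kinophore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-based pharmacophore screening with kinophore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinophore)
```

## The problem

Type-II kinase inhibitors bind the inactive (DFG-out) conformation of a
kinase and engage two sub-sites at once: the ATP-site *front pocket*
(for VEGFR-2, hinge residues Glu917 and Cys919) and the adjacent
allosteric *back pocket* (Glu885 and Asp1046). A structure-based
pharmacophore condenses the geometry of a known inhibitor's interactions
with these residues into an abstract 3D query — hydrogen-bond donor
(HBD), acceptor (HBA) and hydrophobic (HyP) features with spherical
tolerances — that can be matched against large ligand libraries far more
cheaply than docking. `kinophore` implements this funnel end to end:
feature perception, model ranking, tolerance-based 3D matching,
decoy-set and ROC validation, Rule-of-5 filtering, and geometric
interaction profiling of docked poses with a back-to-front verdict.
Docking itself and molecular dynamics are deliberately out of scope;
docked poses are *inputs* to the profiling stage.

## Feature perception

Ligand-side perception uses fixed, documented chemistry:

* **HBD** at every N, O or S carrying at least one hydrogen (explicit,
  or inferred from standard valences on request);
* **HBA** at every O that is not positively charged, and at every N with
  an available lone pair — not positively charged, not amide-like, and
  for aromatic nitrogens only the pyridine type;
* **HyP** at the centroid of every aromatic ring and of every connected
  cluster of three or more aliphatic carbons with no attached
  heteroatom.

Receptor-complementary perception images the pocket onto the ligand
side: opposite every receptor acceptor an HBD feature is placed 2.9 Å
toward the ligand (the canonical hydrogen-bond length), with the
receptor atom recorded as the feature's projected point; donors are
mirrored symmetrically as HBA features; hydrophobic residue sidechains
facing the ligand contribute HyP features at their carbon-cluster
centroids. Receptor polar atoms are identified from residue/atom-name
conventions, so crystal structures without explicit hydrogens work.

Default tolerances are 1.6 Å for polar features and 1.7 Å for
hydrophobes — ordinary pharmacophore practice; both are arguments, not
constants. Candidate models are all feature subsets of a chosen size
range (default 4–5) whose features are pairwise at least 2 Å apart (to
exclude degenerate overlapping features), ranked by a *selectivity
heuristic*: each feature contributes a kind prior (HBD 2.0, HBA 2.0,
HyP 1.5) plus 0.1 × the mean interfeature distance. This score is an
openly documented package heuristic. It is **not** a reimplementation of
any vendor selectivity score, and no specific published selectivity
value is asserted anywhere; only its ordering behaviour matters, and the
test suite pins exactly the ordering that matters in practice: larger
models outrank their submodels, and wider-spread models outrank tighter
ones of equal composition.

## Matching and scoring

`map_ligand()` searches injective, kind-compatible assignments of
perceived ligand features to model features. An assignment is feasible
when every pairwise ligand distance agrees with the model's interfeature
distance within the sum of the two features' tolerances; among feasible
assignments the minimum-RMSD one (optimal rigid superposition, Kabsch)
wins, with exact ties broken lexicographically so results are
bit-for-bit reproducible. All model features must be matched — partial
mappings are rejected, mirroring the use of complete five-feature
matches to select hits. The fit score is
`max(0, 1 − RMSD / mean tolerance)`.

Matching is single-conformer by design: conformer generation is the
caller's concern, and the synthetic generators control geometry
directly. The distance-window pruning and the superposition step are
verified against a brute-force permutation oracle in the tests.

## Validation

`gh_metrics()` implements the Güner–Henry decoy-set statistics for a
database of `D` molecules containing `A` actives, from which a screen
retrieves `Ht` hits including `Ha` actives: % yield `100·Ha/Ht`,
% ratio `100·Ha/A`, enrichment factor `EF = (Ha·D)/(Ht·A)`, false
negatives `A−Ha`, false positives `Ht−Ha`, and the goodness-of-fit
score. The GF definition circulates with two numerators,

$$GF = \frac{Ha\,(3A+Ht)}{4\,Ht\,A}\Bigl(1-\frac{Ht-Ha}{D-A}\Bigr)
\qquad\text{vs.}\qquad
GF = \frac{Ha\,(3Ha+Ht)}{4\,Ht\,A}\Bigl(1-\frac{Ht-Ha}{D-A}\Bigr),$$

which disagree whenever `Ha < A`. On the canonical worked example
(D = 720, A = 24, Ht = 26, Ha = 23) they give 0.90 and 0.87. Because the
typesetting of the defining equation is frequently ambiguous, both
variants are always computed and reported side by side; the report never
silently picks one. Display values follow the conventional reporting
style (yield floored, ratio truncated to one decimal, EF truncated to
two, GF rounded to two); raw full-precision values are always retained.

```{r}
print(gh_metrics(decoy_counts(D = 720, A = 24, Ht = 26, Ha = 23)))
```

`roc_curve()` is a standard threshold sweep; its trapezoid AUC equals
the Mann–Whitney pair statistic with ties counted ½ (asserted to 1e-12
in the tests). Published AUC values for specific compound sets are not
asserted, because those compound identities are not available;
calibration is checked instead on a null simulation (scores independent
of labels), where the mean AUC must sit near ½ and the mean top-10%
enrichment near 1.

## Drug-likeness

`ro5_profile()` computes molecular weight (standard atomic weights,
implicit hydrogens counted when the structure carries none), a fixed
atom-additive logP estimate (documented element-level contribution
table, Crippen-like in spirit), donors as N–H/O–H hydrogens, acceptors
as the classic Lipinski N+O count, and rotatable bonds as non-ring
single bonds between non-terminal heavy atoms with amide C–N excluded.
All five rules are applied as strict `<` by default — following the
wording "less than" for every threshold — with a `strict = FALSE` flag
restoring the classic non-strict reading. A molecular weight of exactly
500 Da therefore *fails* under the default. The occasionally seen
"500 kDa" phrasing is read as the universal 500 Da threshold (a typo, as
no small molecule weighs 500 kDa). Vendor ADMET models are deliberately
not implemented — they have no published equations; the pipeline accepts
an external ADMET table instead of pretending to predict one.

## Interaction profiling

Contacts are classified geometrically, with mutually exclusive
categories per (receptor unit, ligand unit) pair and the precedence
hydrogen bond > π classes > van der Waals:

| category | window (defaults) |
|---|---|
| hydrogen bond | heavy-atom D…A < 3.0 Å; D–H…A ≥ 120° when H explicit |
| π–π stacked | centroid ≤ 5.5 Å, interplanar ≤ 30° |
| π–π T-shaped | centroid ≤ 6.0 Å, interplanar 60–120° |
| π–cation | cation to centroid ≤ 6.0 Å |
| π–σ | C–H carbon to centroid ≤ 4.0 Å, H aimed at the ring |
| π–alkyl | aliphatic C (or Cys/Met S) to centroid ≤ 5.5 Å |
| alkyl–alkyl | closest aliphatic cluster pair ≤ 5.5 Å |
| sulfur–X | divalent S to partner ≤ 3.6 Å |
| van der Waals | residue heavy atom ≤ 4.0 Å, no other record |

The windows are package defaults chosen to bracket the distance ranges
conventionally reported for each class in kinase-inhibitor interaction
tables (π–alkyl ≈ 3.6–5.4 Å, π–cation ≈ 3.1–4.3 Å, π–σ ≈ 2.6–3.7 Å,
π–π ≈ 4.6–5.1 Å, sulfur–X ≈ 3.2 Å); every cutoff is a function argument.
A static test audits that all such reported distances fall inside their
category windows. Hydrogen-bond records always carry the heavy-atom
distance and, when the donor hydrogen is explicit, the H…A distance as
well, because published tables mix both conventions; the table writer
takes a flag. π rings are perceived from aromatic bonds when present,
else from residue templates (Phe/Tyr/His/Trp), with plane fit by SVD.

`classify_type2()` partitions hydrogen bonds by front/back pocket
membership (defaults Glu917/Cys919 vs Glu885/Asp1046, configurable for
other kinases) and declares a pose back-to-front iff both partitions are
nonempty — the selection rule for type-II candidates. The full 16-entry
presence truth table is tested.

## Synthetic data: what it emulates and what it does not

The generators produce every input the pipeline needs, deterministically
from a seed via the package's own Lehmer (MINSTD) stream — never R's
session RNG, so output is byte-identical across platforms and sessions.

* `make_matching_ligand()` places one valence-complete group per model
  feature (hydroxymethyl → HBD, dimethyl ether → HBA, benzene → HyP) so
  perceived centroids land exactly on the model; jitter displaces each
  group by at most the requested amount, which bounds the superposition
  RMSD by the jitter itself.
* `make_decoy_ligand()` guarantees a non-match either by dilating the
  geometry until every pairwise distance leaves every tolerance window
  by more than 3 Å, or by removing a feature kind entirely (donors
  become protonated ammonium groups so no incidental acceptor survives).
* `make_library()` plants exact confusion counts: `planted_Ha` actives
  and `planted_Ht − planted_Ha` inactives as matchers, everything else
  as decoys, shuffled by the seed. The default emulation target is the
  canonical decoy-set experiment: D = 720, A = 24 actives, with 26
  retrieved hits of which 23 are active. The default jitter of 0.15 Å
  keeps matchers comfortably inside the tolerance windows while
  exercising non-zero RMSD paths.
* `make_toy_complex()` lays planted contacts out in separate angular
  sectors on a 10 Å circle, far enough apart that no cross-sector pair
  can enter any default detection window, and realises every planted
  distance exactly. Hydrogen-measured H-bonds beyond 2.2 Å are rejected
  as infeasible (they cannot satisfy the heavy-atom < 3 Å and angle
  ≥ 120° criteria simultaneously), as are π–alkyl plants inside the π–σ
  window.

What the synthetic data does **not** emulate: real conformational
flexibility, property-matched decoys (DUD-E style), tautomers and
protonation ensembles, or crystallographic noise. Passing tests
demonstrate the correctness of the geometry, counting and scoring
machinery under controlled conditions — not retrieval performance on a
commercial library, which depends on inputs outside the package.

## Numerical choices

* Coordinates are Å throughout; no nm conversion exists anywhere.
* Residue identity is (chain, author number, 3-letter name); insertion
  codes are rejected loudly, altlocs resolved by highest occupancy.
* Exact RMSD ties in matching are broken by lexicographic assignment
  order; reflection is excluded in the Kabsch step by sign correction.
* The pharmacophore JSON writer emits full-precision numbers; the
  round-trip identity is tested to 1e-9 Å.
* Degenerate inputs error early and by name: empty libraries, Ht = 0 or
  A = 0 or D = A in the metrics, one-class ROC input, models outside
  3–7 features.

## Problem sizes used by the test suite

The acceptance-level checks run the full 720-compound emulation once
(about ten seconds), a 100-transform invariance sweep, a 50-ligand
brute-force oracle comparison, 100 random ROC sets and a 1000-replicate
null calibration at D = 200 — sizes chosen so the entire suite
exercises every advertised property in well under a minute of compute
while keeping each oracle genuinely independent of the code it checks.

## Known limitations

* LogP is an element-level additive estimate, adequate for rule gating
  on synthetic chemistry, not a substitute for a fitted fragment model.
* Aromaticity is taken from the input (aromatic bond orders or residue
  templates); no electron-counting perception is attempted.
* Single-conformer matching means a flexible molecule mis-posed by its
  conformer generator will be missed; that trade-off is the caller's.
* The interaction profiler reports geometry, not energetics; halogen
  bonds and water-mediated bridges are not classified.
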