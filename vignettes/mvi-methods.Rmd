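---
title: "Methods: how the MVI/CMSP scoring engine works"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: how the MVI/CMSP scoring engine works}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mvindex)
```

## Scope and model

`mvindex` implements a rule-based ordinal scoring framework for
postmortem case evaluation: five physiologic domains (hepatic CYP450
capacity, cytokine load, redox balance, neurochemical integrity,
xenobiotic/metal burden) each scored 0–3, a total over scorable domains
(maximum 15), a mechanistic archetype assigned from the pattern of
non-zero scores, and two interpretive summaries (CMSP Core; vitreous
glucose/β-hydroxybutyrate pattern) that never feed back into scoring.
The engine is deliberately free of estimation: every output is a
deterministic function of the case record and a versioned reference set.
It makes no diagnostic, causal or certification statement of any kind.

The coarse 0–3 ordinal scale is a design commitment, not a limitation to
be refined away: postmortem degradation, platform variability and
biologic spread make continuous severity scores falsely precise, so each
domain reports only a severity *tier* with an auditable basis.

## Specimen validity gating

Every anchor measurement is gated by its specimen's postmortem interval
(PMI, hours between death and collection) before scoring. Liver (CYP and
redox), femoral blood (cytokines) and kidney cortex (corroborative
redox) share a best-within target of 24 h and a maximum sampling PMI of
48 h; vitreous humor extends to 72 h. The gate is three-state:

* `optimal` — PMI strictly below the best-within target (exclusive at
  24 h, mirroring the printed "<24 h");
* `acceptable_flagged` — between best-within (inclusive) and the maximum
  (inclusive, mirroring "≤48 h" / "≤72 h"): scorable, but the report
  carries a flag;
* `NS` — beyond the maximum, or specimen never collected; always with a
  reason.

We kept the flagged middle band rather than collapsing to scorable/NS
because the two printed columns carry information a reviewer wants; no
numeric down-weighting is applied in that band since the framework
specifies none. An NS domain is excluded from the total *and* from the
denominator: the report prints `total / (3 × scorable domains)` so that
missing specimens never deflate apparent severity. This denominator
handling is our choice where the framework specifies NS reporting but
not arithmetic.

## Domain 1: two-step CYP normalization

Domain 1 prevents the classic confound of reading physiologic immaturity
as pathologic suppression by normalizing twice:

1. **%Adult** — the measured value is divided by the adult reference
   scalar: for protein abundance (pmol/mg), the adult mean (CYP3A4 85.8,
   CYP2D6 7.90, CYP2C19 5.02, CYP3A5 4.00); for probe activity
   (pmol/min/mg), the midpoint of the published adult range (e.g.
   CYP3A4 400 from 350–450), since only ranges are published for
   activity.
2. **Age-matched tier** — the %Adult value is compared with the
   developmental expectation for the isoform, measure and age bin.
   Printed tier ranges such as "48–59%" are realized as half-open
   intervals keyed by their lower edges — normal `[60, ∞)`, mild
   `[48, 60)`, moderate `[42, 48)`, severe `[0, 42)` — which resolves
   the integer-gap ambiguity (59.5% is mild) and makes a value exactly
   at the printed minimum grade normal.

Age-bin labels overlap at their printed edges ("1–2 months",
"2–3 months"); we realize them as half-open day intervals partitioning
`[0, ∞)`: `[0,8)`, `[8,31)`, `[31,61)`, `[61,91)`, `[91,183)`,
`[183,366)`, `[366,∞)` (and `[0,31)` / `[0,366)` for the tables printed
with "0–4 weeks" / "0–12 months" rows). This is a calendar-month
approximation chosen once for determinism. The CYP3A5 protein table
prints only an infancy row; we add a `[366,∞)` row marked non-gradable
(no tiers exist to grade against) so the partition property holds for
every table.

Rows where an isoform's capacity is physiologically near zero (e.g.
CYP3A4 in the first week) are non-gradable: the isoform is simply
excluded. CYP3A5 non-expressors (\*3/\*3) are *genotype-zeroed* —
recorded but never graded, contributing a physiologic 0 regardless of
the measured value over any range; unknown or indeterminate genotype is
graded as an expressor, as the reference tables direct.

Protein abundance is the primary, postmortem-stable anchor. Probe
activity substitutes for an isoform only when no protein value exists
and the assay is QC-qualified; when both exist the activity value is
reported as corroboration only. The domain ordinal aggregates gradable
isoforms by the **maximum (worst) tier**. The framework is silent on
aggregation; we use the maximum because reserve limitation is driven by
the most-affected clearance pathway and it is the only symmetric choice
that preserves the 0–3 codomain without introducing weights the
framework explicitly disclaims. Any single gradable isoform suffices for
a scorable Domain 1; if none is gradable at the age, the domain is NS.
A plausibility flag (above 150 %Adult, or above the printed adult
maximum) marks implausible inputs for review but never alters a score.

One documented inconsistency: the framework's design-rationale table
describes CYP thresholds "set at 75/50/25%", which does not match the
tier arithmetic of the printed developmental tables (tiers are defined
as <20% / 20–30% / >30% below the age minimum). The tables are
authoritative and are implemented as printed; the 75/50/25 description
is treated as narrative.

## Domains 2–5

IL-6 (pg/mL), CRP (mg/L), F2-isoprostane fold, vitreous BHB and glucose
(mmol/L) are binned by fixed edges (30/80/300; 10/40/150; 1/2/4;
2.5/5/10; 10/15/25) with **lower-inclusive closure**: a value exactly on
a shared printed edge falls in the lower bin, matching the explicit "≤"
of the normal column and keeping the bin function total and monotone on
`[0, ∞)`. Domain 2 is the maximum of the available cytokine bins
(either marker alone is sufficient evidence; the framework prints
per-marker bins but no combination rule). Domain 3 scores the liver
fold by default; a kidney-cortex value is scored when no liver value
exists but flagged as corroborative tissue only (flagged, not
down-scored — the framework does not quantify a penalty). The fold may
be supplied directly, or as a raw ng/g value when the laboratory has
configured its reference concentration.

Domains 4 and 5 carry no printed bin tables; their ordinals are
adjudicated from the anchor workups (brainstem neuropathology ±
SERT/TPH2 IHC; comprehensive toxicology ± ICP-MS metals) and enter the
engine as validated pass-through values with a required basis string.

## Archetype assignment

The support (domains scoring ≥ 1, NS excluded) is one of 31 non-empty
subsets, each mapped to one of 14 core archetypes; referral rows resolve
combinations without their own archetype to a core one while documenting
domain 4 as *modifier* and domain 5 as *exposure context/modifier*. The
map is total and every referral resolves in one hop (the printed rules
never chain). Conditional rows follow the printed strict inequalities:
cytokine + neurochemical + xenobiotic resolves to the isolated
xenobiotic archetype only when the domain 5 score strictly exceeds
domain 2 (ties stay with the cytokine archetype, as printed); the
neurochemical + xenobiotic pair goes to whichever side is dominant, and
on a tie — a case the framework leaves open — we assign the
neurochemical archetype (lower domain number) with the other as
modifier plus an explicit dominance note, a deterministic and auditable
convention. An NS core domain is excluded from the support and the
assignment proceeds with an interpretive-limitation flag, because the NS
rules require reporting, not abortion of the case.

## CMSP Core and vitreous context

CMSP Core is the unweighted sum (0–9) of the IL-6, CRP and redox
ordinals, labelled minimal (0–1), mild (2–4), moderate (5–7), severe
(8–9). The framework presents the bins but not the combination formula;
the sum is the minimal symmetric choice and the result is labelled an
interpretive summary, never an input to anything. The vitreous pattern
(minimal deviation / stress hyperglycemia / ketosis / mixed
dysregulation / indeterminate) is a pure function of the two vitreous
bins; the printed NS row keys on BHB, and we apply NS handling
symmetrically — either marker NS yields indeterminate rather than
interpreting a half-scorable pair. Non-interference is asserted
end-to-end in the test suite: perturbing vitreous values or validity
across seeded cases never moves a domain score, the total, or the
archetype.

## Synthetic case generator

`generate_case()` inverse-bins a target score vector into measured
values: each value is placed in the central 70% of its target tier's
interval (never on a shared edge, so round trips are robust to the
closure convention), and NS targets are produced by placing the relevant
specimen's PMI beyond its maximum window rather than deleting values —
exercising the gate, not bypassing it. Domain 1 targets are driven
through a CYP3A4 protein measurement; a target at a non-gradable age is
a generation error, mirroring the framework. When exactly one of
Domains 1 and 3 is targeted NS, the redox measurement moves to kidney
cortex so the shared liver PMI cannot couple the two domains.
`generate_cohort()` cycles coverage cohorts through all 31 support
subsets. The generator is a structural fixture: it emulates the
framework's decision surface (age bins, genotype branches, validity
states, tier placement), not the joint biologic distribution of the
analytes — passing round-trip tests demonstrates the engine's logic on
all reachable paths, not calibration against real case material, of
which the framework itself provides none.

## Problem sizes and numerical conventions

The test suite exercises: the full 4^5 = 1024 score-vector grid through
the complete pipeline; 0.1-percentage-point sweeps of %Adult over
`[0, 120]` for every gradable age bin of all eight developmental tables
against an independently transcribed oracle; every printed bin edge at
±1e-9; the 16-cell vitreous truth table; 1,000 seeded round-trip cases
and 1,000 vitreous-perturbation pairs; and 31-case coverage cohorts.
All comparisons of scores are exact (integer); the only tolerances in
the package are the epsilon probes at bin edges. Reports serialize with
stable field order and full precision, so identical inputs give
byte-identical JSON; reference sets carry a version string (with a
content hash when laboratory overrides are active) in every report.

## Known limitations

* Domains 4 and 5 are only as good as their adjudication; the engine
  validates but cannot audit them.
* The day boundaries of calendar age bins, the max aggregation in
  Domains 1–2, the CMSP sum, and the neurochemical-tie convention are
  package conventions where the framework is silent; each is documented
  above and in the function help.
* No analyte decay, temperature or storage modelling: PMI gating is the
  only validity mechanism, as specified.
* Laboratory overrides extend only to adult references and the redox
  reference; a laboratory whose platform disagrees with the framework's
  tier fractions or bin edges cannot (by design) express that here.
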