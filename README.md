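# mvindex

Deterministic scoring engine for the **Metabolic Vulnerability Index
(MVI)** and the **Cytokine-Metabolic Suppression Profile (CMSP)** — a
rule-based framework for characterizing multidomain physiologic constraint
in postmortem (chiefly pediatric/forensic) case evaluation.

It is written for forensic pathology and laboratory-medicine workflows in
which a data analyst must turn a heterogeneous panel of postmortem
measurements — hepatic CYP450 protein abundance or probe activity, femoral
IL-6 and CRP, tissue F2-isoprostanes, vitreous glucose and
β-hydroxybutyrate, adjudicated neuropathology and toxicology findings —
into a reproducible, auditable ordinal summary. The engine contains no
statistics to fit and no diagnostic or cause-of-death logic: every score
is a deterministic function of the measurements and a versioned table of
framework constants.

## The index

Five domains are each scored on an ordinal 0–3 scale
(normal / mild / moderate / severe):

| Domain | Anchor measure | Role |
|---|---|---|
| 1 CYP450 capacity | hepatic CYP3A4/2D6/2C19/3A5 protein abundance (activity when QC-qualified) | core |
| 2 Cytokine load | femoral IL-6 (pg/mL), CRP (mg/L) | core |
| 3 Redox balance | tissue 8-iso-PGF2α fold over laboratory reference | core |
| 4 Neurochemical integrity | brainstem neuropathology ± SERT/TPH2 IHC (adjudicated) | modifier |
| 5 Xenobiotic/metal burden | comprehensive toxicology ± ICP-MS metals (adjudicated) | modifier |

The **MVI total** is the sum of scorable domain ordinals, reported against
a denominator of 3 × (number of scorable domains), so the maximum is 15
when everything is scorable. Domain 1 uses a *two-step normalization*: a
measured value is first expressed as %Adult against the adult reference
(protein: the adult mean; activity: the midpoint of the adult range), then
graded against the age-matched developmental expectation for its isoform,
so physiologic immaturity is never misread as suppression. CYP3A5
non-expressors (*3/*3) are genotype-zeroed: never graded, physiologic
score 0. Each specimen is gated by its postmortem interval (PMI) before
anything downstream is scored; measurements outside the sampling window
are **NS (not scorable)** with an explicit reason, and NS domains shrink
the denominator instead of being imputed as zero.

The pattern of non-zero domain scores (its *support*, one of 31 non-empty
subsets) maps to one of **14 mechanistic archetypes** — e.g. #6
immune-mediated phenoconversion, #11 Core-Multi-Axis Metabolic Collapse —
either directly or through referral rules that document domain 4 as a
modifier and domain 5 as exposure context. Two referrals compare scores
(neurochemical vs xenobiotic dominance; xenobiotic exceeding cytokine).
The **CMSP Core** (sum of the IL-6, CRP and redox ordinals, 0–9) and the
vitreous glucose/BHB contextual pattern are interpretive summaries only:
they never feed back into domain scores, the MVI total, or the archetype.

## Worked example

```r
library(mvindex)
ref  <- load_reference_set()
case <- generate_case(c(3, 2, 2, 1, 2), age_days = 200, seed = 42, ref = ref)
compute_mvi(case, ref)
```

```
=== MVI report: case 'SYN-42' ===
Domain 1 (CYP450 capacity, core): 3
Domain 2 (Cytokine load, core): 2
Domain 3 (Redox balance, core): 2
Domain 4 (Neurochemical integrity, modifier): 1
Domain 5 (Xenobiotic/metal burden, modifier): 2
MVI total: 10 / 15 scorable
Archetype #11: CYP + cytokine + redox (Core-Multi-Axis Metabolic Collapse)
  core domains: 1, 2, 3
  modifiers: D4 (modifier); D5 (exposure_context/modifier)
  referral: {all five domains} -> #11; neurochemical as modifier, xenobiotic/metal as exposure context
CMSP Core: 6/9 (moderate) [IL-6 2, CRP 2, redox 2]
Vitreous context: ketosis (glucose 1, BHB 3)
Reference set: builtin-1.0
```

The generated six-month-old case carries a CYP3A4 protein value in the
severe tier for its age bin (domain 1 = 3), IL-6/CRP in the moderate bins
(domain 2 = 2), an F2-isoprostane fold in the moderate bin (domain 3 = 2),
and adjudicated ordinals 1 and 2 — summing to MVI 10 of 15. With all five
domains non-zero, the combination refers to archetype #11 with domains 4
and 5 documented as modifier and exposure context. The vitreous ketosis
pattern is contextual and changes nothing upstream.

Real cases are built with `case_record()` or read from JSON/JSON-lines/CSV
via `read_cases()`; laboratory adult references can be overridden with
`load_reference_set(config = "lab.yaml")` (tier fractions, bin edges and
PMI windows are framework constants and cannot be overridden).

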