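---
title: "Rule-based Banff classification of kidney allograft rejection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based Banff classification of kidney allograft rejection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(banffdx)
```

## The problem

Assigning a Banff rejection category to a kidney allograft biopsy is a
rule-based exercise over a handful of ordinal lesion scores, yet the rules
have been revised so often that non-pathologists running retrospective or
multicentre studies struggle to apply them consistently across eras.
`banffdx` implements a deterministic classifier that maps one biopsy's
lesion scores (t, i, v, g, ptc, C4d, cg, cv, ci, ct, ptcbm, t-IFTA,
i-IFTA), donor-specific antibody (DSA) status and ABO compatibility to a
primary Banff category, together with the concordance machinery needed to
compare such automated calls against pathologist diagnoses.

Two points of clinical context shape the rule set:

* **ABO-incompatible grafts.** In living-donor programmes that cross blood
  group barriers, C4d deposition in peritubular capillaries is observed in
  the large majority of protocol biopsies without any rejection, so C4d
  positivity carries no diagnostic weight there. The engine treats C4d as
  evidence of antibody interaction only in ABO-compatible grafts.
* **Score-only classification.** The engine sees lesion scores, C4d, DSA
  and ABO status — not prior biopsies, treatment history or clinical
  impressions. It is a standardization tool, not a substitute for
  integrated expert diagnosis, and a fraction of disagreements with
  pathologists is expected and informative.

## The rule set

All lesion scores are ordinal 0–3; a missing score is distinct from 0 and
contributes no evidence (it is treated as 0 wherever a sum or threshold is
evaluated).

### Antibody-mediated rejection (AMR)

Let MVI = g + ptc. Two criteria must both hold:

1. **Histologic criterion** — g ≥ 1, or isolated peritubular capillaritis
   (ptc ≥ 1 with g = 0) unless one of two blocks applies:
   * *concurrent full TCMR*: an acute TCMR grade or the chronic active
     TCMR criterion holds, and it is **not** the case that C4d evidence and
     MVI ≥ 2 still point to antibody interaction. Isolated capillaritis in
     a florid T-cell infiltrate is attributed to the T-cell axis.
   * *ABO-incompatible without positive DSA*: isolated capillaritis in an
     ABO-incompatible graft with negative or unknown DSA is insufficient.
   Borderline tubulitis alone never blocks the criterion.
2. **Interaction criterion** — C4d evidence (C4d ≥ 2 in an ABO-compatible
   graft) or MVI ≥ 2.

When both hold: cg ≥ 1 gives **chronic active AMR** (ptcbm multilayering
alone is not chronicity); otherwise unknown DSA without C4d evidence gives
**equivocal AMR**; otherwise **active AMR**. Negative DSA does not veto the
diagnosis — C4d-negative, DSA-negative AMR by microvascular inflammation
alone was a recognised phenotype under the classification era these rules
implement.

### T-cell-mediated rejection (TCMR)

* **Acute grade**: v = 1/2/3 → IIA/IIB/III (vascular lesions dominate);
  otherwise i ≥ 2 with t = 2 → IA, with t = 3 → IB.
* **Chronic active**: i-IFTA ≥ 2 together with tubulitis — t ≥ 2 in
  preserved cortex, or t-IFTA ≥ 2 in the presence of established atrophy
  (ct ≥ 2). The ct ≥ 2 companion requirement is what separates genuine
  chronic active TCMR from inflammation confined to trivial scarring.
* **Borderline (BC)**: v = 0, no acute grade, and (t ≥ 1 with i ≤ 1, or
  i ≥ 2 with t = 1). Borderline permits i = 0: any tubulitis focus below
  the acute threshold qualifies.

### Composition and priority

The applicable set is the union of the AMR call, the TCMR findings (both
the acute grade and the chronic active criterion when both hold; BC only
when neither does), IFTA graded I–III by max(ci, ct), and C4d staining
without rejection (C4d ≥ 2, ABO-compatible, no rejection category and no
IFTA applicable; suppressed entirely in ABO-incompatible grafts). The
primary diagnosis is the highest-priority applicable category:

> A-AMR (equivocal folded in) → CA-AMR → A-TCMR → CA-TCMR →
> C-AMR-inactive → BC → IFTA → C4d-no-rejection → no-rejection

`C-AMR-inactive` is carried in the vocabulary and priority list for
completeness but no rule in scope emits it. Thrombotic microangiopathy is
accepted as input and carried into reports, but fires no rule: the engine
classifies *through* TMA on the lesion scores alone.

```{r}
classify_biopsy(banff_record("example", g = 1, ptc = 1, c4d = 2,
                             abo = "incompatible", hla_dsa = "-"))
```

## Calibration fixtures

Two packaged fixtures (`load_fixture("table1")`, `load_fixture("table2")`)
transcribe 49 published discrepancy biopsies — cases where a pathologist
and the automated system disagreed — with lesion scores, clinical flags,
the pathologist label and the recorded automated output. They are the
calibration and regression anchor for every rule above; several rule
boundaries (the C4d ≥ 2 threshold, both isolated-ptc blocks, the ct ≥ 2
companion in chronic active TCMR, cg-only chronicity) are fixed by
specific row pairs in these tables.

Fields the published rows omit are back-filled and documented in the
`assumed_fields` attribute: ABO/DSA in the second fixture (from the first
table for cross-listed patients; incompatible/negative for three rows
where that is the only assignment consistent with the recorded output;
compatible/negative by default elsewhere) and ci = ct = 1 for first-table
rows whose recorded output is IFTA, so that an IFTA grade exists. No
acceptance quantity depends on the ci/ct back-fill.

Two rows are flagged `known_deviation` and excluded from exact-match
regression. Record 104601 (compatible, t1, ptc2, C4d1, recorded IFTA)
is irreconcilable with record 104925 (compatible, t2, ptc2, C4d0,
recorded A-AMR) under any score-only rule — the engine calls A-AMR for
both. Record 105064 (isolated ptc2, cg 0, recorded CA-AMR) contradicts
cg-based chronicity; the engine calls A-AMR, a subtype-level deviation
only. All 47 remaining rows match the recorded output at the
AMR/TCMR/non-rejection level.

## Concordance analysis

`build_flow_table()` cross-tabulates canonical pathologist labels against
engine primaries (free-text non-rejection entities collapse into an
`other` bucket on the non-rejection side, mirroring how such cases are
counted in published cohort summaries). `agreement_rate()` reports four
strata — overall, non-rejection, rejection, and exact type within
pathologist-rejection cases — at full precision, rounding to one decimal
in percent only at print time. `cohen_kappa()` adds chance-corrected
agreement over the label union; kappa is an extension beyond the raw
rates and the report labels it as such. `discrepancy_records()` recovers
the two-panel per-family layout of the fixtures from any classified
cohort.

Note the fixtures are *discrepancy* tables: running the concordance module
on them yields near-zero agreement by construction, which is the expected
behaviour, not a defect.

## Synthetic cohorts

The unreleased source cohorts cannot ship with the package, so
`sample_cohort()` generates seeded synthetic ones. Design choices:

* **Rejection sampling against the real engine.** Scores are proposed
  from category-shaped ordinal distributions and accepted once
  `classify_cohort()` assigns the target category, so generated records
  are guaranteed to lie in their category's acceptance region whatever
  the current calibration — the generator can never drift out of sync
  with the rules.
* **Defaults.** The ABO-incompatible fraction defaults to 0.277, the
  proportion reported for a large Japanese living-donor biopsy series.
  Category prevalences default to ≈ 12% rejection mass
  (A-AMR 5%, CA-AMR 2%, A-TCMR 3%, CA-TCMR 2%), IFTA 22%, BC 3.1%,
  C4d-no-rejection 0.8%, the rest no-rejection — the shape of a
  low-prevalence surveillance cohort. Exact per-category prevalences are
  not published; these are the package's own choice and fully
  configurable. DSA positivity defaults to 0.1.
* **Marginal score distributions are arbitrary.** The within-region
  ordinal proposals are uniform-ish weights chosen for coverage, not
  fitted to any real cohort (none is published at score level). Passing
  recovery tests therefore demonstrates generator/engine consistency and
  pipeline correctness, not realism of score marginals, co-occurrence
  structure, longitudinal correlation within patients, or
  pathologist-error patterns — none of which the generator models.
* **Reachability.** `C4d-no-rejection` records are always generated
  ABO-compatible (the category cannot occur in ABO-incompatible grafts)
  and `equivocal-AMR` records always carry unknown DSA; both categories
  have zero default prevalence, so the default expected ABO-incompatible
  fraction shifts by under 0.3% of its value. Unreachable
  category/context pairs (e.g. `C-AMR-inactive`, which no rule emits)
  raise an error naming the conflict.
* **One seeded stream.** Each cohort derives from a single seed recorded
  in its `cohort_seed` attribute; identical specs give byte-identical
  cohorts. `perturb_pathologist_labels()` applies a configurable
  confusion kernel to emulate pathologist discordance.

## Numerical and degenerate-input choices

* Missing scores are parsed from empty cells or dashes (ASCII or
  typographic) and survive CSV round trips; in the DSA column a dash is a
  negative test result, not missing.
* `agreement_rate()` raises on an empty stratum rather than returning
  NaN; `cohen_kappa()` raises when expected agreement is 1.
* An empty applicable set is legal and yields `no-rejection`; the rule
  trace is never empty (it always ends in `primary=`).
* Validation returns findings (record, field, rule) rather than throwing,
  except at classification entry points where findings aggregate into a
  single error.

## Problem sizes

The test suite verifies priority soundness against an independently coded
brute-force oracle over the exhaustive acute-lesion grid — all 24,576
combinations of t, i, v, g, ptc, C4d in 0–3 under every ABO × DSA
context with chronic scores at zero — plus property checks (AMR
monotonicity in g, ABO-incompatible invariance to C4d, acute/borderline
mutual exclusion) and synthetic cohorts of 300–10,000 biopsies; the whole
suite runs in well under a minute. Kappa is cross-checked against both a
brute-force oracle on 100 random tables and an independent library
implementation.

## Known limitations

* The rules implement one classification era; later revisions (e.g.
  removal of DSA-negative, C4d-negative microvascular inflammation from
  the AMR umbrella, and "probable AMR") are out of scope.
* Chronic active TCMR grading (I vs II) and chronic allograft
  arteriopathy are not graded; the engine emits the category only.
* The engine cannot use clinical history, prior biopsies or treatment
  response — exactly the information pathologists do use in the cases
  where the two disagree.
* Full-cohort agreement statistics from the source validation study
  (n ≈ 1,071) are not recomputable here because that dataset is
  unreleased; the package reproduces the row-level discrepancy fixtures
  and the stratified agreement arithmetic on the published aggregate
  counts instead.
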