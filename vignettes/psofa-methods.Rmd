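---
title: "Quantifying sepsis severity in minipigs: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying sepsis severity in minipigs: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psofa)
```

## The scoring model

Experimental intraabdominal sepsis in minipigs — induced by an
intraperitoneal autologous fecal suspension — progresses over roughly a
day from inoculation through an awake progression phase to an invasive
monitoring window at 16–24 h. `psofa` quantifies the severity of the host
response over that window with a pig-adapted Sequential Organ Failure
Assessment (pSOFA) in two forms:

* the **3-domain score** (range 0–12) uses only online measurements —
  the PaO₂/FiO₂ ratio (respiration), mean arterial pressure
  (cardiovascular) and hourly diuresis (renal) — and suits bedside,
  hourly evaluation;
* the **5-domain score** (range 0–20) adds two laboratory domains,
  plasma bilirubin (liver) and platelet count (coagulation), trading
  immediacy for resolution.

Each domain maps its driver to an integer 0–4. Two thresholds are
pig-specific: MAP above 75 mmHg is treated as normal (continuous
anesthesia and analgesia depress blood pressure, so the human 70-mmHg
cutoff would under-call cardiovascular dysfunction), and platelet counts
up to 200 × 10⁹ L⁻¹ are normal (pigs run a broader platelet range than
humans). The respiratory and bilirubin bands are the human ones. A
`mode = "human"` switch exposes the conventional human thresholds
(including the dopamine/epinephrine/dobutamine dose bands in the
cardiovascular domain) for side-by-side comparison; the two modes agree
wherever the threshold sets coincide, e.g. the entire PaO₂/FiO₂ row.

Two conventions resolve ambiguities a printed threshold table leaves
open. First, all categories are half-open and the healthy category is
closed at its printed boundary: a value sitting exactly on a boundary
(PaO₂/FiO₂ = 400, MAP = 75, urine = 0.5, bilirubin = 20,
platelets = 200) takes the *better* score. The bilirubin row prints
"<20" for score 0 and ">20" for score 1, leaving exactly 20 unassigned;
we assign it to score 0, the benign reading, and apply the same rule at
32, 101 and 204. Second, therapy-based scores dominate measurement-based
ones: a norepinephrine dose of ≤0.1 or >0.1 µg kg⁻¹ min⁻¹ forces
cardiovascular 3 or 4 regardless of the supported pressure, and a
cumulative furosemide dose of ≤10 or >10 mg forces renal 3 or 4
regardless of diuresis (exactly 10 mg scores 3). Norepinephrine doses
are interpreted in µg kg⁻¹ min⁻¹ — the human SOFA convention — because
the table prints the 0.1 breakpoint without units. "F" is read as the
cumulative furosemide dose within the monitoring window, consistent with
a 10-mg bolus protocol repeated when refractory.

Missing laboratory values never silently become score 0: a sample
without bilirubin or platelets yields a flagged 3-domain-only result
with `total_5d = NA`. Per-animal summaries are *unrounded* means of the
hourly integer totals; classification decisions always use per-hour
integer totals, never the mean.

The semi-quantitative 0–1 alertness assessment of the awake phase is
deliberately not a domain: it is not comparable to the human Glasgow
Coma Score, and a neurological domain is out of scope. Creatinine-based
renal scoring is likewise excluded — urine output is the more sensitive
renal indicator in this setting, while creatinine rises late and only in
shock.

## Supportive-therapy rules

The cardiovascular and renal domains only make sense jointly with the
goal-directed supportive therapy that generates the drug states they
read. `evaluate_triggers()` encodes the window protocol:

* **norepinephrine** starts when MAP has decreased to the trigger
  (default 55 mmHg, read as ≤55) *and* at least 60 min of crystalloid
  resuscitation have failed to restore it;
* **furosemide** (10 mg iv) is given for urine output strictly below
  0.25 mL kg⁻¹ h⁻¹ despite ongoing fluids, or for ELWI above
  10 mL kg⁻¹, and is repeated while the previous dose is unresponsive
  (urine/ELWI improved by less than a 10% relative tolerance one hour
  later);
* **fluid boluses** (15 mL kg⁻¹ crystalloid) are indicated while the
  stroke volume index sits below the physiological 35–45 mL beat⁻¹ m⁻²
  target.

The action set is a pure function of (sample, therapy state, policy),
and no action fires on a sample inside all target ranges. Norepinephrine
*titration* is not specified by the protocol; the simulator uses a
starting rate of 0.05 µg kg⁻¹ min⁻¹ doubled each hour the unsupported
pressure stays at or below the trigger, documented here as an
assumption. Maintenance fluids given at 6 and 12 h are logged but do not
start the resuscitation clock — only goal-directed boluses inside the
monitoring window count toward the 60-min precondition. Fluid boluses
beyond maintenance are unbounded in simulation (the protocol states no
cap) and every bolus is logged.

## Severity classification

Group allocation follows the Sepsis-3 consensus adapted to the model,
decided at 18 h after inoculation (configurable):

* **sepsis** — total pSOFA ≥ 2 *and* lactate ≥ 2 mmol L⁻¹;
* **septic shock** — the sepsis criteria plus vasopressor dependence:
  norepinephrine running at allocation to hold MAP at the 65-mmHg
  target despite adequate fluids. Shock therefore implies sepsis by
  construction. "Persistent hypotension" is operationalised as being on
  the vasopressor at the allocation hour (the trigger rules themselves
  guarantee a preceding unresponsive fluid challenge). The stricter
  Sepsis-3 reading — lactate ≥ 2 despite resuscitation as an additional
  shock requirement — is available as `strict_lactate_clause`;
* **non-responder** — an inoculated animal meeting neither criterion
  through the end of observation (24 h);
* **fulminant** — an early over-response forcing humane termination
  before the monitoring window.

Whether the score criterion refers to the 3- or 5-domain total is not
pinned down by the consensus text; the package defaults to the 5-domain
total (falling back to the 3-domain total when laboratory values are
missing, and flagging the fallback) since it is the more complete
severity measure. Animals that meet the criteria only after 18 h are
labelled at the first qualifying hour rather than forced into the
non-responder class.

The fulminant rule screens the early (≤15 h) trajectory against its
baseline: by default, at 6 h, lactate at ≥2× and bilirubin at ≥1.5×
baseline *and* venous oxygen saturation and albumin at ≤80% of baseline
(a conjunction), or an explicit acute respiratory/circulatory failure
flag. The exact supplementary thresholds behind the original
humane-endpoint decisions are not published; the multiples/fractions are
configuration with these documented defaults, and the conjunctive form
keeps the rule conservative.

## Oxygen dynamics and microcirculation

Derived quantities follow the standard monitoring formulas:
DO₂ = CO × (1.38 × Hb × SaO₂ + 0.003 × PaO₂) and
VO₂ = CO × (1.38 × Hb × (SaO₂ − SvO₂) + 0.003 × PaO₂). The default
`literal` units mode multiplies exactly these terms (CO in
L min⁻¹, Hb in g dL⁻¹); `ml_per_min` applies the conventional ×10
dL→L factor. Two printed forms are ambiguous and resolved as package
decisions: oxygen extraction is reported as the physiological fraction
ExO₂ = VO₂/DO₂ — the direction consistent with extraction *increasing*
under septic oxygen demand — with the literal inverse available behind
a flag; and the vascular resistance "index" divides by whatever flow is
passed, so callers choose CI (indexed) or CO (literal). For all valid
inputs VO₂ ≤ DO₂, and ExO₂ is invariant to rescaling CO since the flow
cancels.

The De Ritis ratio (AST/ALT) is computed as a liver-damage marker but,
as in the scoring design, never enters the score. Microcirculatory PPV
is the perfused fraction of total detected vessel length (%) on
precomputed segment tables, with optional per-video-quarter averaging;
image acquisition and vessel segmentation are out of scope. PPV is
invariant under subdividing a segment into parts of the same flow
status.

## Microbial load

Inoculum loads come from the standard viable plate count
(colonies × dilution / plated volume, default 0.1 mL plated) taken
retrospectively from the suspension. Total load maps onto the observed
severity bands: below 1.34 × 10⁷ CFU no septic reaction developed;
above 4 × 10⁸ CFU sepsis and septic shock became likely; above 8 × 10⁹
CFU the reaction was fulminant; the span in between is reported as
indeterminate. The breakpoints are open ranges in the source, so
boundary values are assigned to the lower band. Blood-culture records
are carried both as numeric CFU mL⁻¹ and as a qualitative
positive/negative flag, because the laboratory procedure is qualitative
while the correlation analyses need a magnitude; all correlation
operations are rank-based, so unknown axis units (CFU vs CFU mL⁻¹)
cannot change the results.

## Statistical procedures

The analysis layer mirrors a classic nonparametric workflow: Spearman
rank correlation (mid-ranks for ties; exact permutation null for n ≤ 9,
t-approximation otherwise) with a least-squares line and pointwise 95%
band for plotting; Kruskal–Wallis between groups and Friedman within
groups, both followed by Dunn's z-tests (tie-corrected pooled-rank
variance). Dunn p-values are reported *unadjusted* by default to mirror
the rank-based post-hoc convention of the era's desktop statistics
packages; Bonferroni/Holm are selectable and the choice is recorded in
every output table. The omnibus statistics are delegated to
`stats::kruskal.test()` and `stats::friedman.test()`; the Dunn layers
are implemented here because no installed package provides them.

The design-stage sample-size estimate uses Schoenfeld's event count,
d = (z₁₋α/₂ + z₁₋β)² / (p(1−p)(ln HR)²). With the design inputs
HR = 0.2, power 0.9, α = 0.05 and a 1:3 control:septic allocation
(p = 0.25) this gives 22 required events. Converting events into group
sizes requires per-arm event probabilities, which published designs
rarely state precisely; the conversion therefore takes them as explicit
inputs and echoes every assumption, and the package does not claim to
reproduce any particular published animal count.

## The synthetic cohort generator

No animal data are deposited, so the pipeline is exercised end-to-end
on synthetic cohorts built to have the statistical structure the
analysis assumes — not to impersonate measured data.

Each inoculated animal draws a total inoculum load log-uniform over
10^5.8–10^10.2 CFU and a latent severity
`severity_coupling × (log₁₀CFU − min) + N(0, 0.4)`. Trajectory
templates are assigned by latent-severity *rank*: the lowest 5/27
quota becomes non-responders, the highest 3/27 fulminant
over-responders, and the remainder splits into sepsis and septic shock
at its median (for 19 animals: 10 sepsis, 9 shock, the study flow).
Quota assignment keeps the template counts — and hence the 8 excluded
animals of a default 36-animal cohort — exact, and makes the
coupling = 0 case genuinely independent of the inoculum load, which the
parameter-recovery checks rely on.

Templates are piecewise-linear median curves over the grid 0, 6, 12,
then hourly 16–24 h, interpolated between a mild and a severe variant
by the within-template severity percentile, with multiplicative
lognormal measurement noise (3–15% depending on variable; additive for
the saturations). Anchor values are package defaults placed inside the
qualitative ranges the templates emulate: TNF-α peaking at 6 h in both
septic templates; IL-10 peaking at 16 h; bET and HMGB1 rising only in
shock over 16–24 h; leucopenia at 16 h in both septic templates;
persistent lactate ≥ 2 and vasopressor-dependent hypotension only in
shock; a late (20–24 h) bilirubin rise only in shock; progressive
albumin decline everywhere. They are design choices, fixed once, and
not asserted as anyone's measurements.

Crucially, drug states are *not* scripted: the generator runs the
therapy-trigger engine hour by hour inside the monitoring window, so
norepinephrine and furosemide exposures (and hence cardiovascular and
renal scores of 3–4) arise endogenously from the simulated physiology —
shock-template pressures fall through the trigger after an unresponsive
fluid challenge, sepsis-template pressures do not. A running infusion
holds observed MAP at the 65-mmHg target while the underlying pressure
keeps falling. Fulminant animals terminate between 6 and 15 h (earlier
the more severe) and contribute only early samples.

Blood cultures at 18 h are lognormal around a severity-proportional
mean, giving the stronger hemoculture-versus-score association the
analysis layer should detect; non-responders mostly fall below the
1 CFU mL⁻¹ detection limit.

What passing tests on these cohorts shows is that the pipeline recovers
structure that is present by construction — monotone coupling between
microbial load and organ dysfunction, separation of shock from sepsis,
exact label partitions. What they cannot show is fidelity to real
porcine physiology: real trajectories have autocorrelated noise,
inter-animal template heterogeneity, and measurement artifacts (e.g.
catheter-induced platelet aggregation) that the generator does not
model.

## Numerical choices and problem sizes

Scoring thresholds are compared with plain floating-point inequalities;
the threshold-equivalence suite probes every boundary ±10⁻⁶ alongside
~10⁵ random inputs against an independently transcribed chain-of-ifs
oracle. The exact Spearman permutation null enumerates all n! rank
permutations and is capped at n ≤ 9 (362 880 permutations). Degenerate
all-tied inputs to the rank tests are flagged with a warning and
returned with zero statistics rather than NaN. Time-series lookups use
nearest-grid-time matching with ties resolved toward the earlier hour.

The shipped checks use cohort sizes of 20–100 animals, 20 seeds and
three coupling levels for parameter recovery, and 5 000 replicates for
the type-I-error checks of the rank tests (nominal 5% within ±1.5
percentage points) — sizes chosen so the full suite completes in a few
minutes on a single core while keeping Monte-Carlo error well inside
the asserted tolerances.

## Known limitations

* The pig/human threshold table's italic human renal entries are
  garbled in the source; human-mode renal scoring therefore reuses the
  urine-output bands and the furosemide precedence, and human-mode
  dobutamine is interpreted as "any dose" per the human SOFA
  convention. Both are configurable interpretations, not facts.
* The generator's anchor curves are qualitative emulations; no
  quantitative claim about real cohorts should be read off them.
* Mortality prediction, treatment-effect estimation, mixed models and
  survival-curve fitting are out of scope; the sample-size estimator
  covers the design calculation only.
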