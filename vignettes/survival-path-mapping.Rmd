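---
title: "Survival path mapping: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Survival path mapping: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(survmap)
```

## The problem

Patients under long-term oncological surveillance -- the motivating setting
is intermediate-stage (BCLC B) hepatocellular carcinoma -- accumulate
irregular longitudinal data: serum markers, liver function, imaging findings
and performance status, measured at visits that drift around a nominal
3-month cadence, interleaved with treatments and interrupted by death,
censoring or loss to surveillance.  Static staging systems assign one label
at diagnosis; what clinicians need is a *dynamic* re-stratification at each
follow-up.  `survmap` implements survival path mapping: the cohort is
projected onto fixed time slices, and at every slice every current subgroup
is re-examined and, when a prognostic feature emerges, bifurcated.  The
result is a cascading tree whose root-to-leaf chains are *survival paths*;
a patient's position on the tree at any slice carries a prognosis (the
node's median overall survival) and, via the treatment-transition analysis,
actionable structure (chance and incurable nodes).

## The slice transformation

Time zero is diagnosis.  Slice 1 is the baseline window $[-1, 0]$ months;
slices $2..m$ tile $(0, H]$ in half-open windows of length $\Delta$
(defaults $\Delta = 3$, $H = 24$, so $m = 9$).  Windows are contiguous on a
continuous month axis; any measurement in the nominal "dead zone" just
after diagnosis belongs to slice 2's window.  Within a window the *newest*
value of each raw variable is used; exact time ties resolve to the last
record in file order, so the transformation is deterministic.

Raw variables are dichotomized by a rule set
(`default_hcc_rules()` reproduces the customary cut points: AFP at 200 and
400 IU/ml; Child-Pugh B/C vs A and C vs A/B; main-lesion diameter at 50, 70
and 100 mm; the composite lesion burden -- solitary, or 2-3 lesions no
larger than 30 mm, versus more; lesion count at 4; vascular invasion;
distant metastasis; the combined vascular/nodal/metastatic flag; viable
lesion after treatment; performance status above 2).  One raw variable may
feed several features; every rule is total over its domain, and the rule
order is the fixed priority used for all tie-breaks downstream.

Each patient-slice cell has one of three statuses.  `complete` requires
every feature to be computable from in-window data -- there is no
imputation; missingness is represented only through the status machine.
A living patient with an incomplete window is `no_surveillance`, and by
default that state is irrevocable: all later living slices are also
`no_surveillance` even if data reappear.  We read the source convention for
surveillance loss literally as irrevocable; because the alternative
(surveillance may resume) is defensible, `build_slice_panel(sticky_dropout
= FALSE)` provides it, flagged non-canonical.  Slices whose window opens at
or after death or loss to follow-up are `nonexistent`.

Overall survival at slice 1 runs from diagnosis.  At later slices it runs
from the slice's *imaging origin*: the earliest imaging-derived measurement
time inside the window, falling back to the window opening when no imaging
timestamp exists.  This keeps per-slice OS anchored to the examination that
defines the patient's state there.

## The selection cycle and the map

Each per-node selection at a slice is treated as an independent experiment,
so with $m$ slices the working significance level is
$\alpha = \alpha_{\text{family}} / m$ (0.05/9 $\approx$ 0.006).  One cycle
runs:

1. **Screening.** Two-group log-rank test per binary feature at level
   $\alpha$; features with fewer than `min_level_count` (default 2) cases
   in either level are skipped, not tested.
2. **Gate.** Multivariable selection proceeds only when the node can
   support it.  The default is the events-per-variable heuristic, at least
   10 observed deaths per screened candidate; a Schoenfeld power-based
   required-events rule is available (`gate = "power"`).  The candidate
   count is taken after screening, so the gate adapts to what would
   actually enter the model.  Event-based gating (rather than total n) is
   the default because the Cox information is carried by deaths.
3. **Fit.** Cox proportional hazards over the screened candidates, Efron
   tie handling.  Aliased features and features driving a monotone
   likelihood (complete separation) are dropped with a warning.
4. **Backward elimination.** The Cox partial likelihood has no residual
   variance, so the classical partial-F elimination is implemented with
   its standard analogue, the likelihood-ratio chi-square: repeatedly drop
   the feature with the smallest LR statistic while its P is at or above
   $\alpha$, refitting each time, until every retained feature is
   significant.
5. **Importance.** For each retained feature $q$,
   $\Gamma_q = 2(\log L_h - \log L_{h-q}) \ge 0$, the likelihood drop on
   removal; the retained feature with maximal $\Gamma_q$ is the split
   feature.  (We define the importance with the sign that makes it
   non-negative for informative features.)  Exact ties in $\Gamma$ or in
   screening P-values break by rule-set priority, keeping the whole
   procedure deterministic.

The map is built breadth-first.  The whole cohort with complete slice-1
data is the root; a selected feature splits a group into the *upper* child
(longer Kaplan-Meier median OS; an unreached median counts as longest, and
an exact tie sends the favorable feature level up) and the *lower* child.
Every node advances its still-complete members to the next slice and the
cycle repeats until the final slice.  Nodes with fewer than 6 members are
retained for bookkeeping but marked excluded: they are never split, are
dropped from rendered output, and do not enter concordance computations --
the same overfitting guard as the source convention of excluding sub-6-case
subclasses.  Path indices are a visual convention: the upper child keeps
its parent's index, the lower child opens a new one, and paths are finally
relabelled 1..K top-to-bottom by terminal-node median OS.

Features from the same raw variable (AFP at 200 and at 400) may co-enter a
model; collinearity is left to elimination, and if both survive the
higher-$\Gamma$ one splits.  Where the selection prose could be read as
choosing an *eliminated* variable, we select among *retained* variables the
one whose removal drops the likelihood most -- the only reading under which
the selected feature is in the final model.

## Evaluation

* **Node medians** are Kaplan-Meier medians: the first time the estimator
  reaches 0.5 or below, undefined if never reached.
* **Concordance** is Harrell's c computed by explicit pair counting: a
  pair is usable when the earlier time is an event (on ties, when exactly
  one member is an event); tied risk scores count one half, so a constant
  predictor scores exactly 0.5.  Node-based systems rank patients by their
  node's derivation median OS; comparator staging systems are consumed as
  precomputed per-slice ordinal labels.  Confidence intervals use a seeded
  nonparametric bootstrap (percentile bounds); the paired comparison of
  two systems uses a deterministic leave-one-out jackknife standard error
  of the c difference and a Z test at the working level (0.006 by
  default).  We deliberately do not attempt to reproduce any particular
  published CI width for c, since no method for those intervals is stated
  in the source setting; point estimates, not interval widths, are the
  meaningful surface.
* **Bifurcations** are tested with a univariate Cox HR of the lower
  (worse) child versus the upper child -- every reported HR is therefore
  above 1 by construction -- with Wald 95% CI; when one side has no deaths
  the partial likelihood is monotone and a log-rank P is reported instead,
  and comparisons with a side under 6 members are suppressed.
* **Treatment transitions** cross-tabulate surgery/ablation received
  between a bifurcating node's window opening and the child slice's window
  closing against the member's fate (upper child, lower child, died or no
  surveillance).  Pearson chi-square without continuity correction,
  switching to Fisher's exact test when any expected cell is below 5.  The
  treatment window is our own convention (the source setting does not pin
  one down); it spans the interval in which a treatment could plausibly
  drive the observed transition.
* **Classifications.** A *chance node* bifurcates with a child-median gap
  of at least 10 months and more than 80% of its treated members
  transferring upward; an *incurable node* is a bifurcated node with no
  valid (at least 6-member) following node and median OS under 5 months;
  a *long-term path* has terminal median OS above 60 months (an unreached
  median qualifies when follow-up in the node extends past 60).

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical shape of a surveillance
cohort, not liver-cancer biology: nine binary features with chosen baseline
prevalences (0.15-0.50, spanning common marker elevations to rare
metastatic flags) evolving by per-slice flip probabilities; one jittered
visit per observed slice so the newest-value rule is exercised; event times
piecewise-exponential with the hazard updated at slice boundaries to the
baseline rate (default 0.045/month, median survival about 15 months)
multiplied by the hazard ratio of every active planted feature the patient
currently carries; independent exponential censoring; administrative
censoring at 120 months; and per-slice surveillance dropout (default 0.12,
which reproduces the steep attrition of effective cases across slices seen
in real surveillance data).  The latent truth (feature trajectories, true
event times, dropout slices) is returned in a separate sidecar so analysis
pipelines cannot consume it by accident.

What passing tests on these cohorts do show: the selection machinery
controls its false-split rate at the corrected level, recovers planted
multi-level structure, and estimates hazard ratios and medians
consistently.  What they do not show: robustness to informative dropout,
measurement error in the raw variables, treatment effects on the hazard
(the simulated treatment flag is deliberately inert), or non-proportional
hazards -- none of which the generator produces.

The structure-recovery experiment is fixed a priori as: n = 800, planted
splits f1 at slice 1 and f2 at slice 2 with hazard ratio 3 each, planted
features static (flip probabilities 0) and at prevalence 0.5 so the planted
tree is well defined, baseline hazard 0.05/month, light censoring (0.002)
and dropout (0.05), 100 replicates.  The null-rate experiment uses n = 300
with all nine defaults features inert, 1000 replicates.  These sizes keep
the full suite in the minutes range on a single core while leaving the
Monte-Carlo error well below the margins being tested.

## Numerical choices and degenerate inputs

Efron ties in every Cox fit (stated in model output); diverging
coefficients (|beta| > 15) treated as separation and dropped with a
warning; LR statistics clipped at zero before chi-square P-values;
backward-elimination and importance ties broken by rule priority (the
lowest-priority feature is removed first); nodes with no deaths screen to
an empty candidate set with a warning rather than an error; a child with an
unreached median ranks above any reached median; JSON serialization keeps
17 significant digits so maps and panels round-trip bit-exactly.

## Known limitations

Node fusion, learned cut points and adaptive slice intervals are out of
scope by design.  The builder never merges nodes, so sample size decays
geometrically along paths and deep slices are increasingly gated; with
cohorts of a few hundred patients, splits beyond slice 5 or 6 are rare.
Comparator stages are consumed as given labels -- the package does not
compute BCLC/AJCC/ART staging from raw data.  The jackknife Z test for
c-index differences is asymptotic and mildly liberal below roughly 100
patients.
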