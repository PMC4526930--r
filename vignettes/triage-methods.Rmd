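---
title: "Knowledge-graph triage scoring and its evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knowledge-graph triage scoring and its evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edtriage)
```

`edtriage` has two halves: a triage severity engine that converts a
structured patient presentation into a five-level acuity via a curated
diagnosis–finding knowledge graph, and an agreement harness that scores
any such engine against a five-level reference standard. This vignette
explains the model behind each, the tunable parameters, the synthetic-data
generator used for testing, and the design choices made where the
problem left the design genuinely open.

## The severity scale

Severity is ordinal 1–5 throughout the package, with 1 the **most**
severe (immediate lifesaving intervention / "revive") and 5 the least
(no resources expected / "referred"). This matches how five-level triage
scales such as the ESI are printed. Because 1 is the severe end, "rounding
to a higher triage level" means rounding toward the numerically *smaller*
integer — a recurring source of sign confusion that the code resolves once
in `round_severity()` and nowhere else.

## The differential-ranking model

The knowledge base is a bipartite graph: diagnoses, findings, and curated
associations. Each association carries a frequency category — how often the
finding accompanies the diagnosis — from a closed five-word vocabulary:

| category     | curated meaning          | default likelihood |
|--------------|--------------------------|--------------------|
| key          | required for diagnosis   | 0.75               |
| very_common  | >50% of presentations    | 0.75               |
| common       | 10–50%                   | 0.30               |
| uncommon     | 1–10%                    | 0.055              |
| rare         | <1%                      | 0.005              |

The categories name frequency *ranges*; scoring needs point values, and the
defaults are the arithmetic midpoints of those ranges (treating ">50%" as
(50%, 100%]). They are configuration, not constants: `triage_config()`
accepts any monotone replacement.

For a case with findings $F$, the score of diagnosis $d$ is

$$\mathrm{score}(d) \;=\; \pi_d \prod_{f \in F} L(f \mid d)
\;\times\; \rho^{\,|\mathrm{missing\ key}(d)|}$$

with $\pi_d$ the baseline prevalence, $L$ the category likelihood times the
product of matching demographic multipliers (clamped at 1), $L = \epsilon$
(default $10^{-3}$) for a case finding with no association to $d$, and
$\rho$ (default $0.05$) a penalty applied once per *key* association of $d$
whose finding the case lacks. The product form is a deliberate naive-Bayes
assumption — conditional independence of findings given the diagnosis — the
simplest model consistent with a probabilistic graph over
diagnosis–finding edges. Findings merely *absent* (other than key ones)
contribute nothing: the model is open-world and does not represent
negation.

Two parameter choices deserve comment because nothing external fixes them:

* **$\epsilon$ (unmatched finding, default 0.001).** It must be far below
  the `rare` likelihood so an unexplained finding hurts more than a rare
  association, yet strictly positive so a single stray finding cannot
  zero out a diagnosis. Because every diagnosis unassociated with a given
  finding receives the *same* $\epsilon$, a finding unknown to the whole KB
  rescales all scores uniformly and provably leaves ranking and weights
  unchanged (a tested invariant).
* **$\rho$ (missing key finding, default 0.05).** "Required for diagnosis"
  could be enforced hard (score zero). The soft penalty was chosen instead:
  real presentations omit findings (unasked, unrecorded), and a hard zero
  would make the differential brittle against exactly the documentation
  noise triage inputs exhibit. At 0.05 a missing key finding demotes a
  diagnosis by more than the gap between `very_common` and `uncommon`
  evidence, without eliminating it.

Demographic modulation is represented as banded multipliers — half-open age
intervals in years plus a sex filter, multiplying the edge likelihood — for
example a U-shaped age effect uses multipliers >1 for the young and old
bands and <1 in between. A full multi-dimensional density over
demographics would be unidentifiable from curated content; bands with
explicit endpoints are auditable by the physicians who curate them. Race
and symptom-duration modifiers are accepted by the schema but inactive by
default, since no principled default form exists for them.

Ranking sorts by raw score with a fully deterministic tie-break (higher
baseline prevalence, then lexicographic id), truncates to the top $K$
(default 100, the conventional upper bound on a clinician's differential),
and renormalizes the retained scores into weights summing to 1.

## From differential to triage score

Each retained diagnosis contributes an integer case severity: the most
severe `severity_for_diagnosis` among its matched case findings, clamped
into the diagnosis's curated severity range, or the range's rounded
midpoint when no finding matched. Whether a deployed curated system makes
per-diagnosis severity case-dependent at all is not observable from the
outside; the clamped-minimum rule is this package's explicit choice, on the
grounds that the finding that *triggered* a diagnosis's presence in the
differential should also set how alarming that diagnosis is, within the
bounds curation allows.

The fractional severity is the weight-averaged case severity,
$\sum_d w_d s_d \in [1, 5]$. Rounding to the final integer uses a mid-band
rule: fractional parts outside $[0.40, 0.60]$ round to the nearest level;
inside the band the score is genuinely ambiguous and clinical context
decides. If any differential entry whose diagnosis can be urgent/emergent
(most severe attainable level $\le 2$, configurable) recommends a critical
test, or the shortest known symptom duration is under 48 h (configurable;
"short" is nowhere quantified externally, and 48 h separates acute from
subacute presentation in common usage), the score rounds toward higher
urgency; otherwise toward lower. Band endpoints are treated as inclusive,
so exactly .5 and the endpoints .40/.60 always take the contextual path —
erring toward an explicit decision rather than an arbitrary floating-point
nearest-neighbour at the boundary. Both band and endpoints sit in
`triage_config()`.

Vital signs enter as *derived findings*: a measured vital outside its
age-banded reference range (a small infant/child/adult textbook table,
fully replaceable in config) generates `tachycardia`, `hypotension`,
`fever`, `hypoxia`, and so on, which then score exactly like reported
findings. Treating them uniformly keeps the likelihood model closed; a
hook for hard vital-sign overrides (e.g. forcing level 1) exists in the
configuration design space but is deliberately not a default, because
over-weighting minor vital aberrance is a documented failure mode of
automated triage.

## The agreement harness

Validation compares engine scores against a reference standard on the same
cases. For ordinal raters, weighted Cohen's kappa gives partial credit for
near misses:

$$\kappa = \frac{p_o - p_e}{1 - p_e},\qquad
p_o = \frac{1}{n}\sum_{ij} w_{ij} n_{ij},\qquad
p_e = \frac{1}{n^2}\sum_{ij} w_{ij} r_i c_j$$

with $w_{ij} = 1 - |i-j|/(k-1)$ (linear) or $1 - (i-j)^2/(k-1)^2$
(quadratic), $k = 5$ fixed by the scale rather than by the observed
categories. Fixing $k$ matters for subgroup analysis: restricting to the
reference's levels 1–2 leaves columns 3–5 empty, and collapsing to
observed categories would silently change the ordinal distances. The
package therefore filters pairs but retains the full 5×5 shape
(`subgroup_matrix()`).

Both weight schemes are first-class and the report prints both. On the
packaged 73-case validation matrix (`table5_fixture()`) the linear scheme
gives 0.933 and the quadratic scheme 0.947; on the urgent subgroup
(n = 41) the linear scheme gives 0.851. The published report of this
matrix labels its statistic "quadratic" while printing 0.933 and 0.851 —
values that the arithmetic reproduces only under the *linear* weights.
The package does not resolve that discrepancy; it documents it and
reports both schemes so either convention can be read off. Similarly, the
published subgroup table prints an exact-match proportion of 0.947 where
the printed counts give 39/41 ≈ 0.951; the counts are treated as
authoritative.

Confidence intervals use a case-level percentile bootstrap with an
explicit seed (default B = 2000): resample pairs with replacement,
recompute kappa, take the α/2 percentiles. Degenerate resamples with
undefined kappa (all mass in one category for both raters) are skipped and
counted, with a warning past 1%. A percentile bootstrap cannot exceed 1 by
construction; normal-approximation intervals can, which is worth knowing
when comparing against intervals computed elsewhere. Exact reproduction of
any externally printed interval is out of scope, since CI methods are
rarely stated alongside the estimate.

Interpretation bands follow the conventional ordinal-agreement labels
(below 0 none, 0–0.20 slight, 0.21–0.40 fair, 0.41–0.60 moderate,
0.61–0.80 substantial, 0.81–1.0 almost perfect), with interior boundaries
assigned to the lower band as the cut-points are printed.

## The synthetic-data generator

No real curated KB or vignette set can be redistributed, so
`generate_kb()` / `generate_cases()` simulate both with the statistical
structure the engine assumes — they are first-class, tested code, not
ad-hoc fixtures.

KBs draw prevalence log-uniformly on $[10^{-4}, 10^{-1}]$ (disease
frequency spans orders of magnitude; a linear draw would make every
diagnosis common), severity ranges as centre ± 1 around a draw from a
configurable severity mix, frequency categories from a default mix
(very_common 0.2, common 0.4, uncommon 0.3, rare 0.08, key 0.02) chosen to
exercise every scoring branch while keeping key findings as scarce as
curation makes them, and critical-test recommendations on urgent/emergent
diagnoses with probability 0.5. Cases invert the model: sample a true
diagnosis by prevalence, include each associated finding with its category
probability times the demographic multiplier, add spurious findings at an
`extra_finding_rate`, drop included ones at a `dropout_rate`, and resample
any case that ends up empty (every real presentation has at least one
finding). Default noise in the tests is 5% spurious / 10% dropout — mild
documentation noise, deliberately easier than free-text reality.

Because generator and engine share the likelihood model, recovery must be
high; the tests assert the true diagnosis reaches the top-10 differential
in ≥80% of 500 seeded cases and the mean absolute severity error stays
≤0.5. These are regression guards for the pipeline under fixed seeds, not
claims about clinical accuracy: passing them shows the engine correctly
inverts its own generative assumptions, *not* that it triages real
narrative vignettes well. What the synthetic module does not emulate —
free-text entry, negation, correlated findings, systematically missing
vitals, curation gaps for rare exposures — is exactly where a real
deployment would be stressed.

## Numerical and testing notes

Scores are products of many factors in (0, 1]; at the tested scales
(tens of diagnoses, a handful of findings) they stay far above underflow,
but the differential normalizes by the score sum, so only ratios matter.
Oracle tests compare the vectorized implementations against deliberately
naive double-loop reimplementations to $10^{-12}$ *absolute* tolerance —
absolute, because $\kappa$ near 0 suffers catastrophic cancellation in
$(p_o - p_e)$ and relative comparison would amplify last-bit noise.
Problem sizes in the suite (200 random matrices, 500 synthetic cases,
B ≤ 4000 bootstrap resamples) were chosen so the whole suite runs in about
two minutes on one core while still giving the law-of-large-numbers checks
±5-point resolution. All randomness is seeded; `generate_kb()`,
`generate_cases()` and `kappa_bootstrap_ci()` save and restore the
caller's RNG state.

## Known limitations

* The product likelihood ignores finding–finding correlation; clusters of
  related findings over-count evidence.
* Synonym lookup is exact after normalization — no fuzzy matching, no
  negation ("denies chest pain" would match "chest pain").
* Per-diagnosis severity uses the clamped-minimum rule described above;
  alternatives (fixed attribute, weighted blend) are not implemented.
* The evaluation harness is strictly two-rater; multi-rater statistics
  (Fleiss) and discrimination metrics (ROC) are out of scope.
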