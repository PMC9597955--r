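---
title: "Choosing between discordant systematic reviews: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Choosing between discordant systematic reviews: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jadadr)
```

## The decision procedure

When two or more systematic reviews (SRs) with meta-analysis of randomized
trials address the same question but report diverging results, the Jadad
algorithm selects the "best evidence" review through a fixed hierarchy:

- **Step A/B** — do the candidate reviews address the decision maker's
  question? Reviews judged off-question are excluded; if fewer than two
  remain, the single closest review is chosen at Step B and assessment ends.
- **Step C** — do the reviews include the same trials? `jadadr` compares
  normalized trial rosters as sets.
- If **yes**: **Step D** asks whether the reviews are of the same
  methodological quality. Equal quality leads to **Step E** (compare data
  extraction, heterogeneity assessment, and synthesis appropriateness);
  unequal quality leads to **Step F** (choose the highest-quality review).
- If **no**: **Step G** asks whether the reviews apply the same eligibility
  criteria. If yes, **Step H** compares search strategies; if no, **Step I**
  compares publication status, trial-quality assessment, language
  restrictions, and individual-patient-data (IPD) analysis.

`run_jadad()` produces an ordered trace of every verdict and ends at one of
the terminal steps {B, E, F, H, I} with a non-empty chosen set. The engine
is deterministic and invariant to the order in which a case lists its
reviews.

### Why the tie-breaking tiers are parameters

The original publication names the quantities compared at Steps E, H, and I
but prescribes neither an ordering among them nor thresholds. Any concrete
implementation must therefore commit to an *operationalization*, and two
faithful readers can commit differently — which is precisely the
reproducibility problem this package is built to study. `jadadr` makes the
commitment explicit: a `jadad_ruleset()` carries the Step H tier order, the
Step I tier order, and the Step G similarity threshold, and every trace
records which ruleset produced it. The defaults are this package's own
operationalization, not an authoritative one:

| parameter | default | rationale |
|---|---|---|
| `step_h_order` | databases, grey literature, duplicate screening, search date | breadth of the search first, then conduct, then recency |
| `step_i_order` | publication status, trial-quality assessment, language, IPD | mirrors the order the four sub-criteria are conventionally listed |
| `criteria_similarity_threshold` | 0.8 | average per-element PICO-term Jaccard; 0.8 tolerates minor wording drift while rejecting a disjoint element (three matching elements and one disjoint average 0.75) |
| `quality_comparison_mode` | `within_tool_only` | AMSTAR, Oxman–Guyatt, and ROBIS scales are not commensurable; mixed-tool comparisons raise an error instead of coercing |

Comparative selections are lexicographic: candidates are filtered tier by
tier, and **ties keep every maximal review**. Forcing a single winner would
hide exactly the ambiguity the algorithm suffers from in practice — real
assessors do occasionally choose two or three reviews.

Two further numerical conventions apply everywhere:

- **Unknown ranks strictly below any known value.** A review that does not
  report grey-literature searching is never rewarded over one that reports
  "no". This is conservative against poor reporting.
- **Quality scales.** AMSTAR-style labels map to ranks critically-low (1) <
  low < moderate < high < highest (5); ROBIS is binary high-risk < low-risk;
  Oxman–Guyatt uses its native 1–7 ranks. `ordinal_rank` is validated
  against the declared label.

## Direction-of-effect classification

`classify_effect()` reduces a pooled estimate to *favourable*, *null*, or
*unfavourable*:

1. **Significance**: if a p-value is reported, significant iff p < α
   (default 0.05); otherwise significant iff the 95% CI strictly excludes
   the null value (1 for RR/OR, 0 for MD/SMD). The p-value takes precedence
   because published CIs are rounded — a bound printed as −0.00 can touch
   the null while the exact p-value is 0.04.
2. **Direction**: a non-significant estimate is *null*; a significant one is
   *favourable* when the point lies on the outcome's benefit side of the
   null and *unfavourable* otherwise.

The benefit direction (`lower_better` for e.g. pain, fracture, lesion
incidence; `higher_better` for e.g. function scores, range of motion,
disease control) is always a recorded input, never inferred from the data.
A point estimate exactly at the null combined with a claim of significance
is rejected as inconsistent rather than silently classified.

`direction_agreement()` compares the verdicts of two assessments' flagged
primary reviews (the first element of each choice set — the review an effect
estimate is reported for). Pairs with identical choice sets agree by
construction.

## The bundled corpus

The package ships a corpus of 21 published discordant-review cases with
paired assessments (the publishing authors' choice versus an independent
replication), and 27 pooled effect rows for the 13 cases whose choices
disagreed. `load_fixture_tables()` validates the corpus and
`agreement_report()` reproduces its headline statistics (choice agreement,
final-step agreement, direction concordance, ease/timing).

Design decisions embedded in the corpus encoding:

- **Choice agreement is strict set equality.** Four replication choices are
  supersets of the author choice (the same review plus one more); only
  strict equality reproduces the corpus's published 8/13 agree/disagree
  split, so supersets count as disagreement.
- **Multi-review choices are ordered**, with the flagged primary review
  first; direction concordance is classified on primaries.
- **Two same-named 2015 cases** are disambiguated by content (`zhao-2015a`:
  clavicle/constant score; `zhao-2015b`: humeral shaft/non-union). The
  corpus's effect rows are keyed by review labels, which places the
  Ouyang/Heineman block with `zhao-2015b` despite its published heading.
- **Unrecorded metadata is reconstructed minimally and labelled.** Trial
  rosters of the constituent reviews were not published; each review carries
  a distinct placeholder roster encoding the recorded fact that no case's
  reviews shared the same trials (Step C is "no" everywhere). Reviews
  counted but never named are padded as "unnamed" records with
  explicit-unknown metadata. Search profiles are explicit-unknown, so engine
  runs over the corpus are meaningful for *routing* (which terminal step a
  case reaches) but tie at the H/I selections themselves.
- **Ease ratings and timings are synthetic reconstructions** consistent with
  the published aggregates only (see the fixtures README); the published
  four-level wording maps onto the three-colour rubric as green / yellow /
  red with both "moderate-to-hard" and "hard" as red. Three pilot cases are
  flagged and excluded from timing summaries.
- One published tally (19 + 9 = 28 risk-of-bias verdicts across chosen
  reviews versus 27 recorded replication choices) is arithmetically
  inconsistent with the choice table; the corpus preserves the table and no
  code asserts the prose figure. Cochrane-review tallies are computed but
  likewise never asserted.

## The simulator

`generate_cases()` draws synthetic discordant-review cases so that every
pipeline stage is testable without any external data and the
reproducibility phenomenon can be studied quantitatively:

- **Effects.** Each case has a latent true effect θ ~ N(0, τ²) on the log
  scale for RR/OR and the raw scale for MD (default τ = 0.2). Each review
  reports an estimate ~ N(θ, se²) with se uniform on [0.05, 0.4], a 95%
  Wald interval (z = 1.96), and a two-sided Wald p-value; ratio-scale
  results are exponentiated so CI/null-value semantics match the
  classifier. Under τ = 0 the significant-verdict rate is α by
  construction, which the test suite checks at 10,000 simulated reviews
  within three Monte-Carlo standard errors.
- **Rosters.** Each review includes each of the case's trials (universe
  size 30 by default) independently with probability 0.5 — rosters overlap
  substantially but essentially never coincide, matching how the corpus
  behaves at Step C; probability 1 forces Step C to "yes".
- **Cases.** 2–10 reviews per case (the corpus's range), AMSTAR quality
  centred on moderate/high, 2–10 databases, grey-literature and
  duplicate-screening probabilities near one half, and IPD analyses almost
  never (2%), matching their absence from the corpus. PICO term lists are
  jittered per review (drop/add probability 0.15), so Step G's computed
  comparison produces both verdicts.
- **Assessor disagreement is ruleset perturbation only.** Extraction errors
  and data-entry noise are deliberately out of scope so that the mechanism
  being measured — divergent operationalizations of an under-specified
  procedure — stays identifiable. `agreement_curve()` reports Monte-Carlo
  mean choice- and direction-agreement per perturbation cell; identical
  rulesets give agreement 1 exactly, and direction agreement dominates
  choice agreement in every cell because equal choices imply equal primary
  verdicts.

What the simulator does **not** emulate: trial-level data and actual
meta-analytic pooling (pooled estimates are drawn directly), correlated
search metadata (a review with many databases is no likelier to search grey
literature), non-normal effect distributions, and human judgment error.
Passing simulation tests therefore demonstrates the engine's and
classifier's internal guarantees under controlled conditions, not that the
algorithm behaves this way on arbitrary real review corpora.

## Problem sizes and test design

The suite cross-checks every lexicographic selection (Steps E, H, I)
against an independent brute-force pairwise-tournament comparator on 1,000
randomly generated candidate sets, verifies byte-identical traces on
repeated runs, and permutes review order to confirm tie sets are
position-free. Simulation checks use 10–40 cases per property and a
10,000-review calibration run; these sizes give stable verdicts for every
property tested while keeping the default suite around a minute.

## Known limitations

- Step G's computed similarity is term-set overlap; it is a stand-in for
  semantic eligibility comparison and is bypassed whenever a human judgment
  is recorded.
- The corpus cannot support per-case validation of Step H/I *selections*
  (search metadata was not published); those are validated by construction
  and by the brute-force oracle instead, and corpus engine runs are used
  for routing only.
- The ease/timing analysis rests on the synthetic per-case allocation
  described above and should not be cited as published per-case data.
- No inferential statistics (kappa, proportion CIs) are provided; the
  replication analysis is deliberately descriptive.
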