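# Bundled replication corpus

Three UTF-8 CSVs describing 21 published discordant-review cases in which
author groups applied the Jadad algorithm to choose a "best evidence"
systematic review, together with an independent replication of each
assessment.

- `table1_cases.csv` — one row per case: review counts, primary outcome and
  intervention, the outcome's benefit direction, the recorded Step G
  same-criteria judgment from the replication, and a pilot flag (pilot cases
  are excluded from timing summaries).
- `table2_choices.csv` — two rows per case (authors / replication): the final
  decision step (`not_reported` where the author group did not state one),
  the chosen review label(s) with the primary review listed first,
  quality-appraisal tool and judgment where recorded, Cochrane flags, and
  risk-of-bias verdicts per chosen review (semicolon-separated, aligned with
  `chosen`).
- `table3_effects.csv` — 27 pooled effect rows for the 13 cases whose choices
  disagreed (one case's authors chose two reviews, hence two author rows):
  effect measure, point estimate, 95% CI, p-value (`NR` = not reported,
  `<x` = printed upper bound), the published favourable/null verdict, and the
  published per-case direction agreement.

## Notes and known quirks

- Case identifiers are assigned here; the two 2015 cases by the same first
  author are disambiguated by content: `zhao-2015a` (clavicle, constant
  score) and `zhao-2015b` (humeral shaft, non-union). In the published effect
  table the Ouyang 2013 / Heineman 2010 block is headed "Zhao 2015a" although
  those reviews belong to the humeral-shaft case; rows here are keyed by the
  review labels, i.e. to `zhao-2015b`.
- Trial rosters of the constituent reviews were not published; the loader
  assigns each review a distinct one-element placeholder roster encoding the
  recorded finding that no two reviews in any case included the same trials.
- Reviews counted in a case but never named in the published tables are
  padded by the loader as "unnamed" records with explicit-unknown metadata.
- The `ease` and `minutes` columns are SYNTHETIC reconstructions: per-case
  ratings and timings were not published. The values are allocated to match
  every published aggregate (18 rated assessments; 10 easy, all with final
  step H; 6 moderate; one moderate-to-hard and one hard; three of the eight
  moderate-to-hard ratings on Step I assessments; ten timings between 15 and
  47.5 minutes, nine of them on easy-rated assessments; overall mean 60
  minutes). Do not treat individual ease/minutes values as published data.
- The source text reports 12 author assessments ending at Step I while the
  choice table implies 13; the table is preserved as printed and the prose
  figure is not asserted anywhere.
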