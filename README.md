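# dcvkit

Discriminant content validity (DCV) analysis for questionnaire items, in R.

A questionnaire item has discriminant content validity when expert judges
agree that it measures the single theoretical domain it was designed to
measure rather than a blend of several. In a DCV exercise, each judge
allocates every item to up to three domains and rates their confidence in
each allocation (0–100%). dcvkit implements the complete analysis of such
an exercise, and ships the 79-item bilingual (English/Dutch) item bank
built to assess the 14 domains of the refined Theoretical Domains
Framework (TDF) — Knowledge, Skills, Beliefs about capabilities, and so on
— together with the recorded outcomes of its validation by 19 expert
judges.

## The statistic

For a target domain *d*, a judge's allocation is coded +1 when it names
*d* and −1 otherwise, multiplied by the confidence *c*; the judge's score
for (item, *d*) is the sum over their up-to-three allocations (0 when the
judge skipped the item), so single-allocation scores lie in [−1, 1] and
scores in general in [−3, 1]. Per (item, domain) pair, the per-judge
scores are tested with a one-sample one-tailed *t*-test (H₁: mean > 0)
under Benjamini–Hochberg FDR control across all tests in the run. Items
are then classified:

* **pure intended** — significant on the intended domain, no domain
  co-allocated by more than one judge, nothing else significant →
  included in the final questionnaire;
* **mixed** — co-allocated to additional domains → excluded;
* **misclassified** — significant on a non-intended domain → excluded;
* **unclassified** — no evidence either way → excluded.

Inter-rater agreement is quantified with Light's kappa (the mean of
Cohen's kappa over all judge pairs) on the judges' first-choice matrix,
and per domain on binary allocated/not-allocated matrices, with
percentile-bootstrap confidence intervals over items.

## Worked example

Replay the recorded validation study (the raw judge-level data were never
deposited, but the per-item outcome flags were published and are packaged):

```r
library(dcvkit)
replay_classification()
#> Replayed DCV classification of 79 items
#>   included (pure intended): 32
#>   excluded: 47 (39 co-allocated with intended, 8 misclassified)
#>   final items per domain:
#>  D1  D2  D3  D4  D5  D6  D7  D8  D9 D10 D11 D12 D13 D14
#>   4   3   4   3   2   2   0   4   0   4   2   2   2   0
```

Of the 79 items, 32 measured their intended domain and form the final
questionnaire; three domains (Reinforcement, Goals, Behavioral
regulation) retained no items. Run the full pipeline on a synthetic
exercise with the same design (19 judges, 79 items, 14 domains):

```r
sc  <- reference_scenario(seed = 1)
sim <- simulate_allocations(sc, seed = 1)
fit <- dcv(sim$table, bank = sim_item_bank(sc))
fit
#> Discriminant content validity analysis
#>   79 items, 19 judges, 14 domains; 109 (item, domain) tests
#>   alpha = 0.05, FDR = bh, co-allocation threshold = 2 judge(s), rank scope = first
#>   included (pure intended): 49 of 79
#>   excluded: 23 mixed, 5 misclassified, 2 unclassified
#>   overall Light's kappa (all items): 0.69
```

`summary(fit)`, `coef(fit)` and `plot(fit)` expose the per-item test
table, the intended-domain mean weighted judgments, and a classification
dot plot; `write_dcv_report(fit, "out/")` writes the result tables.

Items are stored generically with TACT placeholders (target, action,
context, time) and render against a user mapping:

```r
tact <- tact_mapping(A = "deliver physical activity counseling",
                     C = "primary care", T = "month", Ta = "patients",
                     innovation = "the PA program", profession = "nurse")
render_item(tdf_item_bank()[2, ], tact)
#> [1] "I know the content and objectives of the PA program"
```

A command-line wrapper is installed at `exec/dcvkit`
(`dcvkit run|simulate|replay|render`).

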