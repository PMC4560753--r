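# adhesionrisk

Adhesion risk scoring for gynaecological surgery.

Postoperative adhesions are among the most frequent complications of
abdominopelvic surgery: they cause chronic pain, small-bowel obstruction
and secondary infertility, and they complicate every subsequent operation.
Intraoperative adhesion-reduction agents work, but they are expensive, so
surgeons need a consistent way to identify the women most at risk before
committing resources. `adhesionrisk` implements the consensus **Adhesion
Risk Score (ARS)** — a practical, expert-weighted additive index — as a
validated, testable scoring engine for surgeons, clinical researchers and
data managers working with gynaecological surgical cohorts.

## The score

The ARS consists of two weighted additive sub-scores. Each of 20 risk
factors *f* carries consensus points *w_f* ∈ {0, 1, 2, 3, 4}, and a
sub-score is the plain sum over its ten factors:

```
S_pre  = Σ w_f(x_f),  f ∈ 10 preoperative factors,    S_pre  ∈ [0, 36]
S_peri = Σ w_f(x_f),  f ∈ 10 intraoperative factors,  S_peri ∈ [3, 31]
```

**Preoperative factors** (history and preoperative findings): number of
previous abdominal/pelvic surgeries (0/3/4 points for 0/1/>1), history of
post-surgical adhesions (4), concomitant abdominal or gynaecological
inflammation/infection (4), endometriosis by rASRM stage (1–4),
cancer category (2–3), radiation therapy in intra-abdominal cancer
(local 4, distant 1), keloid scarring (3), and three sequelae of previous
operations — intraperitoneal bleeding with an unexpected Hb drop ≥ 2 g%
(2), postoperative complications (4), postoperative infection ≥ 38 °C for
≥ 2 days (4).

**Perioperative factors** (observed during surgery): quality of existing
adhesions (filmy 2 / vascular 3 / dense 4), severity on the classical
Knightly extent grades (1–4), bleeding > 500 ml (4), procedure duration
(< 90 min 2, 90 min–2 h 3, > 2 h 4), procedure complexity/extent (3),
excessive coagulation > 2 cm² (2), type and site of surgery (1–4),
intra-abdominal foreign bodies (3), electrical scalpel (2), peritoneal
closing (1). Duration and surgery type/site are mandatory — every
operation has both — which is why the perioperative minimum is 3, not 0.

Each sub-score is stratified with inclusive thresholds:

| risk   | preoperative | perioperative |
|--------|--------------|---------------|
| low    | 0–12         | 3–17          |
| medium | 13–24        | 18–28         |
| high   | 25–36        | 29–31         |

The sum of the two sub-scores (the total ARS, 3–67) is descriptive only —
no combined thresholds exist, so risk is always read off the sub-scores.

## Worked example

```r
library(adhesionrisk)

pre <- preoperative_profile(previous_surgery_count = 2,
                            history_postsurgical_adhesions = TRUE,
                            endometriosis = "moderate")
score_preoperative(pre)
#> Preoperative Adhesion Risk Score: 11 (low risk)
#> Contributing factors:
#>   previous_surgery_count                 4
#>   history_postsurgical_adhesions         4
#>   endometriosis                          3

peri <- perioperative_profile(adhesion_quality = "vascular",
                              adhesion_severity = "two_or_three",
                              duration_minutes = 135,
                              surgery_type_site = "laparoscopy_adhesiolysis_uterus",
                              electrical_scalpel = TRUE)
score_perioperative(peri)
#> Perioperative Adhesion Risk Score: 14 (low risk)
#> Contributing factors:
#>   adhesion_quality                       3
#>   adhesion_severity                      2
#>   duration_minutes                       4
#>   surgery_type_site                      3
#>   electrical_scalpel                     2

total_ars(score_preoperative(pre), score_perioperative(peri))
#> [1] 25
```

The patient scores 11 of 36 preoperatively (two prior surgeries at 4
points, a known adhesion history at 4, moderate endometriosis at 3) and
14 of 31 intraoperatively — both in the low-risk stratum. The total of 25
is informational.

Cohorts work the same way in batch: `read_cohort()` validates a CSV or
JSON cohort row by row (invalid rows become structured reports, not
crashes), `score_cohort()` adds sub-scores, categories and the per-factor
point breakdown, `write_results()`/`read_results()` round-trip the output
exactly, and `summarize_cohort()` reports the risk distribution:

```r
coh <- generate_cohort(500, seed = 42)   # synthetic cohort, seeded
summarize_cohort(score_cohort(coh))
#> Adhesion risk cohort summary (500 patient(s))
#>
#> Preoperative Adhesion Risk Score (n = 500)
#>   low    risk:   491  ( 98.2%)
#>   medium risk:     9  (  1.8%)
#>   high   risk:     0  (  0.0%)
#> ...
```

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/ars.R simulate -n 100 --seed 1 -o cohort.csv
Rscript inst/cli/ars.R score -i cohort.csv -o scored.csv
Rscript inst/cli/ars.R report -i scored.csv -o summary.csv
Rscript inst/cli/ars.R thresholds
```

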