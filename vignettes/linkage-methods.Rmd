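---
title: "Linking birth certificates to hospital episodes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking birth certificates to hospital episodes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(natalink)
```

## The problem

Birth and fetal-death certificates are a census of deliveries but
under-report clinical conditions; hospital discharge abstracts carry rich
ICD-coded diagnoses but no certificate identifiers. Research cohorts that
need both — outcomes plus exposure and utilization — must link the two
record systems without a shared person key, using the handful of fields
both carry: dates of birth, delivery hospital, residence, payer,
race/ethnicity, and clinical facts recoverable from ICD codes. Links are
made twice per delivery: certificate to the *birthing person's* delivery
admission, and certificate to the *infant's* birth admission. A fetal death
has no infant record to find, by definition.

The stakes of a wrong decision are asymmetric. A false link contaminates
every downstream analysis with another person's hospital history; a missed
link merely shrinks the cohort (though possibly differentially — which the
evaluation module exists to measure). The method is therefore deliberately
pessimistic: hard eligibility rules first, then a score cutoff, and
unresolvable cases discarded or flagged rather than guessed silently.

## The linkage model

### Blocking

Scoring all certificate × episode pairs is quadratic and pointless; almost
all pairs share nothing. Each *pass* restricts comparison to pairs agreeing
exactly on a small key set, scores that block, accepts what qualifies,
removes linked records and consumed episodes, and hands the remainder to
the next pass. The maternal schedule is:

| pass | blocking keys |
|---|---|
| A | mother's DOB + hospital |
| B | infant's DOB + zip |
| C | infant's DOB + hospital |
| D | mother's DOB + zip |
| E | zip + hospital |
| F | preterm status + infant's DOB |

Pass A catches the clean majority. The later key sets are chosen so that an
error in any single strong field (a mistyped date of birth, a wrong
hospital, a moved zip) still leaves some pass in which the true pair shares
both keys. Since maternal acceptance independently requires the infant DOB
and hospital to link, pass C's keys coincide with the eligibility
conditions: every acceptable pair is generated by some pass, so multi-pass
blocking loses nothing relative to all-pairs search — a fact the test suite
verifies against a brute-force oracle. The infant schedule (A–I) starts
from hospital + infant DOB with three repeat passes so that twins, whose
second episode is identical on the keys, can link after the first twin
consumed one episode, then widens to zip-based keys.

Two key conventions need stating. The maternal abstract has no infant-DOB
field, so the infant's date of birth "matches" a maternal episode when it
falls within the admission stay (admit ≤ DOB ≤ discharge); the blocking
implementation expands stays (capped at 30 days) into per-day keys. And the
pass-F "preterm" key is a *restriction* — both sides must be preterm
(certificate gestation < 37 weeks; episode gestational-age band below 37
weeks) — not a two-valued key, which would otherwise make pass F an
enormous term-birth block.

### Scoring

Within a block, each pair gets an additive score over 18 comparators (see
the README table); per-variable maxima sum to 148. Choices that the printed
point values do not themselves settle:

- **Condition flags score only positive–positive.** Cesarean, previous
  cesarean, hypertension, diabetes, SGA/LGA and infant death award points
  only when *both* sides record the condition. Joint absence is the normal
  state of most pairs and carries almost no identifying information;
  scoring it would hand ~50 free points to every pair of healthy records
  and destroy the meaning of the cutoffs.
- **Race and ethnicity from one combined field.** The files carry a single
  race/ethnicity category. The race comparator is equality of that
  category, with the printed bonus structure (+5 for a concordant minority
  category, +2 for White); Hispanic is treated as a bonus-eligible
  category, since the printed bonus list enumerates races and Hispanic
  ethnicity is not White. The ethnicity comparator scores concordance of
  Hispanic vs non-Hispanic status derived from the same field.
- **Date transposition.** A date contributes its reduced 5 points when
  swapping month and day of one side yields the other and month ≠ day (the
  swap must produce a different, valid date). A differing year with equal
  month/day contributes 0 points but — for the mother's DOB only —
  preserves eligibility (`dob_relaxation_used` is logged per pair). The
  relaxation levels apply to the birthing person's date of birth; the
  infant DOB must link exactly on the maternal side, and exactly or
  transposed on the infant side.
- **Infant-side variable set.** Infant scoring is the same table minus the
  mother's DOB row. Maternal-condition comparators (previous cesarean,
  hypertension, diabetes) remain in the table but their code sets are
  maternity codes, so they contribute nothing on newborn episodes unless
  such codes actually appear — the reduced attainable total is why the
  infant cutoff is lower.

### Acceptance and selection

Maternal: eligibility (mother DOB linked at some level, infant DOB linked,
hospital linked, ≥ 1 other variable linked) **and** total ≥ 40. Infant:
concordant sex **and** total ≥ 31; discordant sex is never accepted. The
cutoffs and rules are identical in every pass. Exhaustive sweeps over all
combinations of per-variable point levels confirm 40 and 31 are exactly the
minima an accepted pair can score, and that 39- and 30-point analogues are
always rejected.

Selection is greedy in descending score: the globally best accepted pair is
assigned first, so a contested episode goes to its higher-scoring claimant;
among one record's equal-best candidates one is chosen uniformly at random
and flagged. Concretely: accepted candidates are sorted by (score
descending, record id, episode id), one uniform tie-break key per row is
drawn from the seeded generator, rows are re-sorted by (score, record id,
key) and scanned, taking each row whose record is unassigned and whose
episode is unconsumed. This makes every random choice reproducible and lets
an independent loop implementation replicate the engine bit for bit.
Whether a globally optimal (maximum-weight matching) assignment would
differ is measurable on small instances; greedy matches the per-record
maximum description and is what the tests pin down.

### Multiples and the longitudinal step

Records of one sibling set may share a single maternal episode, but a
twin/multiple certificate only links to an episode itself coded twin or
multiple (configurable via `require_plurality_concordance`). When same-sex
siblings agree on sex, birthweight band, delivery mode and survival, their
episodes are interchangeable: assignment among them is randomized and
flagged `twin_ambiguous`, because no deterministic choice would be more
than a guess.

Follow-up episodes (readmissions, ED visits) attach within a window — one
year before through one year after delivery for the birthing person, birth
to one year for the infant — when the encrypted SSN matches *and* at least
one further variable corroborates; an SSN match alone never suffices, since
SSNs can be shared or reused. Episodes without an SSN attach on exact DOB
plus at least two of zip, county, payer, race/ethnicity. That variable rule
is this package's concrete reading of "the scoring path applies": most
Table-style comparators (gestational age, birthweight, delivery variables)
do not exist on non-birth episodes, so the full additive score is not
computable there.

## The synthetic cohort

Real certificate and claims files are restricted, so the generator builds a
cohort with the same *statistical shape* and a known truth table. Defaults
were fixed once, from the marginals a large US statewide birth cohort
exhibits: twin rate 3.03%, higher multiples 0.11%, fetal deaths 0.55%,
live-birth gestational-age bands (0.54% at 20–27 weeks through 1.14% at
43–44), band-dependent birthweight distributions and infant-death risks,
payer/race/education distributions, comorbidity prevalences with
*per-source recording sensitivities* (e.g. gestational diabetes: 9.3% true
prevalence, recorded on ~48% of certificates but ~88% of hospital
abstracts — which is what makes the dual-source ascertainment table worth
computing), encrypted-SSN coverage of 80% (mothers) and 5% (infants), and
withholding rates of 5% / 3% standing in for episodes genuinely absent from
claims (out-of-state, home births, unreported).

Episode ICD codes are written from the generated clinical truth using the
era-appropriate revision (ICD-9 before 2016, ICD-10 after), so indicator
derivation inverts the generation on unperturbed data. Three coding corners
are handled explicitly: band groups with no code in one revision (term
gestation has only an ICD-9 code, post-term and macrosomia only ICD-10)
fall back to the other revision's code; the mid-birthweight ICD-10 codes
(P05.09/P05.19) sit under the P05 abnormal-growth family, which also
defines the SGA/LGA indicator, so mid-band weights are emitted with the
ICD-9 band code to avoid asserting a growth abnormality that is not there;
and newborn cesarean status uses P03.4/763.4 rather than the Z38.01-style
codes whose prefixes double as plurality indicators.

The error model perturbs episodes independently per field: month/day
transposition of the patient DOB (skipped and logged when month equals day
or the day exceeds 12), deletion of each of patient DOB, zip, county,
payer, race/ethnicity, and single-digit zip corruption. Independence is the
simplest model that exercises every comparator branch; correlated
missingness (e.g. self-pay records withheld more often) is reproduced in
tests by stratified withholding, which is how the linked-vs-unlinked bias
table is exercised. What the generator does **not** emulate: realistic
geography or hospital volumes, secular trends, duplicated certificates,
mothers with multiple deliveries in the window, or out-of-window episode
noise. Passing tests on this cohort therefore demonstrate correctness of
the *method's mechanics*, not field performance on statewide-scale data.

## Numerical and degenerate-input conventions

- Percentages in every evaluation table are `100·n/d` rounded half-up to
  two decimals (`percent_of()`); counts are never rounded; 0/0 is reported
  as `NA`, never as 0.
- Conflicting band codes on one episode resolve worst-first (shortest
  gestation, lowest birthweight, highest plurality), preserving the
  highest-scoring match opportunity and mirroring clinical coding habits.
- Both ICD revisions are matched on every episode regardless of date: the
  study window spans the 2015 transition and prefix sets make dual matching
  harmless.
- Missing values never match anything: a missing blocking key excludes the
  pair from the block; a variable missing on either side contributes 0 and
  cannot serve as the required "other" variable.
- Truth-based accuracy treats infant links inside an indistinguishable
  sibling set as correct when they land on any class member's true episode:
  the truth labels within such a set are arbitrary (the records are
  exchangeable), so demanding the labeled episode would penalize a
  coin-flip no method can avoid.
- Evaluation problem sizes in the test suite (50 oracle instances of ≈60
  deliveries, 10,000-delivery recovery runs, 800-delivery missingness
  replicates) were chosen as the smallest sizes at which the checked
  properties are statistically unambiguous.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `mother_cutoff` | 40 | minimum accepted maternal link score (points) |
| `infant_cutoff` | 31 | minimum accepted infant link score (points) |
| `require_plurality_concordance` | TRUE | multiples must be coded multiple on both sides |
| `ssn_requires_extra_variable` | TRUE | SSN match needs ≥1 corroborating variable |
| `rng_seed` | 1 | tie-breaking and twin-assignment stream |
| comparator points | Table defaults | overridable via `comparator_spec(...)` for sensitivity analyses |
| code sets | packaged YAML | overridable via `read_code_sets()` |

The ascertainment-only code sets (eclampsia, abruption, chorioamnionitis,
birth-defect groups) are editable defaults chosen as standard prefix
groups; unlike the scoring sets they are not fixed by the method and should
be reviewed before substantive use.

## Known limitations

- Greedy selection is per-record optimal, not globally optimal; contested
  episodes resolve by score order, which can in principle differ from a
  maximum-weight matching.
- The infant-side comparator membership beyond the maternal table minus
  mother-DOB is an interpretation; the reduced set is consistent with the
  lower cutoff but other reduced sets are conceivable.
- Identical-twin assignment is irreducibly random; analyses of multiples
  must respect the `twin_ambiguous` flag.
- The longitudinal non-SSN rule (exact DOB + two corroborating variables)
  is a design choice where the full score table is not computable.
- Linkage quality measured on the synthetic cohort bounds nothing about
  restricted real files; it validates mechanics, determinism and the
  evaluation arithmetic only.
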