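---
title: "Measuring donor engraftment after FMT: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring donor engraftment after FMT: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(engraftr)
```

## The scientific problem

Fecal microbiota transplantation (FMT) transfers a donor's stool-derived
microbial community to a recipient. Whether that community *engrafts* —
whether donor taxa establish and persist in the recipient gut — is the
mechanistic primary endpoint of many FMT trials, separate from any clinical
response. `engraftr` implements the engraftment analysis for a four-arm
capsule-FMT trial design in diarrhea-predominant irritable bowel syndrome:
FMT alone, FMT after a 7-day rifaximin course (R-FMT), FMT after
ciprofloxacin + metronidazole (CM-FMT), and placebo, with stool sampled at
baseline, during antibiotics (antibiotic arms), and 1 and 10 weeks
post-treatment, all profiled as 97%-identity 16S OTU count tables.

## The engraftment statistic

For one subject, let $D$ be the set of OTUs present in the donor material,
$B$ the set present in the subject's baseline stool (collected before any
antibiotics), and $P_t$ the set present in the post-FMT sample at week
$t \in \{1, 10\}$. The engrafted set is

$$E_t = (D \cap P_t) \setminus B,$$

i.e. taxa that can only plausibly have arrived with the transplant: present
in the donor and in the recipient afterwards, but absent beforehand. Presence
means a nonzero count in the filtered table; an optional relative-abundance
floor (`presence_floor`) is available for noise robustness but defaults to 0,
because presence/absence is the natural reading of the definition.

The per-timepoint percentage needs a denominator, and trial reports commonly
omit it. Three are implemented (`mode` in `compute_engraftment()`):

* **abundance** (default): $100 \cdot \sum_{o \in E_t} c_t(o) / \sum_o c_t(o)$,
  the share of post-FMT reads carried by engrafted taxa. This is the default
  because it is scale-free, insensitive to sequencing depth, and weights
  established taxa by how much of the community they occupy, which matches
  the magnitude of typical reported engraftment percentages.
* **donor_richness**: $100 \cdot |E_t| / |D|$ — the fraction of the donor
  repertoire that took.
* **post_richness**: $100 \cdot |E_t| / |P_t|$ — the fraction of the
  post-FMT community that is new donor material.

The primary outcome averages week 1 and week 10; a subject with a single
post-FMT sample keeps that value with a `single_timepoint` flag, and a
subject with neither is excluded (and logged). Subjects without a baseline
sample are excluded, since $B$ is undefined.

**Donor pooling.** In a capsule program where the same donor panel supplies
every FMT arm and per-patient donor assignment is not recorded, the only
faithful donor set is the union over the panel; `donor_policy = "union"` is
therefore the default, with `"listed"` available when per-subject
`donor_ids` metadata is meaningful. Pooling widens $D$, which can only
inflate the engrafted set, so the choice is conservative for *between-arm
contrasts* (all arms are inflated alike) but matters for absolute values —
another reason the abundance denominator, which is insensitive to $|D|$, is
the default.

## OTU table processing

Tables are tidy long tibbles (`sample_id`, `otu_id`, `count`) with a
complete grid, so on-disk round trips are lossless; the disk dialect is the
classic tab-separated layout with OTUs as rows under a `#OTU ID` header
(auto-detected; a `sample_id` header means the transposed orientation).

The standard filter discards OTUs seen in fewer than 2 distinct samples or
with fewer than 10 reads. Two readings of the read rule are possible
(per-sample or total across samples); `engraftr` takes **total across
samples**, the literal reading, with both thresholds inclusive at the
boundary (exactly 2 samples, exactly 10 reads are retained) and both
configurable. The filter is idempotent and never drops samples.

No rarefaction or depth normalisation is applied anywhere by default; an
explicit seeded `rarefy_otu_table()` exists for users who want it, and
`sample_diversity(min_depth=)` can gate out shallow samples. This mirrors
analyses that report a single low-depth sample rather than normalising.

## Diversity and the statistical battery

Shannon diversity is $H = -\sum p_i \ln p_i$ in **nats**; the log base is a
pure scale choice that cancels out of every rank- or t-based comparison, and
natural log is the common default. Timepoint contrasts are two-sided paired
t-tests on within-subject differences; an all-zero difference vector has an
undefined t and is reported as non-significant with a `zero_variance` flag.

The arm contrast for engraftment is the tie-corrected Kruskal–Wallis test
with Dunn's posttest (pooled tie-corrected rank variance, two-sided normal
p, unadjusted by default — matching an analysis plan that explicitly does
not control multiplicity; Bonferroni is available). For total $n \le 10$ an
exact permutation p over all group assignments can replace the chi-square
reference. The Mann–Whitney U test is exact by full enumeration whenever
$\min(n_1, n_2) \le 8$ (ties included, two-sided p as twice the smaller tail,
capped at 1), otherwise a tie- and continuity-corrected normal
approximation.

Because published outcome tables print only (n, mean, sd) per arm, the
ANOVA and t-tests are implemented directly on summaries:
$SSB = \sum n_i(\bar x_i - \bar x)^2$, $SSW = \sum (n_i - 1) s_i^2$, and the
pooled-variance two-sample t. These reproduce, at printed precision, the
four-arm ANOVA of IBS-SSS change (p = 0.55), the baseline-severity ANOVA
(p = 0.03), and the combined-FMT-vs-placebo t-tests (p = 0.68 and 0.47); the
pooled (not Welch) variant is the default because it is the form consistent
with those printed values.

Fisher's 2×2 test uses the conventional probability-mass two-sided rule
(sum of hypergeometric point masses ≤ the observed mass, with a relative
fuzz of 1e-7 against floating-point ties); the R×C Freeman–Halton
generalisation enumerates all tables with the observed margins by recursive
cell filling, with a seeded `r2dtable` Monte-Carlo fallback when the margin
budget exceeds `max_tables`.

**Known inconsistencies in the reference tables.** Two printed p-values are
not reproducible from their own printed inputs and are deliberately *not*
matched: the four-arm ANOVA of IBS-QoL change from the printed summaries
gives 0.21 (printed: 0.61), and the Freeman–Halton test on the printed
adequate-relief counts gives 0.71 (printed: 0.66 — which instead coincides
with a Monte-Carlo chi-square on the same counts); the combined-arms
adequate-relief 2×2 likewise gives ≈0.70 rather than the printed 0.10.
These are documented as discrepancies, most plausibly per-outcome n
differences or a different test variant in the original analysis; the
package reports what the stated tests actually produce.

## Clinical scoring

IBS-SSS is consumed as its 0–500 composite; a responder is a decrease of at
least 50 points (inclusive). IBS-QoL is either consumed as its 0–100 score
or computed from the 34 five-point items via the instrument's linear
transform $100(170 - \sum \text{items})/136$ (item orientation configurable,
since only the transformed range is standardised); a responder improves by
at least 12 points (inclusive). Global improvement on the 1–7 scale counts
6 ("moderately improved") and 7 ("substantially improved") as response;
adequate relief is the dichotomous item itself. Missing inputs propagate to
missing flags — no imputation. `outcomes_table()` assembles the four-arm
and combined-arms views with the ANOVA / Freeman–Halton / pooled-t /
2×2-Fisher tests described above, and subjects with questionnaires but no
week-10 stool stay in the clinical analysis while dropping out of the
engraftment analysis (per-protocol semantics).

## The synthetic trial generator

`simulate_trial()` exists so that every stage can be validated against known
truth without any sequencing data. Its generative model:

* Three OTU pools: recipient-only (120), shared donor/recipient (60), and
  donor-unique (60). Community profiles are log-normal relative abundances
  (sdlog `lognormal_sigma = 1`), a standard neutral-ish abundance model that
  produces the realistic few-dominant/many-rare shape.
* Six donors, each a log-normal profile over shared + donor-unique OTUs;
  the capsule material's donor-unique component is the renormalised mean of
  the donor profiles.
* Each subject's baseline is a log-normal profile over recipient-only +
  shared OTUs — donor-unique OTUs have *probability zero* at baseline, which
  is what makes engraftment identifiable, while shared OTUs exercise the
  "present in donor and baseline → not engraftable" exclusion.
* Antibiotic arms get a during-antibiotics sample: the baseline profile
  with a depletion factor (0.1) applied to a random half of taxa, then
  renormalised — Shannon decreases in expectation. Recovery at the post-FMT
  timepoints returns depleted taxa fully by default (`lost_fraction`
  configures permanent loss).
* Post-FMT profiles are $(1-f)\times$ recovered baseline $+\ f\times$
  donor-unique mixture, so the expected abundance-mode engraftment equals
  $f$ *exactly* in the generating measure. All samples are multinomial draws
  at `depth` reads.

Defaults are fixed at the trial's conditions: 4 arms × 11 subjects, transfer
fractions 0.15 / 0.05 / 0.02 / 0 (chosen to match the observed ordering and
magnitude of engraftment in the three FMT arms and placebo), depth 10,000
reads (the study's typical per-sample depth), seed mandatory and
bit-reproducible. Clinical records are drawn arm-independent (a null
clinical effect) unless `clinical_effect` shifts arm means.

What the generator does **not** emulate: compositional correlation between
taxa, strain-level dynamics, time-varying recovery trajectories, donor
specificity per subject, read-level error, or any association between
engraftment and symptom change. Passing the recovery tests therefore shows
the *measurement pipeline* is unbiased under the stated model — not that
real engraftment behaves this way. Two known small biases exist in opposite
directions on real-shaped data: rare shared/baseline taxa missed by
sampling at baseline can be falsely called engrafted (inflationary, bounded
by their low post-FMT abundance), and engrafted taxa below the detection
limit are missed (deflationary). Both shrink with depth, which the test
suite checks explicitly (depths 1k/10k/100k, decreasing absolute bias).

## Problem sizes and numerical choices in the test suite

The suite validates: set logic against per-element brute force (200 random
triples); the filter against an independent per-OTU predicate scan (20×50
random tables); summary-statistics ANOVA/t against `stats::aov`/`t.test` on
raw data reconstructed to match each (n, mean, sd) exactly; Kruskal–Wallis
against `stats::kruskal.test` and, at $n = 9$, an independent exact
permutation enumeration; Mann–Whitney against full-enumeration oracles
(with and without ties); the 2×2 Fisher against direct hypergeometric
summation over all tables with margins ≤ 6; the Freeman–Halton enumeration
against an independent vectorised enumeration over all 2×3 tables with
total $n \le 12$ and against `stats::fisher.test`; type-I error of the
Kruskal–Wallis test across 1,000 null simulations (nominal 5%, accepted in
[3%, 7%]); and parameter recovery on synthetic trials (10–20 subjects/arm,
depth 10,000, medians within ±2 percentage points of the configured
fractions, ≤ 0.5% under the null). These sizes keep the full suite under a
minute while leaving the recovery margins comfortably away from their
thresholds.

## Limitations

* Engraftment is OTU-level presence/absence; it cannot distinguish a
  transferred strain from an indigenous strain of the same OTU that was
  simply undetected at baseline. Strain-resolved source tracking is out of
  scope.
* The denominator of "percent engraftment" is a design choice, not a
  community standard; absolute values are comparable only within a mode.
* The exact R×C test is enumeration-bound; very large margins fall back to
  Monte-Carlo with a seed.
* The generator's log-normal/multinomial model has no taxon covariance and
  no overdispersion beyond multinomial sampling; real 16S data are noisier.
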