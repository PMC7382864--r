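---
title: "Linking birth registers to a social-registry cohort: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking birth registers to a social-registry cohort: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(birthlink)
```

## The problem

Administrative registers rarely share a unique person identifier. To follow
children of a live-birth register (SINASC-like) into a social-registry
cohort baseline (CadÚnico-like), the mother's record must be found among
tens of millions of candidates using only her name, age or date of birth,
and municipality and state of residence — attributes that are misspelled,
perturbed, or simply absent. A specific complication of this setting is
structural: the mother's date of birth only entered the birth form partway
through the study period, so earlier records can only be matched through
her recorded age.

`birthlink` implements the full similarity-based pipeline for this task —
name standardization and screening, inverted-index blocking with a tiered
query cascade, weighted pairwise scoring, one-to-one assignment, ROC-based
threshold selection from a stratified labeled sample, and quality/bias
reporting — together with a synthetic register generator that plants a
known truth, so every stage can be validated without confidential data.

## Candidate retrieval

The cohort register is indexed once: postings lists map each (field,
token) to the cohort rows carrying it, over the full standardized name,
the individual name tokens, the municipality code, the state code and the
compact date of birth. A probe (one birth record) then goes through three
tiers:

* **exact** — the intersection of the postings of every supplied probe
  attribute (name + municipality, plus mother DOB when the record has
  one). Name equality means the ordered token sequence, the strictest
  reading of attribute equality.
* **semi-fuzzy** — candidates agreeing on all supplied attributes but
  exactly one (the union of leave-one-attribute-out exact intersections,
  minus the exact tier).
* **fuzzy** — candidates sharing at least one name token, ranked by
  shared-token count, then normalized Damerau-Levenshtein similarity of
  the full names, then row number (a deterministic tie-break). Candidates
  whose normalized similarity is not *above* `dl_floor` (default 0.5) are
  discarded; the floor is exclusive, so a floor of 1 retains nothing.

The concatenation exact → semi-fuzzy → fuzzy, deduplicated keeping the
highest tier, is truncated to the best `k = 1000` candidates. Only the
name field is fuzzy-matched; municipality and DOB are relaxed by omission
(the semi-fuzzy tier), since string distance between administrative codes
is not meaningful.

## Pairwise scoring

Each retrieved candidate is compared attribute by attribute:

* mother's name — Jaro–Winkler similarity (prefix scale 0.1, prefix cap
  4). The Jaro core counts common characters within a window of
  `floor(max(|s1|, |s2|)/2) - 1` positions, with the transposition count
  `t` equal to half the matched characters read back in different order.
* mother's date of birth — normalized Hamming similarity
  `1 - d/8` on the 8-digit compact form `YYYYMMDD`. The fixed width is
  this package's serialization convention; a width mismatch is an error,
  never a truncation.
* municipality and state — binary code equality.

The attribute weights reflect discriminatory power: name 1, age-or-DOB 1,
municipality 0.16, state 0.008. The combined score is the
weight-normalized mean

$$ s = \frac{\sum_i w_i s_i}{\sum_i w_i} $$

over the attributes *available on both records*. The combination rule is a
design choice of this package: renormalizing over available attributes
keeps every score in [0, 1] whatever the missingness pattern, which is
what makes a single link threshold comparable between the era with mother
DOB and the era without it.

Records without a usable mother DOB take the **age route**: the age
derived from each candidate's date of birth and the child's date of birth
(exact completed calendar years — never division by 365.25, since an
exact-equality filter is sensitive to off-by-one arithmetic) must equal
the recorded maternal age exactly; candidates failing the gate are
dropped, and survivors receive similarity 1 on the age attribute, carrying
its full weight. When the recorded age itself is missing the gate is
skipped and the attribute is dropped from the weighted mean. The
gate-then-contribute-1 reading is one of two defensible interpretations
(the other being a weightless gate); it was chosen so that both eras have
the same weight mass when their discriminating attribute agrees, and is
applied uniformly.

## One-to-one assignment

All scored pairs compete globally: pairs are sorted by score (descending),
then birth id, then cohort id, and accepted greedily iff neither side is
already taken. This is order-independent — permuting the input changes
nothing — and guarantees no cohort record is assigned twice. A birth whose
candidates are all taken falls to its best available candidate or, if
none, stays unmatched. Ties on score are broken toward the smaller birth
id, a documented arbitrary rule that makes reruns identical.

## Threshold selection

Assigned pairs are sampled for labeling, stratified by score: low
(< 0.90), intermediate (the closed interval [0.90, 0.95]) and high
(> 0.95). The interval-endpoint choice is a convention (the boundary
wording "between 0.90 and 0.95" is inherently ambiguous) and is
configurable. Allocation is proportional to stratum size with a floor of
10 per non-empty stratum, sampling without replacement, deterministic
under the seed; the default sample size is 2000. On synthetic data labels
come from the planted truth; on real data a review file stands in for
clerical review.

The ROC curve is computed over every distinct observed score as a cut
point (rule: score ≥ cut is a link), the AUC by trapezoidal integration —
equivalently, the Mann–Whitney probability that a random true pair
outscores a random false pair, which is how the test suite cross-checks it
(together with `pROC`). The operating threshold maximizes Youden's
J = sensitivity + specificity − 1, ties broken toward the higher threshold
(favoring specificity). Two degenerate cases are handled explicitly: a
one-class sample is an error for ROC construction, and the all-true sample
that noise-free data produces yields the minimum observed score as a
flagged threshold. Classification uses a single threshold with the ≥ rule,
clamped to [0, 1].

## Offspring search

After a mother is linked, her family in the cohort is searched for the
unique member with the child's date of birth and sex. No match returns
null; more than one (same-sex twins sharing a date of birth) is flagged as
ambiguous and left unassigned rather than guessed.

## The synthetic generator

`generate_population()` builds a cohort of adults grouped into families
and a births register in which `round(overlap_fraction × n_births)`
records have a true cohort mother; their children are also planted as
cohort members of the same family so offspring search is exercised.
Maternal attributes on the birth side are copied from the truth and then
corrupted:

* `typo_rate` — per-name probability of 1–2 typographical errors, each
  drawn uniformly from character substitution, deletion, insertion,
  adjacent transposition and token drop (operators that would empty the
  name fall back to substitution);
* `missing_mother_dob_rate` — probability the birth record lacks the
  mother's DOB, emulating the era before the attribute existed and its
  gradual fill-in afterwards;
* `municipality_mismatch_rate` — probability the residence code differs
  between registers (moves, re-registration);
* `age_error_rate` — probability the recorded age is off by one year from
  the derived age, the exact failure mode of the age gate;
* `covariate_missing_rate` — per-covariate probability of an explicit
  `Missing` category, so bias reports exercise their Missing rows.

Defaults (cohort 1000, births 600, overlap 0.6, typo 0.05, DOB missing
0.2, municipality mismatch 0.05, age error 0.05, covariate missing 0.05,
years 2010–2015) are the package's desk-scale study conditions: large
enough that rates are stable to a couple of percentage points, small
enough that the whole validation suite runs in well under a minute per
configuration. Names are composed from bundled token lists (~220 given
names, ~210 surnames plus Portuguese connectives), which double as the
screening lexicon.

Deliberate simplifications, and what they imply for the tests: adult dates
of birth are unique, so the exact-age gate is more discriminating here
than in a real register where age ties are common at scale; given names
carry no sex signal; municipalities are 30 synthetic codes in three
states; every overlapping birth has a distinct mother (the one-to-one
assignment invariant would otherwise cap recall by construction); and when
`overlap_fraction × n_births` exceeds the number of women drawn at the
nominal 55% share, additional cohort members are made female so each
overlapping birth can have its own mother. Passing tests therefore
demonstrate the machinery is correct under the stated error model, not
that real-register accuracy would match these numbers.

## Numerical and design choices

* Damerau-Levenshtein is the **restricted** (optimal string alignment)
  variant, the standard in linkage tooling; it differs from the
  unrestricted distance on rare inputs (e.g. `"CA" → "ABC"` is 3, not 2),
  and the suite pins this behaviour against a brute-force oracle.
* Accent folding and punctuation-to-space replacement happen before token
  comparison; standardization is idempotent.
* Report percentages are rounded half away from zero to 2 decimals,
  matching the presentation convention of the published yearly table.
* Validation problem sizes: blocking recall at cohort 1000 / 600
  overlapping births; cross-product equivalence at cohort 300 / births
  200 with `k` equal to the cohort size and `dl_floor` 0 (the lossless
  retrieval setting; with partial overlap, zero-token-overlap pairs exist
  that no token index can see, so the pair-for-pair comparison is run at
  full overlap where every record's best partner shares a token);
  overlap recovery at the defaults over 5 seeds; the DOB-vs-age ablation
  at cohort 500 / births 300 with `age_error_rate` 0.25, the regime where
  the age gate demonstrably degrades and the direction of the contrast is
  well-defined.

## Limitations

The package models the linkage machinery, not Brazilian demography:
municipality sizes, name frequencies and covariate distributions are
schematic. The clerical review is a file, not an interface. Blocking
recall and accuracy figures measured on synthetic registers characterize
the implementation under its own error model; calibrating the error rates
against a real register pair is the user's task before interpreting
absolute numbers.
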