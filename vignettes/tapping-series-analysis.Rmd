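---
title: "Tapping-series expression analysis: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tapping-series expression analysis: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tapseq)
```

## The problem

Latex is harvested from *Hevea brasiliensis* by tapping the trunk bark, and
the first few tappings of a virgin or rested tree strongly stimulate latex
production. Profiling the latex transcriptome (cDNA-AFLP band intensities)
and proteome (2-DE spot volumes) across the first five tappings asks, for
every feature, a simple question with a time-series answer: relative to the
first tapping, does abundance go up, down, or wander? `tapseq` implements
the desk side of that analysis — normalization, trajectory classification,
differential calling, redundancy removal, annotation triage, qPCR
quantification, and cross-platform concordance — plus a generator that
simulates the whole data structure so every stage is testable without gels.

## Trajectory model and classifier

Each feature yields raw abundance $x_{tr}$ at tapping $t = 1..5$ and
replicate $r$. Replicates are averaged arithmetically (a gel lane is
quantified once; replicate gels are averaged) and the trajectory is
normalized to the first tapping:

$$ r_t = \bar{x}_t / \bar{x}_1, \qquad r_1 = 1 . $$

Classification into the three regulation types and their subtypes is, in
the original assay, a visual judgement on gel images. The computable
procedure here uses three tolerances, all exposed in
`classifier_params()`:

* `delta` (default **1.25**): a trajectory *excurses* upward when
  $\max r_t \ge \delta$ and downward when $\min r_t \le 1/\delta$. No
  excursion in either direction means "unchanged". The default is our
  choice of the smallest fold a densitometry read-out supports calling;
  the original screen scored this by eye, so any numeric value is a
  formalization.
* `eps_end` (default **0.05**): how far the final point $r_5$ must sit from
  baseline before we say the trajectory *ended* above or below the first
  tapping. The comparison is on the fold scale ($r_5 > 1+\varepsilon$
  versus $1/r_5 > 1+\varepsilon$), which makes the classifier exactly
  symmetric under reciprocal trajectories — a property the test suite
  checks.
* `eps_mono` (default **0.15**): consecutive changes within this relative
  band count as "flat" when deciding between *rises successively*,
  *rises then stabilizes* and *rises then declines*.

The decision procedure: a single up-excursion whose endpoint stays at or
above baseline is **up**; if the endpoint has crossed below baseline the
trajectory is **irregular-1** (rise, then fall below the start). The
down/irregular-2 cases mirror this on $1/r$. Both excursions give
irregular, subtype by whether the maximum precedes the minimum.

Within "up", a series with no falling step (beyond `eps_mono`) that ends at
its maximum is subtype 1 when the last step still rises ($r_5 > r_4$) and
subtype 2 when it ends on a plateau; an interior maximum with a discounted
endpoint ($r_5 < \max r (1-\varepsilon_{mono})$) is subtype 3. Requiring a
rising last step for subtype 1 is deliberate: a plateau-ending template
must land in subtype 2, otherwise the two shapes are not separable even at
zero noise. Shapes that match a major type but none of the three idealized
subtypes get subtype **0** — real validation series (e.g. a dip before a
steep late rise) need this bucket, and only the major type feeds
downstream consistency scoring.

## Differential calling

Two rules, matching the two assays:

* **Protein spots**: differentially expressed when abundance changes at
  least 3-fold between tapping 1 and any later tapping
  ($\max(r_t, 1/r_t) \ge 3$) *and* that tapping's two-sided equal-variance
  Student's t-test against tapping 1 has $p \le 0.05$. Ties at exactly
  $\alpha$ count as significant. The fold magnitude is two-sided because
  both directions of regulation were reported.
* **Transcript bands**: the original screen called bands visually; the
  computable surrogate requires a significant one-way fixed-effects ANOVA
  across the five tappings ($p \le \alpha$) plus an excursion of at least
  `delta` (shared with the classifier).

Degenerate inputs follow the sum-of-squares limits: zero between- and
within-group variation gives $p = 1$; positive between- with zero
within-group variation gives $p = 0$. No multiple-testing correction is
applied, matching the original analysis. The conjunction with the 3-fold
filter keeps the protein rule's family-wise false-positive rate under
$\alpha$ on null data even though four t-tests are run per feature — the
acceptance checks measure this on 10,000 null features.

## Redundancy, triage, summaries

Cloned fragments from the same transcript with the same expression pattern
are clustered and only the longest fragment kept. "Same pattern" means the
same *major* type: subtype boundaries depend on tolerances, so clustering
on them would make the non-redundant set tolerance-dependent. Ties in
length keep the lexicographically smallest id, making the operation
deterministic and idempotent.

BLAST hits pass only with E-value $< 10^{-4}$ and score $> 50$ (both
strict). Buckets: *no hit* (nothing passes), *predicted* (best passing hit
is a predicted/hypothetical/uncharacterized protein), *unclassified*, and
*known* with a functional category. The original "unclassified" criterion —
"the functional annotation being multiple" — is qualitative; we formalize
it as: the passing hits map to two or more categories with no majority, or
to no category at all. Category mapping uses an editable keyword lexicon
(`inst/extdata/lexicon.json`) over the 11 functional categories of plant
genes with rubber biosynthesis singled out of secondary metabolism; more
specific categories (e.g. rubber biosynthesis) are matched before broader
ones so "rubber elongation factor" never falls through to generic protein
synthesis keywords.

Summaries cross-tabulate category against major pattern with percentages
rounded **half-up** to one decimal, the rounding used in the printed
tables (83.8, 43.0).

## qPCR quantification

`ddct()` implements $2^{-\Delta\Delta C_T}$: per replicate
$\Delta C_T = C_T^{target} - C_T^{ref}$, per tapping
$\Delta\Delta C_T = \overline{\Delta C_T}(t) - \overline{\Delta C_T}(1)$,
$rq = 2^{-\Delta\Delta C_T}$. Using per-tapping means of replicate
$\Delta C_T$ (rather than averaging per-replicate $rq$) is the standard
form of the method; the spread is still reported as the standard deviation
of per-replicate $rq$, matching "average ± STDEV" plotting. Whether
technical replicates should be averaged before biological ones is not
determined by the source material; the function aggregates whatever
replicate column it is given, so both orders are available to the caller.
The quantity is invariant to adding a constant to all Ct values (machine
offset), which the tests assert. Amplification-efficiency correction and
melt-curve QC are out of scope.

`sq_relative()` handles the semi-quantitative variant: target band
intensities are first divided by the reference-gene band per tapping
(template loading equalized on a constitutive reference), then normalized
to tapping 1.

## Concordance

`score_consistency()` pairs calls by feature id and counts a pair
consistent only when both calls are present and the *major* types agree —
consistency flags in validation tables are coarse, type-level judgements,
so subtypes are ignored. A feature with no call on one platform ("no
band") stays in the denominator as inconsistent. Percentages are half-up
to one decimal. The gel-side calls of the shipped validation fixtures are
printed only as images in the source tables; the fixtures therefore carry
the printed consistency flag as ground truth, and
`sq_validation_calls()` reconstructs the gel call from it (equal major on
concordant rows, a differing placeholder on discordant rows) so that the
scoring function computes the published percentages rather than echoing
them.

`transcript_protein_overlap()` joins protein spots to TDFs on an explicit
gene identifier; sequence-similarity matching is deliberately out of
scope. The shipped counterpart fixture is a synthetic reconstruction (the
spot-level patterns and gene ids are not printed anywhere) encoding the
documented join structure and its single direction-consistent pair.

## The synthetic-data generator

`simulate_trajectories()` draws, per feature, a subtype from
`subtype_mix`, a baseline abundance $\mu$ (lognormal, median 100), and
emits $x_{tr} = \mu\, s(t)\, e^{\sigma Z}$ with $Z$ standard normal.
Multiplicative lognormal noise is the natural model for densitometry:
values are positive and right-skewed, and ratios stay well-defined. The
shape templates $s(t)$ (anchored at $s(1)=1$; see `shape_template()`) give
each subtype an unambiguous zero-noise signature: geometric rise to $f$;
rise to $f$ by tapping 3 then constant; peak $f$ at tapping 3 then decline
to $\sqrt f$; their reciprocals; and the two overshoot shapes for the
irregular subtypes. Defaults: three replicates per tapping (the replicate
structure of the assays), effect fold $f = 3$ (the fold scale at which
the assays call differential abundance), noise $\sigma = 0.2$ (a ~20%
coefficient of variation, a realistic band-densitometry spread; the
within-treatment variance of gel intensities is not published, so this
default is asserted, not inferred), subtype mix 43.0/35.6/21.4% split
evenly within type, and redundancy rate $651/505$. One master seed
derives independent child streams per output table, so truth, intensity,
Ct and FASTA outputs are individually reproducible.

`simulate_qpcr()` maps the same templates into Ct space
($C_T = C_0 - \log_2 s(t) + e$) with a constant-in-expectation reference
gene, emulating a stable internal standard.

What the generator does *not* emulate: gel-image artefacts (smiling,
saturation, background), correlated noise between tappings run on one gel,
amplification-efficiency differences between primer pairs, and the
detection floor that makes low-abundance proteins invisible on 2-DE.
Passing tests on simulated data therefore demonstrate the correctness of
the computations, not the field performance of the assays.

## Problem sizes and numerical choices

The test and acceptance runs use sizes chosen to make Monte-Carlo noise
negligible while keeping a full run interactive on a laptop: 1,000
features for noisy-recovery calibration ($\sigma = 0.1$, $f = 2$), 10,000
null features for the type-I-error measurement, 100 random small instances
for the ANOVA/t-test oracle comparisons at $10^{-10}$ tolerance, and the
651-record funnel for redundancy conservation. Excursion and endpoint
comparisons use plain floating-point comparisons — the tolerances
themselves (`delta`, `eps_mono`, `eps_end`) are the intended guard bands,
so no extra epsilon is layered on top. Zero-variance detection in the
test wrappers uses a relative $10^{-12}$ threshold on the sums of squares.

## Known limitations

* The classifier tolerances are formalizations of a visual call; on real
  gel data the defaults should be tuned against a validation subset.
* Keyword-lexicon categorization is as good as the lexicon; it ships as an
  editable JSON precisely because manual curation beats any keyword list.
* The concordance fixtures reconstruct the unprinted gel-side calls from
  the published flags; they validate the scoring arithmetic, not the gel
  calls themselves.
* No multiple-testing correction or variance shrinkage is offered, by
  design: the package reproduces the original analysis contract.
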