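---
title: "Designing and validating siRNA: models, corrections and synthetic studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and validating siRNA: models, corrections and synthetic studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sirnadesign)
```

# The problem

A 21-nt siRNA duplex silences an mRNA when its guide (antisense) strand
loads into RISC and directs cleavage of the complementary target site.
Designing potent siRNA means three things at once: predicting intrinsic
efficacy from the guide sequence, avoiding unintended targets, and
validating the design by measuring actual knockdown in cells. This
package implements all three stages plus the statistical analysis that
connects them — in particular the observation that *where* a site sits
on the transcript (its region and its distance from the 5' end) shifts
measured potency by tens of percentage points, independently of the
sequence-based score.

# The efficacy model

## Sequence score

Predicted extinction (percent of target mRNA removed) is modelled as an
affine function of the guide strand, numbered 5'→3' and including the
2-nt 3' overhang positions:

* 84 binary indicators "base *b* at guide position *p*" (21 × 4), and
* 84 counts of every 1-, 2- and 3-mer over the guide.

The motif inventory is deliberately exhaustive at k ≤ 3 rather than a
curated list: 168 features keeps the design matrix full-rank at the
scale of a few hundred training pairs while still containing the known
position preferences (e.g. 5' A/U bias of active guides) as special
cases. `train_model()` fits the weights by ridge regression with an
unpenalized intercept, solved in closed form via the SVD; the penalty
defaults to the minimizer of generalized cross-validation over a grid of
61 log-spaced values spanning 1e-8 to 1e4. Ridge was preferred to lasso
as the default because the fit is deterministic and exactly reproducible
(no coordinate-descent path or convergence tolerance), which the
recovery tests rely on; with near-zero penalty and noise-free training
data the fitted predictions reproduce a planted linear model to 1e-6.
Predictions are clipped to [0, 100].

## Positional/location correction

Measured knockdown in validation screens depends on the target-site
position in ways the guide sequence cannot explain. The correction layer
adds two effects to the sequence score, on the percent scale:

* a **location offset** per region — with the CDS as reference 0, the
  5'UTR sits at −39 and the 3'UTR at −26 (equivalently: CDS and 3'UTR
  sites outperform 5'UTR sites by 39 and 13 points);
* a **positional slope** of −1 point per 100 bp of distance of the site
  start from the transcript 5' end.

`apply_positional_correction()` computes
`clip(score + offset(location) + slope × (start − 1)/100, 0, 100)`, so a
CDS site at position 1 is the reference point. The functional form
(additive, linear in position) is the package's own choice: the effects
it encodes were estimated as additive contrasts and a linear slope, and
nothing finer-grained is identifiable from screens of this size. The
position covariate is measured from the transcript 5' extremity by
default; distance from the start codon is supported by passing a
CDS-relative position column to the analysis functions, because the two
conventions differ only by a per-gene constant that the gene term
absorbs in any model that includes it.

Both thresholds worth knowing: candidate filtering applies the strict
`> 80%` rule to the *sequence* score, not the corrected score — the
correction was derived from screens of candidates that had all passed
the sequence threshold, so applying the threshold after correction would
extrapolate it outside its calibration range. Both scores are reported.

# Off-target screening

## Mismatch scan

`shift_add_search()` finds every alignment of a pattern (the 21-nt sense
sequence by default; a transcript that nearly matches the sense strand
is a potential cleavage target of the guide) against a databank
transcript within k mismatches, k = 3 by default. It is a bit-parallel
shift-add matcher: one saturating counter per pattern position, each
`ceil(log2(k+1)) + 1` bits wide with a sticky overflow bit, packed into
a single 64-bit word and updated once per text character. A 21-nt
pattern at k = 3 needs 63 state bits; combinations needing more than 64
(e.g. 32-nt at k = 3) raise an error instructing a chunked search rather
than silently degrading. Mismatch *positions* are recovered by direct
comparison at each reported alignment, which costs O(pattern) per hit
only. Correctness is pinned to a naive sliding-window Hamming oracle on
1000 random instances in the test suite.

## Seed profiling

The second off-target route is miRNA-like repression through seed
matches in 3'UTRs. The seed is guide positions 2–8; its match site on an
mRNA is the *reverse complement* of that heptamer, and
`seed_match_profile()` counts exact occurrences per 3'UTR, binning UTRs
into hit-once, hit-twice and hit-three-plus classes. Two conventions
were genuinely open and are both supported: a strict-identity mode
(matching the heptamer itself) exists because "identity between mRNA and
siRNA seed regions" can be read either way, and overlapping occurrences
are counted because a run of complementary sequence offers multiple
register-shifted sites. Note the bookkeeping identity
`n_seqs = hit1 + hit2 + hit3plus`: the total is the sum of the classes,
which is why the analysis stage never fits it alongside them.

# Knockdown quantification

`relative_quantity()` implements efficiency-corrected comparative-Ct
quantification: with per-cycle amplification rates `e_t`, `e_n` for the
target and reference assays,

```
q = e_t^(Ct_t,cal − Ct_t,sample) / e_n^(Ct_n,cal − Ct_n,sample)
```

relative to a mock-transfected calibrator; with `e = 2` this is exactly
`2^−ΔΔCt`, and knockdown is `100 × (1 − q)` (a quartered ratio = 75%).
`estimate_extinction()` computes q per replicate, averages on the log2
scale (Ct noise is additive, so ratios are log-normal and the log scale
is where averaging is unbiased — a property the tests verify by
simulation), and pools the two reference genes by geometric mean.
Replicate dispersion is the SD of per-replicate log2 ratios. This
aggregation is a documented stand-in for a full hierarchical treatment
of run/normalizer structure, which screens of this size cannot usefully
identify. Per-assay efficiency is a user input (default 2.0; measured
values in (1, 2] are accepted).

Run validation follows screening practice: a run counts only if a known
positive-control siRNA knocks its target down by at least 80%
(`validate_run()`, threshold configurable — 70% is a common variant).

# The covariate analysis

`build_covariate_table()` assembles one record per screened siRNA:
predicted score, target gene, position (bp from the 5' end), location,
off-target transcript count, polynucleotide-tract flag, transcriptome
hit count, the three seed-hit classes (plus their total), target exon
length, exon-junction flag, optional accessibility in [0, 1] (an
externally computed probability; never imputed when absent), and the
measured efficacy.

`fit_full_model()` fits efficacy on all available covariates and runs
per-term ANOVA — sequential (type-I) sums of squares in the documented
covariate order by default, because term order is part of the model
definition here; a marginal drop-one option exists for sensitivity
checks. Sequential SS conserve the total sum of squares, which the tests
assert. Under a pure-noise response every term rejects at the nominal 5%
rate (calibration verified over 1000 simulated panels).

`refit_reduced()` keeps the three informative covariates — gene,
location, position — with BCL2L1 as the gene reference and the 5'UTR as
the location reference, so the CDS coefficient *is* the CDS-vs-5'UTR
contrast and the slope is reported per 100 bp. `per_gene_position_test()`
asks the within-gene question (CDS sites only, simple regression of
efficacy on position); genes with fewer than 4 usable records are
declared not-testable rather than returning a meaningless p-value.

# The synthetic study generator

`simulate_study()` draws complete screening panels from the additive
generating model

```
efficacy = baseline + gene_offset + location_offset
           + slope × (position − 1)/100 + N(0, sd),  clipped to [−50, 100]
```

with defaults: baseline 45; gene offsets (vs BCL2L1 = 0) CSNK2A1 +9,
CSNK2A2 +10, CSNK2B +8, ERCC1 +7, ERCC2 −11, HDAC6 −22, HIF1A 0;
location offsets (vs 5'UTR = 0) CDS +39, 3'UTR +13; slope −1 per 100 bp;
noise SD 10. The panel structure mirrors a realistic first-round
validation screen: 88 siRNA over eight genes (9–15 per gene) on
transcripts of 1128–4099 nt with CDS lengths of 648–3648 nt, sites
placed uniformly along each transcript. Two structural choices had no
external value to copy and are the package's own: HIF1A sits at the
reference level (its offset is not separately resolvable at this scale),
and 35% of each transcript's untranslated length is placed 5' of the CDS
(a typical mRNA architecture; the design table records only total and
CDS lengths). The clipping floor at −50 admits noise-driven apparent
up-regulation, which real screens show.

What the generator does *not* emulate: sequence-dependent efficacy
(scores and sequences are independent of the response), secondary
structure, codon usage, inter-run plate effects, and any correlation
between off-target load and measured knockdown — the non-signal
covariates produced under `full_covariates = TRUE` are draws from
plausible null distributions. Passing recovery tests therefore shows
that the *estimators* are correct and calibrated under the stated model,
not that the model captures everything real screens contain.

`make_transcriptome()`, `plant_offtarget()` (in-place substitution of
near-match copies, with a ground-truth manifest) and `simulate_ct()`
(Ct shifts of `−log(q)/log(e)` cycles plus Gaussian replicate noise, in
triplicate) supply the corresponding fixtures for the other stages. All
generators are bit-reproducible given a seed.

## Problem sizes used in the checks

Monte-Carlo checks use 200 panels of 88 siRNA for effect recovery
(Monte-Carlo SE ≈ 0.013 on the slope, ≈ 0.27 on the CDS contrast), 1000
panels for ANOVA type-I calibration, and 1000 random instances for the
matcher oracle — sizes at which the quantities of interest are estimated
to well within their acceptance bands while the whole suite runs in a
couple of minutes on one core.

# Numerical and degenerate-input choices

* Region labels for windows straddling a boundary use majority overlap
  with ties to the more 3' region (a single label per siRNA is needed;
  boundary behaviour is otherwise arbitrary and is documented rather
  than hidden).
* Spaced selection breaks score ties toward the smaller start, making
  reports deterministic.
* `train_model()` drops singular values below `max(d) × 1e-12`;
  untrained models refuse to predict.
* Transcripts shorter than 21 nt yield an empty candidate list with a
  message, not an error; missing exon annotation yields NA exon context
  with a message.
* RNA input (U) is normalized to DNA (T) on read everywhere; guides and
  sense strands are rendered back as RNA only in report output.

# Known limitations

* The scoring model ships untrained: fitted DSIR weights are not public,
  so scores are meaningful only after training on the user's own
  (guide, efficacy) pairs.
* The off-target scan is a linear scan per (pattern, transcript) pair —
  exact and fast enough for panels against transcript sets, but no
  substitute for an indexed search over a full transcriptome at scale.
* The qPCR aggregation ignores shared-run covariance between estimates;
  dispersion is descriptive, not a full error model.
* The positional correction extrapolates linearly beyond the position
  range it was estimated on; corrected scores are clipped but not
  otherwise guarded.
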