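---
title: "Methods: estimating time-course drift in melodic transitional probabilities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimating time-course drift in melodic transitional probabilities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(melodicdrift)
```

## The question and the estimator

Statistical-learning theory holds that listeners and composers internalise
the transitional probabilities (TPs) of the music they are exposed to:
given the last $n$ tones, some continuations are far more probable than
others, and a composer is more likely to write the continuations their
implicit statistical knowledge favours. If that knowledge shifts over a
career, the TPs embedded in the scores should shift with it. This package
estimates such time-course drift from a chronologically ordered corpus of
works.

The pipeline has five stages.

**1. Melodic proxy.** From each movement's score the *highest-pitch line*
is taken: at every onset where at least one non-grace note begins, the
highest pitch sounding at that instant. Grace notes are excluded; a note
tied across notation, a slurred repetition of the same pitch, or a single
sustained note chosen at several onsets counts once. Movement boundaries
break the sequence; rests inside a movement do not.

**2. Relative encoding.** Every run of $n+1$ consecutive melody tones is
re-expressed relative to its first pitch: the first element becomes 0 and
each other element the signed distance in semitones (so F5, E♭5, D5, C5,
B♭4 becomes $[0,-2,-3,-5,-7]$). Both the context and the outcome live in
this relative space, which makes every statistic transposition-invariant —
the analysis deliberately captures relative-pitch structure and ignores
key.

**3. Markov TP estimation.** For order $n$ the transitional probability of
outcome $e_{n+1}$ after context $e_n$ is the maximum-likelihood count
ratio

$$P(e_{n+1} \mid e_n) = \frac{P(e_{n+1} \cap e_n)}{P(e_n)}
  = \frac{\mathrm{count}(\text{context},\text{outcome})}
         {\mathrm{count}(\text{context})}.$$

No smoothing or back-off is applied: a zero-count context yields an
explicit *absent* value (`NA`), never $0/0$. Movements of a piece are
pooled by summing counts, which equals a weighted average of per-movement
probabilities with context-frequency weights; the piece-level table is
then itself a maximum-likelihood estimate and does not depend on how the
piece is divided into movements.

**4. Universality filter.** Only interval patterns whose full
context-plus-outcome count is at least 1 in *every* piece enter the trend
analysis. A pattern missing from some piece cannot be told apart from an
unobserved context, so its "zero" probability is not evidence about the
composer's knowledge. The retained patterns form a pieces × patterns
matrix of probabilities, rows ordered by the corpus serial index
(publication order, used because publication dates are better attested
than composition dates).

**5. Stepwise trend regression.** The piece serial index is regressed on
the TP columns by forward stepwise selection: at each step the candidate
with the smallest partial $p$-value enters if $p < p_\mathrm{enter}$, then
any included predictor with $p > p_\mathrm{remove}$ is removed, until
nothing changes. Every accepted model is kept on the path. Among path
models in which every predictor's variance inflation factor is below 2 and
every condition index below 20, the model with the *greatest number of
interval patterns* is adopted (ties: higher $R^2$). A negative
coefficient means the pattern's probability falls over the corpus — the
composer uses that once-favoured continuation less and less — and a
positive one means it rises.

## Parameters and their defaults

| parameter | default | meaning |
|---|---|---|
| `orders` | 1–7 | Markov context lengths analysed; order $n$ involves $n+1$ tones |
| `p_enter` | 0.05 | stepwise entry threshold (the analysis' significance level) |
| `p_remove` | 0.10 | stepwise removal threshold; the common default of the major statistical packages, used because the procedure's source convention does not state one. Both thresholds are configurable, and `p_remove = p_enter` is allowed |
| `vif_limit` | 2 | collinearity screen: $\mathrm{VIF}_j = 1/(1-R^2_j)$ from regressing predictor $j$ on the others |
| `ci_limit` | 20 | condition-index screen, computed on the unit-column-scaled, *uncentered* design including the intercept — the convention whose output format the screened tables mirror. The report attaches a model's largest index to its variable rows; the per-dimension indices are in the JSON report |

Standardized coefficients use sample standard deviations,
$\beta_j = B_j \, s_{x_j}/s_y$; degrees of freedom are $n-k-1$ with the
intercept always included.

## The bundled corpus

`sonata_tp_matrix(order)` returns the pooled piece-by-pattern probability
matrices for the 32 Beethoven piano sonatas at orders 1–5 (20, 37, 12, 3
and 1 universal patterns respectively), rows ordered by sonata serial
number. Values carry the three-decimal precision of their printed source;
two row pairs (serial 1/29 at order 1, and 1/11 at order 4) are identical
in that source and are bundled verbatim. Because the inputs are rounded to
three decimals, statistics recomputed from them can differ from fully
precise values in the third decimal; the package's checks therefore use
tolerances of about 0.03 on adjusted $R^2$, 0.4 on $F$ and 5% on
coefficients. At order 5 the single universal six-tone pattern does not
meet the entry criterion and the stepwise path is empty — reported as "no
predictor enters", not as an error.

## The synthetic-corpus generator

`drift_spec()` describes an ordered corpus whose melodies are realizations
of an order-$n$ Markov chain over relative intervals, with one designated
pattern's probability drifting linearly in the piece index $t$:
$p_t = \mathrm{clamp}(p_0 + \text{slope}\,(t-1),\ 0.01,\ 0.99)$, the
remaining outcomes of that context rescaled proportionally so each
distribution still sums to 1. The defaults mirror the bundled corpus'
geometry and a drift large enough to be scientifically interesting:

* 32 pieces × 3 movements × 2000 melody notes — a piano-sonata movement's
  highest-pitch line has on the order of a few thousand notes;
* order 1 with outcomes $\{-2,-1,+1,+2\}$ at probabilities
  $(0.30, 0.25, 0.25, 0.20)$ — small steps dominate real melody;
* target pattern $[0,2]$ with slope $0.012$ per piece step, i.e. a total
  drift of about $0.37$ across the corpus, well clear of the clamp.

Pitches are realized from C4 by cumulative offsets and are deliberately
*not* range-clamped: a drifting interval distribution has a nonzero mean
step, so long realizations wander outside the MIDI range, and clamping
them would corrupt the very interval statistics under study. Since every
statistic is transposition-invariant, absolute pitch is immaterial for
synthetic data; range limits apply only to score-derived events.

What the generator emulates: corpus geometry, relative-interval Markov
structure, movement pooling, and a controlled monotone drift. What it does
not emulate: meter, phrase structure, tonality, key changes, voice
leading, or the heavy-tailed interval distributions of real music. Passing
recovery tests therefore show the *pipeline* detects drift of the designed
size under the stated noise model — not that real corpora contain such
drift.

`recovery_experiment()` runs the complete pipeline per replicate and
reports how often the drifting pattern appears in the adopted final model
with the correct coefficient sign. Because the drifted outcome's siblings
are renormalized against it, their columns anti-correlate with the
target's almost perfectly; the screens (VIF < 2) then reject models
containing both, and the final-model rule falls back to the largest clean
model. This is the intended behaviour of the screening step, and the
experiments exercise it.

## Numerical and design choices

* **Exact onsets.** MusicXML onsets are kept as integer ticks at the least
  common multiple of all `<divisions>` values, so "sounding at the same
  instant" is exact integer arithmetic, never a floating-point tolerance.
* **Slur merging.** "Counted as one" is applied to tied notes and to
  slurred *repetitions of the same pitch* only. Merging slurred notes of
  different pitches would delete melodic intervals wholesale, which cannot
  be what a pitch-transition analysis intends; the narrow reading is the
  package's resolution of an ambiguous convention.
* **Sustained notes.** "Highest pitch at a given point in time" considers
  notes still sounding, not merely notes starting: a held high note
  suppresses lower onsets beneath it. This is the literal reading; the
  alternative (onset-only) would interleave accompaniment tones into the
  melodic line whenever the melody holds.
* **Tie-breaking.** Equal partial $p$-values in stepwise entry resolve to
  the lexicographically smaller pattern (on offset tuples), making runs
  deterministic.
* **Seeds.** Synthetic movements are seeded as a fixed integer hash of
  (spec seed, piece, movement), so corpora are bit-for-bit reproducible
  and individual pieces can be regenerated in isolation.
* **Problem sizes in checks.** The test-suite recovery experiments use 200
  replicates at the default spec; the brute-force n-gram cross-check runs
  a thousand case/order combinations on sequences of up to 200 notes.
  These sizes give binomial standard errors small enough to make the
  0.9/0.15 rate criteria meaningful while keeping a full run of the suite
  around a minute.

## Known limitations

* The highest-pitch line is a proxy; bass or inner-voice melodies are
  invisible to it by construction.
* Universality filtering discards patterns absent from any piece, so the
  analysis says nothing about rare or late-appearing material; the
  time-course claim concerns the composer's *consistently used* patterns.
* Stepwise selection inflates the effective false-positive rate across
  the many candidate columns and the several Markov orders; no
  multiplicity correction is applied across orders, matching the source
  convention, so per-order results should be read as descriptive.
* With serial index as regressand, the fitted trend is linear in rank
  order, not in calendar time.
* Compressed `.mxl`, MEI, ABC and MIDI inputs are out of scope; only
  uncompressed partwise MusicXML is read.
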