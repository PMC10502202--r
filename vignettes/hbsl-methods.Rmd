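---
title: "Modeling auditory statistical learning with hbsl: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling auditory statistical learning with hbsl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hbsl)
```

# The model

`hbsl` simulates how a listener extracts the statistics of a melodic
sequence, chunks its recurring phrases, and composes new material from the
learned representation — and how all of this changes with the listener's
sensitivity to sensory input and with the amount of exposure.

## Dirichlet–Markov learning and reliability

The learner is a fixed-order Markov model over a token alphabet of size
$K$.  Each context $i$ holds a Dirichlet distribution over its transition
probabilities with concentration vector $\alpha_i$, initialized
symmetrically and updated by conjugacy: observing context $i$ followed by
symbol $j$ adds one count to $\alpha_{ij}$.  The predictive transition
probability is the posterior mean $\alpha_{ij}/\alpha_{i0}$ (with
$\alpha_{i0} = \sum_j \alpha_{ij}$), and — the feature that distinguishes
this learner from a maximum-likelihood $n$-gram model — every transition
also carries a *reliability*: the inverse of the marginal Beta variance

$$\mathrm{Var}(p_{ij}) = \frac{\alpha_{ij}\,(\alpha_{i0}-\alpha_{ij})}
 {\alpha_{i0}^2\,(\alpha_{i0}+1)},$$

which grows with accumulated evidence.  Nine B's after ten A's and ninety
B's after a hundred A's both give $p(B\mid A) = 0.9$, but the latter is
held far more reliably; the model distinguishes the two where a
count-ratio estimator cannot.  Note one algebraic subtlety: because the
variance is proportional to $p(1-p)$, a *single* observation that moves a
transition's mean toward $1/2$ can transiently lower its reliability;
reliability ordering by evidence holds at fixed probability and in the
long run, not per observation.

## Bayesian surprise

Learning is traced event by event.  For each incoming symbol the
predictive distribution of its context is captured before and after the
conjugate update, and the Kullback–Leibler divergence
$\sum_k P(k)\log(P(k)/Q(k))$ (in nats, before $\to$ after) is recorded as
the Bayesian surprise of that event.  Trial totals summarize how much the
internal model still moves when the same piece is re-heard; entropy
summaries use base-2 logarithms (bits).

## Sensitivity regimes

Three listener types are modeled by scaling the Dirichlet concentrations:
hypo-sensitive ($\times 0.25$), normal ($\times 1$) and hyper-sensitive
($\times 4$).  Two semantics are implemented:

* `sensitivity_mode = "prior"` (default): the factor scales the prior
  concentration at initialization and every observation adds $+1$.  All
  regimes accumulate identical counts; they differ in how far each
  observation moves the predictive distribution and in their initial
  reliability (hyper > normal > hypo).
* `sensitivity_mode = "increment"`: the prior stays at the base
  concentration and the factor scales the per-observation increment.

The two modes are mirror images of one another in the predictive means (a
weak prior and a large increment both let data dominate), and this has a
consequence worth stating plainly because it constrains what any
implementation of this model family can reproduce.  Under prior scaling,
the *hypo* regime is the one whose posterior is data-dominated: it shows
the largest per-event surprise (its weak prior is overwritten by every
observation), and simultaneously the sharpest learned transition rows —
hence, downstream, the most chunking and the generated corpora closest to
the training statistics.  Under increment scaling all three orderings
flip together.  No parameterization in this family makes the high-surprise
regime also the low-fidelity, low-chunking one: per-event surprise and
posterior sharpness are two faces of the same data-dominance.  The package
defaults to prior scaling, which reproduces the canonical surprise
ordering (hypo > normal > hyper at every trial) and the reliability
ordering; the production-side orderings then come out reversed, and the
experiment tables report them as computed.

# Chunking and hierarchy

Chunking asks which transitions are *jointly* probable and reliable.  All
observed (context, symbol) pairs of a model are scored; probabilities and
reliabilities are each z-normalized across the pairs (a zero-variance
dimension yields all-zero z-scores), and a transition is chunkable when
both z-scores are positive and their product exceeds a threshold $c$.
Maximal runs of consecutive chunkable transitions in the training sequence
are merged into multi-symbol chunks; the chunk inventory is the set of
distinct patterns.  Chunks are then replaced in the stream by unit symbols
(greedy, longest-then-leftmost) and a second-level model with alphabet
$K + \#\text{chunks}$ is trained on the re-encoded stream under the same
sensitivity regime, giving a two-level hierarchy.

The threshold default is $c = 5$, but $c$ must be read *relative to the
sample*: a product of two z-scores has a hard ceiling of roughly
$(N-m)/m$ when $m$ tied transitions share the top of $N$ scored pairs, and
reliability's $1/(p(1-p))$ shape hands its upper tail to rare transitions
out of frequently visited contexts.  On children's-song-sized material
(tens of notes, a handful of motif repetitions) the motif's internal
transitions carry the *maximal* products — the mechanism separates planted
structure cleanly — but those products saturate near 1–3, so at $c = 5$
desk-scale corpora yield empty chunk inventories.  The test suite
therefore checks the scoring pipeline against a brute-force
reimplementation at several thresholds and demonstrates motif recovery at
a threshold matched to the fixture's sample length ($c = 1$); analyses of
larger corpora should expect to re-tune $c$.

# Generation and comparison

Composition samples a token stream from the level-1 model (posterior-mean
transition probabilities by default; a count-ratio option exists), starting
at the training stream's first symbol, expanding chunk units to their
token tuples, and truncating to the training piece's length.  Both the
length and the start symbol are conventions — nothing in the model forces
them — and both are configurable.

Corpora are compared with the training piece through bigram statistics:
each piece's empirical bigram distribution is averaged over the corpus
(unweighted, renormalized) and the Jensen–Shannon divergence (symmetric,
bounded by $\log 2$ nats; supports unioned and smoothed with
$\varepsilon = 10^{-9}$) to the training piece's bigram distribution is
the quantitative similarity measure.  A small exact t-SNE over pairwise JS
divergences is provided for visualization only; embedding distances carry
no quantitative weight.

# Audio and rhythm analysis

## Rendering

Tokens are rendered as an additive tone (three harmonics at amplitudes
1, 0.5, 0.25, or a pure sine) at the equal-temperament frequency of the
note's MIDI pitch, with a 10 ms linear attack and an exponential decay
(time constant one third of the note length), at 16 kHz and 120 bpm by
default.  Band powers depend on these envelope choices, so they are
config-exposed; only within-experiment contrasts are meaningful, not
absolute values.  Rendered signals are z-scored (mean 0, SD 1) before
demodulation so intensity does not leak into modulation features.

## Probabilistic amplitude demodulation

A signal $y_t$ is decomposed as $y_t = m_t c_t$ with a slow positive
modulator and a fast carrier.  The log-modulator carries a stationary
Gaussian-process prior parameterized directly in the frequency domain: a
near-flat passband up to $1/\text{timescale}$ Hz (default 10 Hz, i.e.
timescale 0.1 s) with a raised-cosine roll-off, so the prior acts as a
soft low-pass constraint on $\log m$.  The carrier is white Gaussian.
Marginally $y_t \mid m_t \sim \mathcal N(0, \sigma_c^2 m_t^2)$, and the
modulator is the MAP estimate of the log-envelope, found by L-BFGS on a
block-piecewise parameterization (blocks of $\approx 1/16$ of the cutoff
period, far shorter than the modulator timescale, which makes the exact
block likelihood $\tfrac12 S_b e^{-2u_b}/\sigma_c^2 + B u_b$ cheap and its
gradient closed-form).  The $(m, c)$ scale ambiguity is resolved by fixing
$\operatorname{mean}(m)$ to the signal RMS; the carrier is $y/m$, so
reconstruction is exact by construction.  Non-convergence within
`max_iter` is flagged on the result rather than raised.  An all-zero
signal is handled as a degenerate case (tiny constant modulator, zero
carrier, zero band powers).

## The AM cascade

Rhythm is summarized by demodulating recursively at successively slower
rates.  After the first (nonlinear) demodulation isolates the full
sub-cutoff envelope, the remaining levels operate on the mean-removed
*log* envelope, where the multiplicative decomposition is additive and the
GP MAP smoothing is an exact frequency-domain filter.  Each level removes
the modulation faster than the next band edge; the removed component is
that band's envelope, and band power is its mean-removed mean square.
Band edges are the geometric midpoints of the nominal rates (default
8, 4, 2, 1, 0.5 Hz, straddling the 1–3 Hz phrase-rhythm range), so a 2 Hz
amplitude modulation lands in the 2 Hz band: on synthetic AM noise the
band-power argmax identifies the true modulation rate essentially always
(20/20 seeded replicates across 1, 2 and 4 Hz in the acceptance suite).
The log domain was chosen over the linear domain for the recursion because
it makes the levels exactly additive; this is a design decision, and the
band envelopes are reported in log units.

# The synthetic fixture

The default training input emulates a children's song: 40 notes over an
8-pitch diatonic alphabet, durations quantized to {0.5, 1, 2} beats, with
one fixed 4-note motif planted at 5 evenly spaced, non-overlapping
positions amid uniform-random filler (filler that would create an
accidental extra motif copy is resampled, so the motif count is exact).
This plants exactly the statistical structure the learner targets:
high-probability, high-evidence motif-internal transitions amid diffuse
filler transitions.  It does *not* emulate tonal harmony, meter, phrase-
final lengthening, or the repetition of whole sections, so passing results
say nothing about those aspects of real song corpora.  Any monophonic MIDI
file can replace the fixture via `experiment_config(training_midi = ...)`.

The experiment tokenizes with the `pitch_duration` scheme by default
(tokens are (pitch, quantized-duration) pairs) so that rhythm is part of
the generative alphabet: with pitch-only tokens every generated piece
would inherit a flat rhythm and the acoustic comparison across models
would be vacuous.  `tokenize()` itself defaults to the smaller
pitch-only alphabet.

# The simulation grid

`run_experiment()` crosses the three regimes with cumulative learning
trials (default 5): the trial-$k$ row uses the model after exactly $k$
passes through the piece (snapshots of one cumulative learner, not
independent models).  Per snapshot it records the trial's total surprise
and chunk count, builds the hierarchy (the level-1 model is trained with
$k$ passes as well), generates a corpus (default 100 pieces; 20 in the
desk-scale acceptance runs), computes the JS distance of the corpus-average
bigram distribution to the training piece, and optionally renders every
piece (clipped to 10 s) and averages its AM band powers.  All randomness
derives from the config seed through fixed substream offsets, so runs are
bit-reproducible; `export_results()` writes the tables, a config-hashed
metadata JSON and an MD5 manifest.

Problem sizes in the tests and acceptance script — 40-note training
fixture, 20–100 pieces per model, 8-second PAD test signals, 20 cascade
replicates — are the package's desk-scale defaults; all scale up by
configuration.

# Numerical conventions and edge cases

* Context rows are created lazily; unseen contexts predict uniformly.
* KL inputs must be normalized within $10^{-9}$ and strictly positive
  (Dirichlet means always are); predictive rows sum to 1 within
  $10^{-12}$.
* Chunk-score z-dimensions with zero variance are set to zero, making
  degenerate (perfectly cyclic) training streams chunk-free rather than
  undefined.
* Overlapping chunk candidates are resolved longest-then-leftmost; chunk
  occurrences never overlap.
* Generation, fixture synthesis and t-SNE save and restore the global RNG
  state around their seeded draws.
* MIDI reading collapses polyphony to the monophonic contract (highest
  pitch at a tie; a later overlapping note truncates the ringing one) and
  errors on note-free or malformed files, naming the offending track.

# Known limitations

* Variable-order context trees, forgetting/decay, and more than two
  hierarchy levels are out of scope.
* The sensitivity-regime family cannot jointly produce a high-surprise,
  low-fidelity hypo listener (see above); cross-regime orderings of
  production-side quantities under the default semantics are the mirror
  of the perception-side orderings.
* The full variational PAD posterior is not computed, only the MAP pair;
  PAD parameters are set manually, not learned.
* Absolute band powers depend on the synthetic timbre and tempo; compare
  only within a run.
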