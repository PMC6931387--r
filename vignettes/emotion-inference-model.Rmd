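---
title: "An active inference model of emotional state inference and emotion concept learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An active inference model of emotional state inference and emotion concept learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(affectinf)
```

## The model

`affectinf` simulates an agent that must work out which emotion it is
feeling by selectively attending to the components of its own affective
response, cast as a discrete-state partially observable Markov decision
process solved by active inference.

**Hidden states.** Two factors. Factor 1 is the emotional state, with
four exemplar concepts: SAD, AFRAID, ANGRY, HAPPY. The true state is set
at the start of a six-timestep trial and held fixed. Factor 2 is the
focus of attention: an uninformative *start* state, five covert
attention states (one per information source), and four absorbing
*report* states.

**Outcomes.** Seven modalities. Five content modalities summarize
lower-level information: affective valence (pleasant/unpleasant),
autonomic arousal (high/low), motivated action tendency
(approach/avoid), perceived context (social rejection / crowded event),
and attributed blame (self/other). Each content modality is informative
only while its attention state is occupied; otherwise it emits an
uninformative *null* outcome. A sixth modality delivers social feedback
(correct/incorrect) in report states, and a seventh reads out the
attended location (an identity mapping: the agent always knows where its
attention is).

**Likelihoods (A).** Each emotion concept is a multimodal outcome
profile over the five content modalities:

| emotion | valence | arousal | action | context | blame |
|---|---|---|---|---|---|
| SAD | unpleasant | either | avoid | rejection | self |
| AFRAID | unpleasant | high | avoid | either | other |
| ANGRY | unpleasant | high | approach | rejection | other |
| HAPPY | pleasant | either | either | crowd | flat |

"Either" cells are 0.5/0.5; all other cells are deterministic in the
base pattern. The profiles deliberately overlap — no single cue
identifies an emotion — which is what makes both inference and learning
non-trivial.

**Precision.** Graded likelihood (and transition) precision is obtained
by passing each base column through a softmax of `temp * log(p + 0.1)`
(`apply_precision()`). Temperature 0 yields a flat mapping, temperature
2 a "moderately precise" one in which a deterministic cell retains about
99% of its mass and either/or cells stay at 50/50, and infinity recovers
the base exactly. The epsilon floor of 0.1 is calibrated so that at
temperature 2 a one-hot cell leaks roughly 1% — e.g., a happy agent
still experiences social rejection on about 1% of occasions.

**Transitions (B).** The emotion factor uses a single identity-based
matrix for every action (emotions are stable within a trial); its
precision encodes the agent's beliefs about that stability. The
attention factor is fully controllable: action *k* moves any non-report
state to attention state *k*, the *stay* action holds position, and
report states absorb under every action.

**Preferences (C), priors (D), habits (E).** The agent prefers correct
social feedback (+4 nats) and is strongly averse to incorrect feedback
(−16), and — crucial for the developmental simulations, see below —
expects to have committed to a report by the end of the trial (null
feedback at the final timestep carries −16). Initial priors are flat
over emotions with a point mass on the start state; the habit prior over
the ten actions is uniform unless an attention bias is installed.

## Within-trial inference

At each timestep the agent computes a posterior over its emotional state
given all outcomes so far (`infer_states()`). The emotion factor forms a
chain with per-timestep likelihood messages (digamma-transformed
expected log-likelihoods when Dirichlet learning is active), so each
update sweep performs a full forward–backward message pass whose fixed
point is the exact smoothed posterior. We chose exact message passing
over naive mean-field coordinate ascent deliberately: with a
near-identity stability mapping the mean-field factors polarize each
other (a posterior of 0.99 where exact Bayes gives 0.66), which
systematically triggers premature reports. The per-sweep belief
trajectory is retained as the depolarization analogue for the simulated
neural read-outs (`neural_traces()`: firing = posterior expectations on
a fine within-trial grid, local field potentials = their first temporal
differences).

## Policy evaluation and action

Policies are one-step ("shallow"): at each of the five decision points
the agent scores all ten actions by expected free energy
(`expected_free_energy()`):

G = risk + ambiguity − novelty

* **risk** — divergence of predicted outcomes from preferred outcomes
  (the pragmatic term; preferences are timestep-resolved);
* **ambiguity** — expected conditional entropy of outcomes given states;
* **novelty** — Dirichlet information gain `½(1/a − 1/colsum(a))`
  contracted with predicted outcomes and states, active only for
  learnable likelihood blocks.

The policy posterior is `softmax(ln E − γ·G)` with policy precision
γ = 8 (a β-update mode is available via
`policy_posterior(update_gamma = TRUE)`). Actions are sampled from this
posterior in all headline experiments; an argmax mode (ties broken by
lowest action index) is available and is used for the precision sweep,
where two agents must be compared deterministically.

Early in a trial the epistemic terms dominate and the agent forages:
with precise concepts it typically attends two to four informative
modalities, and the preference asymmetry (+4/−16) sets the implicit
report threshold near 0.85 posterior confidence, at which point the
pragmatic term takes over and the agent reports.

### Why the end-of-trial preference exists

A symmetric preference (±c) makes reporting at a coin-flip posterior
exactly as attractive as its entropy bonus, so a symmetric agent
habitually reports at 50% confidence and cannot exceed ~80% accuracy.
An aversion-heavy preference fixes that but creates a bootstrapping
problem for development: an agent with *flat* likelihoods is never
confident, so reporting is always dominated, no report ever occurs, no
social feedback arrives, and the uniform posteriors keep the Dirichlet
counts symmetric — concept learning can never start. The
timestep-resolved preference resolves this: the agent expects to have
answered by the end of the trial, so the final decision point always
produces a report (random at first, increasingly deliberate as concepts
form), and the precise, innate feedback mapping then supervises the
likelihood updates. This also yields the expected chance floor: a
blank-likelihood agent without learning reports at random and scores
25%.

## Learning between trials

After each trial (`update_A_counts()`, `update_D_counts()`), for every
timestep at which a content modality was attended, the concentration
parameter linking the observed outcome to each emotion is incremented by
η times the end-of-trial retrospective (smoothed) posterior — which
includes the feedback observation, so an "incorrect" outcome
redistributes credit away from the reported concept. Frozen structure
(null emissions, feedback, location) is never updated. The initial-state
prior accumulates similarly at rate η_d.

Defaults (the study conditions of every protocol):

| parameter | value | rationale |
|---|---|---|
| blank concentration a0 | 0.5 | small enough that novelty drives exploration of unlearned modalities, large enough to damp premature commitment ("concept capture") |
| likelihood rate η | 1 | one count per attended observation |
| prior rate η_d | η/50 | the prior gets one full count per trial on a 4-cell vector; at η_d = η it out-concentrates every likelihood column, dominates single-observation posteriors, and turns early mislabelings into self-reinforcing confusions that block later concept acquisition |
| policy precision γ | 8 | joint optimum of learning accuracy and attention-bias effect sizes (a 50-fold habit is worth ln 50 ≈ 3.9 nats; γ·ΔG among attends must not swamp it) |
| preferences | +4 / −16 / −16 | report threshold ≈ 0.85; trial-end reporting |

These magnitudes are the package's own calibration — the framework
fixes their roles but not their values — chosen once against the
qualitative behavioral profile the model must show (two to four
attentional shifts before a confident report; gradual childhood learning
approaching ceiling) and not revisited per experiment.

## The generative process and what the synthetic data emulate

The world (`generative_process()`) samples outcomes from the same base
profiles at its own precision (default temperature 2). Each trial draws
*one* realization per content modality — a trial is a single multimodal
affective episode, so re-attending a modality re-reads the same state of
the world. The true emotion is held fixed within a trial by default; a
finite process `b_temp` lets it drift (off by default — at temperature 2
roughly one trial in nine would contain a mid-trial flip, which
measurably degrades concept learning below the profile the simulations
target, so instability is treated as an explicit manipulation rather
than a background condition).

Schedules: `schedule_interleaved()` cycles the four emotions evenly
(the childhood protocol: 50 each over 200 trials);
`schedule_skewed()` realizes a dominance ratio (50:1 adversity
childhood); the adulthood protocols withhold one emotion for 150
pretraining trials and reintroduce it, optionally after a 100-trial
flood or with the main phase extended to 600 trials.

What these synthetic conditions do **not** emulate: real interoceptive
data have no ground-truth labels arriving as crisp correct/incorrect
feedback after every episode; emotion categories are not four
equifrequent discrete states; and the content modalities are stand-ins
for high-level summaries of an entire hierarchical perception stack.
Passing the reproduction suite therefore validates the computational
mechanism, not any claim about human emotional development.

## Numerical choices and degenerate inputs

* Logarithms are floored at 1e−16; posteriors are never exactly zero.
* `apply_precision()` validates column stochasticity to 1e−8 and all
  construction invariants (normalization to 1e−10, report-state
  absorption) are re-checked by `validate_model()`.
* Argmax ties break to the lowest action index; the sampled mode uses
  the caller's RNG stream only (all protocols take a `seed`).
* Empty schedules return empty, well-formed results.
* A trial with no report (impossible under the default preferences, but
  reachable with user-modified C) scores incorrect.

## Known limitations

* **Somatic-bias happiness.** A fully trained agent whose habits confine
  attention to arousal and action tendency still reports HAPPY correctly
  on roughly a third of happy trials: when the trial's realization is
  low arousal + approach, exact inference *correctly* assigns most
  posterior mass to HAPPY (every rival concept has a sharp cell that
  this pattern contradicts). An approximate-inference agent that locks
  onto sharp-likelihood concepts after the first observation would score
  near 0% here; we report the exact-inference value rather than emulate
  that overconfidence.
* **Concept capture.** With small probability a childhood run settles
  into a stable two-concept confusion (one hidden state absorbs
  another's pattern; correct/incorrect feedback alone cannot relabel
  it), leaving one emotion near 0% and depressing the run's final
  accuracy. The damped prior rate minimizes but does not eliminate
  this; affected deterministic likelihood cells can then miss the ±0.1
  recovery band on seed averages.
* Policies are strictly one-step; there is no multi-step planning, no
  hierarchical lower level generating raw sensory data, no
  model-reduction ("sleep") mechanism, and no secondary emotion
  concepts.

## Problem sizes

The reproduction protocols use the full study conditions: 200-trial
childhood runs, 150-trial pretraining, up to 750 trials for the extended
acquisition variant, 40-trial bias tests, and five replicate seeds per
quantity; a complete reproduction pass is a few minutes of computation.

## A worked trial

```{r trial}
set.seed(11)
model <- build_emotion_model(precision_settings(a_temp = 2, b_temp = 2))
process <- generative_process(a_temp = 2)
trial <- run_trial(model, process, "ANGRY")
trial
round(trial$online_posteriors, 3)
```

The agent samples context (social rejection: sad or angry), blame
(other: not sad), then action tendency (approach: angry, not afraid),
and reports ANGRY at ~0.98 confidence — the characteristic
forage-then-commit profile.

```{r childhood, eval = FALSE}
child <- run_childhood(seed = 1)        # 200 trials, blank start
accuracy_bins(child)                    # 10-trial bins, rising to ~90-100
plot_learning_curve(child)
```
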