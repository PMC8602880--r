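---
title: "Deep temporal active inference: solving, explaining and confabulating in a T-maze"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep temporal active inference: solving, explaining and confabulating in a T-maze}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deepexplain)
```

## The problem

Can an agent explain *why* it did what it did? `deepexplain` implements one
operationalisation of that question: an agent solves a T-maze under a
generative model, is asked in simple language to explain its first or second
move, and answers by inference — it entertains a space of hypothetical
explanations (combinations of moves, reward location and knowledge states),
asks which of them best predicts the course of action it remembers taking,
and speaks the winner. Explanation, in this picture, is retrospective
inference over counterfactual causes of one's own behaviour, and its
pathological limit — explanation unconstrained by data — is confabulation.

## The generative model

### Level 1: maze and language

The fast level is a factorised POMDP over seven hidden-state factors:

| factor | levels | dynamics |
|---|---|---|
| location | centre, left, right, cue | controllable; arms absorb |
| context (= reward side, = semantic slot "side") | left, right | identity |
| query | first, second | identity |
| knowledge | knew, did-not-know | identity |
| verb | explored, guessed, exploited, waited | identity |
| destination | cue, left-arm, right-arm, centre | identity |
| syntax | silent; q1–q4; a1–a7 | deterministic chains |

and four outcome modalities: an exteroceptive signal (which location the
agent occupies and, at the cue, which arm the cue indicates), a reward
(neutral / attractive / aversive), a heard word and a spoken word over a
21-token vocabulary. Sentences are produced by frames: the query frame
*please explain ⟨first|second⟩ move* and the answer frame *I ⟨knowledge⟩
reward-was ⟨side⟩ so-I ⟨verb⟩ ⟨destination⟩*. The context factor is a single
shared factor: it determines both which cue is seen in the maze and which
side token appears at the fourth answer position. One deliberate quirk of
the semantics: a reported move that lands on the reported reward arm is
taken as evidence the location was *known* (verb "exploited"); landing on
the other arm means a *guess*; visiting the cue means *exploration*.

Whenever the syntax factor is anything but silent, the exteroceptive and
reward mappings collapse to centre/neutral for every location and context —
a form of sensory attenuation that disconnects the maze states from their
outcomes while the agent is listening or speaking.

Policies are the ten distinct two-move location trajectories from the centre
(absorbing arms make a first move into an arm determine the second). For
epochs longer than three steps a policy's final move is repeated, which is a
self-transition at the location reached.

### Level 2: the narrative

The slow level holds five factors: the narrative (solve → query → answer,
answer absorbing), the first and second moves, the reward location and the
query type (all others with identity dynamics). A between-level link maps
each level-2 state tuple to (i) an initial-state distribution for every
level-1 factor — the narrative picks the opening syntax state, the reward
location predicts the context, the query type the query slot, and, in answer
epochs, the queried move plus reward location predict the knowledge, verb
and destination slots — and (ii) a policy bias `E` with weight
`exp(kappa * matches)`, counting agreement between a policy's moves and the
level-2 move states.

Belief updating across levels is asynchronous (an adiabatic, mean-field
separation of timescales): level-2 beliefs descend as empirical priors at
the start of an epoch and are updated once from the epoch's evidence at its
end — the expected log-probability of the (policy-averaged) initial-state
posteriors and of the final policy posterior under each tuple's predictions.

### Inference

Within an epoch, each policy's state posterior is computed by *structured*
variational inference: every factor keeps its full temporal chain, updated
by an exact forward–backward pass given mean-field expectations of the other
factors inside the likelihood, sweeping factors until the free energy stops
changing. This scheme is exact for single-factor models (the package tests
it against brute-force enumeration over all state paths) and each factor
update is an exact block minimiser, so the free-energy trace is
non-increasing. A naive fully factorised (per-time-step) mean field was
rejected because its fixed points deviate from the exact chain marginals
even without observations, which would break both the replay mechanism
(beliefs must reduce to the prior rollout under attenuation) and the
enumeration equivalence.

Policies are scored by expected free energy `G` (risk + ambiguity) over the
remaining steps and combined with the accumulated evidence `F` and the
descending bias as `softmax(ln E − G − F)`. `F` accumulates over all
observed steps of the epoch; scoring only the current step is also found in
the literature, but full accumulation is what makes contradicted policies
drop out permanently once the agent has seen itself move. Spoken words are
generated reflexively as the outcome with the highest expected
log-likelihood under the (policy-averaged) predictive beliefs for the
current step, and are then heard back as observations — self-generated
evidence that feeds the next round of inference.

## Tunable parameters

| parameter | default | units / range | role |
|---|---|---|---|
| `pref_attractive` | +3 | log-probability (nats) | prior preference for the reward |
| `pref_aversive` | −6 | nats | avoidance of the punished arm |
| `pref_neutral` | 0 | nats | reference level |
| `pref_centre` | −1 | nats | mild aversion to staying put |
| `kappa` | 2 | nats per matching move | concentration of the narrative policy bias |
| `link_smoothing` | 0.01 | probability mass | softness of the between-level link |
| `horizons` | 3 / 4 / 7 | steps | epoch lengths (maze / query / answer) |
| `max_iter`, `tol` | 16, 1e-4 | sweeps, nats | variational stopping rule |

The preference magnitudes implement the required ordering attractive >
neutral > aversive with a margin large enough that a 50/50 gamble on the
arms is worse than a neutral outcome — this is what gives the cue its
epistemic value at the first move (the risk of committing to an arm under an
uncertain context exceeds the cost of visiting the cue, so policies starting
at the cue dominate the posterior). They are this package's declared
defaults, exposed in `task_config()`, not estimates of any canonical values.
`kappa = 2` makes the descending bias strong enough to dominate policy
selection when nothing else does (the attenuated epochs) while leaving it
soft enough that ascending evidence, not the prior, decides the story.

`link_smoothing` deserves its own paragraph. Each deterministic link column
places `1 − alpha` on the predicted level and spreads `alpha` uniformly over
the rest. Besides keeping ascending log-evidence finite, this grades the
cost of a link violation by the cardinality of the violated slot:
contradicting a two-level slot (context) costs `ln(1/alpha)` while
contradicting a four-level slot (verb, destination) costs `ln(3/alpha)`.
In the confabulation run the agent's first answer cannot be explained by any
level-2 tuple without at least one violation, and exact left/right symmetry
would otherwise leave two minimal-violation stories tied; the cardinality
grading resolves the tie in favour of revising the cheaper slot, yielding a
single coherent story ("a wrong guess") in the second answer. At
`alpha = 0.01` the descending priors remain sharp (the epoch-2 context prior
stays above 0.98).

## Numerical choices

- **Logarithm guard.** Every logarithm is `log(x + 1e-16)`, so structural
  zeros produce large finite penalties (~37 nats) rather than infinities.
- **Probability invariants** are checked at construction with tolerance
  1e-10.
- **Tie-breaking.** All argmax decisions (action selection, reflexive word
  generation, MAP read-outs) break ties towards the lowest index *within a
  1e-9 tolerance band*. Without the band, mathematically exact ties — and
  the task contains exact left/right symmetries — would be resolved by
  floating-point accumulation noise, making the nominal lowest-index rule
  vacuous and the outcome platform-dependent.
- **Verb ordering.** The verb levels are ordered by increasing epistemic
  commitment (explored, guessed, exploited, waited — verbs compatible with
  not knowing the reward location first), so that a data-unconstrained tie
  resolves to the explanation that presumes the least knowledge. This is
  what lets the confabulating agent say "guessed" rather than "exploited"
  when both are equally probable under its beliefs.
- **Degenerate inputs.** All-zero weight vectors, all-`-Inf` log-weights and
  non-positive policy biases raise errors; non-convergence of the
  variational sweeps raises a warning and returns the last iterate.
- **Level-2 projection.** After each update the level-2 joint over tuples is
  projected onto per-factor marginals (mean-field), the same representation
  used by the descending link; the pre-projection joint is kept in the epoch
  record for inspection.
- **Single-pass message exchange.** Evidence ascends once per epoch and
  priors descend once; iterating level-1/level-2 exchanges to joint
  convergence is a possible refinement that was not needed for any of the
  simulated phenomena and would blur the timescale separation.

## What the simulated environment does and does not emulate

The environment is the generative process mirror of the model with the true
context fixed: deterministic maze physics (absorbing arms, a truthful cue),
a scripted query sentence, and an echo of the agent's own spoken words
during answer epochs. All shipped tables are deterministic, so runs are
exactly reproducible and the seed only matters if a user supplies stochastic
tables. Consequently, passing tests demonstrates the *inferential* phenomena
— epistemic cue-seeking, narrative recovery, replay under attenuation,
confabulation and its repair — under noiseless conditions; they say nothing
about robustness to cue unreliability, probabilistic rewards, lexical
ambiguity or learning of the tables themselves (the model's parameters are
fixed, not learned), all of which are out of scope.

## Problem sizes

The shipped simulations are desk-scale by design: a 6144-state factorised
level-1 space evaluated per policy over epochs of 3–7 steps, ten policies,
and a 192-tuple level 2. A full three-epoch run takes on the order of ten
seconds on one core; the enumeration oracles used in tests run on chains of
at most three states, observations and steps, where exact path enumeration
(≤ 27 paths) is trivial.

## Known limitations

- The policy bias channel conditions only on the two move factors; richer
  links (e.g. biasing on the narrative itself) are not expressible in the
  shipped `TaskConfig`.
- Ascending evidence uses initial-state and policy posteriors only; for the
  identity-dynamics factors this is lossless, but a task with within-epoch
  state drift would need time-resolved ascending messages.
- The agent cannot answer "I don't know": the answer frame always fills its
  slots, which is precisely what makes the confabulation variant
  informative.
- Exactly two hierarchical levels; deeper stacks would require recursing the
  descend/ascend machinery.
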