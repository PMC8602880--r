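# deepexplain

Simulation of a **deep temporal active-inference agent that explains its own
actions**. The agent solves a T-maze under a discrete-state generative model,
is then asked — in simple language — why it made its first or second move,
and answers by *inference over counterfactual explanations*. Two emergent
phenomena fall out of the same machinery and are reproduced here: replay of
the solved trajectory in the agent's location beliefs during later, immobile
epochs, and confabulation — an internally consistent but data-unconstrained
story — when the maze epoch never happened.

The package is aimed at computational-neuroscience and machine-understanding
researchers who want a small, fully inspectable reference implementation of
hierarchical discrete active inference with a linguistic read-out.

## The model

The agent entertains a two-level generative model over hidden states
*s*⁽¹⁾, *s*⁽²⁾, policies *π*⁽¹⁾ and outcomes *o*. Inference minimises a
recursively defined variational free energy; at the lowest level, for each
policy,

    F(π) = D_KL[ Q(s⁽¹⁾|π) || P(s⁽¹⁾|π, s⁽²⁾) ] − E_Q [ ln P(o|s⁽¹⁾) ]

and policies are scored prospectively by an expected free energy that is the
sum of **risk** (divergence of predicted outcomes from prior preferences
*C*) and **ambiguity** (expected entropy of the likelihood mapping):

    G(π) = D_KL[ Q(o|π) || P(o|C) ] + E_Q [ H[P(o|s⁽¹⁾)] ]

The policy posterior is `softmax(ln E − G − F)`, where *E* is a prior policy
bias supplied by the level above. Self-produced outcomes (the spoken word)
are generated reflexively, as the outcome maximising the expected
log-likelihood under current beliefs.

Level 1 factorises into maze states (location; reward context) and
linguistic states (queried move, knowledge, verb, destination, syntax);
level 2 holds the narrative (solve → query → answer), the two moves, the
reward location and the query type. Level-2 beliefs descend as empirical
priors (initial states and the policy bias *E*) at each epoch boundary;
completed epochs ascend as log-evidence over level-2 states. Whenever the
syntax is non-silent the maze outcomes are attenuated (fixed at
centre/neutral), decoupling location beliefs from sensation — the mechanism
that lets the prior, carried by the narrative level, replay the solved
trajectory.

## A worked example

```r
library(deepexplain)

res <- run_standard(query_type = "second", true_context = "right", seed = 1)
res$transcript
#> <transcript: 3 epochs | query second | context right>
#>   [solve]
#>     actions: go-cue, go-right
#>   [query]
#>     heard: please explain second move
#>     actions: go-cue, go-right, go-right
#>   [answer]
#>     heard: I knew reward-was right so-I exploited the-right-arm
#>     spoken: I knew reward-was right so-I exploited the-right-arm
#>     actions: go-cue, go-right, go-right, go-right, go-right, go-right

replay_score(res$record)
#> [1] 1
res$transcript$epochs[[1]]$context_posterior
#>            [,1]         [,2]  [,3]
#> left        0.5 1.167183e-16 4e-32
#> right       0.5 1.000000e+00 1e+00
```

Reading the output: during the maze epoch the agent first moves to the cue
(its context belief is 0.5/0.5, so the cue carries epistemic value), the cue
observation resolves the context to "right" (second column of the posterior),
and the agent then exploits the right arm. Queried about the *second* move,
it answers that it **knew** where the reward was and **exploited** the
**right arm** — the slots of the answer sentence. The replay score of 1 means
the maximum-a-posteriori location beliefs in the query and answer epochs
retrace centre → cue → right-arm even though the agent never moves again
(the actions listed there are inferred, not enacted).

The confabulation variant starts at the query epoch, so there is no maze
experience to constrain the story:

```r
cf <- run_confabulation(seed = 1)
paste(cf$transcript$epochs[[2]]$spoken, collapse = " ")
#> [1] "I did-not-know reward-was left so-I guessed the-left-arm"
cf$verdicts$answer1$consistent   # a guess that lands on the asserted reward
#> [1] FALSE                      # arm should have been "knew ... exploited"
paste(cf$transcript$epochs[[3]]$spoken, collapse = " ")
#> [1] "I did-not-know reward-was right so-I guessed the-left-arm"
cf$verdicts$answer2$consistent   # a coherent wrong guess
#> [1] TRUE
```

A command-line wrapper is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/deepexplain-run.R", package="deepexplain"))')" \
  --mode standard --query second --context right --seed 1 --out out/
```

writing `transcript.json`, `beliefs_level1.csv`, `beliefs_level2.csv` and a
run log.

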