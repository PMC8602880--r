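{
  "description": "Canonical configuration of the T-maze explanation task: factor levels, outcome modalities, vocabulary, sentence frames, the ten allowable two-move policies, the semantic rules linking a queried move and the reward location to the spoken explanation, and the default tunable parameters. The full probability tensors are rebuilt from this description by build_model(); model_to_json() exports them verbatim.",
  "config": {
    "true_context": "right",
    "query_type": "second",
    "epochs": ["solve", "query", "answer"],
    "pref_attractive": 3,
    "pref_neutral": 0,
    "pref_aversive": -6,
    "pref_centre": -1,
    "kappa": 2,
    "link_smoothing": 0.01,
    "horizons": [3, 4, 7],
    "seed": 1
  },
  "level1_factors": {
    "location": ["centre", "left", "right", "cue"],
    "context": ["left", "right"],
    "query": ["first", "second"],
    "knowledge": ["knew", "did-not-know"],
    "verb": ["explored", "guessed", "exploited", "waited"],
    "destination": ["cue", "left-arm", "right-arm", "centre"],
    "syntax": ["silent", "q1", "q2", "q3", "q4", "a1", "a2", "a3", "a4", "a5", "a6", "a7"]
  },
  "level1_controllable": [true, false, false, false, false, false, false],
  "actions": {
    "location": ["go-centre", "go-left", "go-right", "go-cue"]
  },
  "outcome_modalities": {
    "extero": ["centre", "left", "right", "cue-left", "cue-right"],
    "reward": ["neutral", "attractive", "aversive"],
    "heard": ["silence", "please", "explain", "first", "second", "move", "I", "knew", "did-not-know", "reward-was", "left", "right", "so-I", "explored", "guessed", "exploited", "waited", "the-cue", "the-left-arm", "the-right-arm", "the-centre"],
    "spoken": ["silence", "please", "explain", "first", "second", "move", "I", "knew", "did-not-know", "reward-was", "left", "right", "so-I", "explored", "guessed", "exploited", "waited", "the-cue", "the-left-arm", "the-right-arm", "the-centre"]
  },
  "preferences": {
    "extero": [-1, 0, 0, 0, 0],
    "reward": [0, 3, -6]
  },
  "vocabulary": ["silence", "please", "explain", "first", "second", "move", "I", "knew", "did-not-know", "reward-was", "left", "right", "so-I", "explored", "guessed", "exploited", "waited", "the-cue", "the-left-arm", "the-right-arm", "the-centre"],
  "query_frame": ["please", "explain", "<query>", "move"],
  "answer_frame": ["I", "<knowledge>", "reward-was", "<side>", "so-I", "<verb>", "<destination>"],
  "policies": [
    {
      "move1": "centre",
      "move2": "centre"
    },
    {
      "move1": "centre",
      "move2": "left"
    },
    {
      "move1": "centre",
      "move2": "right"
    },
    {
      "move1": "centre",
      "move2": "cue"
    },
    {
      "move1": "left",
      "move2": "left"
    },
    {
      "move1": "right",
      "move2": "right"
    },
    {
      "move1": "cue",
      "move2": "centre"
    },
    {
      "move1": "cue",
      "move2": "left"
    },
    {
      "move1": "cue",
      "move2": "right"
    },
    {
      "move1": "cue",
      "move2": "cue"
    }
  ],
  "semantic_link": [
    {
      "move": "centre",
      "reward": "left",
      "knowledge": "did-not-know",
      "verb": "waited",
      "destination": "centre"
    },
    {
      "move": "left",
      "reward": "left",
      "knowledge": "knew",
      "verb": "exploited",
      "destination": "left-arm"
    },
    {
      "move": "right",
      "reward": "left",
      "knowledge": "did-not-know",
      "verb": "guessed",
      "destination": "right-arm"
    },
    {
      "move": "cue",
      "reward": "left",
      "knowledge": "did-not-know",
      "verb": "explored",
      "destination": "cue"
    },
    {
      "move": "centre",
      "reward": "right",
      "knowledge": "did-not-know",
      "verb": "waited",
      "destination": "centre"
    },
    {
      "move": "left",
      "reward": "right",
      "knowledge": "did-not-know",
      "verb": "guessed",
      "destination": "left-arm"
    },
    {
      "move": "right",
      "reward": "right",
      "knowledge": "knew",
      "verb": "exploited",
      "destination": "right-arm"
    },
    {
      "move": "cue",
      "reward": "right",
      "knowledge": "did-not-know",
      "verb": "explored",
      "destination": "cue"
    }
  ],
  "level2_factors": {
    "narrative": ["solve", "query", "answer"],
    "move1": ["centre", "left", "right", "cue"],
    "move2": ["centre", "left", "right", "cue"],
    "reward_loc": ["left", "right"],
    "query_type": ["first", "second"]
  }
}
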