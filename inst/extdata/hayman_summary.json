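{
  "source": "Hayman & Tulving (1989), Experiment 2: between-subjects word-fragment-completion study, published summary statistics",
  "design": {
    "students_total": 84,
    "targets_total": 48,
    "words_per_list": 24,
    "groups": [
      {"group": 1, "instruction": "completion", "cues": "same", "n_subjects": 22},
      {"group": 2, "instruction": "completion", "cues": "different", "n_subjects": 22},
      {"group": 3, "instruction": "recall", "cues": "same", "n_subjects": 20},
      {"group": 4, "instruction": "recall", "cues": "different", "n_subjects": 20}
    ]
  },
  "conditions": [
    {
      "condition": "completion",
      "dpe_printed": 0.104,
      "z_printed": 5.23,
      "ci_printed": [0.066, 0.143],
      "subjects": 44
    },
    {
      "condition": "recall",
      "dpe_printed": 0.121,
      "z_printed": 6.36,
      "ci_printed": [0.084, 0.157],
      "subjects": 40
    }
  ],
  "second_test_conditional_dpe": [
    {"instruction": "completion", "cues": "same", "dpe_printed": 0.06},
    {"instruction": "recall", "cues": "same", "dpe_printed": 0.048},
    {"instruction": "completion", "cues": "different", "dpe_printed": 0.122},
    {"instruction": "recall", "cues": "different", "dpe_printed": 0.137}
  ]
}
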