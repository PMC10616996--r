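{
  "metadata": {
    "instrument": "Patient Evaluation Measure (10-item), synthetic stand-in",
    "version": "synthetic-1",
    "note": "Synthetic parameters emulating the calibrated instrument's informativeness profile; not the published calibration.",
    "transform": {
      "slope": 12.5,
      "offset": 50
    }
  },
  "items": [
    {
      "id": "Q1",
      "label": "Feeling in the hand is now",
      "n_categories": 7,
      "discrimination": 2.3,
      "thresholds": [-2.625, -1.875, -1.125, -0.375, 0.375, 1.125]
    },
    {
      "id": "Q2",
      "label": "Pain when the hand is cold/damp",
      "n_categories": 7,
      "discrimination": 1.8,
      "thresholds": [-2, -1.2, -0.4, 0.4, 1.2, 2]
    },
    {
      "id": "Q3",
      "label": "Pain in the hand most of the time",
      "n_categories": 7,
      "discrimination": 2,
      "thresholds": [-2.15, -1.37, -0.59, 0.19, 0.97, 1.75]
    },
    {
      "id": "Q4",
      "label": "Ability to use the hand for fiddly things",
      "n_categories": 7,
      "discrimination": 2.9,
      "thresholds": [-2.1, -1.4, -0.7, 0, 0.7, 1.4]
    },
    {
      "id": "Q5",
      "label": "General movement of the hand",
      "n_categories": 7,
      "discrimination": 2.1,
      "thresholds": [-2.25, -1.51, -0.77, -0.03, 0.71, 1.45]
    },
    {
      "id": "Q6",
      "label": "Hand grip",
      "n_categories": 7,
      "discrimination": 2.6,
      "thresholds": [-2.4, -1.68, -0.96, -0.24, 0.48, 1.2]
    },
    {
      "id": "Q7",
      "label": "Hand usage for everyday activities",
      "n_categories": 7,
      "discrimination": 5.2,
      "thresholds": [-2, -1.4, -0.8, -0.2, 0.4, 1]
    },
    {
      "id": "Q8",
      "label": "Hand usage for work",
      "n_categories": 7,
      "discrimination": 4.9,
      "thresholds": [-2, -1.38, -0.76, -0.14, 0.48, 1.1]
    },
    {
      "id": "Q9",
      "label": "Feeling when looking at hand appearance",
      "n_categories": 7,
      "discrimination": 1.2,
      "thresholds": [-2.225, -1.375, -0.525, 0.325, 1.175, 2.025]
    },
    {
      "id": "Q10",
      "label": "Feeling when thinking about the hand",
      "n_categories": 7,
      "discrimination": 1.1,
      "thresholds": [-2.1, -1.22, -0.34, 0.54, 1.42, 2.3]
    }
  ]
}
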