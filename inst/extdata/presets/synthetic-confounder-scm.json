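{
  "edges": [
    {
      "parent": "U",
      "child": "X"
    },
    {
      "parent": "U",
      "child": "Y"
    },
    {
      "parent": "X",
      "child": "Y"
    }
  ],
  "latent": [],
  "nodes": [
    "U",
    "X",
    "Y"
  ],
  "seed": {},
  "mechanisms": {
    "U": {
      "levels": [
        "0",
        "1"
      ],
      "parents": [],
      "probs": [
        {
          "0": 0.6,
          "1": 0.4
        }
      ]
    },
    "X": {
      "levels": [
        "0",
        "1"
      ],
      "parents": [
        "U"
      ],
      "probs": [
        {
          "0": 0.8,
          "1": 0.2
        },
        {
          "0": 0.4,
          "1": 0.6
        }
      ]
    },
    "Y": {
      "levels": [
        "0",
        "1"
      ],
      "parents": [
        "U",
        "X"
      ],
      "probs": [
        {
          "0": 0.8,
          "1": 0.2
        },
        {
          "0": 0.6,
          "1": 0.4
        },
        {
          "0": 0.5,
          "1": 0.5
        },
        {
          "0": 0.3,
          "1": 0.7
        }
      ]
    }
  }
}
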