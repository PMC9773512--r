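{
  "edges": [
    {
      "parent": "I",
      "child": "X"
    },
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
  "latent": [
    "U"
  ],
  "nodes": [
    "I",
    "U",
    "X",
    "Y"
  ],
  "seed": {},
  "mechanisms": {
    "I": {
      "levels": [
        "0",
        "1"
      ],
      "parents": [],
      "probs": [
        {
          "0": 0.5,
          "1": 0.5
        }
      ]
    },
    "U": {
      "levels": [
        "0",
        "1"
      ],
      "parents": [],
      "probs": [
        {
          "0": 0.5,
          "1": 0.5
        }
      ]
    },
    "X": {
      "levels": [
        "0",
        "1"
      ],
      "parents": [
        "I",
        "U"
      ],
      "probs": [
        {
          "0": 0.85,
          "1": 0.15
        },
        {
          "0": 0.35,
          "1": 0.65
        },
        {
          "0": 0.6,
          "1": 0.4
        },
        {
          "0": 0.1,
          "1": 0.9
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
          "0": 0.5,
          "1": 0.5
        },
        {
          "0": 0.4,
          "1": 0.6
        },
        {
          "0": 0.0999999999999999,
          "1": 0.9
        }
      ]
    }
  }
}
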