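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
      "child": "Z"
    },
    {
      "parent": "Z",
      "child": "Y"
    }
  ],
  "latent": [
    "U"
  ],
  "nodes": [
    "U",
    "X",
    "Z",
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
        "U"
      ],
      "probs": [
        {
          "0": 0.75,
          "1": 0.25
        },
        {
          "0": 0.35,
          "1": 0.65
        }
      ]
    },
    "Z": {
      "levels": [
        "0",
        "1"
      ],
      "parents": [
        "X"
      ],
      "probs": [
        {
          "0": 0.7,
          "1": 0.3
        },
        {
          "0": 0.25,
          "1": 0.75
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
        "Z"
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
          "0": 0.3,
          "1": 0.7
        },
        {
          "0": 0.1,
          "1": 0.9
        }
      ]
    }
  }
}
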