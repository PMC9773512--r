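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
          "0": 0.7,
          "1": 0.3
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
          "0": 0.85,
          "1": 0.15
        },
        {
          "0": 0.580769230769231,
          "1": 0.419230769230769
        }
      ]
    },
    "Z": {
      "levels": [
        "60",
        "70",
        "80",
        "90"
      ],
      "parents": [
        "X"
      ],
      "probs": [
        {
          "60": 0.08,
          "70": 0.27,
          "80": 0.49,
          "90": 0.16
        },
        {
          "60": 0.1,
          "70": 0.38,
          "80": 0.47,
          "90": 0.05
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
          "0": 0.75,
          "1": 0.25
        },
        {
          "0": 0.9,
          "1": 0.1
        },
        {
          "0": 0.5,
          "1": 0.5
        },
        {
          "0": 0.65,
          "1": 0.35
        },
        {
          "0": 0.28,
          "1": 0.72
        },
        {
          "0": 0.43,
          "1": 0.57
        },
        {
          "0": 0.12,
          "1": 0.88
        },
        {
          "0": 0.27,
          "1": 0.73
        }
      ]
    }
  }
}
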