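[
  {
    "name": "GPN",
    "kind": "linear-sum",
    "numerator": {
      "GP1": 1,
      "GP2": 1,
      "GP3": 1,
      "GP4": 1,
      "GP5": 1,
      "GP6": 1,
      "GP7": 1,
      "GP8": 1,
      "GP9": 1,
      "GP10": 1,
      "GP11": 1,
      "GP12": 1,
      "GP13": 1,
      "GP14": 1,
      "GP15": 1
    },
    "scale": 1
  },
  {
    "name": "S1_total",
    "kind": "linear-sum",
    "numerator": {
      "GP16": 1,
      "GP17": 1,
      "GP18": 1,
      "GP19": 1
    },
    "scale": 1
  },
  {
    "name": "S2_total",
    "kind": "linear-sum",
    "numerator": {
      "GP21": 1,
      "GP22": 1,
      "GP23": 1,
      "GP24": 1
    },
    "scale": 1
  },
  {
    "name": "S_total",
    "kind": "linear-sum",
    "numerator": {
      "GP16": 1,
      "GP17": 1,
      "GP18": 1,
      "GP19": 1,
      "GP21": 1,
      "GP22": 1,
      "GP23": 1,
      "GP24": 1
    },
    "scale": 1
  },
  {
    "name": "G0_total",
    "kind": "linear-sum",
    "numerator": {
      "GP1": 1,
      "GP2": 1,
      "GP3": 1,
      "GP4": 1,
      "GP6": 1
    },
    "scale": 1
  },
  {
    "name": "G1_total",
    "kind": "linear-sum",
    "numerator": {
      "GP7": 1,
      "GP8": 1,
      "GP9": 1,
      "GP10": 1,
      "GP11": 1
    },
    "scale": 1
  },
  {
    "name": "G2_total",
    "kind": "linear-sum",
    "numerator": {
      "GP12": 1,
      "GP13": 1,
      "GP14": 1,
      "GP15": 1
    },
    "scale": 1
  },
  {
    "name": "F_total",
    "kind": "linear-sum",
    "numerator": {
      "GP1": 1,
      "GP4": 1,
      "GP6": 1,
      "GP8": 1,
      "GP9": 1,
      "GP10": 1,
      "GP11": 1,
      "GP14": 1,
      "GP15": 1,
      "GP16": 1,
      "GP18": 1,
      "GP19": 1,
      "GP20": 1,
      "GP23": 1,
      "GP24": 1
    },
    "scale": 1
  },
  {
    "name": "F_neutral",
    "kind": "ratio",
    "numerator": {
      "GP1": 1,
      "GP4": 1,
      "GP6": 1,
      "GP8": 1,
      "GP9": 1,
      "GP10": 1,
      "GP11": 1,
      "GP14": 1,
      "GP15": 1
    },
    "scale": 100,
    "denominator": {
      "GP1": 1,
      "GP2": 1,
      "GP3": 1,
      "GP4": 1,
      "GP5": 1,
      "GP6": 1,
      "GP7": 1,
      "GP8": 1,
      "GP9": 1,
      "GP10": 1,
      "GP11": 1,
      "GP12": 1,
      "GP13": 1,
      "GP14": 1,
      "GP15": 1
    }
  },
  {
    "name": "F_sialo",
    "kind": "ratio",
    "numerator": {
      "GP16": 1,
      "GP18": 1,
      "GP19": 1,
      "GP20": 1,
      "GP23": 1,
      "GP24": 1
    },
    "scale": 100,
    "denominator": {
      "GP16": 1,
      "GP17": 1,
      "GP18": 1,
      "GP19": 1,
      "GP20": 1,
      "GP21": 1,
      "GP22": 1,
      "GP23": 1,
      "GP24": 1
    }
  },
  {
    "name": "B_total",
    "kind": "linear-sum",
    "numerator": {
      "GP3": 1,
      "GP6": 1,
      "GP10": 1,
      "GP11": 1,
      "GP13": 1,
      "GP15": 1,
      "GP19": 1,
      "GP22": 1,
      "GP24": 1
    },
    "scale": 1
  },
  {
    "name": "B_neutral",
    "kind": "ratio",
    "numerator": {
      "GP3": 1,
      "GP6": 1,
      "GP10": 1,
      "GP11": 1,
      "GP13": 1,
      "GP15": 1
    },
    "scale": 100,
    "denominator": {
      "GP1": 1,
      "GP2": 1,
      "GP3": 1,
      "GP4": 1,
      "GP5": 1,
      "GP6": 1,
      "GP7": 1,
      "GP8": 1,
      "GP9": 1,
      "GP10": 1,
      "GP11": 1,
      "GP12": 1,
      "GP13": 1,
      "GP14": 1,
      "GP15": 1
    }
  },
  {
    "name": "B_sialo",
    "kind": "ratio",
    "numerator": {
      "GP19": 1,
      "GP22": 1,
      "GP24": 1
    },
    "scale": 100,
    "denominator": {
      "GP16": 1,
      "GP17": 1,
      "GP18": 1,
      "GP19": 1,
      "GP20": 1,
      "GP21": 1,
      "GP22": 1,
      "GP23": 1,
      "GP24": 1
    }
  },
  {
    "name": "Gal_ratio",
    "kind": "ratio",
    "numerator": {
      "GP1": 1,
      "GP4": 1,
      "GP6": 1
    },
    "scale": 1,
    "denominator": {
      "GP8": 1,
      "GP9": 1,
      "GP10": 1,
      "GP11": 1,
      "GP16": 1,
      "GP14": 2,
      "GP15": 2,
      "GP18": 2,
      "GP19": 2,
      "GP20": 2,
      "GP23": 2,
      "GP24": 2
    }
  },
  {
    "name": "FG0",
    "kind": "ratio",
    "numerator": {
      "GP1": 1,
      "GP4": 1,
      "GP6": 1
    },
    "scale": 1,
    "denominator": {
      "GP1": 1,
      "GP4": 1,
      "GP6": 1,
      "GP8": 1,
      "GP9": 1,
      "GP10": 1,
      "GP11": 1,
      "GP14": 1,
      "GP15": 1,
      "GP16": 1,
      "GP18": 1,
      "GP19": 1,
      "GP20": 1,
      "GP23": 1,
      "GP24": 1
    }
  },
  {
    "name": "FG1",
    "kind": "ratio",
    "numerator": {
      "GP8": 1,
      "GP9": 1,
      "GP10": 1,
      "GP11": 1,
      "GP16": 1
    },
    "scale": 1,
    "denominator": {
      "GP1": 1,
      "GP4": 1,
      "GP6": 1,
      "GP8": 1,
      "GP9": 1,
      "GP10": 1,
      "GP11": 1,
      "GP14": 1,
      "GP15": 1,
      "GP16": 1,
      "GP18": 1,
      "GP19": 1,
      "GP20": 1,
      "GP23": 1,
      "GP24": 1
    }
  },
  {
    "name": "FG2",
    "kind": "ratio",
    "numerator": {
      "GP14": 1,
      "GP15": 1,
      "GP18": 1,
      "GP19": 1,
      "GP20": 1,
      "GP23": 1,
      "GP24": 1
    },
    "scale": 1,
    "denominator": {
      "GP1": 1,
      "GP4": 1,
      "GP6": 1,
      "GP8": 1,
      "GP9": 1,
      "GP10": 1,
      "GP11": 1,
      "GP14": 1,
      "GP15": 1,
      "GP16": 1,
      "GP18": 1,
      "GP19": 1,
      "GP20": 1,
      "GP23": 1,
      "GP24": 1
    }
  }
]
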