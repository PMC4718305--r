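{
  "name": "group_a",
  "events": [
    {
      "type": "bolus",
      "t": -10,
      "dose": 50
    }
  ],
  "pca": {
    "demand_dose": 10,
    "lockout": 10,
    "basal": []
  },
  "demand_policy": {
    "mode": "none"
  },
  "rescue": []
}
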