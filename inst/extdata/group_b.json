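{
  "name": "group_b",
  "events": [
    {
      "type": "infusion",
      "t_start": -10,
      "t_end": 0,
      "rate": 300
    }
  ],
  "pca": {
    "demand_dose": 10,
    "lockout": 15,
    "basal": [
      {
        "t_start": 0,
        "t_end": 60,
        "rate": 20
      },
      {
        "t_start": 60,
        "t_end": null,
        "rate": 10
      }
    ]
  },
  "demand_policy": {
    "mode": "none"
  },
  "rescue": []
}
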