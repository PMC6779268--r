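{
  "comment": "Empirical priors of the canonical Balloon-Windkessel hemodynamic parameters: rate of signal decay kappa (1/s), rate of flow-dependent elimination gamma (1/s), hemodynamic transit time tau (s), Grubb's vessel stiffness exponent alpha, resting oxygen extraction fraction E0, resting blood volume fraction V0. Edit to swap in corrected variants.",
  "mean": {
    "kappa": 0.65,
    "gamma": 0.41,
    "tau": 0.98,
    "alpha": 0.32,
    "e0": 0.34,
    "v0": 0.04
  },
  "var": {
    "kappa": 0.015,
    "gamma": 0.002,
    "tau": 0.0568,
    "alpha": 0.0015,
    "e0": 0.0024,
    "v0": 0.0
  }
}
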