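[
  {
    "symbol": "α",
    "name": "alpha"
  },
  {
    "symbol": "β",
    "name": "beta"
  },
  {
    "symbol": "γ",
    "name": "gamma"
  },
  {
    "symbol": "δ",
    "name": "delta"
  },
  {
    "symbol": "ε",
    "name": "epsilon"
  },
  {
    "symbol": "ζ",
    "name": "zeta"
  },
  {
    "symbol": "η",
    "name": "eta"
  },
  {
    "symbol": "θ",
    "name": "theta"
  },
  {
    "symbol": "ι",
    "name": "iota"
  },
  {
    "symbol": "κ",
    "name": "kappa"
  },
  {
    "symbol": "λ",
    "name": "lambda"
  },
  {
    "symbol": "μ",
    "name": "mu"
  },
  {
    "symbol": "ν",
    "name": "nu"
  },
  {
    "symbol": "ξ",
    "name": "xi"
  },
  {
    "symbol": "ο",
    "name": "omicron"
  },
  {
    "symbol": "π",
    "name": "pi"
  },
  {
    "symbol": "ρ",
    "name": "rho"
  },
  {
    "symbol": "σ",
    "name": "sigma"
  },
  {
    "symbol": "τ",
    "name": "tau"
  },
  {
    "symbol": "υ",
    "name": "upsilon"
  },
  {
    "symbol": "φ",
    "name": "phi"
  },
  {
    "symbol": "χ",
    "name": "chi"
  },
  {
    "symbol": "ψ",
    "name": "psi"
  },
  {
    "symbol": "ω",
    "name": "omega"
  }
]
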