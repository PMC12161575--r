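[
  {
    "name": "desABCD",
    "domains": ["PF00282", "PF13434", "PF13523", "PF04183"],
    "max_intergenic_bp": 5000
  },
  {
    "name": "desGH",
    "domains": ["PF01804", "PF13523"],
    "max_intergenic_bp": 1000
  }
]
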