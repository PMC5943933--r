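{
  "planted_modules": [
    {
      "seed": "g011",
      "members": ["g011", "g010", "g009", "g004"],
      "partner_driver": "g010",
      "effect_size": 3
    }
  ],
  "planted_pairs": [
    {
      "source": "g011",
      "target": "g010"
    }
  ],
  "mutation_pairs": [
    {
      "gene1": "g012",
      "gene2": "g005",
      "mode": "co-occur",
      "strength": 1
    },
    {
      "gene1": "g007",
      "gene2": "g006",
      "mode": "exclusive",
      "strength": 1
    }
  ],
  "signaling_paths": [
    {
      "from": "g011",
      "to": "g010",
      "via": "g005"
    }
  ]
}
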