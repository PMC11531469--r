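{
  "system": {
    "toy": {
      "ring_chains": 6,
      "ring_chain_length": 60,
      "tail_length": 80,
      "binder_count": 0,
      "sigma": 0.7
    },
    "fork": {
      "parental_bp": 23,
      "leading_bp": 90,
      "lagging_bp": 96,
      "leading_gap_nt": 33,
      "lagging_gap_nt": 56
    }
  },
  "dynamics": {
    "timestep": 0.3,
    "temperature": 300,
    "friction": 0.843,
    "replica_temperatures": [300, 310, 320, 330, 340, 350, 360, 370, 380, 390],
    "confinement_radius": 100
  },
  "analysis": {
    "contact_cutoff": 10,
    "grid_spacing": 5,
    "iso_level": 1e-4
  },
  "output": {
    "save_interval": 100
  },
  "seeds": {
    "build": 1,
    "run": 1
  }
}
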