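# Bondi van der Waals radii (Angstrom) used for accessible-surface
# integration, and the scale factor of the distance-based covalent bond
# proxy (keys are quoted so YAML keeps N/O as strings): atoms i, j are bonded iff d_ij <= bond_scale * (r_i + r_j).
radii:
  "C": 1.70
  "N": 1.55
  "O": 1.52
  "H": 1.20
  "S": 1.80
bond_scale: 0.6
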